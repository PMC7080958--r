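#!/usr/bin/env Rscript
# Generate the study cohort: a seeded synthetic segmented-CNA cohort on the
# toy genome with the default planted structure (arm events with exclusive
# per-arm gain/loss propensities, focal events, ~6% chromothripsis-like
# samples, a 14% HPV-like subgroup with 3q gain and no 3p loss) plus a
# 10-fold breakpoint hotspot bin. Writes the SEG file, ground truth and
# clinical table that the later stages consume.

suppressPackageStartupMessages(library(cnascape))

seed <- 20260922
out <- "results"
dir.create(out, showWarnings = FALSE)

cfg <- sim_config(n_samples = 200,
                  hotspot = list(chrom = "1", start = 30e6, end = 31e6,
                                 multiplier = 10))
sim <- simulate_cohort(cfg, seed = seed)

write_seg(sim$cohort, file.path(out, "cohort.seg"))
write_table(sim$truth$events, file.path(out, "truth_events.tsv"))
write_table(sim$truth$samples, file.path(out, "truth_samples.tsv"))
write_table(sim$clinical, file.path(out, "clinical.tsv"))
jsonlite::write_json(list(seed = seed, n_samples = cfg$n_samples,
                          n_segments = nrow(sim$cohort$segments),
                          hotspot = cfg$hotspot),
                     file.path(out, "simulation.json"),
                     auto_unbox = TRUE, digits = NA)

message(sprintf("cohort: %d samples, %d segments; %d planted events (%d ctlp); hotspot bin %s:%g-%g x%g",
                length(sim$cohort$samples), nrow(sim$cohort$segments),
                nrow(sim$truth$events),
                sum(sim$truth$events$kind == "ctlp"),
                cfg$hotspot$chrom, cfg$hotspot$start, cfg$hotspot$end,
                cfg$hotspot$multiplier))
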