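#!/usr/bin/env Rscript
# Scan every sample chromosome for chromothripsis-like patterns (>= 20
# copy-number status switches with adjacent jumps >= 0.4 after the 10-kb
# size filter, clustering log10 likelihood ratio >= 10) and summarize
# incidence, per-chromosome pulverization shares and multi-chromosome
# cases; check calls against the planted ground truth.

suppressPackageStartupMessages(library(cnascape))

out <- "results"
build <- toy_build()
cohort <- read_seg(file.path(out, "cohort.seg"), build)

ctlp <- scan_ctlp(cohort, build, switch_thr = 20, lr_thr = 10,
                  min_seg = 1e4, diff_thr = 0.4)
write_table(ctlp, file.path(out, "ctlp_regions.tsv"))
s <- summarize_ctlp(ctlp, length(cohort$samples))
write_table(s$per_chromosome, file.path(out, "ctlp_per_chromosome.tsv"))

truth <- read_table(file.path(out, "truth_events.tsv"))
planted <- truth[truth$kind == "ctlp", ]
hit_key <- paste(ctlp$sample_id[ctlp$is_ctlp], ctlp$chrom[ctlp$is_ctlp])
planted_key <- paste(planted$sample_id, planted$chrom)

message(sprintf("chromothripsis-like: %d/%d samples (incidence %.1f%%); planted %d, recovered %d, false flags %d",
                s$n_positive, length(cohort$samples), 100 * s$incidence,
                nrow(planted), sum(planted_key %in% hit_key),
                sum(!hit_key %in% planted_key)))
if (nrow(s$per_chromosome))
  message("most affected chromosome: ",
          s$per_chromosome$chrom[1],
          sprintf(" (%d of %d positives, %.0f%%)", s$per_chromosome$n[1],
                  s$n_positive, 100 * s$per_chromosome$fraction[1]))
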