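#!/usr/bin/env Rscript
# Extract CNA breakpoints (adjacent-segment log2 change > 0.4 after
# removing sub-10-kb segments; telomere/centromere boundaries ignored),
# count them on the 1-Mb grid, build a 10,000-permutation null by
# relocating every breakpoint uniformly on its chromosome, and report bins
# enriched at Bonferroni-corrected p < 0.01 with overlap against the
# bundled synthetic CFS/NFR region sets.

suppressPackageStartupMessages(library(cnascape))

out <- "results"
seed <- 20260922
build <- toy_build()
cohort <- read_seg(file.path(out, "cohort.seg"), build)
bins <- make_bins(build, 1e6)

bp <- extract_breakpoints(cohort, build, delta_thr = 0.4, min_seg = 1e4)
write_table(bp, file.path(out, "breakpoints.tsv"))
message(sprintf("breakpoints: %d total, %.1f per sample",
                nrow(bp), nrow(bp) / length(cohort$samples)))

observed <- count_per_bin(bp, bins)
null <- permute_breakpoints(bp, build, bins, n_perm = 1e4, seed = seed)
hot <- hotspot_test(observed, null, alpha = 0.01)

cfs <- read_bed(system.file("extdata", "cfs_synthetic.bed", package = "cnascape"),
                "CFS", build)
nfr <- read_bed(system.file("extdata", "nfr_synthetic.bed", package = "cnascape"),
                "NFR", build)
ov_cfs <- region_overlap(hot, cfs)
ov_nfr <- region_overlap(hot, nfr)
hot$overlaps_cfs <- FALSE; hot$overlaps_cfs[hot$is_hotspot] <- ov_cfs$overlaps
hot$overlaps_nfr <- FALSE; hot$overlaps_nfr[hot$is_hotspot] <- ov_nfr$overlaps
write_table(hot, file.path(out, "hotspots.tsv"))

message(sprintf("hotspot bins: %d (of %d); CFS overlap %s, NFR overlap %s",
                sum(hot$is_hotspot), nrow(bins),
                ifelse(is.na(ov_cfs$fraction), "NA",
                       sprintf("%d (%.0f%%)", ov_cfs$n_overlap, 100 * ov_cfs$fraction)),
                ifelse(is.na(ov_nfr$fraction), "NA",
                       sprintf("%d (%.0f%%)", ov_nfr$n_overlap, 100 * ov_nfr$fraction))))
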