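#!/usr/bin/env Rscript
# Ward clustering (Euclidean distance, ward.D2) of the state-encoded
# bins x samples matrix into two major clusters; per-cluster burden and
# arm-event profiles; HPV and site enrichment of each cluster against the
# simulated clinical table; agreement with the planted subgroup labels.

suppressPackageStartupMessages(library(cnascape))

out <- "results"
build <- toy_build()
cohort <- read_seg(file.path(out, "cohort.seg"), build)
bins <- make_bins(build, 1e6)
calls <- call_states(cohort)

mat <- build_cna_matrix(calls, bins, mode = "state")
cl <- ward_cluster(mat, k = 2)
write_table(cl$assignment, file.path(out, "clusters.tsv"))

arm_events <- call_arm_events(calls, build)
cs <- cluster_summary(cl, calls, arm_events)
write_table(cs$per_cluster, file.path(out, "cluster_summary.tsv"))
write_table(cs$top_arm_events, file.path(out, "cluster_arm_events.tsv"))

clinical <- read_clinical(file.path(out, "clinical.tsv"))
en_hpv <- label_enrichment(cl, clinical, "hpv")
en_site <- label_enrichment(cl, clinical, "site", positive = "nasopharynx")
write_table(en_hpv, file.path(out, "hpv_enrichment.tsv"))
write_table(en_site, file.path(out, "site_enrichment.tsv"))

# genome x samples heatmap with cluster annotation, samples in tree order
ann <- data.frame(cluster = factor(cl$assignment$cluster),
                  row.names = cl$assignment$sample_id)
pheatmap::pheatmap(mat[rowSums(mat != 0) > 0, cl$tree$order],
                   cluster_rows = FALSE, cluster_cols = FALSE,
                   show_rownames = FALSE, show_colnames = FALSE,
                   annotation_col = ann,
                   color = colorRampPalette(c("steelblue", "white", "firebrick"))(3),
                   filename = file.path(out, "cna_heatmap.png"),
                   width = 10, height = 6)

truth <- read_table(file.path(out, "truth_samples.tsv"))
sub <- truth$subgroup[match(cl$assignment$sample_id, truth$sample_id)]
tab <- table(cluster = cl$assignment$cluster, subgroup = sub)
print(tab)
message(sprintf("cluster burden: %s",
                paste(sprintf("cluster %d = %.1f%%", cs$per_cluster$cluster,
                              100 * cs$per_cluster$mean_frac_altered),
                      collapse = ", ")))
message(sprintf("HPV enrichment: min p = %.3g in cluster %d",
                min(en_hpv$p_fisher),
                en_hpv$cluster[which.min(en_hpv$p_fisher)]))
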