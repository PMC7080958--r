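two_block_calls <- function(n_a = 4, n_b = 4, build = toy_build()) {
  # group A: 1q gain; group B: 3p loss
  q1 <- build$arms[build$arms$chrom == "1" & build$arms$arm == "q", ]
  p3 <- build$arms[build$arms$chrom == "3" & build$arms$arm == "p", ]
  rows <- list()
  for (i in seq_len(n_a))
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample_id = sprintf("A%02d", i), chrom = "1",
      start = q1$start, end = q1$end, log2 = 0.5)
  for (i in seq_len(n_b))
    rows[[length(rows) + 1]] <- tibble::tibble(
      sample_id = sprintf("B%02d", i), chrom = "3",
      start = p3$start, end = p3$end, log2 = -0.5)
  call_states(as_cna_cohort(dplyr::bind_rows(rows), build))
}

test_that("matrix build matches hand computation in both modes", {
  b <- bare_build(len = 4e6)
  bins <- make_bins(b, 1e6)
  seg <- tibble::tibble(
    sample_id = rep(c("A", "B"), each = 2),
    chrom = "1",
    start = c(0, 2e6, 0, 2e6),
    end = c(2e6, 4e6, 2e6, 4e6),
    log2 = c(0.5, 0, -0.4, 0.1))
  calls <- call_states(as_cna_cohort(seg, b))
  m <- build_cna_matrix(calls, bins, mode = "state")
  expect_equal(dim(m), c(4L, 2L))
  expect_equal(unname(m[, "A"]), c(1, 1, 0, 0))
  expect_equal(unname(m[, "B"]), c(-1, -1, 0, 0))
  ml <- build_cna_matrix(calls, bins, mode = "log2")
  expect_equal(unname(ml[, "A"]), c(0.5, 0.5, 0, 0))
  expect_equal(unname(ml[, "B"]), c(-0.4, -0.4, 0.1, 0.1))
  # all-neutral cohort -> zero matrix
  seg0 <- seg; seg0$log2 <- 0.05
  m0 <- build_cna_matrix(call_states(as_cna_cohort(seg0, b)), bins)
  expect_true(all(m0 == 0))
})

test_that("state and log2 modes agree in sign beyond the call threshold", {
  sim <- simulate_cohort(sim_config(n_samples = 25), seed = 71)
  bins <- make_bins(sim$cohort$build)
  calls <- call_states(sim$cohort)
  ms <- build_cna_matrix(calls, bins, "state")
  ml <- build_cna_matrix(calls, bins, "log2")
  # a called bin state should almost always share the sign of the weighted
  # mean log2; disagreements can only come from bins mixing opposite events
  called <- ms != 0
  expect_gt(sum(called), 100)
  agree <- sign(ml[called]) == ms[called]
  expect_gte(mean(agree), 0.99)
})

test_that("Ward clustering separates identical-profile groups perfectly", {
  calls <- two_block_calls()
  bins <- make_bins(toy_build())
  cl <- ward_cluster(build_cna_matrix(calls, bins), k = 2)
  truth <- substr(cl$assignment$sample_id, 1, 1)
  expect_equal(ari(cl$assignment$cluster, truth), 1)
  # k = 1 puts everything together; k > n errors
  expect_equal(unique(ward_cluster(build_cna_matrix(calls, bins), 1)$assignment$cluster), 1L)
  expect_error(ward_cluster(build_cna_matrix(calls, bins), 9), "exceeds")
})

test_that("clustering is invariant to column permutation up to labels", {
  sim <- simulate_cohort(sim_two_group_config(n_samples = 40), seed = 72)
  bins <- make_bins(sim$cohort$build)
  mat <- build_cna_matrix(call_states(sim$cohort), bins)
  set.seed(73)
  perm <- sample(ncol(mat))
  cl1 <- ward_cluster(mat, 2)
  cl2 <- ward_cluster(mat[, perm], 2)
  j <- match(cl1$assignment$sample_id, cl2$assignment$sample_id)
  expect_equal(ari(cl1$assignment$cluster, cl2$assignment$cluster[j]), 1)
  # Ward merge heights are monotone non-decreasing
  expect_true(all(diff(cl1$tree$height) >= -1e-9))
})

test_that("cluster summary ranks the planted high-burden group first", {
  sim <- simulate_cohort(sim_two_group_config(n_samples = 60), seed = 74)
  calls <- call_states(sim$cohort)
  bins <- make_bins(sim$cohort$build)
  cl <- ward_cluster(build_cna_matrix(calls, bins), 2)
  ae <- call_arm_events(calls)
  cs <- cluster_summary(cl, calls, ae)
  expect_equal(nrow(cs$per_cluster), 2L)
  # the arm-heavy background must show higher burden than the 3q-only group
  expect_gt(max(cs$per_cluster$mean_frac_altered),
            1.5 * min(cs$per_cluster$mean_frac_altered))
  # single cluster reproduces the cohort-wide mean
  cl1 <- ward_cluster(build_cna_matrix(calls, bins), 1)
  cs1 <- cluster_summary(cl1, calls, ae)
  expect_equal(cs1$per_cluster$mean_frac_altered,
               mean(burden_summary(calls)$per_sample$frac_altered))
})

test_that("label enrichment matches the exact hypergeometric computation", {
  # cluster of 10 with 9 positives vs 90 others with 9 positives
  asg <- tibble::tibble(sample_id = sprintf("S%03d", 1:100),
                        cluster = rep(c(1L, 2L), c(10, 90)))
  clin <- tibble::tibble(sample_id = asg$sample_id,
                         hpv = c(rep("yes", 9), "no",
                                 rep("yes", 9), rep("no", 81)))
  cl <- list(assignment = asg, k = 2)
  en <- label_enrichment(cl, clin, "hpv")
  expect_equal(en$n_positive[en$cluster == 1], 9L)
  expect_lt(en$p_fisher[en$cluster == 1], 0.001)
  expect_equal(en$p_fisher[en$cluster == 1],
               oracle_fisher_p(9, 1, 9, 81), tolerance = 1e-7)
  # balanced label -> p ~ 1
  clin2 <- clin
  clin2$hpv <- rep(c("yes", "no"), 50)
  en2 <- label_enrichment(cl, clin2, "hpv")
  expect_gt(min(en2$p_fisher), 0.5)
  # unknowns excluded; all-unknown errors
  clin3 <- clin; clin3$hpv <- "unknown"
  expect_error(label_enrichment(cl, clin3, "hpv"), "unknown")
})
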