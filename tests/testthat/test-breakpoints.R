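bp_cohort <- function(seg, build = toy_build()) mini_cohort(seg, build)

test_that("breakpoint extraction follows the fixed filter order", {
  b <- bare_build(len = 10e6)
  none <- b$centromeres[0, c("chrom", "start", "end")]
  # adjacent jump of 0.5 -> one breakpoint at the shared boundary
  seg <- tibble::tibble(start = c(0, 5e6), end = c(5e6, 10e6), log2 = c(0, 0.5))
  bp <- extract_breakpoints(bp_cohort(seg, b), b, exclude = none)
  expect_equal(nrow(bp), 1L)
  expect_equal(bp$position, 5e6)
  expect_equal(bp$delta, 0.5)

  # jump of 0.3 is below the strict threshold
  seg$log2 <- c(0, 0.3)
  expect_equal(nrow(extract_breakpoints(bp_cohort(seg, b), b, exclude = none)), 0L)

  # a 5-kb middle segment is removed BEFORE adjacency: A(0.0) B(0.6) C(0.0)
  seg3 <- tibble::tibble(start = c(0, 5e6, 5.005e6),
                         end = c(5e6, 5.005e6, 10e6),
                         log2 = c(0, 0.6, 0))
  expect_equal(nrow(extract_breakpoints(bp_cohort(seg3, b), b, exclude = none)), 0L)

  # non-abutting segments break at the gap midpoint
  segg <- tibble::tibble(start = c(0, 6e6), end = c(5e6, 10e6), log2 = c(0, 0.5))
  bpg <- extract_breakpoints(bp_cohort(segg, b), b, exclude = none)
  expect_equal(bpg$position, 5.5e6)
})

test_that("breakpoints in telomeres and centromeres are ignored", {
  b <- toy_build()  # chr1 centromere 57.5-62.5 Mb, telomere 10 kb
  seg <- tibble::tibble(
    start = c(0, 6e3, 30e6, 60e6, 110e6),
    end = c(6e3, 30e6, 60e6, 110e6, 120e6),
    log2 = c(0.6, 0, 0.8, 0, 0.9))
  # boundaries: 6e3 (telomere), 30e6 (kept), 60e6 (centromere), 110e6 (kept)
  # but the 0-6e3 segment is below min_seg, so the telomere boundary vanishes
  bp <- extract_breakpoints(bp_cohort(seg, b), b)
  expect_equal(bp$position, c(30e6, 110e6))
})

test_that("extraction agrees with the brute-force oracle on random toys", {
  set.seed(402)
  b <- bare_build(len = 10e6)
  zones <- tibble::tibble(chrom = "1", start = c(0, 4.8e6, 10e6 - 1e4),
                          end = c(1e4, 5.2e6, 10e6))
  for (rep in 1:250) {
    seg <- random_segments(n_max = 6, chrom_len = 10e6)
    got <- extract_breakpoints(bp_cohort(seg, b), b, exclude = zones)
    want <- oracle_breakpoints(seg, zones = zones)
    expect_equal(got$position, want$position)
    expect_equal(got$delta, want$delta, tolerance = 1e-12)
  }
})

test_that("raising thresholds or adding zones never adds breakpoints", {
  sim <- simulate_cohort(sim_null_config(30), seed = 52)
  n_at <- function(dt, excl) nrow(extract_breakpoints(sim$cohort,
                                                      delta_thr = dt,
                                                      exclude = excl))
  none <- exclusion_zones(sim$cohort$build)[0, ]
  zones <- exclusion_zones(sim$cohort$build)
  counts <- vapply(c(0.3, 0.4, 0.5, 0.7), n_at, numeric(1), excl = none)
  expect_true(all(diff(counts) <= 0))
  expect_lte(n_at(0.4, zones), n_at(0.4, none))
})

test_that("bin counts conserve breakpoints", {
  b <- toy_build()
  bins <- make_bins(b)
  bp <- tibble::tibble(sample_id = "S1", chrom = "1",
                       position = c(0.1e6, 0.2e6, 1.5e6), delta = 0.5)
  counts <- count_per_bin(bp, bins)
  expect_equal(counts$count[1:3], c(2L, 1L, 0L))
  expect_equal(sum(counts$count), 3L)
  empty <- count_per_bin(bp[0, ], bins)
  expect_true(all(empty$count == 0L))
  set.seed(403)
  many <- tibble::tibble(sample_id = "S1",
                         chrom = sample(b$chromosomes$chrom, 10000, TRUE,
                                        prob = b$chromosomes$length),
                         position = NA_real_, delta = 0.5)
  lens <- b$chromosomes$length[match(many$chrom, b$chromosomes$chrom)]
  many$position <- floor(runif(10000) * lens)
  expect_equal(sum(count_per_bin(many, bins)$count), 10000L)
})

test_that("permutation null is uniform and conserves totals", {
  b <- bare_build(len = 2e6)
  bins <- make_bins(b, 1e6)
  bp <- tibble::tibble(sample_id = "S1", chrom = "1", position = 1.7e6,
                       delta = 0.5)
  null <- permute_breakpoints(bp, b, bins, n_perm = 4000, seed = 9,
                              exclude = b$centromeres[0, ], keep_matrix = TRUE)
  # 1 breakpoint, 2 equal bins: each bin's null mean -> 0.5
  expect_equal(null$null_mean, c(0.5, 0.5), tolerance = 0.05)
  # conservation in every permutation
  expect_true(all(colSums(null$counts) == 1L))

  # chromosome-level expectation ~ N_chrom / n_bins_chrom
  sim <- simulate_cohort(sim_null_config(40), seed = 53)
  bp2 <- extract_breakpoints(sim$cohort)
  bins2 <- make_bins(sim$cohort$build)
  null2 <- permute_breakpoints(bp2, sim$cohort$build, bins2, n_perm = 1000,
                               seed = 10)
  for (cc in c("1", "2", "3")) {
    sel <- bins2$chrom == cc
    n_c <- sum(bp2$chrom == cc)
    expected <- n_c / sum(sel)
    mc_sd <- sd(null2$null_mean[sel]) / sqrt(sum(sel))
    expect_lt(abs(mean(null2$null_mean[sel]) - expected), 3 * mc_sd + 0.02)
  }
})

test_that("hotspot p-values match the brute-force Poisson tail", {
  bins <- make_bins(toy_build())
  n_bins <- nrow(bins)
  obs <- bins; obs$count <- rep(5L, n_bins)
  null <- list(null_mean = rep(5, n_bins), null_sd = rep(2, n_bins),
               n_perm = 1000)
  ht <- hotspot_test(obs, null)
  expect_true(all(ht$p_raw > 0.4))
  expect_false(any(ht$is_hotspot))

  # observed 60 against null mean 5 over ~2800 bins: brute-force tail
  obs$count[7] <- 60L
  ht2 <- hotspot_test(obs, null)
  want <- oracle_poisson_upper(60, 5)
  expect_equal(ht2$p_raw[7], want, tolerance = 1e-10)
  expect_equal(ht2$p_bonferroni[7], min(1, want * n_bins))
  expect_lt(want * 2800, 0.01)
  expect_true(ht2$is_hotspot[7])

  # zero null mean with observed > 0 floors the rate at 1/n_perm
  null0 <- list(null_mean = rep(0, n_bins), null_sd = rep(0, n_bins),
                n_perm = 1000)
  obs0 <- bins; obs0$count <- c(3L, rep(0L, n_bins - 1))
  ht0 <- hotspot_test(obs0, null0)
  expect_equal(ht0$p_raw[1], oracle_poisson_upper(3, 1e-3), tolerance = 1e-9)
  expect_equal(ht0$p_raw[2], 1)
})

test_that("region overlap counts hotspot bins with >= 1 bp intersection", {
  bins <- make_bins(toy_build())
  hs <- bins[1:10, ]
  hs$is_hotspot <- TRUE
  # whole-genome set -> fraction 1; disjoint set -> fraction 0
  whole <- tibble::tibble(chrom = c("1", "2", "3"), start = 0,
                          end = c(120e6, 100e6, 80e6))
  expect_equal(region_overlap(hs, whole)$fraction, 1)
  far <- tibble::tibble(chrom = "3", start = 50e6, end = 60e6)
  expect_equal(region_overlap(hs, far)$fraction, 0)
  # zero hotspots -> missing fraction
  hs$is_hotspot <- FALSE
  expect_true(is.na(region_overlap(hs, whole)$fraction))
})
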