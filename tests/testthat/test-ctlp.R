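osc_segments <- function(n_seg, low = 0.3, high = -0.3, size = 1e6,
                         start = 0) {
  s <- start + (seq_len(n_seg) - 1) * size
  tibble::tibble(start = s, end = s + size,
                 log2 = rep_len(c(low, high), n_seg))
}

test_that("status switches need both a state change and a >= 0.4 jump", {
  # 21 alternating segments at +0.3 / -0.3 -> 20 switches
  seg <- osc_segments(21, 0.3, -0.3)
  expect_equal(count_status_switches(seg), 20L)
  # uniform profile -> 0
  expect_equal(count_status_switches(osc_segments(21, 0.1, 0.1)), 0L)
  # state changes (gain vs neutral) but jump 0.2 < 0.4 -> 0
  expect_equal(count_status_switches(osc_segments(21, 0.3, 0.1)), 0L)
  # jump >= 0.4 but same state (0.9 vs 0.45, both gain) -> 0
  expect_equal(count_status_switches(osc_segments(21, 0.9, 0.45)), 0L)
  # sub-10-kb segments are dropped first
  tiny <- osc_segments(21, 0.3, -0.3, size = 5e3)
  expect_equal(count_status_switches(tiny), 0L)
  # fewer than 2 retained segments -> 0
  expect_equal(count_status_switches(osc_segments(1, 0.3)), 0L)
})

test_that("switch counting matches the pairwise oracle on random profiles", {
  set.seed(404)
  for (rep in 1:200) {
    seg <- random_segments(n_max = 6, chrom_len = 10e6)
    expect_equal(count_status_switches(seg), oracle_switches(seg))
  }
})

test_that("clustering LR equals the explicit two-model Poisson difference", {
  expect_equal(clustering_lr(10, 1e6, 100, 10e6), 0)  # identical rates
  expect_equal(clustering_lr(0, 1e6, 100, 10e6), 0)
  set.seed(405)
  for (rep in 1:1000) {
    G <- runif(1, 50e6, 250e6)
    L <- runif(1, 1e6, G)
    N <- sample(1:200, 1)
    k <- sample(1:N, 1)
    got <- clustering_lr(k, L, N, G)
    if (k / L == N / G) next
    expect_lt(abs(got - oracle_log10_lr(k, L, N, G)), 1e-9)
  }
  # strictly increasing in k for enriched regions
  lr <- clustering_lr(10:60, 30e6, 60, 150e6)
  enriched <- (10:60) / 30e6 > 60 / 150e6
  expect_true(all(diff(lr[enriched]) > 0))
  expect_error(clustering_lr(5, -1, 10, 1e6), "positive")
  expect_error(clustering_lr(11, 1e6, 10, 1e8), "exceed")
})

test_that("scan flags a planted oscillation once and quiet profiles never", {
  b <- toy_build()
  G <- 120e6
  set.seed(406)
  # 40 switches within ~30 Mb, quiet elsewhere
  osc <- simulate_chromothripsis("1", G, n_oscillations = 40, amplitude = 0.6,
                                 size_range = c(6e5, 8e5), start = 40e6)
  quiet <- tibble::tibble(chrom = "1",
                          start = c(0, osc$end[nrow(osc)]),
                          end = c(40e6, G), log2 = 0)
  seg <- rbind(quiet[1, c("start", "end", "log2")],
               osc[, c("start", "end", "log2")],
               quiet[2, c("start", "end", "log2")])
  res <- scan_chromosome(seg, G)
  expect_equal(nrow(res), 1L)
  expect_true(res$is_ctlp)
  expect_equal(res$n_switches, 40L)
  # reported region covers the oscillation within one window step
  expect_lt(abs(res$start - 40e6), 5e6)
  expect_lt(abs(res$end - osc$end[nrow(osc)]), 5e6)

  # quiet chromosome -> empty
  expect_equal(nrow(scan_chromosome(quiet[, c("start", "end", "log2")], G)), 0L)

  # 19 switches never qualify however clustered (switch threshold binds)
  osc19 <- simulate_chromothripsis("1", G, 19, 0.6, c(3e5, 4e5), start = 50e6)
  seg19 <- rbind(tibble::tibble(start = 0, end = 50e6, log2 = 0)[, c("start", "end", "log2")],
                 osc19[, c("start", "end", "log2")],
                 tibble::tibble(start = osc19$end[nrow(osc19)], end = G, log2 = 0))
  expect_equal(nrow(scan_chromosome(seg19, G)), 0L)
})

test_that("chromosomes shorter than the window are scanned as one window", {
  set.seed(407)
  osc <- simulate_chromothripsis("s", 25e6, 24, 0.6, c(3e5, 5e5), start = 1e6)
  # the single whole-chromosome window has k = N, so the clustering LR is 0
  # and nothing can qualify; the scan must return cleanly, not error
  expect_no_error(res <- scan_chromosome(osc, 25e6, window = 30e6))
  expect_equal(nrow(res), 0L)
})

test_that("relaxing any single threshold never removes flagged regions", {
  sim <- simulate_cohort(sim_config(n_samples = 40, ctlp_fraction = 0.3),
                         seed = 61)
  n_flagged <- function(...) sum(scan_ctlp(sim$cohort, ...)$is_ctlp)
  base <- n_flagged()
  expect_gte(n_flagged(switch_thr = 10), base)
  expect_gte(n_flagged(lr_thr = 5), base)
  expect_gte(n_flagged(diff_thr = 0.2), base)
  expect_gte(n_flagged(min_seg = 5e3), base)
})

test_that("cohort summary reproduces published-count arithmetic", {
  # 92 positive samples out of 1,395; 17 on chromosome 8; 10 with a second
  # affected chromosome
  mk <- function(sid, chrom) tibble::tibble(
    sample_id = sid, chrom = chrom, start = 0, end = 40e6,
    n_switches = 25L, log10_lr = 12, is_ctlp = TRUE)
  first_chrom <- c(rep("8", 17), rep(c("6", "11", "3", "5", "2"), 15))
  rows <- lapply(1:92, function(i) mk(sprintf("T%03d", i), first_chrom[i]))
  rows <- c(rows, lapply(1:10, function(i) mk(sprintf("T%03d", i), "17")))
  res <- dplyr::bind_rows(rows)
  s <- summarize_ctlp(res, 1395)
  expect_equal(s$n_positive, 92L)
  expect_equal(s$incidence, 92 / 1395)
  expect_equal(round(100 * s$incidence), 7)  # "about 6%" prints as 6.6
  chr8 <- s$per_chromosome[s$per_chromosome$chrom == "8", ]
  expect_equal(chr8$n, 17L)
  expect_equal(chr8$fraction, 17 / 92)
  expect_equal(round(100 * chr8$fraction), 18)
  expect_equal(s$multi_chromosome_fraction, 10 / 92)
  expect_equal(round(100 * s$multi_chromosome_fraction), 11)
  # degenerate inputs
  expect_error(summarize_ctlp(res, 0), "positive")
  s0 <- summarize_ctlp(res[res$sample_id == "none", ], 10)
  expect_equal(s0$incidence, 0)
  expect_equal(nrow(s0$per_chromosome), 0L)
})
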