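toy_calls <- function(segments, build = toy_build(), ...) {
  call_states(mini_cohort(segments, build), ...)
}

test_that("state calling uses strict cutoffs and partitions segments", {
  seg <- tibble::tibble(start = (0:5) * 1e6, end = (1:6) * 1e6,
                        log2 = c(0.25, -0.21, 0.20, -0.20, 0.0, 1.3))
  calls <- toy_calls(seg)
  expect_equal(calls$state,
               c("gain", "loss", "neutral", "neutral", "neutral", "gain"))
  # partition: every segment in exactly one state
  expect_equal(sum(table(calls$state)), nrow(seg))
  expect_error(call_states(mini_cohort(seg), gain_thr = -0.1), "thresholds")
  expect_error(call_states(mini_cohort(seg), loss_thr = 0.1), "thresholds")
})

test_that("burden summary counts events and handles all-neutral samples", {
  seg <- tibble::tibble(
    sample_id = c("A", "A", "A", "B"),
    chrom = "1",
    start = c(0, 2e6, 6e6, 0),
    end = c(2e6, 6e6, 10e6, 10e6),
    log2 = c(0.5, 0.0, 0.5, 0.01))
  bs <- burden_summary(call_states(mini_cohort(seg)))
  a <- bs$per_sample[bs$per_sample$sample_id == "A", ]
  expect_equal(a$n_events, 2L)
  expect_equal(a$mean_size, 3e6)  # events of 2 Mb and 4 Mb
  b <- bs$per_sample[bs$per_sample$sample_id == "B", ]
  expect_equal(b$n_events, 0L)
  expect_true(is.na(b$mean_size))
  expect_equal(a$frac_altered, 6e6 / 300e6)
})

test_that("planted event counts are recovered when noise stays sub-threshold", {
  cfg <- sim_config(n_samples = 20, noise_sd = 0.02, ctlp_fraction = 0,
                    arm_propensity = list(gain = numeric(0), loss = numeric(0)),
                    subgroup = NULL, focal_rate = 4)
  sim <- simulate_cohort(cfg, seed = 21)
  calls <- call_states(sim$cohort)
  runs <- call_arm_events(calls)  # not used; just exercise on focal-only data
  bs <- burden_summary(calls)
  planted <- table(factor(sim$truth$events$sample_id,
                          levels = bs$per_sample$sample_id))
  # focal events can overlap each other; count called non-neutral runs
  # against planted events only where no two planted events touch
  ev <- sim$truth$events
  untangled <- vapply(bs$per_sample$sample_id, function(s) {
    e <- ev[ev$sample_id == s, ]
    if (nrow(e) < 2) return(TRUE)
    e <- e[order(e$chrom, e$start), ]
    all(e$start[-1] >= e$end[-nrow(e)] | e$chrom[-1] != e$chrom[-nrow(e)])
  }, logical(1))
  expect_gt(sum(untangled), 5)
  expect_equal(bs$per_sample$n_events[untangled],
               as.integer(planted)[untangled])
})

test_that("bin-state frequency follows the majority rule", {
  bins <- make_bins(toy_build())
  # 4 of 10 samples have a gain fully covering bin 1
  seg <- dplyr::bind_rows(lapply(1:10, function(i)
    tibble::tibble(sample_id = sprintf("S%02d", i), chrom = "1",
                   start = 0, end = 2e6,
                   log2 = if (i <= 4) 0.5 else 0)))
  fp <- frequency_profile(call_states(as_cna_cohort(seg, toy_build())), bins)
  expect_equal(fp$gain_freq[1], 0.4)
  expect_equal(fp$loss_freq[1], 0)
  expect_true(all(fp$gain_freq + fp$loss_freq <= 1))

  # 40% coverage of a bin is below the majority rule -> neutral
  seg2 <- tibble::tibble(sample_id = "S1", chrom = "1",
                         start = c(0, 4e5), end = c(4e5, 1e6),
                         log2 = c(0.5, 0))
  fp2 <- frequency_profile(call_states(as_cna_cohort(seg2, toy_build())), bins)
  expect_equal(fp2$gain_freq[1], 0)
})

test_that("bin-state assignment matches the per-unit majority oracle", {
  set.seed(401)
  b <- bare_build(len = 10e6)
  bins <- make_bins(b, 1e6)
  for (rep in 1:60) {
    seg <- random_segments(n_max = 6, chrom_len = 10e6)
    calls <- toy_calls(seg, b)
    want <- oracle_bin_state(seg, bins)
    fp <- frequency_profile(calls, bins)
    got <- ifelse(fp$gain_freq == 1, "gain",
                  ifelse(fp$loss_freq == 1, "loss", "neutral"))
    expect_identical(got, want)
  }
})

test_that("arm events need a >50% single-CNA run and merge adjacent segments", {
  b <- toy_build()
  q3 <- b$arms[b$arms$chrom == "3" & b$arms$arm == "q", ]  # 42.5-80 Mb
  alen <- q3$end - q3$start
  # single gained segment covering 60% of 3q
  seg <- tibble::tibble(chrom = "3", start = q3$start,
                        end = q3$start + 0.6 * alen, log2 = 0.5)
  ev <- call_arm_events(toy_calls(seg, b), b)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$arm, "3q")
  expect_equal(ev$type, "gain")
  expect_equal(ev$covered_fraction, 0.6)

  # exactly 50% -> no event (strict)
  seg50 <- tibble::tibble(chrom = "3", start = q3$start,
                          end = q3$start + 0.5 * alen, log2 = 0.5)
  expect_equal(nrow(call_arm_events(toy_calls(seg50, b), b)), 0L)

  # adjacent 30% + 25% gained segments merge to a 55% run
  segm <- tibble::tibble(chrom = "3",
                         start = q3$start + c(0, 0.30 * alen),
                         end = q3$start + c(0.30, 0.55) * alen,
                         log2 = c(0.45, 0.62))
  evm <- call_arm_events(toy_calls(segm, b), b)
  expect_equal(nrow(evm), 1L)
  expect_equal(evm$covered_fraction, 0.55)
  # and the literal single-segment reading reports none
  expect_equal(nrow(call_arm_events(toy_calls(segm, b), b,
                                    merge_adjacent = FALSE)), 0L)
})

test_that("raising the gain threshold never adds gain arm events", {
  sim <- simulate_cohort(sim_config(n_samples = 30), seed = 31)
  thresholds <- c(0.1, 0.2, 0.3, 0.45)
  n_gain <- vapply(thresholds, function(th) {
    ev <- call_arm_events(call_states(sim$cohort, gain_thr = th))
    sum(ev$type == "gain")
  }, numeric(1))
  expect_true(all(diff(n_gain) <= 0))
})

test_that("arm gain/loss correlation recovers exact anti- and co-linearity", {
  b <- toy_build()
  mk_events <- function(gain_n, loss_n, n_samples) {
    arms <- paste0(b$arms$chrom, b$arms$arm)
    rows <- list()
    for (i in seq_along(arms)) {
      if (gain_n[i] > 0)
        rows <- c(rows, list(tibble::tibble(
          sample_id = sprintf("S%03d", seq_len(gain_n[i])),
          chrom = b$arms$chrom[i], arm = arms[i], type = "gain",
          covered_fraction = 0.8)))
      if (loss_n[i] > 0)
        rows <- c(rows, list(tibble::tibble(
          sample_id = sprintf("S%03d", seq_len(loss_n[i])),
          chrom = b$arms$chrom[i], arm = arms[i], type = "loss",
          covered_fraction = 0.8)))
    }
    dplyr::bind_rows(rows)
  }
  # perfect anti-correlation up to affine map
  ev <- mk_events(gain_n = c(8, 6, 1, 0, 4, 2), loss_n = c(0, 2, 7, 8, 4, 6), 10)
  res <- arm_gain_loss_correlation(ev, 10, b)
  expect_lt(abs(res$r + 1), 1e-12)
  # identical vectors -> +1
  ev2 <- mk_events(gain_n = c(8, 6, 1, 0, 4, 2), loss_n = c(8, 6, 1, 0, 4, 2), 10)
  expect_lt(abs(arm_gain_loss_correlation(ev2, 10, b)$r - 1), 1e-12)
  # zero variance -> missing with warning
  ev3 <- mk_events(gain_n = rep(2, 6), loss_n = c(1:6), 10)
  expect_warning(res3 <- arm_gain_loss_correlation(ev3, 10, b), "variance")
  expect_true(is.na(res3$r))
})
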