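#' Call gain/loss/neutral states on cohort segments
#'
#' Fixed log2-ratio cutoffs, strict inequalities: a segment is a gain iff
#' `log2 > gain_thr`, a loss iff `log2 < loss_thr`, otherwise neutral
#' (boundary values are neutral).
#'
#' @param cohort a `cna_cohort`.
#' @param gain_thr gain cutoff (default 0.2).
#' @param loss_thr loss cutoff (default -0.2); must satisfy
#'   `loss_thr < 0 < gain_thr`.
#' @return a `cna_calls` tibble: the segment table plus a `state` column,
#'   with the build and thresholds kept as attributes.
#' @export
call_states <- function(cohort, gain_thr = 0.2, loss_thr = -0.2) {
  if (!(loss_thr < 0 && 0 < gain_thr))
    stop_bad_param("thresholds must satisfy loss_thr < 0 < gain_thr")
  seg <- cohort$segments
  state <- rep("neutral", nrow(seg))
  state[seg$log2 > gain_thr] <- "gain"
  state[seg$log2 < loss_thr] <- "loss"
  calls <- seg
  calls$state <- state
  attr(calls, "build") <- cohort$build
  attr(calls, "thresholds") <- c(gain = gain_thr, loss = loss_thr)
  attr(calls, "n_samples") <- length(cohort$samples)
  attr(calls, "samples") <- cohort$samples
  class(calls) <- c("cna_calls", class(calls))
  calls
}

calls_build <- function(calls) {
  b <- attr(calls, "build")
  if (is.null(b)) stop_bad_param("calls object lost its build attribute")
  b
}

#' Per-sample and cohort CNA burden
#'
#' An event is one non-neutral called segment. Mean event size averages
#' event lengths; fraction of genome altered divides altered bp by the total
#' autosome length of the build. Samples with no events report 0 events and
#' a missing mean size.
#'
#' @param calls a `cna_calls` object from [call_states()].
#' @return list with `per_sample` (tibble `sample_id`, `n_events`,
#'   `mean_size`, `frac_altered`) and `cohort` (single-row tibble with
#'   cohort means; `mean_size` pools all events).
#' @export
burden_summary <- function(calls) {
  build <- calls_build(calls)
  genome_bp <- sum(build$chromosomes$length)
  samples <- attr(calls, "samples") %||% sort(unique(calls$sample_id))
  ev <- calls[calls$state != "neutral", ]
  width <- ev$end - ev$start
  agg_n <- table(factor(ev$sample_id, levels = samples))
  agg_bp <- tapply(width, factor(ev$sample_id, levels = samples), sum)
  agg_bp[is.na(agg_bp)] <- 0
  per_sample <- tibble::tibble(
    sample_id = samples,
    n_events = as.integer(agg_n),
    mean_size = as.numeric(ifelse(agg_n > 0,
                                  as.numeric(agg_bp) / as.integer(agg_n),
                                  NA_real_)),
    frac_altered = as.numeric(agg_bp) / genome_bp)
  cohort <- tibble::tibble(
    n_samples = length(samples),
    mean_events = mean(per_sample$n_events),
    mean_event_size = if (nrow(ev)) mean(width) else NA_real_,
    mean_frac_altered = mean(per_sample$frac_altered))
  list(per_sample = per_sample, cohort = cohort)
}

# Per-sample bin-state assignment (the bin-state rule shared by the
# frequency profile and the clustering matrix): within each bin a sample is
# gain (loss) iff gained (lost) segments cover more than half of the bin
# and more than the opposite state; ties or <=50% coverage give neutral.
# Returns only non-neutral assignments: tibble(sample_id, index, state).
bin_states <- function(calls, bins) {
  samples <- attr(calls, "samples") %||% sort(unique(calls$sample_id))
  nn <- calls[calls$state != "neutral", , drop = FALSE]
  n_bins <- nrow(bins)
  if (!nrow(nn))
    return(tibble::tibble(sample_id = character(), index = integer(),
                          state = character()))
  gain_bp <- numeric(0); loss_bp <- numeric(0); keys <- numeric(0)
  sidx <- match(nn$sample_id, samples)
  for (cc in unique(nn$chrom)) {
    bsub <- bins[bins$chrom == cc, ]
    ssel <- which(nn$chrom == cc)
    s <- nn[ssel, ]
    first <- findInterval(s$start, bsub$start)
    last <- findInterval(s$end - 1, bsub$start)
    nb <- last - first + 1
    row <- sequence(nb) - 1 + rep(first, nb)
    si <- rep(ssel, nb)
    ov <- pmin(nn$end[si], bsub$end[row]) - pmax(nn$start[si], bsub$start[row])
    key <- (sidx[si] - 1) * n_bins + bsub$index[row]
    is_gain <- nn$state[si] == "gain"
    keys <- c(keys, key)
    gain_bp <- c(gain_bp, ifelse(is_gain, ov, 0))
    loss_bp <- c(loss_bp, ifelse(is_gain, 0, ov))
  }
  g <- rowsum(gain_bp, keys)
  l <- rowsum(loss_bp, keys)
  ukey <- as.numeric(rownames(g))
  bidx <- as.integer((ukey - 1) %% n_bins) + 1L
  spos <- as.integer((ukey - 1) %/% n_bins) + 1L
  blen <- bins$end[bidx] - bins$start[bidx]
  state <- ifelse(g[, 1] > 0.5 * blen & g[, 1] > l[, 1], "gain",
                  ifelse(l[, 1] > 0.5 * blen & l[, 1] > g[, 1], "loss", "neutral"))
  keep <- state != "neutral"
  tibble::tibble(sample_id = samples[spos[keep]],
                 index = bidx[keep], state = state[keep])
}

#' Genome-wide gain/loss frequency profile on a bin grid
#'
#' Applies the per-sample bin-state rule (a state must cover more than half
#' of the bin and beat the opposite state; ties give neutral, so each sample
#' contributes one state per bin and `gain_freq + loss_freq <= 1`), then
#' reports the fraction of samples in each state per bin.
#'
#' @param calls a `cna_calls` object.
#' @param bins bin grid from [make_bins()] on the same build.
#' @return the bin tibble plus `gain_freq`, `loss_freq`, `n_samples`.
#' @export
frequency_profile <- function(calls, bins) {
  n_samples <- attr(calls, "n_samples") %||% length(unique(calls$sample_id))
  bs <- bin_states(calls, bins)
  out <- bins
  out$gain_freq <- as.numeric(tabulate(bs$index[bs$state == "gain"], nrow(bins))) / n_samples
  out$loss_freq <- as.numeric(tabulate(bs$index[bs$state == "loss"], nrow(bins))) / n_samples
  out$n_samples <- n_samples
  out
}

#' Figure-style frequency track
#'
#' Per-chromosome area plot of gain frequency (up, red) and loss frequency
#' (down, blue) along the genome.
#'
#' @param freq output of [frequency_profile()].
#' @return a ggplot object.
#' @export
plot_frequency_profile <- function(freq) {
  freq$chrom <- factor(freq$chrom, levels = unique(freq$chrom))
  mid <- (freq$start + freq$end) / 2e6
  df <- tibble::tibble(chrom = freq$chrom, mb = mid,
                       gain = freq$gain_freq, loss = -freq$loss_freq)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mb)) +
    ggplot2::geom_area(ggplot2::aes(y = .data$gain), fill = "firebrick") +
    ggplot2::geom_area(ggplot2::aes(y = .data$loss), fill = "steelblue") +
    ggplot2::facet_grid(. ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "CNA frequency") +
    ggplot2::ylim(-1, 1) +
    ggplot2::theme_minimal()
}

#' Call arm-level events
#'
#' An arm-level event is a single CNA covering more than half of a
#' chromosome arm (strict `> 0.5`). Because segmentation can split one
#' biological event, maximal runs of consecutive same-state segments are
#' merged first (disable with `merge_adjacent = FALSE` for the literal
#' single-segment reading). At most one gain and one loss event is reported
#' per sample and arm (the largest run of each state).
#'
#' @param calls a `cna_calls` object.
#' @param build a [genome_build()] with arm intervals (defaults to the
#'   cohort's build). Arm-less chromosomes are skipped.
#' @param merge_adjacent merge consecutive same-state segments into runs.
#' @return tibble `sample_id`, `chrom`, `arm` (e.g. `"3q"`), `type`
#'   (`gain`/`loss`), `covered_fraction`.
#' @export
call_arm_events <- function(calls, build = calls_build(calls),
                            merge_adjacent = TRUE) {
  df <- tibble::as_tibble(calls[, c("sample_id", "chrom", "start", "end", "state")])
  df <- df[df$chrom %in% unique(build$arms$chrom), ]
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          arm = character(), type = character(),
                          covered_fraction = numeric())
  if (!nrow(df)) return(empty)
  df <- df[order(df$sample_id, match(df$chrom, build$chromosomes$chrom), df$start), ]
  if (merge_adjacent) {
    grp <- paste(df$sample_id, df$chrom)
    newrun <- c(TRUE, grp[-1] != grp[-nrow(df)] |
                  df$state[-1] != df$state[-nrow(df)])
    run_id <- cumsum(newrun)
    runs <- tibble::tibble(
      sample_id = df$sample_id[newrun],
      chrom = df$chrom[newrun],
      state = df$state[newrun],
      start = as.numeric(tapply(df$start, run_id, min)[as.character(seq_len(sum(newrun)))]),
      end = as.numeric(tapply(df$end, run_id, max)[as.character(seq_len(sum(newrun)))]))
  } else {
    runs <- df
  }
  runs <- runs[runs$state != "neutral", ]
  if (!nrow(runs)) return(empty)
  hits <- dplyr::inner_join(runs, build$arms, by = "chrom",
                            suffix = c("", ".arm"),
                            relationship = "many-to-many")
  ov <- pmin(hits$end, hits$end.arm) - pmax(hits$start, hits$start.arm)
  hits$covered_fraction <- ov / (hits$end.arm - hits$start.arm)
  hits <- hits[hits$covered_fraction > 0.5, ]
  if (!nrow(hits)) return(empty)
  hits$arm_label <- paste0(hits$chrom, hits$arm)
  hits <- dplyr::group_by(hits, .data$sample_id, .data$arm_label, .data$state)
  hits <- dplyr::slice_max(hits, .data$covered_fraction, n = 1, with_ties = FALSE)
  hits <- dplyr::ungroup(hits)
  out <- tibble::tibble(sample_id = hits$sample_id, chrom = hits$chrom,
                        arm = hits$arm_label, type = hits$state,
                        covered_fraction = hits$covered_fraction)
  out[order(out$sample_id, out$arm, out$type), ]
}

#' Correlation between arm-level gain and loss frequencies
#'
#' Per arm of the build, the fraction of samples carrying a gain event and
#' the fraction carrying a loss event; Pearson correlation across arms with
#' a two-sided p-value from the t distribution.
#'
#' @param arm_events tibble from [call_arm_events()].
#' @param n_samples cohort size (denominator of the frequencies).
#' @param build a [genome_build()] supplying the arm universe (arms with no
#'   events enter with frequency 0).
#' @return list with `r`, `p`, and `arm_freqs` (tibble `arm`, `gain_freq`,
#'   `loss_freq`). `r`/`p` are `NA` with a warning when either frequency
#'   vector has zero variance or fewer than 3 arms exist.
#' @export
arm_gain_loss_correlation <- function(arm_events, n_samples, build) {
  arms <- paste0(build$arms$chrom, build$arms$arm)
  freq <- function(type) {
    ev <- arm_events[arm_events$type == type, ]
    cnt <- tapply(ev$sample_id, factor(ev$arm, levels = arms),
                  function(s) length(unique(s)))
    cnt[is.na(cnt)] <- 0
    as.numeric(cnt) / n_samples
  }
  af <- tibble::tibble(arm = arms, gain_freq = freq("gain"),
                       loss_freq = freq("loss"))
  if (length(arms) < 3 || stats::sd(af$gain_freq) == 0 ||
      stats::sd(af$loss_freq) == 0) {
    warning("arm gain/loss correlation undefined (zero variance or < 3 arms)",
            call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, arm_freqs = af))
  }
  ct <- stats::cor.test(af$gain_freq, af$loss_freq, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, arm_freqs = af)
}
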