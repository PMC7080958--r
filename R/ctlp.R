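#' Count copy-number status switches on one chromosome
#'
#' Segments smaller than `min_seg` are dropped first. A switch is a pair of
#' consecutive retained segments whose called states (gain/neutral/loss at
#' the `gain_thr`/`loss_thr` cutoffs) differ AND whose absolute log2
#' difference is at least `diff_thr` (note: the adjacent-difference
#' condition here is `>=`, unlike the strict `>` of breakpoint extraction).
#'
#' @param segments tibble of one sample's segments on one chromosome
#'   (`start`, `end`, `log2`), sorted or not.
#' @param min_seg minimum retained segment size in bp (default 10 kb).
#' @param diff_thr minimum absolute adjacent log2 difference (default 0.4).
#' @param gain_thr,loss_thr state-calling cutoffs (defaults 0.2 / -0.2).
#' @return integer switch count (0 when fewer than 2 segments remain).
#' @export
count_status_switches <- function(segments, min_seg = 1e4, diff_thr = 0.4,
                                  gain_thr = 0.2, loss_thr = -0.2) {
  length(switch_positions(segments, min_seg, diff_thr, gain_thr, loss_thr))
}

# positions (left-segment end) of status switches on one chromosome
switch_positions <- function(segments, min_seg = 1e4, diff_thr = 0.4,
                             gain_thr = 0.2, loss_thr = -0.2) {
  seg <- segments[segments$end - segments$start >= min_seg, , drop = FALSE]
  if (nrow(seg) < 2) return(numeric(0))
  seg <- seg[order(seg$start), ]
  st <- ifelse(seg$log2 > gain_thr, 1L, ifelse(seg$log2 < loss_thr, -1L, 0L))
  n <- nrow(seg)
  is_switch <- st[-1] != st[-n] & abs(seg$log2[-1] - seg$log2[-n]) >= diff_thr
  seg$end[which(is_switch)]
}

#' Poisson clustering likelihood ratio
#'
#' log10 likelihood ratio of a clustered model (Poisson rate `k/L` inside
#' the candidate region) against the homogeneous model (rate `N/G` across
#' the chromosome), evaluated on the `k` events inside the region:
#' `log10_lr = (k * ln(lambda1/lambda0) - (lambda1 - lambda0) * L) / ln(10)`.
#' Zero when `k = 0` or the two rates coincide; positive and increasing in
#' `k` whenever the region is denser than the chromosome average.
#'
#' @param k events (status switches) inside the region.
#' @param L region length in bp.
#' @param N events on the whole chromosome (`k <= N`).
#' @param G chromosome length in bp.
#' @return log10 likelihood ratio (vectorized over its arguments).
#' @export
clustering_lr <- function(k, L, N, G) {
  if (any(L <= 0) || any(G <= 0)) stop_bad_param("L and G must be positive")
  if (any(k > N)) stop_bad_param("k cannot exceed N")
  lambda1 <- k / L
  lambda0 <- N / G
  out <- ifelse(k == 0 | lambda1 == lambda0, 0,
                (k * log(lambda1 / lambda0) - (lambda1 - lambda0) * L) / log(10))
  unname(out)
}

#' Scan one chromosome of one sample for chromothripsis-like patterns
#'
#' Windows of every width from `window` up to the chromosome length (in
#' `step` increments) slide across the chromosome; a window qualifies when
#' it holds at least `switch_thr` copy-number status switches and its
#' Poisson clustering likelihood ratio is at least `lr_thr`. Overlapping
#' qualifying windows are merged, each merged region is trimmed to the span
#' of the switches it contains (re-expanded to `window` if narrower),
#' re-evaluated once, and reported.
#'
#' @param segments one sample's segments on one chromosome (`start`, `end`,
#'   `log2`).
#' @param chrom_length chromosome length in bp.
#' @param window minimum region size in bp (default 30 Mb). Chromosomes
#'   shorter than `window` are evaluated as a single whole-chromosome
#'   window.
#' @param step window start/width increment in bp (default 5 Mb).
#' @param switch_thr minimum status switches (default 20).
#' @param lr_thr minimum log10 likelihood ratio (default 10).
#' @inheritParams count_status_switches
#' @return tibble `start`, `end`, `n_switches`, `log10_lr`, `is_ctlp` (one
#'   row per merged region; empty when no window qualifies).
#' @export
scan_chromosome <- function(segments, chrom_length, window = 30e6, step = 5e6,
                            switch_thr = 20, lr_thr = 10, min_seg = 1e4,
                            diff_thr = 0.4, gain_thr = 0.2, loss_thr = -0.2) {
  if (window <= 0 || step <= 0 || switch_thr <= 0 || lr_thr <= 0)
    stop_bad_param("scan thresholds must be positive")
  empty <- tibble::tibble(start = numeric(), end = numeric(),
                          n_switches = integer(), log10_lr = numeric(),
                          is_ctlp = logical())
  sp <- switch_positions(segments, min_seg, diff_thr, gain_thr, loss_thr)
  N <- length(sp)
  if (N < switch_thr) return(empty)
  G <- chrom_length
  sp <- sort(sp)
  count_in <- function(a, b) {
    # switches with position in [a, b]
    sum(sp >= a & sp <= b)
  }
  if (G <= window) {
    wins <- matrix(c(0, G), 1)
  } else {
    starts <- seq(0, G - window, by = step)
    wins <- do.call(rbind, lapply(starts, function(a) {
      ends <- unique(pmin(seq(a + window, G + step - 1, by = step), G))
      cbind(a, ends)
    }))
  }
  k <- vapply(seq_len(nrow(wins)),
              function(i) count_in(wins[i, 1], wins[i, 2]), numeric(1))
  lr <- clustering_lr(k, wins[, 2] - wins[, 1], N, G)
  ok <- k >= switch_thr & lr >= lr_thr
  if (!any(ok)) return(empty)
  q <- wins[ok, , drop = FALSE]
  q <- q[order(q[, 1], q[, 2]), , drop = FALSE]
  # merge overlapping qualifying windows
  merged <- list(); cur <- q[1, ]
  for (i in seq_len(nrow(q))[-1]) {
    if (q[i, 1] <= cur[2]) cur[2] <- max(cur[2], q[i, 2])
    else { merged <- c(merged, list(cur)); cur <- q[i, ] }
  }
  merged <- c(merged, list(cur))
  rows <- lapply(merged, function(m) {
    inside <- sp[sp >= m[1] & sp <= m[2]]
    a <- min(inside); b <- max(inside)
    if (b - a < window) {  # region length never below the minimum window
      mid <- (a + b) / 2
      a <- max(0, mid - window / 2)
      b <- min(G, a + window)
      a <- max(0, b - window)
    }
    kk <- count_in(a, b)
    lr2 <- clustering_lr(kk, b - a, N, G)
    tibble::tibble(start = a, end = b, n_switches = as.integer(kk),
                   log10_lr = lr2,
                   is_ctlp = kk >= switch_thr && lr2 >= lr_thr)
  })
  dplyr::bind_rows(rows)
}

#' Scan a whole cohort for chromothripsis-like patterns
#'
#' Applies [scan_chromosome()] to every sample and chromosome.
#'
#' @param cohort a `cna_cohort`.
#' @param build a [genome_build()] (defaults to the cohort's).
#' @inheritParams scan_chromosome
#' @return tibble `sample_id`, `chrom`, `start`, `end`, `n_switches`,
#'   `log10_lr`, `is_ctlp` with one row per reported region.
#' @export
scan_ctlp <- function(cohort, build = cohort$build, window = 30e6, step = 5e6,
                      switch_thr = 20, lr_thr = 10, min_seg = 1e4,
                      diff_thr = 0.4, gain_thr = 0.2, loss_thr = -0.2) {
  seg <- cohort$segments
  out <- list()
  for (sid in cohort$samples) {
    ss <- seg[seg$sample_id == sid, ]
    for (cc in unique(ss$chrom)) {
      res <- scan_chromosome(ss[ss$chrom == cc, ], chrom_length(build, cc),
                             window, step, switch_thr, lr_thr, min_seg,
                             diff_thr, gain_thr, loss_thr)
      if (nrow(res)) {
        res$sample_id <- sid
        res$chrom <- cc
        out <- c(out, list(res))
      }
    }
  }
  if (!length(out))
    return(tibble::tibble(sample_id = character(), chrom = character(),
                          start = numeric(), end = numeric(),
                          n_switches = integer(), log10_lr = numeric(),
                          is_ctlp = logical()))
  res <- dplyr::bind_rows(out)
  res[, c("sample_id", "chrom", "start", "end", "n_switches", "log10_lr",
          "is_ctlp")]
}

#' Cohort summary of chromothripsis-like calls
#'
#' A sample is a chromothripsis-like case when at least one of its
#' chromosomes qualifies. Per-chromosome shares use the number of positive
#' samples as denominator (one count per qualifying sample-chromosome), as
#' does the share of cases affecting two or more chromosomes.
#'
#' @param results tibble from [scan_ctlp()].
#' @param n_samples cohort size.
#' @return list: `n_positive`, `incidence` (fraction of the cohort),
#'   `per_chromosome` (tibble `chrom`, `n`, `fraction`), `per_sample`
#'   (tibble `sample_id`, `n_chromosomes`), `multi_chromosome_fraction`.
#' @export
summarize_ctlp <- function(results, n_samples) {
  if (n_samples <= 0) stop_bad_param("n_samples must be positive")
  pos <- results[results$is_ctlp, , drop = FALSE]
  pos_samples <- unique(pos$sample_id)
  n_pos <- length(pos_samples)
  sc <- unique(pos[, c("sample_id", "chrom")])
  per_chrom <- if (n_pos) {
    tab <- table(sc$chrom)
    tibble::tibble(chrom = names(tab), n = as.integer(tab),
                   fraction = as.integer(tab) / n_pos)
  } else {
    tibble::tibble(chrom = character(), n = integer(), fraction = numeric())
  }
  per_sample <- if (n_pos) {
    tab <- table(sc$sample_id)
    tibble::tibble(sample_id = names(tab), n_chromosomes = as.integer(tab))
  } else {
    tibble::tibble(sample_id = character(), n_chromosomes = integer())
  }
  list(n_positive = n_pos,
       incidence = n_pos / n_samples,
       per_chromosome = per_chrom[order(-per_chrom$n), ],
       per_sample = per_sample,
       multi_chromosome_fraction =
         if (n_pos) sum(per_sample$n_chromosomes >= 2) / n_pos else NA_real_)
}
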