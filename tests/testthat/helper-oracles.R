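# Independent brute-force oracles and tiny fixture builders used across the
# suite. Oracles are deliberately naive (loops, per-unit counting, explicit
# log-likelihoods) and share no code with the implementation they check.

# single-chromosome build without centromere/telomeres, for clean geometry
bare_build <- function(len = 2e6, chrom = "1", telomere = 0) {
  genome_build("bare",
               tibble::tibble(chrom = chrom, length = len),
               tibble::tibble(chrom = character(), arm = character(),
                              start = numeric(), end = numeric()),
               tibble::tibble(chrom = character(), start = numeric(),
                              end = numeric()),
               telomere_size = telomere)
}

mini_cohort <- function(segments, build = toy_build()) {
  if (!"sample_id" %in% names(segments)) segments$sample_id <- "S1"
  if (!"chrom" %in% names(segments)) segments$chrom <- "1"
  as_cna_cohort(segments, build)
}

# breakpoint oracle: explicit filter -> adjacency -> delta -> exclusion loop
# over one sample's segments on one chromosome
oracle_breakpoints <- function(seg, delta_thr = 0.4, min_seg = 1e4,
                               zones = NULL) {
  seg <- seg[order(seg$start), ]
  seg <- seg[seg$end - seg$start >= min_seg, ]
  out <- NULL
  if (nrow(seg) >= 2) {
    for (i in seq_len(nrow(seg) - 1)) {
      d <- abs(seg$log2[i + 1] - seg$log2[i])
      pos <- if (seg$start[i + 1] > seg$end[i])
        floor((seg$end[i] + seg$start[i + 1]) / 2) else seg$end[i]
      if (d > delta_thr) out <- rbind(out, data.frame(position = pos, delta = d))
    }
  }
  if (is.null(out)) out <- data.frame(position = numeric(), delta = numeric())
  if (!is.null(zones) && nrow(out)) {
    keep <- rep(TRUE, nrow(out))
    for (j in seq_len(nrow(zones)))
      keep <- keep & !(out$position >= zones$start[j] & out$position < zones$end[j])
    out <- out[keep, ]
  }
  out
}

# per-unit (1-kb lattice) majority oracle for the bin-state rule of one
# sample on one chromosome
oracle_bin_state <- function(seg, bins, gain_thr = 0.2, loss_thr = -0.2,
                             unit = 1e3) {
  vapply(seq_len(nrow(bins)), function(bi) {
    units <- seq(bins$start[bi], bins$end[bi] - unit, by = unit)
    lab <- rep("none", length(units))
    for (i in seq_len(nrow(seg))) {
      cover <- units >= seg$start[i] & units < seg$end[i]
      st <- if (seg$log2[i] > gain_thr) "gain"
      else if (seg$log2[i] < loss_thr) "loss" else "neutral"
      lab[cover] <- st
    }
    g <- sum(lab == "gain"); l <- sum(lab == "loss")
    if (g > length(units) / 2 && g > l) "gain"
    else if (l > length(units) / 2 && l > g) "loss"
    else "neutral"
  }, character(1))
}

# two-model Poisson log-likelihood difference, written out in full
oracle_log10_lr <- function(k, L, N, G) {
  lambda1 <- k / L
  lambda0 <- N / G
  ll_clustered <- k * log(lambda1) - lambda1 * L
  ll_homogeneous <- k * log(lambda0) - lambda0 * L
  (ll_clustered - ll_homogeneous) / log(10)
}

# upper-tail Poisson probability by explicit summation
oracle_poisson_upper <- function(x, lambda, upper = 1000) {
  sum(exp(-lambda + (x:upper) * log(lambda) - lfactorial(x:upper)))
}

# status-switch oracle: explicit pairwise loop
oracle_switches <- function(seg, min_seg = 1e4, diff_thr = 0.4,
                            gain_thr = 0.2, loss_thr = -0.2) {
  seg <- seg[order(seg$start), ]
  seg <- seg[seg$end - seg$start >= min_seg, ]
  if (nrow(seg) < 2) return(0L)
  st <- ifelse(seg$log2 > gain_thr, "g", ifelse(seg$log2 < loss_thr, "l", "n"))
  n <- 0L
  for (i in seq_len(nrow(seg) - 1))
    if (st[i] != st[i + 1] && abs(seg$log2[i + 1] - seg$log2[i]) >= diff_thr)
      n <- n + 1L
  n
}

# Fisher 2x2 two-sided p by hypergeometric enumeration
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  sum(probs[probs <= dhyper(a, m, n, k) * (1 + 1e-7)])
}

# random small segment list on a 1-kb lattice, non-overlapping, sorted
random_segments <- function(n_max = 6, chrom_len = 10e6, unit = 1e3,
                            gappy = TRUE) {
  n <- sample(2:n_max, 1)
  cuts <- sort(sample(seq(unit, chrom_len - unit, by = unit), n - 1))
  start <- c(0, cuts)
  end <- c(cuts, chrom_len)
  if (gappy) {
    shrink <- unit * sample(0:20, n, replace = TRUE)
    end <- pmax(start + unit, end - shrink)
  }
  tibble::tibble(start = start, end = end,
                 log2 = sample(c(-0.7, -0.45, -0.25, 0, 0.1, 0.25, 0.5, 0.8),
                               n, replace = TRUE) +
                   round(stats::runif(n, -0.02, 0.02), 4))
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
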