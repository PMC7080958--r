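in_regions <- function(chrom, pos, regions) {
  hit <- rep(FALSE, length(pos))
  if (is.null(regions) || !nrow(regions)) return(hit)
  for (i in seq_len(nrow(regions))) {
    hit <- hit | (chrom == regions$chrom[i] &
                    pos >= regions$start[i] & pos < regions$end[i])
  }
  hit
}

#' Extract copy-number breakpoints from a cohort
#'
#' The filter order is fixed: (1) segments smaller than `min_seg` are
#' excluded; (2) boundaries between consecutive retained segments are
#' evaluated; (3) a boundary is a breakpoint when the absolute log2
#' difference is strictly greater than `delta_thr`; (4) breakpoints inside
#' telomere/centromere exclusion zones are removed. The breakpoint position
#' is the end of the left segment; when retained segments do not abut, the
#' midpoint of the gap is used.
#'
#' @param cohort a `cna_cohort`.
#' @param build a [genome_build()] (defaults to the cohort's).
#' @param delta_thr minimum absolute log2 change, strict (default 0.4).
#' @param min_seg minimum segment size in bp retained (default 10 kb;
#'   segments strictly smaller are dropped).
#' @param exclude region tibble of excluded zones (defaults to
#'   [exclusion_zones()] of the build; pass an empty tibble to keep all).
#' @return tibble `sample_id`, `chrom`, `position`, `delta`.
#' @export
extract_breakpoints <- function(cohort, build = cohort$build, delta_thr = 0.4,
                                min_seg = 1e4,
                                exclude = exclusion_zones(build)) {
  seg <- cohort$segments
  seg <- seg[seg$end - seg$start >= min_seg, ]
  empty <- tibble::tibble(sample_id = character(), chrom = character(),
                          position = numeric(), delta = numeric())
  if (nrow(seg) < 2) return(empty)
  seg <- seg[order(seg$sample_id,
                   match(seg$chrom, build$chromosomes$chrom), seg$start), ]
  n <- nrow(seg)
  same <- seg$sample_id[-1] == seg$sample_id[-n] & seg$chrom[-1] == seg$chrom[-n]
  left <- which(same)
  if (!length(left)) return(empty)
  delta <- abs(seg$log2[left + 1] - seg$log2[left])
  gap_mid <- floor((seg$end[left] + seg$start[left + 1]) / 2)
  position <- ifelse(seg$start[left + 1] > seg$end[left], gap_mid, seg$end[left])
  bp <- tibble::tibble(sample_id = seg$sample_id[left], chrom = seg$chrom[left],
                       position = position, delta = delta)
  bp <- bp[bp$delta > delta_thr, ]
  bp[!in_regions(bp$chrom, bp$position, exclude), ]
}

bin_index_of <- function(chrom, pos, bins) {
  idx <- rep(NA_integer_, length(pos))
  for (cc in unique(chrom)) {
    bsub <- bins[bins$chrom == cc, ]
    sel <- chrom == cc
    idx[sel] <- bsub$index[findInterval(pos[sel], bsub$start)]
  }
  idx
}

#' Count breakpoints per genome bin
#'
#' @param breakpoints tibble from [extract_breakpoints()].
#' @param bins bin grid from [make_bins()].
#' @return the bin tibble plus a `count` column; counts sum to the number of
#'   breakpoints.
#' @export
count_per_bin <- function(breakpoints, bins) {
  out <- bins
  if (!nrow(breakpoints)) {
    out$count <- 0L
    return(out)
  }
  idx <- bin_index_of(breakpoints$chrom, breakpoints$position, bins)
  stopifnot(!anyNA(idx))  # bins tile the build, so every position maps
  out$count <- tabulate(idx, nrow(bins))
  stopifnot(sum(out$count) == nrow(breakpoints))
  out
}

# Allowed-position intervals per chromosome: complement of exclusion zones.
allowed_intervals <- function(build, exclude) {
  lapply(stats::setNames(nm = build$chromosomes$chrom), function(cc) {
    len <- chrom_length(build, cc)
    z <- exclude[exclude$chrom == cc, , drop = FALSE]
    z <- z[order(z$start), , drop = FALSE]
    s <- 0; ints <- NULL
    for (i in seq_len(nrow(z))) {
      if (z$start[i] > s) ints <- rbind(ints, c(s, z$start[i]))
      s <- max(s, z$end[i])
    }
    if (s < len) ints <- rbind(ints, c(s, len))
    if (is.null(ints)) stop_bad_param("chromosome ", cc, " has no allowed positions")
    ints
  })
}

#' Permutation null for breakpoint bin counts
#'
#' Each permutation relocates every breakpoint to a uniform random allowed
#' position on its own chromosome (telomere/centromere exclusion zones
#' excluded), preserving per-chromosome (and hence per-sample-per-
#' chromosome) breakpoint totals by construction.
#'
#' @param breakpoints tibble from [extract_breakpoints()].
#' @param build a [genome_build()].
#' @param bins bin grid from [make_bins()].
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed (required: the null is part of a seeded run).
#' @param exclude excluded regions (defaults to [exclusion_zones()]).
#' @param keep_matrix also return the full bins x permutations count matrix.
#' @return list `null_mean`, `null_sd` (length `nrow(bins)`), `n_perm`, and
#'   optionally `counts`.
#' @export
permute_breakpoints <- function(breakpoints, build, bins, n_perm = 1e4, seed,
                                exclude = exclusion_zones(build),
                                keep_matrix = FALSE) {
  if (missing(seed)) stop_bad_param("a seed is required for the permutation null")
  if (n_perm < 1) stop_bad_param("n_perm must be >= 1")
  set.seed(seed)
  n_bins <- nrow(bins)
  null_mean <- numeric(n_bins)
  null_sd <- numeric(n_bins)
  counts <- if (keep_matrix) matrix(0L, n_bins, n_perm) else NULL
  ints <- allowed_intervals(build, exclude)
  # shuffled breakpoints stay on their own chromosome, so each chromosome's
  # bin block can be tabulated independently
  for (cc in unique(breakpoints$chrom)) {
    B <- sum(breakpoints$chrom == cc)
    iv <- ints[[cc]]
    w <- iv[, 2] - iv[, 1]
    cw <- cumsum(w)
    total <- cw[length(cw)]
    u <- stats::runif(B * n_perm) * total
    k <- findInterval(u, c(0, cw[-length(cw)]))
    pos <- iv[k, 1] + (u - c(0, cw)[k])
    bsub <- bins[bins$chrom == cc, ]
    nb <- nrow(bsub)
    local <- findInterval(pos, bsub$start)
    perm <- rep(seq_len(n_perm), each = B)
    tab <- matrix(tabulate(local + nb * (perm - 1L), nb * n_perm), nb, n_perm)
    m <- rowMeans(tab)
    v <- rowMeans(tab^2) - m^2
    null_mean[bsub$index] <- m
    null_sd[bsub$index] <- sqrt(pmax(0, v) * n_perm / max(1, n_perm - 1))
    if (keep_matrix) counts[bsub$index, ] <- tab
  }
  out <- list(null_mean = null_mean, null_sd = null_sd, n_perm = n_perm)
  if (keep_matrix) out$counts <- counts
  out
}

#' Test bins for breakpoint enrichment against the permutation null
#'
#' Default p-value is the upper tail of a Poisson law whose mean is the
#' permutation-estimated null mean of the bin (the parametric tail lets
#' Bonferroni-corrected significance go below the 1/n_perm resolution of the
#' raw empirical fraction). Alternatives: `"normal"` (upper-tail normal with
#' the permutation sd and continuity correction) and `"empirical"` (needs
#' `keep_matrix = TRUE` in [permute_breakpoints()]). When a bin's null mean
#' is 0 but breakpoints were observed, the Poisson mean is floored at
#' `1/n_perm`.
#'
#' @param observed output of [count_per_bin()] (bins plus `count`).
#' @param null output of [permute_breakpoints()] on the same bin grid.
#' @param alpha family-wise significance level on the Bonferroni-corrected
#'   p-value (default 0.01).
#' @param method `"poisson"` (default), `"normal"` or `"empirical"`.
#' @return tibble of hotspot results: bins plus `observed`, `null_mean`,
#'   `null_sd`, `p_raw`, `p_bonferroni`, `is_hotspot`.
#' @export
hotspot_test <- function(observed, null, alpha = 0.01,
                         method = c("poisson", "normal", "empirical")) {
  method <- match.arg(method)
  n_bins <- nrow(observed)
  stopifnot(length(null$null_mean) == n_bins)
  obs <- observed$count
  mu <- null$null_mean
  if (method == "poisson") {
    mu_eff <- ifelse(mu == 0 & obs > 0, 1 / null$n_perm, mu)
    p_raw <- ifelse(obs == 0, 1,
                    stats::ppois(obs - 1, mu_eff, lower.tail = FALSE))
  } else if (method == "normal") {
    sd_eff <- pmax(null$null_sd, 1e-9)
    p_raw <- stats::pnorm(obs - 0.5, mu, sd_eff, lower.tail = FALSE)
    p_raw[obs == 0] <- 1
  } else {
    if (is.null(null$counts))
      stop_bad_param("empirical method needs permute_breakpoints(keep_matrix = TRUE)")
    ge <- rowSums(null$counts >= matrix(obs, n_bins, null$n_perm))
    p_raw <- (ge + 1) / (null$n_perm + 1)
  }
  out <- observed
  names(out)[names(out) == "count"] <- "observed"
  out$null_mean <- mu
  out$null_sd <- null$null_sd
  out$p_raw <- pmin(1, p_raw)
  out$p_bonferroni <- pmin(1, out$p_raw * n_bins)
  out$is_hotspot <- out$p_bonferroni < alpha
  out
}

#' Overlap of hotspot bins with a region set
#'
#' A hotspot bin overlaps the set when the intersection is at least 1 bp.
#'
#' @param hotspots tibble from [hotspot_test()] (only rows with
#'   `is_hotspot`, or any bin tibble to annotate in full).
#' @param region_set region tibble (e.g. from [read_bed()]).
#' @param hotspot_only restrict to rows flagged `is_hotspot` (default TRUE
#'   when the column is present).
#' @return list `n_hotspots`, `n_overlap`, `fraction` (missing when there
#'   are no hotspots), and `overlaps` (logical per considered bin).
#' @export
region_overlap <- function(hotspots, region_set,
                           hotspot_only = "is_hotspot" %in% names(hotspots)) {
  bins <- hotspots
  if (hotspot_only) bins <- bins[bins$is_hotspot, ]
  n <- nrow(bins)
  if (!n) return(list(n_hotspots = 0L, n_overlap = 0L, fraction = NA_real_,
                      overlaps = logical(0)))
  hit <- rep(FALSE, n)
  for (i in seq_len(nrow(region_set))) {
    hit <- hit | (bins$chrom == region_set$chrom[i] &
                    pmin(bins$end, region_set$end[i]) -
                    pmax(bins$start, region_set$start[i]) >= 1)
  }
  list(n_hotspots = n, n_overlap = sum(hit), fraction = sum(hit) / n,
       overlaps = hit)
}
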