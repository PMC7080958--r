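#' Build the bins x samples copy-number matrix
#'
#' `mode = "state"` (default) encodes each sample's per-bin call as
#' gain = +1, neutral = 0, loss = -1 using the same bin-state rule as
#' [frequency_profile()]; robust to signal-scale differences between array
#' platforms. `mode = "log2"` stores the segment-length-weighted mean log2
#' ratio per bin (bins with no covering segment are 0).
#'
#' @param calls a `cna_calls` object.
#' @param bins bin grid from [make_bins()].
#' @param mode `"state"` or `"log2"`.
#' @return numeric matrix, `nrow(bins)` rows, one column per sample.
#' @export
build_cna_matrix <- function(calls, bins, mode = c("state", "log2")) {
  mode <- match.arg(mode)
  samples <- attr(calls, "samples") %||% sort(unique(calls$sample_id))
  mat <- matrix(0, nrow(bins), length(samples),
                dimnames = list(NULL, samples))
  if (mode == "state") {
    bs <- bin_states(calls, bins)
    if (nrow(bs)) {
      j <- match(bs$sample_id, samples)
      mat[cbind(bs$index, j)] <- ifelse(bs$state == "gain", 1, -1)
    }
    return(mat)
  }
  # log2 mode: length-weighted mean per bin
  wsum <- matrix(0, nrow(bins), length(samples))
  n_bins <- nrow(bins)
  seg <- calls
  sidx <- match(seg$sample_id, samples)
  for (cc in unique(seg$chrom)) {
    bsub <- bins[bins$chrom == cc, ]
    sel <- which(seg$chrom == cc)
    s <- seg[sel, ]
    first <- findInterval(s$start, bsub$start)
    last <- findInterval(s$end - 1, bsub$start)
    nb <- last - first + 1
    row <- sequence(nb) - 1 + rep(first, nb)
    si <- rep(sel, nb)
    ov <- pmin(seg$end[si], bsub$end[row]) - pmax(seg$start[si], bsub$start[row])
    ij <- cbind(bsub$index[row], sidx[si])
    key <- (ij[, 2] - 1) * n_bins + ij[, 1]
    acc_w <- rowsum(ov, key)
    acc_v <- rowsum(ov * seg$log2[si], key)
    ukey <- as.numeric(rownames(acc_w))
    ij2 <- cbind(as.integer((ukey - 1) %% n_bins) + 1L,
                 as.integer((ukey - 1) %/% n_bins) + 1L)
    mat[ij2] <- mat[ij2] + acc_v[, 1]
    wsum[ij2] <- wsum[ij2] + acc_w[, 1]
  }
  covered <- wsum > 0
  mat[covered] <- mat[covered] / wsum[covered]
  mat
}

#' Ward hierarchical clustering of cohort copy-number profiles
#'
#' Agglomerative clustering of the sample columns on Euclidean distance
#' with Ward linkage (`hclust` method `"ward.D2"`, the Ward criterion on
#' unsquared Euclidean distances), cut into `k` flat clusters. Cluster
#' labels follow `cutree`'s convention (order of first appearance), so the
#' result is deterministic given the input.
#'
#' @param mat bins x samples matrix from [build_cna_matrix()].
#' @param k number of flat clusters (default 2, the two major clusters).
#' @return list: `assignment` (tibble `sample_id`, `cluster`), `tree`
#'   (the `hclust` object), `k`.
#' @export
ward_cluster <- function(mat, k = 2) {
  n <- ncol(mat)
  if (k < 1) stop_bad_param("k must be >= 1")
  if (k > n) stop_bad_param("k = ", k, " exceeds the ", n, " samples")
  d <- stats::dist(t(mat), method = "euclidean")
  tree <- stats::hclust(d, method = "ward.D2")
  labels <- if (k == 1) rep(1L, n) else stats::cutree(tree, k = k)
  list(assignment = tibble::tibble(sample_id = colnames(mat),
                                   cluster = as.integer(labels)),
       tree = tree, k = k)
}

#' Per-cluster CNA burden and arm-event profile
#'
#' @param clustering result of [ward_cluster()].
#' @param calls a `cna_calls` object for the same samples.
#' @param arm_events tibble from [call_arm_events()].
#' @param top_n arm events listed per cluster (default 5).
#' @return list: `per_cluster` (tibble `cluster`, `n_samples`,
#'   `mean_frac_altered`, `mean_arm_events`) and `top_arm_events` (tibble
#'   `cluster`, `arm`, `type`, `n`, `freq`).
#' @export
cluster_summary <- function(clustering, calls, arm_events, top_n = 5) {
  asg <- clustering$assignment
  stopifnot(!anyNA(asg$cluster), nrow(asg) > 0)
  burden <- burden_summary(calls)$per_sample
  burden$cluster <- asg$cluster[match(burden$sample_id, asg$sample_id)]
  arm_events$cluster <- asg$cluster[match(arm_events$sample_id, asg$sample_id)]
  per_cluster <- dplyr::summarise(
    dplyr::group_by(burden, .data$cluster),
    n_samples = dplyr::n(),
    mean_frac_altered = mean(.data$frac_altered),
    mean_arm_events = NA_real_)
  ae_n <- table(factor(arm_events$cluster, levels = per_cluster$cluster))
  per_cluster$mean_arm_events <- as.integer(ae_n) / per_cluster$n_samples
  top <- dplyr::count(arm_events, .data$cluster, .data$arm, .data$type,
                      sort = TRUE, name = "n")
  top$freq <- top$n / per_cluster$n_samples[match(top$cluster, per_cluster$cluster)]
  top <- dplyr::slice_head(dplyr::group_by(top, .data$cluster), n = top_n)
  list(per_cluster = dplyr::ungroup(per_cluster),
       top_arm_events = dplyr::ungroup(top))
}

#' Clinical-label enrichment per cluster
#'
#' For each cluster, a 2x2 table of cluster membership against a binary
#' reading of the clinical label (samples with value `positive` versus the
#' rest), tested with a two-sided Fisher exact test. Samples whose label is
#' `"unknown"` are excluded from the denominators.
#'
#' @param clustering result of [ward_cluster()].
#' @param clinical tibble from [read_clinical()].
#' @param label clinical column name, e.g. `"hpv"`, `"site"`.
#' @param positive label value treated as positive; defaults to `"yes"` for
#'   yes/no variables, otherwise required.
#' @return tibble `cluster`, `n`, `n_positive`, `n_rest`, `rest_positive`,
#'   `odds_ratio`, `p_fisher`.
#' @export
label_enrichment <- function(clustering, clinical, label, positive = NULL) {
  if (!label %in% names(clinical)) stop_bad_param("no column '", label, "' in clinical table")
  asg <- clustering$assignment
  val <- clinical[[label]][match(asg$sample_id, clinical$sample_id)]
  keep <- !is.na(val) & val != "unknown"
  if (!any(keep)) stop_bad_param("all values of '", label, "' are unknown")
  asg <- asg[keep, ]; val <- val[keep]
  if (is.null(positive)) {
    lv <- unique(val)
    positive <- if ("yes" %in% lv) "yes" else
      stop_bad_param("specify `positive` for label '", label, "'")
  }
  is_pos <- val == positive
  rows <- lapply(sort(unique(asg$cluster)), function(cl) {
    a <- sum(asg$cluster == cl & is_pos)
    b <- sum(asg$cluster == cl & !is_pos)
    c <- sum(asg$cluster != cl & is_pos)
    d <- sum(asg$cluster != cl & !is_pos)
    ft <- stats::fisher.test(matrix(c(a, b, c, d), 2, byrow = TRUE))
    tibble::tibble(cluster = cl, n = a + b, n_positive = a,
                   n_rest = c + d, rest_positive = c,
                   odds_ratio = unname(ft$estimate), p_fisher = ft$p.value)
  })
  dplyr::bind_rows(rows)
}
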