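`%||%` <- function(x, y) if (is.null(x)) y else x

stop_bad_param <- function(...) {
  stop(paste0(...), call. = FALSE)
}

#' Normalize chromosome names
#'
#' Strips a leading "chr" prefix (case-insensitively) so that "chr1", "Chr1"
#' and "1" all compare equal.
#'
#' @param x character vector of chromosome names.
#' @return character vector of bare chromosome names.
#' @keywords internal
norm_chrom <- function(x) {
  sub("^chr", "", as.character(x), ignore.case = TRUE)
}

# Deterministic child seeds derived from one run seed; kept below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 1000003 + i) %% 2147483647)
}
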