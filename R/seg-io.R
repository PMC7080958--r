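#' Read a SEG file into a cohort
#'
#' Accepts the TCGA level-3 dialect (`ID/chrom/loc.start/loc.end/num.mark/
#' seg.mean`) and a minimal 5-column form (sample, chrom, start, end, log2);
#' columns are auto-detected from the header. On-disk coordinates are
#' 1-based inclusive and are converted to the internal 0-based half-open
#' convention. Chromosome names are normalized (`"chr1"` and `"1"` compare
#' equal); X/Y rows are dropped with a message; rows on chromosomes unknown
#' to the build are skipped with a warning; rows with missing log2 are
#' dropped with a warning. Overlapping segments within one sample and
#' chromosome are a validation error.
#'
#' @param path tab-delimited SEG file with header.
#' @param build a [genome_build()].
#' @return a `cna_cohort`: list with `segments` (tibble `sample_id`, `chrom`,
#'   `start`, `end`, `n_probes`, `log2`, sorted), `samples`, and `build`.
#' @export
read_seg <- function(path, build) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  lc <- tolower(names(raw))
  pick <- function(cands, default = NA_integer_) {
    i <- which(lc %in% cands)
    if (length(i)) i[1] else default
  }
  i_sample <- pick(c("id", "sample", "sample_id", "sampleid"), 1L)
  i_chrom <- pick(c("chrom", "chromosome", "chr"))
  i_start <- pick(c("loc.start", "start", "loc_start"))
  i_end <- pick(c("loc.end", "end", "loc_end"))
  i_mark <- pick(c("num.mark", "num_mark", "n_probes", "num_probes"))
  i_log2 <- pick(c("seg.mean", "seg_mean", "log2", "segmean", "log2ratio"))
  if (is.na(i_chrom) || is.na(i_start) || is.na(i_end) || is.na(i_log2))
    stop_bad_param("cannot detect SEG columns in header of ", path)

  start <- suppressWarnings(as.numeric(raw[[i_start]]))
  end <- suppressWarnings(as.numeric(raw[[i_end]]))
  log2 <- suppressWarnings(as.numeric(raw[[i_log2]]))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    stop_bad_param("unparseable coordinates in ", path, " at data line ", bad[1])

  seg <- tibble::tibble(
    sample_id = as.character(raw[[i_sample]]),
    chrom = norm_chrom(raw[[i_chrom]]),
    start = start - 1,  # 1-based inclusive -> 0-based half-open
    end = end,
    n_probes = if (!is.na(i_mark)) suppressWarnings(as.integer(raw[[i_mark]])) else NA_integer_,
    log2 = log2)

  sex <- toupper(seg$chrom) %in% c("X", "Y")
  if (any(sex)) {
    message("dropped ", sum(sex), " X/Y segment row(s)")
    seg <- seg[!sex, ]
  }
  unknown <- !seg$chrom %in% build$chromosomes$chrom
  if (any(unknown)) {
    warning("skipped ", sum(unknown), " row(s) on chromosome(s) unknown to build: ",
            paste(unique(seg$chrom[unknown]), collapse = ", "), call. = FALSE)
    seg <- seg[!unknown, ]
  }
  na_sig <- is.na(seg$log2) | !is.finite(seg$log2)
  if (any(na_sig)) {
    warning("dropped ", sum(na_sig), " segment(s) with missing log2", call. = FALSE)
    seg <- seg[!na_sig, ]
  }
  len <- chrom_length(build, seg$chrom)
  seg$start <- pmax(seg$start, 0)
  seg$end <- pmin(seg$end, len)
  seg <- seg[seg$end > seg$start, ]
  as_cna_cohort(seg, build)
}

#' Assemble a cohort object from a segment table
#'
#' Sorts segments by sample, chromosome and start (so construction is
#' independent of input row order) and validates the non-overlap invariant.
#'
#' @param segments tibble with `sample_id`, `chrom`, `start`, `end`, `log2`
#'   (optional `n_probes`), internal 0-based half-open coordinates.
#' @param build a [genome_build()].
#' @return a `cna_cohort`.
#' @export
as_cna_cohort <- function(segments, build) {
  seg <- tibble::as_tibble(segments)
  if (!"n_probes" %in% names(seg)) seg$n_probes <- NA_integer_
  seg <- seg[, c("sample_id", "chrom", "start", "end", "n_probes", "log2")]
  seg <- seg[order(seg$sample_id,
                   match(seg$chrom, build$chromosomes$chrom), seg$start), ]
  # overlap validation per sample+chromosome
  key <- paste(seg$sample_id, seg$chrom)
  same <- key[-1] == key[-nrow(seg)]
  if (nrow(seg) > 1) {
    olap <- same & (seg$start[-1] < seg$end[-nrow(seg)])
    if (any(olap)) {
      i <- which(olap)[1]
      stop_bad_param("overlapping segments for sample ", seg$sample_id[i],
                     " on chromosome ", seg$chrom[i])
    }
  }
  structure(list(segments = seg,
                 samples = sort(unique(seg$sample_id)),
                 build = build),
            class = "cna_cohort")
}

#' @export
print.cna_cohort <- function(x, ...) {
  cat(sprintf("<cna_cohort>: %d samples, %d segments on build '%s'\n",
              length(x$samples), nrow(x$segments), x$build$name))
  invisible(x)
}

#' Write a cohort back to SEG format
#'
#' Coordinates are converted back to the 1-based inclusive on-disk dialect.
#' Output is deterministic (sorted segments, fixed column order) so that a
#' seeded simulation writes byte-identical files across runs.
#'
#' @param cohort a `cna_cohort`.
#' @param path output path.
#' @export
write_seg <- function(cohort, path) {
  seg <- cohort$segments
  out <- data.frame(ID = seg$sample_id, chrom = seg$chrom,
                    loc.start = format(seg$start + 1, scientific = FALSE, trim = TRUE),
                    loc.end = format(seg$end, scientific = FALSE, trim = TRUE),
                    num.mark = seg$n_probes,
                    seg.mean = formatC(seg$log2, format = "g", digits = 15))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a result table as TSV
#'
#' Deterministic column order; p-value columns (names starting with `p_`)
#' are written in scientific notation with 6 significant digits, all other
#' numeric columns at full precision, so tables round-trip through
#' [read_table()].
#'
#' @param records data frame of one result type (may be empty: header-only
#'   file is written).
#' @param path output path.
#' @export
write_table <- function(records, path) {
  df <- as.data.frame(records)
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) {
      df[[nm]] <- if (startsWith(nm, "p_"))
        formatC(df[[nm]], format = "e", digits = 5)
      else
        vapply(df[[nm]], function(v)
          if (is.na(v)) "NA" else formatC(v, format = "g", digits = 15),
          character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a TSV written by [write_table()]
#'
#' Chromosome columns are always read as character (so `"1"` never becomes
#' the integer 1).
#'
#' @param path file path.
#' @return tibble.
#' @export
read_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  for (nm in intersect(c("chrom", "chromosome", "sample_id"), names(df)))
    df[[nm]] <- as.character(df[[nm]])
  tibble::as_tibble(df)
}

CLINICAL_VOCAB <- list(
  site = c("oral cavity", "nasopharynx", "oropharynx", "hypopharynx",
           "larynx", "sinonasal", "unknown"),
  yesno = c("yes", "no", "unknown"))

#' Read a clinical annotation table
#'
#' Tab-delimited with a `sample_id` column (or first column) plus any of
#' `site`, `hpv`, `tobacco`, `alcohol`, `grade`. Values are case-normalized
#' and missing values mapped to `"unknown"`; duplicate sample ids are an
#' error.
#'
#' @param path clinical TSV.
#' @return tibble with normalized category columns.
#' @export
read_clinical <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if (!"sample_id" %in% names(raw)) names(raw)[1] <- "sample_id"
  raw$sample_id <- as.character(raw$sample_id)
  if (anyDuplicated(raw$sample_id))
    stop_bad_param("duplicate sample_id in clinical table: ",
                   raw$sample_id[duplicated(raw$sample_id)][1])
  normalize <- function(x, vocab = NULL) {
    x <- trimws(tolower(as.character(x)))
    x[is.na(x) | x == "" | x == "na"] <- "unknown"
    x[x == "sinonasal cavity"] <- "sinonasal"
    if (!is.null(vocab)) x[!x %in% vocab] <- "unknown"
    x
  }
  for (nm in intersect(c("hpv", "tobacco", "alcohol"), names(raw)))
    raw[[nm]] <- normalize(raw[[nm]], CLINICAL_VOCAB$yesno)
  if ("site" %in% names(raw)) raw$site <- normalize(raw$site, CLINICAL_VOCAB$site)
  if ("grade" %in% names(raw)) raw$grade <- normalize(raw$grade)
  tibble::as_tibble(raw)
}

#' Summarize one clinical variable
#'
#' Counts per category with the proportion among non-missing values (the
#' usual "% of non-missing" convention of clinical summary tables).
#'
#' @param clinical tibble from [read_clinical()] (or same shape).
#' @param var column name, e.g. `"hpv"`.
#' @return tibble `category`, `n`, `pct_known` (percent among known values;
#'   `NA` for the `"unknown"` row).
#' @export
clinical_summary <- function(clinical, var) {
  if (!var %in% names(clinical)) stop_bad_param("no column '", var, "' in clinical table")
  x <- clinical[[var]]
  tab <- table(x)
  known <- sum(tab[names(tab) != "unknown"])
  out <- tibble::tibble(category = names(tab), n = as.integer(tab))
  out$pct_known <- ifelse(out$category == "unknown", NA_real_,
                          100 * out$n / known)
  out[order(-out$n), ]
}
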