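#' Genome build: coordinate frame for all downstream statistics
#'
#' A `genome_build` holds chromosome lengths, p/q arm intervals, centromere
#' intervals and the telomere width treated as excluded at each chromosome
#' end. All internal coordinates are 0-based, half-open; SEG input (1-based
#' inclusive on disk) is converted on read.
#'
#' @param name label for the build (e.g. `"hg19"`, `"toy"`).
#' @param chromosomes tibble with columns `chrom`, `length` (bp, > 0),
#'   in the desired genome order.
#' @param arms tibble with columns `chrom`, `arm` (`"p"` or `"q"`),
#'   `start`, `end`. Chromosomes absent from `arms` are treated as arm-less
#'   and are skipped by arm-level calling.
#' @param centromeres tibble with columns `chrom`, `start`, `end`.
#' @param telomere_size bp treated as telomeric at each chromosome end
#'   (default 10 kb, the UCSC gap-track convention).
#' @return an object of class `genome_build`.
#' @export
genome_build <- function(name, chromosomes, arms, centromeres,
                         telomere_size = 1e4) {
  chromosomes <- tibble::as_tibble(chromosomes)
  arms <- tibble::as_tibble(arms)
  centromeres <- tibble::as_tibble(centromeres)
  stopifnot(all(c("chrom", "length") %in% names(chromosomes)))
  chromosomes$chrom <- norm_chrom(chromosomes$chrom)
  if (any(chromosomes$length <= 0) || any(chromosomes$length != round(chromosomes$length)))
    stop_bad_param("chromosome lengths must be strictly positive integers")
  if (anyDuplicated(chromosomes$chrom))
    stop_bad_param("duplicated chromosome names in build")
  for (tb in list(arms, centromeres)) {
    if (nrow(tb)) {
      len <- chromosomes$length[match(norm_chrom(tb$chrom), chromosomes$chrom)]
      if (any(is.na(len)) || any(tb$start < 0) || any(tb$end > len) ||
          any(tb$start >= tb$end))
        stop_bad_param("arm/centromere intervals must lie within [0, chromosome length)")
    }
  }
  arms$chrom <- norm_chrom(arms$chrom)
  centromeres$chrom <- norm_chrom(centromeres$chrom)
  # ordering invariant: p end <= cen start <= cen end <= q start
  for (cc in intersect(arms$chrom, centromeres$chrom)) {
    p <- arms[arms$chrom == cc & arms$arm == "p", ]
    q <- arms[arms$chrom == cc & arms$arm == "q", ]
    cen <- centromeres[centromeres$chrom == cc, ]
    if (nrow(p) && nrow(cen) && p$end[1] > cen$start[1])
      stop_bad_param("p-arm end exceeds centromere start on chromosome ", cc)
    if (nrow(q) && nrow(cen) && q$start[1] < cen$end[1])
      stop_bad_param("q-arm start precedes centromere end on chromosome ", cc)
  }
  if (telomere_size < 0) stop_bad_param("telomere_size must be >= 0")
  structure(
    list(name = name, chromosomes = chromosomes, arms = arms,
         centromeres = centromeres, telomere_size = telomere_size),
    class = "genome_build")
}

#' @export
print.genome_build <- function(x, ...) {
  cat(sprintf("<genome_build '%s'>: %d chromosomes, %.1f Mb total, %d arms, telomere %g bp\n",
              x$name, nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              nrow(x$arms), x$telomere_size))
  invisible(x)
}

#' Built-in three-chromosome toy build
#'
#' Three autosome-like chromosomes of 120/100/80 Mb with 5-Mb centromeres,
#' used throughout the test-suite and the simulator's fast mode.
#'
#' @param telomere_size telomeric bp excluded at each chromosome end.
#' @return a [genome_build()].
#' @export
toy_build <- function(telomere_size = 1e4) {
  chromosomes <- tibble::tibble(chrom = c("1", "2", "3"),
                                length = c(120e6, 100e6, 80e6))
  centromeres <- tibble::tibble(chrom = c("1", "2", "3"),
                                start = c(57.5e6, 47.5e6, 37.5e6),
                                end = c(62.5e6, 52.5e6, 42.5e6))
  arms <- tibble::tibble(
    chrom = rep(c("1", "2", "3"), each = 2),
    arm = rep(c("p", "q"), 3),
    start = c(0, 62.5e6, 0, 52.5e6, 0, 42.5e6),
    end = c(57.5e6, 120e6, 47.5e6, 100e6, 37.5e6, 80e6))
  genome_build("toy", chromosomes, arms, centromeres, telomere_size)
}

#' Read a UCSC-style cytoband file into a genome build
#'
#' Five tab-delimited columns without header: chrom, start, end, band name,
#' Giemsa stain. Arms are derived from band names (`p*`/`q*`) and the
#' centromere is the union of `acen`-stained bands. The X and Y chromosomes
#' are excluded from the default analysis set to avoid sex bias.
#'
#' @param path cytoband file.
#' @param telomere_size telomeric bp excluded at each chromosome end.
#' @param exclude_sex drop chromosomes X and Y (default TRUE).
#' @return a [genome_build()]. Chromosomes lacking an `acen` band are kept
#'   but flagged arm-less (with a warning) and skipped by arm-level calls.
#' @export
load_cytoband <- function(path, telomere_size = 1e4, exclude_sex = TRUE) {
  cb <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("chrom", "start", "end", "band", "stain"))
  cb$chrom <- norm_chrom(cb$chrom)
  if (exclude_sex) cb <- cb[!toupper(cb$chrom) %in% c("X", "Y"), ]
  if (!nrow(cb)) stop_bad_param("cytoband file has no usable rows: ", path)
  chroms <- unique(cb$chrom)
  # natural order: numeric chromosomes first
  suppressWarnings(num <- as.numeric(chroms))
  chroms <- chroms[order(is.na(num), num, chroms)]
  lengths <- vapply(chroms, function(cc) max(cb$end[cb$chrom == cc]), numeric(1))
  chromosomes <- tibble::tibble(chrom = chroms, length = unname(lengths))

  armless <- character(0)
  arm_rows <- list(); cen_rows <- list()
  for (cc in chroms) {
    sub <- cb[cb$chrom == cc, ]
    acen <- sub[sub$stain == "acen", ]
    if (!nrow(acen)) { armless <- c(armless, cc); next }
    cs <- min(acen$start); ce <- max(acen$end)
    cen_rows[[cc]] <- tibble::tibble(chrom = cc, start = cs, end = ce)
    p <- sub[startsWith(sub$band, "p") & sub$stain != "acen", ]
    q <- sub[startsWith(sub$band, "q") & sub$stain != "acen", ]
    ar <- list()
    if (nrow(p)) ar$p <- tibble::tibble(chrom = cc, arm = "p",
                                        start = min(p$start), end = min(cs, max(p$end)))
    if (nrow(q)) ar$q <- tibble::tibble(chrom = cc, arm = "q",
                                        start = max(ce, min(q$start)), end = max(q$end))
    arm_rows[[cc]] <- dplyr::bind_rows(ar)
  }
  if (length(armless))
    warning("no acen band for chromosome(s) ", paste(armless, collapse = ", "),
            "; flagged arm-less and excluded from arm-level calls", call. = FALSE)
  arms <- if (length(arm_rows)) dplyr::bind_rows(arm_rows) else
    tibble::tibble(chrom = character(), arm = character(),
                   start = numeric(), end = numeric())
  cens <- if (length(cen_rows)) dplyr::bind_rows(cen_rows) else
    tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  genome_build(tools::file_path_sans_ext(basename(path)),
               chromosomes, arms, cens, telomere_size)
}

#' hg19 autosome build bundled with the package
#'
#' Canonical hg19/GRCh37 autosome lengths with centromere (acen) intervals,
#' shipped as a condensed cytoband file (arm boundaries and centromeres are
#' all any operation here needs; sub-band resolution is not stored).
#'
#' @inheritParams load_cytoband
#' @return a 22-autosome [genome_build()].
#' @export
hg19_build <- function(telomere_size = 1e4) {
  path <- system.file("extdata", "hg19_cytoband.tsv", package = "cnascape",
                      mustWork = TRUE)
  b <- load_cytoband(path, telomere_size = telomere_size)
  b$name <- "hg19"
  b
}

#' Write a region set as 3-column BED
#'
#' 0-based half-open coordinates, no header, tab-delimited; round-trips
#' through [read_bed()].
#'
#' @param regions region tibble (`chrom`, `start`, `end`).
#' @param path output path.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(chrom = regions$chrom,
                   start = format(regions$start, scientific = FALSE, trim = TRUE),
                   end = format(regions$end, scientific = FALSE, trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

chrom_length <- function(build, chrom) {
  i <- match(norm_chrom(chrom), build$chromosomes$chrom)
  if (anyNA(i)) stop_bad_param("unknown chromosome: ",
                               paste(chrom[is.na(i)], collapse = ", "))
  build$chromosomes$length[i]
}

#' Tile a genome build with fixed-width bins
#'
#' Each chromosome is divided into contiguous bins of `width` bp; the final
#' bin is truncated at the chromosome end (retained, not dropped, so that
#' bin length enters rate-based statistics correctly). Genome-wide bin
#' indices are contiguous in build order.
#'
#' @param build a [genome_build()].
#' @param width bin width in bp (default 1 Mb).
#' @return tibble with columns `chrom`, `start`, `end`, `index`.
#' @export
make_bins <- function(build, width = 1e6) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop_bad_param("bin width must be a single positive number")
  pieces <- lapply(seq_len(nrow(build$chromosomes)), function(i) {
    len <- build$chromosomes$length[i]
    starts <- seq(0, len - 1, by = width)
    tibble::tibble(chrom = build$chromosomes$chrom[i],
                   start = starts, end = pmin(starts + width, len))
  })
  bins <- dplyr::bind_rows(pieces)
  bins$index <- seq_len(nrow(bins))
  bins
}

#' Telomere and centromere exclusion zones
#'
#' Breakpoints falling inside these regions are ignored by breakpoint
#' extraction and by the permutation null: per chromosome the first and last
#' `telomere_size` bp plus the centromere interval.
#'
#' @param build a [genome_build()].
#' @return a region tibble (`chrom`, `start`, `end`) sorted by chromosome
#'   and start, with attribute `label = "exclusion"`.
#' @export
exclusion_zones <- function(build) {
  ts <- build$telomere_size
  rows <- list(build$centromeres[, c("chrom", "start", "end")])
  if (ts > 0) {
    rows <- c(rows, list(
      tibble::tibble(chrom = build$chromosomes$chrom, start = 0, end = ts),
      tibble::tibble(chrom = build$chromosomes$chrom,
                     start = build$chromosomes$length - ts,
                     end = build$chromosomes$length)))
  }
  out <- dplyr::bind_rows(rows)
  out <- out[order(match(out$chrom, build$chromosomes$chrom), out$start), ]
  out <- tibble::as_tibble(out)
  attr(out, "label") <- "exclusion"
  out
}

#' Read a BED file as a region set
#'
#' Three or more tab-delimited columns (chrom, start, end), 0-based
#' half-open, no header. Intervals are clipped to chromosome bounds when a
#' build is given, and sorted.
#'
#' @param path BED file.
#' @param label label for the set (e.g. `"CFS"`, `"NFR"`).
#' @param build optional [genome_build()] used for clipping and ordering.
#' @return a region tibble (`chrom`, `start`, `end`) with a `label` attribute.
#' @export
read_bed <- function(path, label = basename(path), build = NULL) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop_bad_param("BED file needs >= 3 columns: ", path)
  out <- tibble::tibble(chrom = norm_chrom(bed[[1]]),
                        start = as.numeric(bed[[2]]),
                        end = as.numeric(bed[[3]]))
  if (any(is.na(out$start)) || any(is.na(out$end)) || any(out$start < 0))
    stop_bad_param("malformed BED coordinates in ", path)
  if (!is.null(build)) {
    len <- chrom_length(build, out$chrom)
    out$start <- pmin(out$start, len)
    out$end <- pmin(out$end, len)
    out <- out[out$end > out$start, ]
    out <- out[order(match(out$chrom, build$chromosomes$chrom), out$start), ]
  } else {
    out <- out[order(out$chrom, out$start), ]
  }
  attr(out, "label") <- label
  out
}
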