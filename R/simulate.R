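#' Simulation configuration
#'
#' Defines the generative model for synthetic segmented copy-number
#' cohorts. Per sample, each chromosome is partitioned by a Poisson
#' boundary process (exponential baseline segment lengths); segment means
#' are baseline noise `N(0, noise_sd)` plus the summed amplitudes of the
#' planted events covering them. Planted event classes:
#'
#' * arm events: per-arm exclusive gain-or-loss propensities (an arm is
#'   either gain-prone or loss-prone, which induces the negative arm-level
#'   gain/loss frequency correlation seen in tumor cohorts); one event is a
#'   single segment covering a `arm_frac_range` fraction of the arm.
#' * focal events: Poisson count per sample, log-uniform sizes, random sign.
#' * chromothripsis-like chromosomes: a fraction of samples carries one
#'   oscillating two-state region (see [simulate_chromothripsis()]).
#' * an optional subgroup (HPV-like): carries only its forced arm gains
#'   (default 3q) and never the forbidden losses (default 3p), and is
#'   labeled with its own clinical site and HPV rate.
#' * an optional breakpoint hotspot bin with a rate multiplier, planted via
#'   [plant_hotspot()].
#'
#' Defaults emulate, at toy-genome scale, the cohort structure the analysis
#' stages assume: ~6% chromothripsis-like incidence, ~14% subgroup fraction,
#' focal breakpoint rates comparable (per Mb) to large SNP-array cohorts.
#'
#' @param build a [genome_build()] (default [toy_build()]).
#' @param n_samples cohort size (default 200).
#' @param baseline_mean_len mean baseline segment length in bp (default 2 Mb,
#'   exponential lengths).
#' @param noise_sd sd of segment-mean log2 noise (default 0.05, small enough
#'   that noise alone neither crosses the 0.2 call cutoffs nor the 0.4
#'   breakpoint delta).
#' @param arm_propensity list with named numeric vectors `gain` and `loss`;
#'   names are arm labels (e.g. `"3q"`), values per-sample probabilities.
#' @param arm_amplitude absolute log2 shift of arm events (default 0.4).
#' @param arm_frac_range range of the arm fraction covered (default
#'   0.6--0.95, always above the 0.5 arm-call cutoff).
#' @param focal_rate expected focal events per sample (default 6).
#' @param focal_size_range focal size bounds in bp, log-uniform (default
#'   100 kb -- 10 Mb).
#' @param focal_amplitude absolute log2 shift of focal events (default 0.6).
#' @param ctlp_fraction fraction of samples with a chromothripsis-like
#'   chromosome (default 0.06).
#' @param ctlp_n_oscillations status switches per planted region (default
#'   80).
#' @param ctlp_amplitude oscillation amplitude (default 0.6).
#' @param ctlp_size_range oscillation segment size bounds in bp (default
#'   0.25--0.3 Mb). The clustering likelihood ratio of a region of `k`
#'   switches spanning `L` on a chromosome of length `G` scales as
#'   `k * (ln r - 1 + 1/r) / ln 10` with `r = G/L`, so a detectable plant
#'   (log10 LR >= 10 at the 30-Mb minimum window) needs many tight
#'   oscillations; the defaults give LR ~12--22 on the toy chromosomes,
#'   comfortably above threshold on all of them.
#' @param hotspot optional list `chrom`, `start`, `end`, `multiplier`.
#' @param subgroup optional list `fraction`, `gain_arms`, `no_loss_arms`,
#'   `site`, `hpv_rate`, `background_hpv_rate`; `NULL` disables it.
#' @param clinical list of marginal label frequencies for the non-subgroup
#'   samples.
#' @return a `sim_config` list.
#' @export
sim_config <- function(build = toy_build(),
                       n_samples = 200,
                       baseline_mean_len = 2e6,
                       noise_sd = 0.05,
                       arm_propensity = list(
                         gain = c("1q" = 0.5, "2p" = 0.3, "3q" = 0.45),
                         loss = c("1p" = 0.35, "2q" = 0.3, "3p" = 0.5)),
                       arm_amplitude = 0.4,
                       arm_frac_range = c(0.6, 0.95),
                       focal_rate = 6,
                       focal_size_range = c(1e5, 1e7),
                       focal_amplitude = 0.6,
                       ctlp_fraction = 0.06,
                       ctlp_n_oscillations = 80,
                       ctlp_amplitude = 0.6,
                       ctlp_size_range = c(2.5e5, 3e5),
                       hotspot = NULL,
                       subgroup = list(fraction = 0.14,
                                       gain_arms = "3q",
                                       no_loss_arms = "3p",
                                       site = "nasopharynx",
                                       hpv_rate = 0.9,
                                       background_hpv_rate = 0.05),
                       clinical = list(
                         site_probs = c("oral cavity" = 0.61,
                                        "oropharynx" = 0.097,
                                        "hypopharynx" = 0.062,
                                        "larynx" = 0.148,
                                        "sinonasal" = 0.025,
                                        "nasopharynx" = 0.058),
                         tobacco_yes = 0.694, alcohol_yes = 0.556,
                         site_unknown = 0.1, hpv_unknown = 0.2,
                         tobacco_unknown = 0.2, alcohol_unknown = 0.5)) {
  cfg <- list(build = build, n_samples = n_samples,
              baseline_mean_len = baseline_mean_len, noise_sd = noise_sd,
              arm_propensity = arm_propensity, arm_amplitude = arm_amplitude,
              arm_frac_range = arm_frac_range, focal_rate = focal_rate,
              focal_size_range = focal_size_range,
              focal_amplitude = focal_amplitude,
              ctlp_fraction = ctlp_fraction,
              ctlp_n_oscillations = ctlp_n_oscillations,
              ctlp_amplitude = ctlp_amplitude,
              ctlp_size_range = ctlp_size_range,
              hotspot = hotspot, subgroup = subgroup, clinical = clinical)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fr <- c(cfg$ctlp_fraction,
          if (!is.null(cfg$subgroup)) cfg$subgroup$fraction)
  if (any(fr < 0 | fr > 1)) stop_bad_param("fractions must lie in [0, 1]")
  if (cfg$n_samples < 1 || cfg$focal_rate < 0 || cfg$baseline_mean_len <= 0 ||
      cfg$noise_sd < 0)
    stop_bad_param("rates must be non-negative and sizes positive")
  max_len <- max(cfg$build$chromosomes$length)
  if (cfg$focal_size_range[2] > max_len)
    stop_bad_param("infeasible config: focal size exceeds every chromosome")
  arms <- paste0(cfg$build$arms$chrom, cfg$build$arms$arm)
  known <- c(names(cfg$arm_propensity$gain), names(cfg$arm_propensity$loss))
  if (!all(known %in% arms))
    stop_bad_param("arm propensity names must be arms of the build")
  invisible(cfg)
}

#' Simulate one chromothripsis-like oscillation
#'
#' `n_oscillations + 1` segments alternating between `baseline` and
#' `baseline + amplitude` (starting and ending at baseline level when the
#' count is even), segment sizes uniform in `size_range`, so that
#' [count_status_switches()] on the returned list equals `n_oscillations`
#' by construction whenever `amplitude` is at least the 0.4 difference
#' threshold.
#'
#' @param chrom chromosome name.
#' @param chrom_length chromosome length in bp.
#' @param n_oscillations number of status switches (>= 1).
#' @param amplitude log2 shift of the alternating state.
#' @param size_range segment size bounds in bp.
#' @param start region start (bp); uniform random when `NULL`.
#' @param baseline baseline log2 level (default 0).
#' @param noise_sd segment-mean jitter sd (default 0).
#' @param seed optional RNG seed for standalone use.
#' @return tibble `chrom`, `start`, `end`, `log2` of the oscillating
#'   segments only.
#' @export
simulate_chromothripsis <- function(chrom, chrom_length, n_oscillations,
                                    amplitude, size_range = c(5e5, 8e5),
                                    start = NULL, baseline = 0, noise_sd = 0,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (n_oscillations < 1) stop_bad_param("n_oscillations must be >= 1")
  if (amplitude <= 0) stop_bad_param("amplitude must be positive")
  n_seg <- n_oscillations + 1
  if (n_seg * size_range[1] > chrom_length)
    stop_bad_param("region too small for requested oscillations at minimum segment size")
  sizes <- round(stats::runif(n_seg, size_range[1], size_range[2]))
  span <- sum(sizes)
  if (span > chrom_length)
    stop_bad_param("region too small for requested oscillations")
  if (is.null(start)) start <- floor(stats::runif(1, 0, chrom_length - span + 1))
  bounds <- start + c(0, cumsum(sizes))
  level <- baseline + amplitude * (seq_len(n_seg) %% 2 == 0)
  tibble::tibble(chrom = as.character(chrom),
                 start = bounds[-length(bounds)],
                 end = bounds[-1],
                 log2 = level + stats::rnorm(n_seg, 0, noise_sd))
}

# one sample's segments on one chromosome given planted events
build_chromosome_profile <- function(chrom, len, events, ctlp, cfg) {
  n_draw <- ceiling(3 * len / cfg$baseline_mean_len) + 10
  bl <- cumsum(stats::rexp(n_draw, 1 / cfg$baseline_mean_len))
  bl <- round(bl[bl < len])
  edges <- numeric(0)
  if (!is.null(events) && nrow(events))
    edges <- c(events$start, events$end)
  cbounds <- NULL
  if (!is.null(ctlp)) {
    cbounds <- ctlp$start + c(0, cumsum(ctlp$sizes))
    edges <- c(edges, cbounds[1], cbounds[length(cbounds)])
  }
  # baseline boundaries inside planted events would splinter them
  drop <- rep(FALSE, length(bl))
  if (!is.null(events) && nrow(events))
    for (i in seq_len(nrow(events)))
      drop <- drop | (bl > events$start[i] & bl < events$end[i])
  if (!is.null(cbounds))
    drop <- drop | (bl > cbounds[1] & bl < cbounds[length(cbounds)])
  bounds <- sort(unique(round(c(0, len, bl[!drop], edges,
                                if (!is.null(cbounds)) cbounds))))
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  mids <- (starts + ends) / 2
  amp <- numeric(length(mids))
  if (!is.null(events) && nrow(events))
    for (i in seq_len(nrow(events)))
      amp <- amp + ifelse(mids > events$start[i] & mids < events$end[i],
                          events$amp[i], 0)
  if (!is.null(cbounds)) {
    inside <- mids > cbounds[1] & mids < cbounds[length(cbounds)]
    piece <- findInterval(mids[inside], cbounds)
    amp[inside] <- amp[inside] + ctlp$amplitude * (piece %% 2 == 0)
  }
  tibble::tibble(chrom = chrom, start = starts, end = ends,
                 log2 = amp + stats::rnorm(length(mids), 0, cfg$noise_sd))
}

#' Simulate a segmented copy-number cohort with ground truth
#'
#' Deterministic given `config` and `seed`: identical inputs give
#' byte-identical SEG output (integer coordinates throughout; log2 values
#' come from R's default Mersenne-Twister stream).
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed.
#' @return list: `cohort` (a `cna_cohort`), `truth` (list with `samples`
#'   tibble `sample_id`, `subgroup`; `events` tibble of planted arm/focal/
#'   chromothripsis events; `hotspot` echo of the planted hotspot, if any),
#'   `clinical` (tibble), plus the `config` and `seed` used.
#' @export
simulate_cohort <- function(config, seed) {
  cfg <- config
  validate_sim_config(cfg)
  set.seed(seed)
  build <- cfg$build
  chroms <- build$chromosomes$chrom
  lens <- build$chromosomes$length
  arms <- build$arms
  arms$label <- paste0(arms$chrom, arms$arm)
  sample_ids <- sprintf("S%04d", seq_len(cfg$n_samples))

  seg_rows <- vector("list", cfg$n_samples)
  truth_rows <- list()
  subgroup_flag <- logical(cfg$n_samples)
  clin_rows <- vector("list", cfg$n_samples)

  for (si in seq_len(cfg$n_samples)) {
    sid <- sample_ids[si]
    in_sub <- !is.null(cfg$subgroup) &&
      stats::runif(1) < cfg$subgroup$fraction
    subgroup_flag[si] <- in_sub

    # chromothripsis-like chromosome
    ctlp_by_chrom <- stats::setNames(vector("list", length(chroms)), chroms)
    if (stats::runif(1) < cfg$ctlp_fraction) {
      cc <- sample(chroms, 1, prob = lens)
      n_seg <- cfg$ctlp_n_oscillations + 1
      sizes <- round(stats::runif(n_seg, cfg$ctlp_size_range[1],
                                  cfg$ctlp_size_range[2]))
      span <- sum(sizes)
      len <- lens[match(cc, chroms)]
      if (span > len)
        stop_bad_param("infeasible config: chromothripsis region exceeds chromosome ", cc)
      cstart <- floor(stats::runif(1, 0, len - span + 1))
      ctlp_by_chrom[[cc]] <- list(start = cstart, sizes = sizes,
                                  amplitude = cfg$ctlp_amplitude)
      truth_rows <- c(truth_rows, list(tibble::tibble(
        sample_id = sid, kind = "ctlp", chrom = cc, start = cstart,
        end = cstart + span, arm = NA_character_, type = "ctlp",
        amplitude = cfg$ctlp_amplitude)))
    }

    # arm-level events
    ev_by_chrom <- stats::setNames(vector("list", length(chroms)), chroms)
    add_arm_event <- function(arm_label, type) {
      a <- arms[arms$label == arm_label, ]
      if (!nrow(a)) return()
      if (!is.null(ctlp_by_chrom[[a$chrom]])) return()
      frac <- stats::runif(1, cfg$arm_frac_range[1], cfg$arm_frac_range[2])
      alen <- a$end - a$start
      size <- round(frac * alen)
      st <- floor(stats::runif(1, a$start, a$end - size + 1))
      amp <- if (type == "gain") cfg$arm_amplitude else -cfg$arm_amplitude
      ev_by_chrom[[a$chrom]] <<- rbind(ev_by_chrom[[a$chrom]],
                                       data.frame(start = st, end = st + size,
                                                  amp = amp))
      truth_rows <<- c(truth_rows, list(tibble::tibble(
        sample_id = sid, kind = "arm", chrom = a$chrom, start = st,
        end = st + size, arm = arm_label, type = type, amplitude = amp)))
    }
    if (in_sub) {
      for (al in cfg$subgroup$gain_arms) add_arm_event(al, "gain")
    } else {
      for (al in names(cfg$arm_propensity$gain))
        if (stats::runif(1) < cfg$arm_propensity$gain[[al]])
          add_arm_event(al, "gain")
      for (al in names(cfg$arm_propensity$loss))
        if (stats::runif(1) < cfg$arm_propensity$loss[[al]])
          add_arm_event(al, "loss")
    }

    # focal events
    nf <- stats::rpois(1, cfg$focal_rate)
    for (i in seq_len(nf)) {
      size <- round(exp(stats::runif(1, log(cfg$focal_size_range[1]),
                                     log(cfg$focal_size_range[2]))))
      ok <- lens >= size & vapply(ctlp_by_chrom, is.null, logical(1))
      if (!any(ok)) next
      cc <- sample(chroms[ok], 1, prob = lens[ok])
      len <- lens[match(cc, chroms)]
      st <- floor(stats::runif(1, 0, len - size + 1))
      amp <- sample(c(-1, 1), 1) * cfg$focal_amplitude
      ev_by_chrom[[cc]] <- rbind(ev_by_chrom[[cc]],
                                 data.frame(start = st, end = st + size, amp = amp))
      truth_rows <- c(truth_rows, list(tibble::tibble(
        sample_id = sid, kind = "focal", chrom = cc, start = st,
        end = st + size, arm = NA_character_,
        type = if (amp > 0) "gain" else "loss", amplitude = amp)))
    }

    chrom_segs <- lapply(seq_along(chroms), function(ci)
      build_chromosome_profile(chroms[ci], lens[ci],
                               ev_by_chrom[[chroms[ci]]],
                               ctlp_by_chrom[[chroms[ci]]], cfg))
    ss <- dplyr::bind_rows(chrom_segs)
    ss$sample_id <- sid
    seg_rows[[si]] <- ss

    clin_rows[[si]] <- simulate_clinical_row(sid, in_sub, cfg)
  }

  seg <- dplyr::bind_rows(seg_rows)
  seg$n_probes <- pmax(1L, as.integer(round((seg$end - seg$start) / 5000)))
  cohort <- as_cna_cohort(seg, build)

  truth <- list(
    samples = tibble::tibble(sample_id = sample_ids, subgroup = subgroup_flag),
    events = if (length(truth_rows)) dplyr::bind_rows(truth_rows) else
      tibble::tibble(sample_id = character(), kind = character(),
                     chrom = character(), start = numeric(), end = numeric(),
                     arm = character(), type = character(),
                     amplitude = numeric()),
    hotspot = cfg$hotspot)

  if (!is.null(cfg$hotspot)) {
    cohort <- plant_hotspot(cohort,
                            bin = cfg$hotspot[c("chrom", "start", "end")],
                            multiplier = cfg$hotspot$multiplier,
                            seed = derive_seed(seed, 99991))
    truth$hotspot$n_injected <- attr(cohort, "n_injected")
  }

  list(cohort = cohort, truth = truth,
       clinical = dplyr::bind_rows(clin_rows), config = cfg, seed = seed)
}

simulate_clinical_row <- function(sid, in_sub, cfg) {
  cl <- cfg$clinical
  draw_yn <- function(p_yes, p_unknown) {
    if (stats::runif(1) < p_unknown) "unknown"
    else if (stats::runif(1) < p_yes) "yes" else "no"
  }
  hpv_rate <- if (is.null(cfg$subgroup)) 0.1
  else if (in_sub) cfg$subgroup$hpv_rate else cfg$subgroup$background_hpv_rate
  site <- if (in_sub && !is.null(cfg$subgroup)) cfg$subgroup$site
  else sample(names(cl$site_probs), 1, prob = cl$site_probs)
  if (stats::runif(1) < cl$site_unknown) site <- "unknown"
  tibble::tibble(
    sample_id = sid,
    site = site,
    hpv = draw_yn(hpv_rate, cl$hpv_unknown),
    tobacco = draw_yn(cl$tobacco_yes, cl$tobacco_unknown),
    alcohol = draw_yn(cl$alcohol_yes, cl$alcohol_unknown))
}

#' Null-cohort configuration for breakpoint statistics
#'
#' A cohort with no planted events whose only breakpoints come from
#' baseline segment-mean jumps: exponential 2-Mb segments with segment-mean
#' noise sd 0.18, so that adjacent-segment log2 differences exceed the 0.4
#' breakpoint threshold at a rate giving roughly 17 breakpoints per sample
#' on the 300-Mb toy genome (the per-Mb breakpoint rate reported for large
#' SNP-array tumor cohorts, ~138 per 2.9-Gb genome). Boundary positions are
#' a Poisson process, so surviving breakpoints are uniform on the
#' chromosome -- the uniform null for the hotspot test's type-I behaviour.
#'
#' @param n_samples cohort size (default 100).
#' @param build genome build (default [toy_build()]).
#' @return a [sim_config()].
#' @export
sim_null_config <- function(n_samples = 100, build = toy_build()) {
  sim_config(build = build, n_samples = n_samples,
             baseline_mean_len = 2e6, noise_sd = 0.18,
             arm_propensity = list(gain = numeric(0), loss = numeric(0)),
             focal_rate = 0, ctlp_fraction = 0, hotspot = NULL,
             subgroup = NULL)
}

#' Two-group cohort configuration for clustering benchmarks
#'
#' A cohort with two planted molecular groups: a high-burden background
#' (70%) carrying coherent arm-level events (gains of 1q and 2p, losses of
#' 1p, 2q and 3p at 0.7--0.8 propensity) and a quiet subgroup (30%) whose
#' only arm event is a forced 3q gain -- never a 3p loss -- on top of focal
#' alterations, labeled HPV-positive at 90% versus 5% in the background.
#' This is the HPV-like copy-number subtype structure used to benchmark
#' Ward clustering recovery and clinical-label enrichment.
#'
#' @param n_samples cohort size (default 150).
#' @param build genome build (default [toy_build()]).
#' @return a [sim_config()].
#' @export
sim_two_group_config <- function(n_samples = 150, build = toy_build()) {
  sim_config(build = build, n_samples = n_samples, ctlp_fraction = 0,
             arm_propensity = list(gain = c("1q" = 0.8, "2p" = 0.7),
                                   loss = c("1p" = 0.8, "2q" = 0.7,
                                            "3p" = 0.8)),
             subgroup = list(fraction = 0.3, gain_arms = "3q",
                             no_loss_arms = "3p", site = "nasopharynx",
                             hpv_rate = 0.9, background_hpv_rate = 0.05))
}

#' Plant a breakpoint hotspot into a cohort
#'
#' Injects small spike segments (each contributing two adjacent-segment
#' log2 jumps of 0.6, i.e. two breakpoints above the 0.4 threshold) at
#' uniform random positions inside the target bin until the bin's expected
#' breakpoint count reaches `multiplier` times the chromosome's per-bin
#' background. Spikes are `spike_len` bp (well above the 10-kb minimum
#' segment size) and leave flanks of at least `min_flank` bp so no injected
#' boundary is lost to the size filter.
#'
#' @param cohort a `cna_cohort`.
#' @param bin list or one-row tibble with `chrom`, `start`, `end`.
#' @param multiplier target rate multiple (>= 1; 1 returns the cohort
#'   unchanged).
#' @param seed RNG seed.
#' @param delta log2 offset of the spikes (default 0.6).
#' @param spike_len spike width in bp (default 25 kb).
#' @param min_flank minimum flank width retained around a spike (default
#'   15 kb).
#' @return the modified `cna_cohort`, with attribute `n_injected` (number
#'   of injected breakpoints).
#' @export
plant_hotspot <- function(cohort, bin, multiplier, seed, delta = 0.6,
                          spike_len = 2.5e4, min_flank = 1.5e4) {
  if (multiplier < 1) stop_bad_param("multiplier must be >= 1")
  bin <- as.list(bin)
  build <- cohort$build
  if (!bin$chrom %in% build$chromosomes$chrom ||
      bin$end > chrom_length(build, bin$chrom) || bin$start < 0)
    stop_bad_param("hotspot bin lies outside the build")
  if (multiplier == 1) {
    attr(cohort, "n_injected") <- 0L
    return(cohort)
  }
  set.seed(seed)
  width <- bin$end - bin$start
  bp <- extract_breakpoints(cohort, build)
  n_chrom_bins <- ceiling(chrom_length(build, bin$chrom) / width)
  background <- sum(bp$chrom == bin$chrom) / n_chrom_bins
  n_extra <- round((multiplier - 1) * background)
  n_spikes <- ceiling(n_extra / 2)
  if (n_spikes == 0) {
    attr(cohort, "n_injected") <- 0L
    return(cohort)
  }
  seg <- as.data.frame(cohort$segments)
  samples <- cohort$samples
  injected <- 0L
  for (i in seq_len(n_spikes)) {
    placed <- FALSE
    for (try in seq_len(100)) {
      sid <- sample(samples, 1)
      cand <- which(seg$sample_id == sid & seg$chrom == bin$chrom &
                      seg$start + min_flank < bin$end - spike_len &
                      seg$end - min_flank - spike_len > bin$start)
      if (!length(cand)) next
      h <- cand[sample.int(length(cand), 1)]
      lo <- max(seg$start[h] + min_flank, bin$start)
      hi <- min(seg$end[h] - min_flank, bin$end) - spike_len
      if (hi < lo) next
      x <- floor(stats::runif(1, lo, hi + 1))
      host <- seg[h, ]
      left <- host; left$end <- x
      spike <- host; spike$start <- x; spike$end <- x + spike_len
      spike$log2 <- host$log2 + delta
      right <- host; right$start <- x + spike_len
      seg <- rbind(seg[-h, ], left, spike, right)
      injected <- injected + 2L
      placed <- TRUE
      break
    }
    if (!placed)
      warning("could not place spike ", i, " inside the hotspot bin", call. = FALSE)
  }
  out <- as_cna_cohort(seg, build)
  attr(out, "n_injected") <- injected
  out
}

#' Example clinical table for a large head-and-neck cohort
#'
#' A per-patient clinical table whose marginal composition mirrors the
#' published summaries of large HNSCC meta-cohorts (1,395 patients: 61%
#' oral cavity, 5.8% nasopharynx among known sites; 150 of 1,065 known
#' HPV statuses positive; 69.4% tobacco users among known). Useful for
#' worked examples of [clinical_summary()] without any download.
#'
#' @return tibble with columns `sample_id`, `site`, `hpv`, `tobacco`,
#'   `alcohol`, `grade` (1,395 rows).
#' @export
example_clinical_cohort <- function() {
  fill <- function(counts, total) {
    v <- rep(names(counts), times = counts)
    c(v, rep("unknown", total - length(v)))
  }
  n <- 1395
  tibble::tibble(
    sample_id = sprintf("P%04d", seq_len(n)),
    site = fill(c("oral cavity" = 768, "nasopharynx" = 73,
                  "oropharynx" = 123, "hypopharynx" = 78,
                  "larynx" = 186, "sinonasal" = 31), n),
    hpv = fill(c(yes = 150, no = 915), n),
    tobacco = fill(c(yes = 763, no = 336), n),
    alcohol = fill(c(yes = 370, no = 296), n),
    grade = fill(c("well differentiated" = 186,
                   "moderately differentiated" = 555,
                   "poorly differentiated" = 236), n))
}
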