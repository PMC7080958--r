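#' Pipeline run configuration
#'
#' Collects every tunable threshold of the analysis with defaults equal to
#' the published parameter set the pipeline implements: gain/loss call
#' cutoffs 0.2 / -0.2, breakpoint delta 0.4, minimum segment 10 kb, 1-Mb
#' bin grid, 10,000 permutations, Bonferroni-corrected alpha 0.01, 20
#' status switches and log10 likelihood ratio 10 for chromothripsis-like
#' calls, 2 major clusters.
#'
#' @param gain_thr,loss_thr state-calling cutoffs.
#' @param delta_thr breakpoint log2 difference threshold (strict).
#' @param min_seg minimum segment size in bp.
#' @param bin_width bin width in bp.
#' @param n_perm permutations for the hotspot null.
#' @param alpha family-wise hotspot significance level.
#' @param switch_thr,lr_thr chromothripsis-like thresholds.
#' @param window,step chromothripsis-like scan window and step in bp.
#' @param k number of flat clusters.
#' @param seed RNG seed for the permutation null.
#' @return a `run_config` list.
#' @export
run_config <- function(gain_thr = 0.2, loss_thr = -0.2, delta_thr = 0.4,
                       min_seg = 1e4, bin_width = 1e6, n_perm = 1e4,
                       alpha = 0.01, switch_thr = 20, lr_thr = 10,
                       window = 30e6, step = 5e6, k = 2, seed = 1) {
  structure(list(gain_thr = gain_thr, loss_thr = loss_thr,
                 delta_thr = delta_thr, min_seg = min_seg,
                 bin_width = bin_width, n_perm = n_perm, alpha = alpha,
                 switch_thr = switch_thr, lr_thr = lr_thr, window = window,
                 step = step, k = k, seed = seed),
            class = "run_config")
}

#' Run the full CNA landscape pipeline
#'
#' Stages, in dependency order: state calling; burden, frequency profile
#' and arm-level events (with the arm gain/loss correlation); breakpoint
#' extraction; permutation hotspot test (with optional CFS/NFR overlap);
#' chromothripsis-like scan; Ward clustering (with optional clinical
#' enrichment); run summary. Per-stage tables are written to `out_dir` and
#' a machine-readable `run_summary.json` echoes parameters, seed, per-stage
#' counts and wall time. A stage failure aborts with the stage name and
#' leaves a `FAILED` marker file next to the partial outputs.
#'
#' @param cohort a `cna_cohort` (e.g. from [read_seg()] or
#'   [simulate_cohort()]).
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing); `NULL` skips all
#'   file output.
#' @param clinical optional clinical tibble; enables HPV enrichment.
#' @param cfs,nfr optional region BED paths for hotspot overlap.
#' @return list with the results of every stage plus `summary`.
#' @export
run_pipeline <- function(cohort, config = run_config(), out_dir = NULL,
                         clinical = NULL, cfs = NULL, nfr = NULL) {
  t0 <- Sys.time()
  build <- cohort$build
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(df, name) {
    if (!is.null(out_dir)) write_table(df, file.path(out_dir, name))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      if (!is.null(out_dir))
        writeLines(paste("FAILED at stage:", name, "-", conditionMessage(e)),
                   file.path(out_dir, "FAILED"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  for (pth in c(cfs, nfr))
    if (!is.null(pth) && !file.exists(pth))
      stop_bad_param("region file not found: ", pth)

  calls <- stage("call", call_states(cohort, config$gain_thr, config$loss_thr))
  emit(calls, "calls.tsv")
  bins <- make_bins(build, config$bin_width)

  burden <- stage("burden", burden_summary(calls))
  emit(burden$per_sample, "burden.tsv")
  freq <- stage("freq", frequency_profile(calls, bins))
  emit(freq, "frequency.tsv")
  arm_events <- stage("arms", call_arm_events(calls, build))
  emit(arm_events, "arm_events.tsv")
  arm_corr <- stage("arms",
                    arm_gain_loss_correlation(arm_events,
                                              length(cohort$samples), build))

  breakpoints <- stage("breakpoints",
                       extract_breakpoints(cohort, build, config$delta_thr,
                                           config$min_seg))
  emit(breakpoints, "breakpoints.tsv")
  hotspots <- stage("hotspots", {
    observed <- count_per_bin(breakpoints, bins)
    null <- permute_breakpoints(breakpoints, build, bins,
                                n_perm = config$n_perm, seed = config$seed)
    ht <- hotspot_test(observed, null, alpha = config$alpha)
    if (!is.null(cfs)) {
      ov <- region_overlap(ht, read_bed(cfs, "CFS", build))
      ht$overlaps_cfs <- FALSE
      ht$overlaps_cfs[ht$is_hotspot] <- ov$overlaps
    }
    if (!is.null(nfr)) {
      ov <- region_overlap(ht, read_bed(nfr, "NFR", build))
      ht$overlaps_nfr <- FALSE
      ht$overlaps_nfr[ht$is_hotspot] <- ov$overlaps
    }
    ht
  })
  emit(hotspots, "hotspots.tsv")

  ctlp <- stage("ctlp",
                scan_ctlp(cohort, build, config$window, config$step,
                          config$switch_thr, config$lr_thr, config$min_seg,
                          diff_thr = config$delta_thr,
                          gain_thr = config$gain_thr,
                          loss_thr = config$loss_thr))
  emit(ctlp, "ctlp.tsv")
  ctlp_summary <- stage("ctlp", summarize_ctlp(ctlp, length(cohort$samples)))

  clustering <- stage("cluster", {
    mat <- build_cna_matrix(calls, bins, mode = "state")
    ward_cluster(mat, k = min(config$k, ncol(mat)))
  })
  emit(clustering$assignment, "clusters.tsv")
  enrichment <- NULL
  if (!is.null(clinical) && "hpv" %in% names(clinical))
    enrichment <- stage("cluster",
                        label_enrichment(clustering, clinical, "hpv"))
  if (!is.null(enrichment)) emit(enrichment, "hpv_enrichment.tsv")

  summary <- list(
    parameters = unclass(config),
    seed = config$seed,
    n_samples = length(cohort$samples),
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    stages = list(
      call = list(n_segments = nrow(calls),
                  n_gain = sum(calls$state == "gain"),
                  n_loss = sum(calls$state == "loss")),
      burden = list(mean_events = burden$cohort$mean_events,
                    mean_event_size = burden$cohort$mean_event_size),
      freq = list(n_bins = nrow(freq),
                  max_gain_freq = max(freq$gain_freq),
                  max_loss_freq = max(freq$loss_freq)),
      arms = list(n_events = nrow(arm_events), r = arm_corr$r,
                  p = arm_corr$p),
      breakpoints = list(n = nrow(breakpoints)),
      hotspots = list(n_hotspots = sum(hotspots$is_hotspot)),
      ctlp = list(n_positive = ctlp_summary$n_positive,
                  incidence = ctlp_summary$incidence),
      cluster = list(k = clustering$k,
                     sizes = as.integer(table(clustering$assignment$cluster)))))
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  list(calls = calls, bins = bins, burden = burden, frequency = freq,
       arm_events = arm_events, arm_correlation = arm_corr,
       breakpoints = breakpoints, hotspots = hotspots, ctlp = ctlp,
       ctlp_summary = ctlp_summary, clustering = clustering,
       enrichment = enrichment, summary = summary)
}
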