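#' Run configuration for the end-to-end workflows
#'
#' Collects every stage's parameters with all defaults materialised, so
#' the saved copy of a configuration fully determines a run.  The
#' configuration round-trips losslessly through JSON and is identified by
#' a content hash recorded in every output file name written by
#' [run_pipeline()].
#'
#' @param sim a [sim_config()].
#' @param hmm an [hmm_config()].
#' @param band,cycles beta-envelope parameters.
#' @param threshold burst binarisation threshold.
#' @param windows a [window_spec()] (validated here, so an overlapping
#'   window pair fails before any computation).
#' @param classifier a [classifier_config()].
#' @param fraction edge fraction for [top_fraction()] reporting.
#' @param filter_low,filter_high,filter_order conditioning band (Hz) and
#'   Butterworth order.
#' @param target_fs analysis sampling rate after conditioning.
#' @param orthogonalize apply leakage correction during conditioning
#'   (default FALSE for simulated source-space data, which has no
#'   leakage).
#' @param n_per_group,n_trials simulated cohort size.
#' @param seed global seed.
#' @return list of class `run_config` with element `hash`.
#' @export
run_config <- function(sim = sim_config(), hmm = hmm_config(),
                       band = c(13, 30), cycles = 7, threshold = 2 / 3,
                       windows = window_spec(),
                       classifier = classifier_config(),
                       fraction = 0.05, filter_low = 1, filter_high = 48,
                       filter_order = 4L, target_fs = 100,
                       orthogonalize = FALSE, n_per_group = 6L,
                       n_trials = 30L, seed = 1L) {
  stopifnot(inherits(sim, "sim_config"), inherits(hmm, "hmm_config"),
            inherits(windows, "window_spec"),
            inherits(classifier, "classifier_config"))
  cfg <- list(sim = sim, hmm = hmm, band = band, cycles = cycles,
              threshold = threshold, windows = windows,
              classifier = classifier, fraction = fraction,
              filter_low = filter_low, filter_high = filter_high,
              filter_order = filter_order, target_fs = target_fs,
              orthogonalize = orthogonalize,
              n_per_group = as.integer(n_per_group),
              n_trials = as.integer(n_trials), seed = as.integer(seed))
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "run_config")
}

#' Run an end-to-end workflow on simulated data
#'
#' `"resting"`: simulate -> condition -> per-region TDE-HMM burst
#' detection -> global burst metrics -> Jaccard connectome -> group
#' statistics (and top-fraction edges).  `"task"`: simulate -> condition
#' -> burst detection -> trial tensors for the homologous motor pair ->
#' probability/coincidence courses and rebound-window statistics.  All
#' artifacts are written under `out_dir` with the config hash in the file
#' name; the return value carries the in-memory results.
#'
#' @param config a [run_config()].
#' @param workflow `"resting"` or `"task"`.
#' @param out_dir output directory (created if needed); `NULL` to skip
#'   writing.
#' @return list of stage results (see Details in the vignette).
#' @export
run_pipeline <- function(config, workflow = c("resting", "task"),
                         out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  workflow <- match.arg(workflow)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  tag <- function(name) if (is.null(out_dir)) NULL else
    file.path(out_dir, paste0(name, "-", substr(config$hash, 1, 8)))
  sim <- config$sim
  sim$seed <- config$seed

  if (workflow == "resting") {
    simdat <- simulate_resting(sim, config$n_per_group)
  } else {
    simdat <- simulate_task(sim, config$n_trials, config$n_per_group)
  }
  groups <- vapply(simdat$recordings, `[[`, "", "group")
  ids <- vapply(simdat$recordings, `[[`, "", "subject_id")
  names(groups) <- ids

  detections <- vector("list", length(ids)); names(detections) <- ids
  for (s in seq_along(ids)) {
    rec <- condition_recording(simdat$recordings[[s]], config$filter_low,
                               config$filter_high, config$filter_order,
                               config$target_fs,
                               orthogonalize = config$orthogonalize)
    hmm <- config$hmm
    hmm$seed <- config$seed + s
    detections[[s]] <- c(detect_bursts(rec, hmm, config$band,
                                       config$cycles, config$threshold),
                         list(rec = rec))
  }

  if (workflow == "resting") {
    globals <- lapply(detections, function(d) global_collapse(d$summaries))
    conns <- lapply(detections, function(d) burst_connectome(d$trains))
    metrics <- metric_table(globals, groups)
    gc_rows <- data.frame(subject = ids, group = unname(groups[ids]),
                          metric = "global_connectivity",
                          value = vapply(conns, global_mean_connectivity, 0))
    metrics <- rbind(metrics, gc_rows)
    battery <- run_group_battery(metrics,
                                 families = c("resting_global",
                                              "connectivity"))
    mean_J <- Reduce(`+`, lapply(conns, `[[`, "J")) / length(conns)
    top <- top_fraction(structure(list(J = mean_J,
                                       labels = conns[[1]]$labels),
                                  class = "connectome"), config$fraction)
    if (!is.null(out_dir)) {
      data.table::fwrite(metrics, paste0(tag("metrics"), ".tsv"), sep = "\t")
      data.table::fwrite(battery, paste0(tag("battery"), ".tsv"), sep = "\t")
      data.table::fwrite(top, paste0(tag("top-edges"), ".tsv"), sep = "\t")
      for (s in ids)
        write_connectome_csv(conns[[s]],
                             paste0(tag(paste0("connectome-", s)), ".csv"))
      jsonlite::write_json(list(hash = config$hash, seed = config$seed),
                           paste0(tag("provenance"), ".json"),
                           auto_unbox = TRUE)
    }
    list(workflow = workflow, config = config, simulation = simdat,
         detections = detections, globals = globals, connectomes = conns,
         metrics = metrics, battery = battery, top_edges = top)
  } else {
    motor <- sim_region_labels(sim$n_regions)[1:2]   # homologous pair
    courses <- list(); stats <- list(); coinc <- list()
    for (s in ids) {
      d <- detections[[s]]
      ev <- d$rec$events
      ta <- epoch_trials(d$trains[[motor[1]]], d$envelopes[[motor[1]]],
                         ev, config$windows$half_window_s)
      tb <- epoch_trials(d$trains[[motor[2]]], d$envelopes[[motor[2]]],
                         ev, config$windows$half_window_s)
      courses[[s]] <- list(left = burst_probability_course(ta),
                           right = burst_probability_course(tb),
                           time_s = ta$time_s)
      stats[[s]] <- list(left = window_burst_stats(ta, config$windows),
                         right = window_burst_stats(tb, config$windows))
      coinc[[s]] <- list(course = coincidence_course(ta, tb),
                         pmbr = pmbr_coincidence(ta, tb, config$windows))
    }
    if (!is.null(out_dir)) {
      crs <- do.call(rbind, lapply(ids, function(s) data.frame(
        subject = s, group = unname(groups[s]),
        time_s = courses[[s]]$time_s, left = courses[[s]]$left,
        right = courses[[s]]$right,
        coincidence = as.numeric(coinc[[s]]$course))))
      data.table::fwrite(crs, paste0(tag("task-courses"), ".tsv"),
                         sep = "\t")
      jsonlite::write_json(list(hash = config$hash, seed = config$seed),
                           paste0(tag("provenance"), ".json"),
                           auto_unbox = TRUE)
    }
    list(workflow = workflow, config = config, simulation = simdat,
         detections = detections, courses = courses,
         window_stats = stats, coincidence = coinc)
  }
}
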