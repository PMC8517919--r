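#' Window specification for movement-locked statistics
#'
#' The rebound (PMBR) window is defined as 0.45-0.85 s after the button
#' press; the movement-related suppression (MRBD) window defaults to
#' (-0.3, 0.1) s around the press.  Windows must lie inside the trial and
#' must not overlap.
#'
#' @param pmbr numeric length-2, rebound window in seconds relative to the
#'   press (default `c(0.45, 0.85)`).
#' @param mrbd numeric length-2, suppression window (default
#'   `c(-0.3, 0.1)`).
#' @param half_window_s trial half-width in seconds (default 3).
#' @return list of class `window_spec`.
#' @export
window_spec <- function(pmbr = c(0.45, 0.85), mrbd = c(-0.3, 0.1),
                        half_window_s = 3) {
  stopifnot(length(pmbr) == 2, length(mrbd) == 2, pmbr[1] < pmbr[2],
            mrbd[1] < mrbd[2])
  if (pmbr[1] < -half_window_s || pmbr[2] > half_window_s ||
      mrbd[1] < -half_window_s || mrbd[2] > half_window_s)
    stop("windows must lie within the +/-", half_window_s, " s trial")
  if (max(mrbd[1], pmbr[1]) < min(mrbd[2], pmbr[2]))
    stop("pmbr and mrbd windows overlap")
  structure(list(pmbr = pmbr, mrbd = mrbd, half_window_s = half_window_s),
            class = "window_spec")
}

#' Epoch a burst train into a trial tensor
#'
#' Slices the binary burst indicator and the matched envelope into
#' fixed-length trials of `2 * half_window_s` seconds centred on each
#' event (button press).  Events closer than `half_window_s` to a record
#' edge are dropped (with a message).
#'
#' @param train a `burst_train`.
#' @param env the matched `beta_envelope`.
#' @param events event sample indices (1-based).
#' @param half_window_s trial half-width in seconds (default 3).
#' @return object of class `trial_tensor`: list with `B` (time x trials
#'   binary matrix), `env` (matched envelope matrix), `time_s` (trial
#'   time axis in seconds, 0 at the press), `fs`, `region_id`,
#'   `n_dropped`.
#' @export
epoch_trials <- function(train, env, events, half_window_s = 3) {
  stopifnot(inherits(train, "burst_train"))
  envv <- if (inherits(env, "beta_envelope")) env$env else env
  if (length(envv) != length(train$b))
    stop("train and envelope lengths differ")
  fs <- train$fs
  hw <- round(half_window_s * fs)
  T <- length(train$b)
  ok <- events - hw >= 1L & events + hw - 1L <= T
  if (any(!ok))
    message(sum(!ok), " trial(s) dropped: window overlaps record edge")
  events <- events[ok]
  if (length(events) == 0) stop("no usable trials")
  idx <- vapply(events, function(e) (e - hw):(e + hw - 1L),
                integer(2L * hw))
  B <- matrix(train$b[idx], nrow = 2L * hw)
  E <- matrix(envv[idx], nrow = 2L * hw)
  time_s <- (seq_len(2L * hw) - hw - 1L) / fs   # 0 at the press sample
  structure(list(B = B, env = E, time_s = time_s, fs = fs,
                 region_id = train$region_id, n_dropped = sum(!ok)),
            class = "trial_tensor")
}

#' Burst probability time course
#'
#' For each time point within the trial, the fraction of trials showing a
#' burst at that time.
#'
#' @param tensor a `trial_tensor`.
#' @return numeric vector over `tensor$time_s`, values in `[0, 1]`.
#' @export
burst_probability_course <- function(tensor) {
  stopifnot(inherits(tensor, "trial_tensor"))
  rowMeans(tensor$B)
}

#' Movement-locked window statistics
#'
#' Computes, for one region's trial tensor: the mean burst probability
#' over the rebound (PMBR) window; the burst amplitude during the rebound
#' (per-trial mean of the per-visit envelope maxima for visits
#' intersecting the window — a visit that falls within, begins, or ends
#' during the window is included — averaged across trials); and the burst
#' probability modulation (mean course over PMBR minus mean course over
#' MRBD).
#'
#' @param tensor a `trial_tensor`.
#' @param windows a [window_spec()].
#' @return list with `pmbr_probability`, `pmbr_amplitude` (`NA` with
#'   `amplitude_defined = FALSE` if no visit intersects the window in any
#'   trial), `modulation`.
#' @export
window_burst_stats <- function(tensor, windows = window_spec()) {
  stopifnot(inherits(tensor, "trial_tensor"),
            inherits(windows, "window_spec"))
  course <- burst_probability_course(tensor)
  in_pmbr <- tensor$time_s >= windows$pmbr[1] & tensor$time_s < windows$pmbr[2]
  in_mrbd <- tensor$time_s >= windows$mrbd[1] & tensor$time_s < windows$mrbd[2]
  pmbr_prob <- mean(course[in_pmbr])
  modulation <- pmbr_prob - mean(course[in_mrbd])
  ## per-trial amplitude over visits intersecting the PMBR window
  w_lo <- which(in_pmbr)[1]
  w_hi <- which(in_pmbr)[sum(in_pmbr)]
  per_trial <- rep(NA_real_, ncol(tensor$B))
  for (tr in seq_len(ncol(tensor$B))) {
    r <- rle(tensor$B[, tr])
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    on <- which(r$values == 1L)
    if (length(on) == 0) next
    vs <- starts[on]; ve <- ends[on]                 # closed sample runs
    hit <- vs <= w_hi & ve >= w_lo                   # intersection rule
    if (!any(hit)) next
    per_trial[tr] <- mean(vapply(which(hit), function(k)
      max(tensor$env[vs[k]:ve[k], tr]), 0))
  }
  defined <- any(!is.na(per_trial))
  list(pmbr_probability = pmbr_prob,
       pmbr_amplitude = if (defined) mean(per_trial, na.rm = TRUE)
                        else NA_real_,
       modulation = modulation,
       amplitude_defined = defined)
}

#' Time-resolved burst coincidence between two regions
#'
#' Expands the Jaccard index over trial time: for each time point within
#' the trial, the intersection-over-union is computed across trials
#' (rather than across time).  Time points with an empty union give 0 and
#' are flagged in the `union_empty` attribute.
#'
#' @param ta,tb `trial_tensor` objects for the two regions, with the same
#'   trials.
#' @return numeric vector over trial time with attribute `union_empty`.
#' @export
coincidence_course <- function(ta, tb) {
  stopifnot(inherits(ta, "trial_tensor"), inherits(tb, "trial_tensor"))
  if (ncol(ta$B) != ncol(tb$B)) stop("trial counts differ")
  if (nrow(ta$B) != nrow(tb$B)) stop("trial lengths differ")
  inter <- rowSums(ta$B & tb$B)
  uni <- rowSums(ta$B | tb$B)
  J <- ifelse(uni > 0, inter / uni, 0)
  attr(J, "union_empty") <- uni == 0
  J
}

#' Mean coincidence over the rebound window
#'
#' @param ta,tb `trial_tensor` objects.
#' @param windows a [window_spec()].
#' @return scalar mean of the coincidence course over the PMBR window.
#' @export
pmbr_coincidence <- function(ta, tb, windows = window_spec()) {
  J <- coincidence_course(ta, tb)
  in_pmbr <- ta$time_s >= windows$pmbr[1] & ta$time_s < windows$pmbr[2]
  mean(J[in_pmbr])
}
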