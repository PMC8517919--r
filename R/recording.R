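#' Regional recording container
#'
#' A `regional_recording` holds one subject's regional ("virtual sensor")
#' time series: an R x T matrix of real values, one row per atlas region,
#' together with the sampling rate, region labels, clean-epoch boundaries,
#' optional event samples (e.g. button presses) and optional subject-level
#' metadata (group membership, symptom severity score).
#'
#' Epochs are half-open sample intervals `[start, end)` in 1-based sample
#' units, i.e. an epoch `c(1, 1001)` covers samples 1..1000.  Epochs must be
#' sorted, non-overlapping and lie within `[1, T + 1)`.  If no epochs are
#' given the whole recording is treated as a single epoch.
#'
#' @param data numeric matrix, regions x samples; must be finite.
#' @param fs sampling rate in Hz (positive scalar).
#' @param region_labels character vector, one label per row of `data`.
#' @param subject_id subject identifier string.
#' @param group `"patient"` or `"control"` (or `NA` if unknown).
#' @param epochs integer matrix with columns `start`, `end` (half-open,
#'   1-based), or `NULL` for a single whole-record epoch.
#' @param events optional integer vector of event sample indices.
#' @param symptom_score optional non-negative scalar.
#'
#' @return an object of class `regional_recording`.
#' @export
regional_recording <- function(data, fs, region_labels = NULL,
                               subject_id = "subj", group = NA_character_,
                               epochs = NULL, events = NULL,
                               symptom_score = NULL) {
  if (!is.matrix(data) || !is.numeric(data))
    stop("`data` must be a numeric matrix (regions x samples)")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a positive scalar (Hz)")
  R <- nrow(data); T <- ncol(data)
  if (is.null(region_labels))
    region_labels <- sprintf("R%02d", seq_len(R))
  if (length(region_labels) != R)
    stop("length(region_labels) must equal nrow(data): ",
         length(region_labels), " vs ", R)
  if (is.null(epochs)) {
    epochs <- matrix(c(1L, T + 1L), nrow = 1L,
                     dimnames = list(NULL, c("start", "end")))
  } else {
    epochs <- as.matrix(epochs)
    storage.mode(epochs) <- "integer"
    colnames(epochs) <- c("start", "end")
    validate_epochs(epochs, T)
  }
  if (!is.na(group) && !group %in% c("patient", "control"))
    stop("`group` must be \"patient\", \"control\" or NA")
  if (!is.null(events)) {
    events <- as.integer(events)
    if (any(events < 1L | events > T))
      stop("event sample indices outside the recording")
  }
  if (!is.null(symptom_score)) {
    if (!is.numeric(symptom_score) || length(symptom_score) != 1L ||
        symptom_score < 0)
      stop("`symptom_score` must be a non-negative scalar")
  }
  rownames(data) <- region_labels
  structure(list(
    subject_id    = subject_id,
    group         = group,
    fs            = fs,
    region_labels = region_labels,
    data          = data,
    epochs        = epochs,
    events        = events,
    symptom_score = symptom_score
  ), class = "regional_recording")
}

validate_epochs <- function(epochs, T) {
  if (ncol(epochs) != 2L) stop("`epochs` must have two columns (start, end)")
  if (any(epochs[, 2L] <= epochs[, 1L])) stop("epoch end must exceed start")
  if (any(epochs[, 1L] < 1L) || any(epochs[, 2L] > T + 1L))
    stop("epochs outside [1, T+1)")
  if (nrow(epochs) > 1L) {
    if (is.unsorted(epochs[, 1L], strictly = TRUE))
      stop("epochs must be sorted by start")
    if (any(epochs[-1L, 1L] < epochs[-nrow(epochs), 2L]))
      stop("epochs must not overlap")
  }
  invisible(epochs)
}

#' @export
print.regional_recording <- function(x, ...) {
  cat(sprintf("<regional_recording> %s (%s)\n", x$subject_id,
              ifelse(is.na(x$group), "group unknown", x$group)))
  cat(sprintf("  %d regions x %d samples @ %g Hz (%.1f s), %d epoch(s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs,
              nrow(x$epochs)))
  if (!is.null(x$events))
    cat(sprintf("  %d events\n", length(x$events)))
  if (!is.null(x$symptom_score))
    cat(sprintf("  symptom score %.2f\n", x$symptom_score))
  invisible(x)
}

#' Number of samples / regions of a recording
#' @param rec a `regional_recording`.
#' @return integer count.
#' @keywords internal
n_samples <- function(rec) ncol(rec$data)

#' @rdname n_samples
#' @keywords internal
n_regions <- function(rec) nrow(rec$data)
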