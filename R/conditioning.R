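#' Zero-phase Butterworth band-pass filter
#'
#' Filters each region independently with a Butterworth band-pass applied
#' forward and backward (zero phase, so burst timing is not lag-shifted).
#' The band-pass is realised as a cascade of a high-pass at `low_hz` and a
#' low-pass at `high_hz`, each of order `order`; the cascade has the same
#' pass band as a direct band-pass design but is numerically far better
#' behaved when the lower edge is a tiny fraction of Nyquist (e.g. 1 Hz at
#' a 600 Hz rate).
#'
#' @param rec a [regional_recording()].
#' @param low_hz lower band edge in Hz.
#' @param high_hz upper band edge in Hz.
#' @param order Butterworth order (default 4).
#' @return the filtered recording; epoch and event metadata unchanged.
#' @export
bandpass <- function(rec, low_hz, high_hz, order = 4L) {
  stopifnot(inherits(rec, "regional_recording"))
  nyq <- rec$fs / 2
  if (!(0 < low_hz && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2 (Nyquist ",
         nyq, " Hz)")
  hp <- signal::butter(order, low_hz / nyq, type = "high")
  lp <- signal::butter(order, high_hz / nyq, type = "low")
  out <- rec
  for (i in seq_len(nrow(rec$data))) {
    x <- signal::filtfilt(hp, rec$data[i, ])
    out$data[i, ] <- signal::filtfilt(lp, x)
  }
  if (!all(is.finite(out$data)))
    stop("filtering produced non-finite values")
  out
}

#' Multivariate symmetric orthogonalisation (leakage correction)
#'
#' Removes zero-lag linear mixing ("leakage") between regional time
#' courses by replacing them with a set of mutually orthogonal time
#' courses as close as possible to the originals.  Two steps: (1) the
#' closest orthonormal matrix to the data (analytic solution via the polar
#' decomposition); (2) iterative refinement of the vector lengths — given
#' lengths, the closest scaled-orthonormal frame is recomputed, and given
#' the frame, each length is set to the projection of the original time
#' course onto its orthogonal axis — which strictly decreases the
#' Frobenius distance to the input until convergence.
#'
#' @param rec a [regional_recording()]; requires fewer regions than
#'   samples and a full-rank data matrix.
#' @param tol convergence tolerance on the relative change of total vector
#'   length (default 1e-9).
#' @param max_iter iteration cap (default 200).
#' @return the orthogonalised recording, with attributes
#'   `orthogonalize_trace` (Frobenius distance to the input per iteration)
#'   and `orthogonalize_converged`.
#' @export
symmetric_orthogonalize <- function(rec, tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(rec, "regional_recording"))
  X <- t(rec$data)                       # T x R, columns are regions
  X <- sweep(X, 2, colMeans(X))          # centre: output then has exactly
  R <- ncol(X); T <- nrow(X)             # zero pairwise correlation
  if (R > T) stop("more regions than samples; cannot orthogonalise")
  sv <- svd(X)
  if (sv$d[R] < max(sv$d) * 1e-10) {
    cc <- abs(stats::cor(X))
    diag(cc) <- 0
    bad <- which(cc > 1 - 1e-8, arr.ind = TRUE)
    bad <- unique(sort(bad))
    stop("rank-deficient input; offending (collinear) rows: ",
         paste(rec$region_labels[bad], collapse = ", "))
  }
  ## stage 1: closest orthonormal matrix (polar factor)
  P <- sv$u %*% t(sv$v)
  d <- colSums(P * X)                    # projection lengths
  trace <- norm(X - P %*% diag(d), "F")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    d_old <- d
    s2 <- svd(X %*% diag(d))
    P <- s2$u %*% t(s2$v)
    d <- colSums(P * X)
    trace <- c(trace, norm(X - P %*% diag(d), "F"))
    if (sum(abs(d - d_old)) / sum(abs(d)) < tol) { converged <- TRUE; break }
  }
  out <- rec
  out$data <- t(P %*% diag(d))
  rownames(out$data) <- rec$region_labels
  attr(out, "orthogonalize_trace") <- trace
  attr(out, "orthogonalize_converged") <- converged
  out
}

#' Anti-aliased resampling
#'
#' Resamples every region to `target_fs` (downsampling only): a
#' zero-phase 8th-order Butterworth low-pass at 90% of the target Nyquist
#' removes content that would alias, then samples are taken on the target
#' time grid (exact decimation when the ratio is an integer,
#' interpolation otherwise).  Epoch boundaries and event indices are
#' rescaled consistently (rounded to the nearest output sample).
#'
#' @param rec a [regional_recording()].
#' @param target_fs target sampling rate in Hz; must not exceed `rec$fs`.
#' @return the resampled recording.
#' @export
resample_recording <- function(rec, target_fs) {
  stopifnot(inherits(rec, "regional_recording"))
  if (target_fs > rec$fs) stop("upsampling requested (target_fs > fs)")
  if (target_fs == rec$fs) return(rec)
  ratio <- target_fs / rec$fs
  T_old <- ncol(rec$data)
  T_new <- floor(T_old * ratio)
  lp <- signal::butter(8, 0.9 * target_fs / rec$fs, type = "low")
  ## target grid in original sample units (1-based)
  pos <- 1 + (seq_len(T_new) - 1) / ratio
  out <- rec
  newdata <- matrix(0, nrow(rec$data), T_new)
  for (i in seq_len(nrow(rec$data))) {
    y <- signal::filtfilt(lp, rec$data[i, ])
    newdata[i, ] <- stats::approx(seq_len(T_old), y, xout = pos)$y
  }
  rownames(newdata) <- rec$region_labels
  out$data <- newdata
  out$fs <- target_fs
  ## epoch boundaries are half-open positions: boundary b sits before the
  ## sample at time (b-1)/fs; an event index i marks the sample at i/fs
  bound <- function(b) pmax(1L, pmin(T_new + 1L,
                                     as.integer(round((b - 1) * ratio) + 1L)))
  out$epochs <- cbind(start = bound(rec$epochs[, 1L]),
                      end   = bound(rec$epochs[, 2L]))
  if (!is.null(rec$events))
    out$events <- as.integer(pmax(1, pmin(T_new, round(rec$events * ratio))))
  out
}

gcd_int <- function(a, b) if (b == 0) a else gcd_int(b, a %% b)

#' Per-region standardisation
#'
#' Mean-centres and variance-normalises each region (sample variance 1).
#'
#' @param rec a [regional_recording()].
#' @return the standardised recording.
#' @export
standardize <- function(rec) {
  stopifnot(inherits(rec, "regional_recording"))
  sds <- apply(rec$data, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance region(s): ",
         paste(rec$region_labels[sds == 0], collapse = ", "))
  out <- rec
  out$data <- (rec$data - rowMeans(rec$data)) / sds
  out
}

#' Full conditioning pipeline
#'
#' Applies the fixed conditioning sequence: band-pass filter ->
#' symmetric orthogonalisation -> resample -> standardise.
#'
#' @param rec a [regional_recording()].
#' @param low_hz,high_hz band edges in Hz (defaults 1 and 48).
#' @param order Butterworth order (default 4).
#' @param target_fs analysis sampling rate (default 100 Hz).
#' @param orthogonalize apply leakage correction? (default TRUE; synthetic
#'   data generated directly in source space may skip it)
#' @return the conditioned recording.
#' @export
condition_recording <- function(rec, low_hz = 1, high_hz = 48, order = 4L,
                                target_fs = 100, orthogonalize = TRUE) {
  out <- bandpass(rec, low_hz, high_hz, order)
  if (orthogonalize) out <- symmetric_orthogonalize(out)
  if (target_fs < out$fs) out <- resample_recording(out, target_fs)
  standardize(out)
}
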