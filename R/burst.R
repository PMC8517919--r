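#' Beta-band Morlet amplitude envelope
#'
#' Continuous Morlet wavelet transform of one regional series, stepped at
#' 1 Hz through the band, returning the modulus averaged across
#' frequencies.  The wavelet is realised as an analytic Gaussian filter in
#' the frequency domain with spectral SD `f / cycles` (the frequency-domain
#' picture of a `cycles`-cycle Morlet), normalised so a unit-amplitude
#' sinusoid at a centre frequency yields a per-frequency modulus of ~1
#' there (the band average is smaller, since off-centre frequencies
#' respond less).
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz; must be at least twice the band's upper
#'   edge.
#' @param band frequency band in Hz (default `c(13, 30)`, beta).
#' @param cycles wavelet width in cycles (default 7).
#' @param step frequency step through the band in Hz (default 1).
#' @return object of class `beta_envelope`: list with `env` (non-negative
#'   series, same length as `x`), `band`, `cycles`, `fs`.
#' @export
beta_envelope <- function(x, fs, band = c(13, 30), cycles = 7, step = 1) {
  if (band[2] > fs / 2)
    stop("band upper edge above Nyquist (", fs / 2, " Hz)")
  n <- length(x)
  freqs <- seq(band[1], band[2], by = step)
  xf <- stats::fft(x)
  fax <- (seq_len(n) - 1) * fs / n        # FFT bin frequencies
  env <- numeric(n)
  for (f0 in freqs) {
    sigma_f <- f0 / cycles
    H <- 2 * exp(-(fax - f0)^2 / (2 * sigma_f^2))
    H[fax > fs / 2] <- 0                  # analytic: kill negative freqs
    coef <- stats::fft(xf * H, inverse = TRUE) / n
    env <- env + Mod(coef)
  }
  structure(list(env = env / length(freqs), band = band, cycles = cycles,
                 fs = fs), class = "beta_envelope")
}

#' Identify the burst state
#'
#' The burst state is the HMM state whose probability time course
#' correlates highest (Pearson) with the beta amplitude envelope.  States
#' with an undefined correlation (constant probability course) are
#' excluded; ties at machine precision go to the lower state index (with a
#' message).
#'
#' @param posterior a `state_posterior`.
#' @param env a `beta_envelope` on the same time base.
#' @return integer state index with attribute `correlations` (one value
#'   per state, `NA` where undefined).
#' @export
select_burst_state <- function(posterior, env) {
  stopifnot(inherits(posterior, "state_posterior"),
            inherits(env, "beta_envelope"))
  if (length(env$env) != ncol(posterior$gamma))
    stop("envelope and state posteriors are on different time bases")
  v <- posterior$valid
  cors <- vapply(seq_len(posterior$n_states), function(k) {
    g <- posterior$gamma[k, v]
    if (stats::sd(g) == 0 || stats::sd(env$env[v]) == 0) return(NA_real_)
    stats::cor(g, env$env[v])
  }, 0)
  if (all(is.na(cors)))
    stop("correlation undefined for every state (constant inputs)")
  best <- which(cors == max(cors, na.rm = TRUE))
  if (length(best) > 1)
    message("burst-state correlation tie between states ",
            paste(best, collapse = ", "), "; selecting state ", min(best))
  structure(min(best), correlations = cors)
}

#' Binarise a state probability course into a burst train
#'
#' A sample is in a burst iff the selected state's probability strictly
#' exceeds the threshold (default two thirds).  Visits are maximal runs of
#' burst samples within an epoch; no visit spans an epoch boundary.
#' Samples with undefined posterior (embedding edges) count as non-burst.
#'
#' @param posterior a `state_posterior`.
#' @param state state index (from [select_burst_state()]).
#' @param threshold probability threshold in (0, 1); default `2/3`.
#' @return object of class `burst_train`: list with `b` (0/1 integer
#'   vector), `visits` (matrix with columns `start`, `end`, half-open,
#'   1-based), `fs`, `region_id`.
#' @export
binarize_posterior <- function(posterior, state, threshold = 2 / 3) {
  stopifnot(inherits(posterior, "state_posterior"))
  if (!(threshold > 0 && threshold < 1)) stop("threshold must be in (0,1)")
  g <- posterior$gamma[state, ]
  b <- as.integer(!is.na(g) & g > threshold)
  burst_train(b, posterior$fs, epochs = posterior$epochs,
              region_id = posterior$region_id)
}

#' Construct a burst train from a binary series
#'
#' @param b 0/1 vector of burst indicators.
#' @param fs sampling rate in Hz.
#' @param epochs optional epoch matrix; runs are split at epoch
#'   boundaries.
#' @param region_id label.
#' @return a `burst_train`.
#' @export
burst_train <- function(b, fs, epochs = NULL, region_id = "region") {
  b <- as.integer(b != 0)
  T <- length(b)
  if (is.null(epochs)) epochs <- matrix(c(1L, T + 1L), 1L)
  visits <- list()
  for (e in seq_len(nrow(epochs))) {
    idx <- epochs[e, 1]:(epochs[e, 2] - 1L)
    r <- rle(b[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- r$values == 1L
    if (any(on))
      visits[[length(visits) + 1L]] <-
        cbind(start = idx[1] + starts[on] - 1L,
              end   = idx[1] + ends[on])       # half-open
  }
  visits <- if (length(visits)) do.call(rbind, visits) else
    matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end")))
  structure(list(region_id = region_id, b = b, visits = visits, fs = fs),
            class = "burst_train")
}

#' Visits from a ground-truth table
#'
#' Builds a `burst_train` directly from planted visit intervals (e.g. the
#' generator's ground truth), bypassing detection.
#'
#' @param visits matrix/data.frame with `start`, `end` columns (half-open).
#' @param T series length in samples.
#' @param fs sampling rate.
#' @param region_id label.
#' @return a `burst_train`.
#' @export
train_from_visits <- function(visits, T, fs, region_id = "region") {
  b <- integer(T)
  if (NROW(visits) > 0)
    for (k in seq_len(NROW(visits)))
      b[visits[k, "start"]:(visits[k, "end"] - 1L)] <- 1L
  burst_train(b, fs, region_id = region_id)
}

#' Summary burst metrics for one region
#'
#' Computes the resting-state burst metrics: burst amplitude (mean over
#' visits of the per-visit maximum of the beta envelope), non-burst
#' amplitude (mean envelope over non-burst samples), total burst time
#' (fraction of the recording spent in the burst state), mean visit
#' duration, and visit count rate.
#'
#' @param train a `burst_train`.
#' @param env a `beta_envelope` aligned with the train.
#' @return object of class `burst_summary`: list with fields
#'   `burst_amplitude` (`NA` with `amplitude_defined = FALSE` if there are
#'   no visits), `nonburst_amplitude`, `total_burst_time`,
#'   `mean_duration_s`, `count_rate_hz`, `n_visits`, `region_id`.
#' @export
burst_summary <- function(train, env) {
  stopifnot(inherits(train, "burst_train"), inherits(env, "beta_envelope"))
  if (length(env$env) != length(train$b))
    stop("train and envelope lengths differ")
  T <- length(train$b)
  dur_s <- T / train$fs
  nv <- nrow(train$visits)
  tbt <- sum(train$visits[, "end"] - train$visits[, "start"]) / T
  if (nv > 0) {
    vmax <- vapply(seq_len(nv), function(k)
      max(env$env[train$visits[k, "start"]:(train$visits[k, "end"] - 1L)]), 0)
    amp <- mean(vmax)
    mean_dur <- mean(train$visits[, "end"] - train$visits[, "start"]) /
      train$fs
    defined <- TRUE
  } else {
    amp <- NA_real_; mean_dur <- NA_real_; defined <- FALSE
  }
  nb <- train$b == 0L
  nonburst <- if (any(nb)) mean(env$env[nb]) else NA_real_
  structure(list(region_id = train$region_id,
                 burst_amplitude = amp, nonburst_amplitude = nonburst,
                 total_burst_time = tbt, mean_duration_s = mean_dur,
                 count_rate_hz = nv / dur_s, n_visits = nv,
                 amplitude_defined = defined),
            class = "burst_summary")
}

#' Collapse per-region burst metrics to per-subject global means
#'
#' Unweighted mean across regions for each metric; regions whose amplitude
#' is undefined (no visits) are excluded from the amplitude means and
#' counted.
#'
#' @param summaries list of `burst_summary`, one per region.
#' @return named list with `burst_amplitude`, `nonburst_amplitude`,
#'   `total_burst_time`, `mean_duration_s`, `count_rate_hz`,
#'   `n_excluded_amplitude`.
#' @export
global_collapse <- function(summaries) {
  stopifnot(length(summaries) > 0)
  get <- function(f) vapply(summaries, `[[`, 0, f)
  amp <- get("burst_amplitude")
  n_und <- sum(is.na(amp))
  if (all(is.na(amp)))
    stop("burst amplitude undefined in every region")
  if (n_und > 0)
    message(n_und, " region(s) with undefined amplitude excluded from ",
            "the global amplitude mean")
  list(burst_amplitude = mean(amp, na.rm = TRUE),
       nonburst_amplitude = mean(get("nonburst_amplitude"), na.rm = TRUE),
       total_burst_time = mean(get("total_burst_time")),
       mean_duration_s = mean(get("mean_duration_s"), na.rm = TRUE),
       count_rate_hz = mean(get("count_rate_hz")),
       n_excluded_amplitude = n_und)
}

#' Detect bursts in a conditioned recording
#'
#' Runs the full per-region burst detection for one subject: fit the
#' time-delay-embedded HMM to each regional series independently, compute
#' the beta envelope, pick the burst state (highest correlation between
#' state probability and envelope), and binarise at the threshold.
#'
#' @param rec conditioned [regional_recording()].
#' @param config an [hmm_config()].
#' @param band,cycles envelope parameters.
#' @param threshold binarisation threshold (default `2/3`).
#' @return list with `trains` (list of `burst_train`), `envelopes`,
#'   `summaries` (per-region `burst_summary`), `posteriors`,
#'   `burst_states` (selected index per region).
#' @export
detect_bursts <- function(rec, config = hmm_config(), band = c(13, 30),
                          cycles = 7, threshold = 2 / 3) {
  stopifnot(inherits(rec, "regional_recording"))
  R <- nrow(rec$data)
  trains <- envs <- sums <- posts <- vector("list", R)
  states <- integer(R)
  for (i in seq_len(R)) {
    x <- rec$data[i, ]
    post <- fit_tdehmm(x, rec$fs, config, epochs = rec$epochs,
                       region_id = rec$region_labels[i])
    env <- beta_envelope(x, rec$fs, band, cycles)
    st <- select_burst_state(post, env)
    tr <- binarize_posterior(post, st, threshold)
    trains[[i]] <- tr; envs[[i]] <- env; posts[[i]] <- post
    states[i] <- st
    sums[[i]] <- burst_summary(tr, env)
  }
  names(trains) <- names(envs) <- names(sums) <- rec$region_labels
  list(trains = trains, envelopes = envs, summaries = sums,
       posteriors = posts, burst_states = states)
}
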