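#' Simulation configuration
#'
#' Builds the configuration for the synthetic regional-recording generator.
#' The generator emulates source-space electrophysiological data in which
#' apparently sustained band-limited power arises from transient,
#' pan-spectral burst events riding on 1/f background noise: each burst is
#' an amplitude-modulated carrier packet (carrier frequency drawn uniformly
#' from `carrier_band`, Tukey-windowed) plus a small broadband transient.
#' Bursts are placed by a point process; pairwise burst co-occurrence is
#' planted through shared events so that the coincidence (Jaccard) ground
#' truth is controlled directly.
#'
#' Group effects are planted multiplicatively for subjects labelled
#' `"patient"`: burst amplitudes are scaled by `group_amplitude_factor`,
#' pairwise co-occurrence probabilities by `group_coincidence_factor`, and
#' (task data only) the movement-locked modulation depth by
#' `group_modulation_factor`.  Burst occupancy is left untouched, so
#' patients differ in burst strength and coordination but not in how often
#' they burst.
#'
#' Between-subject variability is introduced by per-subject log-normal
#' scales on burst amplitude and on co-occurrence probability
#' (`subject_sd`, standard deviation on the log scale); the per-subject
#' co-occurrence scale doubles as the planted severity covariate used by
#' [sample_symptom_scores()].
#'
#' @param n_regions number of regions (default 78).  Regions are generated
#'   in homologous left/right pairs labelled `"R01_L", "R01_R", ...`.
#' @param fs sampling rate in Hz (default 100, the analysis rate).
#' @param epoch_length_s length of one clean epoch in seconds (default 10).
#' @param n_epochs number of epochs per resting recording (default 24).
#' @param burst_rate_hz expected burst visits per second per region
#'   (default 1.2; with the default mean duration this yields ~30% burst
#'   occupancy).
#' @param burst_duration_s list with `mean` (seconds) and `cv` (coefficient
#'   of variation) of the log-normal visit-duration distribution.
#' @param burst_amplitude scale of burst packets relative to the
#'   unit-variance background (default 3).
#' @param coincidence_matrix region x region symmetric matrix of planted
#'   pairwise co-occurrence probabilities in `[0, 1]` with unit diagonal,
#'   or `NULL` for the default structure (0.25 between homologous pairs, 0
#'   elsewhere).  Row sums of off-diagonal entries must not exceed 1.
#' @param group_amplitude_factor multiplicative burst-amplitude factor for
#'   patients (default 0.8).
#' @param group_coincidence_factor multiplicative co-occurrence factor for
#'   patients (default 0.7).
#' @param group_modulation_factor multiplicative factor on the
#'   movement-locked modulation depth (`multiplier - 1`) for patients
#'   (default 0.6; task data only).
#' @param task_profile data frame with columns `t_lo`, `t_hi`, `mult`
#'   giving the burst-probability multiplier in windows relative to a
#'   button press; the multiplier is 1 outside all windows.  Default:
#'   0.2 in (-0.3, 0.1) s (movement-related suppression) and 2.0 in
#'   (0.45, 0.85) s (post-movement rebound).
#' @param noise_exponent spectral slope alpha of the 1/f^alpha background
#'   (default 1).
#' @param carrier_band burst carrier frequency range in Hz (default
#'   `c(13, 30)`, beta-dominant).
#' @param subject_sd log-scale SD of per-subject amplitude and coincidence
#'   scales (default 0.15).
#' @param seed integer seed (default 1).
#'
#' @return a list of class `sim_config` with all defaults materialised.
#' @export
sim_config <- function(n_regions = 78, fs = 100, epoch_length_s = 10,
                       n_epochs = 24, burst_rate_hz = 1.2,
                       burst_duration_s = list(mean = 0.3, cv = 0.5),
                       burst_amplitude = 3, coincidence_matrix = NULL,
                       group_amplitude_factor = 0.8,
                       group_coincidence_factor = 0.7,
                       group_modulation_factor = 0.6,
                       task_profile = default_task_profile(),
                       noise_exponent = 1, carrier_band = c(13, 30),
                       subject_sd = 0.15, seed = 1L) {
  if (fs <= 0) stop("fs must be positive")
  if (n_regions < 1) stop("n_regions must be >= 1")
  if (carrier_band[2] >= fs / 2)
    stop("carrier_band upper edge must be below Nyquist")
  if (is.null(coincidence_matrix))
    coincidence_matrix <- homologous_coincidence(n_regions, 0.25)
  C <- coincidence_matrix
  if (!isTRUE(all.equal(C, t(C))) || any(diag(C) != 1) ||
      any(C < 0) || any(C > 1))
    stop("coincidence_matrix must be symmetric in [0,1] with unit diagonal")
  off_rowsum <- rowSums(C) - diag(C)
  if (any(off_rowsum > 1 + 1e-12))
    stop("off-diagonal row sums of coincidence_matrix must be <= 1 ",
         "(shared-event budget)")
  if (burst_rate_hz < 0) stop("burst_rate_hz must be >= 0")
  occ <- burst_rate_hz * burst_duration_s$mean
  if (occ >= 1)
    stop("occupancy saturation: burst_rate_hz x mean duration = ",
         signif(occ, 3), " >= 1; rejected config")
  stopifnot(is.data.frame(task_profile),
            all(c("t_lo", "t_hi", "mult") %in% names(task_profile)))
  structure(list(
    n_regions = as.integer(n_regions), fs = fs,
    epoch_length_s = epoch_length_s, n_epochs = as.integer(n_epochs),
    burst_rate_hz = burst_rate_hz, burst_duration_s = burst_duration_s,
    burst_amplitude = burst_amplitude, coincidence_matrix = C,
    group_amplitude_factor = group_amplitude_factor,
    group_coincidence_factor = group_coincidence_factor,
    group_modulation_factor = group_modulation_factor,
    task_profile = task_profile, noise_exponent = noise_exponent,
    carrier_band = carrier_band, subject_sd = subject_sd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Default movement-locked burst-probability profile
#'
#' Suppression (x0.2) around the button press and elevation (x2.0) in the
#' post-movement rebound window.
#' @return data frame with columns `t_lo`, `t_hi`, `mult` (seconds).
#' @export
default_task_profile <- function() {
  data.frame(t_lo = c(-0.3, 0.45), t_hi = c(0.1, 0.85), mult = c(0.2, 2.0))
}

#' Homologous-pair coincidence matrix
#'
#' Unit diagonal, `p` between members of each consecutive (left, right)
#' region pair, 0 elsewhere — the planted analogue of the empirically
#' dominant homologous (interhemispheric) burst coordination.
#' @param n_regions region count.
#' @param p planted co-occurrence probability for homologous pairs.
#' @return `n_regions` x `n_regions` matrix.
#' @export
homologous_coincidence <- function(n_regions, p = 0.25) {
  C <- diag(1, n_regions)
  if (n_regions >= 2) {
    k <- seq(1L, n_regions - 1L, by = 2L)
    C[cbind(k, k + 1L)] <- p
    C[cbind(k + 1L, k)] <- p
  }
  C
}

#' Dense coincidence matrix with a homologous gradient
#'
#' Baseline co-occurrence `base` between every region pair, raised to
#' `hom` for homologous (left, right) pairs — plants coordination across
#' the whole connectome, strongest interhemispherically, so that a
#' multiplicative group factor produces a globally reduced connectome.
#' Requires `base * (n_regions - 2) + hom <= 1` (shared-event budget).
#'
#' @param n_regions region count.
#' @param base baseline pairwise co-occurrence (default 0.12).
#' @param hom homologous-pair co-occurrence (default 0.25).
#' @return `n_regions` x `n_regions` matrix.
#' @export
all_pairs_coincidence <- function(n_regions, base = 0.12, hom = 0.25) {
  C <- matrix(base, n_regions, n_regions)
  diag(C) <- 1
  H <- homologous_coincidence(n_regions, hom)
  C[H == hom] <- hom
  C
}

sim_region_labels <- function(n_regions) {
  pair <- ceiling(seq_len(n_regions) / 2)
  side <- ifelse(seq_len(n_regions) %% 2 == 1, "L", "R")
  sprintf("R%02d_%s", pair, side)
}

lnorm_pars <- function(mean, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

## 1/f^alpha coloured noise, unit variance, length n
colored_noise <- function(n, fs, alpha) {
  nf <- n %/% 2
  f <- seq_len(nf) * fs / n
  amp <- f^(-alpha / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = amp, argument = ph)
  full <- complex(real = numeric(n))
  full[2:(nf + 1)] <- spec
  if (n %% 2 == 0) {
    full[nf + 1] <- complex(real = amp[nf] * cos(ph[nf]))
    full[seq(n, nf + 2)] <- Conj(spec[seq_len(nf - 1)])
  } else {
    full[seq(n, nf + 1)] <- Conj(spec)
  }
  x <- Re(stats::fft(full, inverse = TRUE))
  as.numeric(scale(x))
}

## Tukey (tapered cosine) window, taper fraction a
tukey_window <- function(n, a = 0.5) {
  if (n == 1) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  lo <- t < a / 2
  hi <- t > 1 - a / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / a - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (t[hi] - 1) / a + 1)))
  w
}

## One burst packet: Tukey-windowed carrier plus a small broadband
## transient, peak amplitude `amp`
burst_packet <- function(n, fs, amp, carrier_band) {
  f <- stats::runif(1, carrier_band[1], carrier_band[2])
  ph <- stats::runif(1, 0, 2 * pi)
  t <- seq_len(n) / fs
  w <- tukey_window(n, 0.5)
  amp * w * (sin(2 * pi * f * t + ph) + 0.3 * stats::rnorm(n))
}

## Candidate burst events for one subject: shared pair pools plus
## independent per-region pools.  Returns data.frame(region, start_s, dur_s,
## event_id) where shared events appear once per member region with a
## common event_id and duration.
draw_events <- function(config, C, duration_s) {
  rate <- config$burst_rate_hz
  R <- config$n_regions
  dp <- lnorm_pars(config$burst_duration_s$mean, config$burst_duration_s$cv)
  ev <- list(); eid <- 0L
  pairs <- which(upper.tri(C) & C > 0, arr.ind = TRUE)
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      m <- stats::rpois(1, rate * C[i, j] * duration_s)
      if (m == 0) next
      st <- stats::runif(m, 0, duration_s)
      du <- stats::rlnorm(m, dp$meanlog, dp$sdlog)
      ids <- eid + seq_len(m); eid <- eid + m
      ev[[length(ev) + 1L]] <- data.frame(
        region = rep(c(i, j), each = m), start_s = rep(st, 2),
        dur_s = rep(du, 2), event_id = rep(ids, 2))
    }
  }
  ind_rate <- pmax(0, rate * (1 - (rowSums(C) - diag(C))))
  for (i in seq_len(R)) {
    m <- stats::rpois(1, ind_rate[i] * duration_s)
    if (m == 0) next
    st <- stats::runif(m, 0, duration_s)
    du <- stats::rlnorm(m, dp$meanlog, dp$sdlog)
    ids <- eid + seq_len(m); eid <- eid + m
    ev[[length(ev) + 1L]] <- data.frame(
      region = i, start_s = st, dur_s = du, event_id = ids)
  }
  if (length(ev) == 0)
    return(data.frame(region = integer(), start_s = numeric(),
                      dur_s = numeric(), event_id = integer()))
  do.call(rbind, ev)
}

## Convert per-region events into non-overlapping sample-domain visits
## clipped at epoch boundaries; hard-core thinning drops events starting
## inside an active visit.
events_to_visits <- function(events, config, amp_scale, T) {
  fs <- config$fs
  ep_len <- round(config$epoch_length_s * fs)
  out <- list()
  for (i in sort(unique(events$region))) {
    e <- events[events$region == i, , drop = FALSE]
    e <- e[order(e$start_s), , drop = FALSE]
    start <- floor(e$start_s * fs) + 1L
    len <- pmax(2L, round(e$dur_s * fs))
    end <- start + len                          # half-open
    ## clip at epoch boundary (no visit spans an epoch boundary)
    ep_end <- (ceiling(start / ep_len)) * ep_len + 1L
    end <- pmin(end, ep_end, T + 1L)
    keep <- end - start >= 2L
    start <- start[keep]; end <- end[keep]
    ids <- e$event_id[keep]
    if (length(start) == 0) next
    ## merge overlapping events into one visit (keeps visits disjoint)
    m_start <- integer(0); m_end <- integer(0); m_id <- integer(0)
    cs <- start[1]; ce <- end[1]; ci <- ids[1]
    if (length(start) > 1) {
      for (k in 2:length(start)) {
        if (start[k] < ce) {
          ce <- max(ce, end[k])
        } else {
          m_start <- c(m_start, cs); m_end <- c(m_end, ce)
          m_id <- c(m_id, ci)
          cs <- start[k]; ce <- end[k]; ci <- ids[k]
        }
      }
    }
    m_start <- c(m_start, cs); m_end <- c(m_end, ce); m_id <- c(m_id, ci)
    start <- m_start; end <- m_end; ids <- m_id
    amp <- config$burst_amplitude * amp_scale *
      stats::rlnorm(length(start), -0.02, 0.2)
    out[[length(out) + 1L]] <- data.frame(
      region = i, start = start, end = end, amplitude = amp,
      event_id = ids)
  }
  if (length(out) == 0)
    return(data.frame(region = integer(), start = integer(),
                      end = integer(), amplitude = numeric(),
                      event_id = integer()))
  do.call(rbind, out)
}

## Render one subject's data matrix: coloured background plus burst packets
render_subject <- function(visits, config, T) {
  R <- config$n_regions
  X <- matrix(0, R, T)
  for (i in seq_len(R))
    X[i, ] <- colored_noise(T, config$fs, config$noise_exponent)
  if (nrow(visits) > 0) {
    for (k in seq_len(nrow(visits))) {
      i <- visits$region[k]
      idx <- visits$start[k]:(visits$end[k] - 1L)
      X[i, idx] <- X[i, idx] +
        burst_packet(length(idx), config$fs, visits$amplitude[k],
                     config$carrier_band)
    }
  }
  X
}

subject_scales <- function(config, group) {
  amp <- stats::rlnorm(1, 0, config$subject_sd) *
    if (group == "patient") config$group_amplitude_factor else 1
  conn <- stats::rlnorm(1, 0, config$subject_sd) *
    if (group == "patient") config$group_coincidence_factor else 1
  list(amp = amp, conn = min(conn, 1 / max(1e-12,
    max(rowSums(config$coincidence_matrix) -
        diag(config$coincidence_matrix)))))
}

#' Simulate resting-state recordings with planted burst structure
#'
#' Generates `n_per_group` control and `n_per_group` patient subjects.
#' Each recording is `n_epochs` x `epoch_length_s` seconds of
#' unit-variance 1/f background plus planted burst packets; pairwise burst
#' co-occurrence follows `coincidence_matrix` (scaled per subject and by
#' the patient coincidence factor), and no planted visit spans an epoch
#' boundary.  The ground truth (visit intervals, per-visit amplitudes,
#' planted co-occurrence, per-subject scales) is returned alongside.
#'
#' @param config a [sim_config()].
#' @param n_per_group subjects per group (>= 1).
#' @return list with elements `recordings` (list of
#'   [regional_recording()]) and `ground_truth` (class
#'   `burst_ground_truth`: per-subject list with `visits` data frame
#'   (`region`, `start`, `end`, `amplitude`, `event_id`; half-open sample
#'   intervals), `group`, `amp_scale`, `conn_scale`, and the subject's
#'   planted `coincidence` matrix).
#' @export
simulate_resting <- function(config, n_per_group) {
  stopifnot(inherits(config, "sim_config"), n_per_group >= 1)
  set.seed(config$seed)
  T <- round(config$epoch_length_s * config$fs) * config$n_epochs
  duration_s <- T / config$fs
  labels <- sim_region_labels(config$n_regions)
  ep_len <- round(config$epoch_length_s * config$fs)
  epochs <- cbind(start = seq(1L, T, by = ep_len),
                  end = seq(ep_len + 1L, T + 1L, by = ep_len))
  groups <- rep(c("control", "patient"), each = n_per_group)
  recs <- vector("list", length(groups))
  gt <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    sc <- subject_scales(config, groups[s])
    C <- config$coincidence_matrix * sc$conn
    diag(C) <- 1
    events <- draw_events(config, C, duration_s)
    visits <- events_to_visits(events, config, sc$amp, T)
    X <- render_subject(visits, config, T)
    id <- sprintf("%s%02d", ifelse(groups[s] == "patient", "P", "C"),
                  ((s - 1L) %% n_per_group) + 1L)
    recs[[s]] <- regional_recording(X, config$fs, labels, subject_id = id,
                                    group = groups[s], epochs = epochs)
    gt[[s]] <- list(subject_id = id, group = groups[s], visits = visits,
                    amp_scale = sc$amp, conn_scale = sc$conn,
                    coincidence = C, T = T)
  }
  names(gt) <- vapply(gt, `[[`, "", "subject_id")
  structure(list(recordings = recs,
                 ground_truth = structure(gt, class = "burst_ground_truth")),
            class = "resting_simulation")
}

## piecewise-constant multiplier of the movement-locked profile at lag t (s)
profile_mult <- function(profile, t) {
  m <- rep(1, length(t))
  for (k in seq_len(nrow(profile))) {
    inside <- t >= profile$t_lo[k] & t < profile$t_hi[k]
    m[inside] <- profile$mult[k]
  }
  m
}

#' Simulate motor-task recordings with movement-locked burst modulation
#'
#' Each subject's recording contains `n_trials` button-press events.  Burst
#' candidates are generated as at rest (including shared coincidence
#' pools), then thinned according to the movement-locked profile evaluated
#' at the candidate's midpoint lag relative to the nearest event: the
#' planted burst probability is suppressed around the press and elevated
#' in the rebound window.  Patients additionally have their modulation
#' depth scaled by `group_modulation_factor` (blunted movement-locked
#' dynamics).  Thinning decisions are taken per shared event, so planted
#' coincidence survives the modulation.
#'
#' @param config a [sim_config()]; `task_profile` must cover lags within
#'   (-3, 3) s.
#' @param n_trials trials per subject (>= 1).
#' @param n_per_group subjects per group.
#' @return as [simulate_resting()], with `events` set on each recording
#'   and per-subject planted profile stored in the ground truth.
#' @export
simulate_task <- function(config, n_trials, n_per_group) {
  stopifnot(inherits(config, "sim_config"), n_per_group >= 1)
  if (n_trials < 1) stop("n_trials must be >= 1")
  prof <- config$task_profile
  if (any(prof$t_lo < -3) || any(prof$t_hi > 3))
    stop("task_profile windows must lie within the (-3, 3) s trial window")
  set.seed(config$seed + 1L)
  fs <- config$fs
  spacing_s <- 7                       # 6 s trial window + 1 s guard
  T <- round((n_trials * spacing_s + 6) * fs)
  duration_s <- T / fs
  labels <- sim_region_labels(config$n_regions)
  event_t <- 3 + spacing_s * (seq_len(n_trials) - 1) +
    stats::runif(n_trials, 0, 0.4)
  groups <- rep(c("control", "patient"), each = n_per_group)
  max_mult <- max(1, prof$mult)
  recs <- vector("list", length(groups))
  gt <- vector("list", length(groups))
  for (s in seq_along(groups)) {
    sc <- subject_scales(config, groups[s])
    mod_f <- if (groups[s] == "patient") config$group_modulation_factor else 1
    sprof <- prof
    sprof$mult <- 1 + (prof$mult - 1) * mod_f
    C <- config$coincidence_matrix * sc$conn
    diag(C) <- 1
    ## candidates at inflated rate, then profile thinning at the midpoint
    cfg_inflated <- config
    cfg_inflated$burst_rate_hz <- config$burst_rate_hz * max_mult
    events <- draw_events(cfg_inflated, C, duration_s)
    if (nrow(events) > 0) {
      ids <- unique(events$event_id)
      mid <- (events$start_s + events$dur_s / 2)[match(ids, events$event_id)]
      lag <- vapply(mid, function(tt) {
        d <- tt - event_t
        d[which.min(abs(d))]
      }, 0)
      keep_p <- profile_mult(sprof, lag) / max_mult
      keep_ids <- ids[stats::runif(length(ids)) < keep_p]
      events <- events[events$event_id %in% keep_ids, , drop = FALSE]
    }
    ## single whole-record epoch: task recordings are continuous
    cfg_noep <- config
    cfg_noep$epoch_length_s <- duration_s
    visits <- events_to_visits(events, cfg_noep, sc$amp, T)
    X <- render_subject(visits, config, T)
    id <- sprintf("%s%02d", ifelse(groups[s] == "patient", "P", "C"),
                  ((s - 1L) %% n_per_group) + 1L)
    recs[[s]] <- regional_recording(
      X, fs, labels, subject_id = id, group = groups[s],
      events = round(event_t * fs))
    gt[[s]] <- list(subject_id = id, group = groups[s], visits = visits,
                    amp_scale = sc$amp, conn_scale = sc$conn,
                    coincidence = C, profile = sprof,
                    event_samples = round(event_t * fs), T = T)
  }
  names(gt) <- vapply(gt, `[[`, "", "subject_id")
  structure(list(recordings = recs,
                 ground_truth = structure(gt, class = "burst_ground_truth")),
            class = "task_simulation")
}

#' Planted severity scores from the simulation ground truth
#'
#' Draws one symptom-severity score per subject with a monotonically
#' decreasing relationship to the planted connectivity covariate (the
#' per-subject co-occurrence scale): `score = baseline - slope * covariate
#' + N(0, noise_sd)`, truncated below at 0.  With planted group effects,
#' patients (lower covariate) score stochastically higher.
#'
#' @param ground_truth a `burst_ground_truth`.
#' @param slope positive slope of the decreasing relationship (default 10).
#' @param noise_sd Gaussian noise SD (default 2).
#' @param baseline intercept (default 15).
#' @param seed integer seed.
#' @return named numeric vector of scores (one per subject).
#' @export
sample_symptom_scores <- function(ground_truth, slope = 10, noise_sd = 2,
                                  baseline = 15, seed = 1L) {
  stopifnot(inherits(ground_truth, "burst_ground_truth"))
  set.seed(seed)
  cov <- vapply(ground_truth, `[[`, 0, "conn_scale")
  sc <- baseline - slope * cov + stats::rnorm(length(cov), 0, noise_sd)
  pmax(sc, 0)
}

#' Planted burst occupancy from ground truth
#'
#' Fraction of samples covered by planted visits, per region or averaged.
#' @param gt_subject one element of a `burst_ground_truth`.
#' @param per_region return per-region values instead of the mean?
#' @return occupancy in `[0, 1]`.
#' @export
planted_occupancy <- function(gt_subject, per_region = FALSE) {
  v <- gt_subject$visits
  T <- gt_subject$T
  regions <- sort(unique(v$region))
  if (length(regions) == 0) return(if (per_region) numeric(0) else 0)
  occ <- vapply(regions, function(i) {
    vi <- v[v$region == i, ]
    sum(vi$end - vi$start) / T
  }, 0)
  if (per_region) stats::setNames(occ, regions) else mean(occ)
}
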