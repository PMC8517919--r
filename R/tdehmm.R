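#' HMM configuration for time-delay-embedded burst detection
#'
#' @param n_states number of hidden states (default 3).
#' @param window_s embedding window duration in seconds (default 0.230);
#'   `round(window_s * fs)` must be an odd lag count >= 3.
#' @param inference `"em"` (maximum-likelihood EM, the default) — see the
#'   methods vignette for the rationale.
#' @param max_iter EM iteration cap (default 100).
#' @param tol relative objective-change convergence tolerance
#'   (default 1e-6).
#' @param n_restarts random restarts; the fit with the best final
#'   objective is kept (default 3).
#' @param seed integer seed controlling initialisation.
#' @param cov_reg ridge added to a state covariance when it collapses
#'   (default 1e-6, relative to mean embedded-space variance).
#' @return list of class `hmm_config`.
#' @export
hmm_config <- function(n_states = 3L, window_s = 0.230, inference = "em",
                       max_iter = 100L, tol = 1e-6, n_restarts = 3L,
                       seed = 1L, cov_reg = 1e-6) {
  if (n_states < 2) stop("n_states must be >= 2")
  inference <- match.arg(inference, "em")
  structure(list(n_states = as.integer(n_states), window_s = window_s,
                 inference = inference, max_iter = as.integer(max_iter),
                 tol = tol, n_restarts = as.integer(n_restarts),
                 seed = as.integer(seed), cov_reg = cov_reg),
            class = "hmm_config")
}

#' Time-delay embedding of a univariate series
#'
#' Builds the L x T' lag-embedded matrix whose column `t` holds the series
#' values at lags `-(L-1)/2 .. (L-1)/2` around sample `t + (L-1)/2`, so a
#' Gaussian state over the embedded space is characterised by an
#' autocovariance pattern over a window of `window_s` seconds.
#'
#' @param x numeric vector.
#' @param fs sampling rate in Hz.
#' @param window_s window duration in seconds; `L = round(window_s * fs)`
#'   must be odd and >= 3.
#' @return L x T' matrix (`T' = length(x) - L + 1`) with attribute
#'   `offset` such that embedded column `t` is centred on original sample
#'   `t + offset` (`offset = (L-1)/2`).
#' @export
tde_embed <- function(x, fs, window_s) {
  L <- as.integer(round(window_s * fs))
  if (L < 3L) stop("embedding window shorter than 3 samples")
  if (L %% 2L == 0L)
    stop("window_s * fs rounds to an even lag count (", L,
         "); choose a window giving an odd count")
  T <- length(x)
  if (T <= L) stop("series shorter than the embedding window")
  Tp <- T - L + 1L
  Y <- matrix(0, L, Tp)
  for (l in seq_len(L)) Y[l, ] <- x[l:(l + Tp - 1L)]
  attr(Y, "offset") <- (L - 1L) %/% 2L
  Y
}

## Scaled forward-backward.  logB: K x T emission log-likelihoods.
## Returns gamma (K x T), xi_sum (K x K summed over transitions), loglik.
#' Forward-backward smoothing for a hidden Markov chain
#'
#' Numerically scaled recursion over one observation segment.
#'
#' @param logB K x T matrix of per-state observation log-likelihoods.
#' @param pi0 initial state distribution (length K).
#' @param A K x K row-stochastic transition matrix.
#' @return list with `gamma` (K x T posterior marginals), `xi_sum`
#'   (K x K expected transition counts), `loglik`.
#' @export
forward_backward <- function(logB, pi0, A) {
  K <- nrow(logB); T <- ncol(logB)
  offs <- apply(logB, 2, max)
  B <- exp(sweep(logB, 2, offs))
  alpha <- matrix(0, K, T); beta <- matrix(0, K, T)
  cvec <- numeric(T)
  a <- pi0 * B[, 1]
  cvec[1] <- sum(a); alpha[, 1] <- a / cvec[1]
  if (T > 1) {
    for (t in 2:T) {
      a <- (crossprod(A, alpha[, t - 1])) * B[, t]
      cvec[t] <- sum(a)
      alpha[, t] <- a / cvec[t]
    }
  }
  beta[, T] <- 1
  if (T > 1) {
    for (t in (T - 1):1) {
      b <- A %*% (B[, t + 1] * beta[, t + 1])
      beta[, t] <- b / cvec[t + 1]
    }
  }
  gamma <- alpha * beta
  gamma <- sweep(gamma, 2, colSums(gamma), "/")
  xi_sum <- matrix(0, K, K)
  if (T > 1) {
    for (t in 1:(T - 1)) {
      xi <- (alpha[, t] %o% (B[, t + 1] * beta[, t + 1])) * A / cvec[t + 1]
      xi_sum <- xi_sum + xi / sum(xi)
    }
  }
  list(gamma = gamma, xi_sum = xi_sum,
       loglik = sum(log(cvec)) + sum(offs))
}

## zero-mean Gaussian emission log-likelihoods for all states
emission_loglik <- function(Y, covs) {
  K <- length(covs); L <- nrow(Y); T <- ncol(Y)
  logB <- matrix(0, K, T)
  for (k in seq_len(K)) {
    U <- chol(covs[[k]])
    z <- backsolve(U, Y, transpose = TRUE)
    logB[k, ] <- -0.5 * (L * log(2 * pi) + 2 * sum(log(diag(U))) +
                           colSums(z^2))
  }
  logB
}

regularize_cov <- function(S, reg) {
  S <- (S + t(S)) / 2
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- reg * mean(diag(S))
  if (min(ev) < floor_ev) S <- S + (floor_ev - min(ev)) * diag(nrow(S))
  S
}

#' Fit a time-delay-embedded HMM to one regional time series
#'
#' Embeds the (conditioned, standardised) series over a `window_s` window
#' and fits a K-state hidden Markov model whose states are zero-mean
#' Gaussians with full covariance over the embedded space, so that each
#' state captures a distinct autocovariance (spectro-temporal) pattern.
#' Fitting is by expectation-maximisation with scaled forward-backward
#' recursions; epochs are treated as independent observation segments
#' (the chain restarts at every epoch boundary) sharing one set of
#' parameters.  The best of `n_restarts` randomised initialisations
#' (k-means on embedded vectors) is returned.
#'
#' @param x numeric vector, one region's conditioned series.
#' @param fs sampling rate in Hz.
#' @param config an [hmm_config()].
#' @param epochs optional epoch matrix (half-open, 1-based sample
#'   intervals); default one segment covering the series.
#' @param region_id label carried through to the result.
#' @return object of class `state_posterior` with fields `gamma` (K x T
#'   state probabilities aligned to original samples; edge samples not
#'   covered by the embedding are `NA`), `valid` (logical mask),
#'   `transition_matrix`, `initial_probs`, `covariances`,
#'   `objective_trace`, `converged`, `collapse_log`, `loglik`, `L`, `fs`.
#' @export
fit_tdehmm <- function(x, fs, config = hmm_config(), epochs = NULL,
                       region_id = "region") {
  K <- config$n_states
  T <- length(x)
  if (is.null(epochs))
    epochs <- matrix(c(1L, T + 1L), 1L)
  segs <- lapply(seq_len(nrow(epochs)), function(e) {
    idx <- epochs[e, 1]:(epochs[e, 2] - 1L)
    tde_embed(x[idx], fs, config$window_s)
  })
  offset <- attr(segs[[1]], "offset")
  L <- nrow(segs[[1]])
  Yall <- do.call(cbind, segs)
  seg_len <- vapply(segs, ncol, 0L)
  seg_end <- cumsum(seg_len)
  seg_start <- seg_end - seg_len + 1L

  best <- NULL
  for (r in seq_len(config$n_restarts)) {
    set.seed(config$seed + 1000L * (r - 1L))
    fit <- em_run(Yall, seg_start, seg_end, K, config)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }

  ## align gamma back to original sample indices
  gamma_full <- matrix(NA_real_, K, T)
  valid <- rep(FALSE, T)
  for (e in seq_along(segs)) {
    cols <- seg_start[e]:seg_end[e]
    smp <- (epochs[e, 1] + offset):(epochs[e, 1] + offset + seg_len[e] - 1L)
    gamma_full[, smp] <- best$gamma[, cols]
    valid[smp] <- TRUE
  }
  structure(list(region_id = region_id, gamma = gamma_full, valid = valid,
                 transition_matrix = best$A, initial_probs = best$pi0,
                 covariances = best$covs,
                 objective_trace = best$trace, converged = best$converged,
                 collapse_log = best$collapse_log,
                 loglik = best$loglik, L = L, offset = offset, fs = fs,
                 epochs = epochs, n_states = K),
            class = "state_posterior")
}

## one EM run from a k-means initialisation (RNG state set by caller)
em_run <- function(Y, seg_start, seg_end, K, config) {
  L <- nrow(Y); T <- ncol(Y)
  ## init responsibilities from k-means on a column subsample
  sub <- if (T > 3000L) sort(sample.int(T, 3000L)) else seq_len(T)
  km <- suppressWarnings(
    stats::kmeans(t(Y[, sub, drop = FALSE]), centers = K, nstart = 1,
                  iter.max = 30))
  ## nearest-centre assignment for all columns
  d2 <- vapply(seq_len(K), function(k)
    colSums((Y - km$centers[k, ])^2), numeric(T))
  assign <- max.col(-d2, ties.method = "first")
  gamma <- matrix(0.05 / (K - 1), K, T)
  gamma[cbind(assign, seq_len(T))] <- 0.95
  A <- matrix(1 / K, K, K); pi0 <- rep(1 / K, K)
  covs <- NULL
  trace <- numeric(0); converged <- FALSE; collapse_log <- character(0)
  ll <- -Inf
  for (it in seq_len(config$max_iter)) {
    ## M-step
    wsum <- rowSums(gamma)
    covs <- lapply(seq_len(K), function(k) {
      S <- (Y * rep(gamma[k, ], each = L)) %*% t(Y) / wsum[k]
      S <- (S + t(S)) / 2
      ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
      if (!ok) {
        collapse_log <<- c(collapse_log,
                           sprintf("iter %d state %d: covariance regularized", it, k))
        S <- regularize_cov(S, max(config$cov_reg, 1e-8))
      }
      S
    })
    if (it > 1) {
      A <- xi_tot / pmax(rowSums(xi_tot), .Machine$double.eps)
      pi0 <- pi_tot / sum(pi_tot)
    }
    ## E-step
    logB <- emission_loglik(Y, covs)
    gamma <- matrix(0, K, T); xi_tot <- matrix(0, K, K)
    pi_tot <- numeric(K); ll_new <- 0
    for (e in seq_along(seg_start)) {
      cols <- seg_start[e]:seg_end[e]
      fb <- forward_backward(logB[, cols, drop = FALSE], pi0, A)
      gamma[, cols] <- fb$gamma
      xi_tot <- xi_tot + fb$xi_sum
      pi_tot <- pi_tot + fb$gamma[, 1]
      ll_new <- ll_new + fb$loglik
    }
    trace <- c(trace, ll_new)
    if (it > 1 && abs(ll_new - ll) / abs(ll) < config$tol) {
      converged <- TRUE
      ll <- ll_new
      break
    }
    ll <- ll_new
  }
  list(gamma = gamma, A = A, pi0 = pi0, covs = covs, loglik = ll,
       trace = trace, converged = converged, collapse_log = collapse_log)
}

#' @export
print.state_posterior <- function(x, ...) {
  cat(sprintf("<state_posterior> %s: K=%d, L=%d lags, %d samples (%d valid)\n",
              x$region_id, x$n_states, x$L, ncol(x$gamma), sum(x$valid)))
  cat(sprintf("  loglik %.2f after %d iterations (%s)\n", x$loglik,
              length(x$objective_trace),
              ifelse(x$converged, "converged", "not converged")))
  invisible(x)
}

#' Viterbi decoding of the most probable state path
#'
#' Maximum a-posteriori state sequence under the fitted parameters.
#' Ties are broken towards the lowest state index.
#'
#' @param posterior a fitted `state_posterior`.
#' @param x the series the posterior was fitted to (needed to recompute
#'   emission likelihoods).
#' @return integer vector of state indices aligned to original samples
#'   (`NA` at edge samples outside the embedding).
#' @export
decode_states <- function(posterior, x) {
  stopifnot(inherits(posterior, "state_posterior"))
  K <- posterior$n_states
  if (K < 2) stop("degenerate single-state model")
  path_full <- rep(NA_integer_, length(x))
  logA <- log(pmax(posterior$transition_matrix, 1e-300))
  for (e in seq_len(nrow(posterior$epochs))) {
    idx <- posterior$epochs[e, 1]:(posterior$epochs[e, 2] - 1L)
    Y <- tde_embed(x[idx], posterior$fs, (posterior$L) / posterior$fs)
    logB <- emission_loglik(Y, posterior$covariances)
    T <- ncol(logB)
    delta <- matrix(-Inf, K, T); psi <- matrix(0L, K, T)
    delta[, 1] <- log(pmax(posterior$initial_probs, 1e-300)) + logB[, 1]
    if (T > 1) {
      for (t in 2:T) {
        m <- delta[, t - 1] + logA      # K x K: from (row) to (col)
        psi[, t] <- apply(m, 2, which.max)
        delta[, t] <- m[cbind(psi[, t], seq_len(K))] + logB[, t]
      }
    }
    path <- integer(T)
    path[T] <- which.max(delta[, T])
    if (T > 1) for (t in (T - 1):1) path[t] <- psi[path[t + 1], t + 1]
    smp <- (posterior$epochs[e, 1] + posterior$offset) +
      seq_len(T) - 1L
    path_full[smp] <- path
  }
  path_full
}
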