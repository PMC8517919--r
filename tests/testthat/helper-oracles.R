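# Independent oracles and shared fixtures, kept deliberately naive so they
# cannot share code paths with the implementation under test.

## exhaustive per-sample Jaccard count
jaccard_brute <- function(a, b) {
  inter <- 0L; uni <- 0L
  for (t in seq_along(a)) {
    if (a[t] == 1L && b[t] == 1L) inter <- inter + 1L
    if (a[t] == 1L || b[t] == 1L) uni <- uni + 1L
  }
  if (uni == 0L) 0 else inter / uni
}

## brute-force HMM smoothing: enumerate all K^T state paths
enum_posterior <- function(logB, pi0, A) {
  K <- nrow(logB); T <- ncol(logB)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  logp <- apply(paths, 1, function(s) {
    lp <- log(pi0[s[1]]) + logB[s[1], 1]
    if (T > 1) for (t in 2:T)
      lp <- lp + log(A[s[t - 1], s[t]]) + logB[s[t], t]
    lp
  })
  w <- exp(logp - max(logp)); w <- w / sum(w)
  gamma <- matrix(0, K, T)
  for (t in seq_len(T)) for (k in seq_len(K))
    gamma[k, t] <- sum(w[paths[, t] == k])
  loglik <- log(sum(exp(logp - max(logp)))) + max(logp)
  list(gamma = gamma, loglik = loglik)
}

## exact two-sided rank-sum p by enumeration over all group assignments
rank_sum_enum <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  us <- apply(splits, 2, function(idx)
    sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * ny / 2
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-12)
}

## alternating low-pass AR(1) / beta-resonant AR(2) series with known regimes
gen_two_regime <- function(seed, n_sec = 30, fs = 100, regime_s = 1) {
  set.seed(seed)
  n <- n_sec * fs
  reg <- rep(rep(0:1, length.out = ceiling(n_sec / regime_s)),
             each = regime_s * fs)[seq_len(n)]
  r <- 0.95; th <- 2 * pi * 20 / fs
  a1 <- 2 * r * cos(th); a2 <- -r^2
  x <- numeric(n)
  for (i in 3:n)
    x[i] <- if (reg[i] == 0) 0.97 * x[i - 1] + rnorm(1) else
      a1 * x[i - 1] + a2 * x[i - 2] + rnorm(1)
  list(x = as.numeric(scale(x)), regimes = reg)
}

## burst trains straight from planted ground truth for subject s
gt_trains <- function(sim, s) {
  gt <- sim$ground_truth[[s]]
  rec <- sim$recordings[[s]]
  lapply(seq_len(nrow(rec$data)), function(i)
    train_from_visits(gt$visits[gt$visits$region == i, , drop = FALSE],
                      ncol(rec$data), rec$fs, rec$region_labels[i]))
}

## per-subject global amplitude + connectivity measured from planted trains
## and the rendered signal's beta envelope
measure_planted_cohort <- function(sim) {
  n <- length(sim$recordings)
  amp <- conn <- numeric(n); grp <- character(n)
  for (s in seq_len(n)) {
    rec <- sim$recordings[[s]]
    trains <- gt_trains(sim, s)
    sums <- lapply(seq_along(trains), function(i)
      burst_summary(trains[[i]], beta_envelope(rec$data[i, ], rec$fs)))
    amp[s] <- suppressMessages(global_collapse(sums)$burst_amplitude)
    conn[s] <- global_mean_connectivity(burst_connectome(trains))
    grp[s] <- rec$group
  }
  list(amp = amp, conn = conn, grp = grp)
}

## label-independent Gaussian feature table (null classifier input)
null_features <- function(seed, n = 20, p = 20) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n)
  colnames(X) <- paste0("F", seq_len(p), "_L--F", seq_len(p), "_R")
  structure(list(X = X,
                 y = factor(rep(c("control", "patient"), each = n / 2),
                            levels = c("control", "patient")),
                 feature_names = colnames(X),
                 subjects = paste0("S", seq_len(n))),
            class = "feature_table")
}

## small fast classifier settings for calibration runs
fast_classifier <- function(seed)
  classifier_config(n_trees = 60, n_resamples = 3, min_features = 3,
                    n_folds = 5, seed = seed)

## random burst-train pair of length <= 20
random_train_pair <- function(seed, max_len = 20) {
  set.seed(seed)
  len <- sample(2:max_len, 1)
  list(a = rbinom(len, 1, runif(1, 0.1, 0.9)),
       b = rbinom(len, 1, runif(1, 0.1, 0.9)))
}
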