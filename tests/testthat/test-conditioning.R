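make_sine_rec <- function(freq, fs = 600, dur = 10) {
  t <- seq_len(fs * dur) / fs
  regional_recording(matrix(sin(2 * pi * freq * t), 1), fs)
}

test_that("band-pass keeps in-band and rejects out-of-band tones", {
  ## interior samples only: filtfilt edge transients excluded
  inner <- 3000:3600
  r20 <- make_sine_rec(20); r80 <- make_sine_rec(80)
  f20 <- bandpass(r20, 1, 48); f80 <- bandpass(r80, 1, 48)
  gain20 <- sd(f20$data[1, inner]) / sd(r20$data[1, inner])
  gain80 <- sd(f80$data[1, inner]) / sd(r80$data[1, inner])
  expect_gt(gain20, 0.99)            # < 1% attenuation in band
  expect_lt(gain80, 0.10)            # > 90% attenuation out of band
  ## zero in, zero out; metadata untouched
  rz <- regional_recording(matrix(0, 1, 6000), 600, events = 100L)
  fz <- bandpass(rz, 1, 48)
  expect_equal(max(abs(fz$data)), 0)
  expect_identical(fz$events, rz$events)
  expect_identical(fz$epochs, rz$epochs)
  expect_error(bandpass(r20, 1, 400), "Nyquist")
})

test_that("symmetric orthogonalisation removes zero-lag correlation", {
  set.seed(11)
  rec <- regional_recording(matrix(rnorm(10 * 5000), 10), 100)
  out <- symmetric_orthogonalize(rec)
  cc <- cor(t(out$data)); diag(cc) <- 0
  expect_lt(max(abs(cc)), 1e-8)
  expect_identical(dim(out$data), dim(rec$data))
  expect_true(all(is.finite(out$data)))
  ## refinement never exceeds the unadjusted first-stage distance, and the
  ## trace is non-increasing
  tr <- attr(out, "orthogonalize_trace")
  X <- t(sweep(t(rec$data), 2, colMeans(t(rec$data))))
  sv <- svd(t(X))
  first_stage <- norm(t(X) - sv$u %*% t(sv$v) %*%
                        diag(colSums((sv$u %*% t(sv$v)) * t(X))), "F")
  expect_lte(min(tr), first_stage + 1e-9)
  expect_true(all(diff(tr) <= 1e-9 * tr[1]))
  expect_true(attr(out, "orthogonalize_converged"))
})

test_that("already-orthogonal input is a fixed point up to row scaling", {
  ## full-period sinusoids at distinct frequencies: exactly orthogonal
  ## and exactly zero-mean
  T <- 2000
  Q <- sapply(1:4, function(k) cos(2 * pi * k * (0:(T - 1)) / T))
  rec <- regional_recording(t(Q %*% diag(c(3, 1, 2, 5))), 100)
  out <- symmetric_orthogonalize(rec)
  for (i in 1:4) {
    x <- rec$data[i, ]; y <- out$data[i, ]
    scale_i <- sum(x * y) / sum(x * x)
    resid <- sqrt(sum((y - scale_i * x)^2) / sum(y^2))
    expect_lt(resid, 1e-8)
  }
})

test_that("rank-deficient input names the offending rows", {
  set.seed(4)
  X <- matrix(rnorm(3 * 1000), 3)
  X[3, ] <- X[1, ]
  rec <- regional_recording(X, 100, region_labels = c("A", "B", "C"))
  expect_error(symmetric_orthogonalize(rec), "A.*C|rank-deficient")
})

test_that("resampling preserves waveforms and rescales indices", {
  fs <- 600
  t <- seq_len(fs * 10) / fs
  rec <- regional_recording(matrix(sin(2 * pi * 5 * t), 1), fs,
                            events = 600L)
  out <- resample_recording(rec, 100)
  expect_equal(out$fs, 100)
  tj <- (1 + (seq_len(ncol(out$data)) - 1) * 6) / 600
  inner <- 100:900
  expect_gt(cor(out$data[1, inner], sin(2 * pi * 5 * tj[inner])), 0.999)
  expect_identical(out$events, 100L)          # sample 600 @600Hz -> 100 @100Hz
  ## identity when target equals source
  expect_identical(resample_recording(rec, fs), rec)
  expect_error(resample_recording(rec, 1200), "upsampling")
})

test_that("standardisation gives zero mean, unit variance, idempotently", {
  t <- seq_len(2000) / 100
  x <- 4 + 3 * sin(2 * pi * 7 * t)
  rec <- regional_recording(rbind(x, 7 * x + 1), 100)
  out <- standardize(rec)
  expect_equal(unname(rowMeans(out$data)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(out$data, 1, sd)), c(1, 1), tolerance = 1e-12)
  ## scale invariance: both rows identical after standardisation
  expect_equal(out$data[1, ], out$data[2, ], tolerance = 1e-10)
  ## idempotence
  again <- standardize(out)
  expect_equal(again$data, out$data, tolerance = 1e-12)
  rec0 <- regional_recording(matrix(c(1, 1, 1, 1), 1), 100)
  expect_error(standardize(rec0), "zero-variance")
})

test_that("conditioning leaves planted burst timing intact", {
  ## simulate at 600 Hz, run the full chain, and compare envelope peak
  ## times inside planted visits before and after conditioning
  cfg <- sim_config(n_regions = 4, n_epochs = 3, fs = 600, seed = 21)
  sim <- simulate_resting(cfg, 1)
  raw <- sim$recordings[[1]]
  cond <- condition_recording(raw, 1, 48, target_fs = 100,
                              orthogonalize = TRUE)
  gt <- sim$ground_truth[[1]]
  env_raw <- beta_envelope(raw$data[1, ], 600)
  env_cond <- beta_envelope(cond$data[1, ], 100)
  v <- gt$visits[gt$visits$region == 1, ]
  v <- v[v$end - v$start > 60, ]              # visits >= 0.1 s
  shifts <- vapply(seq_len(nrow(v)), function(k) {
    idx_raw <- v$start[k]:(v$end[k] - 1)
    pk_raw <- idx_raw[which.max(env_raw$env[idx_raw])] / 600
    lo <- max(1, round(v$start[k] / 6)); hi <- round(v$end[k] / 6)
    idx_cond <- lo:hi
    pk_cond <- idx_cond[which.max(env_cond$env[idx_cond])] / 100
    abs(pk_raw - pk_cond)
  }, 0)
  expect_lt(median(shifts), 0.02)             # < 20 ms
})
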