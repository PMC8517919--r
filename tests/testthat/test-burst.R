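test_that("Morlet envelope is flat for a pure in-band tone and selective", {
  fs <- 100
  x20 <- sin(2 * pi * 20 * seq_len(60 * fs) / fs)
  env <- beta_envelope(x20, fs)
  inner <- 500:5500
  expect_true(all(env$env >= 0))
  expect_lt(sd(env$env[inner]) / mean(env$env[inner]), 0.05)
  ## linearity of the modulus under real scaling
  env2 <- beta_envelope(2 * x20, fs)
  expect_equal(env2$env, 2 * env$env, tolerance = 1e-10)
  ## out-of-band rejection: 5 Hz tone yields < 10% of the 20 Hz response
  x5 <- sin(2 * pi * 5 * seq_len(60 * fs) / fs)
  env5 <- beta_envelope(x5, fs)
  expect_lt(mean(env5$env[inner]) / mean(env$env[inner]), 0.1)
  expect_error(beta_envelope(x20, 40), "Nyquist")
})

make_posterior <- function(gamma, fs = 100) {
  T <- ncol(gamma)
  structure(list(region_id = "r", gamma = gamma, valid = rep(TRUE, T),
                 n_states = nrow(gamma), fs = fs,
                 epochs = matrix(c(1L, T + 1L), 1)),
            class = "state_posterior")
}

test_that("the burst state is the one tracking the beta envelope", {
  set.seed(1)
  T <- 500
  env <- structure(list(env = abs(rnorm(T)) + 0.1, band = c(13, 30),
                        cycles = 7, fs = 100), class = "beta_envelope")
  g2 <- 0.2 + 0.6 * (env$env - min(env$env)) / diff(range(env$env))
  g1 <- runif(T, 0, 1 - g2)
  gamma <- rbind(g1, g2, 1 - g1 - g2)
  st <- select_burst_state(make_posterior(gamma), env)
  expect_equal(as.integer(st), 2L)
  expect_equal(unname(attr(st, "correlations")[2]), 1, tolerance = 1e-12)
  ## constant rows are excluded from the argmax
  gamma_const <- rbind(rep(0.5, T), g2 * 0.5, 0.5 - g2 * 0.5)
  st2 <- select_burst_state(make_posterior(gamma_const), env)
  expect_equal(as.integer(st2), 2L)
  expect_true(is.na(attr(st2, "correlations")[1]))
  ## all-constant: no defined correlation anywhere
  gall <- rbind(rep(0.3, T), rep(0.3, T), rep(0.4, T))
  expect_error(select_burst_state(make_posterior(gall), env), "undefined")
  ## exact tie resolves to the lower index
  gtie <- rbind(g2 / 2, g2 / 2, 1 - g2)
  expect_message(st3 <- select_burst_state(make_posterior(gtie), env),
                 "tie")
  expect_equal(as.integer(st3), 1L)
})

test_that("binarisation is strict at two thirds and respects epochs", {
  gamma <- rbind(c(0.50, 0.70, 0.90, 0.60), c(0.50, 0.30, 0.10, 0.40))
  tr <- binarize_posterior(make_posterior(gamma), 1)
  expect_equal(tr$b, c(0L, 1L, 1L, 0L))
  expect_equal(nrow(tr$visits), 1)
  expect_equal(unname(tr$visits[1, ]), c(2, 4))       # half-open, 2 samples
  ## all below or exactly at threshold: empty train
  gamma2 <- rbind(c(0.5, 2 / 3, 0.6, 2 / 3), c(0.5, 1 / 3, 0.4, 1 / 3))
  tr2 <- binarize_posterior(make_posterior(gamma2), 1)
  expect_equal(sum(tr2$b), 0)
  expect_equal(nrow(tr2$visits), 0)
  ## a run across an epoch boundary is split into two visits
  g <- rbind(rep(0.9, 6), rep(0.1, 6))
  post <- make_posterior(g)
  post$epochs <- cbind(start = c(1L, 4L), end = c(4L, 7L))
  tr3 <- binarize_posterior(post, 1)
  expect_equal(nrow(tr3$visits), 2)
  expect_equal(unname(tr3$visits[, "start"]), c(1, 4))
})

test_that("summary metrics follow their definitions exactly", {
  fs <- 100
  b <- integer(1000); b[11:20] <- 1L               # visit [11, 21), 0.1 s
  env <- structure(list(env = rep(1, 1000), band = c(13, 30), cycles = 7,
                        fs = fs), class = "beta_envelope")
  env$env[15] <- 5
  s <- burst_summary(burst_train(b, fs), env)
  expect_equal(s$burst_amplitude, 5)
  expect_equal(s$total_burst_time, 0.01)
  expect_equal(s$mean_duration_s, 0.1)
  expect_equal(s$count_rate_hz, 0.1)
  ## two visits: mean of per-visit maxima
  b2 <- integer(1000); b2[11:20] <- 1L; b2[51:60] <- 1L
  env$env[55] <- 3; env$env[15] <- 5
  s2 <- burst_summary(burst_train(b2, fs), env)
  expect_equal(s2$burst_amplitude, 4)
  ## empty train
  s0 <- burst_summary(burst_train(integer(1000), fs), env)
  expect_equal(s0$total_burst_time, 0)
  expect_equal(s0$count_rate_hz, 0)
  expect_true(is.na(s0$burst_amplitude))
  expect_false(s0$amplitude_defined)
  ## duration x rate = total burst time
  expect_equal(s2$mean_duration_s * s2$count_rate_hz, s2$total_burst_time,
               tolerance = 1e-12)
})

test_that("global collapse averages regions and excludes undefined ones", {
  fs <- 100
  env <- structure(list(env = rep(2, 500), band = c(13, 30), cycles = 7,
                        fs = fs), class = "beta_envelope")
  b <- integer(500); b[1:50] <- 1L
  s_full <- burst_summary(burst_train(b, fs), env)
  ## identical regions: global equals the common value
  g <- global_collapse(list(s_full, s_full, s_full))
  expect_equal(g$burst_amplitude, s_full$burst_amplitude)
  expect_equal(g$total_burst_time, s_full$total_burst_time)
  expect_equal(g$n_excluded_amplitude, 0)
  ## one undefined region: mean over the rest, exclusion counted
  s_empty <- burst_summary(burst_train(integer(500), fs), env)
  expect_message(g2 <- global_collapse(list(s_full, s_empty)), "excluded")
  expect_equal(g2$burst_amplitude, s_full$burst_amplitude)
  expect_equal(g2$n_excluded_amplitude, 1)
  expect_equal(g2$total_burst_time,
               mean(c(s_full$total_burst_time, 0)))
  expect_error(global_collapse(list(s_empty, s_empty)), "every region")
})

test_that("raising the threshold never increases total burst time", {
  set.seed(5)
  T <- 2000
  g <- pmin(pmax(stats::filter(runif(T), rep(1 / 5, 5),
                               circular = TRUE), 0), 1)
  gamma <- rbind(as.numeric(g), 1 - as.numeric(g))
  post <- make_posterior(gamma)
  tbt <- vapply(c(0.5, 0.6, 2 / 3, 0.75, 0.9), function(th) {
    tr <- binarize_posterior(post, 1, th)
    sum(tr$b) / T
  }, 0)
  expect_true(all(diff(tbt) <= 0))
})

test_that("burst amplitude couples to the overall beta envelope", {
  ## across synthetic subjects, global burst amplitude tracks the
  ## recording-mean envelope (the classical beta-amplitude metric)
  cfg <- sim_config(n_regions = 2, n_epochs = 3, seed = 31)
  sim <- simulate_resting(cfg, 6)
  amp <- envmean <- numeric(length(sim$recordings))
  for (s in seq_along(sim$recordings)) {
    rec <- sim$recordings[[s]]
    trains <- gt_trains(sim, s)
    envs <- lapply(seq_len(2), function(i)
      beta_envelope(rec$data[i, ], rec$fs))
    sums <- lapply(1:2, function(i) burst_summary(trains[[i]], envs[[i]]))
    amp[s] <- suppressMessages(global_collapse(sums)$burst_amplitude)
    envmean[s] <- mean(vapply(envs, function(e) mean(e$env), 0))
  }
  expect_gt(cor(amp, envmean), 0.7)
})
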