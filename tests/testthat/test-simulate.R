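test_that("generator is deterministic under a fixed seed", {
  cfg <- sim_config(n_regions = 2, n_epochs = 2, seed = 5)
  s1 <- simulate_resting(cfg, 1)
  s2 <- simulate_resting(cfg, 1)
  expect_identical(s1$recordings[[1]]$data, s2$recordings[[1]]$data)
  expect_identical(s1$ground_truth[[1]]$visits, s2$ground_truth[[1]]$visits)
  t1 <- simulate_task(cfg, n_trials = 4, n_per_group = 1)
  t2 <- simulate_task(cfg, n_trials = 4, n_per_group = 1)
  expect_identical(t1$recordings[[2]]$data, t2$recordings[[2]]$data)
})

test_that("zero burst rate yields pure background with zero occupancy", {
  cfg <- sim_config(n_regions = 2, n_epochs = 2, burst_rate_hz = 0, seed = 2)
  sim <- simulate_resting(cfg, 1)
  expect_equal(nrow(sim$ground_truth[[1]]$visits), 0)
  expect_equal(planted_occupancy(sim$ground_truth[[1]]), 0)
  ## background is conditioned to unit variance
  expect_equal(unname(apply(sim$recordings[[1]]$data, 1, sd)), c(1, 1),
               tolerance = 1e-6)
})

test_that("saturating occupancy is rejected at config time", {
  expect_error(sim_config(burst_rate_hz = 4,
                          burst_duration_s = list(mean = 0.3, cv = 0.5)),
               "saturation")
})

test_that("planted occupancy tracks rate x mean duration", {
  ## rate 0.6/s, mean visit 0.3 s over 240 s records: occupancy near 0.18
  ## (overlap merging trims the product slightly)
  occ <- vapply(1:20, function(sd) {
    cfg <- sim_config(n_regions = 2, n_epochs = 24, burst_rate_hz = 0.6,
                      burst_duration_s = list(mean = 0.3, cv = 0.5),
                      seed = sd)
    planted_occupancy(simulate_resting(cfg, 1)$ground_truth[[1]])
  }, 0)
  expect_lt(abs(mean(occ) - 0.18), 0.03)
})

test_that("ground-truth visits are sorted, disjoint and inside the record", {
  cfg <- sim_config(n_regions = 4, n_epochs = 6, seed = 9)
  gt <- simulate_resting(cfg, 2)$ground_truth
  for (g in gt) {
    for (i in unique(g$visits$region)) {
      v <- g$visits[g$visits$region == i, ]
      expect_true(all(diff(v$start) > 0))
      expect_true(all(v$start[-1] >= v$end[-nrow(v)]))
      expect_true(all(v$start >= 1) && all(v$end <= g$T + 1))
    }
  }
})

test_that("background periodogram slope matches the configured exponent", {
  cfg <- sim_config(n_regions = 1, n_epochs = 24, burst_rate_hz = 0,
                    noise_exponent = 1, seed = 3)
  rec <- simulate_resting(cfg, 1)$recordings[[1]]
  sp <- spec.pgram(rec$data[1, ], taper = 0, plot = FALSE)
  f <- sp$freq * cfg$fs
  keep <- f > 0.5 & f < 40
  slope <- unname(coef(lm(log(sp$spec[keep]) ~ log(f[keep])))[2])
  expect_lt(abs(slope - (-1)), 0.3)
})

test_that("movement-locked profile shapes the planted probability course", {
  ## suppression x0.2 in (-0.3, 0.1), elevation x2 in (0.45, 0.85):
  ## the planted course must dip near -0.1 s and peak near 0.65 s
  mins <- maxs <- numeric(20)
  for (sd in 1:20) {
    cfg <- sim_config(n_regions = 2, seed = sd)
    sim <- simulate_task(cfg, n_trials = 60, n_per_group = 1)
    rec <- sim$recordings[[1]]
    tr <- gt_trains(sim, 1)[[1]]
    tt <- epoch_trials(tr, rep(0, ncol(rec$data)), rec$events)
    crs <- burst_probability_course(tt)
    inner <- abs(tt$time_s) <= 2          # away from edge smearing
    mins[sd] <- tt$time_s[inner][which.min(crs[inner])]
    maxs[sd] <- tt$time_s[inner][which.max(crs[inner])]
  }
  expect_lt(abs(mean(mins) - (-0.1)), 0.05)
  expect_lt(abs(mean(maxs) - 0.65), 0.05)
})

test_that("flat task profile leaves the course unmodulated", {
  cfg <- sim_config(n_regions = 2, seed = 4,
                    task_profile = data.frame(t_lo = -1, t_hi = 1, mult = 1))
  sim <- simulate_task(cfg, n_trials = 80, n_per_group = 1)
  rec <- sim$recordings[[1]]
  tt <- epoch_trials(gt_trains(sim, 1)[[1]], rep(0, ncol(rec$data)),
                     rec$events)
  crs <- burst_probability_course(tt)
  ## mean course in the two canonical windows should differ only by noise
  w1 <- mean(crs[tt$time_s >= -0.3 & tt$time_s < 0.1])
  w2 <- mean(crs[tt$time_s >= 0.45 & tt$time_s < 0.85])
  expect_lt(abs(w1 - w2), 0.1)
})

test_that("degenerate task requests error", {
  cfg <- sim_config(n_regions = 2, seed = 1)
  expect_error(simulate_task(cfg, n_trials = 0, n_per_group = 1),
               "n_trials")
})

test_that("symptom scores decrease monotonically in the planted covariate", {
  cfg <- sim_config(n_regions = 2, n_epochs = 2, seed = 8)
  gt <- simulate_resting(cfg, 10)$ground_truth
  cov <- vapply(gt, `[[`, 0, "conn_scale")
  ## noiseless: perfect monotone decreasing map
  sc0 <- sample_symptom_scores(gt, slope = 5, noise_sd = 0, seed = 1)
  expect_equal(unname(cor(sc0, cov, method = "spearman")), -1)
  ## slope 0: no dependence planted
  rho_null <- vapply(1:40, function(s) {
    cor(sample_symptom_scores(gt, slope = 0, noise_sd = 1, seed = s), cov,
        method = "spearman")
  }, 0)
  expect_lt(abs(mean(rho_null)), 0.25)
  ## noisy but sloped: negative rho in nearly all seeds
  rho <- vapply(1:50, function(s) {
    cor(sample_symptom_scores(gt, slope = 10, noise_sd = 1, seed = s), cov,
        method = "spearman")
  }, 0)
  expect_gte(mean(rho < 0), 0.95)
})
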