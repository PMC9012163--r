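test_that("stroke synthesis integrates speed to the requested path", {
  cfg <- generator_config(calibrate_path = FALSE)
  set.seed(1)
  s <- simulate_stroke(0.25, 0.725, 0, "DS", cfg)
  dt <- 1 / cfg$rate_hz
  area <- sum((s$speed[-1] + s$speed[-length(s$speed)]) / 2) * dt
  expect_equal(area, 0.725, tolerance = 1e-12)
  expect_true(all(s$vy <= 0)) # DS moves downward
  expect_equal(s$speed[1], 0)
  expect_equal(s$speed[length(s$speed)], 0)

  # doubling the path at fixed duration doubles the measured path
  s2 <- simulate_stroke(0.25, 1.45, 0, "DS", cfg)
  a2 <- sum((s2$speed[-1] + s2$speed[-length(s2$speed)]) / 2) * dt
  expect_equal(a2 / area, 2, tolerance = 0.01)

  expect_error(simulate_stroke(0.2, 0.6, 3, "DS", cfg), "at most")
  expect_error(simulate_stroke(-0.1, 0.6, 0, "DS", cfg), "duration")
})

test_that("capped Poisson rates keep the configured cell means", {
  cfg <- generator_config(calibrate_path = FALSE)
  for (i in seq_len(nrow(cfg$peak_rates))) {
    l <- cfg$peak_rates$lambda[i]
    le <- cfg$peak_rates$lambda_eff[i]
    expect_gte(le, l)
    capped_mean <- sum(pmin(0:50, cfg$max_extra_pulses) * dpois(0:50, le))
    expect_equal(capped_mean, l, tolerance = 1e-6)
  }
  expect_equal(cfg$max_extra_pulses, 2L)
})

test_that("trials have the designed stroke structure", {
  cfg <- generator_config()
  ll <- simulate_trial("S", "CTRL", "ll", 1, config = cfg, noise = FALSE)
  ln <- simulate_trial("S", "CTRL", "ln", 1, config = cfg, noise = FALSE)
  params <- seg_params()
  count_strokes <- function(tr) {
    uni <- resample_trace(tr, params$resample_rate)
    sm <- smooth_trace(uni, params$lowpass_cutoff)
    segment_strokes(velocity_profile(sm), sm, params)
  }
  st_ll <- count_strokes(ll$trace)
  st_ln <- count_strokes(ln$trace)
  expect_equal(nrow(st_ll), 4) # l + l
  expect_equal(nrow(st_ln), 6) # l + n
  expect_equal(st_ll$direction[1:2], c("US", "DS"))
  expect_equal(st_ln$direction, rep(c("US", "DS"), 3))
  # pen-up lead-in and tail
  expect_equal(ll$trace$p[1], 0)
  expect_equal(ll$trace$p[nrow(ll$trace)], 0)
})

test_that("zero dysfluency rates give exactly one peak everywhere", {
  pr <- tibble::tibble(
    group = rep(c("CTRL", "SCZ"), each = 2),
    direction = rep(c("US", "DS"), 2), lambda = 0
  )
  cfg <- generator_config(
    n_subjects_per_group = 2, trials_per_bigram = 2, seed = 4, peak_rates = pr
  )
  co <- simulate_cohort(cfg)
  feat <- extract_features(co$manifest)
  expect_true(all(feat$n_peaks == 1))
  expect_true(all(co$truth$n_extra_pulses == 0))
})

test_that("cohorts have the configured shape and are seed-reproducible", {
  cfg <- generator_config(n_subjects_per_group = 2, trials_per_bigram = 3, seed = 9)
  a <- simulate_cohort(cfg)
  expect_equal(nrow(a$manifest), 2 * 2 * 2 * 3)
  expect_equal(length(unique(a$manifest$subject_id)), 4)
  expect_equal(nrow(a$covariates), 2) # patients only

  b <- simulate_cohort(cfg)
  expect_identical(a$truth, b$truth)
  expect_identical(a$covariates, b$covariates)
  expect_identical(
    as.data.frame(a$manifest$trace[[5]]),
    as.data.frame(b$manifest$trace[[5]])
  )

  c2 <- simulate_cohort(generator_config(n_subjects_per_group = 2, trials_per_bigram = 3, seed = 10))
  expect_false(identical(a$truth$nominal_duration_s, c2$truth$nominal_duration_s))
})

test_that("disabling anticipation nulls the control ln downstroke cells", {
  cfg <- generator_config(anticipation = FALSE, calibrate_path = FALSE)
  dm <- cfg$duration_means
  expect_equal(
    dm$duration_s[dm$group == "CTRL" & dm$direction == "DS" & dm$bigram == "ln"],
    dm$duration_s[dm$group == "CTRL" & dm$direction == "DS" & dm$bigram == "ll"]
  )
  tm <- cfg$trajectory_means
  expect_equal(
    tm$trajectory_cm[tm$group == "CTRL" & tm$direction == "DS" & tm$bigram == "ln"],
    0.625
  )
})

test_that("cohorts written to disk round-trip through the file formats", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_subjects_per_group = 2, trials_per_bigram = 1, seed = 3)
  co <- simulate_cohort(cfg, dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 8)
  back <- read_pen_trace(man$path[1])
  orig <- co$manifest$trace[[1]]
  expect_lt(max(abs(back$x - orig$x)), 1e-6)
  expect_equal(trace_meta(back)$bigram, trace_meta(orig)$bigram)
  cov <- read_covariates(file.path(dir, "covariates.csv"))
  expect_equal(nrow(cov), 2)
})

test_that("clinical covariates realise their target means above the scale floors", {
  set.seed(101)
  cov <- simulate_clinical(sprintf("S%05d", 1:10000), rnorm(10000, 0.84, 0.05))
  expect_equal(mean(cov$panss_p), 16.04, tolerance = 0.2 / 16.04)
  expect_equal(mean(cov$sas), 3.21, tolerance = 0.15 / 3.21)
  expect_equal(mean(cov$cpze), 779.37, tolerance = 12 / 779.37)
  expect_equal(mean(cov$purdue_dom), 13.74, tolerance = 0.25 / 13.74)
  expect_true(all(cov$panss_p >= 7))
  expect_true(all(cov$panss_g >= 16))
  expect_true(all(cov$sas >= 0))
  expect_true(all(cov$purdue_dom >= 0))
})

test_that("the Purdue-trajectory copula hits its target rank correlation", {
  set.seed(202)
  rhos <- rhos0 <- numeric(30)
  for (r in 1:30) {
    traj <- rnorm(24, 0.84, 0.05)
    cov <- simulate_clinical(sprintf("S%02d", 1:24), traj)
    rhos[r] <- cor(cov$purdue_dom, traj, method = "spearman")
    cov0 <- simulate_clinical(sprintf("S%02d", 1:24), traj, rho_purdue_traj = 0)
    rhos0[r] <- cor(cov0$purdue_dom, traj, method = "spearman")
  }
  expect_gte(median(rhos), -0.65)
  expect_lte(median(rhos), -0.35)
  expect_gte(mean(abs(rhos0) < 0.4), 0.9)
})
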