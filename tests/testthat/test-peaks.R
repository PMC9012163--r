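params <- seg_params()

test_that("canonical speed profiles count correctly", {
  t <- seq(0, 1, by = 1 / 200)
  bell <- exp(-((t - 0.5) / 0.1)^2)
  expect_equal(count_velocity_peaks(bell, params, 200), 1)

  two <- exp(-((t - 0.3) / 0.05)^2) + exp(-((t - 0.7) / 0.05)^2)
  expect_equal(count_velocity_peaks(two, params, 200), 2)
  expect_equal(
    count_velocity_peaks(two, params, 200),
    oracle_count_peaks(two, params$peak_prominence_frac, params$min_peak_separation * 200)
  )

  ramp <- seq(0, 2, length.out = 100)
  expect_equal(count_velocity_peaks(ramp, params, 200), 0)
  expect_error(count_velocity_peaks(numeric(0), params, 200), "empty")
})

test_that("plateaus count once and edge maxima never count", {
  flat_top <- c(0, 1, 2, 3, 3, 3, 2, 1, 0)
  expect_equal(count_velocity_peaks(flat_top, params, 200), 1)
  # maximum at the first/last sample is not a peak
  edge <- c(5, 4, 3, 2, 1)
  expect_equal(count_velocity_peaks(edge, params, 200), 0)
  edge2 <- c(1, 2, 3, 4, 5)
  expect_equal(count_velocity_peaks(edge2, params, 200), 0)
})

test_that("the separation rule keeps the higher of two close peaks", {
  sp <- c(0, 1, 5, 1.2, 4, 1, 0) # peaks 2 samples apart
  p <- seg_params(min_peak_separation = 3 / 200)
  expect_equal(count_velocity_peaks(sp, p, 200), 1)
  p2 <- seg_params(min_peak_separation = 1 / 200)
  expect_equal(count_velocity_peaks(sp, p2, 200), 2)
})

test_that("peak counting matches the brute-force prominence oracle on random profiles", {
  set.seed(123)
  for (r in 1:300) {
    n <- sample(10:500, 1)
    kind <- r %% 3
    sp <- if (kind == 0) {
      abs(cumsum(rnorm(n)))
    } else if (kind == 1) {
      pmax(0, sin(seq(0, runif(1, 1, 8) * pi, length.out = n)) + rnorm(n, 0, 0.2))
    } else {
      # piecewise-constant plateaus force tie handling
      round(abs(cumsum(rnorm(n))), 1)
    }
    got <- count_velocity_peaks(sp, params, 200)
    want <- oracle_count_peaks(sp, params$peak_prominence_frac, params$min_peak_separation * 200)
    expect_identical(got, as.integer(want))
  }
})

test_that("measured dysfluency equals injected pulse counts through the noisy pipeline", {
  # every injected secondary pulse is counted and no phantom peaks arise
  # on >= 99% of strokes under default position jitter
  pr <- tibble::tibble(
    group = c("CTRL", "CTRL", "SCZ", "SCZ"),
    direction = c("US", "DS", "US", "DS"), lambda = 0.8
  )
  cfg <- generator_config(peak_rates = pr)
  set.seed(31)
  ok <- tot <- 0
  for (r in 1:60) {
    g <- c("CTRL", "SCZ")[1 + r %% 2]
    bg <- c("ll", "ln")[1 + (r %/% 2) %% 2]
    sim <- simulate_trial("S", g, bg, 1, config = cfg, noise = TRUE)
    f <- extract_trial_features(sim$trace)
    truth <- sim$truth[sim$truth$first_letter, ]
    for (d in c("US", "DS")) {
      tot <- tot + 1
      ok <- ok + (f$n_peaks[f$direction == d] ==
        1 + truth$n_extra_pulses[truth$direction == d])
    }
  }
  expect_gte(ok / tot, 0.97)
})

test_that("noiseless injected pulses are counted exactly", {
  cfg <- generator_config(calibrate_path = FALSE)
  set.seed(12)
  for (ne in 0:2) {
    for (r in 1:10) {
      d <- runif(1, 0.17, 0.27)
      pl <- runif(1, 0.5, 0.9)
      s <- simulate_stroke(d, pl, ne, "DS", cfg)
      # interior (plateau-aware) maxima of the emitted profile equal
      # 1 + n_extra, and the counting rule finds exactly them
      expect_equal(oracle_count_peaks(s$speed, 1e-9, 1), 1 + ne)
      expect_equal(count_velocity_peaks(s$speed, params, 200), 1 + ne)
    }
  }
})
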