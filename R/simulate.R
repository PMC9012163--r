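#' Configuration of the synthetic cohort generator
#'
#' Defines the simulated study: cohort shape, per-cell nominal stroke
#' kinematics, dysfluency rates, noise scales and the detectability
#' margins of injected secondary velocity pulses. The defaults encode a
#' two-group (SCZ vs CTRL) bigram-writing study of motor anticipation:
#' controls lengthen the first letter's downstroke (in both duration,
#' +0.060 s, and path, +0.100 cm) when the next letter is an *n* rather
#' than a repeated *l*; patients show only a small non-directional *ln*
#' elevation (+0.010 s), longer strokes overall (macrography), and more
#' velocity peaks per stroke. Cell means are chosen so that the pooled
#' margins measured by the extraction pipeline land on: DS duration
#' 0.21 s, US 0.20 s, *ln* 0.21 s, *ll* 0.19 s; trajectory SCZ 0.84 cm,
#' CTRL 0.65 cm; dysfluency SCZ 1.47, CTRL 1.09, DS 1.33, US 1.22.
#'
#' Dysfluency is generated by adding `n` secondary velocity pulses per
#' stroke with `n ~ Poisson(lambda)` per (group, direction); the cell
#' mean peak count is `1 + lambda`. The separation margins admit at most
#' two secondary pulses per stroke, so draws are capped at two and the
#' generator internally uses a compensated rate solved so that the
#' capped mean still equals `lambda`.
#'
#' @param n_subjects_per_group Subjects per group (default 24).
#' @param trials_per_bigram Trials per bigram per subject (default 10).
#' @param seed Integer seed; every random draw of the cohort derives
#'   from it.
#' @param rate_hz Emission sampling rate in Hz (default 200).
#' @param anticipation If `FALSE`, the control anticipation effect is
#'   removed (CTRL/ln/DS duration reset to 0.190 s and trajectory to
#'   0.625 cm), giving a null three-way interaction.
#' @param duration_means,trajectory_means Optional replacement tibbles
#'   with columns `group`, `direction`, `bigram` and `duration_s` /
#'   `trajectory_cm`.
#' @param peak_rates Optional replacement tibble with columns `group`,
#'   `direction`, `lambda`.
#' @param subject_sd_duration,subject_sd_trajectory Between-subject
#'   intercept SDs (s, cm).
#' @param trial_sd_duration,trial_sd_trajectory Trial-to-trial SDs
#'   (s, cm).
#' @param jitter_sd Gaussian position jitter SD in cm, added per sample
#'   before any filtering.
#' @param pulse_amp_frac,pulse_width_frac,pulse_sep_frac Secondary-pulse
#'   amplitude relative to the primary peak, width and minimum centre
#'   separation as fractions of the stroke duration.
#' @param slant_deg Fixed stroke slant from vertical, degrees.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_subjects_per_group = 24, trials_per_bigram = 10,
                             seed = 1L, rate_hz = 200, anticipation = TRUE,
                             duration_means = NULL, trajectory_means = NULL,
                             peak_rates = NULL,
                             subject_sd_duration = 0.015, subject_sd_trajectory = 0.05,
                             trial_sd_duration = 0.030, trial_sd_trajectory = 0.08,
                             jitter_sd = 0.002,
                             pulse_amp_frac = 0.70, pulse_width_frac = 0.20,
                             pulse_sep_frac = 0.25, slant_deg = 8,
                             calibrate_path = TRUE) {
  grid <- tidyr::expand_grid(
    group = c("CTRL", "SCZ"), direction = c("US", "DS"), bigram = c("ll", "ln")
  )
  if (is.null(duration_means)) {
    duration_means <- grid |> dplyr::mutate(duration_s = dplyr::case_when(
      direction == "US" & group == "SCZ" & bigram == "ln" ~ 0.205,
      direction == "US" ~ 0.195,
      group == "CTRL" & bigram == "ln" ~ if (anticipation) 0.250 else 0.190,
      group == "SCZ" & bigram == "ln" ~ 0.200,
      TRUE ~ 0.190
    ))
  }
  if (is.null(trajectory_means)) {
    trajectory_means <- grid |> dplyr::mutate(trajectory_cm = dplyr::case_when(
      group == "SCZ" ~ 0.840,
      direction == "DS" & bigram == "ln" ~ if (anticipation) 0.725 else 0.625,
      TRUE ~ 0.625
    ))
  }
  if (is.null(peak_rates)) {
    peak_rates <- tibble::tibble(
      group = c("CTRL", "CTRL", "SCZ", "SCZ"),
      direction = c("US", "DS", "US", "DS"),
      lambda = c(0.0325, 0.1425, 0.4125, 0.5225)
    )
  }
  stopifnot(
    all(duration_means$duration_s > 0), all(trajectory_means$trajectory_cm > 0),
    all(peak_rates$lambda >= 0),
    subject_sd_duration > 0, trial_sd_duration > 0,
    subject_sd_trajectory > 0, trial_sd_trajectory > 0, jitter_sd > 0,
    n_subjects_per_group >= 1, trials_per_bigram >= 1
  )
  max_extra <- max_feasible_pulses(pulse_width_frac, pulse_sep_frac)
  peak_rates$lambda_eff <- vapply(peak_rates$lambda, capped_poisson_rate,
    numeric(1), cap = max_extra
  )
  cfg <- structure(list(
    n_subjects_per_group = as.integer(n_subjects_per_group),
    trials_per_bigram = as.integer(trials_per_bigram),
    seed = as.integer(seed), rate_hz = rate_hz, anticipation = anticipation,
    duration_means = duration_means, trajectory_means = trajectory_means,
    peak_rates = peak_rates, max_extra_pulses = max_extra,
    subject_sd_duration = subject_sd_duration,
    subject_sd_trajectory = subject_sd_trajectory,
    trial_sd_duration = trial_sd_duration,
    trial_sd_trajectory = trial_sd_trajectory,
    jitter_sd = jitter_sd,
    pulse_amp_frac = pulse_amp_frac, pulse_width_frac = pulse_width_frac,
    pulse_sep_frac = pulse_sep_frac, slant_deg = slant_deg,
    path_bias = NULL
  ), class = "generator_config")
  if (isTRUE(calibrate_path)) cfg$path_bias <- calibrate_path_bias(cfg)
  cfg
}

# Measurement bias of the default extraction pipeline: zero-phase
# smoothing rounds the zero-speed cusp at each stroke reversal into an
# arc, lengthening the measured path by a few thousandths of a cm, with
# a further small inflation under trial noise (the bias is convex in
# stroke speed). Estimated per cell as the mean measured-minus-nominal
# path over noiseless plus noisy replicate trials drawn from a fixed
# internal RNG stream, then subtracted from emitted first-letter stroke
# paths so that configured cell means are realised through the full
# pipeline. Cached per configuration.
.calib_cache <- new.env(parent = emptyenv())

calibrate_path_bias <- function(cfg, n_rep = 24L) {
  key <- rlang::hash(list(
    cfg$rate_hz, cfg$duration_means, cfg$trajectory_means,
    cfg$trial_sd_duration, cfg$trial_sd_trajectory, cfg$jitter_sd,
    cfg$pulse_amp_frac, cfg$pulse_width_frac, cfg$pulse_sep_frac,
    cfg$slant_deg, n_rep
  ))
  hit <- .calib_cache[[key]]
  if (!is.null(hit)) return(hit)

  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(20201L)
  params <- seg_params(resample_rate = cfg$rate_hz)
  cfg0 <- cfg
  cfg0$peak_rates$lambda_eff <- 0 # bias is a property of the primary pulse
  rows <- list()
  for (g in c("CTRL", "SCZ")) {
    for (bg in c("ll", "ln")) {
      devs <- matrix(0, n_rep + 1L, 2) # rows: replicates; cols: US, DS
      for (r in seq_len(n_rep + 1L)) {
        sim <- simulate_trial("cal", g, bg, 1L,
          config = cfg0, noise = r > 1L
        )
        f <- extract_trial_features(sim$trace, params)
        nom <- sim$truth[sim$truth$first_letter, ]
        for (di in 1:2) {
          d <- c("US", "DS")[di]
          devs[r, di] <- f$trajectory_cm[f$direction == d] -
            nom$nominal_trajectory_cm[nom$direction == d]
        }
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        group = g, direction = c("US", "DS"), bigram = bg,
        bias_cm = colMeans(devs)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  .calib_cache[[key]] <- out
  out
}

# how many secondary pulses fit: centres must sit in [w/2, 1 - w/2],
# at least sep from the primary peak at 1/2 and pairwise at least sep apart
max_feasible_pulses <- function(width_frac, sep_frac) {
  side <- function(lo, hi) {
    if (hi < lo) return(0L)
    1L + floor((hi - lo) / sep_frac)
  }
  side(width_frac / 2, 0.5 - sep_frac) + side(0.5 + sep_frac, 1 - width_frac / 2)
}

# rate lambda' with E[min(Pois(lambda'), cap)] == target
capped_poisson_rate <- function(target, cap) {
  if (target == 0) return(0)
  capped_mean <- function(l) {
    k <- 0:(cap - 1)
    sum(k * stats::dpois(k, l)) + cap * stats::ppois(cap - 1, l, lower.tail = FALSE)
  }
  stats::uniroot(function(l) capped_mean(l) - target,
    c(target, 4 * target + 1),
    tol = 1e-10
  )$root
}

#' Synthesise one stroke's velocity pulse train
#'
#' Builds a stroke speed profile as a primary raised-cosine pulse over
#' `[0, duration]` plus `n_extra` secondary raised-cosine pulses
#' (relative amplitude `pulse_amp_frac`, width `pulse_width_frac *
#' duration`, centres mutually separated and separated from the primary
#' peak by at least `pulse_sep_frac * duration`), rescaled so the time
#' integral of speed equals `path`. Velocity components follow a fixed
#' slant: `vx = speed * sin(slant)`, `vy = +/- speed * cos(slant)` with
#' the sign set by `direction`. On a noiseless trace the profile has
#' exactly `1 + n_extra` interior speed maxima.
#'
#' @param duration Stroke duration, s (> 0); realised on the emission
#'   grid as `round(duration * rate)` sample intervals.
#' @param path Stroke path length, cm (> 0).
#' @param n_extra Number of secondary pulses; capped by the margins'
#'   feasible maximum, see [generator_config()].
#' @param direction `"US"` or `"DS"`.
#' @param config A [generator_config()] (margins, slant, rate).
#' @return A list with `vx`, `vy`, `speed` sampled on the emission grid
#'   (including both zero-speed endpoints) and `n_intervals`.
#' @export
simulate_stroke <- function(duration, path, n_extra, direction, config = generator_config()) {
  stopifnot(duration > 0, path > 0)
  if (n_extra > config$max_extra_pulses) {
    stop(sprintf(
      "margins admit at most %d secondary pulses per stroke (requested %d)",
      config$max_extra_pulses, n_extra
    ), call. = FALSE)
  }
  n <- max(8L, round(duration * config$rate_hz))
  tau <- (0:n) / n
  speed <- 0.5 * (1 - cos(2 * pi * tau))
  if (n_extra > 0) {
    w <- config$pulse_width_frac
    sep <- config$pulse_sep_frac
    lo1 <- w / 2
    hi1 <- 0.5 - sep
    lo2 <- 0.5 + sep
    hi2 <- 1 - w / 2
    centres <- if (n_extra == 1) {
      if (stats::runif(1) < 0.5) stats::runif(1, lo1, hi1) else stats::runif(1, lo2, hi2)
    } else {
      c(stats::runif(1, lo1, hi1), stats::runif(1, lo2, hi2))
    }
    for (ct in centres) {
      inside <- abs(tau - ct) <= w / 2
      speed[inside] <- speed[inside] +
        config$pulse_amp_frac * 0.5 * (1 + cos(2 * pi * (tau[inside] - ct) / w))
    }
  }
  dt <- 1 / config$rate_hz
  area <- sum((speed[-1] + speed[-length(speed)]) / 2) * dt
  speed <- speed * path / area
  slant <- config$slant_deg * pi / 180
  sgn <- if (direction == "US") 1 else -1
  list(
    speed = speed, vx = speed * sin(slant), vy = sgn * speed * cos(slant),
    n_intervals = n
  )
}

#' Synthesise one handwriting trial
#'
#' Emits a complete pen trace for one bigram trial: a pen-up lead-in,
#' the first letter's upstroke and downstroke drawn from the configured
#' (group, direction, bigram) cells with the subject's intercepts and
#' trial noise, the second letter as nominal connected strokes (two for
#' *l*, four for *n*) carrying no effects, a pen-up tail, and Gaussian
#' position jitter on every sample. Strokes within the pen-down run
#' share their zero-velocity boundary samples, so vertical velocity
#' reverses exactly between strokes.
#'
#' @param subject_id Subject identifier written into the trace.
#' @param group `"SCZ"` or `"CTRL"`.
#' @param bigram `"ll"` or `"ln"`.
#' @param trial Trial index.
#' @param subject_effects List with `duration` and `trajectory` additive
#'   subject intercepts (use 0 for a noiseless nominal trial).
#' @param config A [generator_config()].
#' @param noise If `FALSE`, suppress trial noise and jitter (nominal
#'   cell-mean trial; used by calibration tests).
#' @return A list with `trace` (a [pen_trace()]) and `truth` (a tibble
#'   of per-stroke nominal duration, path and injected pulse count,
#'   with `first_letter` marking the analysis strokes).
#' @export
simulate_trial <- function(subject_id, group, bigram, trial,
                           subject_effects = list(duration = 0, trajectory = 0),
                           config = generator_config(), noise = TRUE) {
  dm <- config$duration_means
  tm <- config$trajectory_means
  pr <- config$peak_rates
  cell_dur <- function(dir, bg) dm$duration_s[dm$group == group & dm$direction == dir & dm$bigram == bg]
  cell_traj <- function(dir, bg) tm$trajectory_cm[tm$group == group & tm$direction == dir & tm$bigram == bg]
  cell_lambda <- function(dir) pr$lambda_eff[pr$group == group & pr$direction == dir]

  # first-letter strokes carry the design cells; second letter is scenery
  dirs <- c("US", "DS", rep(c("US", "DS"), if (bigram == "ll") 1 else 2))
  letter <- c(1L, 1L, rep(2L, length(dirs) - 2L))
  base_dur <- ifelse(dirs == "US", 0.195, 0.190)
  base_traj <- if (group == "SCZ") 0.840 else 0.625
  nom_dur <- ifelse(letter == 1L, vapply(dirs, cell_dur, numeric(1), bg = bigram), base_dur)
  nom_traj <- ifelse(letter == 1L, vapply(dirs, cell_traj, numeric(1), bg = bigram), base_traj)
  k <- length(dirs)
  pb <- config$path_bias
  bias <- if (is.null(pb)) {
    numeric(k)
  } else {
    ifelse(letter == 1L, vapply(dirs, function(d) {
      pb$bias_cm[pb$group == group & pb$direction == d & pb$bigram == bigram]
    }, numeric(1)), 0)
  }

  nom_dur <- unname(nom_dur)
  nom_traj <- unname(nom_traj)
  bias <- unname(bias)
  dur <- nom_dur + subject_effects$duration +
    if (noise) stats::rnorm(k, 0, config$trial_sd_duration) else 0
  traj <- nom_traj + subject_effects$trajectory +
    if (noise) stats::rnorm(k, 0, config$trial_sd_trajectory) else 0
  dur <- pmax(dur, 0.06)
  traj <- pmax(traj, 0.10)
  # emitted path is corrected for the pipeline's reversal-rounding bias;
  # the ground truth records the measurable target
  traj_emit <- pmax(traj - bias, 0.05)
  n_extra <- integer(k)
  if (noise) {
    n_extra[letter == 1L] <- pmin(
      stats::rpois(sum(letter == 1L), vapply(dirs[letter == 1L], cell_lambda, numeric(1))),
      config$max_extra_pulses
    )
  }

  vx <- vy <- NULL
  for (i in seq_len(k)) {
    s <- simulate_stroke(dur[i], traj_emit[i], n_extra[i], dirs[i], config)
    if (is.null(vx)) {
      vx <- s$vx
      vy <- s$vy
    } else {
      vx <- c(vx, s$vx[-1]) # share the zero-speed boundary sample
      vy <- c(vy, s$vy[-1])
    }
  }
  dt <- 1 / config$rate_hz
  x <- 0.5 + c(0, cumsum((vx[-1] + vx[-length(vx)]) / 2 * dt))
  y <- 1.5 + c(0, cumsum((vy[-1] + vy[-length(vy)]) / 2 * dt))

  n_lead <- round(0.05 * config$rate_hz)
  x <- c(rep(x[1], n_lead), x, rep(x[length(x)], n_lead))
  y <- c(rep(y[1], n_lead), y, rep(y[length(y)], n_lead))
  npts <- length(x)
  ndown <- npts - 2 * n_lead
  p <- c(
    rep(0, n_lead),
    if (noise) {
      pmin(pmax(0.6 + stats::rnorm(ndown, 0, 0.03), 0.2), 0.95)
    } else {
      rep(0.6, ndown)
    },
    rep(0, n_lead)
  )
  if (noise) {
    x <- x + stats::rnorm(npts, 0, config$jitter_sd)
    y <- y + stats::rnorm(npts, 0, config$jitter_sd)
  }
  trace <- new_pen_trace((seq_len(npts) - 1) * dt, x, y, p,
    subject_id = as.character(subject_id), group = group, bigram = bigram,
    trial = as.integer(trial), rate_hz = config$rate_hz
  )
  truth <- tibble::new_tibble(list(
    subject_id = rep(as.character(subject_id), k), group = rep(group, k),
    bigram = rep(bigram, k), trial = rep(as.integer(trial), k),
    stroke = seq_len(k) - 1L, letter = letter, direction = dirs,
    first_letter = letter == 1L,
    nominal_duration_s = dur, nominal_trajectory_cm = traj,
    n_extra_pulses = n_extra
  ), nrow = k)
  list(trace = trace, truth = truth)
}

#' Simulate a complete cohort
#'
#' Generates the full synthetic study: `n_subjects_per_group` subjects
#' per group, `trials_per_bigram` trials of each bigram per subject,
#' per-subject random intercepts, plus clinical covariates for the
#' patient group. Fully reproducible from `config$seed`. If `dir` is
#' given, every trace is written as a plain-text trace file along with
#' `manifest.csv`, `ground_truth.csv` and `covariates.csv`; otherwise
#' traces are returned in-memory as a `trace` list-column.
#'
#' @param config A [generator_config()].
#' @param dir Optional output directory.
#' @return A list with `manifest` (tibble; with a `trace` list-column
#'   and, when `dir` is given, a `path` column), `truth`, `covariates`
#'   and `config`.
#' @export
simulate_cohort <- function(config = generator_config(), dir = NULL) {
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  subjects <- tibble::tibble(
    subject_id = c(
      sprintf("CTRL%02d", seq_len(config$n_subjects_per_group)),
      sprintf("SCZ%02d", seq_len(config$n_subjects_per_group))
    ),
    group = rep(c("CTRL", "SCZ"), each = config$n_subjects_per_group),
    eff_duration = stats::rnorm(2 * config$n_subjects_per_group, 0, config$subject_sd_duration),
    eff_trajectory = stats::rnorm(2 * config$n_subjects_per_group, 0, config$subject_sd_trajectory)
  )

  n_trials <- nrow(subjects) * 2L * config$trials_per_bigram
  msub <- mgrp <- mbig <- character(n_trials)
  mtrial <- integer(n_trials)
  traces <- vector("list", n_trials)
  truths <- vector("list", n_trials)
  i <- 0L
  for (si in seq_len(nrow(subjects))) {
    eff <- list(
      duration = subjects$eff_duration[si],
      trajectory = subjects$eff_trajectory[si]
    )
    for (bg in c("ll", "ln")) {
      for (tr in seq_len(config$trials_per_bigram)) {
        sim <- simulate_trial(
          subjects$subject_id[si], subjects$group[si], bg, tr,
          subject_effects = eff, config = config
        )
        i <- i + 1L
        msub[i] <- subjects$subject_id[si]
        mgrp[i] <- subjects$group[si]
        mbig[i] <- bg
        mtrial[i] <- tr
        traces[[i]] <- sim$trace
        truths[[i]] <- sim$truth
      }
    }
  }
  manifest <- tibble::tibble(
    subject_id = msub, group = mgrp, bigram = mbig, trial = mtrial,
    trace = traces
  )
  truth <- dplyr::bind_rows(truths)

  scz <- subjects[subjects$group == "SCZ", ]
  covariates <- simulate_clinical(
    scz$subject_id,
    subject_trajectory = 0.840 + scz$eff_trajectory
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    traces_dir <- file.path(dir, "traces")
    if (!dir.exists(traces_dir)) dir.create(traces_dir)
    manifest$path <- file.path("traces", sprintf(
      "%s_%s_%02d.csv", manifest$subject_id, manifest$bigram, manifest$trial
    ))
    purrr::walk2(manifest$trace, file.path(dir, manifest$path), write_pen_trace)
    readr::write_csv(dplyr::select(manifest, -"trace"), file.path(dir, "manifest.csv"))
    readr::write_csv(truth, file.path(dir, "ground_truth.csv"))
    readr::write_csv(covariates, file.path(dir, "covariates.csv"))
  }
  list(manifest = manifest, truth = truth, covariates = covariates, config = config)
}

#' Simulate clinical covariates for the patient group
#'
#' Draws each clinical variable from a truncated normal whose location
#' is solved so that the realised mean equals the target mean at the
#' target SD scale (lower bounds: PANSS subscales at their scale minima
#' 7/7/16; SAS, CPZE, illness and education years and Purdue subscores
#' at 0). The dominant-hand Purdue score is coupled to each subject's
#' mean stroke trajectory through a Gaussian copula at Spearman rank
#' correlation `rho_purdue_traj` (worse dexterity goes with longer
#' strokes); all other variables are independent.
#'
#' @param subject_id Patient identifiers.
#' @param subject_trajectory Per-subject mean stroke trajectory (cm)
#'   used for the copula coupling.
#' @param rho_purdue_traj Target Spearman correlation between the
#'   dominant-hand Purdue score and trajectory (default -0.5).
#' @return A tibble of covariates keyed by `subject_id`.
#' @export
simulate_clinical <- function(subject_id, subject_trajectory,
                              rho_purdue_traj = -0.5) {
  n <- length(subject_id)
  stopifnot(n >= 1, length(subject_trajectory) == n)
  spec <- clinical_spec()
  draw <- function(v) rtrunc_calibrated(n, spec[[v]]$mean, spec[[v]]$sd, spec[[v]]$lower)

  out <- tibble::tibble(subject_id = as.character(subject_id))
  for (v in setdiff(names(spec), "purdue_dom")) out[[v]] <- draw(v)

  # Gaussian copula: normal scores of trajectory, target rank correlation
  rho_g <- 2 * sin(pi * rho_purdue_traj / 6)
  z_traj <- stats::qnorm((rank(subject_trajectory, ties.method = "average") - 0.5) / n)
  z <- rho_g * z_traj + sqrt(1 - rho_g^2) * stats::rnorm(n)
  s <- spec$purdue_dom
  mloc <- trunc_location(s$mean, s$sd, s$lower)
  out$purdue_dom <- mloc + s$sd * stats::qnorm(
    stats::pnorm((s$lower - mloc) / s$sd) +
      stats::pnorm(z) * stats::pnorm((s$lower - mloc) / s$sd, lower.tail = FALSE)
  )
  out[c(
    "subject_id", "panss_p", "panss_n", "panss_g", "sas", "cpze",
    "illness_years", "education_years", "purdue_dom", "purdue_nondom",
    "purdue_both", "purdue_asm"
  )]
}

clinical_spec <- function() {
  list(
    panss_p = list(mean = 16.04, sd = 5.39, lower = 7),
    panss_n = list(mean = 20.22, sd = 6.96, lower = 7),
    panss_g = list(mean = 33.86, sd = 10.00, lower = 16),
    sas = list(mean = 3.21, sd = 5.09, lower = 0),
    cpze = list(mean = 779.37, sd = 419.28, lower = 0),
    illness_years = list(mean = 15.36, sd = 10.11, lower = 0),
    education_years = list(mean = 10.79, sd = 4.48, lower = 0),
    purdue_dom = list(mean = 13.74, sd = 8.65, lower = 0),
    purdue_nondom = list(mean = 10.73, sd = 2.95, lower = 0),
    purdue_both = list(mean = 8.01, sd = 2.25, lower = 0),
    purdue_asm = list(mean = 28.59, sd = 9.23, lower = 0)
  )
}

# location m such that E[X] == target for X ~ N(m, sd^2) truncated below at lb
trunc_location <- function(target, sd, lb) {
  tmean <- function(m) {
    a <- (lb - m) / sd
    m + sd * stats::dnorm(a) / stats::pnorm(a, lower.tail = FALSE)
  }
  stats::uniroot(function(m) tmean(m) - target,
    c(target - 6 * sd, target + sd),
    tol = 1e-10, extendInt = "upX"
  )$root
}

rtrunc_calibrated <- function(n, target, sd, lb) {
  m <- trunc_location(target, sd, lb)
  plo <- stats::pnorm((lb - m) / sd)
  u <- plo + stats::runif(n) * (1 - plo)
  m + sd * stats::qnorm(u)
}
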