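#' Extract first-letter stroke features from a trial
#'
#' Runs the full trace-to-stroke pipeline — resample, low-pass filter,
#' differentiate, segment — and measures the analysis unit of the
#' anticipation design: the first letter's upstroke (US) and downstroke
#' (DS). Both bigrams studied here (*ll*, *ln*) begin with a cursive *l*,
#' so the first letter is identified positionally as strokes 0 and 1 of
#' the first pen-down run.
#'
#' Quality-control flags: `too_few_strokes` when the first pen-down run
#' has fewer than 2 strokes, and `first_stroke_not_US` when the trial
#' does not open with an ascending stroke. Flagged trials report their
#' kinematic measures as `NA` and are excluded downstream by
#' [aggregate_cells()].
#'
#' @param trace A [pen_trace()].
#' @param params A [seg_params()] list.
#' @return A tibble with two rows (`direction` `"US"`, `"DS"`) and
#'   columns `subject_id`, `group`, `bigram`, `trial`, `direction`,
#'   `duration_s`, `trajectory_cm`, `n_peaks`, `qc_too_few_strokes`,
#'   `qc_first_stroke_not_us`.
#' @export
extract_trial_features <- function(trace, params = seg_params()) {
  validate_pen_samples(trace)
  m <- trace_meta(trace)
  core <- extract_core(trace$t, trace$x, trace$y, trace$p, params)
  tibble::tibble(
    subject_id = m$subject_id, group = m$group, bigram = m$bigram,
    trial = m$trial, direction = c("US", "DS"),
    duration_s = core$duration_s, trajectory_cm = core$trajectory_cm,
    n_peaks = core$n_peaks,
    qc_too_few_strokes = core$too_few, qc_first_stroke_not_us = core$not_us
  )
}

# vector fast path: resample -> smooth (10 Hz segmentation channel +
# dysfluency velocity channel) -> segment -> measure strokes 0 and 1 of
# the first pen-down run
extract_core <- function(tt, x, y, p, params) {
  rate <- params$resample_rate
  dt <- 1 / rate
  n_in <- length(tt)
  if (n_in < 2) stop("trace too short to resample", call. = FALSE)
  grid <- tt[1] + seq(0, floor((tt[n_in] - tt[1]) * rate)) / rate
  if (n_in == length(grid) && max(abs(tt - grid)) < 0.01 * dt) {
    xu <- x
    yu <- y
    pu <- p
  } else {
    xu <- stats::approx(tt, x, grid, rule = 2)$y
    yu <- stats::approx(tt, y, grid, rule = 2)$y
    pu <- stats::approx(tt, p, grid, rule = 2)$y
  }
  if (params$lowpass_cutoff >= rate / 2 || params$dysfluency_cutoff >= rate / 2) {
    stop("filter cutoffs must be below the Nyquist frequency", call. = FALSE)
  }
  bf <- butter_cached(params$lowpass_cutoff / (rate / 2))
  xs <- filtfilt_padded(bf, xu)
  ys <- filtfilt_padded(bf, yu)
  vy <- deriv_central(ys, dt)
  bfd <- butter_cached(params$dysfluency_cutoff / (rate / 2))
  vxd <- deriv_central(filtfilt_padded(bfd, xu), dt)
  vyd <- deriv_central(filtfilt_padded(bfd, yu), dt)
  speed_dys <- sqrt(vxd^2 + vyd^2)

  seg <- segment_core(vy, pu, dt, params)
  first <- which(seg$run == seg$run[1])
  too_few <- length(first) < 2
  not_us <- !too_few && !seg$up[first[1]]
  out <- list(
    duration_s = c(NA_real_, NA_real_), trajectory_cm = c(NA_real_, NA_real_),
    n_peaks = c(NA_integer_, NA_integer_), too_few = too_few, not_us = not_us
  )
  if (too_few || not_us) return(out)
  for (i in 1:2) {
    a <- seg$start[first[i]]
    b <- seg$end[first[i]]
    out$duration_s[i] <- (b - a) * dt
    out$trajectory_cm[i] <- path_length(xs[a:b], ys[a:b])
    out$n_peaks[i] <- count_velocity_peaks(speed_dys[a:b], params, rate)
  }
  out
}

#' Extract features for a whole cohort
#'
#' Maps [extract_trial_features()] over the trials of a cohort, supplied
#' either as a manifest tibble with a `trace` list-column (as returned by
#' [simulate_cohort()]) or as a manifest of file paths (as returned by
#' [read_manifest()]), and binds the results into one long table.
#'
#' @param manifest Cohort manifest tibble; needs either a `trace`
#'   list-column of [pen_trace()] objects or a `path` column.
#' @param params A [seg_params()] list.
#' @return A tibble of trial features, two rows per trial.
#' @export
extract_features <- function(manifest, params = seg_params()) {
  traces <- if ("trace" %in% names(manifest)) {
    manifest$trace
  } else if ("path" %in% names(manifest)) {
    purrr::map(manifest$path, read_pen_trace)
  } else {
    stop("manifest needs a 'trace' list-column or a 'path' column", call. = FALSE)
  }
  n <- length(traces)
  dur <- traj <- matrix(NA_real_, n, 2)
  pk <- matrix(NA_integer_, n, 2)
  too_few <- not_us <- logical(n)
  for (i in seq_len(n)) {
    tr <- traces[[i]]
    core <- extract_core(tr$t, tr$x, tr$y, tr$p, params)
    dur[i, ] <- core$duration_s
    traj[i, ] <- core$trajectory_cm
    pk[i, ] <- core$n_peaks
    too_few[i] <- core$too_few
    not_us[i] <- core$not_us
  }
  idx <- rep(seq_len(n), each = 2)
  tibble::tibble(
    subject_id = manifest$subject_id[idx], group = manifest$group[idx],
    bigram = manifest$bigram[idx], trial = manifest$trial[idx],
    direction = rep(c("US", "DS"), n),
    duration_s = as.vector(t(dur)), trajectory_cm = as.vector(t(traj)),
    n_peaks = as.vector(t(pk)),
    qc_too_few_strokes = too_few[idx], qc_first_stroke_not_us = not_us[idx]
  )
}

#' Aggregate trial features into subject-level cells
#'
#' Averages unflagged trials within each (subject, direction, bigram)
#' cell — the unit that enters the random-intercept mixed model, whose
#' random effect is per subject, not per trial. Cells in which every
#' trial is flagged are dropped (not imputed) and reported in the
#' `dropped_cells` attribute.
#'
#' @param features Trial-feature table from [extract_features()].
#' @return A tibble with one row per (subject, direction, bigram):
#'   `subject_id`, `group`, `direction`, `bigram`, `duration_s`,
#'   `trajectory_cm`, `n_peaks` (means over trials) and `n_trials`.
#'   Attribute `dropped_cells` lists excluded cells.
#' @export
aggregate_cells <- function(features) {
  flagged <- features$qc_too_few_strokes | features$qc_first_stroke_not_us
  ok <- features[!flagged, ]
  cells <- ok |>
    dplyr::group_by(.data$subject_id, .data$group, .data$direction, .data$bigram) |>
    dplyr::summarise(
      duration_s = mean(.data$duration_s),
      trajectory_cm = mean(.data$trajectory_cm),
      n_peaks = mean(.data$n_peaks),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
  all_cells <- features |>
    dplyr::distinct(.data$subject_id, .data$group, .data$direction, .data$bigram)
  dropped <- dplyr::anti_join(all_cells, cells,
    by = c("subject_id", "group", "direction", "bigram")
  )
  attr(cells, "dropped_cells") <- dropped
  cells
}
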