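#' Segmentation and peak-detection parameters
#'
#' Bundles every tunable of the trace-to-stroke pipeline. Defaults are
#' chosen for 200 Hz pen data and strokes in the 150-300 ms range typical
#' of cursive letter production.
#'
#' @param resample_rate Uniform resampling rate, Hz.
#' @param lowpass_cutoff Low-pass corner frequency for position
#'   smoothing, Hz (zero-phase 4th-order Butterworth). This channel
#'   drives stroke segmentation, durations and path lengths.
#' @param dysfluency_cutoff Corner frequency, Hz, of the separate
#'   velocity channel on which velocity peaks are counted. Dysfluency
#'   events live at higher frequencies than stroke-scale movement: a
#'   10 Hz position filter erases them, while raw differentiation
#'   amplifies tablet jitter; 35 Hz passes secondary velocity pulses of
#'   a few tens of ms while keeping the differentiated jitter floor
#'   well below the prominence criterion.
#' @param pressure_threshold Normalised pressure above which the pen
#'   counts as touching the tablet.
#' @param hysteresis_frac Fraction of the pen-down run's maximum
#'   `|vy|` that the vertical velocity must exceed on both sides of a
#'   sign change before the change counts as a stroke boundary.
#' @param min_stroke_duration Candidate strokes shorter than this (s)
#'   are merged into the preceding stroke.
#' @param peak_prominence_frac Minimum topographic prominence of a
#'   velocity peak, as a fraction of the stroke's maximum speed.
#' @param min_peak_separation Minimum time (s) between counted peaks.
#' @return A list of class `seg_params`.
#' @export
seg_params <- function(resample_rate = 200, lowpass_cutoff = 10,
                       dysfluency_cutoff = 35,
                       pressure_threshold = 0.10, hysteresis_frac = 0.05,
                       min_stroke_duration = 0.03,
                       peak_prominence_frac = 0.10,
                       min_peak_separation = 0.02) {
  p <- list(
    resample_rate = resample_rate, lowpass_cutoff = lowpass_cutoff,
    dysfluency_cutoff = dysfluency_cutoff,
    pressure_threshold = pressure_threshold, hysteresis_frac = hysteresis_frac,
    min_stroke_duration = min_stroke_duration,
    peak_prominence_frac = peak_prominence_frac,
    min_peak_separation = min_peak_separation
  )
  if (!all(vapply(p, function(v) is.numeric(v) && length(v) == 1 && is.finite(v) && v > 0, TRUE))) {
    stop("all segmentation parameters must be single positive numbers", call. = FALSE)
  }
  if (hysteresis_frac >= 1 || peak_prominence_frac >= 1) {
    stop("hysteresis_frac and peak_prominence_frac must lie in (0, 1)", call. = FALSE)
  }
  structure(p, class = "seg_params")
}

#' Resample a pen trace onto a uniform time grid
#'
#' Linear interpolation of `x`, `y` and `p` onto `seq(t0, t1, by = 1/rate)`.
#'
#' @param trace A [pen_trace()] with at least 2 samples.
#' @param rate Target rate in Hz.
#' @return A uniform [pen_trace()] with `rate_hz` set.
#' @export
resample_trace <- function(trace, rate) {
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("rate must be a single positive number", call. = FALSE)
  }
  if (nrow(trace) < 2) stop("resampling needs at least 2 samples", call. = FALSE)
  tt <- trace$t
  grid <- tt[1] + seq(0, floor((tt[length(tt)] - tt[1]) * rate)) / rate
  samples <- tibble::tibble(
    t = grid,
    x = stats::approx(tt, trace$x, grid, rule = 2)$y,
    y = stats::approx(tt, trace$y, grid, rule = 2)$y,
    p = stats::approx(tt, trace$p, grid, rule = 2)$y
  )
  retrace(trace, samples, rate_hz = rate)
}

#' Low-pass filter pen positions
#'
#' Zero-phase (forward-backward) 4th-order Butterworth filtering of `x`
#' and `y`; pressure is left untouched. The trace is reflection-padded at
#' both ends before filtering to suppress edge transients, then trimmed.
#'
#' @param trace A uniform [pen_trace()] (run [resample_trace()] first).
#' @param cutoff Corner frequency in Hz; must be below the Nyquist rate.
#' @return The smoothed [pen_trace()].
#' @export
smooth_trace <- function(trace, cutoff = 10) {
  rate <- attr(trace, "rate_hz")
  if (is.na(rate)) stop("smooth_trace needs a uniform trace with a known rate", call. = FALSE)
  if (cutoff >= rate / 2) stop("cutoff must be below the Nyquist frequency", call. = FALSE)
  bf <- butter_cached(cutoff / (rate / 2))
  samples <- trace[c("t", "x", "y", "p")]
  samples$x <- filtfilt_padded(bf, trace$x)
  samples$y <- filtfilt_padded(bf, trace$y)
  retrace(trace, samples, rate_hz = rate)
}

.butter_cache <- new.env(parent = emptyenv())

butter_cached <- function(W) {
  key <- format(W, digits = 12)
  bf <- .butter_cache[[key]]
  if (is.null(bf)) {
    bf <- signal::butter(4, W)
    .butter_cache[[key]] <- bf
  }
  bf
}

# zero-phase (forward-backward) IIR filtering with reflection padding
filtfilt_padded <- function(bf, x) {
  n <- length(x)
  pad <- min(n - 1L, 50L)
  if (pad < 2L) return(x)
  xp <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  b <- bf$b
  a <- bf$a
  nb <- length(b) - 1L
  one_pass <- function(z) {
    # remove the initial level so zero initial conditions see no step
    # (the filter has unit DC gain, so the level passes through exactly)
    z1 <- z[1]
    z <- z - z1
    v <- stats::filter(c(rep(0, nb), z), b, sides = 1)[-seq_len(nb)]
    as.numeric(stats::filter(v, -a[-1], method = "recursive")) + z1
  }
  y <- rev(one_pass(rev(one_pass(xp))))
  y[(pad + 1):(pad + n)]
}

#' Velocity profile of a uniform trace
#'
#' Differentiates positions by central differences in the interior and
#' one-sided differences at the edges, and returns the tangential speed
#' `sqrt(vx^2 + vy^2)`.
#'
#' @param trace A uniform, smoothed [pen_trace()] with at least 3 samples.
#' @return A tibble with columns `t`, `vx`, `vy`, `speed` (cm/s).
#' @export
velocity_profile <- function(trace) {
  n <- nrow(trace)
  if (n < 3) stop("velocity profile needs at least 3 samples", call. = FALSE)
  rate <- attr(trace, "rate_hz")
  if (is.na(rate)) stop("velocity_profile needs a uniform trace", call. = FALSE)
  vx <- deriv_central(trace$x, 1 / rate)
  vy <- deriv_central(trace$y, 1 / rate)
  tibble::tibble(t = trace$t, vx = vx, vy = vy, speed = sqrt(vx^2 + vy^2))
}

deriv_central <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Segment a pen trace into upstrokes and downstrokes
#'
#' Pen-down segments are maximal runs with pressure above
#' `pressure_threshold`. Within each run, stroke boundaries sit at
#' reversals of the vertical velocity `vy`: a sign change counts only
#' once `|vy|` has exceeded `hysteresis_frac * max(|vy|)` on both sides
#' of it, and the boundary is placed at the sample of minimal `|vy|`
#' between the two supra-threshold flanks. Candidate strokes shorter
#' than `min_stroke_duration` are merged into the preceding stroke.
#' Direction is the sign of the mean `vy` over the span (`US` up, `DS`
#' down). Consecutive strokes within a run share their boundary sample
#' (where the vertical velocity is essentially zero) and alternate
#' direction.
#'
#' @param profile Velocity profile from [velocity_profile()] on the same
#'   grid as `trace`.
#' @param trace The uniform smoothed [pen_trace()].
#' @param params A [seg_params()] list.
#' @return A tibble with one row per stroke: `run` (pen-down run id),
#'   `stroke` (0-based index among all pen-down strokes), `direction`
#'   (`"US"`/`"DS"`), `start`, `end` (sample indices, inclusive; interior
#'   boundaries are shared between neighbours), `t_start`, `t_end` and
#'   `duration_s = t_end - t_start`.
#' @export
segment_strokes <- function(profile, trace, params = seg_params()) {
  if (nrow(profile) != nrow(trace)) {
    stop("profile and trace must share the sample grid", call. = FALSE)
  }
  rate <- attr(trace, "rate_hz")
  dt <- 1 / rate
  seg <- segment_core(profile$vy, trace$p, dt, params)
  tibble::tibble(
    run = seg$run, stroke = seq_along(seg$start) - 1L,
    direction = ifelse(seg$up, "US", "DS"),
    start = seg$start, end = seg$end,
    t_start = trace$t[seg$start], t_end = trace$t[seg$end],
    duration_s = (seg$end - seg$start) * dt
  )
}

# vector workhorse shared by segment_strokes() and the fast extraction path
segment_core <- function(vy, p, dt, params) {
  down <- p > params$pressure_threshold
  if (!any(down)) stop("trace has no pen-down samples", call. = FALSE)
  r <- rle(down)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  min_len <- round(params$min_stroke_duration / dt)

  run_id <- integer(0)
  sp_start <- integer(0)
  sp_end <- integer(0)
  up <- logical(0)
  for (ri in seq_along(runs)) {
    i0 <- starts[runs[ri]]
    i1 <- ends[runs[ri]]
    v <- vy[i0:i1]
    bounds <- stroke_boundaries(v, params$hysteresis_frac)
    spans <- merge_short(bounds, length(v), min_len, v)
    m <- length(spans$start)
    run_id <- c(run_id, rep(ri, m))
    sp_start <- c(sp_start, spans$start + i0 - 1L)
    sp_end <- c(sp_end, spans$end + i0 - 1L)
    up <- c(up, vapply(seq_len(m), function(si) {
      mean(v[spans$start[si]:spans$end[si]]) >= 0
    }, TRUE))
  }
  list(run = run_id, start = sp_start, end = sp_end, up = up)
}

# boundary indices (local, within-run) of vy sign reversals with hysteresis
stroke_boundaries <- function(vy, hysteresis_frac) {
  thr <- hysteresis_frac * max(abs(vy))
  if (thr == 0) return(integer(0))
  bounds <- integer(0)
  armed <- 0 # sign of the last supra-threshold excursion
  last_supra <- 1L
  for (i in seq_along(vy)) {
    if (abs(vy[i]) > thr) {
      s <- sign(vy[i])
      if (armed == 0) {
        armed <- s
      } else if (s != armed) {
        seg <- last_supra:i
        bounds <- c(bounds, seg[which.min(abs(vy[seg]))])
        armed <- s
      }
      last_supra <- i
    }
  }
  bounds
}

# build spans from boundaries, merging spans shorter than min_len samples
merge_short <- function(bounds, n, min_len, vy) {
  edges <- sort(unique(c(1L, bounds, n)))
  if (length(edges) < 2) edges <- c(1L, n)
  s <- edges[-length(edges)]
  e <- edges[-1]
  repeat {
    short <- which((e - s) < min_len)
    if (!length(short) || length(s) == 1) break
    i <- short[1]
    if (i == 1) { # no preceding stroke: merge into the following one
      s[2] <- s[1]
    } else {
      e[i - 1] <- e[i]
    }
    s <- s[-i]
    e <- e[-i]
  }
  # defensively merge neighbours that ended up with the same direction
  repeat {
    if (length(s) == 1) break
    dirs <- vapply(seq_along(s), function(i) mean(vy[s[i]:e[i]]) >= 0, TRUE)
    same <- which(dirs[-1] == dirs[-length(dirs)])
    if (!length(same)) break
    i <- same[1]
    e[i] <- e[i + 1]
    s <- s[-(i + 1)]
    e <- e[-(i + 1)]
  }
  list(start = s, end = e)
}

#' Path length of a stroke
#'
#' Arc length of the pen path over a sample span: the sum of Euclidean
#' distances between consecutive samples.
#'
#' @param x,y Position vectors (cm) over the stroke span.
#' @return Length in cm (0 for a single sample).
#' @export
path_length <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum(sqrt(diff(x)^2 + diff(y)^2))
}

#' Count velocity peaks (dysfluency) within a stroke
#'
#' Counts strictly interior local maxima of the speed profile whose
#' topographic prominence is at least `peak_prominence_frac` times the
#' stroke's maximum speed and whose nearest counted neighbour is at
#' least `min_peak_separation` away (higher peaks are kept first).
#' Plateaus count once, at their midpoint; maxima at the span edges are
#' never counted. A smooth single-pulse stroke therefore scores 1.
#'
#' @param speed Speed samples (cm/s) over one stroke span.
#' @param params A [seg_params()] list.
#' @param rate Sampling rate in Hz of the span.
#' @return Non-negative integer count.
#' @export
count_velocity_peaks <- function(speed, params = seg_params(), rate = params$resample_rate) {
  n <- length(speed)
  if (n == 0) stop("empty stroke span", call. = FALSE)
  if (n < 3) return(0L)
  cand <- plateau_maxima(speed)
  if (!length(cand)) return(0L)
  prom_min <- params$peak_prominence_frac * max(speed)
  keep <- cand[vapply(cand, function(i) prominence_at(speed, i) >= prom_min, TRUE)]
  if (!length(keep)) return(0L)
  min_gap <- params$min_peak_separation * rate
  ord <- keep[order(-speed[keep], keep)]
  accepted <- integer(0)
  for (i in ord) {
    if (!length(accepted) || all(abs(accepted - i) >= min_gap)) accepted <- c(accepted, i)
  }
  length(accepted)
}

# indices of interior local maxima, plateaus collapsed to their midpoint
plateau_maxima <- function(x) {
  n <- length(x)
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[i]) j <- j + 1L
      if (j < n && x[j + 1L] < x[i]) {
        mid <- (i + j) %/% 2L
        if (mid > 1L && mid < n) out <- c(out, mid)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  out
}

# topographic prominence of x[i] within the span
prominence_at <- function(x, i) {
  h <- x[i]
  left <- x[seq_len(i - 1)]
  higher <- which(left > h)
  lmin <- min(left[seq.int(if (length(higher)) max(higher) else 1L, i - 1L)])
  right <- x[seq.int(i + 1L, length(x))]
  higher <- which(right > h)
  rmin <- min(right[seq_len(if (length(higher)) min(higher) else length(right))])
  h - max(lmin, rmin)
}
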