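# Independent oracles and fixture builders used across the suite.

# Brute-force O(n^2) peak counter: scans every interior sample, decides
# local-maximum status by walking over plateaus, computes topographic
# prominence by full left/right scans, then enforces the separation rule
# greedily by descending height. Deliberately written without reusing
# any implementation internals.
oracle_count_peaks <- function(speed, prom_frac, min_sep_samples) {
  n <- length(speed)
  if (n < 3) return(0L)
  peaks <- integer(0)
  heights <- numeric(0)
  i <- 2L
  while (i <= n - 1L) {
    # walk right over a plateau of equal values
    j <- i
    while (j < n && speed[j + 1L] == speed[i]) j <- j + 1L
    is_max <- speed[i] > speed[i - 1L] && j < n && speed[j + 1L] < speed[i]
    if (is_max) {
      mid <- (i + j) %/% 2L
      if (mid > 1L && mid < n) {
        peaks <- c(peaks, mid)
        heights <- c(heights, speed[i])
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks)) return(0L)
  prom <- vapply(seq_along(peaks), function(k) {
    idx <- peaks[k]
    h <- heights[k]
    lmin <- h
    for (a in seq(idx - 1L, 1L)) {
      if (speed[a] > h) break
      lmin <- min(lmin, speed[a])
    }
    rmin <- h
    for (b in seq(idx + 1L, n)) {
      if (speed[b] > h) break
      rmin <- min(rmin, speed[b])
    }
    h - max(lmin, rmin)
  }, numeric(1))
  thr <- prom_frac * max(speed)
  keep <- which(prom >= thr)
  if (!length(keep)) return(0L)
  keep <- keep[order(-heights[keep], peaks[keep])]
  chosen <- integer(0)
  for (k in keep) {
    if (!length(chosen) || all(abs(peaks[k] - chosen) >= min_sep_samples)) {
      chosen <- c(chosen, peaks[k])
    }
  }
  length(chosen)
}

# a uniform pen trace built from explicit position functions
make_trace <- function(t, x, y, p = 0.6, rate_hz = 1 / diff(t[1:2]), ...) {
  pen_trace(
    data.frame(t = t, x = x, y = y, p = rep_len(p, length(t))),
    rate_hz = rate_hz, ...
  )
}

# small balanced cell table: ns subjects per group, additive effects
make_cells <- function(ns = 3, mu = 0.2, subj_sd = 0.015, cell_sd = 0.01,
                       effects = NULL) {
  grid <- tidyr::expand_grid(
    subject_id = sprintf("S%02d", seq_len(2 * ns)),
    direction = c("US", "DS"), bigram = c("ll", "ln")
  )
  grid$group <- ifelse(as.integer(sub("S", "", grid$subject_id)) <= ns, "CTRL", "SCZ")
  se <- stats::rnorm(2 * ns, 0, subj_sd)
  names(se) <- sprintf("S%02d", seq_len(2 * ns))
  y <- mu + se[grid$subject_id] + stats::rnorm(nrow(grid), 0, cell_sd)
  if (!is.null(effects)) y <- y + effects(grid)
  grid$duration_s <- unname(y)
  grid$trajectory_cm <- unname(y)
  grid$n_peaks <- 1
  grid$n_trials <- 1L
  grid
}
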