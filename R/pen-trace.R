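#' Construct a pen trace
#'
#' A pen trace is the raw observable of a handwriting trial: an ordered
#' sequence of timestamped pen samples recorded by a digitising tablet,
#' together with trial metadata. It is represented as a tibble with columns
#' `t` (seconds from trial start), `x`, `y` (position in cm, `y` increasing
#' upward, origin at the active area's bottom-left) and `p` (pen pressure
#' normalised to `[0, 1]`; `p = 0` means the pen is lifted), carrying the
#' trial metadata as attributes.
#'
#' @param samples A data frame with numeric columns `t`, `x`, `y`, `p`.
#'   Times must be finite, non-negative and strictly increasing; pressure
#'   must lie in `[0, 1]`.
#' @param subject_id Opaque subject identifier.
#' @param group Group label, one of `"SCZ"`, `"CTRL"` (or `NA`).
#' @param bigram Bigram label, one of `"ll"`, `"ln"` (or `NA`).
#' @param trial Positive integer trial index (or `NA`).
#' @param rate_hz Nominal sampling rate in Hz; `NA` if the sampling is not
#'   uniform.
#'
#' @return A tibble of class `pen_trace`.
#' @export
#' @examples
#' tr <- pen_trace(data.frame(t = c(0, 0.005, 0.01), x = 0, y = 1:3 / 10, p = 0.5))
#' trace_meta(tr)
pen_trace <- function(samples, subject_id = NA_character_, group = NA_character_,
                      bigram = NA_character_, trial = NA_integer_,
                      rate_hz = NA_real_) {
  stopifnot(is.data.frame(samples))
  need <- c("t", "x", "y", "p")
  if (!all(need %in% names(samples))) {
    stop("pen trace samples need columns t, x, y, p", call. = FALSE)
  }
  out <- tibble::as_tibble(samples[need])
  validate_pen_samples(out)
  if (!is.na(group)) group <- match.arg(group, c("SCZ", "CTRL"))
  if (!is.na(bigram)) bigram <- match.arg(bigram, c("ll", "ln"))
  if (!is.na(trial) && (trial < 1 || trial != round(trial))) {
    stop("trial must be a positive integer", call. = FALSE)
  }
  structure(out,
    class = c("pen_trace", class(out)),
    subject_id = as.character(subject_id), group = group, bigram = bigram,
    trial = if (is.na(trial)) NA_integer_ else as.integer(trial),
    rate_hz = as.numeric(rate_hz)
  )
}

validate_pen_samples <- function(df) {
  if (nrow(df) == 0) stop("pen trace has no samples", call. = FALSE)
  if (!all(is.finite(df$t)) || any(df$t < 0)) {
    stop("sample times must be finite and non-negative", call. = FALSE)
  }
  if (nrow(df) > 1 && any(diff(df$t) <= 0)) {
    bad <- which(diff(df$t) <= 0)[1] + 1
    stop(sprintf("sample times must be strictly increasing (violated at sample %d)", bad),
      call. = FALSE
    )
  }
  if (any(!is.finite(df$p)) || any(df$p < 0 | df$p > 1)) {
    stop("pressure must lie in [0, 1]", call. = FALSE)
  }
  invisible(df)
}

#' Trial metadata of a pen trace
#'
#' @param trace A [pen_trace()].
#' @return A one-row tibble with `subject_id`, `group`, `bigram`, `trial`
#'   and `rate_hz`.
#' @export
trace_meta <- function(trace) {
  tibble::tibble(
    subject_id = attr(trace, "subject_id") %||% NA_character_,
    group = attr(trace, "group") %||% NA_character_,
    bigram = attr(trace, "bigram") %||% NA_character_,
    trial = attr(trace, "trial") %||% NA_integer_,
    rate_hz = attr(trace, "rate_hz") %||% NA_real_
  )
}

# rebuild a pen_trace from new samples, keeping metadata
retrace <- function(trace, samples, rate_hz = attr(trace, "rate_hz")) {
  pen_trace(samples,
    subject_id = attr(trace, "subject_id") %||% NA_character_,
    group = attr(trace, "group") %||% NA_character_,
    bigram = attr(trace, "bigram") %||% NA_character_,
    trial = attr(trace, "trial") %||% NA_integer_,
    rate_hz = rate_hz
  )
}

# fast internal constructor for samples known to satisfy the invariants
new_pen_trace <- function(t, x, y, p, subject_id, group, bigram, trial, rate_hz) {
  out <- tibble::new_tibble(
    list(t = t, x = x, y = y, p = p),
    nrow = length(t), class = "pen_trace"
  )
  attr(out, "subject_id") <- subject_id
  attr(out, "group") <- group
  attr(out, "bigram") <- bigram
  attr(out, "trial") <- trial
  attr(out, "rate_hz") <- rate_hz
  out
}

#' @export
print.pen_trace <- function(x, ...) {
  m <- trace_meta(x)
  cat(sprintf(
    "<pen_trace> %d samples over %.3f s  subject=%s group=%s bigram=%s trial=%s rate=%s Hz\n",
    nrow(x), diff(range(x$t)), m$subject_id, m$group, m$bigram,
    as.character(m$trial), as.character(m$rate_hz)
  ))
  NextMethod()
}
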