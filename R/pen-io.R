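#' Convert raw tablet counts to centimetres
#'
#' Digitising tablets report pen position as integer counts at a stated
#' spatial resolution in lines per inch (lpi); physical length is
#' `counts / lpi * 2.54`.
#'
#' @param raw Numeric vector of tablet counts.
#' @param lpi Tablet resolution in lines per inch (must be positive); the
#'   class of tablet targeted here reports 5080 lpi.
#' @return Length in cm.
#' @export
#' @examples
#' counts_to_cm(5080, 5080) # one inch
counts_to_cm <- function(raw, lpi) {
  if (!is.numeric(lpi) || length(lpi) != 1 || !is.finite(lpi) || lpi <= 0) {
    stop("lpi must be a single positive number", call. = FALSE)
  }
  raw / lpi * 2.54
}

#' Read a pen-trace file
#'
#' Reads the plain-text trace format: a `#`-prefixed header block of
#' `key: value` lines (at least `dialect`; optionally `lpi`,
#' `active_height_cm`, `pressure_max`, `y_axis`, `rate_hz`, `subject_id`,
#' `group`, `bigram`, `trial`) followed by a CSV body with columns
#' `t,x,y,p`.
#'
#' Two dialects are understood. `cm`: positions already in cm with `y`
#' increasing upward and pressure in `[0, 1]`. `raw_counts`: positions in
#' integer tablet counts converted via [counts_to_cm()] with the
#' header-declared `lpi`, pressure divided by `pressure_max` (default
#' 8191, i.e. 8192 levels), and — unless the header says `y_axis: up` —
#' the vertical axis flipped to y-up using the declared
#' `active_height_cm`.
#'
#' @param path File path.
#' @param dialect `"auto"` (use the header; the default), `"cm"` or
#'   `"raw_counts"`. An explicit value must agree with a header
#'   declaration when both are present.
#' @return A [pen_trace()] in cm with strictly increasing times.
#' @export
read_pen_trace <- function(path, dialect = c("auto", "cm", "raw_counts")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such trace file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr_idx <- grep("^#", lines)
  hdr_idx <- hdr_idx[hdr_idx == seq_along(hdr_idx)] # leading block only
  hdr <- parse_header(lines[hdr_idx], path)
  body <- lines[-seq_len(length(hdr_idx))]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 2) stop("trace file has no data rows: ", path, call. = FALSE)
  if (!identical(trimws(body[1]), "t,x,y,p")) {
    stop(sprintf("malformed header in %s: expected column line 't,x,y,p' at line %d",
      path, length(hdr_idx) + 1L), call. = FALSE)
  }

  file_dialect <- hdr[["dialect"]]
  if (dialect == "auto") {
    if (is.null(file_dialect)) stop("no dialect declared in header of ", path, call. = FALSE)
    dialect <- file_dialect
  } else if (!is.null(file_dialect) && !identical(file_dialect, dialect)) {
    stop(sprintf("declared dialect '%s' does not match file header '%s' in %s",
      dialect, file_dialect, path), call. = FALSE)
  }
  if (!dialect %in% c("cm", "raw_counts")) {
    stop("unknown dialect '", dialect, "' in ", path, call. = FALSE)
  }

  df <- utils::read.csv(text = body, header = TRUE, colClasses = "character")
  df[] <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  bad <- which(!stats::complete.cases(df) | !apply(is.finite(as.matrix(df)), 1, all))
  if (length(bad)) {
    stop(sprintf("non-numeric or missing cell in %s at line %d",
      path, length(hdr_idx) + 1L + bad[1]), call. = FALSE)
  }
  if (nrow(df) > 1 && any(diff(df$t) <= 0)) {
    bad <- which(diff(df$t) <= 0)[1] + 1
    stop(sprintf("non-increasing timestamps in %s at data row %d", path, bad), call. = FALSE)
  }

  if (dialect == "raw_counts") {
    lpi <- hdr_num(hdr, "lpi", required = TRUE, path = path)
    pmax_lvl <- hdr_num(hdr, "pressure_max") %||% 8191
    if (any(df$p < 0 | df$p > pmax_lvl)) {
      stop(sprintf("pressure outside declared range [0, %g] in %s", pmax_lvl, path),
        call. = FALSE)
    }
    y_axis <- hdr[["y_axis"]] %||% "down"
    df$x <- counts_to_cm(df$x, lpi)
    y_cm <- counts_to_cm(df$y, lpi)
    if (identical(y_axis, "down")) {
      h <- hdr_num(hdr, "active_height_cm", required = TRUE, path = path)
      y_cm <- h - y_cm
    }
    df$y <- y_cm
    df$p <- df$p / pmax_lvl
  } else if (any(df$p < 0 | df$p > 1)) {
    stop("pressure outside declared range [0, 1] in ", path, call. = FALSE)
  }

  nominal <- hdr_num(hdr, "rate_hz") %||% infer_rate(df$t)
  pen_trace(df,
    subject_id = hdr[["subject_id"]] %||% NA_character_,
    group = hdr[["group"]] %||% NA_character_,
    bigram = hdr[["bigram"]] %||% NA_character_,
    trial = as.integer(hdr_num(hdr, "trial") %||% NA_integer_),
    rate_hz = nominal
  )
}

parse_header <- function(lines, path) {
  out <- list()
  for (i in seq_along(lines)) {
    ln <- sub("^#\\s*", "", lines[i])
    if (!nzchar(ln) || !grepl(":", ln)) next
    key <- trimws(sub(":.*$", "", ln))
    val <- trimws(sub("^[^:]*:", "", ln))
    out[[key]] <- val
  }
  out
}

hdr_num <- function(hdr, key, required = FALSE, path = "") {
  v <- hdr[[key]]
  if (is.null(v)) {
    if (required) stop(sprintf("malformed header in %s: missing '%s'", path, key), call. = FALSE)
    return(NULL)
  }
  num <- suppressWarnings(as.numeric(v))
  if (is.na(num)) stop(sprintf("malformed header in %s: '%s' is not numeric", path, key), call. = FALSE)
  num
}

# declare a nominal rate only if sampling is uniform to ~1%
infer_rate <- function(t) {
  if (length(t) < 2) return(NA_real_)
  dt <- diff(t)
  if (max(dt) - min(dt) < 0.01 * mean(dt)) 1 / mean(dt) else NA_real_
}

#' Write a pen trace to a file
#'
#' Writes the `cm` dialect of the trace format with six decimals, so a
#' read-back reproduces the samples to within `1e-6` in each coordinate.
#' Pen-up rows (`p = 0`) are data and are preserved.
#'
#' @param trace A valid [pen_trace()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pen_trace <- function(trace, path) {
  validate_pen_samples(trace)
  m <- trace_meta(trace)
  hdr <- c(
    "# penkin trace v1",
    "# dialect: cm",
    if (!is.na(m$rate_hz)) sprintf("# rate_hz: %g", m$rate_hz),
    if (!is.na(m$subject_id)) paste0("# subject_id: ", m$subject_id),
    if (!is.na(m$group)) paste0("# group: ", m$group),
    if (!is.na(m$bigram)) paste0("# bigram: ", m$bigram),
    if (!is.na(m$trial)) sprintf("# trial: %d", m$trial)
  )
  body <- sprintf("%.6f,%.6f,%.6f,%.6f", trace$t, trace$x, trace$y, trace$p)
  ok <- tryCatch(
    {
      writeLines(c(hdr, "t,x,y,p", body), path)
      TRUE
    },
    error = function(e) stop("cannot write trace to ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  invisible(path)
}

#' Read a cohort manifest
#'
#' A manifest lists one handwriting trial per row with columns
#' `subject_id,group,bigram,trial,path`. Paths are resolved relative to
#' the manifest's directory unless absolute.
#'
#' @param path Manifest CSV path.
#' @param check_paths Verify every trace file exists (default `TRUE`).
#' @return A tibble with the manifest columns, `path` resolved.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  man <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("subject_id", "group", "bigram", "trial", "path")
  if (!all(need %in% names(man))) {
    stop("manifest must have columns ", paste(need, collapse = ","), call. = FALSE)
  }
  man <- dplyr::mutate(man,
    subject_id = as.character(.data$subject_id),
    trial = as.integer(.data$trial)
  )
  if (!all(man$group %in% c("SCZ", "CTRL"))) stop("manifest group must be SCZ or CTRL", call. = FALSE)
  if (!all(man$bigram %in% c("ll", "ln"))) stop("manifest bigram must be ll or ln", call. = FALSE)
  key <- paste(man$subject_id, man$bigram, man$trial)
  if (anyDuplicated(key)) {
    stop("manifest rows must be unique in (subject_id, bigram, trial)", call. = FALSE)
  }
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  if (check_paths) {
    missing <- man$path[!file.exists(man$path)]
    if (length(missing)) {
      stop("manifest references missing trace files, e.g. ", missing[1], call. = FALSE)
    }
  }
  man
}

#' Read a clinical covariate table
#'
#' @param path Covariates CSV path with columns `subject_id,panss_p,
#'   panss_n,panss_g,sas,cpze,illness_years,education_years,purdue_dom,
#'   purdue_nondom,purdue_both,purdue_asm`.
#' @return A tibble keyed by `subject_id`.
#' @export
read_covariates <- function(path) {
  cov <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"subject_id" %in% names(cov)) stop("covariates need a subject_id column", call. = FALSE)
  dplyr::mutate(cov, subject_id = as.character(.data$subject_id))
}
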