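#' @importFrom generics tidy glance augment
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a stroke mixed-model fit
#'
#' @param x A [fit_stroke_lmm()] object.
#' @param ... Unused.
#' @return A tibble with one row per fixed-effect coefficient:
#'   `term`, `estimate`, `std.error`, `statistic`.
#' @method tidy stroke_lmm
#' @export
tidy.stroke_lmm <- function(x, ...) {
  se <- sqrt(diag(x$vcov_beta))
  tibble::tibble(
    term = names(x$beta), estimate = unname(x$beta),
    std.error = unname(se), statistic = unname(x$beta / se)
  )
}

#' One-row summary of a stroke mixed-model fit
#'
#' @param x A [fit_stroke_lmm()] object.
#' @param ... Unused.
#' @return A tibble with `response`, `nobs`, `n_subjects`,
#'   `sigma2_subject`, `sigma2_resid`, `lambda`, `logLik`.
#' @method glance stroke_lmm
#' @export
glance.stroke_lmm <- function(x, ...) {
  tibble::tibble(
    response = x$response, nobs = x$n,
    n_subjects = length(unique(x$data$subject_id)),
    sigma2_subject = x$sigma2_subject, sigma2_resid = x$sigma2_resid,
    lambda = x$lambda, logLik = x$logLik_reml
  )
}

#' Augment the cell table with fitted values and residuals
#'
#' @param x A [fit_stroke_lmm()] object.
#' @param ... Unused.
#' @return The model frame with `.fitted` (fixed-effect prediction) and
#'   `.resid` columns.
#' @method augment stroke_lmm
#' @export
augment.stroke_lmm <- function(x, ...) {
  dplyr::mutate(x$data, .fitted = x$fitted, .resid = x$y - x$fitted)
}
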