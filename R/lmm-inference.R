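#' Partial eta-squared from an F statistic
#'
#' The effect-size measure reported alongside ANOVA-style F tests:
#' \deqn{\eta_p^2 = \frac{df_1 F}{df_1 F + df_2}.}
#'
#' @param f F statistic (>= 0).
#' @param df1 Numerator degrees of freedom (>= 1).
#' @param df2 Denominator degrees of freedom (> 0).
#' @return Partial eta-squared in `[0, 1]`. Vectorised.
#' @export
#' @examples
#' partial_eta_sq(11.69, 1, 138)
partial_eta_sq <- function(f, df1, df2) {
  if (any(f < 0) || any(df1 < 1) || any(df2 <= 0)) {
    stop("need f >= 0, df1 >= 1, df2 > 0", call. = FALSE)
  }
  df1 * f / (df1 * f + df2)
}

#' Type-III F tests with Satterthwaite degrees of freedom
#'
#' Wald F tests of the seven model terms (three main effects, three
#' two-way interactions, the three-way interaction) under sum-to-zero
#' coding — with a balanced complete design these coincide with the
#' classical ANOVA decomposition. Each term in the 2x2x2 design carries
#' one numerator df, so \eqn{F = t^2} for the corresponding coefficient;
#' the denominator df comes from the Satterthwaite approximation, with
#' the variance of the contrast-variance estimate obtained by the delta
#' method over \eqn{(\sigma^2_s, \sigma^2_e)} using the inverse of the
#' numerically differentiated REML information.
#'
#' @param fit A [fit_stroke_lmm()] object.
#' @return A tibble with columns `term`, `F`, `df1`, `df2`, `p`,
#'   `eta_p2`.
#' @export
type3_f_tests <- function(fit) {
  stopifnot(inherits(fit, "stroke_lmm"))
  out <- purrr::map(seq_along(fit$term_labels), function(ti) {
    cols <- which(fit$term_assign == ti)
    if (length(cols) != 1) {
      stop("type3_f_tests supports 1-df terms only (two-level factors)", call. = FALSE)
    }
    cvec <- numeric(fit$p)
    cvec[cols] <- 1
    se2 <- drop(t(cvec) %*% fit$vcov_beta %*% cvec)
    Fv <- unname(fit$beta[cols])^2 / se2
    df2 <- satterthwaite_df(fit, cvec)
    tibble::tibble(
      term = fit$term_labels[ti], F = Fv, df1 = 1, df2 = df2,
      p = stats::pf(Fv, 1, df2, lower.tail = FALSE),
      eta_p2 = partial_eta_sq(Fv, 1, df2)
    )
  })
  dplyr::bind_rows(out)
}

#' Descriptive margin means for each model factor
#'
#' The mean and SD of a measure at each level of Group, Direction and
#' Bigram, pooled over the other factors — the descriptives customarily
#' printed alongside the F tests.
#'
#' @param cells Cell table from [aggregate_cells()].
#' @param response Measure column name.
#' @return A tibble with `factor`, `level`, `mean`, `sd`, `n`.
#' @export
margin_means <- function(cells, response) {
  one <- function(fac) {
    cells |>
      dplyr::group_by(level = .data[[fac]]) |>
      dplyr::summarise(
        mean = mean(.data[[response]], na.rm = TRUE),
        sd = stats::sd(.data[[response]], na.rm = TRUE),
        n = sum(!is.na(.data[[response]])), .groups = "drop"
      ) |>
      dplyr::mutate(factor = fac, .before = 1)
  }
  dplyr::bind_rows(purrr::map(c("group", "direction", "bigram"), one))
}

#' Bigram pairwise contrasts within group and direction
#'
#' The four estimated-marginal-mean contrasts `ll - ln`, one within each
#' (group, direction) cell — the anticipation probe: in controls the
#' downstroke of the first letter is expected to be shorter before a
#' repeated *l* than before an *n*, while patients are expected to show
#' no modulation. Standard errors come from the GLS coefficient
#' covariance, per-contrast denominator df from the Satterthwaite
#' approximation, and the four-contrast family is Holm-adjusted.
#'
#' @param fit A [fit_stroke_lmm()] object.
#' @return A tibble with `group`, `direction`, `contrast`, `estimate`,
#'   `se`, `t`, `df`, `p`, `p_holm`.
#' @export
bigram_contrasts <- function(fit) {
  stopifnot(inherits(fit, "stroke_lmm"))
  grid <- tidyr::expand_grid(group = c("CTRL", "SCZ"), direction = c("US", "DS"))
  rows <- purrr::pmap(grid, function(group, direction) {
    xr <- function(bg) {
      nd <- data.frame(
        group = factor(group, levels = c("CTRL", "SCZ")),
        direction = factor(direction, levels = c("US", "DS")),
        bigram = factor(bg, levels = c("ll", "ln"))
      )
      drop(stats::model.matrix(~ group * direction * bigram, nd,
        contrasts.arg = fit$contrasts
      ))
    }
    cvec <- xr("ll") - xr("ln")
    est <- drop(sum(cvec * fit$beta))
    se <- sqrt(drop(t(cvec) %*% fit$vcov_beta %*% cvec))
    df <- satterthwaite_df(fit, cvec)
    tv <- est / se
    tibble::tibble(
      group = group, direction = direction, contrast = "ll - ln",
      estimate = est, se = se, t = tv, df = df,
      p = 2 * stats::pt(abs(tv), df, lower.tail = FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  out$p_holm <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Spearman correlation matrix with two-sided p-values
#'
#' Spearman rank correlations (average ranks for ties,
#' pairwise-complete observations) between every pair of columns, with
#' two-sided p-values from the t approximation
#' \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on `n - 2` df. Used to relate
#' per-subject mean kinematic measures to clinical covariates.
#'
#' @param subjects Subject-level data frame; all columns other than
#'   `subject_id` are correlated.
#' @return A list of class `spearman_matrix` with elements `rho`, `p`
#'   (symmetric matrices, unit/NA diagonal) and `n` (pairwise n).
#' @export
spearman_matrix <- function(subjects) {
  df <- dplyr::select(as.data.frame(subjects), -dplyr::any_of("subject_id"))
  df <- df[vapply(df, is.numeric, TRUE)]
  if (nrow(df) < 4) stop("need at least 4 subjects", call. = FALSE)
  k <- ncol(df)
  vars <- names(df)
  rho <- p <- nn <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      ok <- stats::complete.cases(df[[i]], df[[j]])
      n <- sum(ok)
      nn[i, j] <- n
      if (n < 4) next
      if (stats::sd(df[[i]][ok]) == 0 || stats::sd(df[[j]][ok]) == 0) next
      r <- stats::cor(df[[i]][ok], df[[j]][ok], method = "spearman")
      rho[i, j] <- r
      if (i == j) {
        p[i, j] <- NA_real_
      } else if (abs(r) >= 1) {
        p[i, j] <- 0
      } else {
        tv <- r * sqrt((n - 2) / (1 - r^2))
        p[i, j] <- 2 * stats::pt(abs(tv), n - 2, lower.tail = FALSE)
      }
    }
  }
  structure(list(rho = rho, p = p, n = nn), class = "spearman_matrix")
}

#' @export
print.spearman_matrix <- function(x, digits = 2, ...) {
  cat("<spearman_matrix> ", ncol(x$rho), " variables\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

#' Tidy a Spearman matrix into long format
#'
#' @param x A [spearman_matrix()] object.
#' @param ... Unused.
#' @return A tibble with `var1`, `var2`, `rho`, `p`, `n` for each
#'   unordered pair.
#' @method tidy spearman_matrix
#' @export
tidy.spearman_matrix <- function(x, ...) {
  vars <- colnames(x$rho)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  tibble::tibble(
    var1 = vars[idx[, 1]], var2 = vars[idx[, 2]],
    rho = x$rho[idx], p = x$p[idx], n = x$n[idx]
  )
}
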