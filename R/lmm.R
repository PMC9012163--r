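#' Fit the random-intercept mixed model for one kinematic measure
#'
#' Fits, by restricted maximum likelihood, the linear mixed model
#' \deqn{y = X\beta + Z b + e, \quad b \sim N(0, \sigma^2_s I),\quad
#'       e \sim N(0, \sigma^2_e I)}
#' where the fixed design crosses Group (CTRL/SCZ), Direction (US/DS)
#' and Bigram (ll/ln) with all interactions under sum-to-zero (effect)
#' coding, and `b` holds one random intercept per subject. The response
#' is a subject-level cell mean from [aggregate_cells()].
#'
#' Estimation profiles the REML criterion down to the single variance
#' ratio \eqn{\lambda = \sigma^2_s / \sigma^2_e}: for fixed
#' \eqn{\lambda} the GLS coefficients and the profiled criterion are
#' closed-form, and \eqn{\lambda} is found by bounded one-dimensional
#' search (with the boundary \eqn{\lambda = 0} checked explicitly).
#'
#' @param cells Cell table from [aggregate_cells()] (columns
#'   `subject_id`, `group`, `direction`, `bigram` and the measures).
#' @param response One of `"duration_s"`, `"trajectory_cm"`, `"n_peaks"`.
#' @param lambda_max Upper bound of the variance-ratio search.
#' @return An object of class `stroke_lmm`.
#' @seealso [type3_f_tests()], [bigram_contrasts()], [tidy.stroke_lmm()]
#' @export
fit_stroke_lmm <- function(cells, response = c("duration_s", "trajectory_cm", "n_peaks"),
                           lambda_max = 1e4) {
  response <- match.arg(response)
  df <- as.data.frame(cells)
  df <- df[!is.na(df[[response]]), , drop = FALSE]
  if (length(unique(df$subject_id[df$group == "SCZ"])) < 2 ||
    length(unique(df$subject_id[df$group == "CTRL"])) < 2) {
    stop("need at least 2 subjects per group", call. = FALSE)
  }
  df$group <- factor(df$group, levels = c("CTRL", "SCZ"))
  df$direction <- factor(df$direction, levels = c("US", "DS"))
  df$bigram <- factor(df$bigram, levels = c("ll", "ln"))
  df$subject_id <- factor(df$subject_id)

  cs <- list(group = "contr.sum", direction = "contr.sum", bigram = "contr.sum")
  X <- stats::model.matrix(~ group * direction * bigram, df, contrasts.arg = cs)
  if (qr(X)$rank < ncol(X)) {
    stop("rank-deficient fixed design (a factor level is entirely missing)", call. = FALSE)
  }
  y <- df[[response]]
  subj <- as.integer(df$subject_id)
  n <- length(y)
  p <- ncol(X)

  ZZt <- outer(subj, subj, "==") * 1
  crit <- function(lambda) reml_profile(lambda, y, X, ZZt)$crit

  opt <- stats::optimize(crit, c(0, lambda_max), tol = 1e-9)
  lambda_hat <- opt$minimum
  if (crit(0) <= opt$objective) lambda_hat <- 0
  if (lambda_hat > 0.999 * lambda_max) {
    stop("variance-ratio search did not converge: optimum at the search bound (lambda ~ ",
      signif(lambda_hat, 3), "); inspect the response scale", call. = FALSE)
  }
  fit <- reml_profile(lambda_hat, y, X, ZZt)
  sigma2_e <- fit$qform / (n - p)
  sigma2_s <- lambda_hat * sigma2_e
  loglik <- -0.5 * (fit$crit + (n - p) * (1 + log(2 * pi) - log(n - p)))

  structure(list(
    response = response, data = tibble::as_tibble(df),
    beta = stats::setNames(drop(fit$beta), colnames(X)),
    vcov_beta = sigma2_e * fit$XtViX_inv,
    sigma2_subject = sigma2_s, sigma2_resid = sigma2_e, lambda = lambda_hat,
    logLik_reml = loglik, fitted = unname(drop(X %*% fit$beta)),
    X = X, ZZt = ZZt, y = y, n = n, p = p,
    term_assign = attr(X, "assign"),
    term_labels = attr(stats::terms(~ group * direction * bigram), "term.labels"),
    contrasts = cs
  ), class = "stroke_lmm")
}

# profiled REML pieces at a given variance ratio lambda
reml_profile <- function(lambda, y, X, ZZt) {
  n <- length(y)
  p <- ncol(X)
  V <- diag(n) + lambda * ZZt
  R <- chol(V)
  Vi_X <- backsolve(R, forwardsolve(t(R), X))
  Vi_y <- backsolve(R, forwardsolve(t(R), y))
  XtViX <- crossprod(X, Vi_X)
  XtViX_inv <- solve(XtViX)
  beta <- XtViX_inv %*% crossprod(X, Vi_y)
  r <- y - X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  qform <- max(drop(crossprod(r, Vi_r)), .Machine$double.xmin)
  crit <- 2 * sum(log(diag(R))) + determinant(XtViX)$modulus[1] + (n - p) * log(qform)
  list(crit = crit, beta = beta, XtViX_inv = XtViX_inv, qform = qform)
}

# unprofiled REML log-likelihood at theta = (sigma2_subject, sigma2_resid);
# used for the numerical information matrix behind Satterthwaite df
reml_loglik_theta <- function(theta, fit) {
  s2s <- theta[1]
  s2e <- theta[2]
  n <- fit$n
  p <- fit$p
  Sig <- diag(s2e, n) + s2s * fit$ZZt
  R <- chol(Sig)
  Vi_X <- backsolve(R, forwardsolve(t(R), fit$X))
  Vi_y <- backsolve(R, forwardsolve(t(R), fit$y))
  XtViX <- crossprod(fit$X, Vi_X)
  beta <- solve(XtViX, crossprod(fit$X, Vi_y))
  r <- fit$y - fit$X %*% beta
  Vi_r <- backsolve(R, forwardsolve(t(R), r))
  -0.5 * (2 * sum(log(diag(R))) + determinant(XtViX)$modulus[1] +
    drop(crossprod(r, Vi_r)) + (n - p) * log(2 * pi))
}

# covariance of a fixed-effect contrast as a function of theta
contrast_var_theta <- function(theta, fit, cvec) {
  s2s <- theta[1]
  s2e <- theta[2]
  Sig <- diag(s2e, fit$n) + s2s * fit$ZZt
  R <- chol(Sig)
  Vi_X <- backsolve(R, forwardsolve(t(R), fit$X))
  XtViX <- crossprod(fit$X, Vi_X)
  drop(t(cvec) %*% solve(XtViX, cvec))
}

# Satterthwaite denominator df for a 1-df contrast:
# df = 2 v^2 / (g' A g), v = c'C(theta)c, g its gradient, A = Var(theta_hat)
satterthwaite_df <- function(fit, cvec) {
  theta <- c(fit$sigma2_subject, fit$sigma2_resid)
  v <- contrast_var_theta(theta, fit, cvec)
  # relative steps: the REML surface's numerical noise floor dominates
  # smaller steps; 1e-2 keeps truncation error ~1e-4 relative
  h <- 0.01 * pmax(theta, fit$sigma2_resid)
  g <- num_grad(function(th) contrast_var_theta(th, fit, cvec), theta, h)
  H <- num_hessian(function(th) -reml_loglik_theta(th, fit), theta, h)
  A <- tryCatch(solve(H), error = function(e) {
    stop("singular REML information matrix: Satterthwaite df unavailable", call. = FALSE)
  })
  den <- drop(t(g) %*% A %*% g)
  df <- if (den <= 0) fit$n - fit$p else 2 * v^2 / den
  min(max(df, 1), fit$n - fit$p)
}

# forward-shifted central differences that respect the theta >= 0 boundary
num_grad <- function(f, x, h) {
  vapply(seq_along(x), function(i) {
    lo <- x
    hi <- x
    hi[i] <- x[i] + h[i]
    lo[i] <- max(x[i] - h[i], 0)
    (f(hi) - f(lo)) / (hi[i] - lo[i])
  }, numeric(1))
}

num_hessian <- function(f, x, h) {
  k <- length(x)
  H <- matrix(0, k, k)
  shift <- function(i, s) {
    z <- x
    z[i] <- max(x[i] + s * h[i], 0)
    z
  }
  f0 <- f(x)
  for (i in seq_len(k)) {
    hi <- shift(i, 1)
    lo <- shift(i, -1)
    H[i, i] <- (f(hi) - 2 * f0 + f(lo)) / ((hi[i] - x[i]) * (x[i] - lo[i]) +
      .Machine$double.eps)
    for (j in seq_len(i - 1)) {
      pp <- shift(i, 1); pp[j] <- max(x[j] + h[j], 0)
      pm <- shift(i, 1); pm[j] <- max(x[j] - h[j], 0)
      mp <- shift(i, -1); mp[j] <- max(x[j] + h[j], 0)
      mm <- shift(i, -1); mm[j] <- max(x[j] - h[j], 0)
      H[i, j] <- H[j, i] <-
        (f(pp) - f(pm) - f(mp) + f(mm)) /
          ((pp[i] - mp[i]) * (pp[j] - pm[j]) + .Machine$double.eps)
    }
  }
  H
}

#' @export
print.stroke_lmm <- function(x, ...) {
  cat(sprintf(
    "<stroke_lmm> response=%s  n=%d obs, %d subjects\n  sigma2_subject=%.4g  sigma2_resid=%.4g  (lambda=%.3g)  REML logLik=%.2f\n",
    x$response, x$n, length(unique(x$data$subject_id)),
    x$sigma2_subject, x$sigma2_resid, x$lambda, x$logLik_reml
  ))
  invisible(x)
}
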