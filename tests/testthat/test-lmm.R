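test_that("partial eta-squared reproduces reported worked examples", {
  # printed alongside the F tests of the study design this models
  expect_equal(round(partial_eta_sq(11.69, 1, 138), 3), 0.078)
  expect_equal(round(partial_eta_sq(12.68, 1, 46), 3), 0.216)
  expect_equal(round(partial_eta_sq(4.39, 1, 138), 3), 0.031)
  expect_equal(partial_eta_sq(0, 1, 100), 0)
  # monotone in F for fixed dfs
  f <- seq(0, 30, by = 0.5)
  expect_true(all(diff(partial_eta_sq(f, 1, 100)) > 0))
  expect_error(partial_eta_sq(-1, 1, 10), "f >= 0")
})

test_that("a constant response collapses to an intercept-only fit", {
  cells <- make_cells(ns = 4, cell_sd = 1e-12, subj_sd = 1e-12)
  cells$duration_s <- 0.42
  fit <- fit_stroke_lmm(cells, "duration_s")
  expect_equal(unname(fit$beta[1]), 0.42, tolerance = 1e-9)
  expect_lt(max(abs(fit$beta[-1])), 1e-9)
  expect_lt(fit$sigma2_subject, 1e-12)
  expect_lt(fit$sigma2_resid, 1e-12)
})

test_that("without subject variance the fit collapses to ordinary least squares", {
  # residuals centred within subject put the between-subject mean square
  # below the within one, so the REML optimum sits at the lambda = 0
  # boundary with certainty and the GLS fit must equal OLS
  set.seed(21)
  cells <- make_cells(ns = 6, subj_sd = 1e-12, cell_sd = 1e-12)
  eps <- rnorm(nrow(cells), 0, 0.02)
  cells$duration_s <- cells$duration_s + eps - stats::ave(eps, cells$subject_id)
  fit <- fit_stroke_lmm(cells, "duration_s")
  expect_lt(fit$lambda, 1e-6)

  d <- as.data.frame(cells)
  d$group <- factor(d$group, c("CTRL", "SCZ"))
  d$direction <- factor(d$direction, c("US", "DS"))
  d$bigram <- factor(d$bigram, c("ll", "ln"))
  ols <- stats::lm(duration_s ~ group * direction * bigram, d,
    contrasts = list(group = "contr.sum", direction = "contr.sum", bigram = "contr.sum")
  )
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)

  # F statistics match the fixed-effects ANOVA and Satterthwaite df
  # land on the OLS residual df
  ft <- type3_f_tests(fit)
  tt <- summary(ols)$coefficients[-1, "t value"]
  expect_equal(ft$F, unname(tt^2), tolerance = 1e-6)
  expect_true(all(abs(ft$df2 - df.residual(ols)) < 1))
})

test_that("the profiled REML optimum matches a brute-force lambda grid", {
  set.seed(33)
  for (r in 1:3) {
    cells <- make_cells(ns = 3 + r, subj_sd = 0.02, cell_sd = 0.01)
    fit <- fit_stroke_lmm(cells, "duration_s")
    d <- fit$data
    X <- fit$X
    y <- fit$y
    ZZt <- fit$ZZt
    crit <- function(l) penkin:::reml_profile(l, y, X, ZZt)$crit
    coarse <- seq(0, 100, by = 0.05)
    cc <- vapply(coarse, crit, numeric(1))
    l0 <- coarse[which.min(cc)]
    fine <- seq(max(0, l0 - 0.05), l0 + 0.05, by = 1e-4)
    fc <- vapply(fine, crit, numeric(1))
    lstar <- fine[which.min(fc)]
    expect_lt(abs(fit$lambda - lstar), 2e-4)
    expect_lte(crit(fit$lambda), min(fc) + 1e-8)
  }
})

test_that("estimates and Satterthwaite df agree with the lme4/lmerTest reference", {
  set.seed(55)
  cells <- make_cells(
    ns = 12, subj_sd = 0.015, cell_sd = 0.01,
    effects = function(g) 0.03 * (g$direction == "DS") +
      0.02 * (g$bigram == "ln") * (g$group == "CTRL")
  )
  fit <- fit_stroke_lmm(cells, "duration_s")

  d <- as.data.frame(cells)
  d$group <- factor(d$group, c("CTRL", "SCZ"))
  d$direction <- factor(d$direction, c("US", "DS"))
  d$bigram <- factor(d$bigram, c("ll", "ln"))
  contrasts(d$group) <- contrasts(d$direction) <- contrasts(d$bigram) <- stats::contr.sum(2)
  ref <- lmerTest::lmer(duration_s ~ group * direction * bigram + (1 | subject_id),
    data = d, REML = TRUE
  )
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(fit$sigma2_subject, vc$vcov[1], tolerance = 1e-4)
  expect_equal(fit$sigma2_resid, vc$vcov[2], tolerance = 1e-4)
  expect_equal(unname(fit$beta), unname(lme4::fixef(ref)), tolerance = 1e-5)
  expect_equal(fit$logLik_reml, as.numeric(stats::logLik(ref)), tolerance = 1e-5)

  at <- as.data.frame(anova(ref, type = 3, ddf = "Satterthwaite"))
  ft <- type3_f_tests(fit)
  expect_equal(ft$F, at[["F value"]], tolerance = 1e-4)
  expect_equal(ft$df2, at$DenDF, tolerance = 0.02)

  # balanced-design structure: between-subject term near n_subj - 2,
  # within-subject terms near the classical split-plot denominator
  expect_true(ft$df2[ft$term == "group"] > 20 && ft$df2[ft$term == "group"] < 24)
  expect_true(all(ft$df2[ft$term != "group"] > 60))
})

test_that("bigram contrasts are symmetric, Holm-dominated and match emmeans", {
  set.seed(66)
  cells <- make_cells(
    ns = 10, subj_sd = 0.015, cell_sd = 0.01,
    effects = function(g) {
      0.06 * (g$group == "CTRL") * (g$direction == "DS") * (g$bigram == "ln")
    }
  )
  fit <- fit_stroke_lmm(cells, "duration_s")
  ct <- bigram_contrasts(fit)
  expect_equal(nrow(ct), 4)
  expect_true(all(ct$p_holm >= ct$p - 1e-12))
  expect_true(all(order(ct$p) == order(ct$p_holm) | ct$p_holm == 1))

  # swapping the bigram labels negates every contrast exactly
  swapped <- cells
  swapped$bigram <- ifelse(cells$bigram == "ll", "ln", "ll")
  ct2 <- bigram_contrasts(fit_stroke_lmm(swapped, "duration_s"))
  expect_equal(ct2$estimate, -ct$estimate, tolerance = 1e-9)

  d <- as.data.frame(cells)
  d$group <- factor(d$group, c("CTRL", "SCZ"))
  d$direction <- factor(d$direction, c("US", "DS"))
  d$bigram <- factor(d$bigram, c("ll", "ln"))
  ref <- lmerTest::lmer(duration_s ~ group * direction * bigram + (1 | subject_id), d)
  em <- as.data.frame(pairs(emmeans::emmeans(ref, ~ bigram | group * direction)))
  em <- em[order(as.character(em$group), as.character(em$direction)), ]
  ct <- ct[order(ct$group, ct$direction), ]
  expect_equal(ct$estimate, em$estimate, tolerance = 1e-5)
  expect_equal(ct$se, em$SE, tolerance = 1e-4)
  expect_equal(ct$df, em$df, tolerance = 0.03)
})

test_that("degenerate designs are rejected", {
  cells <- make_cells(ns = 3)
  expect_error(fit_stroke_lmm(cells[cells$group == "CTRL", ], "duration_s"), "2 subjects")
  one_level <- cells
  one_level$bigram <- "ll"
  expect_error(fit_stroke_lmm(one_level, "duration_s"), "rank")
})
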