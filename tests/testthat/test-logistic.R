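test_that("a 2x2 design recovers the closed-form odds ratio exactly", {
  # outcome rate 0.5 in exposed, 0.25 in unexposed: OR = (1)/(1/3) = 3
  df <- data.frame(exposed = rep(c(1, 1, 0, 0), c(50, 50, 25, 75)),
                   y = rep(c(TRUE, FALSE, TRUE, FALSE), c(50, 50, 25, 75)))
  fit <- fit_logistic(df, "y", "exposed")
  or <- fit$coefficients$or[fit$coefficients$term == "exposed"]
  expect_equal(or, 3, tolerance = 1e-9)
  expect_true(fit$converged)
})

test_that("IRLS matches the reference ML fit on a multi-covariate model", {
  set.seed(12)
  n <- 400
  df <- data.frame(x = rnorm(n),
                   g = sample(c("a", "b", "c"), n, replace = TRUE),
                   z = runif(n) < 0.5)
  eta <- -0.5 + 0.8 * df$x + (df$g == "b") * 0.5 - (df$g == "c") * 0.3 +
    0.6 * df$z
  df$y <- runif(n) < plogis(eta)
  fit <- fit_logistic(df, "y", c("x", "g", "z"), ref_levels = list(g = "a"))
  ref <- glm(y ~ x + g + z, family = binomial, data = df)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-7)
  expect_equal(fit$coefficients$se,
               unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
  expect_equal(fit$loglik, as.numeric(logLik(ref)), tolerance = 1e-8)
  expect_equal(fit$coefficients$or, exp(fit$coefficients$estimate))
  expect_equal(fit$coefficients$or_lo,
               exp(fit$coefficients$estimate -
                     qnorm(0.975) * fit$coefficients$se))
})

test_that("declared reference levels set which level carries OR 1", {
  set.seed(3)
  df <- data.frame(g = sample(c("low", "high"), 300, replace = TRUE))
  df$y <- runif(300) < ifelse(df$g == "high", 0.5, 0.2)
  fit <- fit_logistic(df, "y", "g", ref_levels = list(g = "low"))
  expect_equal(fit$reference_levels$g, "low")
  expect_true(any(grepl("ghigh", fit$coefficients$term)))
})

test_that("a null covariate yields OR near 1", {
  set.seed(91)
  df <- data.frame(x = runif(2000) < 0.5, y = runif(2000) < 0.3)
  fit <- fit_logistic(df, "y", "x")
  co <- fit$coefficients[2, ]
  expect_lt(abs(co$estimate), 3 * co$se)
})

test_that("separation and degenerate designs raise explicit diagnostics", {
  df <- data.frame(x = c(rep(0, 20), rep(1, 20)),
                   y = c(rep(FALSE, 20), rep(TRUE, 20)))
  # complete separation: the likelihood has no finite maximum; the fit
  # must flag it loudly (diverging coefficients), never return silently
  expect_warning(fit_logistic(df, "y", "x"), "separation")
  df2 <- data.frame(x = rnorm(50), y = rep(TRUE, 50))
  expect_error(fit_logistic(df2, "y", "x"), "single class")
  df3 <- data.frame(x = rnorm(50), x2 = 0, y = runif(50) < 0.5)
  df3$x2 <- 2 * df3$x
  expect_error(fit_logistic(df3, "y", c("x", "x2")), "rank deficient")
})

test_that("injected odds ratios are recovered with covering intervals", {
  set.seed(17)
  cfg0 <- generator_config(n_male = 1500, n_female = 1500)
  for (target in c(0.5, 2)) {
    cfg <- inject_known_effect(cfg0, target, covariate = "smoker")
    ors <- replicate(15, {
      co <- generate_cohort(cfg, seed = sample.int(1e6, 1))
      fit <- fit_logistic(as.data.frame(co), "outcome_sim", "smoker")
      fit$coefficients$or[2]
    })
    expect_equal(mean(ors), target, tolerance = 0.1)
  }
})

test_that("Hosmer-Lemeshow: formula, df bound and near-zero statistic on a saturated fit", {
  set.seed(29)
  n <- 1500
  df <- data.frame(x = rnorm(n))
  df$y <- runif(n) < plogis(-0.4 + 0.9 * df$x)
  fit <- fit_logistic(df, "y", "x")
  hl <- hosmer_lemeshow(fit, groups = 10)
  expect_equal(hl$df, nrow(hl$groups) - 2L)
  expect_true(hl$statistic >= 0)
  expect_equal(hl$p_value,
               pchisq(hl$statistic, hl$df, lower.tail = FALSE))
  # recompute the statistic from the returned group table
  expect_equal(hl$statistic,
               sum((hl$groups$obs - hl$groups$exp)^2 /
                     (hl$groups$exp * (1 - hl$groups$exp / hl$groups$n))),
               tolerance = 1e-12)
  expect_error(hosmer_lemeshow(fit, groups = 2), "insufficient groups")
  # saturated binary covariate: expected counts equal observed by ML,
  # so the statistic vanishes (too few groups for a p-value)
  df2 <- data.frame(x = rep(c(0, 1), each = 400))
  df2$y <- c(runif(400) < 0.2, runif(400) < 0.6)
  fit2 <- fit_logistic(df2, "y", "x")
  expect_warning(hl2 <- hosmer_lemeshow(fit2), "without a p-value")
  expect_equal(hl2$statistic, 0, tolerance = 1e-16)
  expect_true(is.na(hl2$p_value))
})

test_that("stratified fits agree across strata under a homogeneous model and skip degenerate strata", {
  set.seed(41)
  cfg <- inject_known_effect(generator_config(n_male = 4000, n_female = 4000),
                             2, covariate = "smoker")
  co <- as.data.frame(generate_cohort(cfg, seed = 61))
  sf <- stratified_analysis(co, outcome = "outcome_sim",
                            covariates = "smoker",
                            ref_levels = list(smoker = "FALSE"))
  ors <- sf$table$or
  expect_true(all(abs(log(ors) - log(2)) < 0.5))
  # a stratum with an all-negative outcome is skipped with a warning
  co2 <- co[co$age < 40, ]
  co2$outcome_sim[co2$age >= 30] <- FALSE
  expect_warning(
    sf2 <- stratified_analysis(co2, outcome = "outcome_sim",
                               covariates = "smoker",
                               ref_levels = list(smoker = "FALSE")),
    "skipped")
  expect_null(sf2$fits[["30-39"]])
  expect_false(is.null(sf2$fits[["20-29"]]))
})
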