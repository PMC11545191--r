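test_that("generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_male = 200, n_female = 200)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(as.data.frame(a)$total_chol_mgdl,
                         as.data.frame(c)$total_chol_mgdl))
})

test_that("per-sex moments match the config within Monte-Carlo error", {
  n <- 8000
  co <- as.data.frame(generate_cohort(
    generator_config(n_male = n, n_female = n), seed = 5))
  cfg <- generator_config()
  for (sex in c("male", "female")) {
    d <- co[co$sex == sex, ]
    p <- cfg[[sex]]
    checks <- list(c("height_cm", "height"), c("sbp_mmHg", "sbp"),
                   c("total_chol_mgdl", "total_chol"), c("hdl_mgdl", "hdl"),
                   c("glucose_mgdl", "glucose"), c("tg_mgdl", "tg"))
    for (ch in checks) {
      m <- p[[ch[2]]]
      se <- m[2] / sqrt(n)
      expect_lt(abs(mean(d[[ch[1]]]) - m[1]), 3.5 * se,
                label = paste(sex, ch[1], "mean deviation"))
    }
    expect_lt(abs(mean(d$smoker) - p$p_smoker), 3.5 * sqrt(0.25 / n))
    expect_lt(abs(mean(d$social_class == "III") - p$social_class[["III"]]),
              3.5 * sqrt(0.25 / n))
  }
})

test_that("age bands follow the configured weights and stay inside 20-70", {
  co <- as.data.frame(generate_cohort(
    generator_config(n_male = 6000, n_female = 0), seed = 8))
  expect_true(all(co$age >= 20 & co$age < 70))
  w <- table(cut(co$age, c(20, 30, 40, 50, 60, 70), right = FALSE)) / nrow(co)
  expect_equal(as.vector(w), unname(generator_config()$male$age_weights),
               tolerance = 0.05)
})

test_that("latent_effect zero makes the risk factors independent", {
  co <- as.data.frame(generate_cohort(
    generator_config(n_male = 20000, n_female = 0, latent_effect = 0),
    seed = 13))
  expect_lt(abs(cor(co$total_chol_mgdl, co$tg_mgdl)), 0.03)
  expect_lt(abs(cor(co$total_chol_mgdl, co$glucose_mgdl)), 0.03)
  expect_lt(abs(cor(co$hdl_mgdl, co$tg_mgdl)), 0.03)
})

test_that("positive latent_effect induces the expected correlation signs", {
  co <- as.data.frame(generate_cohort(
    generator_config(n_male = 10000, n_female = 0, latent_effect = 0.7),
    seed = 14))
  expect_gt(cor(co$total_chol_mgdl, co$tg_mgdl), 0.3)
  expect_gt(cor(co$glucose_mgdl, co$sbp_mmHg), 0.3)
  expect_lt(cor(co$hdl_mgdl, co$total_chol_mgdl), -0.3)
})

test_that("generated rows satisfy schema invariants by construction", {
  co <- as.data.frame(generate_cohort(
    generator_config(n_male = 2000, n_female = 2000), seed = 21))
  expect_true(all(co$sbp_mmHg >= co$dbp_mmHg))
  expect_true(all(co$hdl_mgdl >= 10))
  expect_true(all(co$tg_mgdl > 0))
  expect_true(all(co$med_diet_score >= 0 & co$med_diet_score <= 14))
  expect_true(all((co$med_diet_score >= 9) == co$med_diet_adherent))
  expect_false(any(duplicated(co$id)))
})

test_that("config validation refuses malformed weights and bounds", {
  expect_error(generator_config(male = list(
    age_weights = c(`20-29` = 0.5, `30-39` = 0.1, `40-49` = 0.1,
                    `50-59` = 0.1, `60-70` = 0.1))), "sum to 1")
  expect_error(generator_config(male = list(hdl = c(50, -1))), "SD")
  expect_error(generator_config(male = list(sbp = c(300, 10))),
               "infeasible")
  expect_error(generator_config(latent_effect = 1.2))
})

test_that("injected effects produce a simulated outcome with the stated odds", {
  cfg <- inject_known_effect(generator_config(n_male = 4000, n_female = 4000),
                             target_or = 2, covariate = "smoker")
  co <- as.data.frame(generate_cohort(cfg, seed = 31))
  expect_true("outcome_sim" %in% names(co))
  tab <- table(co$smoker, co$outcome_sim)
  or <- (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
  expect_equal(unname(or), 2, tolerance = 0.25)
  expect_error(inject_known_effect(generator_config(), -1), "positive")
  expect_warning(inject_known_effect(generator_config(), 100), "separation")
})
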