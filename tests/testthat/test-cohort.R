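test_that("BMI formula, monotonicity and domain errors", {
  expect_equal(compute_bmi(83.2, 173.8), 27.5, tolerance = 0.1 / 27.5)
  expect_equal(compute_bmi(66.3, 161.2), 25.5, tolerance = 0.1 / 25.5)
  expect_equal(compute_bmi(100, 100), 100)
  w <- seq(50, 120, by = 5)
  expect_true(all(diff(compute_bmi(w, 170)) > 0))
  h <- seq(150, 200, by = 5)
  expect_true(all(diff(compute_bmi(80, h)) < 0))
  expect_error(compute_bmi(-1, 170), "positive")
  expect_error(compute_bmi(70, 0), "positive")
})

test_that("Friedewald LDL matches TC - HDL - TG/5 with the TG validity bound", {
  expect_equal(friedewald_ldl(200, 50, 100), data.frame(ldl = 130, valid = TRUE))
  r <- friedewald_ldl(200, 50, 401)
  expect_false(r$valid)                       # TG above the 400 bound
  expect_equal(r$ldl, 200 - 50 - 401 / 5)     # still reported, not clamped
  r <- friedewald_ldl(100, 60, 300)
  expect_equal(r$ldl, -20)                    # negative result flagged
  expect_false(r$valid)
  # oracle: direct arithmetic on random valid inputs
  set.seed(4)
  tc <- runif(200, 120, 320); hdl <- runif(200, 25, 90)
  tg <- runif(200, 40, 390)
  expect_equal(friedewald_ldl(tc, hdl, tg)$ldl, tc - hdl - tg / 5)
})

test_that("validation routes bad rows to rejects with reason codes", {
  df <- rbind(make_profile(id = "ok"),
              make_profile(id = "hdl0", hdl_mgdl = 0),
              make_profile(id = "young", age = 17),
              make_profile(id = "old", age = 81),
              make_profile(id = "bp", sbp_mmHg = 70, dbp_mmHg = 90),
              make_profile(id = "diet", med_diet_score = 15))
  res <- validate_cohort(df)
  expect_equal(nrow(res$cohort), 1L)
  expect_equal(res$cohort$id, "ok")
  expect_equal(nrow(res$rejects), 5L)
  expect_match(res$rejects$reason[res$rejects$id == "hdl0"], "nonpositive HDL")
  expect_match(res$rejects$reason[res$rejects$id == "young"],
               "outside scale validity 18-80")
  expect_match(res$rejects$reason[res$rejects$id == "old"],
               "outside scale validity 18-80")
  expect_match(res$rejects$reason[res$rejects$id == "bp"], "SBP below DBP")
  expect_match(res$rejects$reason[res$rejects$id == "diet"], "0-14")
})

test_that("duplicate ids and missing mandatory columns are caught", {
  df <- rbind(make_profile(id = "a"), make_profile(id = "a"))
  res <- validate_cohort(df)
  expect_equal(nrow(res$rejects), 1L)
  expect_match(res$rejects$reason, "duplicate id")
  expect_error(validate_cohort(make_profile()[, -2]),
               "missing mandatory column.*sex")
})

test_that("write -> read round-trips a cohort bit-identically", {
  co <- generate_cohort(generator_config(n_male = 40, n_female = 40), seed = 3)
  base <- as.data.frame(co)[, heartally:::.cohort_columns()]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(base, path)
  back <- read_cohort(path)
  expect_no_rejects(back)
  got <- as.data.frame(back$cohort)
  for (col in names(base))
    expect_identical(got[[col]], base[[col]], info = col)
})

test_that("reading maps foreign headers through a column map and rejects with reasons", {
  df <- rbind(make_profile(id = "r1"), make_profile(id = "r2", hdl_mgdl = 0),
              make_profile(id = "r3"))
  names(df)[names(df) == "hdl_mgdl"] <- "HDL (mg/dl)"
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(read_cohort(path), "missing mandatory column.*hdl_mgdl")
  rej <- withr::local_tempfile(fileext = ".csv")
  res <- read_cohort(path, column_map = list(hdl_mgdl = "HDL (mg/dl)"),
                     rejects_path = rej)
  expect_equal(nrow(res$cohort), 2L)
  expect_match(res$rejects$reason, "nonpositive HDL")
  expect_true(file.exists(rej))
})

test_that("empty and optional-field cohorts write cleanly", {
  df <- make_profile()[0, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(df, path)
  expect_equal(length(readLines(path)), 1L)   # header only
  df2 <- make_profile(waist_cm = NA_real_)
  write_cohort(df2, path)
  back <- read_cohort(path)
  expect_no_rejects(back)
  expect_true(is.na(back$cohort$waist_cm))
})

test_that("derived covariates: diet adherence, sex-specific alcohol, LDL fill-in", {
  df <- rbind(
    make_profile(id = "a", sex = "female", med_diet_score = 9,
                 alcohol_units_week = 14),
    make_profile(id = "b", sex = "female", med_diet_score = 8,
                 alcohol_units_week = 13.9),
    make_profile(id = "c", sex = "male", alcohol_units_week = 20.9),
    make_profile(id = "d", sex = "male", alcohol_units_week = 21),
    make_profile(id = "e", tg_mgdl = 401),
    make_profile(id = "f", ldl_mgdl = 111))
  co <- derive_covariates(validate_cohort(df)$cohort)
  expect_equal(co$med_diet_adherent, c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  expect_equal(co$high_alcohol, c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(co$ldl_mgdl[co$id == "a"], 200 - 50 - 130 / 5)
  expect_false(co$ldl_valid[co$id == "e"])    # TG above Friedewald bound
  expect_equal(co$ldl_mgdl[co$id == "f"], 111)  # measured value kept
  expect_true(co$ldl_valid[co$id == "f"])
})
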