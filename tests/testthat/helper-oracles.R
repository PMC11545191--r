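# Fixture builders and independent oracles used across the suite.

# One valid risk profile as a one-row data.frame; override any field.
make_profile <- function(...) {
  base <- list(id = "p1", sex = "male", age = 45, height_cm = 174,
               weight_kg = 83, sbp_mmHg = 126, dbp_mmHg = 77,
               total_chol_mgdl = 200, hdl_mgdl = 50, tg_mgdl = 130,
               glucose_mgdl = 93, smoker = FALSE, physically_active = TRUE,
               med_diet_score = 10, alcohol_units_week = 0,
               social_class = "II", education = "high_school",
               waist_cm = 90, ldl_mgdl = NA_real_, bp_treated = FALSE,
               glucose_treated = FALSE)
  ov <- list(...)
  for (nm in names(ov)) base[[nm]] <- ov[[nm]]
  as.data.frame(base, stringsAsFactors = FALSE)
}

# Small valid cohort of varied profiles, built in code.
make_small_cohort <- function(n = 6) {
  rows <- lapply(seq_len(n), function(i)
    make_profile(id = paste0("p", i),
                 sex = if (i %% 2) "male" else "female",
                 age = 25 + 5 * i,
                 total_chol_mgdl = 150 + 15 * i,
                 hdl_mgdl = 40 + 3 * i,
                 tg_mgdl = 80 + 40 * i,
                 glucose_mgdl = 70 + 8 * i,
                 smoker = i %% 3 == 0))
  do.call(rbind, rows)
}

# Brute-force all-pairs AUC: concordant + half ties over n1*n0 pairs.
auc_all_pairs <- function(scores, labels) {
  x <- scores[as.logical(labels)]
  y <- scores[!as.logical(labels)]
  cmp <- outer(x, y, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Brute-force Youden maximum over every candidate threshold.
youden_brute <- function(scores, labels, thresholds) {
  labels <- as.logical(labels)
  j <- vapply(thresholds, function(t) {
    sens <- mean(scores[labels] >= t)
    spec <- mean(scores[!labels] < t)
    sens + spec - 1
  }, numeric(1))
  max(j)
}

expect_no_rejects <- function(res) {
  testthat::expect_equal(nrow(res$rejects), 0L,
                         info = paste(res$rejects$reason, collapse = "; "))
}
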