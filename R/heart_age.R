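#' Score a whole cohort's heart age
#'
#' For every individual, sums the six factor points (total cholesterol,
#' HDL-c, glucose, smoking, BMI, blood pressure) from the sex-specific
#' points table, clamps the total to the scale's range, and derives:
#'
#' * `heart_age` = chronological age + clamped total points;
#' * `ally` (avoidable lost life years) = heart age - chronological age,
#'   so a negative value means a heart younger than its owner;
#' * `high_ally` = `ally >= 17` years.
#'
#' The scale caps the years that can be gained relative to chronological
#' age at 20 (clamp floor -20) and the heart-age excess at +19 (clamp
#' ceiling), an asymmetric clamp read literally from the scale's
#' definition; the raw unclamped sum is kept in `total_points` so either
#' convention can be audited.  The scale is only valid for ages 18--80 and
#' refuses others.
#'
#' @param cohort a `cohort_table` with derived covariates (see
#'   [derive_covariates()]); `bmi_kgm2` is computed on the fly if absent.
#' @param table a `points_table`.
#' @return the cohort with columns `points_total_chol`, `points_hdl`,
#'   `points_glucose`, `points_smoker`, `points_bmi`, `points_bp`,
#'   `total_points`, `delta_clamped`, `heart_age`, `ally`, `high_ally`.
#' @export
score_cohort <- function(cohort, table = default_points_table()) {
  prov <- attr(cohort, "provenance")
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) stop("empty cohort")
  .check_sex(df$sex)
  if (any(df$age < 18 | df$age > 80))
    stop("age outside scale validity 18-80")
  if (is.null(df$bmi_kgm2))
    df$bmi_kgm2 <- compute_bmi(df$weight_kg, df$height_cm)
  if (is.null(df$bp_treated)) df$bp_treated <- FALSE
  if (is.null(df$glucose_treated)) df$glucose_treated <- FALSE

  band <- function(factor, value) {
    out <- integer(nrow(df))
    for (sex in c("male", "female")) {
      i <- df$sex == sex
      fac <- table[[sex]][[factor]]
      out[i] <- .band_points(value[i], fac$breaks, fac$points)
    }
    out
  }
  df$points_total_chol <- band("total_chol", df$total_chol_mgdl)
  df$points_hdl <- band("hdl", df$hdl_mgdl)
  df$points_glucose <- band("glucose", df$glucose_mgdl)
  gt <- as.logical(df$glucose_treated)
  df$points_glucose[gt] <- table$male$glucose$treated_points
  df$points_smoker <- ifelse(df$smoker, table$male$smoker$yes,
                             table$male$smoker$no)
  df$points_bmi <- band("bmi", df$bmi_kgm2)
  df$points_bp <- score_bp_band(df$sbp_mmHg, df$dbp_mmHg,
                                as.logical(df$bp_treated), table = table)

  df$total_points <- df$points_total_chol + df$points_hdl +
    df$points_glucose + df$points_smoker + df$points_bmi + df$points_bp
  df$delta_clamped <- pmin(pmax(df$total_points, table$clamp$lower),
                           table$clamp$upper)
  df$heart_age <- df$age + df$delta_clamped
  df$ally <- df$delta_clamped
  df$high_ally <- classify_high_ally(df$ally, table)
  new_cohort_table(df, provenance = prov)
}

#' Heart age of a single risk profile
#'
#' Convenience wrapper around [score_cohort()] for one individual given as
#' a named list; returns the per-factor points and derived quantities.
#'
#' @param profile named list with the cohort schema fields (an `id` is
#'   supplied if absent; lifestyle fields are optional here since they do
#'   not enter the score).
#' @param table a `points_table`.
#' @return list of class `heart_age_result`.
#' @export
#' @examples
#' compute_heart_age(list(sex = "male", age = 45, height_cm = 174,
#'   weight_kg = 83, sbp_mmHg = 126, dbp_mmHg = 77, total_chol_mgdl = 200,
#'   hdl_mgdl = 50, tg_mgdl = 134, glucose_mgdl = 93, smoker = FALSE))
compute_heart_age <- function(profile, table = default_points_table()) {
  defaults <- list(id = "p1", smoker = FALSE, bp_treated = FALSE,
                   glucose_treated = FALSE, physically_active = TRUE,
                   med_diet_score = 9L, alcohol_units_week = 0,
                   social_class = "I", education = "university",
                   tg_mgdl = 100)
  for (nm in names(defaults))
    if (is.null(profile[[nm]])) profile[[nm]] <- defaults[[nm]]
  df <- as.data.frame(profile[lengths(profile) == 1L],
                      stringsAsFactors = FALSE)
  scored <- as.data.frame(score_cohort(new_cohort_table(df), table = table))
  res <- as.list(scored[1L, c("points_total_chol", "points_hdl",
                              "points_glucose", "points_smoker",
                              "points_bmi", "points_bp", "total_points",
                              "delta_clamped", "heart_age", "ally",
                              "high_ally")])
  class(res) <- c("heart_age_result", "list")
  res
}

#' @export
print.heart_age_result <- function(x, ...) {
  cat("Heart-age result: total points", x$total_points,
      "(clamped", x$delta_clamped, ")\n")
  cat("  heart age", x$heart_age, "; ALLY", x$ally,
      if (x$high_ally) "(HIGH)" else "", "\n")
  invisible(x)
}

#' Classify high ALLY heart age
#'
#' ALLY (avoidable lost life years) is the signed gap between heart age
#' and chronological age.  The high-ALLY class uses an inclusive cut-off
#' of 17 years.
#'
#' @param ally numeric, years (vectorized).
#' @param table a `points_table` carrying the cut-off.
#' @return logical.
#' @export
classify_high_ally <- function(ally, table = default_points_table()) {
  if (any(!is.finite(ally))) stop("ally must be finite")
  ally >= table$high_ally_cutoff
}
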