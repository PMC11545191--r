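#' Atherogenic lipid indices and their risk categories
#'
#' Computes the three atherogenic indices -- TC/HDL-c, LDL-c/HDL-c and
#' TG/HDL-c -- and assigns each its risk category.  Only the TC/HDL-c
#' categorization is sex-specific: women are low below 4.5, moderate in
#' `[4.5, 7]` and high above 7; men low below 5, moderate in `[5, 9]` and
#' high above 9.  LDL/HDL and TG/HDL are dichotomized at 3 (inclusive:
#' a ratio of exactly 3 is high).  The LDL-based index is reported as NA
#' wherever the LDL value is flagged invalid (Friedewald out of range);
#' such rows are excluded from LDL analyses but stay in the cohort.
#'
#' @param cohort a `cohort_table` with derived covariates
#'   ([derive_covariates()] is applied if `ldl_valid` is absent).
#' @param table a `points_table` carrying the category thresholds.
#' @return the cohort with columns `tc_hdl`, `ldl_hdl`, `tg_hdl`,
#'   `tc_hdl_cat` (ordered factor low < moderate < high), `ldl_hdl_cat`
#'   and `tg_hdl_cat` (ordered normal < high).
#' @export
compute_indices <- function(cohort, table = default_points_table()) {
  prov <- attr(cohort, "provenance")
  df <- as.data.frame(cohort)
  if (any(df$hdl_mgdl <= 0)) stop("HDL must be positive")
  if (is.null(df$ldl_valid)) {
    df <- as.data.frame(derive_covariates(new_cohort_table(df)))
  }
  df$tc_hdl <- df$total_chol_mgdl / df$hdl_mgdl
  df$ldl_hdl <- ifelse(df$ldl_valid, df$ldl_mgdl / df$hdl_mgdl, NA_real_)
  df$tg_hdl <- df$tg_mgdl / df$hdl_mgdl
  df$tc_hdl_cat <- categorize_tc_hdl(df$tc_hdl, df$sex, table)
  df$ldl_hdl_cat <- categorize_ldl_hdl(df$ldl_hdl, table)
  df$tg_hdl_cat <- categorize_tg_hdl(df$tg_hdl, table)
  new_cohort_table(df, provenance = prov)
}

.two_level <- function(value, high_at) {
  factor(ifelse(value >= high_at, "high", "normal"),
         levels = c("normal", "high"), ordered = TRUE)
}

#' Categorize the TC/HDL-c index
#'
#' @param value positive ratio (vectorized).
#' @param sex `"male"` or `"female"`, recycled against `value`.
#' @param table a `points_table`.
#' @return ordered factor low < moderate < high.
#' @export
#' @examples
#' categorize_tc_hdl(4.6, "female")  # moderate
#' categorize_tc_hdl(4.6, "male")    # low
categorize_tc_hdl <- function(value, sex, table = default_points_table()) {
  .check_sex(sex)
  n <- max(length(value), length(sex))
  value <- rep_len(value, n); sex <- rep_len(sex, n)
  lo <- hi <- numeric(n)
  for (s in c("male", "female")) {
    th <- table$atherogenic$tc_hdl[[s]]
    lo[sex == s] <- th$low_below
    hi[sex == s] <- th$high_above
  }
  out <- ifelse(value < lo, "low", ifelse(value > hi, "high", "moderate"))
  factor(out, levels = c("low", "moderate", "high"), ordered = TRUE)
}

#' Categorize the LDL-c/HDL-c index (high at >= 3)
#' @param value positive ratio; NA propagates.
#' @param table a `points_table`.
#' @return ordered factor normal < high.
#' @export
categorize_ldl_hdl <- function(value, table = default_points_table()) {
  .two_level(value, table$atherogenic$ldl_hdl$high_at)
}

#' Categorize the TG/HDL-c index (elevated at 3 and above)
#' @param value positive ratio.
#' @param table a `points_table`.
#' @return ordered factor normal < high.
#' @export
categorize_tg_hdl <- function(value, table = default_points_table()) {
  .two_level(value, table$atherogenic$tg_hdl$high_at)
}
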