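#' Cohort schema
#'
#' Column names, types and validity rules for a per-individual risk cohort.
#' All analytes are in mg/dL, pressures in mmHg, height in cm, weight in kg.
#' `waist_cm` and `ldl_mgdl` are optional (LDL-c is derivable by the
#' Friedewald formula); `bp_treated` and `glucose_treated` default to
#' `FALSE` when absent.
#' @keywords internal
.schema <- list(
  mandatory = c("id", "sex", "age", "height_cm", "weight_kg",
                "sbp_mmHg", "dbp_mmHg", "total_chol_mgdl", "hdl_mgdl",
                "tg_mgdl", "glucose_mgdl", "smoker", "physically_active",
                "med_diet_score", "alcohol_units_week", "social_class",
                "education"),
  optional = c("waist_cm", "ldl_mgdl", "bp_treated", "glucose_treated"),
  numeric = c("age", "height_cm", "weight_kg", "waist_cm", "sbp_mmHg",
              "dbp_mmHg", "total_chol_mgdl", "hdl_mgdl", "ldl_mgdl",
              "tg_mgdl", "glucose_mgdl", "med_diet_score",
              "alcohol_units_week"),
  logical = c("smoker", "physically_active", "bp_treated", "glucose_treated"),
  social_class = c("I", "II", "III"),
  education = c("elementary", "high_school", "university")
)

.cohort_columns <- function() c(.schema$mandatory, .schema$optional)

new_cohort_table <- function(df, provenance = list()) {
  stopifnot(is.data.frame(df))
  rownames(df) <- NULL
  structure(df, class = c("cohort_table", "data.frame"),
            provenance = provenance)
}

#' @export
print.cohort_table <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("Cohort of", nrow(x), "individuals (",
      sum(x$sex == "male"), "men,", sum(x$sex == "female"), "women )\n")
  if (!is.null(prov$source)) cat("  source:", prov$source, "\n")
  if (!is.null(prov$seed)) cat("  generator seed:", prov$seed, "\n")
  NextMethod()
}

#' Validate cohort rows
#'
#' Applies the schema invariants row by row.  Rows that violate an
#' invariant are never silently dropped: they are routed to a rejects
#' table with a reason code per failed rule.  Rules: age within the
#' scale's validity window 18--80 years; all lipid and glucose values
#' strictly positive (HDL-c > 0 so the ratios are defined); systolic >=
#' diastolic pressure; Mediterranean-diet score an integer in 0--14;
#' alcohol units non-negative; known factor levels; unique ids.
#'
#' @param df a data.frame with schema columns.
#' @return list with `cohort` (a `cohort_table` of accepted rows) and
#'   `rejects` (data.frame of id, row, reason).
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(.schema$mandatory, names(df))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in intersect(.schema$optional, c("bp_treated", "glucose_treated")))
    if (is.null(df[[col]])) df[[col]] <- FALSE
  for (col in setdiff(.schema$optional, names(df))) df[[col]] <- NA_real_
  df <- df[, .cohort_columns()]

  reasons <- vector("list", nrow(df))
  flag <- function(bad, why) {
    bad <- which(!is.na(bad) & bad)
    for (i in bad) reasons[[i]] <<- c(reasons[[i]], why)
  }
  num_bad <- function(col) !is.finite(suppressWarnings(as.numeric(df[[col]])))
  for (col in intersect(.schema$numeric, .schema$mandatory))
    flag(num_bad(col), paste("unparseable numeric:", col))
  flag(!df$sex %in% c("male", "female"), "unknown sex")
  flag(df$age < 18 | df$age > 80, "outside scale validity 18-80")
  flag(df$hdl_mgdl <= 0, "nonpositive HDL")
  flag(df$total_chol_mgdl <= 0, "nonpositive total cholesterol")
  flag(df$tg_mgdl <= 0, "nonpositive triglycerides")
  flag(df$glucose_mgdl <= 0, "nonpositive glucose")
  flag(df$height_cm <= 0 | df$weight_kg <= 0, "nonpositive anthropometry")
  flag(df$sbp_mmHg < df$dbp_mmHg, "SBP below DBP")
  flag(df$sbp_mmHg <= 0 | df$dbp_mmHg <= 0, "nonpositive blood pressure")
  flag(df$med_diet_score < 0 | df$med_diet_score > 14 |
         df$med_diet_score != round(df$med_diet_score),
       "Mediterranean-diet score outside 0-14")
  flag(df$alcohol_units_week < 0, "negative alcohol units")
  flag(!df$social_class %in% .schema$social_class, "unknown social class")
  flag(!df$education %in% .schema$education, "unknown education level")
  flag(duplicated(df$id), "duplicate id")

  bad <- which(lengths(reasons) > 0)
  rejects <- data.frame(
    id = as.character(df$id[bad]),
    row = bad,
    reason = vapply(reasons[bad], paste, character(1), collapse = "; "),
    stringsAsFactors = FALSE)
  keep <- df[setdiff(seq_len(nrow(df)), bad), , drop = FALSE]
  list(cohort = new_cohort_table(keep), rejects = rejects)
}

#' Read a cohort from a delimited file
#'
#' Occupational-health exports rarely agree on column headers, so an
#' optional column map (a named list or a YAML file, `schema_name:
#' file_header`) translates arbitrary headers onto the schema.  Rows that
#' fail validation are returned in a rejects table (and optionally written
#' next to the input) with a reason code; they are never dropped silently.
#'
#' @param path input file.
#' @param sep field delimiter, default comma.
#' @param column_map named list mapping schema names to file headers, or
#'   the path of a YAML file containing such a mapping.
#' @param na_token string representing missing values, default empty field.
#' @param rejects_path optional path; when given, the rejects table is
#'   written there as CSV.
#' @return list with `cohort` and `rejects`, as [validate_cohort()].
#' @export
read_cohort <- function(path, sep = ",", column_map = NULL, na_token = "",
                        rejects_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           na.strings = na_token, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  if (is.character(column_map) && length(column_map) == 1L)
    column_map <- yaml::read_yaml(column_map)
  if (!is.null(column_map)) {
    for (schema_name in names(column_map)) {
      src <- column_map[[schema_name]]
      if (!src %in% names(raw))
        stop("column map names a header not in the file: ", src)
      names(raw)[names(raw) == src] <- schema_name
    }
  }
  missing_cols <- setdiff(.schema$mandatory, names(raw))
  if (length(missing_cols))
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  for (col in intersect(names(raw), .schema$numeric))
    raw[[col]] <- suppressWarnings(as.numeric(raw[[col]]))
  for (col in intersect(names(raw), .schema$logical))
    raw[[col]] <- as.logical(raw[[col]])
  res <- validate_cohort(raw)
  attr(res$cohort, "provenance") <- list(source = path)
  if (!is.null(rejects_path) && nrow(res$rejects))
    utils::write.csv(res$rejects, rejects_path, row.names = FALSE)
  res
}

#' Write a cohort to a delimited file
#'
#' Numeric fields are serialized with 17 significant digits so that
#' `read_cohort(write_cohort(x))` round-trips every double bit-identically.
#' Missing optional fields are emitted as the NA token (default: empty
#' field).
#'
#' @param cohort a `cohort_table` (or plain data.frame with the schema).
#' @param path output file.
#' @param sep field delimiter.
#' @param na_token token for missing values.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, sep = ",", na_token = "") {
  df <- as.data.frame(cohort)
  out <- df
  for (col in names(out)) {
    v <- out[[col]]
    s <- if (is.double(v)) sprintf("%.17g", v) else as.character(v)
    s[is.na(v)] <- na_token
    out[[col]] <- s
  }
  utils::write.table(out, path, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Body mass index
#'
#' @param weight_kg,height_cm positive numerics (vectorized).
#' @return BMI in kg/m^2: `weight / (height/100)^2`.
#' @export
#' @examples
#' compute_bmi(83.2, 173.8)  # ~27.5, the male cohort mean
compute_bmi <- function(weight_kg, height_cm) {
  if (any(weight_kg <= 0 | height_cm <= 0, na.rm = TRUE))
    stop("weight and height must be positive")
  weight_kg / (height_cm / 100)^2
}

#' Friedewald estimate of LDL cholesterol
#'
#' `LDL = TC - HDL - TG/5` (all mg/dL).  The estimate is only reliable
#' when triglycerides do not exceed 400 mg/dL; above that bound, or when
#' the computed LDL is negative, the value is still reported but flagged
#' invalid so downstream LDL-based indices can exclude it.  No clamping.
#'
#' @param total_chol,hdl,tg mg/dL (vectorized).
#' @return data.frame with `ldl` and logical `valid`.
#' @export
friedewald_ldl <- function(total_chol, hdl, tg) {
  ldl <- total_chol - hdl - tg / 5
  data.frame(ldl = ldl, valid = tg <= 400 & ldl >= 0)
}

#' Derived per-individual covariates
#'
#' Adds to the cohort: `bmi_kgm2`; `med_diet_adherent` (14-item score >= 9);
#' `high_alcohol` (>= 14 alcohol units/week for women, >= 21 for men, one
#' unit = 10 g ethanol); `drinker` (any weekly intake); and fills missing
#' `ldl_mgdl` by the Friedewald formula where triglycerides permit, with a
#' `ldl_valid` flag.  Rows with invalid LDL stay in the cohort and are
#' excluded only from LDL-based analyses.
#'
#' @param cohort a `cohort_table`.
#' @return the cohort with derived columns appended.
#' @export
derive_covariates <- function(cohort) {
  prov <- attr(cohort, "provenance")
  df <- as.data.frame(cohort)
  df$bmi_kgm2 <- compute_bmi(df$weight_kg, df$height_cm)
  df$med_diet_adherent <- df$med_diet_score >= 9
  df$high_alcohol <- ifelse(df$sex == "female",
                            df$alcohol_units_week >= 14,
                            df$alcohol_units_week >= 21)
  df$drinker <- df$alcohol_units_week > 0
  fw <- friedewald_ldl(df$total_chol_mgdl, df$hdl_mgdl, df$tg_mgdl)
  need <- is.na(df$ldl_mgdl)
  df$ldl_mgdl[need] <- fw$ldl[need]
  df$ldl_valid <- ifelse(need, fw$valid, df$ldl_mgdl > 0)
  new_cohort_table(df, provenance = prov)
}
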