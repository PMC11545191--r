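#' Load the heart-age points table
#'
#' The point-scoring bands for the six risk factors (total cholesterol,
#' HDL-c, fasting glucose, smoking, BMI, blood pressure) are shipped as a
#' versioned JSON asset rather than hard-coded, so the mapping is auditable
#' data.  Printed bands such as "130--145 / 146--160" are normalized to
#' half-open intervals on the reals (`[130, 146)`, `[146, 161)`, ...) so a
#' continuous laboratory value can never fall between two bands.
#'
#' The two sexes share every factor map except HDL-c, whose ladder is
#' shifted upward for women.  Glucose and blood pressure carry a
#' treatment override: a treated individual scores that factor's maximum
#' points regardless of the measured value.
#'
#' @param version integer asset version (only version 1 exists).
#' @return A list of class `points_table` with per-sex factor maps, the
#'   clamp bounds for the total score, the high-ALLY cut-off and the
#'   atherogenic-index category thresholds.
#' @export
#' @examples
#' pt <- default_points_table()
#' lookup_points("male", "glucose", 126, pt)   # 5
#' lookup_points("female", "hdl", 72, pt)      # -4
default_points_table <- function(version = 1) {
  path <- system.file("extdata", sprintf("points_table_v%d.json", version),
                      package = "heartally")
  if (!nzchar(path)) stop("no points table asset for version ", version)
  pt <- jsonlite::read_json(path, simplifyVector = TRUE)
  class(pt) <- c("points_table", "list")
  pt
}

.pt_factors <- c("total_chol", "hdl", "glucose", "smoker", "bmi", "bp")

.check_sex <- function(sex) {
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'")
}

# Band lookup on half-open intervals [b_i, b_{i+1}); findInterval() returns
# the index of the band a value falls in, 0 for values below the first break.
.band_points <- function(value, breaks, points) {
  if (any(value < 0, na.rm = TRUE)) stop("band value must be non-negative")
  points[findInterval(value, breaks) + 1L]
}

#' Look up the points of one risk factor
#'
#' @param sex `"male"` or `"female"`.
#' @param factor one of `"total_chol"`, `"hdl"`, `"glucose"`, `"smoker"`,
#'   `"bmi"`, `"bp"`.
#' @param value the measured value: numeric for the banded factors, logical
#'   for `"smoker"`, and a length-2 numeric `c(sbp, dbp)` for `"bp"`.
#' @param treated logical; for glucose and blood pressure, `TRUE` overrides
#'   the band lookup and returns the factor's maximum points ("or in
#'   treatment" rule).  Ignored for the other factors.
#' @param table a `points_table`, by default [default_points_table()].
#' @return integer points.
#' @export
lookup_points <- function(sex, factor, value, treated = FALSE,
                          table = default_points_table()) {
  .check_sex(sex)
  if (!factor %in% .pt_factors)
    stop("unknown factor: ", factor)
  fac <- table[[sex]][[factor]]
  switch(factor,
    smoker = {
      if (!is.logical(value)) stop("smoker value must be logical")
      ifelse(value, fac$yes, fac$no)
    },
    bp = {
      if (length(value) != 2L) stop("bp value must be c(sbp, dbp)")
      score_bp_band(value[1L], value[2L], treated, sex = sex, table = table)
    },
    glucose = {
      if (isTRUE(treated)) fac$treated_points
      else .band_points(value, fac$breaks, fac$points)
    },
    .band_points(value, fac$breaks, fac$points)
  )
}

#' Score the blood-pressure factor
#'
#' Systolic and diastolic pressure are banded independently against their
#' own thresholds (`<120 / <80`, `120-139 / 80-89`, `140-159 / 90-99`,
#' `>=160 / >=100`) and the band with the higher points wins: discordant
#' readings are classified by the worse pressure, the convention of staged
#' hypertension categories.  Treated hypertension scores the maximum.
#'
#' @param sbp,dbp systolic and diastolic pressure, mmHg; vectorized.
#' @param treated logical, antihypertensive treatment.
#' @param sex `"male"` or `"female"` (the BP map is identical across sexes).
#' @param table a `points_table`.
#' @return integer points in `[-3, 3]`.
#' @export
score_bp_band <- function(sbp, dbp, treated = FALSE, sex = "male",
                          table = default_points_table()) {
  .check_sex(sex)
  if (any(sbp < dbp, na.rm = TRUE)) stop("sbp must be >= dbp")
  fac <- table[[sex]]$bp
  ps <- fac$points[findInterval(sbp, fac$sbp_breaks) + 1L]
  pd <- fac$points[findInterval(dbp, fac$dbp_breaks) + 1L]
  out <- pmax(ps, pd)
  out[rep_len(as.logical(treated), length(out))] <- fac$treated_points
  out
}

#' Audit the encoded points table
#'
#' Programmatic consistency check of the encoded bands: per-factor point
#' ranges, disjoint full coverage of the positive reals (guaranteed by the
#' break/points encoding, checked for monotone breaks), the per-sex sum of
#' factor minima (the largest number of years that can be gained, -20) and
#' the raw sum of factor maxima (+20 before the +19 clamp), and that the
#' two sexes differ only in the HDL-c map.
#'
#' @param table a `points_table`.
#' @return invisibly, a list with `min_sum` and `max_sum` per sex; errors
#'   if any audit fails.
#' @export
audit_points_table <- function(table = default_points_table()) {
  expected_range <- list(total_chol = c(-5, 2), hdl = c(-5, 2),
                         glucose = c(-5, 5), smoker = c(0, 5),
                         bmi = c(-2, 3), bp = c(-3, 3))
  out <- list()
  for (sex in c("male", "female")) {
    mins <- maxs <- numeric(0)
    for (f in .pt_factors) {
      fac <- table[[sex]][[f]]
      pts <- switch(f,
        smoker = c(fac$no, fac$yes),
        bp = fac$points,
        fac$points)
      if (f %in% c("total_chol", "hdl", "glucose", "bmi")) {
        if (is.unsorted(fac$breaks, strictly = TRUE))
          stop("breaks not strictly increasing for ", sex, " ", f)
        if (length(fac$points) != length(fac$breaks) + 1L)
          stop("points/breaks length mismatch for ", sex, " ", f)
      }
      if (min(pts) != expected_range[[f]][1] || max(pts) != expected_range[[f]][2])
        stop("point range mismatch for ", sex, " ", f)
      mins[f] <- min(pts)
      maxs[f] <- max(pts)
    }
    out[[sex]] <- list(min_sum = sum(mins), max_sum = sum(maxs))
    if (out[[sex]]$min_sum != -20)
      stop("per-factor minima do not sum to -20 for ", sex)
    if (out[[sex]]$max_sum != 20)
      stop("per-factor maxima do not sum to +20 for ", sex)
  }
  same <- vapply(setdiff(.pt_factors, "hdl"), function(f)
    identical(table$male[[f]], table$female[[f]]), logical(1))
  if (!all(same))
    stop("sexes differ outside the HDL map: ",
         paste(names(same)[!same], collapse = ", "))
  if (identical(table$male$hdl, table$female$hdl))
    stop("HDL map should differ between sexes")
  invisible(out)
}

#' @export
print.points_table <- function(x, ...) {
  cat("Heart-age points table (asset version", x$version, ")\n")
  cat("  factors:", paste(.pt_factors, collapse = ", "), "\n")
  cat("  total-points clamp: [", x$clamp$lower, ",", x$clamp$upper, "]\n")
  cat("  high-ALLY cut-off:", x$high_ally_cutoff, "years\n")
  invisible(x)
}
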