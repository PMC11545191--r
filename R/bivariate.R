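#' Bivariate descriptive comparison tables
#'
#' Group-wise description and tests for a binary grouping variable:
#' continuous fields get mean (SD) per group and a Welch two-sample
#' t-test; categorical fields get counts/percentages per group and a
#' chi-square test, falling back to Fisher's exact test whenever any
#' expected cell count is below 5 (the fallback is recorded in the
#' `method` column, never silent).
#'
#' @param cohort a `cohort_table` or data.frame.
#' @param group name of a binary grouping column (e.g. `"sex"` or
#'   `"high_ally"`).
#' @param continuous,categorical character vectors of column names; by
#'   default every numeric / factor-like column except identifiers and
#'   the grouping column.
#' @param correct logical, continuity correction for the 2x2 chi-square
#'   (default FALSE, large-sample convention).
#' @return object of class `bivariate_report` with data.frames
#'   `continuous` (field, per-group mean/sd, t, p) and `categorical`
#'   (field, level, per-group n/percent, statistic, p, method).
#' @export
bivariate_tables <- function(cohort, group = "sex", continuous = NULL,
                             categorical = NULL, correct = FALSE) {
  df <- as.data.frame(cohort)
  g <- df[[group]]
  lv <- sort(unique(as.character(g)))
  if (length(lv) != 2L) stop("grouping variable must be binary")
  if (is.null(continuous))
    continuous <- setdiff(names(df)[vapply(df, is.numeric, logical(1))],
                          c("id", group))
  if (is.null(categorical))
    categorical <- setdiff(names(df)[vapply(df, function(x)
      is.character(x) || is.factor(x) || is.logical(x), logical(1))],
      c("id", group))

  cont <- do.call(rbind, lapply(continuous, function(v) {
    x1 <- df[[v]][g == lv[1]]; x2 <- df[[v]][g == lv[2]]
    tt <- tryCatch(stats::t.test(x1, x2), error = function(e) NULL)
    data.frame(field = v,
               mean_1 = mean(x1, na.rm = TRUE), sd_1 = stats::sd(x1, na.rm = TRUE),
               mean_2 = mean(x2, na.rm = TRUE), sd_2 = stats::sd(x2, na.rm = TRUE),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value)
  }))

  cat_rows <- lapply(categorical, function(v) {
    tab <- table(factor(as.character(df[[v]])), as.character(g))
    if (nrow(tab) < 2L) return(NULL)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5)) {
      ft <- stats::fisher.test(tab)
      stat <- NA_real_; p <- ft$p.value; method <- "fisher"
    } else {
      ct <- stats::chisq.test(tab, correct = correct)
      stat <- unname(ct$statistic); p <- ct$p.value; method <- "chisq"
    }
    data.frame(field = v, level = rownames(tab),
               n_1 = as.vector(tab[, lv[1]]),
               pct_1 = 100 * as.vector(tab[, lv[1]]) / sum(tab[, lv[1]]),
               n_2 = as.vector(tab[, lv[2]]),
               pct_2 = 100 * as.vector(tab[, lv[2]]) / sum(tab[, lv[2]]),
               statistic = stat, p = p, method = method,
               row.names = NULL)
  })
  catdf <- do.call(rbind, Filter(Negate(is.null), cat_rows))
  structure(list(continuous = cont, categorical = catdf,
                 group = group, levels = lv),
            class = "bivariate_report")
}

#' @export
print.bivariate_report <- function(x, ...) {
  cat("Bivariate report by", x$group, "(", x$levels[1], "vs",
      x$levels[2], ")\n")
  cat(" ", nrow(x$continuous), "continuous fields,",
      length(unique(x$categorical$field)), "categorical fields\n")
  invisible(x)
}
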