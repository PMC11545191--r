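#' Analyze a scored cohort
#'
#' Runs the full statistical stage on a cohort that has been scored
#' ([score_cohort()]) and indexed ([compute_indices()]): mean ALLY and
#' high-ALLY prevalence by atherogenic-index level and sex, age-band
#' means, age-stratified logistic regression for high ALLY on the
#' lifestyle and index covariates, and per-sex ROC analysis of each index
#' against high ALLY with the Youden-optimal cut-off.
#'
#' @param scored a scored, indexed `cohort_table`.
#' @param strata_breaks age band edges for the stratified regression.
#' @return list of class `heartally_analysis`: data.frames
#'   `ally_by_index` (mean ALLY per index level), `ally_by_age`,
#'   `prevalence_by_index`, `stratified` (a `stratified_fit`), `auc`
#'   summary, `cutoffs` summary, and `roc` (nested list of `roc_result`
#'   by sex and index).
#' @export
analyze_cohort <- function(scored, strata_breaks = c(20, 30, 40, 50, 60, 70)) {
  df <- as.data.frame(scored)
  idx_levels <- list(tc_hdl = "tc_hdl_cat", ldl_hdl = "ldl_hdl_cat",
                     tg_hdl = "tg_hdl_cat")

  level_rows <- function(stat_fun) {
    out <- list()
    for (sex in c("male", "female")) for (ix in names(idx_levels)) {
      sub <- df[df$sex == sex & !is.na(df[[idx_levels[[ix]]]]), ]
      sp <- split(sub, sub[[idx_levels[[ix]]]], drop = FALSE)
      for (lev in names(sp)) {
        s <- stat_fun(sp[[lev]])
        out[[length(out) + 1L]] <- data.frame(
          sex = sex, index = ix, level = lev, n = nrow(sp[[lev]]), s)
      }
    }
    do.call(rbind, out)
  }
  ally_by_index <- level_rows(function(d)
    data.frame(mean_ally = mean(d$ally), sd_ally = stats::sd(d$ally)))
  prevalence_by_index <- level_rows(function(d)
    data.frame(n_high = sum(d$high_ally),
               pct_high = 100 * mean(d$high_ally)))

  lab <- paste0(strata_breaks[-length(strata_breaks)], "-",
                strata_breaks[-1] - 1)
  band <- cut(df$age, breaks = strata_breaks, labels = lab, right = FALSE,
              include.lowest = TRUE)
  ally_by_age <- do.call(rbind, lapply(c("male", "female"), function(sex) {
    do.call(rbind, lapply(lab, function(s) {
      d <- df[df$sex == sex & !is.na(band) & band == s, ]
      if (!nrow(d)) return(NULL)
      data.frame(sex = sex, age_band = s, n = nrow(d),
                 tc_hdl = mean(d$tc_hdl),
                 ldl_hdl = mean(d$ldl_hdl, na.rm = TRUE),
                 tg_hdl = mean(d$tg_hdl),
                 mean_ally = mean(d$ally), sd_ally = stats::sd(d$ally))
    }))
  }))

  covars <- c("sex", "social_class", "education", "smoker",
              "physically_active", "med_diet_adherent", "drinker",
              "tc_hdl_cat", "ldl_hdl_cat", "tg_hdl_cat")
  refs <- list(sex = "female", social_class = "I", education = "university",
               smoker = "FALSE", physically_active = "TRUE",
               med_diet_adherent = "TRUE", drinker = "FALSE",
               tc_hdl_cat = "low", ldl_hdl_cat = "normal",
               tg_hdl_cat = "normal")
  stratified <- stratified_analysis(df, "high_ally",
                                    intersect(covars, names(df)),
                                    refs, breaks = strata_breaks)

  roc <- list(); auc_rows <- list(); cut_rows <- list()
  for (sex in c("male", "female")) {
    roc[[sex]] <- list()
    for (ix in names(idx_levels)) {
      sub <- df[df$sex == sex & !is.na(df[[ix]]), ]
      r <- tryCatch(roc_curve(sub[[ix]], sub$high_ally),
                    error = function(e) NULL)
      roc[[sex]][[ix]] <- r
      if (is.null(r)) next
      auc_rows[[length(auc_rows) + 1L]] <- data.frame(
        sex = sex, index = ix, auc = r$auc,
        ci_lo = r$auc_ci[1], ci_hi = r$auc_ci[2])
      cut_rows[[length(cut_rows) + 1L]] <- data.frame(
        sex = sex, index = ix, cutoff = r$best_cutoff,
        sensitivity = 100 * r$best_sensitivity,
        specificity = 100 * r$best_specificity, youden = r$youden_j)
    }
  }
  structure(list(ally_by_index = ally_by_index,
                 ally_by_age = ally_by_age,
                 prevalence_by_index = prevalence_by_index,
                 stratified = stratified,
                 auc = do.call(rbind, auc_rows),
                 cutoffs = do.call(rbind, cut_rows),
                 roc = roc),
            class = "heartally_analysis")
}

#' @export
print.heartally_analysis <- function(x, ...) {
  cat("Cohort analysis\n")
  cat("  AUC of indices vs high ALLY:\n")
  print(x$auc, row.names = FALSE)
  invisible(x)
}

#' Render analysis tables to CSV
#'
#' Writes one CSV per table family: mean ALLY by index level and sex,
#' age-band means, high-ALLY prevalence by index level, the stratified
#' odds-ratio table, AUC with CI per index and sex, and the
#' cut-off/sensitivity/specificity/Youden table, plus the ROC operating
#' points per sex and index.
#'
#' @param analysis a `heartally_analysis`.
#' @param out_dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_tables <- function(analysis, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(df, name) {
    if (is.null(df)) return()
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  emit(analysis$ally_by_index, "ally_by_index_level.csv")
  emit(analysis$ally_by_age, "ally_by_age_band.csv")
  emit(analysis$prevalence_by_index, "high_ally_prevalence.csv")
  emit(analysis$stratified$table, "stratified_odds_ratios.csv")
  emit(analysis$auc, "auc_by_index.csv")
  emit(analysis$cutoffs, "youden_cutoffs.csv")
  for (sex in names(analysis$roc))
    for (ix in names(analysis$roc[[sex]])) {
      r <- analysis$roc[[sex]][[ix]]
      if (!is.null(r)) emit(r$points, sprintf("roc_%s_%s.csv", ix, sex))
    }
  invisible(paths)
}

#' Run the whole pipeline
#'
#' One reproducible run: load a cohort from file or simulate one, derive
#' covariates, score heart age, compute the atherogenic indices, run the
#' statistical stage and render the report tables.  A manifest (seed,
#' package version, input description, MD5 of every output) is written
#' alongside the outputs so identical config + seed yields an identical
#' bundle.
#'
#' @param input path of a cohort CSV, or NULL to simulate.
#' @param config a `generator_config` used when `input` is NULL.
#' @param seed integer seed for all randomness in the run.
#' @param out_dir output directory, or NULL to skip rendering.
#' @param column_map passed to [read_cohort()].
#' @return list with `cohort` (scored), `analysis`, `rejects`, `paths`,
#'   `manifest`.
#' @export
run_pipeline <- function(input = NULL, config = generator_config(),
                         seed = 1L, out_dir = NULL, column_map = NULL) {
  if (is.null(input) && is.null(config))
    stop("config error: provide either 'input' or 'config'")
  if (!is.null(input)) {
    res <- read_cohort(input, column_map = column_map)
    cohort <- derive_covariates(res$cohort)
    rejects <- res$rejects
  } else {
    cohort <- generate_cohort(config, seed = seed)
    rejects <- NULL
  }
  scored <- compute_indices(score_cohort(cohort))
  analysis <- analyze_cohort(scored)
  paths <- character(0); manifest <- NULL
  if (!is.null(out_dir)) {
    paths <- render_tables(analysis, out_dir)
    cohort_path <- file.path(out_dir, "scored_cohort.csv")
    write_cohort(scored, cohort_path)
    paths <- c(paths, cohort_path)
    manifest <- list(
      package = "heartally",
      version = as.character(utils::packageVersion("heartally")),
      seed = seed,
      input = if (is.null(input)) "simulated" else input,
      n = nrow(scored),
      outputs = as.list(tools::md5sum(paths)))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  list(cohort = scored, analysis = analysis, rejects = rejects,
       paths = paths, manifest = manifest)
}
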