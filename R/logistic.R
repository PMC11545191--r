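#' Logistic regression by iteratively reweighted least squares
#'
#' Maximum-likelihood binary logistic fit with odds ratios and Wald 95%
#' confidence intervals per non-reference level.  Categorical covariates
#' are expanded against declared reference levels (the level that carries
#' OR = 1 by definition).  Convergence is declared when the largest
#' absolute score (gradient) component falls below `tol`; separation or
#' non-convergence raises an explicit diagnostic rather than returning a
#' silent result.
#'
#' @param data data.frame holding the covariates.
#' @param outcome logical/0-1 vector, or the name of a column of `data`.
#' @param covariates character vector of covariate column names.
#' @param ref_levels named list, reference level per categorical covariate
#'   (defaults to the first sorted level).
#' @param tol convergence tolerance on the score, default 1e-8.
#' @param max_iter iteration cap, default 50.
#' @return object of class `logistic_fit`: `coefficients` (data.frame of
#'   term, estimate, se, z, p, or, or_lo, or_hi), `reference_levels`,
#'   `converged`, `iterations`, `fitted`, `y`, `loglik`, `n`.
#' @export
fit_logistic <- function(data, outcome, covariates, ref_levels = list(),
                         tol = 1e-8, max_iter = 50L) {
  if (is.character(outcome) && length(outcome) == 1L)
    outcome <- data[[outcome]]
  y <- as.numeric(as.logical(outcome))
  df <- as.data.frame(data)[, covariates, drop = FALSE]
  keep <- stats::complete.cases(df) & !is.na(y)
  df <- df[keep, , drop = FALSE]; y <- y[keep]
  if (length(unique(y)) < 2L) stop("outcome has a single class")
  for (v in covariates) {
    if (is.character(df[[v]]) || is.factor(df[[v]]) || is.logical(df[[v]])) {
      f <- factor(df[[v]], ordered = FALSE)
      if (!is.null(ref_levels[[v]])) f <- stats::relevel(f, ref_levels[[v]])
      df[[v]] <- f
    }
  }
  X <- stats::model.matrix(stats::reformulate(covariates), data = df)
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")

  beta <- numeric(ncol(X))
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    score <- drop(crossprod(X, y - mu))
    if (max(abs(score)) < tol) { converged <- TRUE; break }
    w <- mu * (1 - mu)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, score),
                     error = function(e) stop("singular information matrix; ",
                                              "possible separation"))
    beta <- beta + step
  }
  if (!converged && max(abs(drop(crossprod(X, y - stats::plogis(X %*% beta))))) >= tol)
    stop("IRLS did not converge in ", max_iter,
         " iterations; possible separation")
  if (any(abs(beta) > 30))
    warning("very large coefficient(s): quasi-complete separation likely")

  mu <- stats::plogis(drop(X %*% beta))
  H <- crossprod(X * (mu * (1 - mu)), X)
  se <- sqrt(diag(solve(H)))
  zq <- stats::qnorm(0.975)
  coefs <- data.frame(term = colnames(X), estimate = beta, se = se,
                      z = beta / se,
                      p = 2 * stats::pnorm(-abs(beta / se)),
                      or = exp(beta),
                      or_lo = exp(beta - zq * se),
                      or_hi = exp(beta + zq * se),
                      row.names = NULL)
  refs <- lapply(df[covariates], function(col)
    if (is.factor(col)) levels(col)[1L] else NULL)
  structure(list(coefficients = coefs,
                 reference_levels = Filter(Negate(is.null), refs),
                 converged = converged, iterations = it,
                 fitted = mu, y = y,
                 loglik = sum(y * log(mu) + (1 - y) * log(1 - mu)),
                 n = length(y)),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 3, ...) {
  cat("Logistic fit: n =", x$n, "; converged in", x$iterations,
      "iterations; log-likelihood", format(x$loglik, digits = digits), "\n")
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], round, digits)
  print(tab, row.names = FALSE)
  if (length(x$reference_levels)) {
    cat("reference levels (OR = 1):",
        paste(names(x$reference_levels), unlist(x$reference_levels),
              sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Hosmer--Lemeshow goodness-of-fit test
#'
#' Groups individuals into `groups` bins by deciles of predicted risk and
#' compares observed with expected outcome counts:
#' `sum_g (O_g - E_g)^2 / (E_g (1 - E_g / n_g))`, referred to a chi-square
#' with `groups - 2` degrees of freedom.  Bins whose expected count is
#' degenerate (0 or n_g) are merged with their neighbor, with a message.
#'
#' @param fit a `logistic_fit`.
#' @param groups number of risk groups, default 10; must be > 2.
#' @return list with `statistic`, `df`, `p_value`, `groups` (the table of
#'   per-group n, observed and expected counts).
#' @export
hosmer_lemeshow <- function(fit, groups = 10L) {
  stopifnot(inherits(fit, "logistic_fit"))
  if (groups <= 2L) stop("insufficient groups: df = groups - 2 must be > 0")
  p <- fit$fitted; y <- fit$y
  if (length(unique(p)) < groups) {
    g <- factor(p)   # few distinct risks (e.g. saturated categorical fit)
  } else {
    br <- unique(stats::quantile(p, probs = seq(0, 1, length.out = groups + 1)))
    g <- cut(p, breaks = br, include.lowest = TRUE)
  }
  tab <- data.frame(n = as.vector(table(g)),
                    obs = as.vector(tapply(y, g, sum)),
                    exp = as.vector(tapply(p, g, sum)))
  bad <- which(tab$exp <= 0 | tab$exp >= tab$n)
  while (length(bad) && nrow(tab) > 3L) {
    i <- bad[1L]
    j <- if (i == nrow(tab)) i - 1L else i + 1L
    tab[j, ] <- tab[i, ] + tab[j, ]
    tab <- tab[-i, , drop = FALSE]
    message("merged a risk group with degenerate expected count")
    bad <- which(tab$exp <= 0 | tab$exp >= tab$n)
  }
  denom <- tab$exp * (1 - tab$exp / tab$n)
  contrib <- (tab$obs - tab$exp)^2
  stat <- sum(ifelse(contrib == 0, 0, contrib / denom))
  df <- nrow(tab) - 2L
  if (df < 1L) {
    warning("fewer than 3 risk groups: statistic reported without a p-value")
    return(list(statistic = stat, df = df, p_value = NA_real_, groups = tab))
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       groups = tab)
}

#' Age-stratified logistic regression
#'
#' Runs [fit_logistic()] independently within each age band and collects
#' the per-stratum odds-ratio tables, the layout used to ask whether a
#' risk factor's influence on high ALLY heart age changes with age.
#' Strata that are empty or have a single outcome class are skipped with
#' a warning, never silently.
#'
#' @param cohort a scored `cohort_table` (or data.frame) with an `age`
#'   column.
#' @param outcome outcome column name, default `"high_ally"`.
#' @param covariates covariate names passed to [fit_logistic()].
#' @param ref_levels reference levels per categorical covariate.
#' @param breaks age band edges, default `c(20, 30, 40, 50, 60, 70)`.
#' @return list of class `stratified_fit`: `fits` (named list of
#'   `logistic_fit` or NULL for skipped strata) and `table` (long
#'   data.frame of stratum x term odds ratios).
#' @export
stratified_analysis <- function(cohort, outcome = "high_ally", covariates,
                                ref_levels = list(),
                                breaks = c(20, 30, 40, 50, 60, 70)) {
  df <- as.data.frame(cohort)
  lab <- paste0(breaks[-length(breaks)], "-", breaks[-1] - 1)
  band <- cut(df$age, breaks = breaks, labels = lab, right = FALSE,
              include.lowest = TRUE)
  fits <- stats::setNames(vector("list", length(lab)), lab)
  rows <- list()
  for (s in lab) {
    sub <- df[!is.na(band) & band == s, , drop = FALSE]
    if (nrow(sub) == 0L || length(unique(sub[[outcome]])) < 2L) {
      warning("stratum ", s, " skipped: empty or single-class outcome")
      next
    }
    fit <- tryCatch(fit_logistic(sub, outcome, covariates, ref_levels),
                    error = function(e) {
                      warning("stratum ", s, " skipped: ", conditionMessage(e))
                      NULL
                    })
    if (is.null(fit)) next
    fits[[s]] <- fit
    co <- fit$coefficients[fit$coefficients$term != "(Intercept)", ]
    rows[[s]] <- data.frame(stratum = s, co, row.names = NULL)
  }
  structure(list(fits = fits, table = do.call(rbind, c(rows,
                 list(make.row.names = FALSE)))),
            class = "stratified_fit")
}

#' @export
print.stratified_fit <- function(x, ...) {
  done <- names(Filter(Negate(is.null), x$fits))
  cat("Stratified logistic fits over", length(x$fits), "age bands (",
      length(done), "fitted )\n")
  invisible(x)
}
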