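## OLS model suites with family-cluster-robust (CR1) standard errors,
## interaction terms, and the published-table catalogs.

#' Describe a regression model
#'
#' @param outcome outcome column name.
#' @param terms character vector of regressors; products as `"a:b"`.
#' @param cluster clustering column (family id).
#' @param score_term optional name of the polygenic-score column, used to
#'   report the score-alone R-squared.
#' @return A `model_spec` list.
#' @export
model_spec <- function(outcome, terms, cluster = "family_id",
                       score_term = NULL) {
  structure(list(outcome = outcome, terms = terms, cluster = cluster,
                 score_term = score_term), class = "model_spec")
}

#' OLS with cluster-robust standard errors
#'
#' Point estimates are ordinary least squares; the covariance is the cluster
#' sandwich `c (X'X)^-1 [sum_g X_g' u_g u_g' X_g] (X'X)^-1` with the CR1
#' small-sample factor `c = G/(G-1) * (N-1)/(N-K)` (CR0 sets `c = 1`).
#' Rows with missing values on any model variable are dropped listwise.
#'
#' @param data data.frame holding all referenced columns.
#' @param spec a [model_spec()].
#' @param type `"CR1"` (default) or `"CR0"`.
#' @return Object of class `model_fit`: `coefficients`, `se`, `vcov`, `r2`,
#'   `r2_score_alone`, `n_obs`, `n_families`, plus the fitting ingredients
#'   needed for prediction.
#' @export
fit_ols_clustered <- function(data, spec, type = c("CR1", "CR0")) {
  type <- match.arg(type)
  assert_cols(data, unique(c(spec$outcome, all.vars(reformulate(spec$terms)),
                             spec$cluster)), "model data")
  f <- reformulate(spec$terms, response = spec$outcome)
  use <- complete.cases(data[, unique(c(spec$outcome,
                                        all.vars(reformulate(spec$terms)),
                                        spec$cluster))])
  n_drop <- sum(!use)
  if (n_drop > 0) message(sprintf("fit_ols_clustered: %d row(s) dropped listwise", n_drop))
  d <- data[use, , drop = FALSE]
  X <- model.matrix(f, d)
  y <- d[[spec$outcome]]
  cl <- as.character(d[[spec$cluster]])
  G <- length(unique(cl))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_poly("singular design; collinear term(s): %s", paste(dep, collapse = ", "))
  }
  if (G < 2) stop_poly("need at least 2 clusters; found %d", G)
  fit <- lm.fit(X, y)
  beta <- fit$coefficients
  u <- fit$residuals
  N <- nrow(X); K <- ncol(X)
  bread <- chol2inv(qr.R(qrX))
  dimnames(bread) <- list(colnames(X), colnames(X))
  meat <- crossprod(rowsum(X * u, cl))
  cfac <- if (type == "CR1") G / (G - 1) * (N - 1) / (N - K) else 1
  V <- cfac * bread %*% meat %*% bread
  r2 <- 1 - sum(u^2) / sum((y - mean(y))^2)
  r2_score <- NA_real_
  if (!is.null(spec$score_term) && spec$score_term %in% names(d)) {
    s <- d[[spec$score_term]]
    r2_score <- summary(lm(y ~ s))$r.squared
  }
  structure(list(coefficients = beta, se = sqrt(diag(V)), vcov = V,
                 r2 = r2, r2_score_alone = r2_score,
                 n_obs = N, n_families = G, spec = spec,
                 terms_formula = f), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("OLS of %s (cluster-robust on %s): n = %d in %d families\n",
              x$spec$outcome, x$spec$cluster, x$n_obs, x$n_families))
  tab <- data.frame(estimate = x$coefficients, se = x$se,
                    z = x$coefficients / x$se)
  tab$p <- 2 * pnorm(-abs(tab$z))
  print(round(tab, 4))
  cat(sprintf("R2 = %.4f", x$r2))
  if (!is.na(x$r2_score_alone))
    cat(sprintf("; R2 for score w/out other controls = %.4f", x$r2_score_alone))
  cat("\n")
  invisible(x)
}

#' Fit a fixed catalog of intergenerational models
#'
#' Reproduces the published model layouts on an analysis table (one row per
#' offspring): `"table4"` runs the parental-education / offspring-score /
#' parental-score ladder, `"table5"` the score-by-maternal-education and
#' score-by-maternal-score interaction models, `"table7"` the variants adding
#' the father's education and score. Models referencing columns absent from
#' `data` (e.g. parental scores in a cohort without parental genotypes) are
#' skipped with a message.
#'
#' @param data analysis data.frame (see [cohort_analysis_table()]).
#' @param suite `"table4"`, `"table5"` or `"table7"`.
#' @param interaction_main_effects include all constituent main effects in
#'   interaction models (default). `FALSE` reproduces the published variant
#'   of the gene-gene interaction model that omits the maternal-score main
#'   effect.
#' @param cluster clustering column.
#' @return Named list of [fit_ols_clustered()] fits.
#' @export
run_model_suite <- function(data, suite = c("table4", "table5", "table7"),
                            interaction_main_effects = TRUE,
                            cluster = "family_id") {
  suite <- match.arg(suite)
  base <- c("sex_female", "age")
  if ("survey_year" %in% names(data) && !all(is.na(data$survey_year)) &&
      stats::sd(data$survey_year, na.rm = TRUE) > 0) {
    base <- c(base, "survey_year")
  }
  gg_terms <- if (interaction_main_effects) {
    c("score_std", "mother_score_std", "score_std:mother_score_std")
  } else c("score_std", "score_std:mother_score_std")
  catalog <- switch(suite,
    table4 = list(
      m1 = c(base, "mother_edu"),
      m2 = c(base, "score_std"),
      m3 = c(base, "mother_edu", "score_std"),
      m4 = c(base, "mother_score_std"),
      m5 = c(base, "mother_edu", "mother_score_std"),
      m6 = c(base, "mother_edu", "score_std", "mother_score_std")),
    table5 = list(
      m1 = c(base, "mother_edu", "score_std"),
      m2 = c(base, "mother_edu", "score_std", "score_std:mother_edu"),
      m3 = c(base, "mother_edu", gg_terms)),
    table7 = list(
      m1 = c(base, "mother_edu", "father_edu"),
      m2 = c(base, "mother_edu", "father_edu", "score_std",
             "mother_score_std", "father_score_std"),
      m3 = c(base, "mother_edu", "father_edu", "score_std")))
  fits <- list()
  for (nm in names(catalog)) {
    vars <- all.vars(reformulate(catalog[[nm]]))
    if (!all(vars %in% names(data))) {
      message(sprintf("run_model_suite: skipping %s/%s (missing: %s)", suite, nm,
                      paste(setdiff(vars, names(data)), collapse = ", ")))
      next
    }
    score_term <- if ("score_std" %in% catalog[[nm]]) "score_std"
      else if ("mother_score_std" %in% catalog[[nm]]) "mother_score_std"
      else NULL
    fits[[nm]] <- fit_ols_clustered(
      data, model_spec("edu_years", catalog[[nm]], cluster = cluster,
                       score_term = score_term))
  }
  if (!length(fits)) stop_poly("no model in suite %s could be fitted", suite)
  class(fits) <- "model_suite"
  fits
}

#' @export
print.model_suite <- function(x, ...) {
  cat(format_model_table(x))
  invisible(x)
}

#' Render a model suite as a publication-style text table
#' @param fits a [run_model_suite()] result.
#' @return A single character string.
#' @export
format_model_table <- function(fits) {
  terms <- unique(unlist(lapply(fits, function(f) names(f$coefficients))))
  lines <- sprintf("%-34s %s", "", paste(sprintf("%14s", names(fits)), collapse = ""))
  for (tm in terms) {
    cells <- vapply(fits, function(f) {
      if (tm %in% names(f$coefficients)) {
        sprintf("%7.3f(%5.3f)", f$coefficients[[tm]], f$se[[tm]])
      } else sprintf("%14s", "")
    }, character(1))
    lines <- c(lines, sprintf("%-34s %s", tm, paste(cells, collapse = "")))
  }
  r2 <- vapply(fits, function(f) sprintf("%14.3f", f$r2), character(1))
  lines <- c(lines, sprintf("%-34s %s", "R2", paste(r2, collapse = "")))
  rs <- vapply(fits, function(f)
    if (is.na(f$r2_score_alone)) sprintf("%14s", "")
    else sprintf("%14.3f", f$r2_score_alone), character(1))
  lines <- c(lines, sprintf("%-34s %s", "R2 score alone", paste(rs, collapse = "")))
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Predicted schooling advantage from the gene-gene interaction model
#'
#' Given a fit containing the offspring-score main effect and the
#' offspring-score-by-maternal-score product, returns the expected extra
#' years of schooling for a child `z_child` SDs above the score mean whose
#' mother is `z_mother` SDs above the maternal-score mean, holding all else
#' fixed: `beta_score * z_child + beta_int * z_child * z_mother`.
#'
#' @param fit a [fit_ols_clustered()] result.
#' @param z_child,z_mother score z-values.
#' @param score_term,interaction_term coefficient names.
#' @return Years of schooling.
#' @export
predict_interaction_advantage <- function(fit, z_child, z_mother,
                                          score_term = "score_std",
                                          interaction_term = "score_std:mother_score_std") {
  cf <- fit$coefficients
  if (!(score_term %in% names(cf))) {
    stop_poly("fit lacks the score main effect '%s'", score_term)
  }
  it <- if (interaction_term %in% names(cf)) interaction_term else {
    rev_name <- paste(rev(strsplit(interaction_term, ":")[[1]]), collapse = ":")
    if (!(rev_name %in% names(cf))) {
      stop_poly("fit lacks the interaction term '%s'", interaction_term)
    }
    rev_name
  }
  unname(cf[[score_term]] * z_child + cf[[it]] * z_child * z_mother)
}
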