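## The headline statistic: convert the score-conditional attenuation of the
## parental-education coefficient into the genetic share of the
## intergenerational association, plus a cluster-bootstrap test of the
## coefficient difference.

#' Percent attenuation of a coefficient
#'
#' `100 * (beta_raw - beta_adj) / beta_raw`; the sign is preserved, so a
#' coefficient that *grew* under adjustment yields a negative attenuation.
#'
#' @param beta_raw coefficient without the score control (non-zero).
#' @param beta_adj same coefficient with the offspring score controlled.
#' @return Attenuation in percent.
#' @export
attenuation <- function(beta_raw, beta_adj) {
  if (!is.finite(beta_raw) || beta_raw == 0) {
    stop_poly("attenuation undefined: beta_raw is zero or non-finite")
  }
  100 * (beta_raw - beta_adj) / beta_raw
}

#' Genetic share of the intergenerational association
#'
#' Scales the observed attenuation of the parental-education coefficient up
#' to what a perfectly measured genetic factor would imply:
#' `share = attenuation_pct * (h2 / r2_score) * relatedness`.
#' The heritability-to-score ratio `h2 / r2_score` compensates for the
#' score's limited predictive power, and `relatedness` (0.5 for parent and
#' child) for partial genetic sharing. The two published groupings of the
#' same arithmetic are both rendered: a single combined multiplier
#' (`(h2/r2) * r`, e.g. 5) or a heritability factor applied before
#' relatedness (e.g. 7.58 then 0.5). A `scale_factor` can be supplied
#' directly in place of `h2 / r2_score`.
#'
#' @param attenuation_pct percent attenuation (see [attenuation()]).
#' @param h2 assumed or estimated SNP heritability, with
#'   `0 < r2_score <= h2 <= 1`.
#' @param r2_score predictive R-squared of the score run alone.
#' @param relatedness genetic sharing between the parent and child (default
#'   0.5).
#' @param scale_factor optional direct override of `h2 / r2_score`.
#' @return Object of class `genetic_share` (a number with the pieces as
#'   attributes); `as.numeric()` gives the share in percent.
#' @export
genetic_share <- function(attenuation_pct, h2 = NULL, r2_score = NULL,
                          relatedness = 0.5, scale_factor = NULL) {
  if (relatedness <= 0 || relatedness > 1) {
    stop_poly("relatedness must lie in (0, 1]")
  }
  if (is.null(scale_factor)) {
    if (is.null(h2) || is.null(r2_score)) {
      stop_poly("supply either scale_factor or both h2 and r2_score")
    }
    if (r2_score <= 0 || h2 > 1) stop_poly("need 0 < r2_score and h2 <= 1")
    if (r2_score > h2) {
      stop_poly("r2_score (%.4g) exceeds h2 (%.4g): the score cannot out-predict heritability",
                r2_score, h2)
    }
    scale_factor <- h2 / r2_score
  } else if (scale_factor < 1) {
    stop_poly("scale_factor below 1 is inconsistent with r2_score <= h2")
  }
  share <- attenuation_pct * scale_factor * relatedness
  structure(share, scale_factor = scale_factor, relatedness = relatedness,
            combined_multiplier = scale_factor * relatedness,
            attenuation_pct = attenuation_pct, class = "genetic_share")
}

#' @export
print.genetic_share <- function(x, ...) {
  cat(sprintf(
    "genetic share: %.2f%% of the intergenerational association\n  = attenuation %.3g%% x scaling factor %.3g x relatedness %.2g (combined multiplier %.3g)\n",
    as.numeric(x), attr(x, "attenuation_pct"), attr(x, "scale_factor"),
    attr(x, "relatedness"), attr(x, "combined_multiplier")))
  invisible(x)
}

#' Cluster-bootstrap test of a coefficient difference across two models
#'
#' Tests whether a coefficient (typically maternal education) differs between
#' a model without and with the offspring score. The classical Hausman
#' variance formula is invalid here because neither estimator is efficient,
#' so the difference `delta = beta_raw - beta_adj` is bootstrapped by
#' resampling whole families with replacement; `stat = delta / SE_boot` is
#' referred to the normal distribution. Point estimates come from the full
#' sample.
#'
#' @param data analysis data.frame.
#' @param spec_raw,spec_adj [model_spec()]s sharing outcome, sample and the
#'   tested term.
#' @param term tested coefficient name.
#' @param n_boot bootstrap replicates (>= 999 recommended for inference).
#' @param seed RNG seed.
#' @return List: `delta`, `se_boot`, `stat`, `p_value`, `n_boot`.
#' @export
coefficient_difference_test <- function(data, spec_raw, spec_adj, term,
                                        n_boot = 999L, seed = 1L) {
  if (spec_raw$outcome != spec_adj$outcome ||
      spec_raw$cluster != spec_adj$cluster) {
    stop_poly("the two specs must share outcome and cluster variable")
  }
  fit_raw <- fit_ols_clustered(data, spec_raw)
  fit_adj <- fit_ols_clustered(data, spec_adj)
  for (f in list(fit_raw, fit_adj)) {
    if (!(term %in% names(f$coefficients))) {
      stop_poly("term '%s' missing from a fitted model", term)
    }
  }
  delta <- fit_raw$coefficients[[term]] - fit_adj$coefficients[[term]]
  vars <- unique(c(spec_raw$outcome, all.vars(reformulate(spec_raw$terms)),
                   all.vars(reformulate(spec_adj$terms)), spec_raw$cluster))
  d <- data[complete.cases(data[, vars]), vars, drop = FALSE]
  f_raw <- reformulate(spec_raw$terms, response = spec_raw$outcome)
  f_adj <- reformulate(spec_adj$terms, response = spec_adj$outcome)
  X_raw <- model.matrix(f_raw, d)
  X_adj <- model.matrix(f_adj, d)
  y <- d[[spec_raw$outcome]]
  fam <- as.character(d[[spec_raw$cluster]])
  fam_rows <- split(seq_len(nrow(d)), fam)
  G <- length(fam_rows)
  j_raw <- match(term, colnames(X_raw))
  j_adj <- match(term, colnames(X_adj))
  deltas <- with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(G, G, replace = TRUE)
      rows <- unlist(fam_rows[pick], use.names = FALSE)
      b_raw <- lm.fit(X_raw[rows, , drop = FALSE], y[rows])$coefficients[j_raw]
      b_adj <- lm.fit(X_adj[rows, , drop = FALSE], y[rows])$coefficients[j_adj]
      b_raw - b_adj
    }, numeric(1))
  })
  se <- stats::sd(deltas)
  stat <- if (se > 0) delta / se else 0
  list(delta = unname(delta), se_boot = se, stat = unname(stat),
       p_value = 2 * pnorm(-abs(stat)), n_boot = n_boot)
}

#' End-to-end mediation analysis on a cohort
#'
#' Fits the raw model (parental education without the score) and the adjusted
#' model (score added) with family-clustered SEs, computes the attenuation of
#' the parental-education coefficient, the score-alone R-squared, and scales
#' up to the genetic share of the intergenerational association via
#' [genetic_share()]. Heritability comes from a [reml_fit()] result or is
#' supplied directly.
#'
#' @param data analysis data.frame (see [cohort_analysis_table()]).
#' @param h2 assumed heritability, or `NULL` to take it from `reml`.
#' @param reml optional `reml_result` supplying `h2`.
#' @param relatedness parent-offspring genetic sharing (default 0.5).
#' @param term mediated coefficient (default `"mother_edu"`).
#' @param covars baseline covariates present in both models.
#' @param diff_test run [coefficient_difference_test()] as well.
#' @param n_boot,seed bootstrap controls when `diff_test = TRUE`.
#' @return Object of class `mediation_result`.
#' @export
end_to_end_mediation <- function(data, h2 = NULL, reml = NULL,
                                 relatedness = 0.5, term = "mother_edu",
                                 covars = c("sex_female", "age"),
                                 diff_test = FALSE, n_boot = 999L, seed = 1L) {
  if (is.null(h2)) {
    if (is.null(reml)) stop_poly("supply h2 or a reml result")
    h2 <- reml$h2
  }
  covars <- intersect(covars, names(data))
  spec_raw <- model_spec("edu_years", c(covars, term))
  spec_adj <- model_spec("edu_years", c(covars, term, "score_std"),
                         score_term = "score_std")
  fit_raw <- fit_ols_clustered(data, spec_raw)
  fit_adj <- fit_ols_clustered(data, spec_adj)
  beta_raw <- fit_raw$coefficients[[term]]
  beta_adj <- fit_adj$coefficients[[term]]
  att <- attenuation(beta_raw, beta_adj)
  r2_score <- fit_adj$r2_score_alone
  share <- genetic_share(att, h2 = h2, r2_score = r2_score,
                         relatedness = relatedness)
  dt <- if (diff_test) {
    coefficient_difference_test(data, spec_raw, spec_adj, term,
                                n_boot = n_boot, seed = seed)
  } else NULL
  structure(list(term = term, beta_raw = beta_raw, beta_adj = beta_adj,
                 attenuation_pct = att, r2_score = r2_score, h2 = h2,
                 relatedness = relatedness,
                 scale_factor = attr(share, "scale_factor"),
                 combined_multiplier = attr(share, "combined_multiplier"),
                 genetic_share_pct = as.numeric(share),
                 diff_test = dt, fit_raw = fit_raw, fit_adj = fit_adj),
            class = "mediation_result")
}

#' @export
print.mediation_result <- function(x, ...) {
  cat("Mediation of the parental-education coefficient by the offspring score\n")
  cat(sprintf("  %s: %.4f (raw) -> %.4f (score-adjusted); attenuation %.3f%%\n",
              x$term, x$beta_raw, x$beta_adj, x$attenuation_pct))
  cat(sprintf("  score-alone R2 %.4f, h2 %.3f -> scaling factor %.3f; relatedness %.2f\n",
              x$r2_score, x$h2, x$scale_factor, x$relatedness))
  cat(sprintf("  genetic share of the intergenerational association: %.2f%%\n",
              x$genetic_share_pct))
  if (!is.null(x$diff_test)) {
    cat(sprintf("  coefficient-difference test: delta %.4f, boot SE %.4f, p = %.3f\n",
                x$diff_test$delta, x$diff_test$se_boot, x$diff_test$p_value))
  }
  invisible(x)
}
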