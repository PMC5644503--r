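## Within-family / between-family decomposition of the score-education
## regression, and sibling intraclass correlations.

#' Decompose a regression into within- and between-family components
#'
#' The within fit regresses family-demeaned outcome on family-demeaned
#' regressors (families with a single member contribute nothing); the between
#' fit uses one row of unweighted family means per family; the total fit is
#' pooled OLS. Individual-level covariates (sex, age) are demeaned alongside
#' in the within fit. All three use family-cluster-robust (CR1) standard
#' errors. For a single regressor with no covariates the total slope equals
#' `w * within + (1 - w) * between_weighted`, where `w` is the within share
#' of the regressor's sum of squares and `between_weighted` the family-size
#' weighted between slope (stored alongside the unweighted reporting fit).
#'
#' @param data analysis data.frame.
#' @param score_col regressor of interest (default the standardized score).
#' @param outcome outcome column.
#' @param covars individual-level covariates carried in all three fits.
#' @param family family id column.
#' @return Object of class `decomp_result` with `within`, `between`, `total`
#'   fits, variance shares, and family/sibling counts.
#' @export
within_between_decompose <- function(data, score_col = "score_std",
                                     outcome = "edu_years",
                                     covars = c("sex_female", "age"),
                                     family = "family_id") {
  covars <- intersect(covars, names(data))
  vars <- c(outcome, score_col, covars, family)
  assert_cols(data, vars, "decomposition data")
  d <- data[complete.cases(data[, vars]), vars, drop = FALSE]
  fam <- as.character(d[[family]])
  sizes <- table(fam)
  multi <- names(sizes)[sizes >= 2]
  if (length(multi) < 2) {
    stop_poly("within fit needs >= 2 families with >= 2 members; found %d",
              length(multi))
  }

  # within: demean everything inside multi-member families
  dm <- d[fam %in% multi, , drop = FALSE]
  fm <- as.character(dm[[family]])
  for (v in c(outcome, score_col, covars)) {
    dm[[v]] <- dm[[v]] - ave(dm[[v]], fm)
  }
  if (max(abs(dm[[score_col]])) < 1e-12) {
    stop_poly("regressor '%s' is constant within every family; within slope undefined",
              score_col)
  }
  within <- fit_ols_clustered(dm, model_spec(outcome, c(covars, score_col),
                                             cluster = family,
                                             score_term = score_col))

  # between: unweighted family means, one row per family
  agg <- aggregate(d[, c(outcome, score_col, covars)], by = list(fid = fam), mean)
  names(agg)[1] <- family
  between <- fit_ols_clustered(agg, model_spec(outcome, c(covars, score_col),
                                               cluster = family,
                                               score_term = score_col))

  total <- fit_ols_clustered(d, model_spec(outcome, c(covars, score_col),
                                           cluster = family,
                                           score_term = score_col))

  # variance shares and the size-weighted between slope used by the identity
  x <- d[[score_col]]; y <- d[[outcome]]
  xbar_f <- ave(x, fam); ybar_f <- ave(y, fam)
  ss_within <- sum((x - xbar_f)^2)
  ss_total <- sum((x - mean(x))^2)
  ss_between <- sum((xbar_f - mean(x))^2)
  beta_between_weighted <- sum((xbar_f - mean(x)) * (ybar_f - mean(y))) / ss_between
  structure(list(within = within, between = between, total = total,
                 share_within = ss_within / ss_total,
                 share_between = ss_between / ss_total,
                 beta_between_weighted = beta_between_weighted,
                 n_families = length(sizes),
                 n_multi_families = length(multi),
                 n_sibling_pairs = sum(choose(sizes, 2))),
            class = "decomp_result")
}

#' @export
print.decomp_result <- function(x, ...) {
  s <- function(f, nm) sprintf("%6.3f (%5.3f)", f$coefficients[[nm]], f$se[[nm]])
  nm <- x$within$spec$score_term
  cat("Within/between-family decomposition\n")
  cat(sprintf("  within  slope: %s  (R2 score alone %.4f)\n",
              s(x$within, nm), x$within$r2_score_alone))
  cat(sprintf("  between slope: %s  (R2 score alone %.4f)\n",
              s(x$between, nm), x$between$r2_score_alone))
  cat(sprintf("  total   slope: %s  (R2 score alone %.4f)\n",
              s(x$total, nm), x$total$r2_score_alone))
  cat(sprintf("  within share of regressor SS: %.3f; %d families (%d with siblings), %d sibling pairs\n",
              x$share_within, x$n_families, x$n_multi_families, x$n_sibling_pairs))
  invisible(x)
}

#' One-way ANOVA intraclass correlation
#'
#' ICC(1) from the one-way random-effects ANOVA:
#' `(MSB - MSW) / (MSB + (k0 - 1) MSW)` with the unbalanced-design mean
#' family size `k0 = (N - sum n_g^2 / N) / (G - 1)`. A pairwise alternative
#' (mean Pearson correlation over all ordered within-family pairs) is
#' available for sensitivity analysis.
#'
#' @param values numeric vector.
#' @param family_ids family labels, same length.
#' @param method `"anova"` (default) or `"pairwise"`.
#' @return The intraclass correlation.
#' @export
intraclass_correlation <- function(values, family_ids,
                                   method = c("anova", "pairwise")) {
  method <- match.arg(method)
  ok <- is.finite(values) & !is.na(family_ids)
  values <- values[ok]; fam <- as.character(family_ids[ok])
  sizes <- table(fam)
  keep <- fam %in% names(sizes)[sizes >= 2]
  if (!any(keep)) stop_poly("no family with >= 2 members")
  if (method == "pairwise") {
    v <- values[keep]; f <- fam[keep]
    idx <- split(seq_along(v), f)
    pairs <- do.call(rbind, lapply(idx, function(ii) {
      if (length(ii) < 2) return(NULL)
      cmb <- t(combn(ii, 2))
      rbind(cmb, cmb[, 2:1, drop = FALSE])   # both orders: symmetric estimator
    }))
    return(cor(v[pairs[, 1]], v[pairs[, 2]]))
  }
  # ANOVA ICC(1) over families with >= 2 members
  v <- values[keep]; f <- fam[keep]
  N <- length(v); G <- length(unique(f))
  gm <- mean(v)
  means <- tapply(v, f, mean)          # same (alphabetical) order as table(f)
  ng <- as.vector(table(f))
  ssb <- sum(ng * (means - gm)^2)
  ssw <- sum((v - means[f])^2)
  msb <- ssb / (G - 1)
  msw <- ssw / (N - G)
  k0 <- (N - sum(ng^2) / N) / (G - 1)
  (msb - msw) / (msb + (k0 - 1) * msw)
}
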