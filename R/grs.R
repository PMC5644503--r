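## Polygenic (genomic risk) scores: weighted allele-count sums with allele
## harmonization, plus z-standardization within an analysis sample.

#' Compute a polygenic score from a weight table
#'
#' The raw score for person j is the weighted sum over shared SNPs of the
#' effect-allele dosage, `sum_i w_i x_ij`, with weights on the
#' years-of-schooling scale taken from an external GWAS. Weights whose effect
#' allele matches the panel's *other* allele are harmonized by flipping the
#' dosage (`2 - x`), with a warning; an allele that matches neither is a hard
#' error naming the SNP. Missing dosages are mean-imputed via
#' [impute_dosages()].
#'
#' @param genotypes a [genotype_matrix()].
#' @param weights weight table with columns `snp_id`, `effect_allele`,
#'   `weight`.
#' @return A data.frame of class `score_vector` with columns `person_id`,
#'   `raw_score`; attribute `n_snps_used` records the SNP overlap.
#' @export
compute_score <- function(genotypes, weights) {
  assert_cols(weights, c("snp_id", "effect_allele", "weight"), "weight table")
  panel <- genotypes$panel
  m <- match(weights$snp_id, panel$snp_id)
  use <- which(!is.na(m))
  if (!length(use)) stop_poly("no SNPs shared between weight table and genotype panel")
  pidx <- m[use]
  wa <- weights$effect_allele[use]
  same <- wa == panel$effect_allele[pidx]
  flip <- !same & wa == panel$other_allele[pidx]
  bad <- !same & !flip
  if (any(bad)) {
    stop_poly("allele code mismatch for SNP(s): %s",
              paste(head(weights$snp_id[use[bad]], 5), collapse = ", "))
  }
  if (any(flip)) {
    warning(sprintf("compute_score: flipped dosage for %d SNP(s) to the weight table's effect allele",
                    sum(flip)), call. = FALSE)
  }
  genotypes <- impute_dosages(genotypes)
  X <- genotypes$dosage[, pidx, drop = FALSE]
  X[, flip] <- 2 - X[, flip]
  raw <- as.vector(X %*% weights$weight[use])
  out <- data.frame(person_id = genotypes$sample_id, raw_score = raw,
                    stringsAsFactors = FALSE)
  attr(out, "n_snps_used") <- length(use)
  class(out) <- c("score_vector", "data.frame")
  out
}

#' Standardize a polygenic score
#'
#' Adds `std_score = (raw - mean)/sd`, with moments taken over the reference
#' set (default: every scored person). The sample standard deviation (n-1
#' denominator) is used. Scores are conventionally standardized *within
#' generation*, mirroring coefficients reported per standard deviation of the
#' offspring (or parental) score distribution; pass `reference_ids`
#' accordingly.
#'
#' @param score a [compute_score()] result (the `raw_score` column is always
#'   the input, so the operation is idempotent).
#' @param reference_ids optional person ids whose moments define the scale.
#' @return The score table with a `std_score` column.
#' @export
standardize_score <- function(score, reference_ids = NULL) {
  assert_cols(score, c("person_id", "raw_score"), "score vector")
  ref <- if (is.null(reference_ids)) rep(TRUE, nrow(score)) else
    score$person_id %in% reference_ids
  if (!any(ref)) stop_poly("reference set is empty")
  mu <- mean(score$raw_score[ref])
  s <- stats::sd(score$raw_score[ref])
  if (!is.finite(s) || s == 0) stop_poly("reference scores have zero variance")
  score$std_score <- (score$raw_score - mu) / s
  score
}
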