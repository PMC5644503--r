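## Genomic relatedness matrix (centered/scaled identity-by-state estimator)
## and greedy cryptic-relatedness pruning.

#' Compute the genomic relatedness matrix
#'
#' Off-diagonal entries are the standard centered-and-scaled estimator
#' `A_jk = (1/M) sum_i (x_ij - 2 p_i)(x_ik - 2 p_i) / (2 p_i (1 - p_i))`;
#' diagonal entries use
#' `A_jj = 1 + (1/M) sum_i (x_ij^2 - (1 + 2 p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`.
#' Allele frequencies default to in-sample estimates; external frequencies
#' can be supplied. Missing dosages are mean-imputed first.
#'
#' @param genotypes a [genotype_matrix()] with N >= 2 samples and M >= 1 SNPs.
#' @param freqs optional numeric vector of effect-allele frequencies.
#' @return Object of class `grm`: `sample_id`, symmetric matrix `A`,
#'   `n_snps`.
#' @export
compute_grm <- function(genotypes, freqs = NULL) {
  X <- impute_dosages(genotypes)$dosage
  n <- nrow(X); m <- ncol(X)
  if (n < 2) stop_poly("GRM needs at least 2 samples")
  p <- freqs %||% (colMeans(X) / 2)
  if (any(p <= 0 | p >= 1)) {
    bad <- which(p <= 0 | p >= 1)
    stop_poly("monomorphic SNP(s) must be filtered before GRM construction: %s",
              paste(head(colnames(X)[bad], 5), collapse = ", "))
  }
  den <- 2 * p * (1 - p)
  Z <- sweep(X, 2, 2 * p)
  Z <- sweep(Z, 2, sqrt(den), "/")
  A <- tcrossprod(Z) / m
  # GCTA-style diagonal
  diag(A) <- 1 + colMeans((t(X)^2 - (1 + 2 * p) * t(X) + 2 * p^2) / den)
  dimnames(A) <- list(rownames(X), rownames(X))
  structure(list(sample_id = rownames(X), A = A, n_snps = m), class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  off <- x$A[upper.tri(x$A)]
  cat(sprintf("grm: %d samples, %d SNPs; mean off-diagonal %.4g (sd %.4g)\n",
              length(x$sample_id), x$n_snps, mean(off), stats::sd(off)))
  invisible(x)
}

#' Greedy pruning of related pairs
#'
#' While any off-diagonal relatedness is at or above `cutoff`, the individual
#' involved in the most violating pairs is dropped (ties broken by the
#' lexicographically smaller sample id). The conventional cutoff of 0.025
#' retains only pairs less than 2.5 percent related, eliminating cryptic
#' relatives before REML.
#'
#' @param grm a [compute_grm()] result.
#' @param cutoff positive relatedness threshold.
#' @return List with the pruned `grm` and the character vector `dropped_ids`.
#' @export
filter_relatedness <- function(grm, cutoff = 0.025) {
  if (!is.numeric(cutoff) || cutoff <= 0) stop_poly("cutoff must be > 0")
  A <- grm$A
  ids <- grm$sample_id
  viol <- A >= cutoff
  diag(viol) <- FALSE
  cnt <- rowSums(viol)
  alive <- rep(TRUE, length(ids))
  ord <- order(ids)                      # lexicographic rank for tie-breaks
  rank_lex <- integer(length(ids)); rank_lex[ord] <- seq_along(ids)
  dropped <- integer(0)
  while (any(cnt > 0)) {
    mx <- max(cnt)
    cand <- which(cnt == mx)
    j <- cand[which.min(rank_lex[cand])]
    cnt <- cnt - viol[, j]
    cnt[j] <- 0
    viol[j, ] <- FALSE; viol[, j] <- FALSE
    alive[j] <- FALSE
    dropped <- c(dropped, j)
  }
  if (!any(alive)) stop_poly("relatedness filter removed every sample (cutoff %.4g)", cutoff)
  out <- structure(list(sample_id = ids[alive],
                        A = A[alive, alive, drop = FALSE],
                        n_snps = grm$n_snps), class = "grm")
  list(grm = out, dropped_ids = ids[!alive])
}

#' Scale-consistent relatedness cutoff for miniature SNP panels
#'
#' The conventional 2.5% cutoff presumes array-scale panels where GRM
#' estimation noise (SD = `1/sqrt(M)`) is far below 0.025. On simulated
#' panels with a few thousand SNPs, 0.025 sits *inside* the noise
#' distribution and the greedy prune would discard most of an unrelated
#' sample. This helper keeps the cutoff at `cutoff` whenever the panel is
#' large enough for that to be meaningful, and otherwise raises it to
#' `noise_sd_mult` estimation-noise SDs so that only genuinely related pairs
#' (e.g. siblings at ~0.5) are removed.
#'
#' @param cutoff nominal relatedness cutoff (default 0.025).
#' @param m_snps number of SNPs in the panel.
#' @param noise_sd_mult how many noise SDs the effective cutoff must clear.
#' @return A numeric cutoff, `max(cutoff, noise_sd_mult / sqrt(m_snps))`.
#' @export
effective_relatedness_cutoff <- function(cutoff = 0.025, m_snps,
                                         noise_sd_mult = 5) {
  max(cutoff, noise_sd_mult / sqrt(m_snps))
}
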