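test_that("GRM matches the brute-force elementwise oracle", {
  geno <- toy_genotypes(8, 5, seed = 11)
  grm <- compute_grm(geno)
  p <- colMeans(geno$dosage) / 2
  expect_equal(grm$A, oracle_grm(geno$dosage, p), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("GRM centering, self-similarity and invariances", {
  # dosages exactly at 2p for everyone -> zero off-diagonals
  geno1 <- genotype_matrix(matrix(1, 4, 3,
                                  dimnames = list(letters[1:4], c("x", "y", "z"))))
  A1 <- compute_grm(geno1, freqs = rep(0.5, 3))$A
  expect_equal(max(abs(A1[upper.tri(A1)])), 0)

  # duplicated individual: off-diagonal approximately 1 at large M
  geno <- toy_genotypes(6, 4000, seed = 12)
  X <- rbind(geno$dosage, dup = geno$dosage[1, ])
  rownames(X) <- c(geno$sample_id, "dup")
  # drawn panel frequencies: in-sample ones can be monomorphic at n = 7
  grm <- compute_grm(genotype_matrix(X, panel = geno$panel),
                     freqs = geno$panel$freq)
  expect_lt(abs(grm$A["ID001", "dup"] - 1), 4 / sqrt(4000) + 0.05)

  # SNP reordering and wholesale duplication leave A unchanged
  base <- compute_grm(geno, freqs = geno$panel$freq)$A
  set.seed(15)
  perm <- sample(ncol(geno$dosage))
  gp <- genotype_matrix(geno$dosage[, perm],
                        panel = snp_panel(geno$panel$snp_id[perm],
                                          freq = geno$panel$freq[perm]))
  expect_equal(compute_grm(gp, freqs = gp$panel$freq)$A, base, tolerance = 1e-12)
  gd <- genotype_matrix(cbind(geno$dosage, geno$dosage),
                        panel = snp_panel(c(geno$panel$snp_id,
                                            paste0(geno$panel$snp_id, "_b")),
                                          freq = rep(geno$panel$freq, 2)))
  expect_equal(compute_grm(gd, freqs = gd$panel$freq)$A, base, tolerance = 1e-12)

  mono <- genotype_matrix(matrix(c(2, 2, 2, 0, 1, 2), 3, 2,
                                 dimnames = list(letters[1:3], c("m", "ok"))))
  expect_error(compute_grm(mono), "monomorphic")
})

test_that("relatedness pruning removes exactly the violating structure", {
  geno <- toy_genotypes(30, 800, seed = 13)
  grm <- compute_grm(geno)
  cutoff <- effective_relatedness_cutoff(0.025, 800)
  fl <- filter_relatedness(grm, cutoff)
  expect_length(fl$dropped_ids, 0)                # no violations -> identity
  expect_equal(fl$grm$A, grm$A)

  # plant a duplicate pair (relatedness ~ 1) -> exactly one of the two dropped
  X <- geno$dosage
  X[2, ] <- X[1, ]
  g2 <- compute_grm(genotype_matrix(X, panel = geno$panel))
  fl2 <- filter_relatedness(g2, cutoff)
  expect_length(fl2$dropped_ids, 1)
  expect_true(fl2$dropped_ids %in% c("ID001", "ID002"))

  # random planted violations: exhaustive post-check
  A <- diag(12) * 0.98
  set.seed(14)
  A[upper.tri(A)] <- runif(66, -0.02, 0.02)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  for (pr in list(c(1, 5), c(2, 5), c(5, 9), c(3, 11))) {
    A[pr[1], pr[2]] <- A[pr[2], pr[1]] <- 0.3
  }
  ids <- sprintf("s%02d", 1:12)
  dimnames(A) <- list(ids, ids)
  grm3 <- structure(list(sample_id = ids, A = A, n_snps = 1000L), class = "grm")
  fl3 <- filter_relatedness(grm3, 0.025)
  off <- fl3$grm$A[upper.tri(fl3$grm$A)]
  expect_true(all(off < 0.025))
  expect_lte(length(fl3$dropped_ids), 3)          # greedy hits the hub (s05)
  expect_true("s05" %in% fl3$dropped_ids)

  expect_error(filter_relatedness(grm, cutoff = 0), "cutoff")
  # pairwise pruning always retains at least one sample, and ties go to the
  # lexicographically smaller id
  tiny <- structure(list(sample_id = c("b", "a"),
                         A = matrix(c(1, .9, .9, 1), 2,
                                    dimnames = list(c("b", "a"), c("b", "a"))),
                         n_snps = 10L), class = "grm")
  fl_t <- filter_relatedness(tiny, 0.025)
  expect_identical(fl_t$dropped_ids, "a")
})

test_that("effective cutoff stays nominal on dense panels and scales up on sparse ones", {
  expect_equal(effective_relatedness_cutoff(0.025, 500000), 0.025)
  expect_equal(effective_relatedness_cutoff(0.025, 5000), 5 / sqrt(5000))
  expect_gt(effective_relatedness_cutoff(0.025, 5000), 0.025)
})
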