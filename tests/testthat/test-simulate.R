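test_that("founder genotypes follow Hardy-Weinberg moments and are reproducible", {
  g <- draw_founder_genotypes(4000, 3, freq_range = c(0.499, 0.501), seed = 1)
  expect_equal(mean(g$dosage), 1, tolerance = 0.03)
  expect_equal(var(as.vector(g$dosage)), 0.5, tolerance = 0.03)
  g2 <- draw_founder_genotypes(4000, 3, freq_range = c(0.499, 0.501), seed = 1)
  expect_identical(g$dosage, g2$dosage)
  expect_error(draw_founder_genotypes(10, 5, freq_range = c(0.9, 0.1)),
               "degenerate")

  gb <- draw_founder_genotypes(5000, 50, seed = 3)
  phat <- colMeans(gb$dosage) / 2
  se <- sqrt(gb$panel$freq * (1 - gb$panel$freq) / (2 * 5000))
  expect_lt(max(abs(phat - gb$panel$freq) / se), 4.5)
})

test_that("true effects are scaled to the stated genic variance", {
  panel <- draw_founder_genotypes(10, 200, seed = 2)$panel
  # the printed components are V(G) = 1.20, V(P) = 6.10, so the exact ratio
  # is 1.20/6.10 = 0.1967 (prints as 0.20)
  eff <- make_true_effects(panel, h2_true = 1.20 / 6.10, vp_target = 6.10,
                           seed = 5)
  S <- 2 * panel$freq * (1 - panel$freq)
  expect_equal(sum(S * eff$weight^2), 1.20, tolerance = 1e-12)
  eff0 <- make_true_effects(panel, h2_true = 0, seed = 5)
  expect_true(all(eff0$weight == 0))
})

test_that("weight noise respects the heritability ceiling", {
  panel <- draw_founder_genotypes(10, 100, seed = 2)$panel
  eff <- make_true_effects(panel, 0.2, 6.1, seed = 5)
  expect_error(make_noisy_weights(eff, panel, 0.2, 0.3), "exceed")
  nz <- make_noisy_weights(eff, panel, 0.2, 0.2, seed = 1)   # zero-noise limit
  expect_equal(attr(nz, "tau2"), 0)
  expect_equal(nz$weight, eff$weight)
  noisy <- make_noisy_weights(eff, panel, 0.2, 0.026, seed = 1)
  expect_gt(attr(noisy, "tau2"), 0)
})

test_that("Mendelian transmission is consistent with parental genotypes", {
  panel <- snp_panel(c("s1", "s2"), freq = c(0.5, 0.5))
  par <- genotype_matrix(matrix(c(2, 2, 1, 1), 2, 2,
                                dimnames = list(c("m", "f"), c("s1", "s2"))),
                         panel = panel)
  ped <- pedigree(data.frame(
    family_id = "fam", person_id = c("m", "f", sprintf("c%03d", 1:400)),
    father_id = c(NA, NA, rep("f", 400)), mother_id = c(NA, NA, rep("m", 400)),
    sex = c("F", "M", rep("F", 400)),
    generation = c("parent", "parent", rep("offspring", 400))))
  kids <- transmit_genotypes(par, ped, seed = 4)
  expect_true(all(kids$dosage[, "s1"] == 2))          # both parents homozygous
  tab <- table(factor(kids$dosage[, "s2"], levels = 0:2)) / 400
  expect_lt(max(abs(tab - c(0.25, 0.5, 0.25))), 0.08) # het x het ratios

  # no child can carry more copies than the parents can transmit
  g <- toy_genotypes(40, 30, seed = 8)
  ids <- g$sample_id
  ped2 <- pedigree(data.frame(
    family_id = rep(sprintf("f%02d", 1:20), 3)[1:60],
    person_id = c(ids[1:40], sprintf("k%02d", 1:20)),
    father_id = c(rep(NA, 40), ids[21:40]),
    mother_id = c(rep(NA, 40), ids[1:20]),
    sex = c(rep(c("F", "M"), each = 20), rep("M", 20)),
    generation = c(rep("parent", 40), rep("offspring", 20))))
  kids2 <- transmit_genotypes(g, ped2, seed = 5)
  Xm <- g$dosage[1:20, ]; Xf <- g$dosage[21:40, ]
  expect_true(all(kids2$dosage <= (Xm > 0) + (Xf > 0)))
  expect_true(all(kids2$dosage >= (Xm == 2) + (Xf == 2)))
  bad <- ped2; bad$father_id[41] <- "ghost"
  expect_error(transmit_genotypes(g, pedigree(bad)), "ghost")
})

test_that("relative correlations of the genetic value match theory under random mating", {
  cfg <- sim_config(n_families = 5000, m_snps = 300, r_spouse_edu = 0,
                    r_spouse_grs = 0, n_burnin = 1, calibrate = FALSE,
                    calibrate_score = FALSE, sib_sizes = 2L, sib_probs = 1,
                    seed = 17)
  b <- simulate_cohort(cfg)
  off <- b$pedigree[b$pedigree$generation == "offspring", ]
  g <- b$g
  fam <- split(off$person_id, off$family_id)
  sib1 <- vapply(fam, `[`, character(1), 1)
  sib2 <- vapply(fam, `[`, character(1), 2)
  r_sib <- cor(g[sib1], g[sib2])
  expect_lt(abs(r_sib - 0.5), 3 / sqrt(5000) * 0.75 + 0.02)
  r_po <- cor(g[off$person_id], g[off$mother_id])
  expect_lt(abs(r_po - 0.5), 3 / sqrt(10000) * 0.75 + 0.02)
})

test_that("assortative mating hits its spousal targets and inflates sibling ICC", {
  b <- default_cohort()      # calibrated run at n_families = 2000
  r <- b$realized
  cfg <- b$config
  expect_lt(abs(r$r_spouse_edu - cfg$r_spouse_edu), 0.02)
  expect_lt(abs(r$r_spouse_grs - cfg$r_spouse_grs), 0.02)
  expect_lt(abs(r$sib_icc_score - (1 + cfg$r_spouse_grs) / 2), 0.035)
  expect_equal(r$h2_founder, cfg$h2_true, tolerance = 1e-6)
  expect_lt(abs(r$var_g_offspring / (cfg$h2_true * cfg$vp_target) - 1), 0.10)

  # zero assortment: spousal correlations vanish
  cfg0 <- sim_config(n_families = 1500, m_snps = 200, r_spouse_edu = 0,
                     r_spouse_grs = 0, n_burnin = 2, calibrate = FALSE,
                     seed = 19)
  r0 <- simulate_cohort(cfg0)$realized
  expect_lt(abs(r0$r_spouse_edu), 0.06)
  expect_lt(abs(r0$r_spouse_grs), 0.06)

  # infeasible spousal target pair errors with a diagnostic
  expect_error(polytrans:::calibrate_mating_index(0, 0.9, 0.9), "infeasible")
})

test_that("phenotype model nulls and variance budget behave", {
  cfg <- sim_config(n_families = 1500, m_snps = 200, gamma_within = 0,
                    gamma_between = 0, theta_gxg = 0, calibrate = FALSE,
                    calibrate_score = FALSE, seed = 23)
  b <- simulate_cohort(cfg)
  adf <- cohort_analysis_table(b)
  # score is irrelevant conditional on both parents' education
  fit <- fit_ols_clustered(adf, model_spec("edu_years",
                                           c("mother_edu", "father_edu",
                                             "score_std")))
  expect_lt(abs(fit$coefficients[["score_std"]]),
            2.5 * fit$se[["score_std"]] + 0.02)
  # an impossible variance budget is reported, not silently absorbed
  cfg_bad <- sim_config(n_families = 300, m_snps = 50, gamma_within = 40,
                        gamma_between = 40, calibrate = FALSE, seed = 1)
  expect_error(simulate_cohort(cfg_bad), "residual variance")
})

test_that("cohort simulation is deterministic and writes a manifest", {
  td <- withr::local_tempdir()
  cfg <- sim_config(n_families = 60, m_snps = 40, calibrate = FALSE, seed = 77)
  b1 <- simulate_cohort(cfg, out_dir = file.path(td, "a"))
  b2 <- simulate_cohort(cfg, out_dir = file.path(td, "b"))
  expect_identical(b1$genotypes$dosage, b2$genotypes$dosage)
  expect_identical(b1$phenotypes$edu_years, b2$phenotypes$edu_years)
  expect_identical(readLines(file.path(td, "a", "manifest.json")),
                   readLines(file.path(td, "b", "manifest.json")))
  expect_true(file.exists(file.path(td, "a", "genotypes.tsv")))
})
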