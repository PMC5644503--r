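test_that("attenuation arithmetic", {
  expect_equal(attenuation(0.3, 0.3), 0)
  expect_equal(attenuation(0.30, 0.30 * (1 - 0.038)), 3.8)
  set.seed(71)
  for (i in 1:20) {
    br <- runif(1, 0.1, 0.5); ba <- rnorm(1, br, 0.05)
    expect_equal(attenuation(br, ba), 100 * (br - ba) / br)
  }
  expect_error(attenuation(0, 0.1), "beta_raw")
})

test_that("genetic share reproduces both published groupings", {
  s1 <- genetic_share(3.8, scale_factor = 7.58, relatedness = 0.5)
  expect_equal(as.numeric(s1), 14.402, tolerance = 1e-12)
  expect_equal(round(as.numeric(s1), 1), 14.4)
  s2 <- genetic_share(3.33, scale_factor = 10, relatedness = 0.5)  # combined 5
  expect_equal(attr(s2, "combined_multiplier"), 5)
  expect_equal(as.numeric(s2), 16.65, tolerance = 1e-12)
  expect_lt(abs(as.numeric(s2) - 100 / 6), 0.05)                   # ~ one-sixth
  expect_equal(as.numeric(genetic_share(0, scale_factor = 7.58)), 0)
  # h2 / r2 route and invariants
  s3 <- genetic_share(3.8, h2 = 0.20, r2_score = 0.0264)
  expect_equal(attr(s3, "scale_factor"), 0.20 / 0.0264)
  expect_equal(as.numeric(genetic_share(7.6, h2 = .2, r2_score = .026)),
               2 * as.numeric(genetic_share(3.8, h2 = .2, r2_score = .026)))
  expect_equal(as.numeric(genetic_share(3.8, h2 = .2, r2_score = .052)),
               as.numeric(genetic_share(3.8, h2 = .2, r2_score = .026)) / 2)
  # noiseless score at full relatedness: share equals attenuation
  expect_equal(as.numeric(genetic_share(3.8, h2 = .2, r2_score = .2,
                                        relatedness = 1)), 3.8)
  expect_error(genetic_share(3.8, h2 = 0.02, r2_score = 0.1), "out-predict")
  expect_error(genetic_share(3.8, scale_factor = 0.5), "below 1")
  expect_error(genetic_share(3.8, scale_factor = 2, relatedness = 0), "relatedness")
})

test_that("coefficient-difference test: identity, determinism, null size", {
  b <- default_cohort()
  adf <- cohort_analysis_table(b)
  spec <- model_spec("edu_years", c("sex_female", "age", "mother_edu"))
  same <- coefficient_difference_test(adf, spec, spec, "mother_edu",
                                      n_boot = 99, seed = 3)
  expect_equal(same$delta, 0)
  expect_gt(same$p_value, 0.99)
  spec_adj <- model_spec("edu_years", c("sex_female", "age", "mother_edu",
                                        "score_std"))
  t1 <- coefficient_difference_test(adf, spec, spec_adj, "mother_edu",
                                    n_boot = 199, seed = 5)
  t2 <- coefficient_difference_test(adf, spec, spec_adj, "mother_edu",
                                    n_boot = 199, seed = 5)
  expect_identical(t1, t2)
  expect_error(coefficient_difference_test(adf, spec, spec_adj, "absent"),
               "missing")
})

test_that("null world yields near-zero genetic share; strong mediation is detected", {
  cfg0 <- sim_config(n_families = 2500, m_snps = 200, gamma_within = 0,
                     gamma_between = 0, b_father = 0, b_mother = 0.35,
                     calibrate = FALSE, seed = 81)
  adf0 <- cohort_analysis_table(simulate_cohort(cfg0))
  md0 <- end_to_end_mediation(adf0, h2 = 0.2)
  expect_lt(abs(md0$genetic_share_pct), 8)

  # strong mediation, large effects: the difference test should fire
  cfg1 <- sim_config(n_families = 2500, m_snps = 200, gamma_within = 1.2,
                     gamma_between = 1.2, b_father = 0, b_mother = 0.35,
                     r2_score_target = 0.19, calibrate = FALSE, seed = 83)
  adf1 <- cohort_analysis_table(simulate_cohort(cfg1))
  md1 <- end_to_end_mediation(adf1, h2 = 0.2, diff_test = TRUE,
                              n_boot = 299, seed = 7)
  expect_gt(md1$diff_test$stat, 2)
  expect_gt(md1$attenuation_pct, md0$attenuation_pct)
})

test_that("fitted mediation chain matches its covariance-algebra plim", {
  # single-parent path, uniform genetic effect, random mating: the setting
  # in which the scaling statistic's plim has a clean closed form
  h2 <- 0.2; vp <- 6.1; bm <- 0.35; gam <- 0.3; r2t <- 0.026
  cfg <- sim_config(n_families = 3000, m_snps = 300, seed = 404,
                    r_spouse_edu = 0, r_spouse_grs = 0, b_father = 0,
                    b_mother = bm, gamma_within = gam, gamma_between = gam,
                    h2_true = h2, r2_score_target = r2t,
                    calibrate = FALSE, n_burnin = 1)
  adf <- cohort_analysis_table(simulate_cohort(cfg))
  md <- end_to_end_mediation(adf, h2 = h2, covars = character(0))

  sdg <- sqrt(h2 * vp)
  c_gm <- 0.5 * sdg                       # cov(z(g_child), edu_mother)
  c_cm <- bm * vp + gam * c_gm            # cov(edu_child, edu_mother)
  v_c <- vp                               # generator holds vp fixed
  rho <- sqrt(r2t) / ((bm * c_gm + gam) / sqrt(v_c))  # score-g correlation
                                          # implied by the calibrated R2
  c_sm <- rho * c_gm
  c_cs <- bm * c_sm + gam * rho
  beta_raw <- c_cm / vp
  beta_adj <- solve(matrix(c(vp, c_sm, c_sm, 1), 2), c(c_cm, c_cs))[1]
  att_plim <- 100 * (beta_raw - beta_adj) / beta_raw
  share_plim <- att_plim * (h2 / r2t) * 0.5

  expect_equal(md$beta_raw, beta_raw, tolerance = 0.02)
  expect_equal(md$attenuation_pct, att_plim, tolerance = 0.15 * att_plim + 0.5)
  expect_equal(md$genetic_share_pct, share_plim,
               tolerance = 0.15 * share_plim + 2)
})

test_that("end-to-end mediation consumes a REML heritability", {
  b <- default_cohort()
  adf <- cohort_analysis_table(b)
  fake_reml <- structure(list(h2 = 0.25), class = "reml_result")
  md <- end_to_end_mediation(adf, reml = fake_reml)
  expect_equal(md$h2, 0.25)
  expect_equal(md$genetic_share_pct,
               md$attenuation_pct * (0.25 / md$r2_score) * 0.5,
               tolerance = 1e-10)
  expect_error(end_to_end_mediation(adf), "h2 or a reml")
})
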