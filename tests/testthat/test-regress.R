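test_that("singleton clusters reduce CR0 to HC0", {
  set.seed(31)
  d <- data.frame(y = rnorm(40), x = rnorm(40), family_id = sprintf("f%02d", 1:40))
  fit <- fit_ols_clustered(d, model_spec("y", "x"), type = "CR0")
  X <- cbind(1, d$x)
  u <- lm.fit(X, d$y)$residuals
  bread <- solve(crossprod(X))
  hc0 <- bread %*% crossprod(X * u) %*% bread
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-12)
})

test_that("cluster sandwich matches the per-cluster summation oracle", {
  d <- data.frame(y = c(1.2, 0.7, 3.1, 2.2, 4.9, 4.1),
                  x = c(0.1, 0.4, 1.1, 1.3, 2.2, 2.6),
                  family_id = c("a", "a", "a", "b", "b", "b"))
  fit <- fit_ols_clustered(d, model_spec("y", "x"))
  X <- cbind(1, d$x)
  V <- oracle_cluster_vcov(X, d$y, d$family_id)
  expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-12)
  expect_equal(unname(fit$se), unname(sqrt(diag(V))), tolerance = 1e-12)
  # CR1 covariance is symmetric PSD
  expect_equal(fit$vcov, t(fit$vcov))
  expect_true(all(eigen(fit$vcov, symmetric = TRUE)$values > -1e-12))
})

test_that("design pathologies raise named errors", {
  d <- data.frame(y = rnorm(10), x = rnorm(10),
                  family_id = rep(c("one", "two"), 5))
  d$x2 <- d$x * 2
  expect_error(fit_ols_clustered(d, model_spec("y", c("x", "x2"))), "x2")
  d$family_id <- "one"
  expect_error(fit_ols_clustered(d, model_spec("y", "x")), "clusters")
})

test_that("coefficients are invariant to row permutation and orthogonal noise", {
  b <- default_cohort()
  adf <- cohort_analysis_table(b)
  spec <- model_spec("edu_years", c("sex_female", "age", "mother_edu",
                                    "score_std"), score_term = "score_std")
  f1 <- fit_ols_clustered(adf, spec)
  set.seed(5)
  adf2 <- adf[sample(nrow(adf)), ]
  f2 <- fit_ols_clustered(adf2, spec)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$se, f2$se, tolerance = 1e-10)
  adf$junk <- rnorm(nrow(adf))
  f3 <- fit_ols_clustered(adf, model_spec("edu_years",
                                          c("sex_female", "age", "mother_edu",
                                            "score_std", "junk")))
  expect_equal(f3$coefficients[["mother_edu"]], f1$coefficients[["mother_edu"]],
               tolerance = 0.01)
})

test_that("the maternal-education effect is recovered in a controlled world", {
  cfg <- sim_config(n_families = 2000, m_snps = 200, b_mother = 0.35,
                    b_father = 0, gamma_within = 0, gamma_between = 0,
                    r_spouse_edu = 0, r_spouse_grs = 0, n_burnin = 1,
                    calibrate = FALSE, seed = 43)
  adf <- cohort_analysis_table(simulate_cohort(cfg))
  fit <- fit_ols_clustered(adf, model_spec("edu_years",
                                           c("sex_female", "age", "mother_edu")))
  expect_equal(unname(fit$coefficients[["mother_edu"]]), 0.35, tolerance = 0.02)
})

test_that("model suites run, report score R2, and recover the GxG interaction", {
  b <- default_cohort()
  adf <- cohort_analysis_table(b)
  t4 <- run_model_suite(adf, "table4")
  expect_named(t4, c("m1", "m2", "m3", "m4", "m5", "m6"))
  expect_equal(t4$m2$r2_score_alone, b$config$r2_score_target, tolerance = 2e-3)
  expect_gt(t4$m1$coefficients[["mother_edu"]],
            t4$m3$coefficients[["mother_edu"]])   # attenuation direction
  t5 <- run_model_suite(adf, "table5")
  expect_true(any(c("score_std:mother_edu", "mother_edu:score_std") %in%
                    names(t5$m2$coefficients)))
  t7 <- run_model_suite(adf, "table7")
  expect_true(all(c("mother_edu", "father_edu") %in% names(t7$m1$coefficients)))
  txt <- format_model_table(t4)
  expect_match(txt, "mother_edu")
  expect_match(txt, "R2 score alone")

  # parent-child genotype interaction, fitted on the true genetic values
  cfgi <- sim_config(n_families = 2500, m_snps = 200, theta_gxg = 0.15,
                     calibrate = FALSE, seed = 51)
  adfi <- cohort_analysis_table(simulate_cohort(cfgi))
  fi <- fit_ols_clustered(adfi, model_spec("edu_years",
                                           c("sex_female", "age", "mother_edu",
                                             "zg", "zg:mother_zg")))
  est <- fi$coefficients[["zg:mother_zg"]]
  expect_lt(abs(est - 0.15), 2 * fi$se[["zg:mother_zg"]] + 0.01)
})

test_that("interaction advantage is the published arithmetic", {
  fit <- structure(list(coefficients = c("(Intercept)" = 9.3,
                                         score_std = 0.10,
                                         "score_std:mother_score_std" = 0.15)),
                   class = "model_fit")
  expect_equal(predict_interaction_advantage(fit, 0, 1), 0)
  expect_equal(predict_interaction_advantage(fit, 1, 0), 0.10)
  expect_equal(predict_interaction_advantage(fit, 1, 1), 0.25)
  bad <- structure(list(coefficients = c("(Intercept)" = 1)), class = "model_fit")
  expect_error(predict_interaction_advantage(bad, 1, 1), "score main effect")
})
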