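## Forward simulator for a two-generation cohort: founders under
## Hardy-Weinberg, several burn-in generations of assortative mating on a
## noisy education/score index (so gametic-phase disequilibrium reaches its
## mating equilibrium), then a recorded parent generation whose couples have
## 1-3 children by Mendelian transmission at unlinked loci. Structural
## coefficients are calibration targets taken from published fitted tables,
## not asserted mechanisms.

#' Simulator configuration
#'
#' Defaults describe the survey-calibrated world used throughout the package:
#' SNP heritability 0.20 and phenotypic variance 6.10 years^2, spousal
#' education correlation 0.61, spousal score correlation 0.22, score
#' predictive R-squared 0.026, structural parental-education effects of 0.17
#' years per year for each parent (so the mother-only gross coefficient is
#' about 0.30), and within/between-family genetic effects of 0.32 and 0.27
#' years per SD.
#'
#' @param n_families number of couples in the recorded parent generation.
#' @param m_snps number of unlinked biallelic SNPs.
#' @param freq_range effect-allele frequency interval, strictly inside (0,1).
#' @param h2_true target SNP heritability of education.
#' @param vp_target phenotypic variance of education (years^2).
#' @param r_spouse_edu,r_spouse_grs target spousal correlations of education
#'   and of the (noisy, standardized) polygenic score.
#' @param r2_score_target target predictive R-squared of the noisy score on
#'   offspring education; must not exceed `h2_true`.
#' @param b_mother,b_father structural effects of each parent's education
#'   (years per year).
#' @param gamma_within,gamma_between effects of own vs sibling-mean genetic
#'   value (years per SD).
#' @param theta_gxg offspring-genotype by maternal-genotype interaction
#'   (years per SD^2).
#' @param sib_sizes,sib_probs sibship-size distribution.
#' @param mu_edu_parent,mu_edu_offspring generation means (years).
#' @param n_burnin burn-in generations of assortative mating before the
#'   recorded cohort (5 approaches equilibrium within ~1%).
#' @param mate_on_score include the score in the mating index (`FALSE` =
#'   phenotype-only assortment; the spousal score correlation then emerges).
#' @param calibrate refine the score-noise and mating-index parameters
#'   against a pilot simulation so realized moments hit their targets.
#' @param n_pilot pilot size for calibration.
#' @param seed master seed; every stage derives its own stream from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_families = 2000L, m_snps = 500L,
                       freq_range = c(0.05, 0.95),
                       h2_true = 0.20, vp_target = 6.10,
                       r_spouse_edu = 0.61, r_spouse_grs = 0.22,
                       r2_score_target = 0.026,
                       b_mother = 0.17, b_father = 0.17,
                       gamma_within = 0.32, gamma_between = 0.27,
                       theta_gxg = 0,
                       sib_sizes = c(1L, 2L, 3L), sib_probs = c(0.3, 0.4, 0.3),
                       mu_edu_parent = 10.2, mu_edu_offspring = 13.4,
                       n_burnin = 6L, mate_on_score = TRUE,
                       calibrate = TRUE, calibrate_score = TRUE,
                       n_pilot = 4000L, n_calib_rounds = 3L,
                       seed = 42L) {
  cfg <- list(n_families = as.integer(n_families), m_snps = as.integer(m_snps),
              freq_range = freq_range, h2_true = h2_true, vp_target = vp_target,
              r_spouse_edu = r_spouse_edu, r_spouse_grs = r_spouse_grs,
              r2_score_target = r2_score_target,
              b_mother = b_mother, b_father = b_father,
              gamma_within = gamma_within, gamma_between = gamma_between,
              theta_gxg = theta_gxg,
              sib_sizes = as.integer(sib_sizes), sib_probs = sib_probs,
              mu_edu_parent = mu_edu_parent, mu_edu_offspring = mu_edu_offspring,
              n_burnin = as.integer(n_burnin), mate_on_score = mate_on_score,
              calibrate = calibrate, calibrate_score = calibrate_score,
              n_pilot = as.integer(n_pilot),
              n_calib_rounds = as.integer(n_calib_rounds),
              seed = as.integer(seed))
  if (cfg$n_families < 2 || cfg$m_snps < 1) stop_poly("need >= 2 families and >= 1 SNP")
  if (cfg$h2_true < 0 || cfg$h2_true > 1) stop_poly("h2_true must lie in [0,1]")
  if (cfg$r2_score_target > cfg$h2_true) {
    stop_poly("r2_score_target (%.3g) cannot exceed h2_true (%.3g)",
              cfg$r2_score_target, cfg$h2_true)
  }
  if (length(cfg$freq_range) != 2 || cfg$freq_range[1] <= 0 ||
      cfg$freq_range[2] >= 1 || cfg$freq_range[1] >= cfg$freq_range[2]) {
    stop_poly("freq_range must be a nondegenerate interval inside (0,1)")
  }
  if (!all(is.finite(c(cfg$gamma_within, cfg$gamma_between, cfg$theta_gxg,
                       cfg$b_mother, cfg$b_father)))) {
    stop_poly("structural coefficients must be finite")
  }
  if (length(cfg$sib_sizes) != length(cfg$sib_probs) ||
      any(cfg$sib_probs < 0) || sum(cfg$sib_probs) <= 0) {
    stop_poly("invalid sibship-size distribution")
  }
  cfg$sib_probs <- cfg$sib_probs / sum(cfg$sib_probs)
  class(cfg) <- "sim_config"
  cfg
}

#' Draw founder genotypes under Hardy-Weinberg equilibrium
#'
#' Effect-allele frequencies are uniform on `freq_range`; dosages are
#' independent `Binomial(2, p_i)` across loci and individuals.
#'
#' @param n_individuals founders to draw.
#' @param m_snps number of SNPs.
#' @param freq_range frequency interval strictly inside (0,1).
#' @param seed RNG seed.
#' @param id_prefix prefix for generated sample ids.
#' @return A [genotype_matrix()] whose panel records the drawn frequencies.
#' @export
draw_founder_genotypes <- function(n_individuals, m_snps,
                                   freq_range = c(0.05, 0.95), seed = 1L,
                                   id_prefix = "F") {
  if (m_snps < 1) stop_poly("m_snps must be >= 1")
  if (freq_range[1] <= 0 || freq_range[2] >= 1 || freq_range[1] >= freq_range[2]) {
    stop_poly("degenerate freq_range")
  }
  with_seed(as.integer(seed), {
    p <- runif(m_snps, freq_range[1], freq_range[2])
    X <- matrix(rbinom(n_individuals * m_snps, 2L, rep(p, each = n_individuals)),
                n_individuals, m_snps)
  })
  panel <- snp_panel(sprintf("snp%05d", seq_len(m_snps)), freq = p)
  genotype_matrix(X, panel = panel,
                  sample_id = sprintf("%s%06d", id_prefix, seq_len(n_individuals)))
}

#' Draw true per-SNP effects for a polygenic trait
#'
#' Effects are i.i.d. normal, rescaled so the additive genic variance
#' `sum_i 2 p_i (1 - p_i) beta_i^2` equals `h2_true * vp_target` (e.g. 1.20
#' years^2 for h2 = 0.20 and vp = 6.10). `h2_true = 0` yields all-zero
#' weights.
#'
#' @param panel an [snp_panel()] with frequencies filled.
#' @param h2_true target heritability.
#' @param vp_target phenotypic variance.
#' @param seed RNG seed.
#' @return A weight table (`snp_id`, `effect_allele`, `weight`).
#' @export
make_true_effects <- function(panel, h2_true, vp_target = 6.10, seed = 1L) {
  if (anyNA(panel$freq)) stop_poly("panel frequencies must be filled")
  m <- nrow(panel)
  beta <- with_seed(as.integer(seed), rnorm(m))
  S <- 2 * panel$freq * (1 - panel$freq)
  if (h2_true == 0) {
    beta <- rep(0, m)
  } else {
    beta <- beta * sqrt(h2_true * vp_target / sum(S * beta^2))
  }
  data.frame(snp_id = panel$snp_id, effect_allele = panel$effect_allele,
             weight = beta, stringsAsFactors = FALSE)
}

#' Add estimation noise to true effects
#'
#' Emulates a GWAS-estimated weight table: `w_i = beta_i + eta_i` with
#' `eta_i ~ N(0, tau2)` chosen so that `cor^2(score, g) = r2_target / h2_true`
#' in a Hardy-Weinberg founder population, hence a score-on-phenotype
#' R-squared of about `r2_target`. `tau2` can be overridden (the cohort
#' simulator does this after pilot calibration).
#'
#' @param true_effects weight table from [make_true_effects()].
#' @param panel the matching [snp_panel()].
#' @param h2_true heritability used to scale the true effects.
#' @param r2_target target score R-squared, `0 < r2_target <= h2_true`.
#' @param seed RNG seed.
#' @param tau2 optional noise variance override.
#' @return A weight table; attribute `tau2` records the noise variance.
#' @export
make_noisy_weights <- function(true_effects, panel, h2_true, r2_target,
                               seed = 1L, tau2 = NULL) {
  if (r2_target <= 0) stop_poly("r2_target must be positive")
  if (r2_target > h2_true) {
    stop_poly("r2_target (%.3g) exceeds h2_true (%.3g): the score cannot out-predict heritability",
              r2_target, h2_true)
  }
  S <- 2 * panel$freq * (1 - panel$freq)
  vg <- sum(S * true_effects$weight^2)
  if (is.null(tau2)) {
    tau2 <- vg * (h2_true / r2_target - 1) / sum(S)
  }
  eta <- with_seed(as.integer(seed), rnorm(nrow(panel), 0, sqrt(tau2)))
  out <- true_effects
  out$weight <- true_effects$weight + eta
  attr(out, "tau2") <- tau2
  out
}

# project a drawn residual to be exactly orthogonal (in-sample) to the
# systematic components and rescale to the exact target variance; a cheap
# variance-reduction device so realized cohort moments track their targets
# instead of wandering with the residual draw
orthogonalize_residual <- function(e, M, target_var) {
  if (target_var <= 0) return(rep(0, length(e)))
  keep <- apply(M, 2, function(col) stats::sd(col) > 0)
  if (any(keep)) {
    e <- stats::lm.fit(cbind(1, M[, keep, drop = FALSE]), e)$residuals
  } else {
    e <- e - mean(e)
  }
  e * sqrt(target_var / stats::var(e))
}

## ---------------------------------------------------------------------------
## mating

# Solve the mating-index loadings (a, b, noise SD s) so that exact
# rank-matching on I = a z(edu) + b z(score) + s eps yields the target
# spousal correlations. With couples matched on I, r_spouse(x) ~= cor(x, I)^2,
# so we need cor(I, edu) = sqrt(r_edu) and cor(I, score) = sqrt(r_grs); given
# cor(edu, score) = rho_es this is a 2x2 linear solve, feasible iff the
# implied 3x3 correlation matrix is positive semidefinite.
calibrate_mating_index <- function(rho_es, r_edu, r_grs, mate_on_score = TRUE) {
  if (r_edu < 0 || r_grs < 0 || r_edu >= 1 || r_grs >= 1) {
    stop_poly("spousal correlation targets must lie in [0,1)")
  }
  if (r_edu == 0 && (r_grs == 0 || !mate_on_score)) {
    return(list(a = 0, b = 0, s = 1))
  }
  rho_Ie <- sqrt(r_edu)
  if (!mate_on_score) {
    return(list(a = rho_Ie, b = 0, s = sqrt(1 - rho_Ie^2)))
  }
  rho_Is <- sqrt(r_grs)
  den <- 1 - rho_es^2
  a <- (rho_Ie - rho_es * rho_Is) / den
  b <- (rho_Is - rho_es * rho_Ie) / den
  q <- a * rho_Ie + b * rho_Is
  if (q > 1 - 1e-8) {
    stop_poly(paste0("infeasible spousal-correlation target pair: r_edu=%.3g, ",
                     "r_grs=%.3g with cor(edu,score)=%.3g require index variance ",
                     "share %.3g > 1"), r_edu, r_grs, rho_es, q)
  }
  list(a = a, b = b, s = sqrt(1 - q))
}

# Rank-match mothers and fathers on the noisy index; avoid pairing siblings
# by swapping with the neighbouring rank.
pair_by_index <- function(edu, score, sex, fam, params, seed) {
  idx_f <- which(sex == "F"); idx_m <- which(sex == "M")
  if (length(idx_f) != length(idx_m)) {
    stop_poly("need equal numbers of prospective mothers and fathers (got %d F, %d M)",
              length(idx_f), length(idx_m))
  }
  zsafe <- function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  n <- length(idx_f)
  I <- with_seed(as.integer(seed), {
    eps <- rnorm(length(edu))
    out <- numeric(length(edu))
    for (ii in list(idx_f, idx_m)) {
      out[ii] <- params$a * zsafe(edu[ii]) + params$b * zsafe(score[ii]) +
        params$s * eps[ii]
    }
    out
  })
  mo <- idx_f[order(I[idx_f])]
  fa <- idx_m[order(I[idx_m])]
  if (!is.null(fam)) {
    for (pass in 1:2) {
      for (i in seq_len(n)) {
        if (fam[mo[i]] == fam[fa[i]]) {
          j <- if (i < n) i + 1L else i - 1L
          tmp <- fa[i]; fa[i] <- fa[j]; fa[j] <- tmp
        }
      }
    }
  }
  list(mothers = mo, fathers = fa)
}

#' Form couples by noisy-index assortative mating
#'
#' Prospective mothers and fathers are rank-matched on a latent index
#' `a z(edu) + b z(score) + s eps`, with loadings solved in closed form so
#' the realized spousal education and score correlations hit their targets
#' (see the methods vignette). With `r_edu = r_grs = 0` the index is pure
#' noise and mating is random.
#'
#' @param phenotypes data.frame with `person_id`, `edu_years`, `sex`.
#' @param scores numeric score vector aligned with `phenotypes` rows.
#' @param r_edu,r_grs target spousal correlations.
#' @param seed RNG seed.
#' @param mate_on_score include the score in the index.
#' @param rho_es correlation of education and score among founders (defaults
#'   to the empirical value).
#' @param index_params optional precomputed `list(a, b, s)` override.
#' @param sib_group optional family labels used to avoid sibling couples.
#' @return data.frame with `mother_id`, `father_id`, one row per couple.
#' @export
assign_couples <- function(phenotypes, scores, r_edu, r_grs, seed = 1L,
                           mate_on_score = TRUE, rho_es = NULL,
                           index_params = NULL, sib_group = NULL) {
  assert_cols(phenotypes, c("person_id", "edu_years", "sex"), "founder phenotypes")
  if (is.null(index_params)) {
    if (is.null(rho_es)) {
      rho_es <- if (stats::sd(scores) > 0) cor(phenotypes$edu_years, scores) else 0
    }
    index_params <- calibrate_mating_index(rho_es, r_edu, r_grs, mate_on_score)
  }
  pr <- pair_by_index(phenotypes$edu_years, scores, phenotypes$sex,
                      sib_group, index_params, seed)
  data.frame(mother_id = phenotypes$person_id[pr$mothers],
             father_id = phenotypes$person_id[pr$fathers],
             stringsAsFactors = FALSE)
}

#' Mendelian transmission at unlinked loci
#'
#' Each parent contributes one allele per SNP: the transmitted count is
#' `Bernoulli(dosage/2)`, independent across loci and children (no linkage,
#' no phase).
#'
#' @param parent_genotypes [genotype_matrix()] covering every stated parent.
#' @param ped a [pedigree()]; offspring rows must name genotyped parents.
#' @param seed RNG seed.
#' @return A `genotype_matrix` for the offspring (panel inherited).
#' @export
transmit_genotypes <- function(parent_genotypes, ped, seed = 1L) {
  off <- ped[ped$generation == "offspring", , drop = FALSE]
  mi <- match(off$mother_id, parent_genotypes$sample_id)
  fi <- match(off$father_id, parent_genotypes$sample_id)
  if (anyNA(mi) || anyNA(fi)) {
    miss <- unique(c(off$mother_id[is.na(mi)], off$father_id[is.na(fi)]))
    stop_poly("parental dosage missing for: %s", paste(head(miss, 5), collapse = ", "))
  }
  Xm <- parent_genotypes$dosage[mi, , drop = FALSE]
  Xf <- parent_genotypes$dosage[fi, , drop = FALSE]
  if (anyNA(Xm) || anyNA(Xf)) stop_poly("parental dosages contain missing values")
  nm <- length(Xm)
  child <- with_seed(as.integer(seed), {
    matrix(rbinom(nm, 1L, as.vector(Xm) / 2) + rbinom(nm, 1L, as.vector(Xf) / 2),
           nrow(Xm), ncol(Xm))
  })
  genotype_matrix(child, panel = parent_genotypes$panel,
                  sample_id = off$person_id)
}

#' Simulate education phenotypes on a pedigree
#'
#' Parents receive `edu = mu_parent + g + e` with the residual variance set
#' so the generation's heritability is `h2_true` and total variance
#' `vp_target` (already-generated parental educations can be passed through
#' unchanged). Children receive
#' `edu = mu + b_mother edu_mom + b_father edu_dad + gamma_between z(gbar) +
#' gamma_within (z(g) - z(gbar)) + theta_gxg z(g) z(g_mom) + e`,
#' with `gbar` the sibship mean of the true genetic value and the residual
#' variance solved so total phenotypic variance hits `vp_target` (a negative
#' implied residual variance is an error reporting the variance budget).
#' Age, sex and survey year are generated as nuisance covariates with zero
#' structural effect.
#'
#' @param ped a [pedigree()].
#' @param g named vector of true genetic values (years scale) for everyone.
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @param parent_edu optional named vector of pre-assigned parent educations.
#' @return A phenotype data.frame for all persons in `ped`.
#' @export
simulate_phenotypes <- function(ped, g, config, seed = 1L, parent_edu = NULL) {
  cfg <- config
  par <- ped[ped$generation == "parent", , drop = FALSE]
  off <- ped[ped$generation == "offspring", , drop = FALSE]
  gp <- g[par$person_id]; go <- g[off$person_id]
  seeds <- vapply(c("parent_e", "child_e", "nuisance"),
                  function(s) stage_seed(seed, s), integer(1))
  if (is.null(parent_edu)) {
    ve_par <- cfg$vp_target - stats::var(gp)
    if (is.na(ve_par)) ve_par <- cfg$vp_target
    if (ve_par < 0) {
      stop_poly("negative parental residual variance: var(g)=%.3f > vp=%.3f",
                stats::var(gp), cfg$vp_target)
    }
    e_par <- with_seed(seeds[["parent_e"]], rnorm(nrow(par)))
    # realized-moment control: residuals exactly orthogonal to g with exact
    # variance, so the founder heritability is h2_true by construction
    e_par <- orthogonalize_residual(e_par, cbind(gp), ve_par)
    parent_edu <- cfg$mu_edu_parent + gp + e_par
    names(parent_edu) <- par$person_id
  }
  # offspring systematic part
  zg <- if (stats::sd(go) > 0) zscale(go) else rep(0, length(go))
  gbar <- ave(go, off$family_id)
  zgbar <- if (stats::sd(gbar) > 0) zscale(gbar) else rep(0, length(gbar))
  gm <- g[off$mother_id]
  mothers <- unique(off$mother_id)
  gmu <- mean(g[mothers]); gms <- stats::sd(g[mothers])
  zgm <- if (is.finite(gms) && gms > 0) (gm - gmu) / gms else rep(0, length(gm))
  sys <- cfg$b_mother * parent_edu[off$mother_id] +
    cfg$b_father * parent_edu[off$father_id] +
    cfg$gamma_between * zgbar +
    cfg$gamma_within * (zg - zgbar) +
    cfg$theta_gxg * zg * zgm
  ve_off <- cfg$vp_target - stats::var(sys)
  if (ve_off < 0) {
    stop_poly(paste0("negative offspring residual variance: systematic variance ",
                     "%.3f exceeds vp_target %.3f (parental path %.3f, genetic %.3f)"),
              stats::var(sys), cfg$vp_target,
              stats::var(cfg$b_mother * parent_edu[off$mother_id] +
                           cfg$b_father * parent_edu[off$father_id]),
              stats::var(cfg$gamma_between * zgbar + cfg$gamma_within * (zg - zgbar)))
  }
  e_off <- with_seed(seeds[["child_e"]], rnorm(nrow(off)))
  e_off <- orthogonalize_residual(
    e_off, cbind(parent_edu[off$mother_id], parent_edu[off$father_id],
                 zg, zgbar, zg * zgm), ve_off)
  child_edu <- cfg$mu_edu_offspring + (sys - mean(sys)) + e_off
  nuis <- with_seed(seeds[["nuisance"]], {
    list(age_o = round(rnorm(nrow(off), 40, 7.7), 1),
         age_p = round(rnorm(nrow(par), 68, 10.5), 1),
         yr = sample(2002:2012, nrow(off) + nrow(par), replace = TRUE))
  })
  data.frame(
    person_id = c(par$person_id, off$person_id),
    edu_years = unname(c(parent_edu[par$person_id], child_edu)),
    age = c(nuis$age_p, nuis$age_o),
    sex = c(par$sex, off$sex),
    survey_year = nuis$yr,
    stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## cohort orchestration

# One full simulation pass with fixed calibration parameters.
# params: list(index = list(a,b,s), tau2 = numeric or NULL)
sim_core <- function(cfg, params, seed) {
  n <- cfg$n_families
  m <- cfg$m_snps
  founders <- draw_founder_genotypes(2L * n, m, cfg$freq_range,
                                     seed = stage_seed(seed, "founders"))
  panel <- founders$panel
  beta_tab <- make_true_effects(panel, cfg$h2_true, cfg$vp_target,
                                seed = stage_seed(seed, "effects"))
  noisy_tab <- make_noisy_weights(beta_tab, panel, cfg$h2_true,
                                  max(cfg$r2_score_target, 1e-12),
                                  seed = stage_seed(seed, "weights"),
                                  tau2 = params$tau2)
  beta <- beta_tab$weight
  wn <- noisy_tab$weight
  X <- founders$dosage
  sex <- rep(c("F", "M"), n)
  fam <- seq_len(2L * n)                     # founders: everyone own family
  h2 <- cfg$h2_true
  # burn-in: index mating, two children per couple, constant population size
  for (t in seq_len(cfg$n_burnin)) {
    gg <- as.vector(X %*% beta)
    sc <- as.vector(X %*% wn)
    zg <- if (stats::sd(gg) > 0) zscale(gg) else rep(0, length(gg))
    eduz <- sqrt(h2) * zg + sqrt(1 - h2) *
      with_seed(stage_seed(seed, paste0("burn_e", t)), rnorm(2L * n))
    pr <- pair_by_index(eduz, sc, sex, fam, params$index,
                        stage_seed(seed, paste0("burn_i", t)))
    Xm <- X[rep(pr$mothers, each = 2L), , drop = FALSE]
    Xf <- X[rep(pr$fathers, each = 2L), , drop = FALSE]
    X <- with_seed(stage_seed(seed, paste0("burn_t", t)), {
      matrix(rbinom(length(Xm), 1L, as.vector(Xm) / 2) +
               rbinom(length(Xm), 1L, as.vector(Xf) / 2),
             nrow(Xm), ncol(Xm))
    })
    sex <- rep(c("F", "M"), n)
    fam <- rep(seq_len(n), each = 2L)
  }
  # recorded parent generation: rescale effects so var(g) = h2 * vp exactly
  g0 <- as.vector(X %*% beta)
  if (h2 > 0 && stats::var(g0) > 0) {
    cscale <- sqrt(h2 * cfg$vp_target / stats::var(g0))
    beta <- beta * cscale
    wn <- wn * cscale
  }
  g_par <- as.vector(X %*% beta)
  sc_par <- as.vector(X %*% wn)
  zgp <- if (stats::sd(g_par) > 0) zscale(g_par) else rep(0, length(g_par))
  eps_par <- orthogonalize_residual(
    with_seed(stage_seed(seed, "parent_eduz"), rnorm(2L * n)),
    cbind(zgp), 1 - h2)
  eduz <- sqrt(h2) * zgp + eps_par
  pr <- pair_by_index(eduz, sc_par, sex, fam, params$index,
                      stage_seed(seed, "mating"))
  parent_ids <- sprintf("P%06d", seq_len(2L * n))
  parents <- genotype_matrix(X, panel = panel, sample_id = parent_ids)
  mother_ids <- parent_ids[pr$mothers]
  father_ids <- parent_ids[pr$fathers]
  fam_ids <- sprintf("FAM%05d", seq_len(n))
  parent_edu <- cfg$mu_edu_parent + sqrt(cfg$vp_target) * eduz
  names(parent_edu) <- parent_ids

  k <- if (length(cfg$sib_sizes) == 1L) rep(cfg$sib_sizes, n) else
    with_seed(stage_seed(seed, "sibs"),
              sample(cfg$sib_sizes, n, replace = TRUE, prob = cfg$sib_probs))
  off_fam <- rep(seq_len(n), k)
  n_off <- sum(k)
  off_ids <- sprintf("C%06d", seq_len(n_off))
  off_sex <- with_seed(stage_seed(seed, "offsex"),
                       sample(c("F", "M"), n_off, replace = TRUE))
  ped <- pedigree(data.frame(
    family_id = c(rep(fam_ids, 2L), fam_ids[off_fam]),
    person_id = c(mother_ids, father_ids, off_ids),
    father_id = c(rep(NA_character_, 2L * n), father_ids[off_fam]),
    mother_id = c(rep(NA_character_, 2L * n), mother_ids[off_fam]),
    sex = c(rep("F", n), rep("M", n), off_sex),
    generation = c(rep("parent", 2L * n), rep("offspring", n_off)),
    stringsAsFactors = FALSE))
  offspring <- transmit_genotypes(parents, ped, seed = stage_seed(seed, "transmit"))
  g_all <- c(stats::setNames(g_par, parent_ids),
             stats::setNames(as.vector(offspring$dosage %*% beta), off_ids))
  phen <- simulate_phenotypes(ped, g_all, cfg, seed = stage_seed(seed, "pheno"),
                              parent_edu = parent_edu)

  all_geno <- genotype_matrix(rbind(parents$dosage, offspring$dosage),
                              panel = panel,
                              sample_id = c(parent_ids, off_ids))
  beta_tab$weight <- beta
  noisy_out <- noisy_tab; noisy_out$weight <- wn
  scores <- compute_score(all_geno, noisy_out)
  # Exact score calibration on the realized cohort. The measured score is
  # g + noise, where the noise mixes the field that took part in mating
  # (eta1, high spousal correlation) with a fresh field eta2 (low spousal
  # correlation): noise = q (sqrt(l) X eta1 + sqrt(1-l) X eta2). The mix l
  # pins the spousal score correlation and the scale q pins the offspring
  # education-on-score R2; both are solved per run, so these two calibration
  # targets hold exactly while genotypes and phenotypes are untouched.
  g_vec <- g_all[scores$person_id]
  v1 <- scores$raw_score - g_vec
  premix_r_sp <- {
    s_tmp <- stats::setNames(g_vec + v1, scores$person_id)
    stats::cor(s_tmp[mother_ids], s_tmp[father_ids])
  }
  if (isTRUE(cfg$calibrate_score %||% TRUE) &&
      cfg$h2_true > 0 && cfg$r2_score_target > 0 && stats::sd(v1) > 0) {
    eta2 <- with_seed(stage_seed(seed, "weights2"),
                      rnorm(m, 0, sqrt(attr(noisy_tab, "tau2"))))
    v2 <- as.vector(all_geno$dosage %*% eta2)
    off_sel <- scores$person_id %in% off_ids
    edu_off <- stats::setNames(phen$edu_years, phen$person_id)[
      scores$person_id[off_sel]]
    mo_i <- match(mother_ids, scores$person_id)
    fa_i <- match(father_ids, scores$person_id)
    uo <- g_vec[off_sel]; ve_edu <- stats::var(edu_off)
    a0 <- stats::cov(uo, edu_off)
    solve_q <- function(vmix) {
      vo <- vmix[off_sel]
      a1 <- stats::cov(vo, edu_off)
      vu <- stats::var(uo); vv <- stats::var(vo); cuv <- stats::cov(uo, vo)
      fq <- function(q) (a0 + q * a1)^2 /
        ((vu + 2 * q * cuv + q^2 * vv) * ve_edu) - cfg$r2_score_target
      if (fq(0) <= 0) 0 else if (fq(50) > 0) 50 else
        stats::uniroot(fq, c(0, 50), tol = 1e-10)$root
    }
    r_sp_of <- function(l) {
      vmix <- sqrt(l) * v1 + sqrt(1 - l) * v2
      q <- solve_q(vmix)
      s <- g_vec + q * vmix
      list(r = stats::cor(s[mo_i], s[fa_i]), q = q, l = l, vmix = vmix)
    }
    target_rs <- cfg$r_spouse_grs
    sol <- r_sp_of(1)
    if (cfg$mate_on_score && target_rs > 0 && sol$r > target_rs) {
      lo <- r_sp_of(0)
      sol <- if (lo$r >= target_rs) lo else {
        lstar <- stats::uniroot(function(l) r_sp_of(l)$r - target_rs,
                                c(0, 1), tol = 1e-8)$root
        r_sp_of(lstar)
      }
    }
    scores$raw_score <- g_vec + sol$q * sol$vmix
    eta1 <- wn - beta
    noisy_out$weight <- beta +
      sol$q * (sqrt(sol$l) * eta1 + sqrt(1 - sol$l) * eta2)
    attr(noisy_out, "tau2") <- attr(noisy_tab, "tau2") * sol$q^2
    attr(noisy_out, "q_rescale") <- sol$q
    attr(noisy_out, "l_mix") <- sol$l
  }
  is_par <- scores$person_id %in% parent_ids
  sp <- standardize_score(scores[is_par, ], reference_ids = parent_ids)
  so <- standardize_score(scores[!is_par, ], reference_ids = off_ids)
  scores <- rbind(sp, so)

  bundle <- structure(list(
    genotypes = all_geno, pedigree = ped, phenotypes = phen,
    true_effects = beta_tab, noisy_weights = noisy_out,
    g = g_all, scores = scores, config = cfg, seed = seed,
    couples = data.frame(family_id = fam_ids, mother_id = mother_ids,
                         father_id = father_ids, stringsAsFactors = FALSE)),
    class = "cohort_bundle")
  bundle$realized <- realized_moments(bundle)
  bundle$realized$r_spouse_grs_premix <- premix_r_sp
  bundle
}

# Moments used for calibration and reporting.
realized_moments <- function(bundle) {
  phen <- bundle$phenotypes
  cps <- bundle$couples
  edu <- stats::setNames(phen$edu_years, phen$person_id)
  sc <- stats::setNames(bundle$scores$std_score, bundle$scores$person_id)
  raw <- stats::setNames(bundle$scores$raw_score, bundle$scores$person_id)
  off <- bundle$pedigree[bundle$pedigree$generation == "offspring", ]
  g <- bundle$g
  noise_raw <- raw - g[names(raw)]            # score minus true genetic value
  par_ids <- c(cps$mother_id, cps$father_id)
  list(
    r_spouse_edu = cor(edu[cps$mother_id], edu[cps$father_id]),
    r_spouse_grs = cor(sc[cps$mother_id], sc[cps$father_id]),
    rho_es_parent = cor(edu[par_ids], raw[par_ids]),
    r2_score_offspring = cor(sc[off$person_id], edu[off$person_id])^2,
    sib_icc_score = tryCatch(
      intraclass_correlation(sc[off$person_id], off$family_id),
      error = function(e) NA_real_),
    sib_icc_edu = tryCatch(
      intraclass_correlation(edu[off$person_id], off$family_id),
      error = function(e) NA_real_),
    h2_founder = stats::var(g[par_ids]) / stats::var(edu[par_ids]),
    var_g_offspring = stats::var(g[off$person_id]),
    var_edu_offspring = stats::var(edu[off$person_id]),
    cov_g_edu_offspring = stats::cov(g[off$person_id], edu[off$person_id]),
    var_noise_offspring = stats::var(noise_raw[off$person_id]),
    cov_g_noise_offspring = stats::cov(g[off$person_id], noise_raw[off$person_id]),
    cov_noise_edu_offspring = stats::cov(noise_raw[off$person_id], edu[off$person_id]),
    var_g_parent = stats::var(g[par_ids]),
    var_noise_parent = stats::var(noise_raw[par_ids]),
    cov_g_edu_parent = stats::cov(g[par_ids], edu[par_ids]),
    mean_sibs = mean(table(off$family_id)))
}

#' Simulate a full two-generation cohort
#'
#' Orchestrates founder drawing, burn-in assortative mating, couple
#' formation, Mendelian transmission, phenotype generation and scoring. When
#' `config$calibrate` is `TRUE` (default) a pilot simulation first refines
#' the score-noise variance and mating-index loadings so the realized
#' spousal correlations and offspring score R-squared hit their targets;
#' every stage draws from a named RNG stream derived from the master seed,
#' so runs are exactly reproducible.
#'
#' @param config a [sim_config()].
#' @param out_dir optional directory: cohort files are written in the
#'   package's delimited formats plus a `manifest.json` recording config and
#'   seed.
#' @return A `cohort_bundle`: genotypes, pedigree, phenotypes, true and noisy
#'   weight tables, true genetic values `g`, standardized scores, couples,
#'   realized moments, and the calibration parameters used.
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  cfg <- config
  seed <- cfg$seed
  rho0 <- if (cfg$r2_score_target > 0) sqrt(cfg$r2_score_target) else 0
  params <- list(index = calibrate_mating_index(rho0, cfg$r_spouse_edu,
                                                cfg$r_spouse_grs,
                                                cfg$mate_on_score),
                 tau2 = NULL)
  # pilot-based index calibration needs enough couples for the realized
  # spousal correlations to be estimable; below that the closed-form index
  # is used as-is
  if (cfg$calibrate && cfg$h2_true > 0 && cfg$r2_score_target > 0 &&
      cfg$n_families >= 1000L) {
    pcfg <- cfg
    pcfg$n_families <- min(cfg$n_families, cfg$n_pilot)
    # working spousal targets on the correlation scale, nudged multiplicatively
    # each round so burn-in equilibrium drift is absorbed
    eff_re <- cfg$r_spouse_edu
    eff_rs <- min(0.9, 1.3 * cfg$r_spouse_grs)
    params$index <- calibrate_mating_index(rho0, eff_re, eff_rs,
                                           cfg$mate_on_score)
    for (round in seq_len(max(1L, cfg$n_calib_rounds))) {
      pilot <- sim_core(pcfg, params, stage_seed(seed, paste0("pilot", round)))
      mo <- pilot$realized
      ok_re <- cfg$r_spouse_edu == 0 ||
        abs(mo$r_spouse_edu - cfg$r_spouse_edu) < 0.008
      # the matched noise field must overshoot the spousal score target so
      # the per-run mix solve can reach it exactly from above
      aim_rs <- min(0.9, 1.3 * cfg$r_spouse_grs)
      ok_rs <- cfg$r_spouse_grs == 0 || !cfg$mate_on_score ||
        (mo$r_spouse_grs_premix > 1.12 * cfg$r_spouse_grs &&
           mo$r_spouse_grs_premix < 1.5 * cfg$r_spouse_grs)
      if (ok_re && ok_rs) break
      # damped multiplicative step: full correction chases pilot sampling
      # noise and oscillates, 0.6 converges geometrically on the systematic
      # part of the discrepancy
      bump <- function(eff, target, realized) {
        if (target <= 0 || !is.finite(realized) || realized <= 1e-4) return(eff)
        min(0.9, eff * (target / realized)^0.6)
      }
      eff_re <- bump(eff_re, cfg$r_spouse_edu, mo$r_spouse_edu)
      eff_rs <- bump(eff_rs, aim_rs, mo$r_spouse_grs_premix)
      params$index <- calibrate_mating_index(mo$rho_es_parent, eff_re, eff_rs,
                                             cfg$mate_on_score)
    }
  }
  bundle <- sim_core(cfg, params, stage_seed(seed, "main"))
  bundle$seed <- seed
  bundle$calibration <- params
  if (!is.null(out_dir)) write_cohort(bundle, out_dir)
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  off <- sum(x$pedigree$generation == "offspring")
  cat(sprintf("cohort_bundle: %d couples, %d offspring, %d SNPs (seed %d)\n",
              nrow(x$couples), off, ncol(x$genotypes$dosage), x$seed))
  r <- x$realized
  cat(sprintf("  spousal edu r %.3f | spousal score r %.3f | sib score ICC %.3f\n",
              r$r_spouse_edu, r$r_spouse_grs, r$sib_icc_score))
  cat(sprintf("  offspring score R2 %.4f | founder h2 %.3f\n",
              r$r2_score_offspring, r$h2_founder))
  invisible(x)
}

#' Write a cohort bundle to disk in the package's delimited formats
#'
#' @param bundle a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_genotypes(bundle$genotypes, file.path(out_dir, "genotypes.tsv"))
  write_pedigree(bundle$pedigree, file.path(out_dir, "pedigree.tsv"))
  write_phenotypes(bundle$phenotypes, file.path(out_dir, "phenotypes.tsv"))
  write_weights(bundle$true_effects, file.path(out_dir, "weights_true.tsv"))
  write_weights(bundle$noisy_weights, file.path(out_dir, "weights_noisy.tsv"))
  sc <- bundle$scores
  sc$raw_score <- fmt_num(sc$raw_score)
  sc$std_score <- fmt_num(sc$std_score)
  fwrite(sc, file.path(out_dir, "scores.tsv"), sep = "\t", quote = FALSE)
  cfg <- bundle$config
  manifest <- list(config = unclass(cfg), seed = bundle$seed,
                   realized = lapply(bundle$realized, unname))
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Offspring-level analysis table
#'
#' One row per offspring with the columns the regression, decomposition and
#' mediation modules expect: education, nuisance covariates, standardized
#' own/maternal/paternal scores, true genetic values (`zg`, `mother_zg`) and
#' parental educations.
#'
#' @param bundle a [simulate_cohort()] result.
#' @return A data.frame.
#' @export
cohort_analysis_table <- function(bundle) {
  ped <- bundle$pedigree
  off <- ped[ped$generation == "offspring", ]
  phen <- bundle$phenotypes
  edu <- stats::setNames(phen$edu_years, phen$person_id)
  age <- stats::setNames(phen$age, phen$person_id)
  yr <- stats::setNames(phen$survey_year, phen$person_id)
  sc <- stats::setNames(bundle$scores$std_score, bundle$scores$person_id)
  g <- bundle$g
  zof <- zscale(g[off$person_id])
  mothers <- unique(off$mother_id)
  zmo <- stats::setNames(as.vector(scale(g[mothers])), mothers)
  data.frame(
    person_id = off$person_id,
    family_id = off$family_id,
    edu_years = unname(edu[off$person_id]),
    sex_female = as.numeric(off$sex == "F"),
    age = unname(age[off$person_id]),
    survey_year = unname(yr[off$person_id]),
    score_std = unname(sc[off$person_id]),
    zg = zof,
    mother_edu = unname(edu[off$mother_id]),
    father_edu = unname(edu[off$father_id]),
    mother_score_std = unname(sc[off$mother_id]),
    father_score_std = unname(sc[off$father_id]),
    mother_zg = unname(zmo[off$mother_id]),
    stringsAsFactors = FALSE)
}
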