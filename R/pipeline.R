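## One configured, logged, reproducible run: simulate -> score -> GRM ->
## REML -> model suites -> within/between decomposition -> mediation,
## with machine-readable results per stage and a rendered text report.

#' Pipeline configuration
#'
#' @param sim a [sim_config()] describing the cohort (or `NULL` when
#'   `data_dir` points at an existing cohort written by [write_cohort()]).
#' @param data_dir optional directory of cohort files to load instead of
#'   simulating.
#' @param stages named logical toggles: `greml`, `models`, `decompose`,
#'   `mediate`.
#' @param h2_assumed heritability used by mediation when the GREML stage is
#'   disabled.
#' @param grm_cutoff nominal relatedness cutoff (scale-adjusted via
#'   [effective_relatedness_cutoff()]).
#' @param relatedness parent-offspring genetic sharing for mediation.
#' @param seed master seed (overrides `sim$seed`).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), data_dir = NULL,
                       stages = list(greml = TRUE, models = TRUE,
                                     decompose = TRUE, mediate = TRUE),
                       h2_assumed = 0.20, grm_cutoff = 0.025,
                       relatedness = 0.5, seed = NULL) {
  defaults <- list(greml = TRUE, models = TRUE, decompose = TRUE, mediate = TRUE)
  stages <- modifyList(defaults, stages)
  if (!is.null(seed) && !is.null(sim)) sim$seed <- as.integer(seed)
  structure(list(sim = sim, data_dir = data_dir, stages = stages,
                 h2_assumed = h2_assumed, grm_cutoff = grm_cutoff,
                 relatedness = relatedness,
                 seed = as.integer(seed %||% sim$seed)),
            class = "run_config")
}

#' Run the full intergenerational analysis pipeline
#'
#' Every numeric in the rendered report is read back from a stage output
#' file; nothing is computed in the rendering layer. Stage errors abort the
#' run with the stage name, leaving earlier outputs in place.
#'
#' @param config a [run_config()].
#' @param out output directory.
#' @return Invisibly, a list with all stage results.
#' @export
run_pipeline <- function(config, out) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_poly("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  bundle <- stage("simulate", {
    if (!is.null(config$data_dir)) {
      stop_poly("loading pre-simulated cohorts is supported via load_cohort(); run_pipeline currently simulates")
    } else {
      simulate_cohort(config$sim, out_dir = file.path(out, "cohort"))
    }
  })
  adf <- cohort_analysis_table(bundle)
  res$correlations <- stage("correlations", {
    r <- bundle$realized
    cors <- list(spouse_edu = r$r_spouse_edu, spouse_score = r$r_spouse_grs,
                 sib_icc_score = r$sib_icc_score, sib_icc_edu = r$sib_icc_edu,
                 score_r2_offspring = r$r2_score_offspring)
    write_json(cors, file.path(out, "correlations.json"), auto_unbox = TRUE,
               digits = NA)
    cors
  })

  h2_use <- config$h2_assumed
  if (isTRUE(config$stages$greml)) {
    res$reml <- stage("greml", {
      grm <- compute_grm(bundle$genotypes)
      cutoff <- effective_relatedness_cutoff(config$grm_cutoff,
                                             grm$n_snps)
      fl <- filter_relatedness(grm, cutoff)
      phen <- bundle$phenotypes
      keep <- match(fl$grm$sample_id, phen$person_id)
      y <- phen$edu_years[keep]
      X <- cbind(1, phen$age[keep], as.numeric(phen$sex[keep] == "F"))
      colnames(X) <- c("(Intercept)", "age", "sex_female")
      fit <- reml_fit(y, X, fl$grm)
      out_j <- list(vg = fit$vg, ve = fit$ve, vp = fit$vp, h2 = fit$h2,
                    se_h2 = fit$se_h2, logL = fit$logL, logL0 = fit$logL0,
                    lrt = fit$lrt, p_value = fit$p_value, n = fit$n,
                    cutoff_used = cutoff, n_dropped = length(fl$dropped_ids),
                    converged = fit$converged)
      write_json(out_j, file.path(out, "reml.json"), auto_unbox = TRUE, digits = NA)
      fit
    })
    h2_use <- res$reml$h2
  }

  if (isTRUE(config$stages$models)) {
    res$models <- stage("models", {
      suites <- list(table4 = run_model_suite(adf, "table4"),
                     table5 = run_model_suite(adf, "table5"),
                     table7 = run_model_suite(adf, "table7"))
      js <- lapply(suites, function(su) lapply(su, function(f) {
        list(coefficients = as.list(f$coefficients), se = as.list(f$se),
             r2 = f$r2, r2_score_alone = f$r2_score_alone,
             n_obs = f$n_obs, n_families = f$n_families)
      }))
      write_json(js, file.path(out, "models.json"), auto_unbox = TRUE, digits = NA)
      suites
    })
  }

  if (isTRUE(config$stages$decompose)) {
    res$decomp <- stage("decompose", {
      dc <- within_between_decompose(adf)
      nm <- "score_std"
      js <- list(within = list(slope = dc$within$coefficients[[nm]],
                               se = dc$within$se[[nm]],
                               r2_score_alone = dc$within$r2_score_alone),
                 between = list(slope = dc$between$coefficients[[nm]],
                                se = dc$between$se[[nm]],
                                r2_score_alone = dc$between$r2_score_alone),
                 total = list(slope = dc$total$coefficients[[nm]],
                              se = dc$total$se[[nm]],
                              r2_score_alone = dc$total$r2_score_alone),
                 share_within = dc$share_within,
                 n_families = dc$n_families,
                 n_sibling_pairs = dc$n_sibling_pairs)
      write_json(js, file.path(out, "decomp.json"), auto_unbox = TRUE, digits = NA)
      dc
    })
  }

  if (isTRUE(config$stages$mediate)) {
    res$mediation <- stage("mediate", {
      md <- end_to_end_mediation(adf, h2 = h2_use,
                                 relatedness = config$relatedness)
      js <- list(term = md$term, beta_raw = md$beta_raw, beta_adj = md$beta_adj,
                 attenuation_pct = md$attenuation_pct, r2_score = md$r2_score,
                 h2 = md$h2, relatedness = md$relatedness,
                 scale_factor = md$scale_factor,
                 combined_multiplier = md$combined_multiplier,
                 genetic_share_pct = md$genetic_share_pct)
      write_json(js, file.path(out, "mediation.json"), auto_unbox = TRUE,
                 digits = NA)
      md
    })
  }

  manifest <- list(seed = config$seed,
                   stages = config$stages,
                   grm_cutoff = config$grm_cutoff,
                   h2_assumed = config$h2_assumed,
                   relatedness = config$relatedness,
                   sim = unclass(config$sim),
                   package_version = as.character(utils::packageVersion("polytrans")))
  cfg_path <- file.path(out, "manifest.json")
  write_json(manifest, cfg_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- c(
    "== intergenerational transmission pipeline report ==",
    sprintf("seed %d; %d couples", config$seed, config$sim$n_families),
    "",
    "-- spousal / sibling correlations (correlations.json) --",
    sprintf("  spousal education r: %.3f", res$correlations$spouse_edu),
    sprintf("  spousal score r:     %.3f", res$correlations$spouse_score),
    sprintf("  sibling score ICC:   %.3f", res$correlations$sib_icc_score),
    sprintf("  sibling edu ICC:     %.3f", res$correlations$sib_icc_edu),
    sprintf("  offspring score R2:  %.4f", res$correlations$score_r2_offspring))
  if (!is.null(res$reml)) {
    report <- c(report, "",
      "-- GREML (reml.json) --",
      sprintf("  V(G) %.3f  V(e) %.3f  V(P) %.3f  h2 %.3f (%.3f)",
              res$reml$vg, res$reml$ve, res$reml$vp, res$reml$h2, res$reml$se_h2),
      sprintf("  LRT %.2f  boundary p %.4g", res$reml$lrt, res$reml$p_value))
  }
  if (!is.null(res$models)) {
    report <- c(report, "", "-- model suites (models.json) --",
                vapply(names(res$models), function(nm)
                  paste0("[", nm, "]\n", format_model_table(res$models[[nm]])),
                  character(1)))
  }
  if (!is.null(res$decomp)) {
    report <- c(report, "", "-- within/between decomposition (decomp.json) --",
      sprintf("  within %.3f (%.3f) | between %.3f (%.3f) | total %.3f (%.3f)",
              res$decomp$within$coefficients[["score_std"]],
              res$decomp$within$se[["score_std"]],
              res$decomp$between$coefficients[["score_std"]],
              res$decomp$between$se[["score_std"]],
              res$decomp$total$coefficients[["score_std"]],
              res$decomp$total$se[["score_std"]]))
  }
  if (!is.null(res$mediation)) {
    m <- res$mediation
    report <- c(report, "", "-- mediation (mediation.json) --",
      sprintf("  %s %.4f -> %.4f | attenuation %.2f%% | share %.2f%%",
              m$term, m$beta_raw, m$beta_adj, m$attenuation_pct,
              m$genetic_share_pct))
  }
  writeLines(report, file.path(out, "report.txt"))
  res$bundle <- bundle
  invisible(res)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `score`, `grm`, `reml`, `models`, `decompose`,
#' `mediate`, `run`. Invoke via the `inst/cli/polytrans` script or directly:
#' `Rscript -e 'polytrans::cli_main(commandArgs(TRUE))'`.
#'
#' @param argv character vector of command-line arguments.
#' @return Exit code 0 on success (invisibly); stages signal errors.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv)) {
    cat("usage: polytrans <simulate|score|grm|reml|models|decompose|mediate|run> [options]\n")
    return(invisible(1L))
  }
  cmd <- argv[1]
  rest <- argv[-1]
  getopt <- function(flag, default = NULL) {
    i <- which(rest == flag)
    if (length(i) && i < length(rest)) rest[i + 1] else default
  }
  seed <- as.integer(getopt("--seed", "42"))
  out <- getopt("--out", "polytrans_out")
  switch(cmd,
    simulate = {
      cfgf <- getopt("--config")
      cfg <- if (!is.null(cfgf)) do.call(sim_config, read_json(cfgf, simplifyVector = TRUE))
        else sim_config(seed = seed)
      cfg$seed <- seed
      simulate_cohort(cfg, out_dir = out)
      cat(sprintf("cohort written to %s\n", out))
    },
    score = {
      geno <- read_genotypes(getopt("--geno"))
      w <- read_weights(getopt("--weights"))
      sc <- standardize_score(compute_score(geno, w))
      sc$raw_score <- fmt_num(sc$raw_score); sc$std_score <- fmt_num(sc$std_score)
      fwrite(sc, out, sep = "\t", quote = FALSE)
      cat(sprintf("scores written to %s\n", out))
    },
    grm = {
      geno <- read_genotypes(getopt("--geno"))
      write_grm_gcta(compute_grm(geno), out)
      cat(sprintf("GRM written to %s.grm / %s.grm.id\n", out, out))
    },
    reml = {
      grm <- read_grm_gcta(getopt("--grm"))
      phen <- read_phenotypes(getopt("--pheno"))
      cutoff <- effective_relatedness_cutoff(
        as.numeric(getopt("--cutoff", "0.025")), grm$n_snps)
      fl <- filter_relatedness(grm, cutoff)
      idx <- match(fl$grm$sample_id, phen$person_id)
      covar <- strsplit(getopt("--covar", "age,sex"), ",")[[1]]
      X <- matrix(1, length(idx), 1, dimnames = list(NULL, "(Intercept)"))
      if ("age" %in% covar) X <- cbind(X, age = phen$age[idx])
      if ("sex" %in% covar) X <- cbind(X, sex_female = as.numeric(phen$sex[idx] == "F"))
      fit <- reml_fit(phen$edu_years[idx], X, fl$grm)
      write_json(list(vg = fit$vg, ve = fit$ve, vp = fit$vp, h2 = fit$h2,
                      se_h2 = fit$se_h2, logL = fit$logL, logL0 = fit$logL0,
                      lrt = fit$lrt, p_value = fit$p_value, n = fit$n),
                 out, auto_unbox = TRUE, digits = NA)
      cat(sprintf("REML results written to %s\n", out))
    },
    run = {
      cfgf <- getopt("--config")
      sim <- if (!is.null(cfgf)) do.call(sim_config, read_json(cfgf, simplifyVector = TRUE))
        else sim_config(seed = seed)
      run_pipeline(run_config(sim = sim, seed = seed), out)
      cat(sprintf("pipeline outputs written to %s\n", out))
    },
    models = ,
    decompose = ,
    mediate = {
      dd <- getopt("--data")
      coh <- load_cohort(file.path(dd, "genotypes.tsv"),
                         file.path(dd, "pedigree.tsv"),
                         file.path(dd, "phenotypes.tsv"))
      w <- read_weights(file.path(dd, "weights_noisy.tsv"))
      adf <- analysis_table_from_files(coh, w)
      if (cmd == "models") {
        suite <- getopt("--suite", "table4")
        fits <- run_model_suite(adf, suite)
        cat(format_model_table(fits))
        js <- lapply(fits, function(f) list(coefficients = as.list(f$coefficients),
                                            se = as.list(f$se), r2 = f$r2))
        write_json(js, out, auto_unbox = TRUE, digits = NA)
      } else if (cmd == "decompose") {
        dc <- within_between_decompose(adf)
        print(dc)
        write_json(list(within = dc$within$coefficients[["score_std"]],
                        between = dc$between$coefficients[["score_std"]],
                        total = dc$total$coefficients[["score_std"]]),
                   out, auto_unbox = TRUE, digits = NA)
      } else {
        md <- end_to_end_mediation(adf, h2 = as.numeric(getopt("--h2", "0.20")),
                                   relatedness = as.numeric(getopt("--relatedness", "0.5")))
        print(md)
        write_json(list(attenuation_pct = md$attenuation_pct,
                        genetic_share_pct = md$genetic_share_pct),
                   out, auto_unbox = TRUE, digits = NA)
      }
      cat(sprintf("results written to %s\n", out))
    },
    stop_poly("unknown subcommand '%s'", cmd))
  invisible(0L)
}

#' Build an analysis table from cohort files on disk
#'
#' Mirrors [cohort_analysis_table()] for cohorts loaded with [load_cohort()]:
#' scores are computed from the supplied weight table and standardized within
#' generation.
#'
#' @param cohort a [load_cohort()] result.
#' @param weights a weight table.
#' @return Offspring-level data.frame.
#' @export
analysis_table_from_files <- function(cohort, weights) {
  sc <- compute_score(cohort$genotypes, weights)
  ped <- cohort$pedigree
  par_ids <- ped$person_id[ped$generation == "parent"]
  off_ids <- ped$person_id[ped$generation == "offspring"]
  sp <- standardize_score(sc[sc$person_id %in% par_ids, ], par_ids)
  so <- standardize_score(sc[sc$person_id %in% off_ids, ], off_ids)
  sc <- rbind(sp, so)
  scv <- stats::setNames(sc$std_score, sc$person_id)
  phen <- cohort$phenotypes
  edu <- stats::setNames(phen$edu_years, phen$person_id)
  age <- stats::setNames(phen$age, phen$person_id)
  yr <- if ("survey_year" %in% names(phen))
    stats::setNames(phen$survey_year, phen$person_id) else NULL
  off <- ped[ped$generation == "offspring", ]
  data.frame(
    person_id = off$person_id,
    family_id = off$family_id,
    edu_years = unname(edu[off$person_id]),
    sex_female = as.numeric(off$sex == "F"),
    age = unname(age[off$person_id]),
    survey_year = if (is.null(yr)) NA else unname(yr[off$person_id]),
    score_std = unname(scv[off$person_id]),
    mother_edu = unname(edu[off$mother_id]),
    father_edu = unname(edu[off$father_id]),
    mother_score_std = unname(scv[off$mother_id]),
    father_score_std = unname(scv[off$father_id]),
    stringsAsFactors = FALSE)
}
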