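## Single-component GREML: restricted maximum likelihood for
##   y = X b + g + e,  g ~ N(0, A vg),  e ~ N(0, I ve),
## fitted by EM warm start followed by average-information (AI) updates.
## The GRM is eigendecomposed once, so every likelihood evaluation is O(N K).

#' Boundary p-value for a single variance component LRT
#'
#' The null value vg = 0 lies on the boundary of the parameter space, so the
#' LRT statistic is asymptotically a 50:50 mixture of a point mass at zero
#' and chi-square(1); the p-value is `0.5 * Pr(chisq_1 >= lrt)`.
#'
#' @param lrt non-negative likelihood-ratio statistic (values above -1e-6 are
#'   clamped to zero).
#' @return The mixture p-value.
#' @export
lrt_boundary_pvalue <- function(lrt) {
  if (!is.numeric(lrt) || length(lrt) != 1L) stop_poly("lrt must be a single number")
  if (lrt < -1e-6) stop_poly("negative LRT statistic: %g", lrt)
  lrt <- max(0, lrt)
  0.5 * pchisq(lrt, df = 1, lower.tail = FALSE)
}

# restricted log-likelihood and workhorse quantities in the rotated basis
# (yt, Xt are U'y, U'X for A = U diag(d) U')
reml_eval <- function(vg, ve, d, yt, Xt) {
  lam <- pmax(vg * d + ve, 1e-12)
  W <- Xt / lam
  XtVX <- crossprod(Xt, W)
  ch <- chol(XtVX)
  beta <- backsolve(ch, forwardsolve(t(ch), crossprod(W, yt)))
  r <- yt / lam - W %*% beta            # P y in rotated coordinates
  yPy <- sum(yt * r)
  ldV <- sum(log(lam))
  ldX <- 2 * sum(log(diag(ch)))
  n <- length(yt); k <- ncol(Xt)
  ll <- -0.5 * ((n - k) * log(2 * pi) + ldV + ldX + yPy)
  list(ll = ll, lam = lam, W = W, XtVX = XtVX, r = as.vector(r), yPy = yPy,
       beta = as.vector(beta))
}

# apply the projection P to a vector, given reml_eval output
reml_Pv <- function(ev, v) {
  v / ev$lam - ev$W %*% solve(ev$XtVX, crossprod(ev$W, v))
}

reml_gradients <- function(ev, d, Xt) {
  lam <- ev$lam
  iXtVX <- solve(ev$XtVX)
  trPD <- sum(d / lam) - sum(iXtVX * crossprod(Xt, Xt * (d / lam^2)))
  trPI <- sum(1 / lam) - sum(iXtVX * crossprod(Xt, Xt * (1 / lam^2)))
  yPDPy <- sum(d * ev$r^2)
  yPIPy <- sum(ev$r^2)
  list(g = -0.5 * c(trPD - yPDPy, trPI - yPIPy),
       trPD = trPD, trPI = trPI, yPDPy = yPDPy, yPIPy = yPIPy)
}

#' Fit a single-component GREML model
#'
#' Maximizes the restricted likelihood of `y = X b + g + e` with
#' `g ~ (0, A vg)` and `e ~ (0, I ve)`. Three EM-REML warm-start iterations
#' are followed by average-information updates with step-halving whenever the
#' restricted log-likelihood would decrease; `vg` is constrained non-negative
#' (active-set clamp at the boundary). Convergence is declared when the
#' log-likelihood changes by less than `tol`. The null model (`vg = 0`) is
#' profiled in closed form; the likelihood-ratio statistic and boundary
#' p-value (see [lrt_boundary_pvalue()]) are attached.
#'
#' Standard errors come from the inverse average-information matrix, with the
#' delta method for the heritability ratio `h2 = vg / (vg + ve)`.
#'
#' @param y numeric phenotype vector, ordered as `grm$sample_id`.
#' @param X fixed-effect design matrix including an intercept; default
#'   intercept only. Typical covariates: age, sex.
#' @param grm a (filtered) [compute_grm()] result.
#' @param max_iter maximum iterations (default 100).
#' @param tol convergence tolerance on the log-likelihood (default 1e-8).
#' @param n_em number of EM warm-start iterations (default 3).
#' @return Object of class `reml_result`: `vg`, `ve`, `vp`, `h2`, `se_vg`,
#'   `se_ve`, `se_h2`, `logL`, `logL0`, `lrt`, `p_value`, `n_iterations`,
#'   `converged`, `boundary`, `n`, `beta`.
#' @export
reml_fit <- function(y, X = NULL, grm, max_iter = 100L, tol = 1e-8,
                     n_em = 3L) {
  A <- grm$A
  n <- length(y)
  if (n != nrow(A)) stop_poly("length(y) (%d) != GRM dimension (%d)", n, nrow(A))
  if (n < 30) warning("reml_fit: fewer than 30 samples; estimates will be unstable",
                      call. = FALSE)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  k <- ncol(X)
  if (qr(X)$rank < k) stop_poly("fixed-effect design X is rank deficient")

  eg <- eigen(A, symmetric = TRUE)
  d <- eg$values
  yt <- crossprod(eg$vectors, y)[, 1]
  Xt <- crossprod(eg$vectors, X)

  vp <- stats::var(y)
  vg <- ve <- vp / 2
  ev <- reml_eval(vg, ve, d, yt, Xt)
  ll <- ev$ll
  converged <- FALSE
  it <- 0L
  boundary <- FALSE
  AI <- NULL
  while (it < max_iter) {
    it <- it + 1L
    gr <- reml_gradients(ev, d, Xt)
    if (it <= n_em) {
      vg_new <- vg + vg^2 * (gr$yPDPy - gr$trPD) / n
      ve_new <- ve + ve^2 * (gr$yPIPy - gr$trPI) / n
    } else {
      u1 <- d * ev$r
      u2 <- ev$r
      P1 <- reml_Pv(ev, u1); P2 <- reml_Pv(ev, u2)
      AI <- 0.5 * matrix(c(sum(u1 * P1), sum(u1 * P2),
                           sum(u1 * P2), sum(u2 * P2)), 2, 2)
      step <- tryCatch(solve(AI, gr$g), error = function(e) gr$g / max(diag(AI), 1))
      vg_new <- vg + step[1]
      ve_new <- ve + step[2]
      # step halving against likelihood decreases / infeasible points
      half <- 0L
      repeat {
        vg_try <- max(vg_new, 0)
        ve_try <- max(ve_new, 1e-8 * vp)
        ev_try <- reml_eval(vg_try, ve_try, d, yt, Xt)
        if (ev_try$ll >= ll - 1e-10 || half >= 12L) break
        half <- half + 1L
        vg_new <- vg + (vg_new - vg) / 2
        ve_new <- ve + (ve_new - ve) / 2
      }
    }
    vg_new <- max(vg_new, 0)
    ve_new <- max(ve_new, 1e-8 * vp)
    ev_new <- reml_eval(vg_new, ve_new, d, yt, Xt)
    delta_ll <- ev_new$ll - ll
    vg <- vg_new; ve <- ve_new; ev <- ev_new
    if (ev_new$ll >= ll || it > n_em) ll <- ev_new$ll
    if (it > n_em && abs(delta_ll) < tol) {
      converged <- TRUE
      break
    }
  }
  boundary <- vg <= 1e-8 * vp
  if (!converged) {
    warning("reml_fit did not converge; result flagged", call. = FALSE)
  }

  # AI matrix at the optimum for standard errors
  gr <- reml_gradients(ev, d, Xt)
  u1 <- d * ev$r; u2 <- ev$r
  P1 <- reml_Pv(ev, u1); P2 <- reml_Pv(ev, u2)
  AI <- 0.5 * matrix(c(sum(u1 * P1), sum(u1 * P2),
                       sum(u1 * P2), sum(u2 * P2)), 2, 2)
  Vc <- tryCatch(solve(AI), error = function(e) matrix(NA_real_, 2, 2))
  vptot <- vg + ve
  h2 <- vg / vptot
  dh <- c(ve, -vg) / vptot^2
  se_h2 <- sqrt(max(0, t(dh) %*% Vc %*% dh))

  # null model: vg = 0, ve profiled in closed form (rotation is orthogonal)
  fit0 <- lm.fit(Xt, yt)
  rss0 <- sum(fit0$residuals^2)
  ve0 <- rss0 / (n - k)
  ldX0 <- determinant(crossprod(Xt), logarithm = TRUE)$modulus[1]
  ll0 <- -0.5 * ((n - k) * log(2 * pi) + n * log(ve0) +
                   (ldX0 - k * log(ve0)) + rss0 / ve0)
  lrt <- max(0, 2 * (ev$ll - ll0))
  structure(list(vg = vg, ve = ve, vp = vptot, h2 = h2,
                 se_vg = sqrt(max(0, Vc[1, 1])), se_ve = sqrt(max(0, Vc[2, 2])),
                 se_h2 = as.numeric(se_h2),
                 logL = ev$ll, logL0 = ll0, lrt = lrt,
                 p_value = lrt_boundary_pvalue(lrt),
                 n_iterations = it, converged = converged,
                 boundary = boundary, n = n, beta = ev$beta),
            class = "reml_result")
}

#' @export
print.reml_result <- function(x, ...) {
  cat("GREML variance-component estimates\n")
  cat(sprintf("  V(G): %8.3f (%.3f)\n", x$vg, x$se_vg))
  cat(sprintf("  V(e): %8.3f (%.3f)\n", x$ve, x$se_ve))
  cat(sprintf("  V(P): %8.3f\n", x$vp))
  cat(sprintf("  V(G)/V(P): %.3f (%.3f)\n", x$h2, x$se_h2))
  cat(sprintf("  logL %.2f  logL0 %.2f  LRT %.2f  p %.4g (boundary mixture)\n",
              x$logL, x$logL0, x$lrt, x$p_value))
  cat(sprintf("  n = %d, %d iterations, converged: %s%s\n", x$n, x$n_iterations,
              x$converged, if (x$boundary) " (vg at boundary)" else ""))
  invisible(x)
}

#' Simulate an unrelated GREML cohort with stated variance components
#'
#' Draws founders under Hardy-Weinberg at `m` unlinked SNPs, assigns i.i.d.
#' normal per-SNP effects scaled so the additive genic variance equals `vg`,
#' and adds `N(0, ve)` residuals: the textbook generating model for
#' single-component GREML.
#'
#' @param n samples; @param m SNPs; @param vg genetic variance; @param ve
#'   residual variance; @param freq_range allele-frequency interval;
#'   @param seed RNG seed.
#' @return List with `genotypes`, `y`, `g`, `effects`.
#' @export
simulate_greml_cohort <- function(n, m, vg, ve, freq_range = c(0.05, 0.95),
                                  seed = 1L) {
  vp <- vg + ve
  geno <- draw_founder_genotypes(n, m, freq_range, seed = stage_seed(seed, "geno"))
  eff <- make_true_effects(geno$panel, h2_true = vg / vp, vp_target = vp,
                           seed = stage_seed(seed, "effects"))
  g <- as.vector(geno$dosage %*% eff$weight)
  e <- with_seed(stage_seed(seed, "resid"), rnorm(n, 0, sqrt(ve)))
  list(genotypes = geno, y = g + e, g = g, effects = eff)
}
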