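# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (double loops, dense algebra) so they share no code path
# with the implementation they check.

# GRM by direct per-element evaluation of the estimator formula
oracle_grm <- function(X, p) {
  n <- nrow(X); m <- ncol(X)
  den <- 2 * p * (1 - p)
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (k in seq_len(n)) {
      if (j == k) {
        A[j, j] <- 1 + mean((X[j, ]^2 - (1 + 2 * p) * X[j, ] + 2 * p^2) / den)
      } else {
        A[j, k] <- mean((X[j, ] - 2 * p) * (X[k, ] - 2 * p) / den)
      }
    }
  }
  A
}

# cluster sandwich by explicit per-cluster summation
oracle_cluster_vcov <- function(X, y, cluster, type = "CR1") {
  beta <- solve(crossprod(X), crossprod(X, y))
  u <- as.vector(y - X %*% beta)
  bread <- solve(crossprod(X))
  meat <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cluster)) {
    idx <- which(cluster == g)
    Xg <- X[idx, , drop = FALSE]
    ug <- u[idx]
    s <- crossprod(Xg, ug)
    meat <- meat + s %*% t(s)
  }
  G <- length(unique(cluster)); N <- nrow(X); K <- ncol(X)
  cfac <- if (type == "CR1") G / (G - 1) * (N - 1) / (N - K) else 1
  cfac * bread %*% meat %*% bread
}

# dense-matrix restricted log-likelihood at given variance components
oracle_reml_loglik <- function(y, X, A, vg, ve) {
  n <- length(y); k <- ncol(X)
  V <- vg * A + ve * diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
  as.numeric(-0.5 * ((n - k) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus[1] +
                       determinant(XtViX, logarithm = TRUE)$modulus[1] +
                       t(y) %*% P %*% y))
}

# profile the restricted likelihood over a heritability grid (vp profiled
# analytically at each grid point)
oracle_reml_grid <- function(y, X, A, grid = seq(0.01, 0.99, by = 0.01)) {
  n <- length(y); k <- ncol(X)
  ll <- vapply(grid, function(h2) {
    V0 <- h2 * A + (1 - h2) * diag(n)
    Vi <- solve(V0)
    XtViX <- t(X) %*% Vi %*% X
    P0 <- Vi - Vi %*% X %*% solve(XtViX, t(X) %*% Vi)
    vp_hat <- as.numeric(t(y) %*% P0 %*% y) / (n - k)
    -0.5 * ((n - k) * log(2 * pi) +
              determinant(V0, logarithm = TRUE)$modulus[1] + n * log(vp_hat) +
              determinant(XtViX, logarithm = TRUE)$modulus[1] - k * log(vp_hat) +
              (n - k))
  }, numeric(1))
  list(grid = grid, ll = ll, h2_hat = grid[which.max(ll)], ll_max = max(ll))
}

toy_genotypes <- function(n, m, seed = 1, freq = NULL) {
  set.seed(seed)
  p <- freq %||% runif(m, 0.2, 0.8)
  X <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  genotype_matrix(X, panel = snp_panel(sprintf("rs%03d", seq_len(m)), freq = p),
                  sample_id = sprintf("ID%03d", seq_len(n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared mid-size default cohort, simulated once per test run
.poly_cache <- new.env(parent = emptyenv())
default_cohort <- function() {
  if (is.null(.poly_cache$bundle)) {
    .poly_cache$bundle <- simulate_cohort(
      sim_config(n_families = 2000, m_snps = 300, seed = 99))
  }
  .poly_cache$bundle
}
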