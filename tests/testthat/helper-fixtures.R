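# Shared fixtures and independent oracles for the test suite.

# small synthetic-cohort configuration for fast end-to-end tests
small_config <- function(n_vertices = 40, n_regions = 8, seed = 1, ...) {
  sim_config(n_vertices = n_vertices, n_regions = n_regions, seed = seed,
             ...)
}

# Dense linear-algebra oracle for the GP: explicit inverse/determinant,
# independent of the package's Cholesky implementation.
oracle_kernel <- function(theta, X1, X2) {
  d <- ncol(X1)
  sf2 <- exp(theta[1])
  ell <- exp(theta[2:(d + 1)])
  sl2 <- exp(theta[d + 2])
  sb2 <- exp(theta[d + 3])
  K <- matrix(0, nrow(X1), nrow(X2))
  for (i in seq_len(nrow(X1))) {
    for (j in seq_len(nrow(X2))) {
      q <- sum(((X1[i, ] - X2[j, ]) / ell)^2)
      K[i, j] <- sf2 * exp(-0.5 * q) + sl2 * sum(X1[i, ] * X2[j, ]) + sb2
    }
  }
  K
}

oracle_nlml <- function(theta, X, y, jitter_rel = 1e-6) {
  n <- length(y)
  d <- ncol(X)
  sn2 <- exp(theta[d + 4])
  K <- oracle_kernel(theta, X, X)
  jit <- jitter_rel * (mean(diag(K)) + sn2)
  Kn <- K + diag(sn2 + jit, n)
  yc <- y - mean(y)
  0.5 * drop(t(yc) %*% solve(Kn) %*% yc) +
    0.5 * determinant(Kn, logarithm = TRUE)$modulus +
    0.5 * n * log(2 * pi)
}

oracle_predict <- function(theta, X, y, Xs, jitter_rel = 1e-6) {
  n <- length(y)
  d <- ncol(X)
  sn2 <- exp(theta[d + 4])
  K <- oracle_kernel(theta, X, X)
  jit <- jitter_rel * (mean(diag(K)) + sn2)
  Kn <- K + diag(sn2 + jit, n)
  Ks <- oracle_kernel(theta, X, Xs)
  yc <- y - mean(y)
  Kinv <- solve(Kn)
  mu <- drop(t(Ks) %*% Kinv %*% yc) + mean(y)
  kss <- diag(oracle_kernel(theta, Xs, Xs))
  v <- kss - diag(t(Ks) %*% Kinv %*% Ks)
  list(mean = mu, var_latent = pmax(v, 0), var_noise = sn2)
}

# draw one dataset from the GP prior with given hyperparameters
sample_gp <- function(theta, X, seed) {
  withr::with_seed(seed, {
    n <- nrow(X)
    d <- ncol(X)
    sn2 <- exp(theta[d + 4])
    K <- oracle_kernel(theta, X, X) + diag(sn2 + 1e-10, n)
    L <- t(chol(K))
    drop(L %*% rnorm(n))
  })
}

# brute-force Benjamini-Hochberg step-up: evaluate every candidate i
bh_bruteforce <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  istar <- 0
  for (i in seq_len(m)) if (ps[i] <= i / m * q) istar <- i
  rej <- logical(m)
  if (istar > 0) rej[p <= ps[istar]] <- TRUE
  rej
}

# covariate matrix for ad hoc GP tests
toy_covariates <- function(n, seed = 1) {
  withr::with_seed(seed, {
    age <- runif(n, 6, 31)
    cbind(age = (age - mean(age)) / sd(age),
          sex_male = rbinom(n, 1, 0.5))
  })
}

rgumbel <- function(n, mu = 0, beta = 1) {
  mu - beta * log(-log(runif(n)))
}

# The paper-scale pipeline run shared by the acceptance tests: default
# study conditions (206 TD + 321 ASD, prevalence 0.4, magnitude 4 SD,
# 34 regions) at a 200-vertex geometry, 10-fold CV. Computed once.
.acceptance_cache <- new.env(parent = emptyenv())
acceptance_run <- function() {
  if (is.null(.acceptance_cache$run)) {
    cfg <- sim_config(n_vertices = 200, seed = 20260901)
    rc <- run_config(sim = cfg, folds = 10, restarts = 2, seed = 20260901)
    .acceptance_cache$run <- run_pipeline(rc, verbose = FALSE)
  }
  .acceptance_cache$run
}
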