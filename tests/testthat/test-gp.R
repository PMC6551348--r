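test_that("single-observation NLML equals the closed form", {
  X <- matrix(0, 1, 1)
  y <- 5  # centering makes the effective target 0
  theta <- c(log(0.3), 0, log(0.2), log(0.1), log(0.05))
  # prior variance at x = 0: sf2 + sb2 + sn2 (linear term vanishes)
  v <- 0.3 + 0.1 + 0.05
  nlml <- neg_log_marginal_likelihood(theta, X, y, jitter = 1e-12)
  expect_equal(as.numeric(nlml), 0.5 * log(2 * pi * v), tolerance = 1e-6)
})

test_that("NLML and gradient match the dense-algebra oracle", {
  for (n in c(4, 20, 50)) {
    X <- toy_covariates(n, seed = n)
    y <- withr::with_seed(n, 3 - 0.4 * X[, 1] + rnorm(n, 0, 0.2))
    theta <- c(log(0.05), 0.2, -0.1, log(0.01), log(0.02), log(0.04))
    got <- neg_log_marginal_likelihood(theta, X, y, grad = TRUE)
    want <- oracle_nlml(theta, X, y)
    expect_equal(as.numeric(got), as.numeric(want), tolerance = 1e-8)

    # analytic gradient against central finite differences
    g <- attr(got, "gradient")
    for (j in seq_along(theta)) {
      h <- 1e-5
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      fd <- (oracle_nlml(tp, X, y) - oracle_nlml(tm, X, y)) / (2 * h)
      expect_equal(g[j], as.numeric(fd), tolerance = 1e-4)
    }
  }
})

test_that("duplicated training points do not blow up the likelihood", {
  X <- rbind(toy_covariates(5), toy_covariates(5))
  y <- rep(rnorm(5), 2)
  theta <- c(log(0.05), 0, 0, log(0.01), log(0.01), log(1e-9))
  nlml <- neg_log_marginal_likelihood(theta, X, y)
  expect_true(is.finite(as.numeric(nlml)))
})

test_that("predictions match the dense-algebra oracle", {
  n <- 5
  X <- toy_covariates(n, seed = 8)
  y <- withr::with_seed(8, rnorm(n, 3, 0.3))
  Xs <- toy_covariates(7, seed = 9)
  theta <- c(log(0.1), 0.1, -0.3, log(0.02), log(0.05), log(0.01))
  model <- structure(list(theta = theta, X = X, y = y, y_mean = mean(y),
                          jitter = 1e-6, n = n,
                          covariate_names = colnames(X)),
                     class = "vertex_gp")
  got <- predict_vertex(model, Xs)
  want <- oracle_predict(theta, X, y, Xs)
  expect_equal(got$mean, want$mean, tolerance = 1e-8)
  expect_equal(got$var_latent, want$var_latent, tolerance = 1e-8)
  expect_equal(got$var_noise[1], want$var_noise, tolerance = 1e-12)
})

test_that("with noise at the jitter floor the GP interpolates its training data", {
  n <- 25
  X <- toy_covariates(n, seed = 4)
  y <- withr::with_seed(4, 2.5 - 0.3 * X[, 1] + 0.1 * X[, 2])
  theta <- c(log(0.5), 0, 0, log(0.1), log(0.1), log(1e-10))
  model <- structure(list(theta = theta, X = X, y = y, y_mean = mean(y),
                          jitter = 1e-9, n = n,
                          covariate_names = colnames(X)),
                     class = "vertex_gp")
  pr <- predict_vertex(model, X)
  expect_lt(max(abs(pr$mean - y)), 1e-6)
})

test_that("predictive variance grows toward the prior far from the data", {
  n <- 30
  X <- toy_covariates(n, seed = 5)
  y <- withr::with_seed(5, rnorm(n))
  sf2 <- 0.4
  # stationary-only configuration: linear and bias variances negligible
  theta <- c(log(sf2), 0, 0, log(1e-12), log(1e-12), log(0.05))
  model <- structure(list(theta = theta, X = X, y = y, y_mean = mean(y),
                          jitter = 1e-9, n = n,
                          covariate_names = colnames(X)),
                     class = "vertex_gp")
  near <- predict_vertex(model, matrix(c(0, 0), 1, 2))
  far <- predict_vertex(model, matrix(c(50, 0), 1, 2))
  expect_gt(far$var_latent, near$var_latent)
  expect_lte(far$var_latent, sf2 + 1e-8)
  expect_gt(far$var_latent, 0.99 * sf2)
})

test_that("a constant target collapses to its own value with shrunken variances", {
  n <- 30
  X <- toy_covariates(n, seed = 6)
  y <- rep(2.8, n)
  m <- fit_vertex_model(X, y, restarts = 2, seed = 1)
  pr <- predict_vertex(m, X)
  expect_lt(max(abs(pr$mean - 2.8)), 1e-3)
  expect_lt(pr$var_noise[1], 1e-4)
})

test_that("fits below the training-size floor are refused", {
  X <- toy_covariates(10)
  expect_error(fit_vertex_model(X, rnorm(10)), class = "normdev_too_few")
  expect_silent(invisible(fit_vertex_model(X, rnorm(10) + 3, floor_n = 5,
                                           restarts = 1)))
})

test_that("hyperparameters are recovered from data generated by the model", {
  # identifiable regime: short length-scale, so the sample carries many
  # independent wiggles that pin down the signal variance
  true_theta <- c(log(0.25), log(0.1), log(0.005), log(0.005), log(0.04))
  n <- 200
  err_sig <- err_noise <- numeric(10)
  for (r in 1:10) {
    X <- toy_covariates(n, seed = 300 + r)[, 1, drop = FALSE]
    y <- sample_gp(true_theta, X, seed = 400 + r)
    m <- fit_vertex_model(X, y, restarts = 3, seed = r)
    err_sig[r] <- m$theta[1] - true_theta[1]
    err_noise[r] <- m$theta[5] - true_theta[5]
  }
  expect_lte(median(abs(err_sig)), 0.3)
  expect_lte(median(abs(err_noise)), 0.3)
})

test_that("removing training points never shrinks predictive uncertainty", {
  theta <- c(log(0.2), 0, 0, log(0.05), log(0.05), log(0.03))
  X <- toy_covariates(40, seed = 12)
  y <- withr::with_seed(12, rnorm(40, 3, 0.3))
  Xq <- toy_covariates(6, seed = 13)
  model_for <- function(idx) {
    structure(list(theta = theta, X = X[idx, , drop = FALSE], y = y[idx],
                   y_mean = mean(y[idx]), jitter = 1e-9, n = length(idx),
                   covariate_names = colnames(X)),
              class = "vertex_gp")
  }
  v40 <- predict_vertex(model_for(1:40), Xq)$var_latent
  v20 <- predict_vertex(model_for(1:20), Xq)$var_latent
  v10 <- predict_vertex(model_for(1:10), Xq)$var_latent
  expect_true(all(v20 >= v40 - 1e-9))
  expect_true(all(v10 >= v20 - 1e-9))
})

test_that("tidy and glance summarize a vertex fit", {
  X <- toy_covariates(30, seed = 2)
  y <- withr::with_seed(2, 3 + rnorm(30, 0, 0.2))
  m <- fit_vertex_model(X, y, restarts = 2)
  td <- tidy(m)
  expect_equal(nrow(td), 6)
  expect_true(all(td$value > 0))
  expect_equal(glance(m)$n, 30)
})
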