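#' Covariate design for the normative model
#'
#' Builds the numeric covariate matrix used by the per-vertex Gaussian
#' process: standardized age plus a male dummy, optionally extended with
#' mean-imputed IQ (with a missingness indicator), site dummies and a
#' surface-quality surrogate. Standardization constants are taken from a
#' reference (training) table so that held-out and clinical subjects are
#' mapped onto the training scale.
#'
#' @param data cohort tibble with at least `age` and `sex`.
#' @param covariates character vector drawn from
#'   `c("age", "sex", "iq", "site", "quality")`.
#' @param reference cohort tibble supplying standardization constants
#'   (defaults to `data`); in the normative fit this is the typically
#'   developing training fold.
#' @return numeric matrix with one row per subject and an attribute
#'   `scaling` recording the constants used.
#' @export
build_covariates <- function(data, covariates = c("age", "sex"),
                             reference = data) {
  allowed <- c("age", "sex", "iq", "site", "quality")
  bad <- setdiff(covariates, allowed)
  if (length(bad) > 0) {
    abort(paste0("unknown covariates: ", paste(bad, collapse = ", ")))
  }
  cols <- list()
  scaling <- list()
  if ("age" %in% covariates) {
    mu <- mean(reference$age)
    s <- sd(reference$age)
    if (!is.finite(s) || s == 0) s <- 1
    cols$age <- (data$age - mu) / s
    scaling$age <- c(mean = mu, sd = s)
  }
  if ("sex" %in% covariates) {
    cols$sex_male <- as.numeric(data$sex == "male")
  }
  if ("iq" %in% covariates) {
    mu <- mean(reference$iq, na.rm = TRUE)
    if (!is.finite(mu)) mu <- 100
    iq <- data$iq
    miss <- is.na(iq)
    iq[miss] <- mu
    s <- sd(reference$iq, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    cols$iq <- (iq - mu) / s
    cols$iq_missing <- as.numeric(miss)
    scaling$iq <- c(mean = mu, sd = s)
  }
  if ("site" %in% covariates) {
    lev <- sort(unique(as.character(reference$site)))
    for (l in lev[-1]) {
      cols[[paste0("site_", l)]] <- as.numeric(as.character(data$site) == l)
    }
    scaling$site_levels <- lev
  }
  if ("quality" %in% covariates) {
    mu <- mean(reference$quality_surrogate, na.rm = TRUE)
    s <- sd(reference$quality_surrogate, na.rm = TRUE)
    if (!is.finite(mu)) mu <- 0
    if (!is.finite(s) || s == 0) s <- 1
    q <- data$quality_surrogate
    q[is.na(q)] <- mu
    cols$quality <- (q - mu) / s
    scaling$quality <- c(mean = mu, sd = s)
  }
  X <- do.call(cbind, cols)
  rownames(X) <- data$subject_id
  attr(X, "scaling") <- scaling
  X
}

#' Precompute covariate distance structures for repeated fits
#'
#' The squared-distance matrices and linear-kernel Gram matrix depend
#' only on the covariates; when many vertices share one covariate matrix
#' (every vertex of a training fold), computing them once saves
#' substantial time.
#'
#' @param X covariate matrix.
#' @return opaque list consumed by [fit_vertex_model()].
#' @export
gp_precompute <- function(X) {
  .gp_precompute(as.matrix(X))
}

default_theta <- function(X, y) {
  vy <- var(y)
  if (!is.finite(vy) || vy < 1e-12) vy <- 1e-12
  d <- ncol(X)
  c(log(0.5 * vy),            # RBF signal variance
    rep(0, d),                # unit length-scales on the standardized scale
    log(0.1 * vy),            # linear variance
    log(0.1 * vy),            # bias variance
    log(0.5 * vy))            # noise variance
}

#' Negative log marginal likelihood of one vertex model
#'
#' Evaluates \eqn{-\log N(y \mid 0, K(X,X) + \sigma^2_n I)} for the
#' composite kernel (ARD squared-exponential + linear + bias) after
#' centering `y`; a relative jitter is added to the diagonal before the
#' Cholesky factorization, escalating tenfold up to three times if the
#' factorization fails.
#'
#' @param theta log-scale hyperparameters: `log sf2`, one `log ell` per
#'   covariate column, `log sl2`, `log sb2`, `log sn2`.
#' @param X covariate matrix (rows subjects).
#' @param y measurement vector.
#' @param center center `y` before evaluation (default `TRUE`).
#' @param jitter relative diagonal jitter.
#' @param grad also return the gradient with respect to `theta`.
#' @return the scalar NLML, with attribute `"gradient"` when requested.
#' @export
neg_log_marginal_likelihood <- function(theta, X, y, center = TRUE,
                                        jitter = 1e-6, grad = FALSE) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) abort("length(y) must equal nrow(X)")
  if (length(y) < 1) abort("need at least one observation")
  if (!all(is.finite(theta))) abort("non-finite hyperparameters")
  if (length(theta) != ncol(X) + 4) {
    abort(sprintf("theta must have length %d (got %d)", ncol(X) + 4,
                  length(theta)))
  }
  yc <- if (center) y - mean(y) else y
  res <- .gp_nlml_grad(theta, X, yc, jitter, 3L, grad)
  if (!isTRUE(res$ok)) {
    abort("covariance not positive definite after jitter escalation")
  }
  out <- res$nlml
  if (grad) attr(out, "gradient") <- res$grad
  out
}

#' Fit one vertex's normative Gaussian process
#'
#' Empirical-Bayes (type-II maximum likelihood) fit: kernel
#' hyperparameters maximize the log marginal likelihood via multi-restart
#' L-BFGS-B on the log scale. The first restart starts from data-driven
#' values (variance split between signal and noise, unit length-scales);
#' the rest perturb it with seeded standard-normal noise.
#'
#' @param X covariate matrix (subjects in rows).
#' @param y measurement vector (mm).
#' @param restarts number of optimizer restarts (>= 1).
#' @param seed integer seed for the restart perturbations.
#' @param floor_n minimum number of training subjects.
#' @param jitter relative diagonal jitter.
#' @param maxit L-BFGS-B iteration cap per restart.
#' @param pre optional precomputed distance structure from
#'   [gp_precompute()]; pass it when fitting many vertices that share the
#'   same covariate matrix.
#' @param extra_inits optional list of additional starting values (log
#'   scale), e.g. warm starts from a neighbouring vertex; used on top of
#'   the `restarts` initializations.
#' @return object of class `vertex_gp` with the fitted hyperparameters,
#'   the training data and the achieved log marginal likelihood.
#' @export
fit_vertex_model <- function(X, y, restarts = 5, seed = 1, floor_n = 20,
                             jitter = 1e-6, maxit = 100, pre = NULL,
                             extra_inits = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (length(y) != n) abort("length(y) must equal nrow(X)")
  if (n < floor_n) {
    abort(sprintf("need at least %d training subjects, got %d", floor_n, n),
          class = "normdev_too_few")
  }
  if (anyNA(X) || anyNA(y)) abort("covariates and targets must be complete")
  if (is.null(pre)) pre <- gp_precompute(X)
  ymean <- mean(y)
  yc <- y - ymean
  th0 <- default_theta(X, yc)
  inits <- withr::with_seed(seed, {
    c(list(th0), extra_inits,
      purrr::map(seq_len(max(0, restarts - 1)),
                 function(i) th0 + rnorm(length(th0))))
  })
  obj <- function(th) {
    if (!all(is.finite(th))) return(NULL)
    v <- .gp_nlml_grad_pre(th, pre$D, pre$XXt, yc, jitter, 3L, TRUE)
    if (!isTRUE(v$ok)) return(NULL)
    out <- v$nlml
    attr(out, "gradient") <- v$grad
    out
  }
  best <- NULL
  for (init in inits) {
    # cache: L-BFGS-B calls fn and gr at the same point back to back
    last <- new.env(parent = emptyenv())
    fn <- function(th) {
      v <- obj(th)
      if (is.null(v)) return(1e10)
      last$th <- th
      last$g <- attr(v, "gradient")
      as.numeric(v)
    }
    gr <- function(th) {
      if (!is.null(last$th) && identical(th, last$th)) return(last$g)
      v <- obj(th)
      if (is.null(v)) return(rep(0, length(th)))
      attr(v, "gradient")
    }
    fit <- tryCatch(
      optim(init, fn, gr, method = "L-BFGS-B",
            lower = rep(-15, length(init)), upper = rep(8, length(init)),
            # stop when the NLML improves by less than ~1e-6 per step
            control = list(maxit = maxit, factr = 1e-6 / .Machine$double.eps)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    abort("all optimizer restarts failed to converge",
          class = "normdev_fit_failed")
  }
  structure(
    list(theta = best$par, X = X, y = y, y_mean = ymean,
         nlml = best$value, jitter = jitter, n = n,
         covariate_names = colnames(X), restarts = restarts, seed = seed),
    class = "vertex_gp")
}

#' Predict from a fitted vertex model
#'
#' Exact Gaussian-process predictive equations: mean
#' \eqn{k_*^T (K+\sigma^2_n I)^{-1} y} (plus the restored training mean)
#' and latent variance \eqn{k_{**} - k_*^T (K+\sigma^2_n I)^{-1} k_*},
#' clipped at zero. The observation-noise variance is returned alongside
#' so callers can form the total predictive variance.
#'
#' @param model a `vertex_gp` fit.
#' @param Xstar query covariate matrix with the training columns.
#' @return tibble with `mean`, `var_latent`, `var_noise`.
#' @export
predict_vertex <- function(model, Xstar) {
  stopifnot(inherits(model, "vertex_gp"))
  Xstar <- as.matrix(Xstar)
  if (ncol(Xstar) != ncol(model$X)) {
    abort(sprintf("covariate dimension mismatch: model has %d, query has %d",
                  ncol(model$X), ncol(Xstar)))
  }
  pr <- .gp_predict(model$theta, model$X, model$y - model$y_mean, Xstar,
                    model$jitter, 3L)
  tibble::tibble(mean = as.numeric(pr$mean) + model$y_mean,
                 var_latent = as.numeric(pr$var_latent),
                 var_noise = pr$var_noise)
}

#' @export
print.vertex_gp <- function(x, ...) {
  cat("<vertex_gp> n =", x$n, " covariates:",
      paste(x$covariate_names, collapse = ", "), "\n")
  cat("  NLML:", format(x$nlml, digits = 6), "\n")
  invisible(x)
}

#' @rdname fit_vertex_model
#' @param x a `vertex_gp` object.
#' @param ... unused.
#' @export
tidy.vertex_gp <- function(x, ...) {
  d <- length(x$theta) - 4
  nm <- c("log_signal_variance",
          paste0("log_lengthscale_", x$covariate_names %||% seq_len(d)),
          "log_linear_variance", "log_bias_variance", "log_noise_variance")
  tibble::tibble(term = nm, estimate = as.numeric(x$theta),
                 value = exp(as.numeric(x$theta)))
}

#' @rdname fit_vertex_model
#' @export
glance.vertex_gp <- function(x, ...) {
  tibble::tibble(nlml = x$nlml, n = x$n, restarts = x$restarts)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
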