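#' Fit the vertexwise normative model with cross-validated predictions
#'
#' The central fitting routine. For every vertex a Gaussian-process
#' regression of the measurement on the covariates is estimated from the
#' typically developing (TD) subjects by empirical Bayes. TD subjects
#' receive strictly out-of-fold predictions under k-fold
#' cross-validation (the model predicting a TD subject never saw that
#' subject); clinical (non-TD) subjects are predicted from a final model
#' refit on all TD subjects. Age is standardized using the training-fold
#' TD statistics.
#'
#' Within each fold the optimizer is warm-started from the previous
#' vertex's optimum (in addition to the data-driven initialization and
#' any random restarts), which speeds up the thousands of per-vertex
#' fits without changing the fitted model class.
#'
#' @param cohort cohort tibble (`subject_id`, `group`, `age`, `sex`,
#'   ...); rows must align with `measures`.
#' @param measures a [measure_matrix()] (or bare matrix) of
#'   subjects-by-vertices values.
#' @param covariates covariate set for [build_covariates()].
#' @param folds number of cross-validation folds (>= 2).
#' @param seed integer seed controlling fold assignment and restarts.
#' @param restarts optimizer initializations per vertex fit (the
#'   data-driven start, the warm start when available, then random
#'   perturbations).
#' @param floor_n minimum training-set size per fit.
#' @param stratify_sex balance fold assignment within sex.
#' @param verbose print fold progress.
#' @return object of class `normative_pred`: prediction matrices
#'   (`yhat`, `var_latent`, `var_noise`), `provenance` per subject,
#'   `fold` assignment for TD subjects, `failed_vertices`, the
#'   per-vertex full-model hyperparameters, and the subject table.
#' @export
normative_model <- function(cohort, measures, covariates = c("age", "sex"),
                            folds = 10, seed = 1, restarts = 3,
                            floor_n = 20, stratify_sex = FALSE,
                            verbose = FALSE) {
  Y <- if (inherits(measures, "measure_matrix")) measures$values else
    as.matrix(measures)
  if (nrow(Y) != nrow(cohort)) abort("cohort rows must align with measures")
  if (folds < 2) abort("folds must be at least 2")
  td <- which(cohort$group == "TD")
  asd <- which(cohort$group != "TD")
  if (length(td) < folds) {
    abort(sprintf("need at least %d TD subjects for %d-fold CV", folds,
                  folds))
  }
  V <- ncol(Y)
  n <- nrow(Y)

  fold_of <- withr::with_seed(stage_seed(seed, "folds"), {
    if (stratify_sex) {
      f <- integer(length(td))
      for (s in unique(cohort$sex[td])) {
        i <- which(cohort$sex[td] == s)
        f[i] <- sample(rep(seq_len(folds), length.out = length(i)))
      }
      f
    } else {
      sample(rep(seq_len(folds), length.out = length(td)))
    }
  })
  if (any(tabulate(fold_of, folds) == 0)) {
    abort("a fold received no subjects; reduce the number of folds")
  }

  yhat <- matrix(NA_real_, n, V, dimnames = dimnames(Y))
  s2_lat <- matrix(NA_real_, n, V, dimnames = dimnames(Y))
  s2_noise <- matrix(NA_real_, n, V, dimnames = dimnames(Y))
  failed <- rep(FALSE, V)
  theta_full <- vector("list", V)

  fit_block <- function(train_idx, test_idx, block_seed) {
    # one training set, all vertices; returns predictions on test_idx
    ref <- cohort[train_idx, , drop = FALSE]
    Xtr <- build_covariates(ref, covariates, reference = ref)
    Xte <- build_covariates(cohort[test_idx, , drop = FALSE], covariates,
                            reference = ref)
    pre <- gp_precompute(Xtr)
    warm <- NULL
    out <- list(yhat = matrix(NA_real_, length(test_idx), V),
                s2l = matrix(NA_real_, length(test_idx), V),
                s2n = matrix(NA_real_, length(test_idx), V),
                failed = rep(FALSE, V), theta = vector("list", V))
    for (v in seq_len(V)) {
      y <- Y[train_idx, v]
      m <- tryCatch(
        fit_vertex_model(Xtr, y,
                         restarts = max(1, restarts - !is.null(warm)),
                         seed = block_seed + v, floor_n = floor_n,
                         pre = pre, extra_inits = warm),
        error = function(e) e)
      if (inherits(m, "normdev_too_few")) stop(m)
      if (inherits(m, "error")) { out$failed[v] <- TRUE; next }
      warm <- list(m$theta)
      out$theta[[v]] <- m$theta
      pr <- predict_vertex(m, Xte)
      out$yhat[, v] <- pr$mean
      out$s2l[, v] <- pr$var_latent
      out$s2n[, v] <- pr$var_noise
    }
    out
  }

  for (f in seq_len(folds)) {
    if (verbose) message("fold ", f, "/", folds)
    test <- td[fold_of == f]
    train <- td[fold_of != f]
    if (length(train) == 0) abort("a fold emptied the training set")
    res <- fit_block(train, test, stage_seed(seed, "fit") + f * 10000L)
    yhat[test, ] <- res$yhat
    s2_lat[test, ] <- res$s2l
    s2_noise[test, ] <- res$s2n
    failed <- failed | res$failed
  }

  if (verbose) message("full TD refit")
  if (length(asd) > 0) {
    res <- fit_block(td, asd, stage_seed(seed, "fit"))
    yhat[asd, ] <- res$yhat
    s2_lat[asd, ] <- res$s2l
    s2_noise[asd, ] <- res$s2n
    failed <- failed | res$failed
    theta_full <- res$theta
  } else {
    res <- fit_block(td, td[1], stage_seed(seed, "fit"))
    failed <- failed | res$failed
    theta_full <- res$theta
  }

  provenance <- rep(NA_character_, n)
  provenance[td] <- paste0("cv-fold-", fold_of)
  provenance[asd] <- "full-model"

  if (any(failed)) {
    yhat[, failed] <- NA_real_
    s2_lat[, failed] <- NA_real_
    s2_noise[, failed] <- NA_real_
    warn(sprintf("%d vertices failed to fit and are excluded downstream",
                 sum(failed)))
  }

  structure(
    list(yhat = yhat, var_latent = s2_lat, var_noise = s2_noise,
         provenance = provenance, fold = fold_of, td_rows = td,
         asd_rows = asd, failed_vertices = failed,
         theta_full = theta_full, covariates = covariates,
         folds = folds, seed = seed,
         subjects = cohort[, intersect(
           c("subject_id", "group", "sex", "age", "schedule"),
           names(cohort))]),
    class = "normative_pred")
}

#' @export
print.normative_pred <- function(x, ...) {
  cat("<normative_pred>", nrow(x$yhat), "subjects x", ncol(x$yhat),
      "vertices;", x$folds, "folds;", sum(x$failed_vertices),
      "failed vertices\n")
  invisible(x)
}

#' @rdname normative_model
#' @param x a `normative_pred` object.
#' @param ... unused.
#' @export
tidy.normative_pred <- function(x, ...) {
  tibble::tibble(
    subject_id = rep(rownames(x$yhat), times = ncol(x$yhat)),
    vertex = rep(seq_len(ncol(x$yhat)) - 1L, each = nrow(x$yhat)),
    yhat = as.numeric(x$yhat),
    var_latent = as.numeric(x$var_latent),
    var_noise = as.numeric(x$var_noise),
    provenance = rep(x$provenance, times = ncol(x$yhat)))
}

#' Evaluate normative-model fit on the reference cohort
#'
#' Per-vertex agreement between observed and out-of-fold predicted
#' values in the TD cohort: Pearson correlation with its t-test p-value,
#' root-mean-square error, and a Benjamini-Hochberg significance flag
#' across vertices. Vertices whose prediction vector has zero variance
#' (or which failed to fit) get an undefined correlation and are never
#' flagged significant.
#'
#' @param pred a `normative_pred`.
#' @param measures the measurement matrix the model was fit to.
#' @param q FDR level across vertices.
#' @return tibble of class `fit_evaluation`: `vertex`, `cor`, `p`,
#'   `rmse`, `significant`.
#' @export
evaluate_fit <- function(pred, measures, q = 0.05) {
  stopifnot(inherits(pred, "normative_pred"))
  if (q < 0 || q > 1) abort("q must lie in [0, 1]")
  Y <- if (inherits(measures, "measure_matrix")) measures$values else
    as.matrix(measures)
  td <- pred$td_rows
  obs <- Y[td, , drop = FALSE]
  fit <- pred$yhat[td, , drop = FALSE]
  n <- length(td)
  V <- ncol(Y)
  cors <- rep(NA_real_, V)
  ps <- rep(NA_real_, V)
  rmse <- unname(sqrt(colMeans((obs - fit)^2)))
  ok <- !pred$failed_vertices
  for (v in which(ok)) {
    sy <- sd(fit[, v])
    if (!is.finite(sy) || sy == 0) next
    r <- cor(obs[, v], fit[, v])
    cors[v] <- r
    tt <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
    ps[v] <- 2 * pt(-abs(tt), n - 2)
  }
  adj <- p.adjust(ps, method = "BH")
  sig <- !is.na(adj) & adj <= q & q > 0
  out <- tibble::tibble(vertex = seq_len(V) - 1L, cor = cors, p = ps,
                        rmse = rmse, significant = sig)
  class(out) <- c("fit_evaluation", class(out))
  attr(out, "q") <- q
  attr(out, "n") <- n
  out
}

#' @rdname evaluate_fit
#' @param object a `fit_evaluation`.
#' @param ... unused.
#' @export
glance.fit_evaluation <- function(object, ...) {
  tibble::tibble(
    n_vertices = nrow(object),
    n_significant = sum(object$significant),
    median_cor = median(object$cor, na.rm = TRUE),
    median_rmse = median(object$rmse, na.rm = TRUE),
    q = attr(object, "q"))
}
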