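#' Trimmed-top extreme deviation score
#'
#' A subject's atypicality summary: the mean of the `ceil(fraction * m)`
#' largest absolute Z scores across the supplied vertices. With the
#' default 1% fraction this is a noise-robust stand-in for the single
#' maximum deviation.
#'
#' @param z numeric vector of Z scores (one subject); `NA` entries are
#'   dropped.
#' @param fraction top fraction to average over, in (0, 1].
#' @return nonnegative scalar.
#' @export
extreme_score <- function(z, fraction = 0.01) {
  z <- z[!is.na(z)]
  if (length(z) == 0) abort("empty Z vector")
  if (fraction <= 0 || fraction > 1) abort("fraction must lie in (0, 1]")
  k <- max(1L, ceiling(fraction * length(z)))
  mean(sort(abs(z), decreasing = TRUE)[seq_len(k)])
}

#' Per-region extreme deviation scores
#'
#' Applies [extreme_score()] within each parcel of a vertex-to-region
#' parcellation; the averaging count floors at one vertex, so small
#' regions return their maximum |Z|.
#'
#' @param z one subject's vertexwise Z scores.
#' @param parcellation tibble (`vertex`, `region`) covering every
#'   vertex, or a region label vector aligned with `z`.
#' @param fraction top fraction per region.
#' @return named numeric vector, one score per region.
#' @export
regional_extreme_scores <- function(z, parcellation, fraction = 0.01) {
  region <- if (is.data.frame(parcellation)) {
    if (nrow(parcellation) != length(z)) {
      abort("parcellation must cover every vertex")
    }
    parcellation$region[order(parcellation$vertex)]
  } else {
    if (length(parcellation) != length(z)) {
      abort("parcellation must cover every vertex")
    }
    parcellation
  }
  vapply(split(z, region), extreme_score, numeric(1), fraction = fraction)
}

#' Extreme deviation scores for a cohort
#'
#' Computes each subject's global trimmed-top-1% score across all
#' vertices and the per-region analogue.
#'
#' @param x an [npm()] object (or a Z matrix).
#' @param parcellation tibble (`vertex`, `region`).
#' @param fraction top fraction.
#' @param subjects optional subject table when `x` is a bare matrix.
#' @return object of class `extreme_scores`: tibble `global`
#'   (subject-level) and tibble `regional` (subject x region, long).
#' @export
extreme_scores <- function(x, parcellation, fraction = 0.01,
                           subjects = NULL) {
  Z <- if (inherits(x, "npm")) x$Z else as.matrix(x)
  subjects <- subjects %||% if (inherits(x, "npm")) x$subjects else
    tibble::tibble(subject_id = rownames(Z) %||%
                     sprintf("sub-%04d", seq_len(nrow(Z))))
  glob <- apply(Z, 1, extreme_score, fraction = fraction)
  reg <- t(apply(Z, 1, regional_extreme_scores, parcellation = parcellation,
                 fraction = fraction))
  global <- dplyr::bind_cols(subjects,
                             tibble::tibble(score = unname(glob)))
  regional <- tibble::tibble(
    subject_id = rep(subjects$subject_id, times = ncol(reg)),
    region = rep(colnames(reg), each = nrow(reg)),
    score = as.numeric(reg))
  structure(list(global = global, regional = regional,
                 fraction = fraction),
            class = "extreme_scores")
}

#' @export
print.extreme_scores <- function(x, ...) {
  cat("<extreme_scores>", nrow(x$global), "subjects, top fraction",
      x$fraction, "\n")
  invisible(x)
}

#' @rdname extreme_scores
#' @param ... unused.
#' @export
tidy.extreme_scores <- function(x, ...) x$global

#' Maximum-likelihood Gumbel fit
#'
#' Fits the type-I extreme-value (Gumbel) distribution
#' \eqn{F(x) = \exp(-\exp(-(x - \mu)/\beta))} to subject-level extreme
#' scores by maximum likelihood, solving the one-dimensional profile
#' equation for the scale and recovering the location in closed form.
#'
#' @param x numeric scores (n >= 10, non-constant).
#' @return object of class `gumbel_fit` with `mu`, `beta`, `loglik`,
#'   `n`, `converged`.
#' @export
fit_gumbel <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10) abort("need at least 10 scores")
  if (sd(x) == 0) abort("scores are constant; scale is degenerate")
  xbar <- mean(x)
  # profile equation: beta = mean(x) - sum(x w) / sum(w) with softmax
  # weights w_i proportional to exp(-x_i / beta)
  g <- function(beta) {
    s <- -x / beta
    w <- exp(s - max(s))
    beta - xbar + sum(x * w) / sum(w)
  }
  b0 <- sd(x) * sqrt(6) / pi
  lo <- b0 / 100
  hi <- b0 * 100
  while (g(lo) > 0 && lo > 1e-12) lo <- lo / 10
  while (g(hi) < 0 && hi < 1e12) hi <- hi * 10
  sol <- tryCatch(uniroot(g, c(lo, hi), tol = 1e-10),
                  error = function(e) NULL)
  converged <- !is.null(sol)
  beta <- if (converged) sol$root else b0
  s <- -x / beta
  mu <- -beta * (max(s) + log(mean(exp(s - max(s)))))
  z <- (x - mu) / beta
  loglik <- -n * log(beta) - sum(z) - sum(exp(-z))
  structure(list(mu = mu, beta = beta, loglik = loglik, n = n,
                 converged = converged),
            class = "gumbel_fit")
}

#' @export
print.gumbel_fit <- function(x, ...) {
  cat(sprintf("<gumbel_fit> mu = %.4f, beta = %.4f (n = %d, loglik = %.2f)\n",
              x$mu, x$beta, x$n, x$loglik))
  invisible(x)
}

#' @rdname fit_gumbel
#' @param x a `gumbel_fit`.
#' @param ... unused.
#' @export
tidy.gumbel_fit <- function(x, ...) {
  tibble::tibble(term = c("location", "scale"),
                 estimate = c(x$mu, x$beta))
}

#' @rdname fit_gumbel
#' @param object a `gumbel_fit`.
#' @export
glance.gumbel_fit <- function(object, ...) {
  tibble::tibble(mu = object$mu, beta = object$beta,
                 loglik = object$loglik, n = object$n,
                 converged = object$converged)
}

#' Gumbel density
#'
#' @param x quantiles.
#' @param mu location.
#' @param beta scale (> 0).
#' @return density values.
#' @export
dgumbel <- function(x, mu = 0, beta = 1) {
  z <- (x - mu) / beta
  exp(-z - exp(-z)) / beta
}

#' Cohort membership of the most extreme subjects
#'
#' Ranks subjects by extreme score (descending, ties broken by stable
#' input order), counts how many of the top `k` belong to the case
#' group, and returns the tail probability of at least that count under
#' a chosen null: `hypergeometric` (draws without replacement from the
#' realized cohort sizes), `binomial-cohort` (draws with replacement at
#' the cohort case proportion), or `binomial-half` (a fair-coin null).
#'
#' @param scores numeric subject scores.
#' @param group group labels; `case_level` identifies the case group.
#' @param k size of the top set.
#' @param null null model for the tail probability.
#' @param case_level label counted as a case.
#' @return tibble with `k`, `observed` cases in the top `k`, `null`,
#'   and `p`.
#' @export
topk_membership_test <- function(scores, group, k = 15,
                                 null = c("hypergeometric",
                                          "binomial-cohort",
                                          "binomial-half"),
                                 case_level = "ASD") {
  null <- match.arg(null)
  n <- length(scores)
  if (length(group) != n) abort("group labels must match scores")
  if (k > n) abort("k cannot exceed the number of subjects")
  if (length(unique(group)) < 2) abort("two groups are required")
  ord <- order(-scores)              # stable for ties
  top <- group[ord[seq_len(k)]]
  x <- sum(top == case_level)
  n_case <- sum(group == case_level)
  p <- switch(null,
    "hypergeometric" = phyper(x - 1, n_case, n - n_case, k,
                              lower.tail = FALSE),
    "binomial-cohort" = pbinom(x - 1, k, n_case / n, lower.tail = FALSE),
    "binomial-half" = pbinom(x - 1, k, 0.5, lower.tail = FALSE))
  tibble::tibble(k = k, observed = x, n_case = n_case, n = n,
                 null = null, p = p)
}
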