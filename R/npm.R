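#' Subject-specific deviation Z scores
#'
#' Standardizes each observed measurement against the normative
#' prediction: `Z = (y - yhat) / sqrt(var_latent + var_noise)`. The
#' denominator is the total predictive standard deviation, combining
#' uncertainty about the latent normative function with observation
#' noise, so Z is comparable across subjects and vertices.
#'
#' @param y observed values (vector or matrix).
#' @param yhat predictive means, same shape.
#' @param var_latent latent predictive variances (>= 0).
#' @param var_noise noise variances (> 0).
#' @return Z scores with the shape of `y`.
#' @export
compute_z <- function(y, yhat, var_latent, var_noise) {
  if (any(var_latent < 0, na.rm = TRUE)) abort("var_latent must be >= 0")
  if (any(var_noise <= 0, na.rm = TRUE)) abort("var_noise must be > 0")
  (y - yhat) / sqrt(var_latent + var_noise)
}

#' Benjamini-Hochberg rejection flags
#'
#' Step-up procedure: with ordered p-values `p(1) <= ... <= p(m)`,
#' reject all hypotheses with `p <= p(i*)` where
#' `i* = max{i : p(i) <= (i/m) q}`. Missing p-values are never rejected
#' and do not count toward `m`.
#'
#' @param p vector of p-values in (0, 1].
#' @param q FDR level in (0, 1).
#' @return logical rejection flags aligned with `p`.
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  if (q <= 0 || q >= 1) abort("q must lie in (0, 1)")
  if (any(p <= 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in (0, 1]")
  adj <- p.adjust(p, method = "BH")
  !is.na(adj) & adj <= q
}

#' Threshold one subject's Z map by within-subject FDR
#'
#' Two-sided p-values `2 * pnorm(-|Z|)` are corrected across that
#' subject's vertices by Benjamini-Hochberg at level `q`; surviving
#' vertices carry the sign of Z.
#'
#' @param z numeric vector of one subject's vertexwise Z scores;
#'   `NA` entries (excluded vertices) are skipped and do not count
#'   toward the number of tests.
#' @param q within-subject FDR level.
#' @return integer vector in `{-1, 0, 1}` aligned with `z`.
#' @export
npm_threshold <- function(z, q = 0.05) {
  mask <- integer(length(z))
  ok <- !is.na(z)
  if (!any(ok)) return(mask)
  p <- 2 * pnorm(-abs(z[ok]))
  p <- pmax(p, .Machine$double.xmin)
  rej <- bh_fdr(p, q)
  mask[ok][rej] <- as.integer(sign(z[ok][rej]))
  mask
}

#' Normative probability maps for a fitted cohort
#'
#' Converts normative predictions into per-subject deviation maps:
#' vertexwise Z scores, two-sided normal p-values, and a signed mask of
#' vertices surviving within-subject FDR correction at level `q`.
#' Vertices excluded from fitting are excluded from each subject's
#' family of tests.
#'
#' @param pred a `normative_pred` from [normative_model()].
#' @param measures the corresponding measurement matrix.
#' @param q within-subject FDR level.
#' @return object of class `npm` with matrices `Z`, `p`, `mask`, the
#'   level `q` and the subject table.
#' @export
npm <- function(pred, measures, q = 0.05) {
  stopifnot(inherits(pred, "normative_pred"))
  Y <- if (inherits(measures, "measure_matrix")) measures$values else
    as.matrix(measures)
  if (!all(dim(Y) == dim(pred$yhat))) {
    abort("measures do not match the prediction matrices")
  }
  Z <- compute_z(Y, pred$yhat, pred$var_latent, pred$var_noise)
  p <- 2 * pnorm(-abs(Z))
  p[] <- pmax(p, .Machine$double.xmin)
  mask <- t(apply(Z, 1, npm_threshold, q = q))
  dimnames(mask) <- dimnames(Z)
  structure(list(Z = Z, p = p, mask = mask, q = q,
                 subjects = pred$subjects,
                 failed_vertices = pred$failed_vertices),
            class = "npm")
}

#' @export
print.npm <- function(x, ...) {
  cat("<npm>", nrow(x$Z), "subjects x", ncol(x$Z), "vertices; q =",
      x$q, "\n")
  cat("  subjects with >= 1 significant vertex:",
      sum(rowSums(abs(x$mask), na.rm = TRUE) > 0), "\n")
  invisible(x)
}

#' @rdname npm
#' @param x an `npm` object.
#' @param ... unused.
#' @export
tidy.npm <- function(x, ...) {
  tibble::tibble(
    subject_id = rep(rownames(x$Z), times = ncol(x$Z)),
    vertex = rep(seq_len(ncol(x$Z)) - 1L, each = nrow(x$Z)),
    z = as.numeric(x$Z),
    p = as.numeric(x$p),
    mask = as.integer(x$mask))
}

#' @rdname npm
#' @param object an `npm` object.
#' @export
glance.npm <- function(object, ...) {
  any_dev <- rowSums(abs(object$mask), na.rm = TRUE) > 0
  tibble::tibble(
    n_subjects = nrow(object$Z),
    n_vertices = ncol(object$Z),
    q = object$q,
    prop_subjects_with_deviation = mean(any_dev),
    mean_significant_vertices = mean(rowSums(abs(object$mask),
                                             na.rm = TRUE)))
}
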