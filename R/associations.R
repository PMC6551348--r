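#' Spearman rank correlation
#'
#' Mid-rank (average ranks for ties) Spearman correlation of two paired
#' vectors after dropping incomplete pairs. The p-value uses the
#' t-approximation for n >= 10 and exact permutation enumeration below
#' that.
#'
#' @param x,y paired numeric vectors.
#' @return tibble with `rho`, `p` and `n` (complete pairs); `rho` is
#'   `NA` when either rank vector is constant.
#' @export
spearman_cor <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n))
  }
  rho <- cor(rx, ry)
  p <- if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, 1e-300))
    2 * pt(-abs(tt), n - 2)
  } else {
    spearman_perm_p(rx, ry, rho)
  }
  tibble::tibble(rho = rho, p = min(p, 1), n = n)
}

# exact two-sided permutation p-value over all n! orderings of y
spearman_perm_p <- function(rx, ry, rho_obs) {
  perms <- all_permutations(length(ry))
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(n), pos)
      out[row, ] <- c(pos, rest[sub[r, ]])
      row <- row + 1
    }
  }
  out
}

#' Associate extreme deviation scores with symptom severity
#'
#' Spearman correlations between deviation scores and every symptom
#' score among ASD subjects, computed globally and per region, overall
#' and within each sex. Regional tests are corrected by
#' Benjamini-Hochberg within each (symptom, stratum) family across
#' regions; the global score is tested at the nominal level in its own
#' row. Subjects missing a symptom score are dropped only from that
#' score's entries (pairwise-complete), with the n used recorded per
#' cell.
#'
#' @param scores an [extreme_scores()] object.
#' @param cohort cohort tibble with symptom columns.
#' @param symptoms symptom column names (defaults to the six standard
#'   scores present in `cohort`).
#' @param q FDR level per regional family.
#' @param min_n smallest stratum size computed (entries below are
#'   returned with `NA` and flagged).
#' @return tibble of class `association_table`: `scope`, `symptom`,
#'   `stratum`, `rho`, `p`, `n`, `significant`, `family`.
#' @export
associate <- function(scores, cohort, symptoms = NULL, q = 0.05,
                      min_n = 3) {
  stopifnot(inherits(scores, "extreme_scores"))
  symptoms <- symptoms %||%
    intersect(c("adi_social", "adi_communication", "adi_rrb",
                "ados_total", "ados_social", "ados_rrb"), names(cohort))
  if (length(symptoms) == 0) abort("no symptom columns found")
  asd <- dplyr::filter(cohort, .data$group != "TD")
  if (nrow(asd) == 0) abort("no ASD subjects to associate")
  glob <- scores$global[match(asd$subject_id, scores$global$subject_id), ]
  reg_wide <- scores$regional |>
    tidyr::pivot_wider(names_from = "region", values_from = "score")
  reg_wide <- reg_wide[match(asd$subject_id, reg_wide$subject_id), ]
  regions <- setdiff(names(reg_wide), "subject_id")
  strata <- c(list(all = seq_len(nrow(asd))),
              split(seq_len(nrow(asd)), asd$sex))

  one <- function(score_vec, rows, symptom) {
    sy <- asd[[symptom]][rows]
    sc <- score_vec[rows]
    ok <- complete.cases(sc, sy)
    if (sum(ok) < min_n) {
      return(tibble::tibble(rho = NA_real_, p = NA_real_, n = sum(ok)))
    }
    spearman_cor(sc, sy)
  }

  rows <- purrr::imap(strata, function(idx, stratum) {
    purrr::map(symptoms, function(sym) {
      g <- one(glob$score, idx, sym) |>
        dplyr::mutate(scope = "global", symptom = sym, stratum = stratum)
      r <- purrr::map(regions, function(rg) {
        one(reg_wide[[rg]], idx, sym) |>
          dplyr::mutate(scope = rg, symptom = sym, stratum = stratum)
      }) |> dplyr::bind_rows()
      dplyr::bind_rows(g, r)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  rows <- rows |>
    dplyr::mutate(family = dplyr::if_else(
      .data$scope == "global", "global",
      paste(.data$symptom, .data$stratum, sep = ":"))) |>
    dplyr::group_by(.data$family) |>
    dplyr::mutate(significant = dplyr::case_when(
      is.na(.data$p) ~ FALSE,
      .data$scope == "global" ~ .data$p < 0.05,
      TRUE ~ bh_fdr(pmax(.data$p, .Machine$double.xmin), q))) |>
    dplyr::ungroup() |>
    dplyr::select("scope", "symptom", "stratum", "rho", "p", "n",
                  "significant", "family")
  class(rows) <- c("association_table", class(rows))
  attr(rows, "q") <- q
  rows
}

#' Post hoc confound associations
#'
#' Descriptive (uncorrected) Spearman associations between each
#' subject's global extreme deviation score and potential confounds
#' (IQ, the surface-quality surrogate), per cohort. These are post hoc
#' checks, reported without multiplicity correction.
#'
#' @param scores an [extreme_scores()] object.
#' @param cohort cohort tibble.
#' @param confounds confound column names present in `cohort`.
#' @return tibble: `confound`, `group`, `rho`, `p`, `n`, `post_hoc`.
#' @export
confound_checks <- function(scores, cohort,
                            confounds = c("iq", "quality_surrogate")) {
  confounds <- intersect(confounds, names(cohort))
  glob <- scores$global
  out <- purrr::map(confounds, function(cf) {
    purrr::map(unique(cohort$group), function(g) {
      rows <- which(cohort$group == g)
      sc <- glob$score[match(cohort$subject_id[rows],
                             glob$subject_id)]
      cv <- cohort[[cf]][rows]
      ok <- complete.cases(sc, cv)
      if (sum(ok) < 3 || sd(rank(cv[ok])) == 0) {
        return(tibble::tibble(confound = cf, group = g, rho = NA_real_,
                              p = NA_real_, n = sum(ok)))
      }
      s <- spearman_cor(sc, cv)
      tibble::tibble(confound = cf, group = g, rho = s$rho, p = s$p,
                     n = s$n)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  if (nrow(out) > 0) out$post_hoc <- TRUE
  out
}
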