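#' Overlap maps of individual deviations
#'
#' Counts, at every vertex, how many subjects of each cohort (and of
#' each schedule within cohort) carry an FDR-significant deviation of
#' each sign, and summarises the proportion of subjects contributing at
#' least one significant vertex to each map. This is the cohort-level
#' view of individualized deviations: unlike a group contrast, the
#' deviations counted here need not overlap across subjects.
#'
#' @param x an [npm()] object, or a signed mask matrix.
#' @param group cohort labels per subject (taken from `x$subjects` when
#'   `x` is an `npm`).
#' @param schedule optional schedule labels per subject.
#' @return object of class `overlap_map` with tibbles `counts` (vertex
#'   x group x schedule x sign) and `contributors` (per-map subject
#'   proportions).
#' @export
overlap_map <- function(x, group = NULL, schedule = NULL) {
  if (inherits(x, "npm")) {
    mask <- x$mask
    group <- group %||% x$subjects$group
    schedule <- schedule %||% x$subjects$schedule
  } else {
    mask <- as.matrix(x)
  }
  if (is.null(group)) abort("group labels are required")
  if (length(group) != nrow(mask)) {
    abort("group labels must match the mask rows")
  }
  if (!is.null(schedule) && length(schedule) != nrow(mask)) {
    abort("schedule labels must match the mask rows")
  }
  strata <- list()
  for (g in unique(group)) {
    strata[[paste(g, "all", sep = "|")]] <- which(group == g)
    if (!is.null(schedule)) {
      for (s in unique(schedule[group == g])) {
        strata[[paste(g, s, sep = "|")]] <- which(group == g & schedule == s)
      }
    }
  }
  counts <- purrr::imap(strata, function(rows, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- mask[rows, , drop = FALSE]
    tibble::tibble(
      vertex = rep(seq_len(ncol(mask)) - 1L, 2),
      group = parts[1], schedule = parts[2],
      sign = rep(c("positive", "negative"), each = ncol(mask)),
      count = c(colSums(m == 1, na.rm = TRUE),
                colSums(m == -1, na.rm = TRUE)))
  }) |> dplyr::bind_rows()
  contributors <- purrr::imap(strata, function(rows, key) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    m <- mask[rows, , drop = FALSE]
    tibble::tibble(
      group = parts[1], schedule = parts[2], n_subjects = length(rows),
      n_with_deviation = sum(rowSums(abs(m), na.rm = TRUE) > 0),
      proportion = ifelse(length(rows) == 0, 0,
                          sum(rowSums(abs(m), na.rm = TRUE) > 0) /
                            length(rows)))
  }) |> dplyr::bind_rows()
  structure(list(counts = counts, contributors = contributors),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat("<overlap_map>\n")
  print(x$contributors)
  invisible(x)
}

#' @rdname overlap_map
#' @param ... unused.
#' @export
tidy.overlap_map <- function(x, ...) x$counts

#' Mass-univariate case-control contrast
#'
#' The classical vertexwise general linear model: ordinary least
#' squares of each vertex's measurement on diagnosis, (centered) age
#' polynomial terms and optionally sex, with a t-test on the diagnosis
#' coefficient (or the age-by-diagnosis interaction) and
#' Benjamini-Hochberg correction across vertices. Optionally fit
#' separately within each sex.
#'
#' @param measures a [measure_matrix()] or subjects-by-vertices matrix.
#' @param cohort cohort tibble aligned with `measures`; `group` codes
#'   diagnosis (`TD` reference).
#' @param age_powers subset of `c(1, 2, 3)`: age polynomial terms
#'   (centered age).
#' @param include_sex include a sex covariate in the pooled model.
#' @param stratify_by_sex fit male and female subjects separately.
#' @param interaction test the age-by-diagnosis interaction instead of
#'   the diagnosis main effect.
#' @param q FDR level across vertices (per stratum).
#' @return tibble of class `glm_result`: `vertex`, `stratum`,
#'   `estimate` (mm), `t`, `p`, `significant`, plus a model descriptor
#'   attribute.
#' @export
glm_case_control <- function(measures, cohort, age_powers = 1,
                             include_sex = TRUE, stratify_by_sex = FALSE,
                             interaction = FALSE, q = 0.05) {
  Y <- if (inherits(measures, "measure_matrix")) measures$values else
    as.matrix(measures)
  if (nrow(Y) != nrow(cohort)) abort("cohort rows must align with measures")
  if (!all(age_powers %in% 1:3)) abort("age_powers must be within 1:3")
  if (interaction && !(1 %in% age_powers)) {
    abort("the interaction model needs the linear age term")
  }
  strata <- if (stratify_by_sex) {
    split(seq_len(nrow(cohort)), cohort$sex)
  } else {
    list(all = seq_len(nrow(cohort)))
  }
  res <- purrr::imap(strata, function(rows, label) {
    co <- cohort[rows, , drop = FALSE]
    dx <- as.numeric(co$group != "TD")
    age_c <- co$age - mean(co$age)
    X <- cbind(`(Intercept)` = 1, diagnosis = dx)
    for (p in sort(age_powers)) {
      X <- cbind(X, setNames(list(age_c^p), paste0("age", p))[[1]])
      colnames(X)[ncol(X)] <- paste0("age", p)
    }
    if (include_sex && !stratify_by_sex && length(unique(co$sex)) > 1) {
      X <- cbind(X, sex_male = as.numeric(co$sex == "male"))
    }
    if (interaction) X <- cbind(X, `diagnosis:age` = dx * age_c)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) {
      bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
      abort(paste0("design is rank deficient; collinear columns: ",
                   paste(bad, collapse = ", ")))
    }
    term <- if (interaction) "diagnosis:age" else "diagnosis"
    n <- nrow(X)
    df <- n - ncol(X)
    beta <- qr.coef(qrX, Y[rows, , drop = FALSE])
    resid <- Y[rows, , drop = FALSE] - X %*% beta
    sigma2 <- colSums(resid^2) / df
    j <- which(colnames(X) == term)
    xtxinv_jj <- chol2inv(chol(crossprod(X)))[j, j]
    est <- beta[term, ]
    se <- sqrt(sigma2 * xtxinv_jj)
    tstat <- est / se
    pval <- 2 * pt(-abs(tstat), df)
    tibble::tibble(vertex = seq_len(ncol(Y)) - 1L, stratum = label,
                   estimate = unname(est), t = unname(tstat),
                   p = unname(pval), df = df,
                   significant = bh_fdr(pmax(pval, .Machine$double.xmin), q))
  }) |> dplyr::bind_rows()
  class(res) <- c("glm_result", class(res))
  attr(res, "model") <- list(age_powers = age_powers,
                             include_sex = include_sex,
                             stratify_by_sex = stratify_by_sex,
                             interaction = interaction, q = q)
  res
}

#' @rdname glm_case_control
#' @param object a `glm_result`.
#' @param ... unused.
#' @export
glance.glm_result <- function(object, ...) {
  object |>
    dplyr::group_by(.data$stratum) |>
    dplyr::summarise(n_vertices = dplyr::n(),
                     n_significant = sum(.data$significant),
                     prop_significant = mean(.data$significant),
                     .groups = "drop")
}
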