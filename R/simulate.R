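#' Simulate cohort demographics
#'
#' Draws the demographic table for a synthetic cross-sectional cohort:
#' group, sex, age, study schedule, IQ, site and a surface-quality
#' surrogate. Group sizes, male counts and schedule counts are applied
#' as exact counts (largest-remainder rounding of the configured
#' proportions) so repeated draws differ only in the continuous
#' variables. Ages are uniform within each schedule's window; schedule D
#' is the only stratum with IQ < 70. Symptom columns are created empty
#' and filled later by [simulate_symptoms()].
#'
#' @param config a [sim_config()] object.
#' @return tibble with one row per subject (TD block first); columns
#'   `subject_id`, `group`, `sex`, `age`, `schedule`, `iq`, `site`,
#'   `quality_surrogate` and the six symptom scores (all `NA`).
#' @export
simulate_demographics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(stage_seed(config$seed, "demographics"), {
    groups <- list(td = config$n_td, asd = config$n_asd)
    rows <- purrr::imap(groups, function(n, g) {
      if (n == 0) return(NULL)
      sched_n <- exact_counts(config$schedule_probs[[g]], n)
      if (sched_n[["D"]] > 0 && g == "td") {
        # D is defined by IQ < 70; a TD stratum there is a config error
        abort("schedule D requested for the TD group, which has no IQ < 70 stratum")
      }
      schedule <- rep(names(sched_n), sched_n)
      age <- purrr::map_dbl(schedule, function(s) {
        w <- config$age_windows[[s]]
        runif(1, w[1], w[2])
      })
      n_male <- round(config$male_fraction[[g]] * n)
      sex <- rep("female", n)
      sex[sample.int(n, n_male)] <- "male"
      iq <- purrr::map_dbl(schedule, function(s) {
        if (s == "D") return(runif(1, 50, 70))
        rtruncnorm_low(1, config$iq_mean[[g]], config$iq_sd[[g]], 70)
      })
      tibble::tibble(
        group = ifelse(g == "td", "TD", "ASD"),
        sex = sex, age = age, schedule = schedule, iq = iq,
        site = paste0("site", sample.int(config$n_sites, n, replace = TRUE)),
        quality_surrogate = rnorm(n))
    })
    demo <- dplyr::bind_rows(rows)
    demo$subject_id <- sprintf("sub-%04d", seq_len(nrow(demo)))
    # missing IQ only among ASD subjects outside schedule D
    idx <- which(demo$group == "ASD" & demo$schedule != "D")
    k <- min(config$n_missing_iq, length(idx))
    if (k > 0) demo$iq[sample(idx, k)] <- NA_real_
    for (s in config$symptom_targets$score) demo[[s]] <- NA_real_
    dplyr::relocate(demo, "subject_id")
  })
}

# largest-remainder apportionment of n among named proportions
exact_counts <- function(probs, n) {
  raw <- probs * n
  cnt <- floor(raw)
  left <- n - sum(cnt)
  if (left > 0) {
    ord <- order(raw - cnt, decreasing = TRUE)
    cnt[ord[seq_len(left)]] <- cnt[ord[seq_len(left)]] + 1
  }
  setNames(as.integer(cnt), names(probs))
}

rtruncnorm_low <- function(n, mean, sd, lower) {
  u <- runif(n, pnorm(lower, mean, sd), 1)
  qnorm(pmin(u, 1 - 1e-12), mean, sd)
}

#' Simulate vertexwise measurements, parcellation and ground truth
#'
#' Generates the subjects-by-vertices thickness matrix. Every subject's
#' expected value at vertex v follows the configured trajectory
#' polynomial `intercept + linear*age + quadratic*age^2` plus the sex
#' offset for males, with independent Gaussian noise per vertex. A
#' deterministic subset of ASD subjects (exactly
#' `round(prevalence * n_asd)` of them) additionally carries planted
#' deviations: whole contiguous parcels shifted by a magnitude drawn
#' once per subject-region (in local noise-SD units), signed by the
#' subject's schedule. All planted effects are recorded in the returned
#' ground truth.
#'
#' @param demo demographics tibble from [simulate_demographics()].
#' @param config the [sim_config()] that produced `demo`.
#' @return list with elements `measures` (a `measure_matrix`),
#'   `parcellation` (tibble `vertex`, `region`) and `truth` (class
#'   `ground_truth`).
#' @export
simulate_measurements <- function(demo, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(demo) != config$n_td + config$n_asd) {
    abort("demographics table size does not match config")
  }
  tr <- config$trajectories
  V <- config$n_vertices
  n <- nrow(demo)
  male <- as.numeric(demo$sex == "male")
  basis <- cbind(1, demo$age, demo$age^2, male)
  mu <- basis %*% t(cbind(tr$intercept, tr$linear, tr$quadratic,
                          tr$sex_offset))
  noise <- withr::with_seed(stage_seed(config$seed, "measurements"), {
    matrix(rnorm(n * V), n, V) %*% diag(tr$noise_sd, V)
  })
  values <- mu + noise

  parcellation <- make_parcellation(V, config$n_regions)
  region_vertices <- split(seq_len(V), parcellation$region)

  mask <- matrix(0L, n, V)
  delta_mm <- matrix(0, n, V)
  planted <- tibble::tibble(subject_id = character(), region = character(),
                            magnitude = numeric(), sign = integer())
  asd_idx <- which(demo$group == "ASD")
  n_carriers <- round(config$deviation_prevalence * length(asd_idx))
  if (n_carriers > 0) {
    withr::with_seed(stage_seed(config$seed, "deviations"), {
      carriers <- sort(sample(asd_idx, n_carriers))
      recs <- purrr::map(carriers, function(i) {
        regs <- sample(names(region_vertices), config$deviation_extent)
        mag <- rnorm(config$deviation_extent,
                     config$deviation_magnitude_mean,
                     config$deviation_magnitude_sd)
        sgn <- if (config$deviation_sign[[demo$schedule[i]]] == "positive")
          1L else -1L
        tibble::tibble(subject_id = demo$subject_id[i], region = regs,
                       magnitude = mag, sign = sgn)
      })
      planted <- dplyr::bind_rows(recs)
    })
    row_of <- setNames(seq_len(n), demo$subject_id)
    for (k in seq_len(nrow(planted))) {
      i <- row_of[[planted$subject_id[k]]]
      vs <- region_vertices[[planted$region[k]]]
      mask[i, vs] <- planted$sign[k]
      delta_mm[i, vs] <- planted$sign[k] * planted$magnitude[k] *
        tr$noise_sd[vs]
    }
    values <- values + delta_mm
  }

  subject_summary <- demo |>
    dplyr::select("subject_id", "group", "schedule") |>
    dplyr::left_join(
      planted |>
        dplyr::group_by(.data$subject_id) |>
        dplyr::summarise(magnitude = mean(abs(.data$magnitude)),
                         .groups = "drop"),
      by = "subject_id") |>
    dplyr::mutate(magnitude = dplyr::coalesce(.data$magnitude, 0),
                  carrier = .data$magnitude > 0)

  truth <- structure(
    list(mask = mask, delta_mm = delta_mm, planted = planted,
         subject = subject_summary, trajectories = tr, seed = config$seed),
    class = "ground_truth")

  list(measures = measure_matrix(values, demo$subject_id, "thickness"),
       parcellation = parcellation, truth = truth)
}

#' Construct a measurement matrix object
#'
#' @param values numeric subjects-by-vertices matrix (mm or mm^2).
#' @param subject_ids row identifiers.
#' @param measure `"thickness"` or `"area"`.
#' @return object of class `measure_matrix`.
#' @export
measure_matrix <- function(values, subject_ids = rownames(values),
                           measure = c("thickness", "area")) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (!all(is.finite(values))) abort("measurements must be finite")
  if (is.null(subject_ids)) abort("subject ids are required")
  rownames(values) <- subject_ids
  colnames(values) <- paste0("v", seq_len(ncol(values)) - 1L)
  structure(list(values = values,
                 vertex_ids = seq_len(ncol(values)) - 1L,
                 measure = measure),
            class = "measure_matrix")
}

#' @export
print.measure_matrix <- function(x, ...) {
  cat("<measure_matrix>", nrow(x$values), "subjects x", ncol(x$values),
      "vertices (", x$measure, ")\n")
  invisible(x)
}

make_parcellation <- function(n_vertices, n_regions) {
  sizes <- exact_counts(rep(1 / n_regions, n_regions), n_vertices)
  tibble::tibble(
    vertex = seq_len(n_vertices) - 1L,
    region = rep(sprintf("R%02d", seq_len(n_regions)), sizes))
}

#' Simulate symptom scores linked to planted deviations
#'
#' Fills the ASD symptom columns. Each score is built from a
#' rank-preserving Gaussian-copula link with the subject's planted
#' deviation magnitude: the latent correlation is calibrated (by solving
#' the closed-form expected Spearman correlation given the realized tied
#' ranks) so that the population Spearman correlation between magnitude
#' and score matches the configured target, then the latent values are
#' rescaled to the configured mean and SD. Whole instruments are blanked
#' for the configured numbers of subjects, and every TD entry stays
#' missing.
#'
#' @param demo demographics tibble.
#' @param truth `ground_truth` from [simulate_measurements()].
#' @param config the originating [sim_config()].
#' @return `demo` with symptom columns filled for ASD subjects.
#' @export
simulate_symptoms <- function(demo, truth, config) {
  stopifnot(inherits(config, "sim_config"), inherits(truth, "ground_truth"))
  st <- config$symptom_targets
  if (any(abs(st$link) > 1)) abort("symptom link strengths must lie in [-1, 1]")
  asd <- which(demo$group == "ASD")
  if (length(asd) == 0) return(demo)
  mag <- truth$subject$magnitude[match(demo$subject_id[asd],
                                       truth$subject$subject_id)]
  if (anyNA(mag)) abort("ground truth does not cover every ASD subject")
  n <- length(asd)
  withr::with_seed(stage_seed(config$seed, "symptoms"), {
    rm_ <- rank(mag, ties.method = "average")
    zt <- qnorm((rm_ - 0.5) / n)
    zt <- if (sd(zt) > 0) (zt - mean(zt)) / sd(zt) else rep(0, n)
    for (k in seq_len(nrow(st))) {
      target <- st$link[k]
      r <- if (sd(zt) == 0 || target == 0) 0 else
        calibrate_copula_r(zt, rm_, target)
      eps <- rnorm(n)
      lat <- r * zt + sqrt(1 - r^2) * eps
      lat <- if (sd(lat) > 0) (lat - mean(lat)) / sd(lat) else lat
      demo[[st$score[k]]][asd] <- st$mean[k] + st$sd[k] * lat
    }
    drop_adi <- sample(asd, min(config$n_missing_adi, n))
    drop_ados <- sample(asd, min(config$n_missing_ados, n))
    for (s in st$score[st$instrument == "adi"]) demo[[s]][drop_adi] <- NA_real_
    for (s in st$score[st$instrument == "ados"]) demo[[s]][drop_ados] <- NA_real_
  })
  demo
}

# Expected Spearman correlation between the (tied) magnitudes and a
# latent score s = r*zt + sqrt(1-r^2)*eps, computed exactly from
# E[rank(s_i)] = 1 + sum_j Phi(r (zt_i - zt_j) / sqrt(2(1 - r^2))).
expected_spearman <- function(zt, rm_, r) {
  n <- length(zt)
  if (abs(r) >= 1) r <- sign(r) * 0.999999
  dz <- outer(zt, zt, "-")
  P <- pnorm(r * dz / sqrt(2 * (1 - r^2)))
  erank <- 1 + (rowSums(P) - 0.5)  # remove the i = j term (Phi(0))
  num <- sum((rm_ - mean(rm_)) * (erank - (n + 1) / 2))
  den <- sd(rm_) * sqrt(n - 1) * sqrt(n * (n^2 - 1) / 12)
  num / den
}

calibrate_copula_r <- function(zt, rm_, target) {
  f <- function(r) expected_spearman(zt, rm_, r) - target
  lo <- -0.9999; hi <- 0.9999
  flo <- f(lo); fhi <- f(hi)
  if (flo > 0) return(lo)   # target below the achievable range
  if (fhi < 0) return(hi)   # target above the achievable range
  uniroot(f, c(lo, hi), tol = 1e-4)$root
}

#' Simulate a complete synthetic cohort
#'
#' Runs [simulate_demographics()], [simulate_measurements()] and
#' [simulate_symptoms()] under one configuration.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_cohort` with elements `cohort`,
#'   `measures`, `parcellation`, `truth` and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  demo <- simulate_demographics(config)
  meas <- simulate_measurements(demo, config)
  cohort <- simulate_symptoms(demo, meas$truth, config)
  structure(list(cohort = cohort, measures = meas$measures,
                 parcellation = meas$parcellation, truth = meas$truth,
                 config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  print(x$config)
  cat("  cohort:", nrow(x$cohort), "subjects;",
      sum(x$truth$subject$carrier), "deviation carriers\n")
  invisible(x)
}
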