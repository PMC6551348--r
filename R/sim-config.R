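#' Simulation configuration for a synthetic cross-sectional cohort
#'
#' Bundles every parameter of the synthetic-cohort generator. The
#' defaults emulate the statistical structure of a heterogeneous
#' cross-sectional autism study: 206 typically developing (TD) subjects
#' (127 male) and 321 autistic (ASD) subjects (232 male) aged 6-31,
#' stratified into four schedules (A adults 18-30, B adolescents 12-17,
#' C children 6-11, D adolescents/adults with IQ < 70), cortical
#' thickness declining approximately linearly with age at most vertices
#' with an inverted-U trajectory at a minority, a small sex offset,
#' per-vertex Gaussian noise, and sparse subject-specific deviations in
#' the ASD group whose sign depends on the schedule (negative in
#' children, positive in adolescents/adults) and whose magnitude drives
#' symptom scores through a rank-preserving Gaussian-copula link.
#'
#' Per-vertex trajectory coefficients, sex offsets and noise SDs are
#' drawn deterministically from `seed` when the configuration is built,
#' so a config object fully determines the cohort.
#'
#' @param n_td,n_asd group sizes.
#' @param male_fraction named vector of male proportions per group.
#' @param schedule_probs list of per-group schedule probabilities over
#'   `c(A, B, C, D)`; converted to exact counts.
#' @param age_windows list mapping schedule to `c(min, max)` age in
#'   years.
#' @param iq_mean,iq_sd named per-group IQ moments (schedules A-C,
#'   truncated at 70); schedule D draws IQ uniformly in \[50, 70).
#' @param n_missing_iq number of ASD subjects (schedules A-C) with
#'   missing IQ.
#' @param n_sites number of acquisition sites.
#' @param n_vertices,n_regions synthetic cortical geometry; regions are
#'   contiguous equal-sized vertex blocks.
#' @param frac_inverted_u fraction of vertices given an inverted-U
#'   (negative-quadratic) age trajectory instead of a linear decline.
#' @param intercept_mean,intercept_sd,slope_mean,slope_sd linear-vertex
#'   trajectory coefficient distributions (mm, mm/year).
#' @param peak_age_range,peak_value_mean,peak_value_sd,quad_range
#'   inverted-U vertex parameters: peak age window (years), thickness at
#'   the peak (mm), and the magnitude range of the negative quadratic
#'   coefficient (mm/year^2).
#' @param sex_offset_mean,sex_offset_sd per-vertex male-minus-female
#'   offset distribution (mm).
#' @param noise_sd_range per-vertex residual SD range (mm).
#' @param deviation_prevalence proportion of ASD subjects carrying
#'   planted deviations (applied as an exact count).
#' @param deviation_extent number of regions affected per carrier.
#' @param deviation_magnitude_mean,deviation_magnitude_sd magnitude of
#'   each planted subject-region deviation, in units of the local noise
#'   SD.
#' @param deviation_sign named map schedule -> `"positive"`/`"negative"`.
#' @param symptom_targets tibble of symptom-score definitions: `score`,
#'   `instrument`, target `mean`, `sd` and Spearman `link` with the
#'   planted deviation magnitude.
#' @param n_missing_adi,n_missing_ados ASD subjects missing each
#'   instrument entirely.
#' @param seed integer master seed.
#' @return object of class `sim_config` (a validated list, including a
#'   `trajectories` tibble of per-vertex coefficients).
#' @export
sim_config <- function(n_td = 206,
                       n_asd = 321,
                       male_fraction = c(td = 127 / 206, asd = 232 / 321),
                       schedule_probs = list(
                         td = c(A = 84, B = 70, C = 52, D = 0) / 206,
                         asd = c(A = 125, B = 112, C = 64, D = 20) / 321),
                       age_windows = list(A = c(18, 30), B = c(12, 17),
                                          C = c(6, 11), D = c(12, 30)),
                       iq_mean = c(td = 108.22, asd = 100.89),
                       iq_sd = c(td = 14.24, asd = 18.53),
                       n_missing_iq = 5,
                       n_sites = 6,
                       n_vertices = 1000,
                       n_regions = 34,
                       frac_inverted_u = 0.2,
                       intercept_mean = 3.0, intercept_sd = 0.2,
                       slope_mean = -0.02, slope_sd = 0.007,
                       peak_age_range = c(8, 14),
                       peak_value_mean = 2.9, peak_value_sd = 0.2,
                       quad_range = c(0.001, 0.003),
                       sex_offset_mean = 0.05, sex_offset_sd = 0.02,
                       noise_sd_range = c(0.15, 0.25),
                       deviation_prevalence = 0.4,
                       deviation_extent = 2,
                       deviation_magnitude_mean = 4,
                       deviation_magnitude_sd = 0.5,
                       deviation_sign = c(A = "positive", B = "positive",
                                          C = "negative", D = "positive"),
                       symptom_targets = default_symptom_targets(),
                       n_missing_adi = 13,
                       n_missing_ados = 63,
                       seed = 1) {
  cfg <- list(
    n_td = n_td, n_asd = n_asd, male_fraction = male_fraction,
    schedule_probs = schedule_probs, age_windows = age_windows,
    iq_mean = iq_mean, iq_sd = iq_sd, n_missing_iq = n_missing_iq,
    n_sites = n_sites, n_vertices = n_vertices, n_regions = n_regions,
    frac_inverted_u = frac_inverted_u,
    intercept_mean = intercept_mean, intercept_sd = intercept_sd,
    slope_mean = slope_mean, slope_sd = slope_sd,
    peak_age_range = peak_age_range, peak_value_mean = peak_value_mean,
    peak_value_sd = peak_value_sd, quad_range = quad_range,
    sex_offset_mean = sex_offset_mean, sex_offset_sd = sex_offset_sd,
    noise_sd_range = noise_sd_range,
    deviation_prevalence = deviation_prevalence,
    deviation_extent = deviation_extent,
    deviation_magnitude_mean = deviation_magnitude_mean,
    deviation_magnitude_sd = deviation_magnitude_sd,
    deviation_sign = deviation_sign,
    symptom_targets = symptom_targets,
    n_missing_adi = n_missing_adi, n_missing_ados = n_missing_ados,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  cfg$trajectories <- draw_trajectories(cfg)
  structure(cfg, class = "sim_config")
}

#' @rdname sim_config
#' @export
default_symptom_targets <- function() {
  tibble::tribble(
    ~score,              ~instrument, ~mean, ~sd,  ~link,
    "adi_social",        "adi",       16.20, 6.71, -0.10,
    "adi_communication", "adi",       13.11, 5.69, -0.10,
    "adi_rrb",           "adi",        4.32, 2.69, -0.15,
    "ados_total",        "ados",       5.12, 2.77, -0.10,
    "ados_social",       "ados",       5.78, 2.62, -0.10,
    "ados_rrb",          "ados",       4.78, 2.76, -0.21)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_td >= 0, cfg$n_asd >= 0, cfg$n_td + cfg$n_asd > 0)
  if (cfg$n_vertices < 1 || cfg$n_regions < 1) {
    abort("n_vertices and n_regions must be positive")
  }
  if (cfg$n_regions > cfg$n_vertices) {
    abort("n_regions must not exceed n_vertices")
  }
  if (any(cfg$male_fraction < 0) || any(cfg$male_fraction > 1)) {
    abort("male_fraction must lie in [0, 1]")
  }
  for (g in names(cfg$schedule_probs)) {
    p <- cfg$schedule_probs[[g]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(sprintf("schedule_probs$%s must be nonnegative and sum to 1", g))
    }
    if (!identical(names(p), c("A", "B", "C", "D"))) {
      abort("schedule_probs must be named A, B, C, D")
    }
  }
  for (w in cfg$age_windows) {
    if (w[1] >= w[2]) abort("each age window needs min < max")
  }
  if (cfg$deviation_prevalence < 0 || cfg$deviation_prevalence > 1) {
    abort("deviation_prevalence must lie in [0, 1]")
  }
  if (cfg$deviation_extent < 1 || cfg$deviation_extent > cfg$n_regions) {
    abort("deviation_extent must lie in [1, n_regions]")
  }
  if (any(cfg$noise_sd_range <= 0)) abort("noise_sd_range must be positive")
  if (!all(cfg$deviation_sign %in% c("positive", "negative"))) {
    abort("deviation_sign values must be 'positive' or 'negative'")
  }
  st <- cfg$symptom_targets
  if (any(abs(st$link) > 1)) {
    abort("symptom link strengths must lie in [-1, 1]")
  }
  invisible(cfg)
}

# Per-vertex trajectory coefficients CT(age) = b0 + b1 age + b2 age^2
# (+ sex offset for males), drawn once from the config seed.
draw_trajectories <- function(cfg) {
  withr::with_seed(stage_seed(cfg$seed, "trajectories"), {
    V <- cfg$n_vertices
    inv_u <- seq_len(V) <= round(cfg$frac_inverted_u * V)
    b0 <- rnorm(V, cfg$intercept_mean, cfg$intercept_sd)
    b1 <- rnorm(V, cfg$slope_mean, cfg$slope_sd)
    b2 <- rep(0, V)
    if (any(inv_u)) {
      k <- sum(inv_u)
      peak <- runif(k, cfg$peak_age_range[1], cfg$peak_age_range[2])
      q <- -runif(k, cfg$quad_range[1], cfg$quad_range[2])
      pv <- rnorm(k, cfg$peak_value_mean, cfg$peak_value_sd)
      b2[inv_u] <- q
      b1[inv_u] <- -2 * q * peak          # vertex peaks at `peak`
      b0[inv_u] <- pv - b1[inv_u] * peak - q * peak^2
    }
    tibble::tibble(
      vertex = seq_len(V) - 1L,
      intercept = b0, linear = b1, quadratic = b2,
      sex_offset = rnorm(V, cfg$sex_offset_mean, cfg$sex_offset_sd),
      noise_sd = runif(V, cfg$noise_sd_range[1], cfg$noise_sd_range[2]),
      inverted_u = inv_u)
  })
}

# Deterministic per-stage substream of the master seed (kept < 2^31).
stage_seed <- function(seed, stage) {
  offs <- c(trajectories = 11L, demographics = 23L, measurements = 37L,
            deviations = 41L, symptoms = 53L, folds = 67L, fit = 71L,
            analysis = 83L)
  if (!stage %in% names(offs)) abort(paste("unknown stage:", stage))
  as.integer((as.double(seed) * 97L + offs[[stage]]) %% 2147483647)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_td, "TD +", x$n_asd, "ASD;",
      x$n_vertices, "vertices /", x$n_regions, "regions; seed", x$seed, "\n")
  cat("  deviation prevalence", x$deviation_prevalence, "| extent",
      x$deviation_extent, "regions | magnitude",
      x$deviation_magnitude_mean, "SD\n")
  invisible(x)
}
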