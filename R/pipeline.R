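#' Pipeline run configuration
#'
#' Gathers every stage parameter of an end-to-end run with defaults
#' matching the analysis design: 10-fold cross-validation, FDR level
#' 0.05 at every corrected stage, trimmed top fraction 0.01, top-15
#' enrichment test.
#'
#' @param sim a [sim_config()] to simulate inputs, or `NULL` when
#'   loading from files.
#' @param cohort_path,measures_path,parcellation_path input files (used
#'   when `sim` is `NULL`).
#' @param covariates covariate set for the normative model.
#' @param folds cross-validation folds.
#' @param q_fit,q_npm,q_glm,q_assoc FDR levels for model evaluation,
#'   within-subject deviation maps, the case-control GLM and the
#'   regional symptom associations.
#' @param fraction trimmed top fraction for extreme scores.
#' @param top_k size of the extreme top set.
#' @param null null model for the top-k membership test.
#' @param restarts optimizer initializations per vertex fit.
#' @param stratify_sex stratify CV folds by sex.
#' @param age_powers age polynomial for the GLM.
#' @param seed master seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), cohort_path = NULL,
                       measures_path = NULL, parcellation_path = NULL,
                       covariates = c("age", "sex"), folds = 10,
                       q_fit = 0.05, q_npm = 0.05, q_glm = 0.05,
                       q_assoc = 0.05, fraction = 0.01, top_k = 15,
                       null = "hypergeometric", restarts = 3,
                       stratify_sex = FALSE, age_powers = 1, seed = 1) {
  if (is.null(sim) &&
      (is.null(cohort_path) || is.null(measures_path) ||
       is.null(parcellation_path))) {
    abort("provide either a sim config or all three input paths")
  }
  structure(list(sim = sim, cohort_path = cohort_path,
                 measures_path = measures_path,
                 parcellation_path = parcellation_path,
                 covariates = covariates, folds = folds, q_fit = q_fit,
                 q_npm = q_npm, q_glm = q_glm, q_assoc = q_assoc,
                 fraction = fraction, top_k = top_k, null = null,
                 restarts = restarts, stratify_sex = stratify_sex,
                 age_powers = age_powers, seed = as.integer(seed)),
            class = "run_config")
}

#' Run the full deviation-mapping pipeline
#'
#' Executes, in order: cohort simulation (or loading), the vertexwise
#' normative fit with out-of-fold reference predictions, model
#' evaluation, normative probability maps, deviation overlap maps and
#' the case-control GLM, extreme-value scoring (Gumbel fits per cohort
#' and the top-k membership test), symptom associations and confound
#' checks. Identical configurations produce identical outputs.
#'
#' @param config a [run_config()].
#' @param out_dir optional directory; when given, every stage output is
#'   written as TSV with seed and configuration hash in its header,
#'   plus a `manifest.yaml`.
#' @param verbose log stage progress to stderr.
#' @return object of class `normdev_run` with each stage's result and
#'   the manifest.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (verbose) message("[normdev] ", ...)
  t0 <- Sys.time()

  say("stage 1/6: inputs")
  if (!is.null(config$sim)) {
    sim <- simulate_cohort(config$sim)
    cohort <- sim$cohort
    measures <- sim$measures
    parcellation <- sim$parcellation
    truth <- sim$truth
  } else {
    cohort <- load_cohort(config$cohort_path)
    measures <- load_measure_matrix(config$measures_path)
    parcellation <- load_parcellation(config$parcellation_path)
    truth <- NULL
  }

  say("stage 2/6: normative model (", config$folds, "-fold CV, ",
      ncol(measures$values), " vertices)")
  pred <- normative_model(cohort, measures, covariates = config$covariates,
                          folds = config$folds, seed = config$seed,
                          restarts = config$restarts,
                          stratify_sex = config$stratify_sex,
                          verbose = verbose)
  fit_eval <- evaluate_fit(pred, measures, q = config$q_fit)

  say("stage 3/6: normative probability maps")
  maps <- npm(pred, measures, q = config$q_npm)

  say("stage 4/6: overlap maps and case-control GLM")
  overlap <- overlap_map(maps)
  glm_res <- glm_case_control(measures, cohort,
                              age_powers = config$age_powers,
                              q = config$q_glm)

  say("stage 5/6: extreme-value scores")
  scores <- extreme_scores(maps, parcellation, fraction = config$fraction)
  gumbel <- list()
  for (g in unique(cohort$group)) {
    sc <- scores$global$score[scores$global$group == g]
    gumbel[[g]] <- tryCatch(fit_gumbel(sc), error = function(e) NULL)
  }
  topk <- topk_membership_test(scores$global$score, cohort$group,
                               k = min(config$top_k, nrow(cohort)),
                               null = config$null)

  say("stage 6/6: symptom associations")
  assoc <- tryCatch(associate(scores, cohort, q = config$q_assoc),
                    error = function(e) NULL)
  confounds <- tryCatch(confound_checks(scores, cohort),
                        error = function(e) NULL)

  manifest <- list(
    seed = config$seed,
    config_hash = unname(hash(config)),
    package_version = pkg_version(),
    n_subjects = nrow(cohort),
    n_td = sum(cohort$group == "TD"),
    n_asd = sum(cohort$group != "TD"),
    n_vertices = ncol(measures$values),
    n_regions = length(unique(parcellation$region)),
    folds = config$folds,
    failed_vertices = sum(pred$failed_vertices),
    glm_significant = sum(glm_res$significant),
    subjects_with_deviation =
      sum(rowSums(abs(maps$mask), na.rm = TRUE) > 0),
    topk_observed = topk$observed,
    topk_p = topk$p)

  run <- structure(
    list(cohort = cohort, measures = measures,
         parcellation = parcellation, truth = truth, pred = pred,
         fit_eval = fit_eval, npm = maps, overlap = overlap,
         glm = glm_res, scores = scores, gumbel = gumbel, topk = topk,
         associations = assoc, confounds = confounds,
         manifest = manifest, config = config),
    class = "normdev_run")

  if (!is.null(out_dir)) write_run(run, out_dir)
  say(sprintf("done in %.1f min",
              as.numeric(Sys.time() - t0, units = "mins")))
  run
}

#' @export
print.normdev_run <- function(x, ...) {
  m <- x$manifest
  cat("<normdev_run>", m$n_td, "TD +", m$n_asd, "ASD x", m$n_vertices,
      "vertices\n")
  cat("  GLM significant vertices:", m$glm_significant, "\n")
  cat("  subjects with >= 1 significant deviation:",
      m$subjects_with_deviation, "\n")
  cat(sprintf("  top-%d membership: %d cases, p = %.3g (%s)\n",
              x$topk$k, x$topk$observed, x$topk$p, x$topk$null))
  invisible(x)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(seed = run$manifest$seed,
               config_hash = run$manifest$config_hash)
  p <- function(f) file.path(out_dir, f)
  write_tsv_meta(run$cohort, p("cohort.tsv"), meta)
  write_measure_matrix(run$measures, p("measures.tsv"), meta)
  write_parcellation(run$parcellation, p("parcellation.tsv"), meta)
  write_tsv_meta(tibble::as_tibble(run$fit_eval), p("fit_evaluation.tsv"),
                 meta)
  zd <- dplyr::bind_cols(tibble::tibble(subject_id = rownames(run$npm$Z)),
                         tibble::as_tibble(run$npm$Z))
  write_tsv_meta(zd, p("z_scores.tsv"), meta)
  md <- dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(run$npm$mask)),
    tibble::as_tibble(run$npm$mask))
  write_tsv_meta(md, p("npm_mask.tsv"), meta)
  write_tsv_meta(run$overlap$counts, p("overlap_counts.tsv"), meta)
  write_tsv_meta(run$overlap$contributors, p("overlap_contributors.tsv"),
                 meta)
  write_tsv_meta(tibble::as_tibble(run$glm), p("glm.tsv"), meta)
  write_tsv_meta(run$scores$global, p("extreme_global.tsv"), meta)
  write_tsv_meta(run$scores$regional, p("extreme_regional.tsv"), meta)
  gt <- purrr::imap(run$gumbel, function(g, grp) {
    if (is.null(g)) return(NULL)
    tibble::tibble(group = grp, mu = g$mu, beta = g$beta,
                   loglik = g$loglik, n = g$n)
  }) |> dplyr::bind_rows()
  write_tsv_meta(gt, p("gumbel_fits.tsv"), meta)
  write_tsv_meta(run$topk, p("topk_test.tsv"), meta)
  if (!is.null(run$associations)) {
    write_tsv_meta(tibble::as_tibble(run$associations),
                   p("associations.tsv"), meta)
  }
  if (!is.null(run$confounds)) {
    write_tsv_meta(run$confounds, p("confounds.tsv"), meta)
  }
  yaml::write_yaml(run$manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}
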