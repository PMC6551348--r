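#' Plot per-vertex model-fit quality
#'
#' Histogram of the out-of-fold Pearson correlations between observed
#' and predicted values, shaded by FDR significance.
#'
#' @param object a [evaluate_fit()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fit_evaluation <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cor,
                                       fill = .data$significant)) +
    ggplot2::geom_histogram(bins = 40, boundary = 0) +
    ggplot2::labs(x = "out-of-fold correlation (observed vs predicted)",
                  y = "vertices", fill = "FDR significant") +
    ggplot2::theme_minimal()
}

#' Plot deviation overlap counts along the vertex axis
#'
#' One panel per deviation sign; lines per cohort (whole-cohort maps).
#'
#' @param object an [overlap_map()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.overlap_map <- function(object, ...) {
  d <- dplyr::filter(object$counts, .data$schedule == "all")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$vertex, y = .data$count,
                                  colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~sign, ncol = 1) +
    ggplot2::labs(x = "vertex", y = "subjects with significant deviation",
                  colour = "cohort") +
    ggplot2::theme_minimal()
}

#' Plot extreme-score distributions with Gumbel fits
#'
#' Histograms of the per-subject trimmed-top extreme scores by cohort;
#' when Gumbel fits are supplied their densities are overlaid.
#'
#' @param object an [extreme_scores()] result.
#' @param gumbel optional named list of [fit_gumbel()] fits per group.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.extreme_scores <- function(object, gumbel = NULL, ...) {
  d <- object$global
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$score,
                                       fill = .data$group)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 40, alpha = 0.5,
                            position = "identity") +
    ggplot2::labs(x = "extreme deviation score (|Z|)", y = "density",
                  fill = "cohort") +
    ggplot2::theme_minimal()
  if (!is.null(gumbel)) {
    grid <- seq(min(d$score), max(d$score), length.out = 200)
    dens <- purrr::imap(gumbel, function(g, grp) {
      if (is.null(g)) return(NULL)
      tibble::tibble(score = grid, group = grp,
                     density = dgumbel(grid, g$mu, g$beta))
    }) |> dplyr::bind_rows()
    p <- p + ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$score, y = .data$density,
                   colour = .data$group),
      inherit.aes = FALSE)
  }
  p
}

#' Plot regional symptom associations
#'
#' Tile map of Spearman correlations per region, symptom and stratum;
#' FDR-surviving cells are outlined.
#'
#' @param object an [associate()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.association_table <- function(object, ...) {
  d <- dplyr::filter(object, .data$scope != "global")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$symptom, y = .data$scope,
                                  fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = dplyr::filter(d, .data$significant),
                       colour = "black", linewidth = 0.6, fill = NA) +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = "region", fill = "Spearman rho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}
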