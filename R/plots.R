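#' Plot a differential-acetylation fit
#'
#' Replicate-style scatter of per-region mean scores in group A versus
#' group B on the log10 scale, coloured by class. Variable regions split
#' visibly above (enriched) and below (deprived) the 45-degree diagonal.
#'
#' @param object A `diffac` object.
#' @param pseudocount Added before the log transform (default 0.5).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot diffac
#' @export
autoplot.diffac <- function(object, pseudocount = 0.5, ...) {
  df <- object$table
  ggplot2::ggplot(df, ggplot2::aes(
    x = log10(.data$mean_A + pseudocount),
    y = log10(.data$mean_B + pseudocount),
    colour = .data$class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      stable = "grey60", enriched = "#d95f02", deprived = "#1b9e77")) +
    ggplot2::labs(
      x = "log10 mean score, group A",
      y = "log10 mean score, group B",
      colour = NULL,
      title = sprintf("Differential acetylation (p <= %g)",
                      object$params$p_threshold))
}

#' Plot motif enrichment Z-scores
#'
#' Bar chart of per-motif bootstrap Z-scores with the significance
#' thresholds marked.
#'
#' @param object A `motif_enrichment_result` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot motif_enrichment_result
#' @export
autoplot.motif_enrichment_result <- function(object, ...) {
  zt <- attr(object, "z_threshold") %||% 3
  df <- as_tibble(tidy(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$motif_id, y = .data$z,
                                   fill = .data$call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = c(-zt, zt), linetype = 2,
                        colour = "grey40") +
    ggplot2::scale_fill_manual(values = c(
      over = "#d95f02", under = "#1b9e77", ns = "grey60")) +
    ggplot2::labs(x = NULL, y = "bootstrap Z-score", fill = NULL)
}

#' Plot a replicate-concordance density grid
#'
#' @param grid A `density_grid` from [replicate_density_grid()].
#' @return A ggplot object (filled raster with the diagonal marked).
#' @export
plot_density_grid <- function(grid) {
  df <- expand.grid(x = grid$x, y = grid$y)
  df$density <- as.vector(grid$z)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "log10 score, replicate 1",
                  y = "log10 score, replicate 2", fill = "density")
}
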