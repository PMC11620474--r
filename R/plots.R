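#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot quadrant proportions with resampling uncertainty
#'
#' @param object A `quadrant_resample` from [resample_proportions()].
#' @param ... Unused.
#' @return A ggplot: bar per quadrant with +/-1 sd error bars.
#' @export
autoplot.quadrant_resample <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$quadrant, y = 100 * .data$mean)
  ) +
    ggplot2::geom_col(fill = "grey65") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$mean - .data$sd),
                   ymax = 100 * (.data$mean + .data$sd)),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "% of mutants",
                  title = sprintf("Quadrant proportions (%d resamples)",
                                  object$B)) +
    ggplot2::theme_minimal()
}

#' Plot an inferred beneficial mutation-rate density
#'
#' @param object A `dfe_grid` from [invert_dfe()].
#' @param ... Unused.
#' @return A ggplot of `mu_hat(s)` with Poisson intervals, log-log scales.
#' @export
autoplot.dfe_grid <- function(object, ...) {
  df <- dplyr::filter(tidy(object), .data$count > 0 | .data$mu_hi > 0)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mid, y = .data$mu_hat)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mu_lo, ymax = .data$mu_hi)
    ) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "selection coefficient s (per cycle)",
                  y = expression(hat(mu)(s) ~ "(per cell per cycle per s)")) +
    ggplot2::theme_minimal()
}

#' Performance-space scatter of mutants
#'
#' Fermentation vs respiration performance change relative to the parental
#' strain, the plane on which pleiotropic (upper-right quadrant) and modular
#' adaptation separate.
#'
#' @param deltas Parent-referenced performance tibble (columns `fer`, `res`,
#'   `se_fer`, `se_res`; a `quadrant` column is added if missing).
#' @param errorbars Draw +/-1 SE bars (default TRUE).
#' @return A ggplot.
#' @export
plot_performance_space <- function(deltas, errorbars = TRUE) {
  if (!"quadrant" %in% names(deltas)) deltas <- classify_quadrant(deltas)
  p <- ggplot2::ggplot(
    deltas,
    ggplot2::aes(x = .data$fer, y = .data$res, colour = .data$quadrant)
  ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(alpha = 0.8)
  if (errorbars && all(c("se_fer", "se_res") %in% names(deltas))) {
    p <- p +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$res - .data$se_res,
                     ymax = .data$res + .data$se_res),
        alpha = 0.3, width = 0
      ) +
      ggplot2::geom_errorbarh(
        ggplot2::aes(xmin = .data$fer - .data$se_fer,
                     xmax = .data$fer + .data$se_fer),
        alpha = 0.3, height = 0
      )
  }
  p +
    ggplot2::labs(x = "fermentation performance / h (vs parent)",
                  y = "respiration performance / h (vs parent)") +
    ggplot2::theme_minimal()
}

#' Lineage frequency trajectories of a simulated evolution
#'
#' @param sim An `evolution_sim` from [simulate_evolution()].
#' @param top_n Label the `top_n` lineages by final frequency (others drawn
#'   in grey).
#' @return A ggplot of log10 barcode frequencies over transfers.
#' @export
plot_lineage_trajectories <- function(sim, top_n = 20L) {
  freq <- sim$counts |>
    dplyr::group_by(.data$timepoint) |>
    dplyr::mutate(freq = .data$count / sum(.data$count)) |>
    dplyr::ungroup()
  final <- freq |>
    dplyr::filter(.data$timepoint == max(.data$timepoint)) |>
    dplyr::slice_max(.data$freq, n = top_n)
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$timepoint,
                                     y = pmax(.data$freq, 1e-7),
                                     group = .data$barcode)) +
    ggplot2::geom_line(colour = "grey80") +
    ggplot2::geom_line(
      data = dplyr::semi_join(freq, final, by = "barcode"),
      ggplot2::aes(colour = .data$barcode),
      show.legend = FALSE
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "transfer", y = "barcode frequency") +
    ggplot2::theme_minimal()
}
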