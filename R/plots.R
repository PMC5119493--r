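#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_vline scale_y_log10 labs facet_wrap annotate geom_ribbon
#' @export
ggplot2::autoplot

#' Plot a batch trajectory
#'
#' Log-scale densities per lineage over time, with depletion events marked.
#'
#' @param object A `gal_trajectory`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gal_trajectory <- function(object, ...) {
  df <- object$states %>% filter(.data$density_cells_per_ml > 0)
  ev <- object$events %>% filter(.data$kind != "horizon")
  ggplot(df, aes(
    .data$time_h, .data$density_cells_per_ml,
    colour = paste(.data$genotype, .data$phenotype)
  )) +
    geom_line() +
    geom_point(size = 0.8) +
    geom_vline(xintercept = ev$time_h, linetype = "dotted", colour = "grey40") +
    scale_y_log10() +
    labs(
      x = "time (h)", y = "density (cells/ml)", colour = "lineage",
      title = sprintf("%s-mode batch culture", object$mode)
    )
}

#' Plot an equilibrium fit
#'
#' Relative fitness against initial focal fraction, the fitted curve, the
#' neutral line and the estimated crossing with its confidence interval.
#'
#' @param object A `gal_equilibrium`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gal_equilibrium <- function(object, ...) {
  grid <- tibble(f_i = seq(min(object$data$f_i), max(object$data$f_i), length.out = 200))
  grid$w_rel <- as.numeric(predict(object$fit, newdata = grid))
  p <- ggplot(object$data, aes(.data$f_i, .data$w_rel)) +
    geom_point(alpha = 0.6) +
    geom_line(data = grid, colour = "steelblue") +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(
      x = "initial GAL-ON fraction", y = "relative fitness (GAL-ON)",
      title = sprintf("equilibrium at f* = %.3f", object$f_star)
    )
  if (!object$boundary) {
    p <- p +
      annotate("rect",
        xmin = object$ci_low, xmax = object$ci_high,
        ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue"
      ) +
      geom_vline(xintercept = object$f_star, colour = "steelblue")
  }
  p
}

#' Plot an evolution experiment
#'
#' Pooled GAL-ON fraction per cycle, one panel per replicate.
#'
#' @param object A `gal_evolution`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gal_evolution <- function(object, ...) {
  df <- object$runs %>%
    group_by(.data$replicate, .data$cycle) %>%
    summarise(fraction_on = .data$fraction_on[1], .groups = "drop")
  ggplot(df, aes(.data$cycle, .data$fraction_on)) +
    geom_line() +
    geom_point(size = 0.7) +
    facet_wrap(~replicate) +
    labs(x = "cycle", y = "pooled GAL-ON fraction")
}

#' Plot frequency-dependent fitness of the pure strategists
#'
#' The two strategists' doublings against initial GAL-ON fraction; their
#' crossing marks the evolutionarily stable mix.
#'
#' @param curve Output of [fitness_vs_fraction()].
#' @return A ggplot.
#' @export
plot_fitness_curve <- function(curve) {
  df <- curve %>%
    tidyr::pivot_longer(c("generations_on", "generations_off"),
      names_to = "strain", values_to = "generations"
    ) %>%
    mutate(strain = ifelse(.data$strain == "generations_on", "GAL-ON", "GAL-OFF"))
  ggplot(df, aes(.data$initial_fraction_on, .data$generations, colour = .data$strain)) +
    geom_line() +
    geom_point() +
    labs(x = "initial GAL-ON fraction", y = "fitness (doublings)", colour = NULL)
}
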