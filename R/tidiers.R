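#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a batch trajectory
#'
#' @param x A `gal_trajectory`.
#' @param ... Unused.
#' @return The tidy states tibble (`time_h`, `genotype`, `phenotype`,
#'   `density_cells_per_ml`, `glucose_pct`, `galactose_pct`), one row per
#'   lineage per event time.
#' @export
tidy.gal_trajectory <- function(x, ...) x$states

#' @rdname tidy.gal_trajectory
#' @return For `glance()`: a one-row summary of the run.
#' @export
glance.gal_trajectory <- function(x, ...) {
  tibble(
    mode = x$mode, horizon_h = x$env$horizon_h,
    n_genotypes = length(unique(x$final$genotype)),
    final_density = sum(x$final$density),
    glucose_residual_pct = x$resources_final[["glucose"]],
    galactose_residual_pct = x$resources_final[["galactose"]],
    n_events = nrow(x$events)
  )
}

#' Tidy an equilibrium estimate
#'
#' @param x A `gal_equilibrium` from [fit_equilibrium()].
#' @param ... Unused.
#' @return `tidy()`: one row per crossing with the estimate and CI;
#'   `glance()`: fit metadata and quality.
#' @export
tidy.gal_equilibrium <- function(x, ...) {
  tibble(
    f_star = x$f_star, ci_low = x$ci_low, ci_high = x$ci_high,
    boundary = x$boundary, n_crossings = length(x$roots)
  )
}

#' @rdname tidy.gal_equilibrium
#' @export
glance.gal_equilibrium <- function(x, ...) {
  r2 <- if (inherits(x$fit, "lm")) summary(x$fit)$r.squared else NA_real_
  tibble(
    method = x$method, degree = x$degree, n_records = nrow(x$data),
    n_boot = x$n_boot, level = x$level, r_squared = r2
  )
}

#' Tidy a dilution run or evolution experiment
#'
#' @param x A `gal_dilution_run` or `gal_evolution`.
#' @param ... Unused.
#' @return The per-cycle tibble; `glance()` on an evolution object returns
#'   the per-replicate outcomes.
#' @export
tidy.gal_dilution_run <- function(x, ...) x$frequencies

#' @rdname tidy.gal_dilution_run
#' @export
tidy.gal_evolution <- function(x, ...) x$runs

#' @rdname tidy.gal_dilution_run
#' @export
glance.gal_evolution <- function(x, ...) x$outcomes
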