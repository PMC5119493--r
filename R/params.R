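#' Sugar environment for one batch-culture game
#'
#' Defines the two resources of the foraging game: the initial glucose and
#' galactose concentrations (% w/v) and the incubation horizon. The standard
#' competition-assay environment is 0.03% glucose + 0.05% galactose incubated
#' for 20 h, by which time both sugars are consumed.
#'
#' @param glucose_pct Initial glucose concentration, % w/v. Non-negative.
#' @param galactose_pct Initial galactose concentration, % w/v. Non-negative.
#' @param horizon_h Incubation time in hours. Must be positive.
#'
#' @return An object of class `sugar_env`.
#' @export
#' @examples
#' sugar_env()                      # the standard mixed-sugar assay
#' sugar_env(0.1, 0, horizon_h = 24) # pure-glucose evolution condition
sugar_env <- function(glucose_pct = 0.03, galactose_pct = 0.05, horizon_h = 20) {
  stopifnot(is.numeric(glucose_pct), is.numeric(galactose_pct), is.numeric(horizon_h))
  if (glucose_pct < 0 || galactose_pct < 0) {
    abort("sugar concentrations must be >= 0", class = "galgame_validation_error")
  }
  if (!is.finite(horizon_h) || horizon_h <= 0) {
    abort("horizon_h must be a positive finite number", class = "galgame_validation_error")
  }
  structure(
    list(glucose_pct = glucose_pct, galactose_pct = galactose_pct, horizon_h = horizon_h),
    class = "sugar_env"
  )
}

#' @export
print.sugar_env <- function(x, ...) {
  cat(sprintf(
    "<sugar_env> glucose %.4g%% w/v, galactose %.4g%% w/v, horizon %.4g h\n",
    x$glucose_pct, x$galactose_pct, x$horizon_h
  ))
  invisible(x)
}

#' Kinetic parameters of the GAL-ON and GAL-OFF phenotypes
#'
#' Growth rates, yields and the GAL-expression cost that define how the two
#' phenotypes convert sugars into cells. Growth is exponential while a usable
#' resource remains and stops when it is exhausted (threshold kinetics), so
#' every parameter acts on a piecewise-exponential trajectory.
#'
#' The defaults are calibrated to the mixed-sugar competition assay: a
#' 0.01% glucose preculture grows from ~3e4 to ~6e6 cells/ml (yield
#' 6e7 cells/ml per % w/v), galactose supports fewer cells per unit mass,
#' and GAL-ON cells pay a substantial growth-rate penalty while glucose is
#' present (pathway commitment plus expression burden), which is what makes
#' the OFF phenotype the better glucose competitor. With these defaults the
#' 0.03%/0.05% game has its stable GAL-ON fraction near 0.43.
#'
#' @param r_glucose Maximum growth rate on glucose, 1/h.
#' @param r_galactose Maximum growth rate on galactose, 1/h.
#' @param yield_glucose,yield_galactose Cells produced per ml per % w/v of
#'   sugar consumed.
#' @param cost_rate Rate penalty in `[0, 1)` paid by GAL-ON cells while they
#'   grow in the presence of glucose (diauxic mode) or on their own resource
#'   (idealized exclusive mode). Multiplies the rate by `1 - cost_rate`.
#' @param cost_yield Yield penalty in `[0, 1)` for GAL-ON cells; multiplies
#'   their yields by `1 - cost_yield`.
#' @param co_consumption Fraction in `[0, 1]` of the galactose growth rate
#'   that GAL-ON cells realize while glucose is still present.
#' @param lag_off_to_gal Hours after glucose depletion before an OFF cell with
#'   `post_depletion_switch` starts growing on galactose. `Inf` (default)
#'   models the engineered pure strategist whose GAL network stays silent for
#'   the whole assay.
#'
#' @return An object of class `phenotype_params`.
#' @export
phenotype_params <- function(r_glucose = 0.45, r_galactose = 0.36,
                             yield_glucose = 6e7, yield_galactose = 2.4e7,
                             cost_rate = 0.5, cost_yield = 0.1,
                             co_consumption = 0.1, lag_off_to_gal = Inf) {
  if (any(c(r_glucose, r_galactose) < 0)) {
    abort("growth rates must be >= 0", class = "galgame_validation_error")
  }
  if (any(c(yield_glucose, yield_galactose) <= 0)) {
    abort("yields must be > 0", class = "galgame_validation_error")
  }
  if (cost_rate < 0 || cost_rate >= 1 || cost_yield < 0 || cost_yield >= 1) {
    abort("cost_rate and cost_yield must lie in [0, 1)", class = "galgame_validation_error")
  }
  if (co_consumption < 0 || co_consumption > 1) {
    abort("co_consumption must lie in [0, 1]", class = "galgame_validation_error")
  }
  if (lag_off_to_gal < 0) {
    abort("lag_off_to_gal must be >= 0 (may be Inf)", class = "galgame_validation_error")
  }
  structure(
    list(
      r_glucose = r_glucose, r_galactose = r_galactose,
      yield_glucose = yield_glucose, yield_galactose = yield_galactose,
      cost_rate = cost_rate, cost_yield = cost_yield,
      co_consumption = co_consumption, lag_off_to_gal = lag_off_to_gal
    ),
    class = "phenotype_params"
  )
}

#' @export
print.phenotype_params <- function(x, ...) {
  cat("<phenotype_params>\n")
  cat(sprintf("  r_glucose %.3g/h, r_galactose %.3g/h\n", x$r_glucose, x$r_galactose))
  cat(sprintf(
    "  yields %.3g / %.3g cells/ml per %% w/v\n",
    x$yield_glucose, x$yield_galactose
  ))
  cat(sprintf(
    "  cost_rate %.3g, cost_yield %.3g, co_consumption %.3g, lag %.3g h\n",
    x$cost_rate, x$cost_yield, x$co_consumption, x$lag_off_to_gal
  ))
  invisible(x)
}

#' Heritable strategy genotypes
#'
#' A strategy is the heritable rule assigning phenotypes to cells: with
#' probability `p_on` a cell adopts the GAL-ON phenotype at the start of a
#' growth cycle, otherwise GAL-OFF. `p_on = 1` with no switching is the pure
#' GAL-ON strategist, `p_on = 0` the pure GAL-OFF strategist, and anything in
#' between is a mixed strategist. Optional per-hour stochastic switching rates
#' move cells between the phenotype compartments during growth.
#'
#' Strategies are one-row tibbles so that a co-culture inoculum is simply
#' `dplyr::bind_rows()` of strategies with a `density` column (see
#' [pure_pair()]).
#'
#' @param label Genotype identifier.
#' @param p_on Probability in `[0, 1]` of adopting the GAL-ON phenotype at
#'   the start of a cycle.
#' @param switch_on_rate,switch_off_rate Per-hour stochastic phenotype
#'   switching rates (OFF to ON, ON to OFF). Default 0.
#' @param post_depletion_switch Should OFF cells activate galactose growth
#'   after glucose runs out (wild-type-like), subject to the lag in
#'   [phenotype_params()]? Default `FALSE` (engineered pure strategist).
#'
#' @return A one-row tibble describing the genotype.
#' @export
#' @examples
#' strategy("ON", 1)
#' strategy("WT", 0.4, post_depletion_switch = TRUE)
strategy <- function(label, p_on, switch_on_rate = 0, switch_off_rate = 0,
                     post_depletion_switch = FALSE) {
  if (!is.numeric(p_on) || length(p_on) != 1 || is.na(p_on) || p_on < 0 || p_on > 1) {
    abort("p_on must be a single number in [0, 1]", class = "galgame_validation_error")
  }
  if (switch_on_rate < 0 || switch_off_rate < 0) {
    abort("switching rates must be >= 0", class = "galgame_validation_error")
  }
  tibble(
    genotype = as.character(label), p_on = p_on,
    switch_on_rate = switch_on_rate, switch_off_rate = switch_off_rate,
    post_depletion_switch = isTRUE(post_depletion_switch)
  )
}

#' Inoculum for a two-strain pure-strategist competition
#'
#' Convenience constructor for the canonical co-culture: a pure GAL-ON and a
#' pure GAL-OFF strategist mixed at a given initial GAL-ON fraction.
#'
#' @param fraction_on Initial GAL-ON fraction in `[0, 1]`.
#' @param total_density Total inoculum density, cells/ml. The assay standard
#'   is ~3e4 cells/ml.
#' @param post_depletion_switch Passed to both strategies; `TRUE` gives
#'   wild-type-like late galactose activation of OFF cells.
#'
#' @return A two-row inoculum tibble (columns of [strategy()] plus `density`).
#' @export
pure_pair <- function(fraction_on, total_density = 3e4, post_depletion_switch = FALSE) {
  stopifnot(fraction_on >= 0, fraction_on <= 1, total_density > 0)
  bind_rows(
    strategy("ON", 1, post_depletion_switch = post_depletion_switch),
    strategy("OFF", 0, post_depletion_switch = post_depletion_switch)
  ) %>%
    mutate(density = c(fraction_on, 1 - fraction_on) * total_density)
}

# validate an inoculum tibble; returns it with defaults filled in
check_inoculum <- function(inoculum) {
  if (!is.data.frame(inoculum) || !all(c("genotype", "p_on", "density") %in% names(inoculum))) {
    abort("inoculum must be a data frame with genotype, p_on and density columns",
      class = "galgame_validation_error"
    )
  }
  inoculum <- as_tibble(inoculum)
  if (!"switch_on_rate" %in% names(inoculum)) inoculum$switch_on_rate <- 0
  if (!"switch_off_rate" %in% names(inoculum)) inoculum$switch_off_rate <- 0
  if (!"post_depletion_switch" %in% names(inoculum)) inoculum$post_depletion_switch <- FALSE
  if (anyDuplicated(inoculum$genotype)) {
    abort("genotype labels must be unique", class = "galgame_validation_error")
  }
  if (any(inoculum$density < 0) || sum(inoculum$density) <= 0) {
    abort("inoculum densities must be >= 0 with positive total", class = "galgame_validation_error")
  }
  if (any(inoculum$p_on < 0 | inoculum$p_on > 1)) {
    abort("p_on must lie in [0, 1]", class = "galgame_validation_error")
  }
  inoculum
}
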