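#' Fitness as number of doublings over a batch cycle
#'
#' The assay's fitness currency: `log2` of the fold-change of a genotype's
#' pooled density between inoculation and a probe time.
#'
#' @param traj A `gal_trajectory`.
#' @param genotype Genotype label present in the trajectory.
#' @param t_probe Probe time in hours; `NULL` (default) uses the end of the
#'   trajectory.
#' @return Number of doublings (may be negative only through density loss,
#'   which batch growth never produces; `-Inf` with a warning if the final
#'   density is zero).
#' @export
#' @examples
#' traj <- simulate_batch(sugar_env(), pure_pair(0.4), phenotype_params())
#' endpoint_generations(traj, "ON")
endpoint_generations <- function(traj, genotype, t_probe = NULL) {
  stopifnot(inherits(traj, "gal_trajectory"))
  d0 <- traj$lineages0 %>%
    filter(.data$genotype == .env$genotype) %>%
    pull(.data$density) %>%
    sum()
  if (length(d0) == 0 || is.na(d0)) {
    abort(sprintf("genotype '%s' not present", genotype), class = "galgame_validation_error")
  }
  if (d0 <= 0) {
    abort(sprintf("genotype '%s' has zero initial density", genotype),
      class = "galgame_validation_error"
    )
  }
  dT <- genotype_density(traj, genotype, t_probe)
  if (dT <= 0) {
    warn(sprintf("genotype '%s' reached zero density; returning -Inf", genotype))
    return(-Inf)
  }
  log2(dT / d0)
}

#' Frequency-dependent fitness of the two pure strategists
#'
#' Runs one fresh batch competition of the pure GAL-ON and GAL-OFF
#' strategists at each initial GAL-ON fraction, and reports each strain's
#' doublings at the end of the cycle, the total density at a probe time
#' (default 16 h, before low-ON cultures saturate), and the relative fitness
#' of the ON strain (ratio of log growth factors, the competition-assay
#' statistic).
#'
#' @inheritParams simulate_batch
#' @param fraction_grid Initial GAL-ON fractions, all in (0, 1).
#' @param t_probe Probe time (h) for the density readout.
#' @param total_density Total inoculum density, cells/ml.
#' @param post_depletion_switch Passed to [pure_pair()].
#' @return A tibble with one row per grid value: `initial_fraction_on`,
#'   `generations_on`, `generations_off`, `density_at_probe`,
#'   `relative_fitness_on`.
#' @export
fitness_vs_fraction <- function(env, params, mode = c("diauxic", "exclusive"),
                                fraction_grid = seq(0.05, 0.95, by = 0.1),
                                t_probe = 16, total_density = 3e4,
                                post_depletion_switch = FALSE) {
  mode <- match.arg(mode)
  if (length(fraction_grid) == 0) {
    abort("fraction_grid must be non-empty", class = "galgame_validation_error")
  }
  if (any(fraction_grid <= 0 | fraction_grid >= 1)) {
    abort("fraction_grid values must lie in (0, 1)", class = "galgame_validation_error")
  }
  purrr::map_dfr(fraction_grid, function(f) {
    traj <- simulate_batch(
      env, pure_pair(f, total_density, post_depletion_switch), params, mode
    )
    gon <- endpoint_generations(traj, "ON")
    goff <- endpoint_generations(traj, "OFF")
    dens <- sum(density_at(traj, min(t_probe, env$horizon_h))$density_cells_per_ml)
    tibble(
      initial_fraction_on = f, generations_on = gon, generations_off = goff,
      density_at_probe = dens,
      relative_fitness_on = (gon * log(2)) / (goff * log(2))
    )
  })
}

#' Invasion fitness of a rare strategy
#'
#' Relative fitness of an invader introduced at frequency `epsilon` into a
#' resident population, over one batch cycle: the ratio of the two
#' genotypes' log growth factors (the same statistic the competition assay
#' computes from optical densities and strain fractions).
#'
#' @inheritParams simulate_batch
#' @param resident,invader One-row [strategy()] tibbles.
#' @param epsilon Invader initial frequency, in (0, 0.1].
#' @param total_density Total inoculum density, cells/ml.
#' @return Invader relative fitness (dimensionless; > 1 means the invader
#'   outgrew the resident).
#' @export
invasion_fitness <- function(resident, invader, env, params,
                             mode = c("diauxic", "exclusive"),
                             epsilon = 0.01, total_density = 3e4) {
  mode <- match.arg(mode)
  if (epsilon <= 0 || epsilon > 0.1) {
    abort("epsilon must lie in (0, 0.1]", class = "galgame_validation_error")
  }
  pair_relative_fitness(invader, resident, epsilon, env, params, mode, total_density)
}

# relative fitness of genotype a at initial frequency freq_a against b,
# over one batch cycle: ratio of log growth factors
pair_relative_fitness <- function(a, b, freq_a, env, params, mode, total_density) {
  a <- mutate(a, density = freq_a * total_density)
  b <- mutate(b, density = (1 - freq_a) * total_density)
  if (a$genotype == b$genotype) a$genotype <- paste0(a$genotype, ".invader")
  traj <- simulate_batch(env, check_inoculum(bind_rows(a, b)), params, mode)
  g_a <- log(genotype_density(traj, a$genotype) / a$density)
  g_b <- log(genotype_density(traj, b$genotype) / b$density)
  g_a / g_b
}

#' Mutual invasibility of two strategies
#'
#' Tests whether each strategy invades the other when rare — the hallmark of
#' a protected polymorphism under negative frequency-dependent selection.
#'
#' @inheritParams invasion_fitness
#' @param a,b One-row [strategy()] tibbles.
#' @return A two-row tibble (`invader`, `resident`, `w_rel`, `invades`) with
#'   attribute `mutually_invasible`.
#' @export
mutual_invasibility <- function(a, b, env, params, mode = c("diauxic", "exclusive"),
                                epsilon = 0.01, total_density = 3e4) {
  mode <- match.arg(mode)
  w_ab <- invasion_fitness(b, a, env, params, mode, epsilon, total_density)
  w_ba <- invasion_fitness(a, b, env, params, mode, epsilon, total_density)
  out <- tibble(
    invader = c(a$genotype, b$genotype),
    resident = c(b$genotype, a$genotype),
    w_rel = c(w_ab, w_ba),
    invades = c(w_ab > 1, w_ba > 1)
  )
  attr(out, "mutually_invasible") <- all(out$invades)
  out
}

#' Evolutionarily stable GAL-ON fraction
#'
#' Locates the initial GAL-ON fraction at which the pure GAL-ON and GAL-OFF
#' strategists undergo the same number of doublings over one batch cycle.
#' The fitness difference is scanned on a grid; each sign change is refined
#' by bisection to `|delta f| <= f_tol`. Without a sign change the favored
#' boundary (0 or 1) is returned with `boundary = TRUE`. Multiple interior
#' crossings are all returned with a warning.
#'
#' @inheritParams fitness_vs_fraction
#' @param f_tol Bisection tolerance on the fraction.
#' @param grid_n Size of the initial scanning grid.
#' @return A tibble (one row per crossing, or a single boundary row):
#'   `f_stable`, `boundary`, `n_crossings`.
#' @export
#' @examples
#' stable_fraction(sugar_env(), phenotype_params()) # about 0.43
stable_fraction <- function(env, params, mode = c("diauxic", "exclusive"),
                            total_density = 3e4, f_tol = 1e-4, grid_n = 21,
                            post_depletion_switch = FALSE) {
  mode <- match.arg(mode)
  dfun <- function(f) {
    traj <- simulate_batch(
      env, pure_pair(f, total_density, post_depletion_switch), params, mode
    )
    suppressWarnings(
      endpoint_generations(traj, "ON") - endpoint_generations(traj, "OFF")
    )
  }
  grid <- seq(1e-3, 1 - 1e-3, length.out = grid_n)
  vals <- vapply(grid, dfun, numeric(1))
  sgn <- sign(vals)
  flips <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  exact <- which(vals == 0)
  if (length(flips) == 0 && length(exact) == 0) {
    side <- if (mean(vals > 0) >= 0.5) 1 else 0
    return(tibble(f_stable = side, boundary = TRUE, n_crossings = 0L))
  }
  roots <- c(
    grid[exact],
    vapply(flips, function(i) {
      uniroot(dfun, c(grid[i], grid[i + 1]), tol = f_tol / 10)$root
    }, numeric(1))
  )
  roots <- sort(unique(roots))
  if (length(roots) > 1) {
    warn(sprintf(
      "fitness difference crosses zero %d times; all crossings returned",
      length(roots)
    ))
  }
  tibble(f_stable = roots, boundary = FALSE, n_crossings = length(roots))
}

#' Growth-optimal GAL-ON fraction
#'
#' The phenotype mix that maximizes population growth: the fraction
#' minimizing the time at which both sugars are exhausted (at the optimum of
#' the idealized exclusive game the two resources are depleted
#' simultaneously). Found by a coarse grid scan refined with golden-section
#' search.
#'
#' @inheritParams fitness_vs_fraction
#' @param f_tol Tolerance on the optimal fraction.
#' @return A tibble: `f_opt`, `t_deplete_h` (joint depletion time),
#'   `t_glucose_h`, `t_galactose_h`, `boundary`.
#' @export
optimal_fraction <- function(env, params, mode = c("exclusive", "diauxic"),
                             total_density = 3e4, f_tol = 1e-3,
                             post_depletion_switch = FALSE) {
  mode <- match.arg(mode)
  if (env$glucose_pct <= 0 || env$galactose_pct <= 0) {
    f <- if (env$glucose_pct <= 0) 1 else 0
    return(tibble(
      f_opt = f, t_deplete_h = NA_real_, t_glucose_h = NA_real_,
      t_galactose_h = NA_real_, boundary = TRUE
    ))
  }
  sim_env <- sugar_env(env$glucose_pct, env$galactose_pct, max(env$horizon_h, 500))
  times <- function(f) {
    traj <- simulate_batch(
      sim_env, pure_pair(f, total_density, post_depletion_switch), params, mode
    )
    ev <- traj$events
    tg <- ev$time_h[ev$kind == "glucose_depleted"][1]
    tb <- ev$time_h[ev$kind == "galactose_depleted"][1]
    c(glu = if (is.na(tg)) Inf else tg, gal = if (is.na(tb)) Inf else tb)
  }
  obj <- function(f) max(times(f))
  grid <- seq(0.005, 0.995, length.out = 41)
  vals <- vapply(grid, obj, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(i - 1, 1)]
  hi <- grid[min(i + 1, length(grid))]
  opt <- optimize(obj, c(lo, hi), tol = f_tol / 5)
  tt <- times(opt$minimum)
  tibble(
    f_opt = opt$minimum, t_deplete_h = opt$objective,
    t_glucose_h = tt[["glu"]], t_galactose_h = tt[["gal"]], boundary = FALSE
  )
}

#' Sweep a game parameter and track both solution concepts
#'
#' Recomputes the evolutionarily stable fraction and the growth-optimal
#' fraction along one axis: the GAL-ON growth penalty (`cost`, setting
#' `cost_rate` and `cost_yield` jointly), or one of the sugar
#' concentrations.
#'
#' @inheritParams fitness_vs_fraction
#' @param axis `"cost"`, `"glucose"` or `"galactose"`.
#' @param values At least two axis values.
#' @return A tibble with `axis`, `value`, `f_stable`, `stable_boundary`,
#'   `f_opt`; attribute `monotonicity` summarises the direction of each
#'   column.
#' @export
parameter_sweep <- function(env, params, mode = c("exclusive", "diauxic"),
                            axis = c("cost", "glucose", "galactose"), values,
                            total_density = 3e4) {
  mode <- match.arg(mode)
  axis <- match.arg(axis)
  if (length(values) < 2) {
    abort("need at least two axis values", class = "galgame_validation_error")
  }
  rows <- purrr::map_dfr(values, function(v) {
    e <- env
    p <- params
    if (axis == "cost") {
      p <- phenotype_params(
        p$r_glucose, p$r_galactose, p$yield_glucose, p$yield_galactose,
        cost_rate = v, cost_yield = v,
        co_consumption = p$co_consumption, lag_off_to_gal = p$lag_off_to_gal
      )
    } else if (axis == "glucose") {
      e <- sugar_env(v, env$galactose_pct, env$horizon_h)
    } else {
      e <- sugar_env(env$glucose_pct, v, env$horizon_h)
    }
    fs <- stable_fraction(e, p, mode, total_density)
    fo <- optimal_fraction(e, p, mode, total_density)
    tibble(
      axis = axis, value = v,
      f_stable = fs$f_stable[1], stable_boundary = fs$boundary[1],
      f_opt = fo$f_opt[1]
    )
  })
  dir <- function(x) {
    d <- diff(x)
    if (all(d >= -1e-9)) "non-decreasing" else if (all(d <= 1e-9)) "non-increasing" else "non-monotone"
  }
  attr(rows, "monotonicity") <- c(f_stable = dir(rows$f_stable), f_opt = dir(rows$f_opt))
  rows
}

#' Neutral uninvasibility of the mixed strategist at its ESS mix
#'
#' At the stable phenotype mix both phenotypes have equal fitness, so when a
#' resident mixed strategist with `p_on` equal to the stable fraction
#' dominates the population, every rare mutant — pure or mixed — grows at
#' the same rate as the resident: the mixed strategist is neutrally
#' uninvasible at high frequencies. This function tabulates invader relative
#' fitness for a set of mutants across resident frequencies.
#'
#' @inheritParams fitness_vs_fraction
#' @param mutants A tibble of [strategy()] rows (one per mutant).
#' @param resident_freq_grid Resident frequencies in (0, 1).
#' @param resident_p_on ON-probability of the resident mixed strategist;
#'   `NULL` (default) uses the game's stable fraction. A value further than
#'   1e-3 from the stable fraction triggers a warning since neutrality is
#'   only expected at the ESS mix.
#' @return A tibble: `mutant`, `resident_freq`, `w_rel`.
#' @export
ess_neutrality <- function(env, params, mode = c("diauxic", "exclusive"),
                           mutants = bind_rows(strategy("ON", 1), strategy("OFF", 0)),
                           resident_freq_grid = c(0.5, 0.9, 0.99),
                           resident_p_on = NULL, total_density = 3e4) {
  mode <- match.arg(mode)
  fs <- stable_fraction(env, params, mode, total_density)
  if (is.null(resident_p_on)) resident_p_on <- fs$f_stable[1]
  if (abs(resident_p_on - fs$f_stable[1]) > 1e-3) {
    warn("resident p_on differs from the stable fraction; neutrality is not expected")
  }
  resident <- strategy("resident", resident_p_on)
  purrr::map_dfr(seq_len(nrow(mutants)), function(i) {
    mut <- mutants[i, ]
    purrr::map_dfr(resident_freq_grid, function(q) {
      w <- pair_relative_fitness(mut, resident, 1 - q, env, params, mode, total_density)
      tibble(mutant = mut$genotype, resident_freq = q, w_rel = w)
    })
  })
}
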