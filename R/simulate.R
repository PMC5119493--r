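#' Simulate one batch-culture foraging game
#'
#' Integrates clonal populations growing on glucose and galactose in a single
#' batch, exactly, by an event-driven scheme: between events (resource
#' depletions, the OFF-to-galactose lag expiring, the horizon) every lineage
#' grows exponentially, and depletion times are solved from the closed-form
#' consumption integrals. Two model variants are available:
#'
#' * `exclusive`: the idealized two-resource game. ON-phenotype cells grow
#'   only on galactose at `r_galactose * (1 - cost_rate)` with yield
#'   `yield_galactose * (1 - cost_yield)`; OFF cells only on glucose at
#'   `r_glucose`.
#' * `diauxic`: the empirically motivated variant. While glucose remains,
#'   both phenotypes grow on it (ON paying `cost_rate` on its rate and
#'   `cost_yield` on its yield) and ON cells additionally realize
#'   `co_consumption` of the galactose rate. After glucose depletion ON cells
#'   grow on galactose at the full `r_galactose`; OFF cells join them after
#'   `lag_off_to_gal` hours, and only for genotypes with
#'   `post_depletion_switch` set.
#'
#' @param env A [sugar_env()].
#' @param inoculum A tibble with one row per genotype: `genotype`, `p_on`,
#'   `density` (cells/ml) and optionally switching rates and
#'   `post_depletion_switch`. Build with [strategy()] / [pure_pair()].
#' @param params A [phenotype_params()].
#' @param mode `"exclusive"` or `"diauxic"`.
#' @param phenotype_realization `"expectation"` splits each genotype's
#'   density deterministically as `p_on` ON; `"binomial"` draws ON cell
#'   counts binomially in a well of `volume_ml`.
#' @param seed Integer seed for binomial realization (ignored for
#'   expectation). The global RNG state is left untouched.
#' @param volume_ml Simulated culture volume used to convert densities to
#'   integer cells for binomial realization.
#'
#' @return A `gal_trajectory`: a list with `states` (tidy tibble of
#'   per-lineage densities and resource levels at every event time),
#'   `events`, `consumption` (cumulative per-lineage sugar use), `mode`,
#'   `env`, `params` and internal segment data enabling exact evaluation at
#'   arbitrary times via [density_at()].
#' @export
#' @examples
#' traj <- simulate_batch(sugar_env(), pure_pair(0.4), phenotype_params(), "diauxic")
#' traj$events
simulate_batch <- function(env, inoculum, params, mode = c("diauxic", "exclusive"),
                           phenotype_realization = c("expectation", "binomial"),
                           seed = NULL, volume_ml = 0.2) {
  mode <- match.arg(mode)
  phenotype_realization <- match.arg(phenotype_realization)
  stopifnot(inherits(env, "sugar_env"), inherits(params, "phenotype_params"))
  inoculum <- check_inoculum(inoculum)

  lineages <- realize_inoculum(inoculum, phenotype_realization, seed, volume_ml)
  out <- integrate_batch(lineages, inoculum, env, params, mode)

  structure(
    list(
      states = out$states, events = out$events, consumption = out$consumption,
      final = out$final, resources_final = out$resources_final,
      segments = out$segments, mode = mode, env = env, params = params,
      inoculum = inoculum, lineages0 = lineages
    ),
    class = "gal_trajectory"
  )
}

# split genotype densities into on/off phenotype compartments
realize_inoculum <- function(inoculum, method, seed, volume_ml) {
  split_one <- function(density, p_on) {
    if (method == "expectation") {
      c(on = density * p_on, off = density * (1 - p_on))
    } else {
      n_cells <- round(density * volume_ml)
      n_on <- realize_phenotypes(p_on, n_cells, method = "binomial", seed = seed)[["n_on"]]
      c(on = n_on / volume_ml, off = (n_cells - n_on) / volume_ml)
    }
  }
  rows <- purrr::map2(inoculum$density, inoculum$p_on, split_one)
  tibble(
    genotype = rep(inoculum$genotype, each = 2),
    phenotype = rep(c("on", "off"), times = nrow(inoculum)),
    density = unlist(rows, use.names = FALSE)
  )
}

#' @export
print.gal_trajectory <- function(x, ...) {
  fin <- x$final
  cat(sprintf(
    "<gal_trajectory> %s mode, %.4g h, %d genotypes, final density %.3g cells/ml\n",
    x$mode, x$env$horizon_h, length(unique(fin$genotype)), sum(fin$density)
  ))
  cat(sprintf(
    "  residual glucose %.3g%%, galactose %.3g%%; events: %s\n",
    x$resources_final[["glucose"]], x$resources_final[["galactose"]],
    paste(x$events$kind, collapse = ", ")
  ))
  invisible(x)
}

#' Evaluate a trajectory at arbitrary times
#'
#' Densities are evaluated exactly from the stored piecewise-exponential
#' segments (no interpolation error).
#'
#' @param traj A `gal_trajectory`.
#' @param t_h Time(s) in hours, within `[0, horizon]`.
#' @return A tibble with `time_h`, `genotype`, `phenotype`,
#'   `density_cells_per_ml`.
#' @export
density_at <- function(traj, t_h) {
  stopifnot(inherits(traj, "gal_trajectory"))
  horizon <- traj$env$horizon_h
  purrr::map_dfr(t_h, function(tt) {
    if (tt < 0 || tt > horizon + 1e-9) {
      abort("t_h must lie within [0, horizon]", class = "galgame_validation_error")
    }
    tt <- min(tt, horizon)
    seg <- NULL
    for (s in traj$segments) {
      if (tt <= s$t1 + 1e-12) {
        seg <- s
        break
      }
    }
    if (is.null(seg)) seg <- traj$segments[[length(traj$segments)]]
    rel <- min(max(tt - seg$t0, 0), seg$t1 - seg$t0)
    dens <- vapply(seg$terms, eval_terms, numeric(1), t = rel)
    tibble(
      time_h = tt, genotype = seg$genotype, phenotype = seg$phenotype,
      density_cells_per_ml = dens
    )
  })
}

#' Pooled density of one genotype at a probe time
#'
#' @param traj A `gal_trajectory`.
#' @param genotype Genotype label.
#' @param t_h Probe time in hours; `NULL` means the end of the trajectory.
#' @return Density in cells/ml (phenotypes pooled).
#' @export
genotype_density <- function(traj, genotype, t_h = NULL) {
  if (is.null(t_h)) t_h <- traj$env$horizon_h
  d <- density_at(traj, t_h)
  d <- d[d$genotype == genotype, ]
  if (nrow(d) == 0) {
    abort(sprintf("genotype '%s' not present in trajectory", genotype),
      class = "galgame_validation_error"
    )
  }
  sum(d$density_cells_per_ml)
}

#' Time to deplete a shared resource under exponential demand
#'
#' Solves for the unique `t` with
#' \deqn{\sum_i (N_i / Y_i)\,(e^{r_i t} - 1) = R,}
#' the time at which lineages with densities `N_i`, growth rates `r_i` and
#' yields `Y_i`, all growing exclusively on the resource, have consumed the
#' amount `R`. Newton iteration with a bisection safeguard; the residual
#' resource balance is driven below `1e-9 * R`.
#'
#' @param densities,rates,yields Equal-length numeric vectors describing the
#'   consuming lineages.
#' @param resource_level Available resource, same units as `densities/yields`
#'   imply. Must be positive.
#' @return Depletion time in hours, or `Inf` when total demand never reaches
#'   `resource_level` (e.g. no growing consumers).
#' @export
#' @examples
#' solve_depletion_time(6e7 * 0.05, 0.4, 6e7, 0.05) # one lineage, N = Y R: log(2)/r
solve_depletion_time <- function(densities, rates, yields, resource_level) {
  stopifnot(length(densities) == length(rates), length(rates) == length(yields))
  if (any(densities < 0) || any(rates < 0) || any(yields <= 0)) {
    abort("densities and rates must be >= 0, yields > 0", class = "galgame_validation_error")
  }
  if (resource_level <= 0) {
    abort("resource_level must be > 0", class = "galgame_validation_error")
  }
  keep <- densities > 0 & rates > 0
  if (!any(keep)) {
    return(Inf)
  }
  terms <- term_list(
    densities[keep] * rates[keep] / yields[keep],
    rates[keep]
  )
  solve_terms_depletion(terms, resource_level, Inf)
}

#' Realize phenotypes for a clonal population
#'
#' Assigns GAL-ON/GAL-OFF phenotypes to `n_cells` cells of a genotype with
#' ON-probability `p_on`, either in expectation (infinite-population limit)
#' or by a seeded binomial draw.
#'
#' @param p_on ON probability in `[0, 1]` (a [strategy()] row's `p_on`).
#' @param n_cells Number of cells, >= 0.
#' @param method `"expectation"` or `"binomial"`.
#' @param seed Integer seed for the binomial draw; the global RNG state is
#'   preserved.
#' @return A named numeric vector `c(n_on = , n_off = )`.
#' @export
realize_phenotypes <- function(p_on, n_cells, method = c("expectation", "binomial"),
                               seed = NULL) {
  method <- match.arg(method)
  if (!is.numeric(p_on) || p_on < 0 || p_on > 1) {
    abort("p_on must lie in [0, 1]", class = "galgame_validation_error")
  }
  if (n_cells < 0) abort("n_cells must be >= 0", class = "galgame_validation_error")
  if (method == "expectation") {
    n_on <- p_on * n_cells
  } else {
    draw <- function() rbinom(1, n_cells, p_on)
    n_on <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  c(n_on = n_on, n_off = n_cells - n_on)
}

#' Convert between optical density and cell density
#'
#' Linear conversion assuming 3e7 cells/ml at A600 = 1.0.
#'
#' @param value Non-negative value(s) to convert.
#' @param direction `"od_to_density"` or `"density_to_od"`.
#' @return Converted value(s).
#' @export
#' @examples
#' convert_od(1.0) # 3e7 cells/ml
#' convert_od(6e6, "density_to_od") # 0.2
convert_od <- function(value, direction = c("od_to_density", "density_to_od")) {
  direction <- match.arg(direction)
  if (any(value < 0)) abort("value must be >= 0", class = "galgame_validation_error")
  if (direction == "od_to_density") value * OD_CELLS_PER_ML else value / OD_CELLS_PER_ML
}
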