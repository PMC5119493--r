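#' Measurement-noise model for synthetic competition assays
#'
#' Emulates the two dominant error sources of the competition assay:
#' multiplicative lognormal noise on plate-reader optical densities
#' (coefficient of variation `od_cv`) and binomial counting noise on the
#' cytometer's fraction estimates (`n_events_per_well` events gated per
#' well). `od_cv = 0` together with `n_events_per_well = Inf` gives the
#' deterministic, noise-free limit.
#'
#' @param od_cv Coefficient of variation of OD noise, >= 0.
#' @param n_events_per_well Events per well (>= 1, may be `Inf`).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(od_cv = 0.05, n_events_per_well = 20000) {
  if (od_cv < 0) abort("od_cv must be >= 0", class = "galgame_validation_error")
  if (n_events_per_well < 1) {
    abort("n_events_per_well must be >= 1", class = "galgame_validation_error")
  }
  structure(
    list(od_cv = od_cv, n_events_per_well = n_events_per_well),
    class = "noise_model"
  )
}

noisy_od <- function(od, cv) {
  if (cv == 0) {
    return(od)
  }
  sdl <- sqrt(log(1 + cv^2))
  od * rlnorm(length(od), meanlog = -sdl^2 / 2, sdlog = sdl) # mean-preserving
}

noisy_fraction <- function(f, n_events) {
  if (!is.finite(n_events)) {
    return(f)
  }
  rbinom(length(f), n_events, f) / n_events
}

#' Generate a synthetic competition-assay dataset
#'
#' Emulates the 60-culture competition experiment: pure GAL-ON and GAL-OFF
#' strategists mixed at a grid of initial GAL-ON fractions with several
#' biological replicates per level, grown in the diauxic batch game,
#' measured as optical densities (with lognormal noise) and cytometry
#' fractions (with binomial noise). The generator returns the records in
#' the competition-CSV schema together with the noiseless stable fraction
#' of the underlying game as ground truth.
#'
#' @inheritParams simulate_batch
#' @param fraction_levels Initial GAL-ON fractions; default 10 levels
#'   spanning low to high.
#' @param replicates_per_level Biological replicates per level (default 6,
#'   giving 60 cultures).
#' @param noise A [noise_model()].
#' @param total_density Total inoculum density, cells/ml.
#' @param seed Integer seed; generation is reproducible given the seed.
#' @return A list: `records` (tibble in the competition schema with the
#'   focal strain = GAL-ON) and `f_true` (noiseless stable fraction).
#' @export
gen_competition_dataset <- function(env = sugar_env(), params = phenotype_params(),
                                    mode = "diauxic",
                                    fraction_levels = seq(0.05, 0.95, length.out = 10),
                                    replicates_per_level = 6,
                                    noise = noise_model(), seed = NULL,
                                    total_density = 3e4) {
  stopifnot(inherits(noise, "noise_model"), replicates_per_level >= 1)
  if (any(fraction_levels <= 0 | fraction_levels >= 1)) {
    abort("fraction_levels must lie in (0, 1)", class = "galgame_validation_error")
  }
  f_true <- stable_fraction(env, params, mode, total_density)$f_stable[1]

  # one deterministic simulation per level, reused across replicates
  sims <- purrr::map(fraction_levels, function(f) {
    traj <- simulate_batch(env, pure_pair(f, total_density), params, mode)
    list(
      f_i = f,
      f_f = genotype_density(traj, "ON") / sum(traj$final$density),
      od_i = convert_od(total_density, "density_to_od"),
      od_f = convert_od(sum(traj$final$density), "density_to_od")
    )
  })

  make <- function() {
    purrr::map_dfr(seq_along(sims), function(i) {
      s <- sims[[i]]
      purrr::map_dfr(seq_len(replicates_per_level), function(rep) {
        tibble(
          focal = "ON", other = "OFF",
          f_i = noisy_fraction(s$f_i, noise$n_events_per_well),
          f_f = noisy_fraction(s$f_f, noise$n_events_per_well),
          od_i = noisy_od(s$od_i, noise$od_cv),
          od_f = noisy_od(s$od_f, noise$od_cv),
          glucose_pct = env$glucose_pct, galactose_pct = env$galactose_pct,
          replicate = rep
        )
      })
    })
  }
  records <- if (is.null(seed)) make() else withr::with_seed(seed, make())
  list(records = records, f_true = f_true)
}

#' Generate a bimodal cytometry event table
#'
#' Draws per-cell log10 fluorescence values from a two-component Gaussian
#' mixture on the log10 scale: with probability `f_on` from the GAL-ON
#' component, otherwise from the GAL-OFF component. Defaults give the
#' clearly separated bimodal histogram of a mixed ON/OFF population.
#'
#' @param f_on True GAL-ON fraction in `[0, 1]`.
#' @param n_events Number of events (>= 1); the cytometer standard is
#'   20,000+ per well.
#' @param mu_off,mu_on Component means (log10 a.u.), `mu_on > mu_off`.
#' @param sigma_off,sigma_on Component spreads (> 0).
#' @param seed Integer seed.
#' @return A tibble with columns `event_id` and `log10_yfp`.
#' @export
gen_cytometry_events <- function(f_on, n_events = 20000,
                                 mu_off = 1.5, mu_on = 3.0,
                                 sigma_off = 0.25, sigma_on = 0.25, seed = NULL) {
  if (f_on < 0 || f_on > 1) abort("f_on must lie in [0, 1]", class = "galgame_validation_error")
  if (n_events < 1) abort("n_events must be >= 1", class = "galgame_validation_error")
  if (mu_on <= mu_off) abort("mu_on must exceed mu_off", class = "galgame_validation_error")
  if (sigma_off <= 0 || sigma_on <= 0) {
    abort("sigmas must be > 0", class = "galgame_validation_error")
  }
  draw <- function() {
    on <- runif(n_events) < f_on
    rnorm(n_events, ifelse(on, mu_on, mu_off), ifelse(on, sigma_on, sigma_off))
  }
  vals <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  tibble(event_id = seq_len(n_events), log10_yfp = vals)
}
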