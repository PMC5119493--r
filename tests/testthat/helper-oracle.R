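# Brute-force forward-Euler integrator: the independent oracle for the
# event-driven simulator. Implements the same model rules (threshold
# resource availability, per-phenotype growth components, OFF-to-galactose
# lag) by naive small-step integration. Deliberately shares no code with
# the package's segment machinery.
euler_batch <- function(env, inoculum, params, mode, dt = 1e-4) {
  inoculum <- galgame:::check_inoculum(inoculum)
  n_g <- nrow(inoculum)
  n_on <- inoculum$density * inoculum$p_on
  n_off <- inoculum$density * (1 - inoculum$p_on)
  glu <- env$glucose_pct
  gal <- env$galactose_pct
  t <- 0
  glu_dep_t <- if (glu <= 0) 0 else NA
  steps <- ceiling(env$horizon_h / dt)
  for (s in seq_len(steps)) {
    d_on <- numeric(n_g)
    d_off <- numeric(n_g)
    d_glu <- 0
    d_gal <- 0
    for (i in seq_len(n_g)) {
      if (mode == "exclusive") {
        if (gal > 0) {
          r <- params$r_galactose * (1 - params$cost_rate)
          d_on[i] <- d_on[i] + r * n_on[i]
          d_gal <- d_gal - r * n_on[i] / (params$yield_galactose * (1 - params$cost_yield))
        }
        if (glu > 0) {
          d_off[i] <- d_off[i] + params$r_glucose * n_off[i]
          d_glu <- d_glu - params$r_glucose * n_off[i] / params$yield_glucose
        }
      } else {
        if (glu > 0) {
          d_off[i] <- d_off[i] + params$r_glucose * n_off[i]
          d_glu <- d_glu - params$r_glucose * n_off[i] / params$yield_glucose
          r <- params$r_glucose * (1 - params$cost_rate)
          d_on[i] <- d_on[i] + r * n_on[i]
          d_glu <- d_glu - r * n_on[i] / (params$yield_glucose * (1 - params$cost_yield))
          if (gal > 0) {
            rc <- params$co_consumption * params$r_galactose
            d_on[i] <- d_on[i] + rc * n_on[i]
            d_gal <- d_gal - rc * n_on[i] / (params$yield_galactose * (1 - params$cost_yield))
          }
        } else if (gal > 0) {
          d_on[i] <- d_on[i] + params$r_galactose * n_on[i]
          d_gal <- d_gal - params$r_galactose * n_on[i] /
            (params$yield_galactose * (1 - params$cost_yield))
          lag_ok <- inoculum$post_depletion_switch[i] &&
            is.finite(params$lag_off_to_gal) &&
            !is.na(glu_dep_t) && (t - glu_dep_t) >= params$lag_off_to_gal
          if (lag_ok) {
            d_off[i] <- d_off[i] + params$r_galactose * n_off[i]
            d_gal <- d_gal - params$r_galactose * n_off[i] /
              (params$yield_galactose * (1 - params$cost_yield))
          }
        }
      }
      s_on <- inoculum$switch_on_rate[i]
      s_off <- inoculum$switch_off_rate[i]
      if (s_on > 0 || s_off > 0) {
        d_on[i] <- d_on[i] + s_on * n_off[i] - s_off * n_on[i]
        d_off[i] <- d_off[i] + s_off * n_on[i] - s_on * n_off[i]
      }
    }
    n_on <- n_on + dt * d_on
    n_off <- n_off + dt * d_off
    glu <- max(glu + dt * d_glu, 0)
    gal <- max(gal + dt * d_gal, 0)
    t <- t + dt
    if (glu <= 0 && is.na(glu_dep_t)) glu_dep_t <- t
  }
  list(
    final = tibble::tibble(
      genotype = rep(inoculum$genotype, 2),
      phenotype = rep(c("on", "off"), each = n_g),
      density = c(n_on, n_off)
    ),
    glucose = glu, galactose = gal
  )
}

# small random game generator for property tests
random_game <- function() {
  list(
    env = sugar_env(runif(1, 0.005, 0.08), runif(1, 0.005, 0.08), runif(1, 2, 6)),
    params = phenotype_params(
      r_glucose = runif(1, 0.2, 0.7), r_galactose = runif(1, 0.15, 0.6),
      yield_glucose = runif(1, 2e7, 8e7), yield_galactose = runif(1, 1e7, 6e7),
      cost_rate = runif(1, 0, 0.6), cost_yield = runif(1, 0, 0.3),
      co_consumption = runif(1, 0, 0.3),
      lag_off_to_gal = sample(c(Inf, runif(1, 0.2, 1.5)), 1)
    ),
    inoculum = dplyr::bind_rows(
      strategy("A", runif(1), post_depletion_switch = sample(c(TRUE, FALSE), 1)),
      strategy("B", runif(1), post_depletion_switch = sample(c(TRUE, FALSE), 1))
    ) %>% dplyr::mutate(density = runif(2, 1e4, 1e6)),
    mode = sample(c("exclusive", "diauxic"), 1)
  )
}
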