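# a fully symmetric exclusive game: equal rates, yields and resources, no cost
symmetric_game <- function(cost_rate = 0, cost_yield = 0) {
  list(
    env = sugar_env(0.05, 0.05, 300),
    params = phenotype_params(
      r_glucose = 0.4, r_galactose = 0.4,
      yield_glucose = 6e7, yield_galactose = 6e7,
      cost_rate = cost_rate, cost_yield = cost_yield
    )
  )
}

test_that("doublings follow the closed form on the calibration densities", {
  # growth from ~3e4 to ~6e6 cells/ml is log2(200) doublings
  p <- phenotype_params(cost_rate = 0, cost_yield = 0)
  traj <- simulate_batch(sugar_env(0.0995, 0, 100), pure_pair(0, 3e4), p, "diauxic")
  expect_equal(endpoint_generations(traj, "OFF"), log2(200), tolerance = 1e-6)
  # unchanged density is zero doublings
  traj0 <- simulate_batch(
    sugar_env(0.03, 0.05, 5),
    pure_pair(0.5), phenotype_params(r_glucose = 0, r_galactose = 0), "diauxic"
  )
  expect_equal(endpoint_generations(traj0, "ON"), 0)
  expect_error(endpoint_generations(traj0, "nope"), class = "galgame_validation_error")
})

test_that("endpoint doublings agree with the Euler oracle in the default game", {
  traj <- simulate_batch(sugar_env(), pure_pair(0.4), phenotype_params(), "diauxic")
  oracle <- euler_batch(sugar_env(), pure_pair(0.4), phenotype_params(), "diauxic", dt = 1e-4)
  on0 <- 0.4 * 3e4
  want <- log2(sum(oracle$final$density[oracle$final$genotype == "ON"]) / on0)
  expect_equal(endpoint_generations(traj, "ON"), want, tolerance = 0.005 * want)
})

test_that("the symmetric zero-cost game balances at one half", {
  g <- symmetric_game()
  curve <- fitness_vs_fraction(g$env, g$params, "exclusive", fraction_grid = 0.5)
  expect_equal(curve$generations_on, curve$generations_off, tolerance = 1e-9)
  fs <- stable_fraction(g$env, g$params, "exclusive")
  expect_equal(fs$f_stable, 0.5, tolerance = 1e-4)
  fo <- optimal_fraction(g$env, g$params, "exclusive")
  expect_equal(fo$f_opt, 0.5, tolerance = 1e-3)
})

test_that("fitness-vs-fraction reproduces the assay's frequency dependence", {
  curve <- fitness_vs_fraction(sugar_env(), phenotype_params(), "diauxic",
    fraction_grid = seq(0.1, 0.9, by = 0.1)
  )
  # GAL-ON doublings fall with its own frequency (galactose is shared);
  # its relative fitness is strictly decreasing across the whole range
  expect_true(all(diff(curve$generations_on[curve$initial_fraction_on < 0.85]) < 0))
  expect_true(all(diff(curve$relative_fitness_on) < 0))
  # OFF doublings rise as the slow-on-glucose ON strain takes over the culture
  expect_true(all(diff(curve$generations_off) > 0))
  # ON-dominated cultures have reached saturation by 16 h while OFF-dominated
  # cultures are still growing
  below <- curve$density_at_probe[curve$initial_fraction_on <= 0.3]
  expect_true(all(diff(below) > 0))
  at <- function(f) curve$density_at_probe[which.min(abs(curve$initial_fraction_on - f))]
  expect_gt(at(0.7), at(0.2))
  expect_error(
    fitness_vs_fraction(sugar_env(), phenotype_params(), fraction_grid = numeric(0)),
    class = "galgame_validation_error"
  )
})

test_that("yield-cost stable fraction matches its closed form", {
  # equal resources R and yields, pure yield cost c: equal doublings at
  # f* = (1-c) R / (R + (1-c) R)
  for (c in c(0, 0.1, 0.2, 0.4)) {
    g <- symmetric_game(cost_rate = 0, cost_yield = c)
    fs <- stable_fraction(g$env, g$params, "exclusive")
    expect_false(fs$boundary[1])
    expect_equal(fs$f_stable[1], (1 - c) / (2 - c), tolerance = 1e-3)
  }
})

test_that("single-resource games return flagged boundaries", {
  p <- phenotype_params()
  fs <- stable_fraction(sugar_env(0, 0.05, 40), p, "exclusive")
  expect_true(fs$boundary)
  expect_equal(fs$f_stable, 1)
  fs2 <- stable_fraction(sugar_env(0.05, 0, 40), p, "exclusive")
  expect_true(fs2$boundary)
  expect_equal(fs2$f_stable, 0)
  fo <- optimal_fraction(sugar_env(0, 0.05, 40), p, "exclusive")
  expect_true(fo$boundary)
  expect_equal(fo$f_opt, 1)
})

test_that("identical strategies have relative fitness exactly one", {
  w <- invasion_fitness(
    strategy("res", 0.4), strategy("inv", 0.4),
    sugar_env(), phenotype_params(), "diauxic"
  )
  expect_identical(w, 1)
  expect_error(
    invasion_fitness(strategy("a", 1), strategy("b", 0), sugar_env(),
      phenotype_params(),
      epsilon = 0.5
    ),
    class = "galgame_validation_error"
  )
})

test_that("pure strategists are mutually invasible in mixed sugars only", {
  p <- phenotype_params()
  mi <- mutual_invasibility(
    strategy("ON", 1), strategy("OFF", 0), sugar_env(), p, "diauxic"
  )
  expect_true(all(mi$w_rel > 1))
  expect_true(attr(mi, "mutually_invasible"))
  # glucose-only: GAL-ON pays its cost for nothing, OFF favored at any
  # invasion frequency
  for (eps in c(0.01, 0.1)) {
    w_on <- invasion_fitness(
      strategy("OFF", 0), strategy("ON", 1),
      sugar_env(0.03, 0, 20), p, "diauxic", epsilon = eps
    )
    expect_lt(w_on, 1)
  }
})

test_that("optimal fraction equalizes depletion times and beats a grid search", {
  g <- symmetric_game(cost_rate = 0.3, cost_yield = 0.3)
  fo <- optimal_fraction(g$env, g$params, "exclusive")
  expect_lt(
    abs(fo$t_glucose_h - fo$t_galactose_h),
    0.01 * fo$t_deplete_h
  )
  # exhaustive oracle at resolution 0.001
  grid <- seq(0.3, 0.9, by = 0.001)
  tt <- vapply(grid, function(f) {
    traj <- simulate_batch(
      sugar_env(g$env$glucose_pct, g$env$galactose_pct, 300),
      pure_pair(f), g$params, "exclusive"
    )
    ev <- traj$events
    max(
      ev$time_h[ev$kind == "glucose_depleted"][1],
      ev$time_h[ev$kind == "galactose_depleted"][1]
    )
  }, numeric(1))
  expect_lt(abs(fo$f_opt - grid[which.min(tt)]), 2e-3)
})

test_that("a steeper GAL-ON penalty separates the two solution concepts", {
  g <- symmetric_game()
  sweep <- parameter_sweep(g$env, g$params, "exclusive",
    axis = "cost",
    values = c(0, 0.3)
  )
  expect_equal(sweep$f_stable[1], 0.5, tolerance = 1e-3)
  expect_equal(sweep$f_opt[1], 0.5, tolerance = 2e-3)
  expect_lt(sweep$f_stable[2], sweep$f_stable[1])
  expect_gt(sweep$f_opt[2], sweep$f_opt[1])
  expect_gt(sweep$f_opt[2] - sweep$f_stable[2], 0.05)
  expect_error(
    parameter_sweep(g$env, g$params, axis = "cost", values = 0.1),
    class = "galgame_validation_error"
  )
})

test_that("relabeling the two resources mirrors the stable fraction", {
  env <- sugar_env(0.02, 0.045, 200)
  p <- phenotype_params(
    r_glucose = 0.5, r_galactose = 0.3,
    yield_glucose = 5e7, yield_galactose = 3e7,
    cost_rate = 0.2, cost_yield = 0.15
  )
  swapped_env <- sugar_env(0.045, 0.02, 200)
  # swapping resources and their kinetics maps ON onto OFF; the GAL-ON cost
  # must ride along, so compare against the zero-cost game and its mirror
  p0 <- phenotype_params(
    r_glucose = 0.5, r_galactose = 0.3,
    yield_glucose = 5e7, yield_galactose = 3e7,
    cost_rate = 0, cost_yield = 0
  )
  p0_swap <- phenotype_params(
    r_glucose = 0.3, r_galactose = 0.5,
    yield_glucose = 3e7, yield_galactose = 5e7,
    cost_rate = 0, cost_yield = 0
  )
  f1 <- stable_fraction(env, p0, "exclusive")$f_stable
  f2 <- stable_fraction(swapped_env, p0_swap, "exclusive")$f_stable
  expect_equal(f1, 1 - f2, tolerance = 2e-4)
})

test_that("doublings of both strategists agree at the stable fraction", {
  fs <- stable_fraction(sugar_env(), phenotype_params(), "diauxic")
  traj <- simulate_batch(sugar_env(), pure_pair(fs$f_stable), phenotype_params(), "diauxic")
  expect_lt(
    abs(endpoint_generations(traj, "ON") - endpoint_generations(traj, "OFF")),
    1e-3
  )
})

test_that("serial dilution converges to the stable fraction from both sides", {
  fs <- stable_fraction(sugar_env(), phenotype_params(), "diauxic")$f_stable
  run_from <- function(f0) {
    run <- run_dilution_schedule(
      sugar_env(), pure_pair(f0), phenotype_params(), "diauxic",
      dilution_schedule(30, 20, 100),
      keep_trajectories = FALSE
    )
    run$frequencies %>%
      dplyr::filter(genotype == "ON", cycle == 30) %>%
      dplyr::pull(frequency)
  }
  expect_lt(abs(run_from(0.1) - fs), 0.02)
  expect_lt(abs(run_from(0.9) - fs), 0.02)
})

test_that("pseudo-chemostat co-cultures converge to a shared interior mix", {
  run_from <- function(f0) {
    run <- run_dilution_schedule(
      sugar_env(0.03, 0.05, 3), pure_pair(f0), phenotype_params(), "diauxic",
      pseudo_chemostat_schedule(120),
      keep_trajectories = FALSE
    )
    run$frequencies %>%
      dplyr::filter(genotype == "ON", cycle == 120) %>%
      dplyr::pull(frequency)
  }
  lo <- run_from(0.05)
  hi <- run_from(0.95)
  expect_gt(lo, 0.1)
  expect_lt(hi, 0.9)
  expect_lt(abs(lo - hi), 0.05)
})

test_that("the ESS mix is neutrally uninvasible at high resident frequency", {
  env <- sugar_env()
  p <- phenotype_params()
  tab <- ess_neutrality(env, p, "diauxic", resident_freq_grid = c(0.99))
  expect_true(all(abs(tab$w_rel - 1) <= 0.02))
  # an identical mutant is exactly neutral at any frequency
  fs <- stable_fraction(env, p, "diauxic")$f_stable
  self <- ess_neutrality(env, p, "diauxic",
    mutants = strategy("self", fs),
    resident_freq_grid = c(0.3, 0.9)
  )
  expect_equal(self$w_rel, c(1, 1))
  # the mixed strategist invades both pure residents when rare
  w_vs_off <- invasion_fitness(
    strategy("OFF", 0), strategy("mix", fs), env, p, "diauxic",
    epsilon = 0.01
  )
  w_vs_on <- invasion_fitness(
    strategy("ON", 1), strategy("mix", fs), env, p, "diauxic",
    epsilon = 0.01
  )
  expect_gt(w_vs_off, 1)
  expect_gt(w_vs_on, 1)
  expect_warning(
    ess_neutrality(env, p, "diauxic",
      resident_p_on = 0.9,
      resident_freq_grid = 0.5
    ),
    "neutrality"
  )
})
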