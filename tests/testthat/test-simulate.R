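test_that("mass is conserved: final cells equal yield times resource used", {
  # pure-ON exclusive game with zero cost and a long horizon: all galactose
  # converted at full yield
  p <- phenotype_params(cost_rate = 0, cost_yield = 0)
  env <- sugar_env(0, 0.05, 100)
  traj <- simulate_batch(env, pure_pair(1, 3e4), p, "exclusive")
  expect_equal(
    sum(traj$final$density) - 3e4, p$yield_galactose * 0.05,
    tolerance = 1e-9
  )
  expect_equal(unname(traj$resources_final["galactose"]), 0)
})

test_that("zero growth rates leave the initial state unchanged", {
  p <- phenotype_params(r_glucose = 0, r_galactose = 0)
  traj <- simulate_batch(sugar_env(), pure_pair(0.4), p, "diauxic")
  expect_equal(sum(traj$final$density), 3e4)
  expect_equal(unname(traj$resources_final), c(0.03, 0.05))
})

test_that("depletion time has its closed form for a single lineage", {
  # demand reaches R exactly when e^{rt} - 1 = 1
  expect_equal(solve_depletion_time(6e7 * 0.05, 0.4, 6e7, 0.05), log(2) / 0.4,
    tolerance = 1e-8
  )
  expect_identical(solve_depletion_time(0, 0.4, 6e7, 0.05), Inf)
  expect_identical(solve_depletion_time(c(1e4, 1e5), c(0, 0), c(6e7, 6e7), 0.05), Inf)
  expect_error(solve_depletion_time(1e4, 0.4, 6e7, 0), class = "galgame_validation_error")
})

test_that("depletion time matches a fine-grained forward-Euler integration", {
  # two lineages with distinct rates sharing one resource
  withr::with_seed(11, {
    for (rep in 1:3) {
      n <- runif(2, 1e4, 1e5)
      r <- runif(2, 0.2, 0.6)
      y <- runif(2, 2e7, 8e7)
      level <- runif(1, 0.01, 0.05)
      t_solved <- solve_depletion_time(n, r, y, level)
      # naive integration
      dt <- 1e-4
      t <- 0
      cons <- 0
      nn <- n
      while (cons < level && t < 100) {
        cons <- cons + dt * sum(r * nn / y)
        nn <- nn + dt * r * nn
        t <- t + dt
      }
      expect_lt(abs(t_solved - t), 1e-3)
    }
  })
})

test_that("event-driven trajectories match the Euler oracle on random games", {
  withr::with_seed(42, {
    for (rep in 1:6) {
      g <- random_game()
      traj <- simulate_batch(g$env, g$inoculum, g$params, g$mode)
      oracle <- euler_batch(g$env, g$inoculum, g$params, g$mode, dt = 1e-4)
      got <- dplyr::arrange(traj$final, genotype, phenotype)
      want <- dplyr::arrange(oracle$final, genotype, phenotype)
      denom <- pmax(want$density, 1)
      expect_lt(max(abs(got$density - want$density) / denom), 1e-3)
    }
  })
})

test_that("mass balance holds across randomized games in both modes", {
  withr::with_seed(7, {
    for (rep in 1:25) {
      g <- random_game()
      traj <- simulate_batch(g$env, g$inoculum, g$params, g$mode)
      p <- g$params
      cons <- traj$consumption
      y_glu <- ifelse(cons$phenotype == "on" & g$mode == "diauxic",
        p$yield_glucose * (1 - p$cost_yield), p$yield_glucose
      )
      y_gal <- p$yield_galactose * (1 - p$cost_yield)
      if (g$mode == "exclusive") {
        y_gal <- rep(p$yield_galactose * (1 - p$cost_yield), nrow(cons))
      } else {
        # post-lag OFF growth also uses the GAL-ON yield
        y_gal <- rep(p$yield_galactose * (1 - p$cost_yield), nrow(cons))
      }
      produced <- sum(cons$glucose_pct * y_glu) + sum(cons$galactose_pct * y_gal)
      gained <- sum(traj$final$density) - sum(traj$lineages0$density)
      expect_equal(produced, gained, tolerance = 1e-6)
      # resource bookkeeping closes
      expect_equal(
        sum(cons$glucose_pct), g$env$glucose_pct - unname(traj$resources_final["glucose"]),
        tolerance = 1e-6
      )
      expect_equal(
        sum(cons$galactose_pct), g$env$galactose_pct - unname(traj$resources_final["galactose"]),
        tolerance = 1e-6
      )
    }
  })
})

test_that("resources are non-increasing and total density non-decreasing", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      g <- random_game()
      traj <- simulate_batch(g$env, g$inoculum, g$params, g$mode)
      tot <- traj$states %>%
        dplyr::group_by(time_h) %>%
        dplyr::summarise(
          dens = sum(density_cells_per_ml),
          glu = glucose_pct[1], gal = galactose_pct[1], .groups = "drop"
        ) %>%
        dplyr::arrange(time_h)
      expect_true(all(diff(tot$dens) >= -1e-6 * max(tot$dens)))
      expect_true(all(diff(tot$glu) <= 1e-12))
      expect_true(all(diff(tot$gal) <= 1e-12))
      expect_true(all(diff(tot$time_h) > 0))
    }
  })
})

test_that("negative frequency dependence: rare GAL-ON out-divides common GAL-ON", {
  env <- sugar_env()
  p <- phenotype_params()
  gen_at <- function(f) {
    endpoint_generations(simulate_batch(env, pure_pair(f), p, "diauxic"), "ON")
  }
  expect_gt(gen_at(0.1), gen_at(0.9))
})

test_that("phenotype realization honors its contracts", {
  expect_equal(realize_phenotypes(1, 500), c(n_on = 500, n_off = 0))
  expect_equal(realize_phenotypes(0, 123), c(n_on = 0, n_off = 123))
  expect_equal(realize_phenotypes(0.37, 1000)[["n_on"]], 370)
  draw <- realize_phenotypes(0.4, 20000, "binomial", seed = 5)
  expect_identical(draw, realize_phenotypes(0.4, 20000, "binomial", seed = 5))
  # 3-sigma binomial band around p
  expect_lt(abs(draw[["n_on"]] / 20000 - 0.4), 3 * sqrt(0.4 * 0.6 / 20000))
  expect_error(realize_phenotypes(1.2, 10), class = "galgame_validation_error")
})

test_that("OD conversion is linear with a lossless round trip", {
  expect_equal(convert_od(1.0), 3e7)
  expect_equal(convert_od(0.2), 6e6)
  expect_equal(convert_od(0), 0)
  expect_equal(convert_od(convert_od(0.123), "density_to_od"), 0.123)
  expect_error(convert_od(-1), class = "galgame_validation_error")
})

test_that("identical inputs give bit-identical trajectories", {
  g <- withr::with_seed(3, random_game())
  t1 <- simulate_batch(g$env, g$inoculum, g$params, g$mode,
    phenotype_realization = "binomial", seed = 99
  )
  t2 <- simulate_batch(g$env, g$inoculum, g$params, g$mode,
    phenotype_realization = "binomial", seed = 99
  )
  expect_identical(t1$states, t2$states)
  expect_identical(t1$events, t2$events)
})

test_that("stochastic phenotype switching integrates exactly", {
  # one genotype with switching in exclusive mode, checked against Euler
  ino <- strategy("wt", 0.5, switch_on_rate = 0.08, switch_off_rate = 0.05) %>%
    dplyr::mutate(density = 5e4)
  env <- sugar_env(0.02, 0.03, 4)
  p <- phenotype_params(cost_rate = 0.2, cost_yield = 0.1)
  traj <- simulate_batch(env, ino, p, "exclusive")
  oracle <- euler_batch(env, ino, p, "exclusive", dt = 1e-4)
  got <- dplyr::arrange(traj$final, phenotype)$density
  want <- dplyr::arrange(oracle$final, phenotype)$density
  expect_lt(max(abs(got - want) / pmax(want, 1)), 1e-3)
})

test_that("dilution runs preserve symmetric frequencies and detect extinction", {
  # identical kinetics for both genotypes: frequencies must stay constant
  ino <- dplyr::bind_rows(strategy("A", 0), strategy("B", 0)) %>%
    dplyr::mutate(density = c(2e4, 1e4))
  run <- run_dilution_schedule(
    sugar_env(0.03, 0, 10), ino, phenotype_params(), "diauxic",
    dilution_schedule(5, 10, 50)
  )
  freqs <- run$frequencies %>% dplyr::filter(genotype == "A")
  expect_equal(freqs$frequency, rep(2 / 3, 5), tolerance = 1e-12)
  # a population that cannot grow is flushed out
  run2 <- run_dilution_schedule(
    sugar_env(0, 0, 5), pure_pair(0.5), phenotype_params(), "exclusive",
    dilution_schedule(10, 5, 1000)
  )
  expect_true(run2$extinct)
  expect_lt(max(run2$frequencies$cycle), 10)
})

test_that("glucose-only pseudo-chemostat flushes out the costly GAL-ON strain", {
  run <- run_dilution_schedule(
    sugar_env(0.03, 0, 3), pure_pair(0.5), phenotype_params(), "diauxic",
    pseudo_chemostat_schedule(15)
  )
  f_on <- run$frequencies %>%
    dplyr::filter(genotype == "ON") %>%
    dplyr::pull(frequency)
  expect_true(all(diff(f_on) < 0))
  expect_lt(dplyr::last(f_on), 0.05)
})

test_that("density_at evaluates trajectories exactly between events", {
  traj <- simulate_batch(sugar_env(), pure_pair(0.4), phenotype_params(), "diauxic")
  # at an event time the stored state and the segment evaluation agree
  ev_t <- traj$events$time_h[1]
  at_ev <- density_at(traj, ev_t)
  stored <- traj$states %>% dplyr::filter(abs(time_h - ev_t) < 1e-12)
  expect_equal(
    dplyr::arrange(at_ev, genotype, phenotype)$density_cells_per_ml,
    dplyr::arrange(stored, genotype, phenotype)$density_cells_per_ml,
    tolerance = 1e-9
  )
  # before the first event growth is exponential at the glucose-phase rates
  d4 <- density_at(traj, 4)
  off4 <- d4$density_cells_per_ml[d4$genotype == "OFF" & d4$phenotype == "off"]
  expect_equal(off4, 0.6 * 3e4 * exp(0.45 * 4), tolerance = 1e-9)
  expect_error(density_at(traj, 25), class = "galgame_validation_error")
})
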