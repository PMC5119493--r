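#' Configuration for an in-silico serial-dilution evolution experiment
#'
#' Mirrors the laboratory protocol: a founder strategy is propagated through
#' daily grow-dilute cycles (default 26 cycles: one 200-fold and one
#' 500-fold dilution early on, then 1,000-fold daily, together ~250
#' generations of regrowth), with mutation acting on the strategy parameter
#' `p_on` and binomial sampling of survivors at each bottleneck.
#'
#' Two mutation sources are modeled. Standing variation: the doxycycline
#' induction preculture grows the founder for `preculture_generations`
#' doublings before the experiment starts, so the inoculum already carries
#' pre-existing strategy mutants at frequency
#' `mutation_rate * preculture_generations`. This is what lets a
#' pure-GAL-OFF population in pure galactose — where the founder cannot
#' divide at all — be rescued by a constitutive GAL-ON mutant in most
#' replicates while the rest wash out to extinction. De novo: each cycle
#' draws mutations from the divisions performed; a mutant arising mid-cycle
#' carries a Luria-Delbruck clone size (~1/U) into the bottleneck.
#'
#' The default mutation kernel reflects the two mutation classes the
#' experiment can produce in quantity — loss of function (`p_on = 0`) and
#' constitutive activation (`p_on = 1`) — plus rare tuning mutations drawn
#' uniformly on (0, 1) that allow clonal mixed strategists to arise.
#'
#' @param founder A one-row [strategy()] tibble; the engineered pure
#'   strategists of the competition assays are the laboratory founders.
#' @param env A [sugar_env()]; the three laboratory conditions are 0.1%
#'   glucose, 0.1% galactose, and the 0.03%/0.05% mixture, grown 24 h per
#'   cycle.
#' @param params A [phenotype_params()].
#' @param schedule Dilution factors, one per cycle.
#' @param mutation_rate Per-division probability of a strategy mutation
#'   (any lesion disabling or constitutively activating the engineered
#'   induction circuit).
#' @param mutation_kernel Function `n -> n` new `p_on` values.
#' @param preculture_generations Doublings of founder growth during the
#'   induction preculture that seed standing variation (default
#'   `log2(200)`, the 0.01% glucose induction step).
#' @param n_replicates Number of replicate populations.
#' @param initial_density Founder density at cycle 1, cells/ml.
#' @param volume_ml Simulated well volume; populations are integer cell
#'   counts in this volume, so bottlenecks carry real drift.
#' @return An object of class `evolution_config`.
#' @export
evolution_config <- function(founder = strategy("OFF", 0),
                             env = sugar_env(0.03, 0.05, 24),
                             params = phenotype_params(),
                             schedule = c(200, 500, rep(1000, 24)),
                             mutation_rate = 3e-5,
                             mutation_kernel = default_mutation_kernel,
                             preculture_generations = log2(200),
                             n_replicates = 8,
                             initial_density = 7.5e4, volume_ml = 0.2) {
  if (any(schedule <= 1)) {
    abort("dilution factors must be > 1", class = "galgame_validation_error")
  }
  if (mutation_rate < 0 || mutation_rate > 1) {
    abort("mutation_rate must lie in [0, 1]", class = "galgame_validation_error")
  }
  stopifnot(is.function(mutation_kernel), n_replicates >= 1, initial_density > 0)
  structure(
    list(
      founder = check_inoculum(mutate(founder, density = initial_density)),
      env = env, params = params, schedule = schedule,
      mutation_rate = mutation_rate, mutation_kernel = mutation_kernel,
      preculture_generations = preculture_generations,
      n_replicates = n_replicates, initial_density = initial_density,
      volume_ml = volume_ml
    ),
    class = "evolution_config"
  )
}

#' @rdname evolution_config
#' @param n Number of mutant `p_on` values to draw.
#' @export
default_mutation_kernel <- function(n) {
  u <- runif(n)
  ifelse(u < 0.45, 0, ifelse(u < 0.9, 1, runif(n)))
}

#' Run the serial-dilution evolution experiment
#'
#' Each cycle: phenotypes are realized binomially per genotype, the
#' population grows for the cycle's duration in fresh medium (diauxic
#' model), mutations are drawn binomially from the number of divisions
#' (each founding one cell of a new genotype with `p_on` from the mutation
#' kernel), and survivors of the bottleneck are sampled binomially. The
#' pooled GAL-ON fraction is recorded at the start of every cycle (the
#' realized phenotype mix). A replicate whose population hits zero cells is
#' labeled extinct and truncated.
#'
#' Outcomes over the final five cycles: `fixed_on` (pooled fraction ON
#' > 0.95), `fixed_off` (< 0.05), otherwise `interior_mix`; `extinct` when
#' the population collapsed.
#'
#' @param config An [evolution_config()].
#' @param seed Integer seed; replicate `r` derives its own stream.
#' @return An object of class `gal_evolution`: list with `runs` (tibble:
#'   `replicate`, `cycle`, `genotype`, `p_on`, `frequency`, `fraction_on`,
#'   `density_end`), `outcomes` (tibble: `replicate`, `outcome`,
#'   `final_fraction_on`), and `config`.
#' @export
evolve <- function(config, seed = 1) {
  stopifnot(inherits(config, "evolution_config"))
  runs <- purrr::map_dfr(seq_len(config$n_replicates), function(rep) {
    withr::with_seed((seed + 104729L * rep) %% 2147483647L, {
      evolve_one(config) %>% mutate(replicate = rep)
    })
  })
  outcomes <- runs %>%
    group_by(.data$replicate) %>%
    summarise(
      outcome = classify_outcome(.data$fraction_on[!duplicated(.data$cycle)],
        extinct = any(.data$extinct)
      ),
      final_fraction_on = mean(tail(.data$fraction_on[!duplicated(.data$cycle)], 5)),
      .groups = "drop"
    )
  structure(list(runs = runs, outcomes = outcomes, config = config),
    class = "gal_evolution"
  )
}

classify_outcome <- function(fraction_series, extinct) {
  if (extinct) {
    return("extinct")
  }
  f <- mean(tail(fraction_series, 5))
  if (f > 0.95) "fixed_on" else if (f < 0.05) "fixed_off" else "interior_mix"
}

# single replicate; RNG scope is managed by the caller
evolve_one <- function(config) {
  vol <- config$volume_ml
  genotab <- config$founder %>%
    mutate(count = round(.data$density * vol)) %>%
    select("genotype", "p_on", "switch_on_rate", "switch_off_rate",
      "post_depletion_switch", "count"
    )
  # standing variation from the induction preculture
  pre_freq <- min(config$mutation_rate * config$preculture_generations, 1)
  if (pre_freq > 0) {
    n_pre <- rbinom(1, genotab$count[1], pre_freq)
    if (n_pre > 0) {
      pre_p <- config$mutation_kernel(n_pre)
      genotab$count[1] <- genotab$count[1] - n_pre
      for (p in pre_p) {
        key <- sprintf("p%.6f", p)
        hit <- which(genotab$genotype == key)
        if (length(hit) == 1) {
          genotab$count[hit] <- genotab$count[hit] + 1
        } else {
          genotab <- bind_rows(
            genotab, mutate(genotab[1, ], genotype = key, p_on = p, count = 1)
          )
        }
      }
    }
  }
  rows <- list()
  extinct <- FALSE
  for (cyc in seq_along(config$schedule)) {
    n_on <- rbinom(nrow(genotab), genotab$count, genotab$p_on)
    fraction_on <- sum(n_on) / sum(genotab$count)
    lineages <- tibble(
      genotype = rep(genotab$genotype, each = 2),
      phenotype = rep(c("on", "off"), nrow(genotab)),
      density = as.vector(rbind(n_on, genotab$count - n_on)) / vol
    )
    out <- integrate_batch(lineages, genotab, config$env, config$params, "diauxic")
    end <- out$final %>%
      group_by(.data$genotype) %>%
      summarise(density = sum(.data$density), .groups = "drop")
    end <- genotab %>%
      select(-"count") %>%
      left_join(end, by = "genotype") %>%
      mutate(cells = round(.data$density * vol))

    # mutation: drawn from the divisions each genotype underwent this cycle.
    # A mutant arising mid-cycle leaves a clone by the end of the cycle;
    # for a neutral marker in an exponentially expanding population the
    # clone size is ~1/U for U uniform (the Luria-Delbruck jackpot tail),
    # capped by the parent's cell count.
    divisions <- pmax(end$cells - genotab$count, 0)
    n_mut <- rbinom(length(divisions), divisions, config$mutation_rate)
    if (sum(n_mut) > 0) {
      new_p <- config$mutation_kernel(sum(n_mut))
      parents <- rep(seq_along(n_mut), n_mut)
      for (j in seq_along(new_p)) {
        clone <- min(ceiling(1 / runif(1)), end$cells[parents[j]])
        if (clone < 1) next
        end$cells[parents[j]] <- end$cells[parents[j]] - clone
        key <- sprintf("p%.6f", new_p[j])
        hit <- which(end$genotype == key)
        if (length(hit) == 1) {
          end$cells[hit] <- end$cells[hit] + clone
        } else {
          parent <- end[parents[j], ]
          end <- bind_rows(end, mutate(parent, genotype = key, p_on = new_p[j], cells = clone))
        }
      }
    }

    total <- sum(end$cells)
    rows[[cyc]] <- tibble(
      cycle = cyc, genotype = end$genotype, p_on = end$p_on,
      frequency = if (total > 0) end$cells / total else NA_real_,
      fraction_on = fraction_on, density_end = end$cells / vol,
      extinct = FALSE
    )
    survivors <- rbinom(nrow(end), end$cells, 1 / config$schedule[cyc])
    end$count <- survivors
    genotab <- end %>%
      filter(.data$count > 0) %>%
      select(-"density", -"cells")
    if (nrow(genotab) == 0 || sum(genotab$count) == 0) {
      extinct <- TRUE
      break
    }
  }
  out <- bind_rows(rows)
  if (extinct && nrow(out) > 0) out$extinct[out$cycle == max(out$cycle)] <- TRUE
  out
}

#' @export
print.gal_evolution <- function(x, ...) {
  cat(sprintf(
    "<gal_evolution> %d replicate(s), %d cycle(s); outcomes: %s\n",
    x$config$n_replicates, length(x$config$schedule),
    paste(sprintf("%s=%d", names(table(x$outcomes$outcome)), table(x$outcomes$outcome)),
      collapse = ", "
    )
  ))
  invisible(x)
}

#' Colony-purification assay on an evolved population
#'
#' Distinguishes the two ways a population can show a stable phenotype mix:
#' genetic coexistence of pure strategists (colonies split between ~0 and
#' ~1 GAL-ON) versus a clonal population of mixed strategists (every colony
#' individually reproduces an interior fraction). Colonies are founded by
#' single cells sampled by genotype frequency; each is regrown clonally in
#' the assay environment and its realized GAL-ON fraction recorded.
#'
#' @param population A tibble with columns `genotype`, `p_on` and `count`
#'   (or `frequency`), e.g. the final cycle of a [evolve()] run.
#' @param n_colonies Number of colonies picked (>= 2; cannot exceed the
#'   population cell count when counts are given).
#' @param env,params Assay environment (defaults: the mixed-sugar game).
#' @param n_assay_cells Cells realized per colony culture.
#' @param seed Integer seed.
#' @return A list: `colonies` (tibble `colony`, `genotype`, `p_on`,
#'   `fraction_on`) and `classification` in
#'   `c("coexistence_of_pures", "clonal_mixed", "monomorphic")`.
#' @export
colony_assay <- function(population, n_colonies = 24, env = sugar_env(),
                         params = phenotype_params(), n_assay_cells = 20000,
                         seed = NULL) {
  stopifnot(is.data.frame(population), all(c("genotype", "p_on") %in% names(population)))
  if (n_colonies < 2) {
    abort("n_colonies must be >= 2", class = "galgame_validation_error")
  }
  w <- if ("count" %in% names(population)) population$count else population$frequency
  if (is.null(w) || all(w <= 0)) {
    abort("population needs positive count or frequency weights", class = "galgame_validation_error")
  }
  if ("count" %in% names(population) && n_colonies > sum(population$count)) {
    abort("n_colonies exceeds the population cell count", class = "galgame_validation_error")
  }
  run <- function() {
    picks <- sample.int(nrow(population), n_colonies, replace = TRUE, prob = w)
    purrr::map_dfr(seq_along(picks), function(i) {
      p <- population$p_on[picks[i]]
      n_on <- rbinom(1, n_assay_cells, p)
      tibble(
        colony = i, genotype = population$genotype[picks[i]], p_on = p,
        fraction_on = colony_fraction(n_on, n_assay_cells, env, params)
      )
    })
  }
  colonies <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  fr <- colonies$fraction_on
  interior <- fr > 0.05 & fr < 0.95
  classification <- if (mean(interior) >= 0.5) {
    "clonal_mixed"
  } else if (any(fr >= 0.95) && any(fr <= 0.05)) {
    "coexistence_of_pures"
  } else {
    "monomorphic"
  }
  list(colonies = colonies, classification = classification)
}

# grow one clonal colony culture and read its end-of-cycle ON fraction
colony_fraction <- function(n_on, n_total, env, params) {
  dens <- 3e4
  lineages <- tibble(
    genotype = "colony", phenotype = c("on", "off"),
    density = dens * c(n_on, n_total - n_on) / n_total
  )
  genotab <- strategy("colony", n_on / n_total)
  out <- integrate_batch(lineages, genotab, env, params, "diauxic")
  fin <- out$final
  sum(fin$density[fin$phenotype == "on"]) / sum(fin$density)
}

#' Generations of regrowth implied by a dilution schedule
#'
#' Under the regrow-to-saturation assumption each cycle contributes
#' `log2(dilution factor)` doublings, so the experiment's total is
#' `sum(log2(factors))`. The standard 26-cycle protocol (24 daily
#' 1,000-fold dilutions plus early 200- and 500-fold rounds) gives ~256
#' generations, matching the reported ~250.
#'
#' @param schedule Numeric vector of dilution factors, all > 1.
#' @return Total generations of regrowth.
#' @export
#' @examples
#' expected_generations(c(200, 500, rep(1000, 24)))
expected_generations <- function(schedule) {
  if (length(schedule) == 0 || any(schedule <= 1)) {
    abort("all dilution factors must be > 1", class = "galgame_validation_error")
  }
  sum(log2(schedule))
}
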