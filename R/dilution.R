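#' Grow-dilute schedules
#'
#' Helpers for the two laboratory protocols: daily 1,000-fold dilution after
#' a day of growth, and the pseudo-chemostat (2-fold dilution every 3 h that
#' mimics continuous culture at a constant dilution rate).
#'
#' @param n_cycles Number of grow-dilute cycles.
#' @param grow_h Growth duration per cycle, hours.
#' @param dilution_factor Fold-dilution applied after each cycle (> 1).
#' @return A tibble with columns `grow_h` and `dilution_factor`.
#' @export
dilution_schedule <- function(n_cycles, grow_h = 24, dilution_factor = 1000) {
  stopifnot(n_cycles >= 1)
  if (any(dilution_factor <= 1)) {
    abort("dilution factors must be > 1", class = "galgame_validation_error")
  }
  tibble(
    grow_h = rep_len(grow_h, n_cycles),
    dilution_factor = rep_len(dilution_factor, n_cycles)
  )
}

#' @rdname dilution_schedule
#' @export
pseudo_chemostat_schedule <- function(n_cycles, grow_h = 3, dilution_factor = 2) {
  dilution_schedule(n_cycles, grow_h, dilution_factor)
}

#' Run a repeated-dilution culture
#'
#' Runs consecutive batch cycles: each cycle grows the population in fresh
#' medium for `grow_h` hours via [simulate_batch()], then divides all
#' densities by the cycle's dilution factor to seed the next cycle. Genotype
#' frequencies are recorded at the end of every cycle. If the total
#' population falls below one cell per simulated volume the run is flagged
#' extinct and the series truncated.
#'
#' @inheritParams simulate_batch
#' @param schedule A tibble from [dilution_schedule()] (columns `grow_h`,
#'   `dilution_factor`), one row per cycle.
#' @param keep_trajectories Keep every cycle's `gal_trajectory` (memory
#'   heavy for long runs)? Default `TRUE`.
#'
#' @return A list of class `gal_dilution_run` with `frequencies` (tibble:
#'   `cycle`, `genotype`, `frequency`, `density_end`, `density_start`),
#'   `trajectories` (list, if kept), and `extinct` flag.
#' @export
run_dilution_schedule <- function(env, inoculum, params, mode = c("diauxic", "exclusive"),
                                  schedule,
                                  phenotype_realization = c("expectation", "binomial"),
                                  seed = NULL, volume_ml = 0.2,
                                  keep_trajectories = TRUE) {
  mode <- match.arg(mode)
  phenotype_realization <- match.arg(phenotype_realization)
  stopifnot(is.data.frame(schedule), all(c("grow_h", "dilution_factor") %in% names(schedule)))
  if (any(schedule$dilution_factor <= 1)) {
    abort("dilution factors must be > 1", class = "galgame_validation_error")
  }
  inoculum <- check_inoculum(inoculum)

  current <- inoculum
  rows <- list()
  trajs <- list()
  extinct <- FALSE
  for (cyc in seq_len(nrow(schedule))) {
    cyc_env <- sugar_env(env$glucose_pct, env$galactose_pct, schedule$grow_h[cyc])
    cyc_seed <- if (is.null(seed)) NULL else (seed + 7919L * cyc) %% 2147483647L
    traj <- simulate_batch(cyc_env, current, params, mode,
      phenotype_realization = phenotype_realization,
      seed = cyc_seed, volume_ml = volume_ml
    )
    if (keep_trajectories) trajs[[cyc]] <- traj
    end <- traj$final %>%
      group_by(.data$genotype) %>%
      summarise(density = sum(.data$density), .groups = "drop")
    total <- sum(end$density)
    rows[[cyc]] <- tibble(
      cycle = cyc, genotype = end$genotype,
      frequency = if (total > 0) end$density / total else NA_real_,
      density_start = sum(current$density), density_end = total
    )
    diluted <- total / schedule$dilution_factor[cyc]
    if (diluted < 1 / volume_ml) {
      extinct <- TRUE
      break
    }
    current <- current %>%
      select(-"density") %>%
      left_join(end, by = "genotype") %>%
      mutate(density = .data$density / schedule$dilution_factor[cyc])
  }

  structure(
    list(
      frequencies = bind_rows(rows), trajectories = trajs, extinct = extinct,
      schedule = schedule, env = env, params = params, mode = mode
    ),
    class = "gal_dilution_run"
  )
}

#' @export
print.gal_dilution_run <- function(x, ...) {
  n_cyc <- max(x$frequencies$cycle)
  last <- x$frequencies %>% filter(.data$cycle == n_cyc)
  cat(sprintf(
    "<gal_dilution_run> %d cycle(s)%s; final frequencies: %s\n",
    n_cyc, if (x$extinct) " (extinct)" else "",
    paste(sprintf("%s=%.3f", last$genotype, last$frequency), collapse = ", ")
  ))
  invisible(x)
}
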