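#' Read and validate measurement tables
#'
#' Strict CSV readers for the three table schemas the package exchanges:
#'
#' * competition records:
#'   `focal,other,f_i,f_f,od_i,od_f,glucose_pct,galactose_pct,replicate`
#' * cytometry event tables: `event_id,log10_yfp`
#' * trajectories:
#'   `time_h,genotype,phenotype,density_cells_per_ml,glucose_pct,galactose_pct`
#'
#' Validation failures (missing columns, non-numeric cells, out-of-range
#' values) are reported with the offending rows. An empty file raises a
#' distinct error from malformed content.
#'
#' @param path CSV file path.
#' @return A validated tibble.
#' @export
read_competition_records <- function(path) {
  df <- read_schema(path,
    required = c(
      "focal", "other", "f_i", "f_f", "od_i", "od_f",
      "glucose_pct", "galactose_pct", "replicate"
    ),
    numeric_cols = c("f_i", "f_f", "od_i", "od_f", "glucose_pct", "galactose_pct")
  )
  check_range(df, "f_i", 0, 1)
  check_range(df, "f_f", 0, 1)
  check_range(df, "od_i", 0, Inf, open_lower = TRUE)
  check_range(df, "od_f", 0, Inf, open_lower = TRUE)
  df
}

#' @rdname read_competition_records
#' @export
read_event_table <- function(path) {
  df <- read_schema(path,
    required = c("event_id", "log10_yfp"),
    numeric_cols = "log10_yfp"
  )
  if (nrow(df) == 0) {
    abort("event table has no events", class = "galgame_validation_error")
  }
  df
}

#' @rdname read_competition_records
#' @export
read_trajectory <- function(path) {
  read_schema(path,
    required = c(
      "time_h", "genotype", "phenotype", "density_cells_per_ml",
      "glucose_pct", "galactose_pct"
    ),
    numeric_cols = c("time_h", "density_cells_per_ml", "glucose_pct", "galactose_pct")
  )
}

read_schema <- function(path, required, numeric_cols) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path), class = "galgame_io_error")
  }
  if (file.size(path) == 0) {
    abort(sprintf("file is empty: %s", path), class = "galgame_empty_file_error")
  }
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(
      sprintf("missing column(s): %s", paste(missing, collapse = ", ")),
      class = "galgame_validation_error"
    )
  }
  for (col in numeric_cols) {
    vals <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(vals) & !is.na(df[[col]]))
    if (length(bad) > 0) {
      abort(
        sprintf(
          "column %s has non-numeric value(s) on row(s): %s",
          col, paste(bad, collapse = ", ")
        ),
        class = "galgame_validation_error"
      )
    }
    df[[col]] <- vals
  }
  df
}

check_range <- function(df, col, lo, hi, open_lower = FALSE) {
  v <- df[[col]]
  bad <- which(v > hi | if (open_lower) v <= lo else v < lo)
  if (length(bad) > 0) {
    abort(
      sprintf(
        "column %s out of range on row(s): %s (value %g)",
        col, paste(bad, collapse = ", "), v[bad[1]]
      ),
      class = "galgame_validation_error"
    )
  }
  invisible(df)
}

#' Write package tables to CSV
#'
#' Counterparts of the readers; values are written at full precision so a
#' write-read round trip is lossless.
#'
#' @param x The tibble to write.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_competition_records <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_competition_records
#' @export
write_event_table <- function(x, path) {
  readr::write_csv(x, path)
  invisible(path)
}

#' @rdname write_competition_records
#' @param traj A `gal_trajectory`.
#' @export
write_trajectory <- function(traj, path) {
  readr::write_csv(tidy(traj), path)
  invisible(path)
}

#' Run a named analysis pipeline from a configuration file
#'
#' Ties the stages into reproducible runs. The configuration (YAML, or JSON
#' — both are parsed) names one of three pipelines and its parameters; all
#' quantities carry unit-suffixed keys (`glucose_pct`, `horizon_h`, ...)
#' and unknown keys are rejected.
#'
#' * `cost_sweep`: stable and growth-optimal fractions across a GAL-ON
#'   cost grid; writes `sweep.csv`.
#' * `competition_analysis`: synthetic (or provided) competition records,
#'   fitness statistics and the equilibrium estimate; writes `records.csv`,
#'   `fitness.csv` and `equilibrium.json`.
#' * `evolution_experiment`: the serial-dilution evolution experiment;
#'   writes `evolution_runs.csv` and `evolution_outcomes.csv`.
#'
#' A JSON manifest (config snapshot, seeds, artifact paths with checksums,
#' package version, timestamp) is written alongside the outputs; rerunning
#' with the same config and seed reproduces identical artifact checksums.
#'
#' @param config Path to a YAML/JSON configuration file, or an equivalent
#'   named list.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @return The manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config, out_dir = ".", seed = 1) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (is.null(cfg$pipeline)) {
    abort("config must name a pipeline", class = "galgame_validation_error")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  known <- c(
    "pipeline", "glucose_pct", "galactose_pct", "horizon_h", "mode",
    "cost_values", "records_csv", "fraction_levels", "replicates_per_level",
    "od_cv", "n_events_per_well", "n_boot", "founder_p_on", "schedule",
    "mutation_rate", "n_replicates", "degree", "lag_off_to_gal_h"
  )
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(
      sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")),
      class = "galgame_validation_error"
    )
  }
  env <- sugar_env(
    cfg$glucose_pct %||% 0.03, cfg$galactose_pct %||% 0.05, cfg$horizon_h %||% 20
  )
  outputs <- character(0)

  if (cfg$pipeline == "cost_sweep") {
    sweep <- parameter_sweep(
      env, phenotype_params(), cfg$mode %||% "exclusive",
      axis = "cost", values = cfg$cost_values %||% seq(0, 0.5, by = 0.1)
    )
    outputs <- file.path(out_dir, "sweep.csv")
    readr::write_csv(sweep, outputs)
  } else if (cfg$pipeline == "competition_analysis") {
    if (!is.null(cfg$records_csv)) {
      records <- read_competition_records(cfg$records_csv)
      f_true <- NA_real_
    } else {
      gen <- gen_competition_dataset(
        env, phenotype_params(),
        fraction_levels = cfg$fraction_levels %||% seq(0.05, 0.95, length.out = 10),
        replicates_per_level = cfg$replicates_per_level %||% 6,
        noise = noise_model(cfg$od_cv %||% 0.05, cfg$n_events_per_well %||% 20000),
        seed = seed
      )
      records <- gen$records
      f_true <- gen$f_true
    }
    fitness <- competition_fitness(records)
    est <- fit_equilibrium(fitness,
      degree = cfg$degree %||% 5,
      n_boot = cfg$n_boot %||% 1000, seed = seed
    )
    outputs <- file.path(out_dir, c("records.csv", "fitness.csv", "equilibrium.json"))
    readr::write_csv(records, outputs[1])
    readr::write_csv(fitness, outputs[2])
    jsonlite::write_json(
      list(
        f_star = est$f_star, ci_low = est$ci_low, ci_high = est$ci_high,
        boundary = est$boundary, n_boot = est$n_boot, f_true = f_true
      ),
      outputs[3],
      auto_unbox = TRUE, digits = NA
    )
  } else if (cfg$pipeline == "evolution_experiment") {
    config_evo <- evolution_config(
      founder = strategy("founder", cfg$founder_p_on %||% 0,
        post_depletion_switch = TRUE
      ),
      env = sugar_env(
        cfg$glucose_pct %||% 0.03, cfg$galactose_pct %||% 0.05,
        cfg$horizon_h %||% 24
      ),
      params = phenotype_params(lag_off_to_gal = cfg$lag_off_to_gal_h %||% 3),
      schedule = cfg$schedule %||% c(200, 500, rep(1000, 24)),
      mutation_rate = cfg$mutation_rate %||% 1e-5,
      n_replicates = cfg$n_replicates %||% 8
    )
    ev <- evolve(config_evo, seed = seed)
    outputs <- file.path(out_dir, c("evolution_runs.csv", "evolution_outcomes.csv"))
    readr::write_csv(ev$runs, outputs[1])
    readr::write_csv(ev$outcomes, outputs[2])
  } else {
    abort(sprintf("unknown pipeline: %s", cfg$pipeline), class = "galgame_validation_error")
  }

  manifest <- list(
    pipeline = cfg$pipeline, config = cfg, seed = seed,
    outputs = as.list(setNames(unname(tools::md5sum(outputs)), basename(outputs))),
    package_version = as.character(utils::packageVersion("galgame")),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
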