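# Event-driven integration core.
#
# Between events every lineage compartment follows a linear ODE, so its
# density is a sum of (coef * t^ord * exp(lambda*t)) terms (ord > 0 only in
# the defective-eigenvalue switching case). Resource consumption is the
# time integral of those terms scaled by rate/yield, which keeps depletion
# times and mass balance exact to solver tolerance rather than step size.
# Terms are plain lists of numeric vectors (coef, lambda, ord); this loop
# is the package's hot path.

# integral of s^ord * exp(lambda*s) over [0, t], vectorized over terms
exp_integral <- function(lambda, t, ord) {
  small <- abs(lambda * t) < 1e-7
  out <- numeric(length(lambda))
  i0 <- ord == 0
  s <- small & i0
  out[s] <- t * (1 + lambda[s] * t / 2 + (lambda[s] * t)^2 / 6)
  b <- !small & i0
  out[b] <- expm1(lambda[b] * t) / lambda[b]
  i1 <- ord == 1
  s <- small & i1
  out[s] <- t^2 / 2 + lambda[s] * t^3 / 3
  b <- !small & i1
  out[b] <- (t * exp(lambda[b] * t)) / lambda[b] - expm1(lambda[b] * t) / lambda[b]^2
  out
}

eval_terms <- function(terms, t) {
  if (length(terms$coef) == 0) return(0)
  sum(terms$coef * t^terms$ord * exp(terms$lambda * t))
}

integrate_terms <- function(terms, t) {
  if (length(terms$coef) == 0) return(0)
  sum(terms$coef * exp_integral(terms$lambda, t, terms$ord))
}

term_list <- function(coef, lambda, ord = rep(0, length(coef))) {
  keep <- coef != 0
  list(coef = coef[keep], lambda = lambda[keep], ord = ord[keep])
}

cat_terms <- function(a, b) {
  list(coef = c(a$coef, b$coef), lambda = c(a$lambda, b$lambda), ord = c(a$ord, b$ord))
}

scale_terms <- function(a, s) {
  list(coef = a$coef * s, lambda = a$lambda, ord = a$ord)
}

# Solve integrate_terms(terms, t) == level for t in (0, t_max].
# Newton iteration safeguarded by bisection; residual <= rel_tol * level.
# Returns Inf when demand over t_max never reaches level.
solve_terms_depletion <- function(terms, level, t_max, rel_tol = 1e-9) {
  if (level <= 0) return(0)
  if (length(terms$coef) == 0) return(Inf)
  g <- function(t) integrate_terms(terms, t) - level
  if (is.finite(t_max)) {
    if (g(t_max) < 0) return(Inf)
    hi <- t_max
  } else {
    hi <- 1
    while (g(hi) < 0) {
      hi <- hi * 2
      if (hi > 1e9) return(Inf)
    }
  }
  lo <- 0
  t <- hi / 2
  tol <- rel_tol * level
  for (iter in 1:200) {
    val <- g(t)
    if (abs(val) <= tol) return(t)
    if (val > 0) hi <- t else lo <- t
    dv <- eval_terms(terms, t)
    t_new <- if (dv > 0) t - val / dv else NA_real_
    if (!is.finite(t_new) || t_new <= lo || t_new >= hi) t_new <- (lo + hi) / 2
    t <- t_new
  }
  t
}

# Per-genotype segment dynamics: phenotype compartments (on, off) with
# growth rates r_on/r_off and first-order switching transfers.
genotype_terms <- function(n_on, n_off, r_on, r_off, s_on, s_off) {
  if (s_on == 0 && s_off == 0) {
    return(list(
      on = term_list(n_on, r_on),
      off = term_list(n_off, r_off)
    ))
  }
  a11 <- r_on - s_off
  a22 <- r_off - s_on
  disc <- (a11 - a22)^2 + 4 * s_on * s_off
  n0 <- c(n_on, n_off)
  if (disc > 1e-12 * max(1, a11^2, a22^2)) {
    sq <- sqrt(disc)
    lam <- c((a11 + a22 + sq) / 2, (a11 + a22 - sq) / 2)
    vecs <- vapply(lam, function(l) {
      v <- if (s_on != 0) c(s_on, l - a11) else c(l - a22, s_off)
      v / max(abs(v), .Machine$double.eps)
    }, numeric(2))
    ab <- solve(vecs, n0)
    list(
      on = term_list(ab * vecs[1, ], lam),
      off = term_list(ab * vecs[2, ], lam)
    )
  } else {
    # repeated eigenvalue: N(t) = exp(l t) (I + (A - l I) t) N0
    l <- (a11 + a22) / 2
    w <- c((a11 - l) * n0[1] + s_on * n0[2], s_off * n0[1] + (a22 - l) * n0[2])
    list(
      on = term_list(c(n0[1], w[1]), c(l, l), c(0, 1)),
      off = term_list(c(n0[2], w[2]), c(l, l), c(0, 1))
    )
  }
}

# Growth components for one (genotype, phenotype) compartment under the
# current resource availability. Returns a list of (resource, rho, yield).
active_components <- function(mode, phenotype, pds, glucose, galactose,
                              lag_open, p) {
  comps <- list()
  if (mode == "exclusive") {
    if (phenotype == "on" && galactose > 0) {
      comps[[1]] <- list(
        resource = "galactose",
        rho = p$r_galactose * (1 - p$cost_rate),
        yield = p$yield_galactose * (1 - p$cost_yield)
      )
    } else if (phenotype == "off" && glucose > 0) {
      comps[[1]] <- list(resource = "glucose", rho = p$r_glucose, yield = p$yield_glucose)
    }
  } else {
    if (glucose > 0) {
      if (phenotype == "off") {
        comps[[1]] <- list(resource = "glucose", rho = p$r_glucose, yield = p$yield_glucose)
      } else {
        comps[[1]] <- list(
          resource = "glucose",
          rho = p$r_glucose * (1 - p$cost_rate),
          yield = p$yield_glucose * (1 - p$cost_yield)
        )
        if (galactose > 0 && p$co_consumption > 0) {
          comps[[2]] <- list(
            resource = "galactose",
            rho = p$co_consumption * p$r_galactose,
            yield = p$yield_galactose * (1 - p$cost_yield)
          )
        }
      }
    } else if (galactose > 0) {
      if (phenotype == "on" || (pds && lag_open)) {
        comps[[1]] <- list(
          resource = "galactose",
          rho = p$r_galactose,
          yield = p$yield_galactose * (1 - p$cost_yield)
        )
      }
    }
  }
  comps[!vapply(comps, function(cp) cp$rho <= 0, logical(1))]
}

# One full batch integration. lineages: data frame genotype/phenotype/density
# (both phenotypes present per genotype); genotab: one row per genotype with
# switching rates and post_depletion_switch.
integrate_batch <- function(lineages, genotab, env, params, mode) {
  t <- 0
  glucose <- env$glucose_pct
  galactose <- env$galactose_pct
  horizon <- env$horizon_h
  lag_time <- NA_real_ # absolute time OFF cells may start on galactose
  any_pds <- any(genotab$post_depletion_switch) && is.finite(params$lag_off_to_gal)
  if (glucose <= 0 && any_pds) lag_time <- params$lag_off_to_gal

  n_lin <- nrow(lineages)
  lin_geno <- lineages$genotype
  lin_phen <- lineages$phenotype
  dens <- lineages$density
  geno_idx <- match(lin_geno, genotab$genotype)
  pds <- genotab$post_depletion_switch[geno_idx]
  consumption <- matrix(0, nrow = n_lin, ncol = 2,
    dimnames = list(NULL, c("glucose", "galactose"))
  )

  state_t <- 0
  state_dens <- list(dens)
  state_glu <- glucose
  state_gal <- galactose
  ev_t <- numeric(0)
  ev_kind <- character(0)
  segments <- list()

  n_iter <- 0
  repeat {
    n_iter <- n_iter + 1
    if (n_iter > 1000) abort("event loop failed to reach the horizon", class = "galgame_internal_error")
    lag_open <- !is.na(lag_time) && t >= lag_time - 1e-12

    comp_list <- vector("list", n_lin)
    rate_tot <- numeric(n_lin)
    for (i in seq_len(n_lin)) {
      comp_list[[i]] <- active_components(
        mode, lin_phen[i], pds[i], glucose, galactose, lag_open, params
      )
      rate_tot[i] <- sum(vapply(comp_list[[i]], `[[`, numeric(1), "rho"))
    }
    terms <- vector("list", n_lin)
    for (gi in seq_len(nrow(genotab))) {
      ion <- which(geno_idx == gi & lin_phen == "on")
      ioff <- which(geno_idx == gi & lin_phen == "off")
      tm <- genotype_terms(
        dens[ion], dens[ioff], rate_tot[ion], rate_tot[ioff],
        genotab$switch_on_rate[gi], genotab$switch_off_rate[gi]
      )
      terms[[ion]] <- tm$on
      terms[[ioff]] <- tm$off
    }

    dt_max <- horizon - t
    boundary <- "horizon"
    if (!is.na(lag_time) && t < lag_time - 1e-12 && lag_time - t < dt_max) {
      dt_max <- lag_time - t
      boundary <- "lag_elapsed"
    }

    # candidate depletion events; compartment i consumes resource X at rate
    # rho_X/yield_X * N_i(t), so depletion shares the density terms with
    # rescaled coefficients
    cand <- c(glucose_depleted = Inf, galactose_depleted = Inf)
    res_terms <- list(glucose = NULL, galactose = NULL)
    for (res in c("glucose", "galactose")) {
      level <- if (res == "glucose") glucose else galactose
      if (level <= 0) next
      acc <- term_list(numeric(0), numeric(0))
      for (i in seq_len(n_lin)) {
        for (cp in comp_list[[i]]) {
          if (cp$resource == res) {
            acc <- cat_terms(acc, scale_terms(terms[[i]], cp$rho / cp$yield))
          }
        }
      }
      if (length(acc$coef) == 0) next
      res_terms[[res]] <- acc
      cand[[paste0(res, "_depleted")]] <- solve_terms_depletion(acc, level, dt_max)
    }

    te <- min(cand, dt_max)
    kinds <- names(cand)[cand <= te + 1e-12]
    if (te >= dt_max - 1e-12) {
      te <- dt_max
      kinds <- unique(c(kinds, boundary))
    }

    new_dens <- vapply(terms, eval_terms, numeric(1), t = te)
    cons_g <- if (!is.null(res_terms$glucose)) integrate_terms(res_terms$glucose, te) else 0
    cons_b <- if (!is.null(res_terms$galactose)) integrate_terms(res_terms$galactose, te) else 0
    for (i in seq_len(n_lin)) {
      for (cp in comp_list[[i]]) {
        consumption[i, cp$resource] <- consumption[i, cp$resource] +
          integrate_terms(scale_terms(terms[[i]], cp$rho / cp$yield), te)
      }
    }
    segments[[length(segments) + 1]] <- list(
      t0 = t, t1 = t + te, genotype = lin_geno, phenotype = lin_phen, terms = terms
    )
    glucose_was <- glucose
    glucose <- max(glucose - cons_g, 0)
    galactose <- max(galactose - cons_b, 0)
    if ("glucose_depleted" %in% kinds) glucose <- 0
    if ("galactose_depleted" %in% kinds) galactose <- 0
    dens <- new_dens
    t <- t + te

    if ("glucose_depleted" %in% kinds && glucose_was > 0 && any_pds && is.na(lag_time)) {
      lag_time <- t + params$lag_off_to_gal
    }
    ev_t <- c(ev_t, rep(t, length(kinds)))
    ev_kind <- c(ev_kind, kinds)
    state_t <- c(state_t, t)
    state_dens[[length(state_dens) + 1]] <- dens
    state_glu <- c(state_glu, glucose)
    state_gal <- c(state_gal, galactose)
    if (t >= horizon - 1e-12) break
    if (length(kinds) == 0) break # defensive; cannot normally happen
  }

  n_states <- length(state_t)
  states <- tibble(
    time_h = rep(state_t, each = n_lin),
    genotype = rep(lin_geno, n_states),
    phenotype = rep(lin_phen, n_states),
    density_cells_per_ml = unlist(state_dens, use.names = FALSE),
    glucose_pct = rep(state_glu, each = n_lin),
    galactose_pct = rep(state_gal, each = n_lin)
  )
  list(
    states = states,
    events = tibble(time_h = ev_t, kind = ev_kind),
    segments = segments,
    consumption = tibble(
      genotype = lin_geno, phenotype = lin_phen,
      glucose_pct = consumption[, "glucose"], galactose_pct = consumption[, "galactose"]
    ),
    final = tibble(genotype = lin_geno, phenotype = lin_phen, density = dens),
    resources_final = c(glucose = glucose, galactose = galactose)
  )
}
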