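#' Simulation configuration for FBA
#'
#' Encodes the minimal-medium growth simulation: glucose as the sole organic
#' carbon source at a capped uptake rate, a configurable oxygen policy, and
#' the objective reaction (the biomass equation by default).
#'
#' @param substrate_exchange_id exchange reaction of the carbon substrate
#'   (default `"EX_glc__D_e"`).
#' @param substrate_uptake maximum substrate uptake, mmol gDCW^-1 h^-1
#'   (default 10). Applied to the exchange lower bound as `-substrate_uptake`
#'   (negative exchange flux = uptake).
#' @param objective_id objective reaction id; `NULL` uses the model's
#'   active objective.
#' @param oxygen_policy `"unbounded-uptake"` (aerobic, the default: the O2
#'   exchange lower bound is opened to -1000) or a non-negative number fixing
#'   the maximum O2 uptake rate.
#' @param solver_tolerance LP tolerance (default 1e-9).
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(substrate_exchange_id = "EX_glc__D_e",
                       substrate_uptake = 10,
                       objective_id = NULL,
                       oxygen_policy = "unbounded-uptake",
                       solver_tolerance = 1e-9) {
  stopifnot(substrate_uptake >= 0, solver_tolerance > 0)
  if (!(identical(oxygen_policy, "unbounded-uptake") ||
    (is.numeric(oxygen_policy) && length(oxygen_policy) == 1 && oxygen_policy >= 0))) {
    stop("oxygen_policy must be \"unbounded-uptake\" or a non-negative number")
  }
  structure(
    list(
      substrate_exchange_id = substrate_exchange_id,
      substrate_uptake = substrate_uptake,
      objective_id = objective_id,
      oxygen_policy = oxygen_policy,
      solver_tolerance = solver_tolerance
    ),
    class = "sim_config"
  )
}

# Is each exchanged metabolite an organic carbon source? Inorganic carbon
# (CO2, CO, carbonate) does not count; unknown formulas are left untouched.
exchanged_met_organic <- function(model) {
  exch <- which(is_exchange(model))
  vapply(exch, function(j) {
    mid <- names(model$reactions$stoichiometry[[j]])
    f <- model$metabolites$formula[match(mid, model$metabolites$id)]
    nC <- element_count(f)
    !is.na(nC) && nC > 0 && !(f %in% c("CO2", "CO", "HCO3", "CO3", "H2CO3"))
  }, logical(1))
}

find_oxygen_exchange <- function(model) {
  exch <- which(is_exchange(model))
  for (j in exch) {
    mid <- names(model$reactions$stoichiometry[[j]])
    f <- model$metabolites$formula[match(mid, model$metabolites$id)]
    if (!is.na(f) && f == "O2") {
      return(model$reactions$id[j])
    }
  }
  NA_character_
}

# Apply the minimal-medium contract: substrate uptake capped, every other
# organic-carbon exchange closed to uptake, oxygen per policy.
fba_condition_model <- function(model, config) {
  stopifnot(inherits(model, "metabolic_model"), inherits(config, "sim_config"))
  sub_i <- reaction_index(model, config$substrate_exchange_id)
  exch <- which(is_exchange(model))
  organic <- exchanged_met_organic(model)
  for (k in seq_along(exch)) {
    j <- exch[k]
    if (j != sub_i && organic[k] && model$reactions$lb[j] < 0) {
      model$reactions$lb[j] <- 0
    }
  }
  model$reactions$lb[sub_i] <- -config$substrate_uptake
  o2_id <- find_oxygen_exchange(model)
  if (!is.na(o2_id)) {
    o2_i <- reaction_index(model, o2_id)
    if (identical(config$oxygen_policy, "unbounded-uptake")) {
      model$reactions$lb[o2_i] <- -1000
    } else {
      model$reactions$lb[o2_i] <- -config$oxygen_policy
    }
  }
  model
}

resolve_objective <- function(model, config) {
  obj <- config$objective_id %||% model$objective_id
  if (is.null(obj) || is.na(obj)) {
    stop("no objective set: the model has no active objective and the config names none")
  }
  reaction_index(model, obj) # errors if absent
  obj
}

lp_from_model <- function(model) {
  list(
    A = stoich_matrix(model),
    b = rep(0, nrow(model$metabolites)),
    lb = model$reactions$lb,
    ub = model$reactions$ub
  )
}

solve_lp_on <- function(model, objective_id, maximize = TRUE, tol = 1e-9) {
  lp <- lp_from_model(model)
  obj <- as.numeric(model$reactions$id == objective_id)
  lp_solve(obj, lp$A, lp$b, lp$lb, lp$ub, maximize = maximize, tol = tol)
}

#' Solve the flux balance analysis LP
#'
#' Maximizes the objective flux subject to the steady-state constraint
#' `S v = 0` and the flux bounds, after conditioning the model to minimal
#' medium: the substrate exchange's uptake is capped at
#' `config$substrate_uptake` and every other organic-carbon exchange is
#' closed to uptake (CO2 is inorganic and stays open, so CO2-fixing routes
#' remain available).
#'
#' @param model a `metabolic_model` with an objective (or an objective named
#'   in `config`).
#' @param config a [sim_config()].
#' @return an object of class `flux_state`: `fluxes` (named vector,
#'   `NA` unless optimal), `objective_value`, `objective_id`, `status`
#'   (`"optimal"`, `"infeasible"`, or a solver failure code).
#' @export
#' @examples
#' model <- build_core_model()
#' fs <- solve_fba(model, sim_config())
#' fs$objective_value
solve_fba <- function(model, config = sim_config()) {
  validate_model(model)
  objective_id <- resolve_objective(model, config)
  cm <- fba_condition_model(model, config)
  res <- solve_lp_on(cm, objective_id, maximize = TRUE, tol = config$solver_tolerance)
  fluxes <- if (res$status == "optimal") {
    stats::setNames(res$x, cm$reactions$id)
  } else {
    stats::setNames(rep(NA_real_, nrow(cm$reactions)), cm$reactions$id)
  }
  structure(
    list(
      fluxes = fluxes,
      objective_value = if (res$status == "optimal") res$objective else NA_real_,
      objective_id = objective_id,
      status = res$status
    ),
    class = "flux_state"
  )
}

#' @export
print.flux_state <- function(x, ...) {
  cat("<flux_state> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective (", x$objective_id, "): ", format(x$objective_value, digits = 6), "\n", sep = "")
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  ", nz, " of ", length(x$fluxes), " reactions carry flux\n", sep = "")
  }
  invisible(x)
}

#' Maximum steady-state violation of a flux vector
#'
#' @param model a `metabolic_model`.
#' @param fluxes named flux vector (e.g. `flux_state$fluxes`).
#' @return `max |S v|` over metabolites.
#' @export
steady_state_residual <- function(model, fluxes) {
  S <- stoich_matrix(model)
  max(abs(S %*% fluxes[colnames(S)]))
}

#' Flux variability of one reaction at (a fraction of) the optimum
#'
#' FBA optima are often degenerate: many flux vectors attain the same
#' objective. The min/max flux of a reaction over the optimal face is the
#' honest summary of what the optimum implies for that reaction; this
#' package reports product secretion rates as this interval (with the
#' midpoint as the headline number).
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @param reaction_id reaction whose flux range is wanted.
#' @param fraction_of_optimum hold the objective at at least this fraction
#'   of its optimum (default 1.0, the optimal face itself).
#' @return an object of class `flux_interval`: `reaction_id`, `min_flux`,
#'   `max_flux`.
#' @export
flux_variability <- function(model, config = sim_config(), reaction_id,
                             fraction_of_optimum = 1.0) {
  stopifnot(fraction_of_optimum >= 0, fraction_of_optimum <= 1)
  validate_model(model)
  objective_id <- resolve_objective(model, config)
  reaction_index(model, reaction_id)
  cm <- fba_condition_model(model, config)
  base <- solve_lp_on(cm, objective_id, maximize = TRUE, tol = config$solver_tolerance)
  if (base$status != "optimal") {
    stop("flux_variability: base FBA problem is ", base$status)
  }
  iv <- fva_range(cm, objective_id, base$objective, fraction_of_optimum,
    reaction_id,
    tol = config$solver_tolerance
  )
  structure(
    list(reaction_id = reaction_id, min_flux = iv[1], max_flux = iv[2]),
    class = "flux_interval"
  )
}

# min/max of one reaction on a conditioned model with the objective held at
# >= fraction * opt (small absolute slack absorbs solver roundoff)
fva_range <- function(cmodel, objective_id, opt, fraction, reaction_id, tol = 1e-9) {
  floor_val <- if (opt >= 0) fraction * opt else opt * (2 - fraction)
  floor_val <- floor_val - max(1e-9, 1e-9 * abs(opt))
  oi <- reaction_index(cmodel, objective_id)
  cmodel$reactions$lb[oi] <- max(cmodel$reactions$lb[oi], floor_val)
  lo <- solve_lp_on(cmodel, reaction_id, maximize = FALSE, tol = tol)
  hi <- solve_lp_on(cmodel, reaction_id, maximize = TRUE, tol = tol)
  if (lo$status != "optimal" || hi$status != "optimal") {
    stop("flux variability subproblem not optimal for ", reaction_id)
  }
  c(min(lo$objective, hi$objective), max(lo$objective, hi$objective))
}

#' @export
print.flux_interval <- function(x, ...) {
  cat(
    "<flux_interval> ", x$reaction_id, ": [",
    format(x$min_flux, digits = 6), ", ", format(x$max_flux, digits = 6), "]\n",
    sep = ""
  )
  invisible(x)
}

#' Robustness analysis: sweep one controlling flux against the objective
#'
#' Re-solves FBA with the control reaction's flux fixed (both bounds) at
#' each of `steps` evenly spaced values between `lo` and `hi`, recording the
#' re-optimized objective. The classic use is sweeping the glucose uptake
#' rate against growth for a wild-type vs an engineered model. Infeasible
#' grid points are recorded with objective 0 and flagged, so the grid stays
#' complete.
#'
#' @param model a `metabolic_model`.
#' @param config a [sim_config()].
#' @param control_reaction_id reaction whose flux is swept.
#' @param lo,hi sweep range (`lo < hi`).
#' @param steps number of grid points (>= 2).
#' @param uptake if `TRUE` the swept values are uptake rates of an exchange
#'   reaction: the fixed flux is `-value` while `parameter_values` keeps the
#'   positive uptake scale (default `FALSE`: values are signed fluxes).
#' @return an object of class `robustness_profile` with fields
#'   `control_reaction_id`, `parameter_values`, `objective_values`,
#'   `objective_id`, `feasible`.
#' @export
robustness_scan <- function(model, config = sim_config(), control_reaction_id,
                            lo, hi, steps, uptake = FALSE) {
  stopifnot(steps >= 2, lo < hi)
  validate_model(model)
  objective_id <- resolve_objective(model, config)
  ci <- reaction_index(model, control_reaction_id)
  cm <- fba_condition_model(model, config)
  grid <- seq(lo, hi, length.out = steps)
  objs <- numeric(steps)
  feas <- logical(steps)
  for (k in seq_len(steps)) {
    v <- if (uptake) -grid[k] else grid[k]
    cmk <- cm
    cmk$reactions$lb[ci] <- v
    cmk$reactions$ub[ci] <- v
    res <- solve_lp_on(cmk, objective_id, maximize = TRUE, tol = config$solver_tolerance)
    feas[k] <- res$status == "optimal"
    objs[k] <- if (feas[k]) res$objective else 0
  }
  structure(
    list(
      control_reaction_id = control_reaction_id,
      parameter_values = grid,
      objective_values = objs,
      objective_id = objective_id,
      feasible = feas,
      uptake = uptake
    ),
    class = "robustness_profile"
  )
}

#' @export
as.data.frame.robustness_profile <- function(x, ...) {
  data.frame(
    parameter = x$parameter_values,
    objective = x$objective_values,
    feasible = x$feasible
  )
}

#' @export
print.robustness_profile <- function(x, ...) {
  cat(
    "<robustness_profile> ", x$control_reaction_id,
    if (x$uptake) " (uptake scale)" else "",
    " vs ", x$objective_id, ", ",
    length(x$parameter_values), " points in [",
    format(min(x$parameter_values)), ", ", format(max(x$parameter_values)), "]\n",
    sep = ""
  )
  if (any(!x$feasible)) cat("  ", sum(!x$feasible), " infeasible points (objective recorded as 0)\n", sep = "")
  invisible(x)
}
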