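#' Configuration for the enforced-production flux scan
#'
#' @param product_exchange_id exchange reaction of the product whose
#'   secretion is enforced (e.g. the fumarate exchange).
#' @param control_level first enforced secretion level, mmol gDCW^-1 h^-1
#'   (default 0.4, just above the knockout's natural secretion rate).
#' @param max_level `"auto"` (default: the FBA maximum of the product flux
#'   under the same medium) or a number.
#' @param steps number of evenly spaced enforcement levels (>= 3,
#'   default 10).
#' @param classification_tolerance relative tolerance for trajectory
#'   classification and fold definedness (default 0.01: absorbs solver
#'   noise without masking few-percent flux changes).
#' @param objective_id growth objective; `NULL` uses the model's objective.
#' @return an object of class `scan_config`.
#' @export
scan_config <- function(product_exchange_id = "EX_fum_e",
                        control_level = 0.4,
                        max_level = "auto",
                        steps = 10,
                        classification_tolerance = 0.01,
                        objective_id = NULL) {
  stopifnot(
    control_level >= 0, steps >= 3, classification_tolerance > 0,
    identical(max_level, "auto") || (is.numeric(max_level) && length(max_level) == 1)
  )
  if (is.numeric(max_level) && max_level <= control_level) {
    stop("max_level must exceed control_level")
  }
  structure(
    list(
      product_exchange_id = product_exchange_id,
      control_level = control_level,
      max_level = max_level,
      steps = as.integer(steps),
      classification_tolerance = classification_tolerance,
      objective_id = objective_id
    ),
    class = "scan_config"
  )
}

#' Classify a flux trajectory across enforced production levels
#'
#' A trajectory is `"increased"` when no consecutive step decreases by more
#' than the tolerance (relative to the trajectory's largest magnitude) and
#' the net change exceeds that tolerance; `"decreased"` symmetrically;
#' anything else -- including flat ("unchanged") and non-monotone
#' ("ruleless") trajectories, and the all-zero trajectory -- is
#' `"irregular"`.
#'
#' @param trajectory numeric vector of fluxes, one per level (length >= 3).
#' @param tolerance relative tolerance (default 0.01).
#' @return one of `"increased"`, `"decreased"`, `"irregular"`.
#' @export
#' @examples
#' classify_trajectory(c(1.0, 1.2, 1.5, 1.8)) # increased
#' classify_trajectory(c(1.0, 1.0, 1.0)) # irregular (unchanged)
#' classify_trajectory(c(1.0, 2.0, 0.5)) # irregular (ruleless)
classify_trajectory <- function(trajectory, tolerance = 0.01) {
  if (length(trajectory) < 3) {
    stop("trajectory must have at least 3 levels, got ", length(trajectory))
  }
  scale <- max(abs(trajectory))
  if (scale == 0) {
    return("irregular")
  }
  eps <- tolerance * scale
  d <- diff(trajectory)
  net <- trajectory[length(trajectory)] - trajectory[1]
  if (all(d >= -eps) && net > eps) {
    return("increased")
  }
  if (all(d <= eps) && net < -eps) {
    return("decreased")
  }
  "irregular"
}

#' Endpoint fold-change of a flux trajectory
#'
#' The scalar summarizing a reaction's flux response across the scan:
#' `|flux at the maximum level| / |flux at the control level|`. When the
#' control flux magnitude is below `tolerance * max|trajectory|` the ratio
#' is undefined; the sentinel `NA` is returned with the absolute endpoint
#' change attached as attribute `"abs_change"` (also attached for defined
#' folds).
#'
#' @param trajectory numeric vector of fluxes (length >= 2).
#' @param tolerance relative tolerance for the zero-baseline test
#'   (default 0.01).
#' @return the fold (or `NA`), with attribute `abs_change`.
#' @export
#' @examples
#' compute_fold(c(2, 2, 2)) # 1
#' compute_fold(c(1, 1.4, 1.82)) # 1.82
#' compute_fold(c(0, 1.5, 3)) # NA, abs_change 3
compute_fold <- function(trajectory, tolerance = 0.01) {
  if (length(trajectory) < 2) stop("trajectory must have at least 2 levels")
  first <- trajectory[1]
  last <- trajectory[length(trajectory)]
  scale <- max(abs(trajectory))
  abs_change <- abs(last - first)
  fold <- if (scale == 0 || abs(first) < tolerance * scale) {
    NA_real_
  } else {
    abs(last) / abs(first)
  }
  structure(fold, abs_change = abs_change)
}

#' Enforced-production flux scan (FSEOF-style target identification)
#'
#' Fixes the product exchange flux (both bounds) at each of `steps` evenly
#' spaced levels from the control level to the theoretical maximum,
#' re-solves FBA with growth as the objective, and resolves every
#' reaction's flux at each level by flux variability at the growth optimum
#' (interval midpoint -- the same degenerate-optimum policy used for
#' secretion rates). Reactions whose flux rises monotonically with enforced
#' production are the overexpression candidates; [rank_targets()] orders
#' them by fold.
#'
#' Run this on the model that already carries the intended deletions (the
#' workflow scans the fumarase-knockout model).
#'
#' @param model a `metabolic_model` (typically a knockout).
#' @param sim_cfg a [sim_config()].
#' @param scan_cfg a [scan_config()].
#' @return an object of class `flux_scan_table`: `rows` (data.frame with
#'   `reaction_id`, `subsystem`, `profile_class`, `fold`, `abs_change`),
#'   `trajectories` (reactions x levels matrix), `levels`,
#'   `growth` (growth optimum per level), `config`.
#' @export
enforced_production_scan <- function(model, sim_cfg = sim_config(),
                                     scan_cfg = scan_config()) {
  validate_model(model)
  objective_id <- scan_cfg$objective_id %||% resolve_objective(model, sim_cfg)
  pi <- reaction_index(model, scan_cfg$product_exchange_id)
  cm <- fba_condition_model(model, sim_cfg)
  tol <- sim_cfg$solver_tolerance

  max_level <- scan_cfg$max_level
  if (identical(max_level, "auto")) {
    res <- solve_lp_on(cm, scan_cfg$product_exchange_id, maximize = TRUE, tol = tol)
    if (res$status != "optimal") {
      stop("cannot resolve max_level: product maximization is ", res$status)
    }
    max_level <- res$objective
  }
  if (max_level <= scan_cfg$control_level) {
    stop(
      "control_level (", scan_cfg$control_level,
      ") must lie below the maximum attainable production (", format(max_level), ")"
    )
  }
  levels <- seq(scan_cfg$control_level, max_level, length.out = scan_cfg$steps)

  rids <- cm$reactions$id
  traj <- matrix(NA_real_,
    nrow = length(rids), ncol = scan_cfg$steps,
    dimnames = list(rids, sprintf("level_%g", levels))
  )
  growth <- numeric(scan_cfg$steps)
  for (k in seq_len(scan_cfg$steps)) {
    L <- levels[k]
    cmk <- cm
    cmk$reactions$lb[pi] <- L
    cmk$reactions$ub[pi] <- L
    res <- solve_lp_on(cmk, objective_id, maximize = TRUE, tol = tol)
    if (res$status != "optimal") {
      stop("enforced level ", format(L), " is ", res$status)
    }
    growth[k] <- res$objective
    for (j in seq_along(rids)) {
      iv <- fva_range(cmk, objective_id, res$objective, 1.0, rids[j], tol = tol)
      traj[j, k] <- (iv[1] + iv[2]) / 2
    }
  }

  folds <- numeric(length(rids))
  absch <- numeric(length(rids))
  classes <- character(length(rids))
  for (j in seq_along(rids)) {
    classes[j] <- classify_trajectory(traj[j, ], scan_cfg$classification_tolerance)
    f <- compute_fold(traj[j, ], scan_cfg$classification_tolerance)
    folds[j] <- as.numeric(f)
    absch[j] <- attr(f, "abs_change")
  }
  rows <- data.frame(
    reaction_id = rids,
    subsystem = cm$reactions$subsystem,
    profile_class = classes,
    fold = folds,
    abs_change = absch,
    stringsAsFactors = FALSE
  )
  scan_cfg$max_level <- max_level
  structure(
    list(
      rows = rows, trajectories = traj, levels = levels,
      growth = growth, config = scan_cfg, objective_id = objective_id
    ),
    class = "flux_scan_table"
  )
}

#' Rank overexpression candidates from a flux scan
#'
#' Keeps the `"increased"` rows and sorts them by fold, descending.
#' Undefined folds (zero flux at the control level) rank after all defined
#' folds, ordered by their absolute flux change; remaining ties break
#' alphabetically by reaction id.
#'
#' @param table a `flux_scan_table` from [enforced_production_scan()].
#' @return the ranked subset of `table$rows` (possibly zero rows).
#' @export
rank_targets <- function(table) {
  stopifnot(inherits(table, "flux_scan_table"))
  inc <- table$rows[table$rows$profile_class == "increased", , drop = FALSE]
  if (nrow(inc) == 0) {
    return(inc)
  }
  defined <- !is.na(inc$fold)
  key1 <- ifelse(defined, 0, 1) # defined folds first
  key2 <- ifelse(defined, -inc$fold, -inc$abs_change)
  inc <- inc[order(key1, key2, inc$reaction_id), , drop = FALSE]
  rownames(inc) <- NULL
  inc
}

#' @export
print.flux_scan_table <- function(x, ...) {
  cat(
    "<flux_scan_table> ", nrow(x$rows), " reactions x ", length(x$levels),
    " enforced levels of ", x$config$product_exchange_id,
    " in [", format(min(x$levels)), ", ", format(max(x$levels)), "]\n",
    sep = ""
  )
  print(table(x$rows$profile_class))
  inc <- rank_targets(x)
  if (nrow(inc)) {
    cat("top candidates:\n")
    print(utils::head(inc, 5), row.names = FALSE)
  }
  invisible(x)
}

#' @export
as.data.frame.flux_scan_table <- function(x, ...) {
  cbind(
    x$rows[, c("reaction_id", "subsystem")],
    as.data.frame(x$trajectories, row.names = FALSE),
    x$rows[, c("profile_class", "fold", "abs_change")]
  )
}
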