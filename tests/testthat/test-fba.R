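core <- build_core_model()

test_that("the growth optimum is feasible, positive and at steady state", {
  fs <- solve_fba(core, sim_config())
  expect_identical(fs$status, "optimal")
  expect_gt(fs$objective_value, 0)
  expect_lt(steady_state_residual(core, fs$fluxes), 1e-6)
  # the substrate cap is applied to the exchange lower bound (uptake = negative)
  expect_gte(fs$fluxes[["EX_glc__D_e"]], -10 - 1e-9)
})

test_that("minimal-medium conditioning closes organic uptake but leaves CO2 open", {
  cm <- fluxscan:::fba_condition_model(core, sim_config())
  rid <- cm$reactions$id
  expect_identical(cm$reactions$lb[rid == "EX_glc__D_e"], -10)
  expect_identical(cm$reactions$lb[rid == "EX_co2_e"], -1000) # inorganic carbon stays open
  expect_identical(cm$reactions$lb[rid == "EX_o2_e"], -1000) # aerobic default
  expect_identical(cm$reactions$lb[rid == "EX_etoh_e"], 0) # organic carbon closed
  cm2 <- fluxscan:::fba_condition_model(core, sim_config(oxygen_policy = 2.5))
  expect_identical(cm2$reactions$lb[cm2$reactions$id == "EX_o2_e"], -2.5)
})

test_that("a missing objective is a configuration error, not a silent default", {
  m <- core
  m$objective_id <- NA_character_
  expect_error(solve_fba(m, sim_config()), "no objective")
  expect_identical(
    solve_fba(m, sim_config(objective_id = "BIOMASS"))$objective_value,
    solve_fba(core, sim_config())$objective_value
  )
})

test_that("flux variability pins the objective to itself and nests with fraction", {
  cfg <- sim_config()
  opt <- solve_fba(core, cfg)$objective_value
  self_iv <- flux_variability(core, cfg, "BIOMASS", 1.0)
  expect_equal(self_iv$min_flux, opt, tolerance = 1e-6)
  expect_equal(self_iv$max_flux, opt, tolerance = 1e-6)
  # the optimal face allows no wild-type fumarate secretion
  fum_1 <- flux_variability(core, cfg, "EX_fum_e", 1.0)
  expect_equal(fum_1$min_flux, 0, tolerance = 1e-6)
  expect_equal(fum_1$max_flux, 0, tolerance = 1e-6)
  # relaxing the objective floor can only widen the interval
  fum_09 <- flux_variability(core, cfg, "EX_fum_e", 0.9)
  expect_lte(fum_09$min_flux, fum_1$min_flux + 1e-9)
  expect_gte(fum_09$max_flux, fum_1$max_flux - 1e-9)
})

test_that("the optimum is invariant under reordering of reactions and metabolites", {
  withr::local_seed(5)
  base <- solve_fba(core, sim_config())$objective_value
  perm <- core
  pr <- sample(nrow(perm$reactions))
  pm <- sample(nrow(perm$metabolites))
  perm$reactions <- perm$reactions[pr, ]
  perm$metabolites <- perm$metabolites[pm, ]
  rownames(perm$reactions) <- NULL
  rownames(perm$metabolites) <- NULL
  expect_lt(abs(solve_fba(perm, sim_config())$objective_value - base), 1e-9)
})

test_that("relaxing any single bound never lowers the optimum", {
  withr::local_seed(17)
  cfg <- sim_config()
  base <- solve_fba(core, cfg)$objective_value
  internal <- which(!is_exchange(core))
  for (i in sample(internal, 8)) {
    looser <- core
    looser$reactions$ub[i] <- looser$reactions$ub[i] * 1.5
    if (looser$reactions$lb[i] < 0) looser$reactions$lb[i] <- looser$reactions$lb[i] * 1.5
    expect_gte(solve_fba(looser, cfg)$objective_value, base - 1e-9)
  }
})

test_that("robustness over glucose uptake is non-decreasing on the core model", {
  prof <- robustness_scan(core, sim_config(), "EX_glc__D_e", 0, 10, 11, uptake = TRUE)
  expect_identical(length(prof$objective_values), 11L)
  expect_true(all(prof$feasible))
  expect_true(all(diff(prof$objective_values) >= -1e-9))
  # a one-point sweep at the default uptake equals plain FBA there
  expect_equal(
    prof$objective_values[11],
    solve_fba(core, sim_config())$objective_value,
    tolerance = 1e-9
  )
})

test_that("the knockout robustness curve never rises above the wild-type curve", {
  ko <- delete_gene(core, "FUM1")
  cfg <- sim_config()
  wt_prof <- robustness_scan(core, cfg, "EX_glc__D_e", 0, 20, 9, uptake = TRUE)
  ko_prof <- robustness_scan(ko, cfg, "EX_glc__D_e", 0, 20, 9, uptake = TRUE)
  expect_true(all(ko_prof$objective_values <= wt_prof$objective_values + 1e-9))
  # per-point cross-check against the independent LP oracle at three uptakes
  idx <- c(3, 6, 9)
  reqs <- lapply(idx, function(k) {
    cm <- conditioned(ko, cfg)
    cm <- set_bounds(cm, "EX_glc__D_e",
      lb = -ko_prof$parameter_values[k],
      ub = -ko_prof$parameter_values[k]
    )
    list(model = cm, op = "fba")
  })
  res <- cobra_oracle(reqs)
  for (j in seq_along(idx)) {
    expect_equal(res[[j]]$objective, ko_prof$objective_values[idx[j]], tolerance = 1e-6)
  }
})

test_that("infeasible grid points are recorded with objective 0, keeping the grid", {
  m <- build_core_model(core_model_config(atp_maintenance = 5))
  # forcing zero glucose uptake starves the mandatory ATP drain
  prof <- robustness_scan(m, sim_config(), "EX_glc__D_e", 0, 10, 6, uptake = TRUE)
  expect_identical(length(prof$objective_values), 6L)
  expect_false(prof$feasible[1])
  expect_identical(prof$objective_values[1], 0)
  expect_true(any(prof$feasible))
})

test_that("objective values agree with cobrapy/GLPK on the canonical model", {
  res <- cobra_oracle(list(list(model = conditioned(core), op = "fba")))
  mine <- solve_fba(core, sim_config())$objective_value
  expect_equal(mine, res[[1]]$objective, tolerance = 1e-6)
})
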