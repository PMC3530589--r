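core <- build_core_model()
ko <- delete_gene(core, "FUM1")

test_that("trajectory classification follows the increased/decreased/irregular scheme", {
  expect_identical(classify_trajectory(c(1.0, 1.2, 1.5, 1.8)), "increased")
  expect_identical(classify_trajectory(c(1.8, 1.5, 1.2, 1.0)), "decreased")
  expect_identical(classify_trajectory(c(1.0, 1.0, 1.0)), "irregular") # unchanged
  expect_identical(classify_trajectory(c(1.0, 2.0, 0.5)), "irregular") # ruleless
  expect_identical(classify_trajectory(c(0, 0, 0)), "irregular") # all-zero
  # a sub-tolerance dip does not break monotonicity
  expect_identical(classify_trajectory(c(1.0, 1.5, 1.499, 2.0), tolerance = 0.01), "increased")
  expect_identical(classify_trajectory(c(1.0, 1.5, 1.40, 2.0), tolerance = 0.01), "irregular")
  expect_error(classify_trajectory(c(1, 2)), "at least 3")
})

test_that("classification is invariant under uniform positive scaling", {
  withr::local_seed(31)
  for (rep in 1:20) {
    traj <- stats::rnorm(6)
    for (s in c(1e-3, 1, 250)) {
      expect_identical(classify_trajectory(traj * s), classify_trajectory(traj))
    }
  }
})

test_that("fold is the endpoint ratio, with an NA sentinel for zero baselines", {
  expect_equal(as.numeric(compute_fold(c(2, 2, 2))), 1)
  expect_equal(as.numeric(compute_fold(c(1, 1.3, 1.82))), 1.82)
  f0 <- compute_fold(c(0, 1.5, 3))
  expect_true(is.na(as.numeric(f0)))
  expect_equal(attr(f0, "abs_change"), 3)
  # sign is dropped: a reversible reaction deepening in reverse still folds up
  expect_equal(as.numeric(compute_fold(c(-1, -1.5, -2))), 2)
  expect_error(compute_fold(1.0), "at least 2")
})

test_that("the enforced-production scan is faithful to its clamp and its grid", {
  scn <- enforced_production_scan(
    ko, sim_config(),
    scan_config(control_level = 0.4, steps = 5)
  )
  expect_identical(length(scn$levels), 5L)
  expect_identical(dim(scn$trajectories), c(nrow(ko$reactions), 5L))
  # clamp fidelity: the product's own trajectory is the level grid
  expect_lt(max(abs(scn$trajectories["EX_fum_e", ] - scn$levels)), 1e-9)
  # levels run from the control to the resolved maximum, strictly increasing
  expect_identical(scn$levels[1], 0.4)
  expect_true(all(diff(scn$levels) > 0))
  expect_equal(scn$config$max_level, 10, tolerance = 1e-6) # all carbon to fumarate
  # growth is non-increasing in the enforced level
  expect_true(all(diff(scn$growth) <= 1e-9))
  # every reaction receives exactly one class label
  expect_true(all(scn$rows$profile_class %in% c("increased", "decreased", "irregular")))
  # pyruvate carboxylase feeds the oxidative route to fumarate: non-decreasing
  expect_true(all(diff(scn$trajectories["PC", ]) >= -1e-9))
  # per-level growth cross-check against the independent LP oracle
  reqs <- lapply(c(1, 3, 5), function(k) {
    cm <- conditioned(ko, sim_config())
    cm <- set_bounds(cm, "EX_fum_e", lb = scn$levels[k], ub = scn$levels[k])
    list(model = cm, op = "fba")
  })
  res <- cobra_oracle(reqs)
  expect_equal(scn$growth[1], res[[1]]$objective, tolerance = 1e-6)
  expect_equal(scn$growth[3], res[[2]]$objective, tolerance = 1e-6)
  expect_equal(scn$growth[5], res[[3]]$objective, tolerance = 1e-6)
})

test_that("scan levels below the knockout's natural secretion stay feasible", {
  scn <- enforced_production_scan(
    ko, sim_config(),
    scan_config(control_level = 0.1, max_level = "auto", steps = 5)
  )
  expect_identical(length(scn$growth), 5L)
  expect_true(all(scn$growth >= 0))
  expect_lt(max(abs(scn$trajectories["EX_fum_e", ] - scn$levels)), 1e-9)
})

test_that("classes of strictly monotone trajectories are stable across grid density", {
  cfg3 <- scan_config(control_level = 0.4, steps = 3)
  cfg10 <- scan_config(control_level = 0.4, steps = 10)
  s3 <- enforced_production_scan(ko, sim_config(), cfg3)
  s10 <- enforced_production_scan(ko, sim_config(), cfg10)
  strict10 <- vapply(seq_len(nrow(s10$rows)), function(j) {
    d <- diff(s10$trajectories[j, ])
    all(d > 1e-9) || all(d < -1e-9)
  }, logical(1))
  expect_gt(sum(strict10), 0)
  expect_identical(
    s3$rows$profile_class[strict10],
    s10$rows$profile_class[strict10]
  )
})

test_that("ranking puts pyruvate carboxylase first among pathway enzymes", {
  scn <- enforced_production_scan(
    ko, sim_config(),
    scan_config(control_level = 0.4, steps = 5)
  )
  ranked <- rank_targets(scn)
  expect_true(all(ranked$profile_class == "increased"))
  # defined folds are sorted descending
  def <- ranked$fold[!is.na(ranked$fold)]
  expect_true(all(diff(def) <= 1e-12))
  # among the classic amplification-panel enzymes (lower glycolysis plus
  # anaplerosis), pyruvate carboxylase shows the steepest fold; the toy's
  # lumped PPP gives the hexose isomerase an outsized endpoint ratio, so the
  # comparison set is the enzyme panel, not every glycolytic reaction
  panel <- c("ENO", "GAPD", "PGK", "PGM", "PYK", "TPI", "PC")
  enz <- ranked[ranked$reaction_id %in% panel, ]
  expect_identical(enz$reaction_id[1], "PC")
  expect_gt(enz$fold[1], 1.5)
  expect_true(all(enz$fold[enz$reaction_id != "PC"] < enz$fold[enz$reaction_id == "PC"]))
})

test_that("a scan with no increased reactions ranks an empty table", {
  fake <- enforced_production_scan(
    ko, sim_config(),
    scan_config(control_level = 0.4, steps = 3)
  )
  fake$rows$profile_class <- "decreased"
  expect_identical(nrow(rank_targets(fake)), 0L)
})

test_that("infeasible enforcement levels and bad control levels are refused", {
  expect_error(
    enforced_production_scan(
      ko, sim_config(),
      scan_config(control_level = 11, max_level = 12, steps = 3)
    ),
    "infeasible|not optimal"
  )
  expect_error(
    enforced_production_scan(
      ko, sim_config(),
      scan_config(control_level = 10.5, max_level = "auto", steps = 3)
    ),
    "control_level"
  )
  expect_error(scan_config(control_level = 0.4, max_level = 0.3), "exceed")
})
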