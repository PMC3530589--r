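# Field-by-field equivalence of two models, with bounds compared to 1e-9
# and GPRs compared by truth table (logical equivalence, not string identity).
expect_models_equivalent <- function(a, b) {
  expect_identical(a$metabolites$id, b$metabolites$id)
  expect_identical(a$metabolites$compartment, b$metabolites$compartment)
  expect_identical(a$reactions$id, b$reactions$id)
  expect_identical(a$reactions$subsystem, b$reactions$subsystem)
  expect_lt(max(abs(a$reactions$lb - b$reactions$lb)), 1e-9)
  expect_lt(max(abs(a$reactions$ub - b$reactions$ub)), 1e-9)
  expect_identical(
    lapply(a$reactions$stoichiometry, function(s) s[order(names(s))]),
    lapply(b$reactions$stoichiometry, function(s) s[order(names(s))])
  )
  expect_setequal(a$genes, b$genes)
  expect_identical(a$objective_id, b$objective_id)
  for (i in seq_len(nrow(a$reactions))) {
    ea <- parse_gpr(a$reactions$gpr[i])
    eb <- parse_gpr(b$reactions$gpr[i])
    genes <- gpr_genes(ea)
    expect_setequal(gpr_genes(eb), genes)
    if (length(genes) > 0 && length(genes) <= 4) {
      grid <- expand.grid(rep(list(c(TRUE, FALSE)), length(genes)))
      names(grid) <- genes
      for (k in seq_len(nrow(grid))) {
        asg <- unlist(grid[k, , drop = FALSE])
        expect_identical(gpr_eval(ea, asg), gpr_eval(eb, asg),
          info = paste("GPR mismatch at", a$reactions$id[i])
        )
      }
    }
  }
}

test_that("write/read round-trips preserve the core model in both dialects", {
  m <- build_core_model()
  for (dialect in c("cobra-json", "sbml-fbc")) {
    path <- tempfile(fileext = if (dialect == "cobra-json") ".json" else ".xml")
    write_model(m, path, dialect)
    m2 <- read_model(path, dialect = "auto")
    expect_models_equivalent(m, m2)
  }
})

test_that("dialect auto-detection falls back to content sniffing", {
  m <- build_core_model()
  p_json <- tempfile() # no extension
  write_model(m, p_json, dialect = "cobra-json")
  expect_s3_class(read_model(p_json), "metabolic_model")
  p_xml <- tempfile()
  write_model(m, p_xml, dialect = "sbml-fbc")
  expect_identical(read_model(p_xml)$objective_id, "BIOMASS")
})

test_that("large finite bounds survive a round trip exactly", {
  m <- build_core_model()
  m <- set_bounds(m, "GAPD", ub = 999999)
  for (dialect in c("cobra-json", "sbml-fbc")) {
    path <- tempfile(fileext = ".bin")
    write_model(m, path, dialect)
    m2 <- read_model(path, dialect = dialect)
    expect_identical(m2$reactions$ub[m2$reactions$id == "GAPD"], 999999)
  }
})

test_that("validation rejects a GPR gene missing from the gene list, naming the reaction", {
  doc <- list(
    id = "bad",
    metabolites = list(list(id = "a_c", name = "a", compartment = "c")),
    reactions = list(list(
      id = "R1", name = "r1", metabolites = list(a_c = -1),
      lower_bound = 0, upper_bound = 10, gene_reaction_rule = "YPL262W",
      subsystem = "", objective_coefficient = 0
    )),
    genes = list() # YPL262W deliberately absent
  )
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "R1.*YPL262W")
})

test_that("an unparseable GPR is reported with the offending reaction", {
  doc <- list(
    id = "bad2",
    metabolites = list(list(id = "a_c", name = "a", compartment = "c")),
    reactions = list(list(
      id = "Rbroken", name = "r", metabolites = list(a_c = -1),
      lower_bound = 0, upper_bound = 10, gene_reaction_rule = "A and (B",
      subsystem = "", objective_coefficient = 0
    )),
    genes = list(list(id = "A"), list(id = "B"))
  )
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  expect_error(read_model(path), "Rbroken")
})

test_that("malformed files raise parse errors naming the file", {
  p1 <- tempfile(fileext = ".json")
  writeLines("{ not json", p1)
  expect_error(read_model(p1), "parse error")
  p2 <- tempfile(fileext = ".xml")
  writeLines("<sbml><unclosed>", p2)
  expect_error(read_model(p2), "parse error")
  expect_error(read_model(tempfile(fileext = ".json")), "does not exist")
  expect_error(write_model(build_core_model(), file.path(tempfile(), "x", "y.json")), "directory")
})

test_that("structural invariant violations are rejected with the element named", {
  m <- build_core_model()
  bad <- m
  bad$reactions$lb[3] <- bad$reactions$ub[3] + 1
  expect_error(validate_model(bad), bad$reactions$id[3])
  bad2 <- m
  bad2$objective_id <- "NOT_A_REACTION"
  expect_error(validate_model(bad2), "NOT_A_REACTION")
  bad3 <- m
  bad3$metabolites$compartment[5] <- ""
  expect_error(validate_model(bad3), bad3$metabolites$id[5])
  bad4 <- m
  bad4$reactions$stoichiometry[[2]] <- c(ghost_met = -1)
  expect_error(validate_model(bad4), "ghost_met")
})

test_that("an independent reader (cobrapy) parses both dialects with identical counts", {
  m <- build_core_model()
  pj <- tempfile(fileext = ".json")
  px <- tempfile(fileext = ".xml")
  write_model(m, pj, "cobra-json")
  write_model(m, px, "sbml-fbc")
  res <- cobra_oracle(list(
    list(path = pj, op = "fba"),
    list(path = px, op = "fba")
  ))
  for (r in res) {
    expect_identical(r$n_metabolites, nrow(m$metabolites))
    expect_identical(r$n_reactions, nrow(m$reactions))
    expect_identical(r$n_genes, length(m$genes))
  }
  # and both dialects define the same optimization problem
  expect_equal(res[[1]]$objective, res[[2]]$objective, tolerance = 1e-9)
})
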