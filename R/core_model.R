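#' Configuration for the yeast-core model generator
#'
#' Describes the small central-carbon network the generator emits: stepwise
#' glycolysis, a lumped oxidative pentose-phosphate reaction for NADPH,
#' pyruvate decarboxylase/alcohol dehydrogenase (the ethanol branch),
#' mitochondrial pyruvate oxidation and an oxidative TCA cycle including
#' aconitase and fumarase, the reductive anaplerotic branch (pyruvate
#' carboxylase, cytosolic malate dehydrogenase, reversible cytosolic
#' fumarase) that fixes CO2, lumped oxidative phosphorylation (P/O = 2),
#' exchanges for glucose / O2 / CO2 / ethanol / fumarate, and a biomass
#' pseudo-reaction draining pyruvate, oxaloacetate, ATP and NADPH.
#'
#' @param include_reductive_branch include pyruvate carboxylase, cytosolic
#'   malate dehydrogenase and the reversible cytosolic fumarase
#'   (default `TRUE`). With `FALSE` the network has no anaplerotic
#'   oxaloacetate source and the mitochondrial fumarase is forced
#'   irreversible-forward (fumarate -> malate, the oxidative direction).
#' @param include_fum1 gene-associate both fumarases to `FUM1`
#'   (default `TRUE`); with `FALSE` fumarase carries no GPR.
#' @param include_ethanol_branch include pyruvate decarboxylase and alcohol
#'   dehydrogenase plus the ethanol exchange (default `TRUE`).
#' @param atp_maintenance lower bound of the non-growth ATP maintenance
#'   reaction, mmol gDCW^-1 h^-1 (default 0: the reductive fumarate route is
#'   energetically neutral, so any forced maintenance drain would make the
#'   2 mol/mol theoretical yield unattainable).
#' @param glucose_uptake default glucose uptake cap encoded in the glucose
#'   exchange lower bound, mmol gDCW^-1 h^-1 (default 10).
#' @return an object of class `core_model_config`.
#' @export
core_model_config <- function(include_reductive_branch = TRUE,
                              include_fum1 = TRUE,
                              include_ethanol_branch = TRUE,
                              atp_maintenance = 0,
                              glucose_uptake = 10) {
  stopifnot(atp_maintenance >= 0, glucose_uptake >= 0)
  structure(
    list(
      include_reductive_branch = isTRUE(include_reductive_branch),
      include_fum1 = isTRUE(include_fum1),
      include_ethanol_branch = isTRUE(include_ethanol_branch),
      atp_maintenance = atp_maintenance,
      glucose_uptake = glucose_uptake
    ),
    class = "core_model_config"
  )
}

#' Build the deterministic yeast-core metabolic model
#'
#' Generates a mass-balanced central-carbon model of S. cerevisiae with
#' analytically known optima (see the package vignette for the worked
#' algebra). The canonical model (default config) is bit-identical across
#' runs and platforms: no randomness is involved.
#'
#' Key designed properties of the canonical model: the maximum fumarate
#' yield on glucose is exactly 2 mol/mol (reductive, CO2-fixing route);
#' biomass optimum is strictly positive at the default glucose uptake;
#' deleting `FUM1` lowers growth by a few percent while forcing a small
#' strictly positive fumarate secretion, while the wild-type secretes none.
#'
#' Toy conventions, stated openly: cofactor pools (ATP/ADP, NAD(H),
#' NADP(H), CoA) are shared across compartments and carried with carbon-free
#' pseudo-formulas (`"R"`), so the carbon-balance check counts skeleton
#' carbons only; acetyl-CoA counts its 2 acetyl carbons; succinate
#' dehydrogenase is lumped to NAD and oxidative phosphorylation to P/O = 2.
#'
#' @param config a [core_model_config()]; defaults to the canonical one.
#' @return a validated [metabolic_model()] with objective `BIOMASS`.
#' @export
#' @examples
#' model <- build_core_model()
#' model
build_core_model <- function(config = core_model_config()) {
  stopifnot(inherits(config, "core_model_config"))

  met <- function(id, name, compartment, formula) {
    data.frame(id = id, name = name, compartment = compartment, formula = formula, stringsAsFactors = FALSE)
  }
  mets <- rbind(
    met("glc__D_e", "D-glucose", "e", "C6H12O6"),
    met("glc__D_c", "D-glucose", "c", "C6H12O6"),
    met("g6p_c", "glucose 6-phosphate", "c", "C6H11O9P"),
    met("f6p_c", "fructose 6-phosphate", "c", "C6H11O9P"),
    met("fdp_c", "fructose 1,6-bisphosphate", "c", "C6H10O12P2"),
    met("dhap_c", "dihydroxyacetone phosphate", "c", "C3H5O6P"),
    met("g3p_c", "glyceraldehyde 3-phosphate", "c", "C3H5O6P"),
    met("13dpg_c", "1,3-bisphosphoglycerate", "c", "C3H4O10P2"),
    met("3pg_c", "3-phosphoglycerate", "c", "C3H4O7P"),
    met("2pg_c", "2-phosphoglycerate", "c", "C3H4O7P"),
    met("pep_c", "phosphoenolpyruvate", "c", "C3H2O6P"),
    met("pyr_c", "pyruvate", "c", "C3H3O3"),
    met("pyr_m", "pyruvate", "m", "C3H3O3"),
    met("accoa_m", "acetyl-CoA (acetyl carbons)", "m", "C2H3O"),
    met("coa_m", "coenzyme A (carrier)", "m", "R"),
    met("cit_m", "citrate", "m", "C6H5O7"),
    met("icit_m", "isocitrate", "m", "C6H5O7"),
    met("akg_m", "2-oxoglutarate", "m", "C5H4O5"),
    met("succoa_m", "succinyl-CoA (succinyl carbons)", "m", "C4H4O4"),
    met("succ_m", "succinate", "m", "C4H4O4"),
    met("fum_m", "fumarate", "m", "C4H2O4"),
    met("mal_m", "(S)-malate", "m", "C4H4O5"),
    met("oaa_m", "oxaloacetate", "m", "C4H2O5"),
    met("oaa_c", "oxaloacetate", "c", "C4H2O5"),
    met("mal_c", "(S)-malate", "c", "C4H4O5"),
    met("fum_c", "fumarate", "c", "C4H2O4"),
    met("fum_e", "fumarate", "e", "C4H2O4"),
    met("acald_c", "acetaldehyde", "c", "C2H4O"),
    met("etoh_c", "ethanol", "c", "C2H6O"),
    met("etoh_e", "ethanol", "e", "C2H6O"),
    met("co2_c", "carbon dioxide", "c", "CO2"),
    met("co2_m", "carbon dioxide", "m", "CO2"),
    met("co2_e", "carbon dioxide", "e", "CO2"),
    met("o2_c", "oxygen", "c", "O2"),
    met("o2_e", "oxygen", "e", "O2"),
    met("atp_c", "ATP (energy carrier)", "c", "R"),
    met("adp_c", "ADP (energy carrier)", "c", "R"),
    met("nad_c", "NAD+ (redox carrier)", "c", "R"),
    met("nadh_c", "NADH (redox carrier)", "c", "R"),
    met("nadp_c", "NADP+ (redox carrier)", "c", "R"),
    met("nadph_c", "NADPH (redox carrier)", "c", "R")
  )

  rxs <- list()
  rx <- function(id, name, subsystem, stoich, lb, ub, gpr = "") {
    rxs[[length(rxs) + 1]] <<- list(
      id = id, name = name, subsystem = subsystem,
      lb = lb, ub = ub, gpr = gpr, stoichiometry = stoich
    )
  }
  fum_gpr <- if (config$include_fum1) "FUM1" else ""

  ## exchanges (negative flux = uptake)
  rx("EX_glc__D_e", "D-glucose exchange", "Exchange", c(glc__D_e = -1), -config$glucose_uptake, 1000)
  rx("EX_o2_e", "O2 exchange", "Exchange", c(o2_e = -1), -1000, 1000)
  rx("EX_co2_e", "CO2 exchange", "Exchange", c(co2_e = -1), -1000, 1000)
  rx("EX_fum_e", "fumarate exchange", "Exchange", c(fum_e = -1), 0, 1000)
  if (config$include_ethanol_branch) {
    rx("EX_etoh_e", "ethanol exchange", "Exchange", c(etoh_e = -1), 0, 1000)
  }

  ## transport
  rx("GLCt", "glucose transport", "Transport", c(glc__D_e = -1, glc__D_c = 1), 0, 1000)
  rx("O2t", "O2 diffusion", "Transport", c(o2_e = -1, o2_c = 1), -1000, 1000)
  rx("CO2t", "CO2 diffusion", "Transport", c(co2_e = -1, co2_c = 1), -1000, 1000)
  rx("CO2tm", "CO2 diffusion, mitochondrial", "Transport", c(co2_c = -1, co2_m = 1), -1000, 1000)
  rx("FUMtm", "fumarate transport, mitochondrial", "Transport", c(fum_m = -1, fum_c = 1), -1000, 1000)
  rx("FUMt", "fumarate efflux", "Transport", c(fum_c = -1, fum_e = 1), 0, 1000)
  rx("PYRt2m", "pyruvate transport, mitochondrial", "Transport", c(pyr_c = -1, pyr_m = 1), 0, 1000)
  rx("OAAtm", "oxaloacetate transport, mitochondrial", "Transport", c(oaa_c = -1, oaa_m = 1), -1000, 1000)
  if (config$include_ethanol_branch) {
    rx("ETOHt", "ethanol efflux", "Transport", c(etoh_c = -1, etoh_e = 1), 0, 1000)
  }

  ## glycolysis (ids follow the standard BiGG-style abbreviations)
  rx("HEX1", "hexokinase", "Glycolysis/Gluconeogenesis",
    c(glc__D_c = -1, atp_c = -1, g6p_c = 1, adp_c = 1), 0, 1000, "HXK1 or HXK2")
  rx("PGI", "glucose-6-phosphate isomerase", "Glycolysis/Gluconeogenesis",
    c(g6p_c = -1, f6p_c = 1), -1000, 1000, "PGI1")
  rx("PFK", "phosphofructokinase", "Glycolysis/Gluconeogenesis",
    c(f6p_c = -1, atp_c = -1, fdp_c = 1, adp_c = 1), 0, 1000, "PFK1 and PFK2")
  rx("FBA", "fructose-bisphosphate aldolase", "Glycolysis/Gluconeogenesis",
    c(fdp_c = -1, dhap_c = 1, g3p_c = 1), -1000, 1000, "FBA1")
  rx("TPI", "triose-phosphate isomerase", "Glycolysis/Gluconeogenesis",
    c(dhap_c = -1, g3p_c = 1), -1000, 1000, "TPI1")
  rx("GAPD", "glyceraldehyde-3-phosphate dehydrogenase", "Glycolysis/Gluconeogenesis",
    c(g3p_c = -1, nad_c = -1, `13dpg_c` = 1, nadh_c = 1), -1000, 1000, "TDH1 or TDH2 or TDH3")
  rx("PGK", "phosphoglycerate kinase", "Glycolysis/Gluconeogenesis",
    c(`13dpg_c` = -1, adp_c = -1, `3pg_c` = 1, atp_c = 1), -1000, 1000, "PGK1")
  rx("PGM", "phosphoglycerate mutase", "Glycolysis/Gluconeogenesis",
    c(`3pg_c` = -1, `2pg_c` = 1), -1000, 1000, "GPM1")
  rx("ENO", "enolase", "Glycolysis/Gluconeogenesis",
    c(`2pg_c` = -1, pep_c = 1), -1000, 1000, "ENO1 or ENO2")
  rx("PYK", "pyruvate kinase", "Glycolysis/Gluconeogenesis",
    c(pep_c = -1, adp_c = -1, pyr_c = 1, atp_c = 1), 0, 1000, "CDC19")

  ## lumped oxidative pentose-phosphate pathway (sole NADPH source):
  ## 3 g6p + 6 NADP+ -> 2 f6p + g3p + 3 CO2 + 6 NADPH   (18 C in, 18 C out)
  rx("PPP", "oxidative pentose phosphate pathway (lumped)", "Pentose Phosphate Pathway",
    c(g6p_c = -3, nadp_c = -6, f6p_c = 2, g3p_c = 1, co2_c = 3, nadph_c = 6), 0, 1000, "ZWF1")

  ## ethanol branch
  if (config$include_ethanol_branch) {
    rx("PDC", "pyruvate decarboxylase", "Pyruvate Metabolism",
      c(pyr_c = -1, acald_c = 1, co2_c = 1), 0, 1000, "PDC1")
    rx("ADH", "alcohol dehydrogenase", "Pyruvate Metabolism",
      c(acald_c = -1, nadh_c = -1, etoh_c = 1, nad_c = 1), 0, 1000, "ADH1")
  }

  ## mitochondrial pyruvate oxidation + oxidative TCA cycle
  rx("PDHm", "pyruvate dehydrogenase", "Pyruvate Metabolism",
    c(pyr_m = -1, coa_m = -1, nad_c = -1, accoa_m = 1, co2_m = 1, nadh_c = 1), 0, 1000, "PDA1 and PDB1")
  rx("CSm", "citrate synthase", "Citric Acid Cycle",
    c(accoa_m = -1, oaa_m = -1, cit_m = 1, coa_m = 1), 0, 1000, "CIT1")
  rx("ACONTm", "aconitase", "Citric Acid Cycle",
    c(cit_m = -1, icit_m = 1), -1000, 1000, "ACO1")
  rx("ICDHxm", "isocitrate dehydrogenase (NAD+)", "Citric Acid Cycle",
    c(icit_m = -1, nad_c = -1, akg_m = 1, co2_m = 1, nadh_c = 1), 0, 1000, "IDH1 and IDH2")
  rx("AKGDm", "2-oxoglutarate dehydrogenase", "Citric Acid Cycle",
    c(akg_m = -1, coa_m = -1, nad_c = -1, succoa_m = 1, co2_m = 1, nadh_c = 1), 0, 1000, "KGD1 and KGD2")
  rx("SUCOASm", "succinyl-CoA synthetase", "Citric Acid Cycle",
    c(succoa_m = -1, adp_c = -1, succ_m = 1, coa_m = 1, atp_c = 1), 0, 1000, "LSC1 and LSC2")
  rx("SUCDm", "succinate dehydrogenase (lumped to NAD)", "Citric Acid Cycle",
    c(succ_m = -1, nad_c = -1, fum_m = 1, nadh_c = 1), 0, 1000, "SDH1 and SDH2")
  rx("FUMm", "fumarase, mitochondrial", "Citric Acid Cycle",
    c(fum_m = -1, mal_m = 1),
    if (config$include_reductive_branch) -1000 else 0, 1000, fum_gpr)
  rx("MDHm", "malate dehydrogenase, mitochondrial", "Citric Acid Cycle",
    c(mal_m = -1, nad_c = -1, oaa_m = 1, nadh_c = 1), -1000, 1000, "MDH1")

  ## reductive anaplerotic branch (CO2-fixing route to fumarate)
  if (config$include_reductive_branch) {
    rx("PC", "pyruvate carboxylase", "Anaplerotic reactions",
      c(pyr_c = -1, co2_c = -1, atp_c = -1, oaa_c = 1, adp_c = 1), 0, 1000, "PYC1 or PYC2")
    rx("MDH", "malate dehydrogenase, cytosolic", "Pyruvate Metabolism",
      c(oaa_c = -1, nadh_c = -1, mal_c = 1, nad_c = 1), -1000, 1000, "MDH2")
    rx("FUM", "fumarase, cytosolic", "Citric Acid Cycle",
      c(mal_c = -1, fum_c = 1), -1000, 1000, fum_gpr)
  }

  ## lumped oxidative phosphorylation, P/O = 2
  rx("NADHOR", "NADH oxidation / oxidative phosphorylation (P/O = 2)", "Oxidative Phosphorylation",
    c(nadh_c = -1, o2_c = -0.5, adp_c = -2, nad_c = 1, atp_c = 2), 0, 1000)

  ## non-growth ATP maintenance
  rx("ATPM", "non-growth ATP maintenance", "Maintenance",
    c(atp_c = -1, adp_c = 1), config$atp_maintenance, 1000)

  ## biomass pseudo-reaction: drains precursors in 3:1:12:4 proportions,
  ## scaled x10 so the optimum lands in a realistic specific-growth range
  rx("BIOMASS", "biomass pseudo-reaction", "Biomass",
    c(pyr_c = -30, oaa_c = -10, atp_c = -120, nadph_c = -40, adp_c = 120, nadp_c = 40),
    0, 1000)

  rdf <- data.frame(
    id = vapply(rxs, `[[`, character(1), "id"),
    name = vapply(rxs, `[[`, character(1), "name"),
    subsystem = vapply(rxs, `[[`, character(1), "subsystem"),
    lb = vapply(rxs, `[[`, numeric(1), "lb"),
    ub = vapply(rxs, `[[`, numeric(1), "ub"),
    gpr = vapply(rxs, `[[`, character(1), "gpr"),
    stringsAsFactors = FALSE
  )
  rdf$stoichiometry <- lapply(rxs, `[[`, "stoichiometry")

  metabolic_model(mets, rdf, objective_id = "BIOMASS", id = "yeast_core_fumarate")
}

#' Seeded variant of the core model with jittered internal bounds
#'
#' Returns the model [build_core_model()] would produce for `config`, with
#' every internal (non-exchange, non-biomass, non-maintenance) reaction cap
#' reproducibly jittered by a uniform +/-10%: positive upper bounds and
#' negative lower bounds are scaled, zeros are kept. Stoichiometry, GPRs and
#' the objective are untouched, so all steady-state invariants of the
#' canonical model hold for every variant. The same seed always yields the
#' identical model.
#'
#' @param config a [core_model_config()].
#' @param seed non-negative integer seed.
#' @return a validated `metabolic_model`.
#' @export
make_variant <- function(config = core_model_config(), seed = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  model <- build_core_model(config)
  keep <- is_exchange(model) | model$reactions$subsystem %in% c("Biomass", "Maintenance")
  with_seed(as.integer(seed), {
    for (i in which(!keep)) {
      f_ub <- stats::runif(1, 0.9, 1.1)
      f_lb <- stats::runif(1, 0.9, 1.1)
      model$reactions$ub[i] <- model$reactions$ub[i] * f_ub
      model$reactions$lb[i] <- model$reactions$lb[i] * f_lb
    }
  })
  model$id <- sprintf("%s_variant%d", model$id, as.integer(seed))
  validate_model(model)
  model
}
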