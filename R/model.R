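#' Construct a constraint-based metabolic model
#'
#' The central container of the package: metabolites, reactions with
#' stoichiometry / flux bounds / GPR rules, the gene set, and the active
#' objective reaction. Flux units follow the field convention of
#' mmol gDCW^-1 h^-1, with the biomass pseudo-reaction flux in h^-1.
#'
#' @param metabolites data.frame with columns `id`, `name`, `compartment`,
#'   `formula` (chemical formula; may be `NA` when unknown).
#' @param reactions data.frame with columns `id`, `name`, `subsystem`,
#'   `lb`, `ub`, `gpr` (rule string, `""` when not gene-associated) and a
#'   list-column `stoichiometry` of named numeric vectors
#'   (metabolite id -> signed coefficient, negative = consumed).
#' @param genes character vector of gene ids; defaults to the union of all
#'   genes mentioned in GPR rules.
#' @param objective_id id of the objective reaction, or `NA` if unset.
#' @param id model identifier string.
#' @param validate run [validate_model()] on the result (default `TRUE`).
#' @return an object of class `metabolic_model`.
#' @export
metabolic_model <- function(metabolites, reactions, genes = NULL,
                            objective_id = NA_character_, id = "model",
                            validate = TRUE) {
  stopifnot(is.data.frame(metabolites), is.data.frame(reactions))
  need_m <- c("id", "name", "compartment", "formula")
  need_r <- c("id", "name", "subsystem", "lb", "ub", "gpr", "stoichiometry")
  missing_m <- setdiff(need_m, names(metabolites))
  missing_r <- setdiff(need_r, names(reactions))
  if (length(missing_m)) stop("metabolites lack column(s): ", paste(missing_m, collapse = ", "))
  if (length(missing_r)) stop("reactions lack column(s): ", paste(missing_r, collapse = ", "))
  metabolites <- as.data.frame(metabolites[need_m], stringsAsFactors = FALSE)
  reactions <- as.data.frame(reactions[need_r], stringsAsFactors = FALSE)
  rownames(metabolites) <- NULL
  rownames(reactions) <- NULL
  if (is.null(genes)) {
    genes <- unique(unlist(lapply(reactions$gpr, function(g) gpr_genes(parse_gpr(g)))))
    genes <- sort(as.character(genes %||% character(0)))
  }
  m <- structure(
    list(
      id = id,
      metabolites = metabolites,
      reactions = reactions,
      genes = as.character(genes),
      objective_id = objective_id
    ),
    class = "metabolic_model"
  )
  if (validate) validate_model(m)
  m
}

#' Validate a metabolic model's structural invariants
#'
#' Checks, with an error naming the offending element on first violation:
#' unique metabolite / reaction / gene ids; non-empty compartments;
#' `lb <= ub` for every reaction; every stoichiometry references existing
#' metabolites; exchange reactions touch exactly one metabolite; internal
#' reactions have non-empty stoichiometry; every GPR parses and only uses
#' genes present in the model's gene set; the objective (when set) names an
#' existing reaction.
#'
#' @param model a `metabolic_model`.
#' @return `TRUE`, invisibly; otherwise an error.
#' @export
validate_model <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mets <- model$metabolites
  rxns <- model$reactions
  if (anyDuplicated(mets$id)) {
    stop("duplicate metabolite id: ", mets$id[duplicated(mets$id)][1])
  }
  if (anyDuplicated(rxns$id)) {
    stop("duplicate reaction id: ", rxns$id[duplicated(rxns$id)][1])
  }
  if (any(bad <- (is.na(mets$compartment) | !nzchar(mets$compartment)))) {
    stop("metabolite with empty compartment: ", mets$id[bad][1])
  }
  if (any(bad <- (rxns$lb > rxns$ub))) {
    stop("reaction with lb > ub: ", rxns$id[bad][1])
  }
  for (i in seq_len(nrow(rxns))) {
    st <- rxns$stoichiometry[[i]]
    unknown <- setdiff(names(st), mets$id)
    if (length(unknown)) {
      stop(
        "reaction ", rxns$id[i], " references unknown metabolite(s): ",
        paste(unknown, collapse = ", ")
      )
    }
    if (length(st) == 0) {
      stop("reaction ", rxns$id[i], " has empty stoichiometry")
    }
    expr <- tryCatch(parse_gpr(rxns$gpr[i]), error = function(e) {
      stop("reaction ", rxns$id[i], ": ", conditionMessage(e), call. = FALSE)
    })
    missing_genes <- setdiff(gpr_genes(expr), model$genes)
    if (length(missing_genes)) {
      stop(
        "reaction ", rxns$id[i], " GPR uses gene(s) absent from the model: ",
        paste(missing_genes, collapse = ", ")
      )
    }
  }
  if (!is.na(model$objective_id) && !(model$objective_id %in% rxns$id)) {
    stop("objective reaction not in model: ", model$objective_id)
  }
  invisible(TRUE)
}

#' Stoichiometric matrix S of a model
#'
#' @param model a `metabolic_model`.
#' @return dense numeric matrix, metabolites x reactions, with dimnames.
#' @export
stoich_matrix <- function(model) {
  stopifnot(inherits(model, "metabolic_model"))
  mids <- model$metabolites$id
  rids <- model$reactions$id
  S <- matrix(0, nrow = length(mids), ncol = length(rids), dimnames = list(mids, rids))
  for (j in seq_along(rids)) {
    st <- model$reactions$stoichiometry[[j]]
    S[names(st), j] <- st
  }
  S
}

#' Which reactions are exchange (boundary) reactions?
#'
#' An exchange reaction touches exactly one metabolite; by the sign
#' convention used throughout, negative flux is uptake and positive flux is
#' secretion of that metabolite.
#'
#' @param model a `metabolic_model`.
#' @return logical vector along `model$reactions`.
#' @export
is_exchange <- function(model) {
  vapply(model$reactions$stoichiometry, function(st) length(st) == 1L, logical(1))
}

reaction_index <- function(model, reaction_id) {
  i <- match(reaction_id, model$reactions$id)
  if (is.na(i)) stop("reaction not in model: ", reaction_id)
  i
}

#' Set the flux bounds of one reaction
#'
#' @param model a `metabolic_model`.
#' @param reaction_id reaction to modify.
#' @param lb,ub new bounds; `NULL` leaves a bound unchanged.
#' @return the modified model.
#' @export
set_bounds <- function(model, reaction_id, lb = NULL, ub = NULL) {
  i <- reaction_index(model, reaction_id)
  if (!is.null(lb)) model$reactions$lb[i] <- lb
  if (!is.null(ub)) model$reactions$ub[i] <- ub
  if (model$reactions$lb[i] > model$reactions$ub[i]) {
    stop("set_bounds would leave lb > ub on ", reaction_id)
  }
  model
}

#' Carbon balance of every internal reaction
#'
#' Multiplies each reaction's stoichiometry by the per-metabolite carbon
#' counts (from the metabolite formulas) and sums. Exchange reactions and
#' biomass-type pseudo-reactions (subsystem `"Biomass"`) drain mass by
#' design and are reported as `NA`. Metabolites with unknown formula
#' propagate `NA`.
#'
#' @param model a `metabolic_model`.
#' @return named numeric vector, reaction id -> net carbon per unit flux
#'   (0 means elementally consistent for carbon).
#' @export
carbon_balance <- function(model) {
  carbons <- element_count(model$metabolites$formula)
  names(carbons) <- model$metabolites$id
  exch <- is_exchange(model)
  out <- vapply(seq_len(nrow(model$reactions)), function(j) {
    if (exch[j] || identical(model$reactions$subsystem[j], "Biomass")) {
      return(NA_real_)
    }
    st <- model$reactions$stoichiometry[[j]]
    sum(st * carbons[names(st)])
  }, numeric(1))
  names(out) <- model$reactions$id
  out
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", x$id, "\n", sep = "")
  cat(
    "  ", nrow(x$metabolites), " metabolites, ", nrow(x$reactions),
    " reactions (", sum(is_exchange(x)), " exchanges), ",
    length(x$genes), " genes\n",
    sep = ""
  )
  cat("  objective: ", if (is.na(x$objective_id)) "(unset)" else x$objective_id, "\n", sep = "")
  invisible(x)
}
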