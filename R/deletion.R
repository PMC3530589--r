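#' Simulate a single-gene deletion by GPR evaluation
#'
#' Returns a copy of the model in which every reaction whose GPR rule
#' evaluates to `FALSE` under "this gene absent, all other genes present"
#' has both flux bounds set to zero (no flux). Reactions with isozyme
#' (`or`) backup survive; reactions requiring the gene in a complex (`and`)
#' are disabled. All other reactions are untouched.
#'
#' @param model a `metabolic_model`.
#' @param gene_id gene to delete; must be in `model$genes` (an error lists
#'   near-miss ids otherwise).
#' @return the knockout model; `attr(, "disabled_reactions")` carries the
#'   ids of the reactions that were shut off.
#' @export
#' @examples
#' ko <- delete_gene(build_core_model(), "FUM1")
#' attr(ko, "disabled_reactions")
delete_gene <- function(model, gene_id) {
  stopifnot(inherits(model, "metabolic_model"), is.character(gene_id), length(gene_id) == 1)
  if (!(gene_id %in% model$genes)) {
    near <- utils::head(agrep(gene_id, model$genes, max.distance = 0.25, value = TRUE), 5)
    stop(
      "gene not in model: ", gene_id,
      if (length(near)) paste0(" (did you mean: ", paste(near, collapse = ", "), "?)") else ""
    )
  }
  assignment <- stats::setNames(FALSE, gene_id)
  disabled <- character(0)
  for (i in seq_len(nrow(model$reactions))) {
    expr <- parse_gpr(model$reactions$gpr[i])
    if (!gpr_eval(expr, assignment, default = TRUE)) {
      model$reactions$lb[i] <- 0
      model$reactions$ub[i] <- 0
      disabled <- c(disabled, model$reactions$id[i])
    }
  }
  attr(model, "disabled_reactions") <- disabled
  model
}

#' Growth/production phenotype of a single-gene knockout
#'
#' Runs FBA on the wild-type and the knockout model under the same
#' minimal-medium configuration, and resolves the knockout's product
#' secretion by flux variability at the growth optimum (fraction 1.0) --
#' the honest way to report a secretion rate where the optimum is
#' degenerate.
#'
#' @param model the wild-type `metabolic_model`.
#' @param config a [sim_config()].
#' @param gene_id gene to delete, or the sentinel `"none"` to evaluate the
#'   unmodified model (wild-type phenotype).
#' @param product_exchange_id exchange reaction of the product of interest
#'   (e.g. the fumarate exchange).
#' @return an object of class `deletion_result`: `gene_id`,
#'   `disabled_reaction_ids`, `growth_rate`, `wildtype_growth_rate`,
#'   `growth_ratio` (knockout / wild-type optimum; 0 when the wild-type
#'   optimum is 0), and `product_interval` (a `flux_interval`).
#' @export
simulate_deletion <- function(model, config = sim_config(), gene_id,
                              product_exchange_id) {
  validate_model(model)
  reaction_index(model, product_exchange_id)
  ko <- if (identical(gene_id, "none")) model else delete_gene(model, gene_id)
  disabled <- attr(ko, "disabled_reactions") %||% character(0)

  wt_state <- solve_fba(model, config)
  if (wt_state$status != "optimal") {
    stop("wild-type FBA failed: ", wt_state$status)
  }
  ko_state <- solve_fba(ko, config)
  if (ko_state$status != "optimal") {
    stop("knockout (", gene_id, ") FBA failed: ", ko_state$status)
  }
  product_interval <- flux_variability(ko, config, product_exchange_id,
    fraction_of_optimum = 1.0
  )
  ratio <- if (wt_state$objective_value > 0) {
    ko_state$objective_value / wt_state$objective_value
  } else {
    0
  }
  structure(
    list(
      gene_id = gene_id,
      disabled_reaction_ids = disabled,
      growth_rate = ko_state$objective_value,
      wildtype_growth_rate = wt_state$objective_value,
      growth_ratio = ratio,
      product_interval = product_interval,
      knockout_state = ko_state,
      wildtype_state = wt_state
    ),
    class = "deletion_result"
  )
}

#' @export
print.deletion_result <- function(x, ...) {
  cat("<deletion_result> gene: ", x$gene_id, "\n", sep = "")
  cat(
    "  disabled reactions: ",
    if (length(x$disabled_reaction_ids)) paste(x$disabled_reaction_ids, collapse = ", ") else "(none)",
    "\n",
    sep = ""
  )
  cat(
    "  growth: ", format(x$growth_rate, digits = 4), " vs wild-type ",
    format(x$wildtype_growth_rate, digits = 4),
    " (ratio ", format(x$growth_ratio, digits = 4), ")\n",
    sep = ""
  )
  iv <- x$product_interval
  cat(
    "  product ", iv$reaction_id, " at the knockout optimum: [",
    format(iv$min_flux, digits = 4), ", ", format(iv$max_flux, digits = 4), "]",
    " (midpoint ", format((iv$min_flux + iv$max_flux) / 2, digits = 4), ")\n",
    sep = ""
  )
  invisible(x)
}
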