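#' Read a metabolic model from SBML-FBC or COBRA-JSON
#'
#' Supports the two dialects genome-scale yeast models are distributed in:
#' SBML Level 3 with the FBC version 2 package (flux bounds as parameters,
#' gene products, an active objective) and COBRA-JSON (`metabolites` /
#' `reactions` / `genes` arrays with `lower_bound` / `upper_bound` keys).
#' Dialect `"auto"` decides by file extension (`.json` vs `.xml`/`.sbml`)
#' and falls back to content sniffing (`{` vs `<`).
#'
#' Compartment tags (including suffix conventions like `_c`/`_m`/`_e` in
#' metabolite ids) are preserved verbatim and never interpreted. Bounds are
#' kept exactly as the file states them; the conventional +/-1000 "infinite"
#' bound is not rewritten.
#'
#' @param path file to read.
#' @param dialect `"auto"` (default), `"cobra-json"` or `"sbml-fbc"`.
#' @return a validated [metabolic_model()].
#' @export
read_model <- function(path, dialect = c("auto", "cobra-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("model file does not exist: ", path)
  if (dialect == "auto") dialect <- sniff_dialect(path)
  switch(dialect,
    "cobra-json" = read_cobra_json(path),
    "sbml-fbc" = read_sbml_fbc(path)
  )
}

#' Write a metabolic model to SBML-FBC or COBRA-JSON
#'
#' The written file round-trips: [read_model()] on the output yields a model
#' with identical ids, stoichiometries and subsystems, bounds equal to within
#' 1e-9, and logically equivalent GPR rules.
#'
#' @param model a validated `metabolic_model`.
#' @param path output file path.
#' @param dialect `"cobra-json"` or `"sbml-fbc"`; `"auto"` picks by extension.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, dialect = c("auto", "cobra-json", "sbml-fbc")) {
  dialect <- match.arg(dialect)
  validate_model(model)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("xml", "sbml")) "sbml-fbc" else "cobra-json"
  }
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("cannot write model, directory does not exist: ", dir)
  switch(dialect,
    "cobra-json" = write_cobra_json(model, path),
    "sbml-fbc" = write_sbml_fbc(model, path)
  )
  invisible(path)
}

sniff_dialect <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") return("cobra-json")
  if (ext %in% c("xml", "sbml")) return("sbml-fbc")
  head <- readChar(path, nchars = 200, useBytes = TRUE)
  head <- sub("^[[:space:]]+", "", head)
  if (startsWith(head, "{")) return("cobra-json")
  if (startsWith(head, "<")) return("sbml-fbc")
  stop("cannot determine model dialect of ", path, "; pass dialect= explicitly")
}

## ---- COBRA-JSON ----------------------------------------------------------

read_cobra_json <- function(path) {
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = FALSE),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  for (key in c("metabolites", "reactions")) {
    if (is.null(doc[[key]])) stop("parse error in ", path, ": missing '", key, "' array")
  }
  mets <- data.frame(
    id = vapply(doc$metabolites, function(m) as.character(m$id), character(1)),
    name = vapply(doc$metabolites, function(m) as.character(m$name %||% m$id), character(1)),
    compartment = vapply(doc$metabolites, function(m) as.character(m$compartment %||% ""), character(1)),
    formula = vapply(doc$metabolites, function(m) {
      f <- m$formula
      if (is.null(f) || length(f) == 0) NA_character_ else as.character(f)
    }, character(1)),
    stringsAsFactors = FALSE
  )
  stoich <- lapply(doc$reactions, function(r) {
    st <- unlist(r$metabolites)
    if (is.null(st)) st <- numeric(0)
    storage.mode(st) <- "double"
    st
  })
  rxns <- data.frame(
    id = vapply(doc$reactions, function(r) as.character(r$id), character(1)),
    name = vapply(doc$reactions, function(r) as.character(r$name %||% r$id), character(1)),
    subsystem = vapply(doc$reactions, function(r) as.character(r$subsystem %||% ""), character(1)),
    lb = vapply(doc$reactions, function(r) as.numeric(r$lower_bound %||% -1000), numeric(1)),
    ub = vapply(doc$reactions, function(r) as.numeric(r$upper_bound %||% 1000), numeric(1)),
    gpr = vapply(doc$reactions, function(r) as.character(r$gene_reaction_rule %||% ""), character(1)),
    stringsAsFactors = FALSE
  )
  rxns$stoichiometry <- stoich
  genes <- vapply(doc$genes %||% list(), function(g) as.character(g$id), character(1))
  objc <- vapply(doc$reactions, function(r) as.numeric(r$objective_coefficient %||% 0), numeric(1))
  objective_id <- if (any(objc != 0)) rxns$id[which(objc != 0)[1]] else NA_character_
  metabolic_model(mets, rxns,
    genes = genes, objective_id = objective_id,
    id = as.character(doc$id %||% tools::file_path_sans_ext(basename(path)))
  )
}

write_cobra_json <- function(model, path) {
  mets <- lapply(seq_len(nrow(model$metabolites)), function(i) {
    m <- model$metabolites[i, ]
    out <- list(id = m$id, name = m$name, compartment = m$compartment)
    if (!is.na(m$formula)) out$formula <- m$formula
    out
  })
  rxns <- lapply(seq_len(nrow(model$reactions)), function(i) {
    r <- model$reactions[i, ]
    list(
      id = r$id,
      name = r$name,
      metabolites = as.list(r$stoichiometry[[1]]),
      lower_bound = r$lb,
      upper_bound = r$ub,
      gene_reaction_rule = r$gpr,
      subsystem = r$subsystem,
      objective_coefficient = if (!is.na(model$objective_id) && r$id == model$objective_id) 1 else 0
    )
  })
  genes <- lapply(model$genes, function(g) list(id = g, name = g))
  doc <- list(
    id = model$id,
    version = "1",
    metabolites = mets,
    reactions = rxns,
    genes = genes,
    compartments = as.list(stats::setNames(
      unique(model$metabolites$compartment),
      unique(model$metabolites$compartment)
    ))
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

## ---- SBML Level 3 + FBC v2 -----------------------------------------------

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sbml_sid <- function(x) gsub("[^A-Za-z0-9_]", "__", x)

or_na <- function(x, default) if (length(x) == 0 || is.na(x)) default else x

# attribute lookup ignoring namespace prefixes ("fbc:id" matches "id")
attr_any <- function(node, name) {
  a <- xml2::xml_attrs(node)
  hit <- which(sub("^[^:]+:", "", names(a)) == name)
  if (length(hit) == 0) NA_character_ else unname(a[hit[1]])
}

xfind <- function(node, ...) {
  parts <- vapply(list(...), function(p) sprintf("*[local-name()='%s']", p), character(1))
  xml2::xml_find_all(node, paste0(".//", paste(parts, collapse = "/")))
}

read_sbml_fbc <- function(path) {
  doc <- tryCatch(
    xml2::read_xml(path),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e), call. = FALSE)
  )
  mdl <- xml2::xml_find_first(doc, "//*[local-name()='model']")
  if (inherits(mdl, "xml_missing")) stop("parse error in ", path, ": no <model> element")

  strip_prefix <- function(id, prefix) {
    ifelse(startsWith(id, prefix), substring(id, nchar(prefix) + 1), id)
  }

  sp <- xfind(mdl, "listOfSpecies", "species")
  mets <- data.frame(
    id = strip_prefix(vapply(sp, function(s) attr_any(s, "id"), character(1)), "M_"),
    name = vapply(sp, function(s) {
      n <- attr_any(s, "name")
      if (is.na(n)) attr_any(s, "id") else n
    }, character(1)),
    compartment = vapply(sp, function(s) or_na(attr_any(s, "compartment"), ""), character(1)),
    formula = vapply(sp, function(s) attr_any(s, "chemicalFormula"), character(1)),
    stringsAsFactors = FALSE
  )

  params <- xfind(mdl, "listOfParameters", "parameter")
  pvals <- stats::setNames(
    vapply(params, function(p) as.numeric(attr_any(p, "value")), numeric(1)),
    vapply(params, function(p) attr_any(p, "id"), character(1))
  )

  gps <- xfind(mdl, "listOfGeneProducts", "geneProduct")
  gp_label <- stats::setNames(
    vapply(gps, function(g) {
      lab <- attr_any(g, "label")
      if (is.na(lab)) attr_any(g, "id") else lab
    }, character(1)),
    vapply(gps, function(g) attr_any(g, "id"), character(1))
  )

  parse_assoc <- function(node) {
    ln <- xml2::xml_name(node)
    if (ln == "geneProductRef") {
      gid <- attr_any(node, "geneProduct")
      lab <- if (gid %in% names(gp_label)) gp_label[[gid]] else strip_prefix(gid, "G_")
      return(structure(list(op = "gene", gene = lab), class = "gpr_expression"))
    }
    kids <- xml2::xml_children(node)
    args <- lapply(kids, parse_assoc)
    if (ln == "and") {
      return(structure(list(op = "and", args = args), class = "gpr_expression"))
    }
    if (ln == "or") {
      return(structure(list(op = "or", args = args), class = "gpr_expression"))
    }
    stop("unsupported geneProductAssociation node <", ln, ">")
  }

  rx <- xfind(mdl, "listOfReactions", "reaction")
  stoich <- vector("list", length(rx))
  gprs <- character(length(rx))
  subsys <- character(length(rx))
  lbs <- numeric(length(rx))
  ubs <- numeric(length(rx))
  rids <- character(length(rx))
  rnames <- character(length(rx))
  for (i in seq_along(rx)) {
    r <- rx[[i]]
    rid_raw <- attr_any(r, "id")
    rids[i] <- strip_prefix(rid_raw, "R_")
    nm <- attr_any(r, "name")
    rnames[i] <- if (is.na(nm)) rids[i] else nm
    st <- numeric(0)
    for (sref in xfind(r, "listOfReactants", "speciesReference")) {
      mid <- strip_prefix(attr_any(sref, "species"), "M_")
      coef <- as.numeric(or_na(attr_any(sref, "stoichiometry"), "1"))
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) - coef
    }
    for (sref in xfind(r, "listOfProducts", "speciesReference")) {
      mid <- strip_prefix(attr_any(sref, "species"), "M_")
      coef <- as.numeric(or_na(attr_any(sref, "stoichiometry"), "1"))
      st[mid] <- (if (mid %in% names(st)) st[[mid]] else 0) + coef
    }
    stoich[[i]] <- st
    lbp <- attr_any(r, "lowerFluxBound")
    ubp <- attr_any(r, "upperFluxBound")
    if (is.na(lbp) || is.na(ubp) || !(lbp %in% names(pvals)) || !(ubp %in% names(pvals))) {
      stop("reaction ", rid_raw, " in ", path, " lacks resolvable FBC flux bounds")
    }
    lbs[i] <- pvals[[lbp]]
    ubs[i] <- pvals[[ubp]]
    assoc <- xml2::xml_find_first(r, "./*[local-name()='geneProductAssociation']")
    gprs[i] <- if (inherits(assoc, "xml_missing")) {
      ""
    } else {
      tryCatch(
        gpr_to_string(parse_assoc(xml2::xml_child(assoc))),
        error = function(e) {
          stop("GPR error in reaction ", rid_raw, ": ", conditionMessage(e), call. = FALSE)
        }
      )
    }
    note_p <- xml2::xml_find_all(r, ".//*[local-name()='notes']//*[local-name()='p']")
    subsys[i] <- ""
    for (p in note_p) {
      txt <- xml2::xml_text(p)
      if (grepl("^\\s*SUBSYSTEM:", txt)) {
        subsys[i] <- trimws(sub("^\\s*SUBSYSTEM:", "", txt))
      }
    }
  }
  rxns <- data.frame(
    id = rids, name = rnames, subsystem = subsys,
    lb = lbs, ub = ubs, gpr = gprs, stringsAsFactors = FALSE
  )
  rxns$stoichiometry <- stoich

  objective_id <- NA_character_
  objs <- xml2::xml_find_first(mdl, ".//*[local-name()='listOfObjectives']")
  if (!inherits(objs, "xml_missing")) {
    active <- attr_any(objs, "activeObjective")
    for (ob in xml2::xml_find_all(objs, "./*[local-name()='objective']")) {
      if (is.na(active) || identical(attr_any(ob, "id"), active)) {
        fo <- xml2::xml_find_first(ob, ".//*[local-name()='fluxObjective']")
        if (!inherits(fo, "xml_missing")) {
          objective_id <- strip_prefix(attr_any(fo, "reaction"), "R_")
          break
        }
      }
    }
  }

  genes <- unname(gp_label)
  if (length(genes) == 0) {
    genes <- NULL # derive from GPRs
  }
  metabolic_model(mets, rxns,
    genes = genes, objective_id = objective_id,
    id = or_na(attr_any(mdl, "id"), tools::file_path_sans_ext(basename(path)))
  )
}

write_sbml_fbc <- function(model, path) {
  doc <- xml2::xml_new_root("sbml",
    xmlns = SBML_CORE_NS, "xmlns:fbc" = SBML_FBC_NS,
    level = "3", version = "1", "fbc:required" = "false"
  )
  mdl <- xml2::xml_add_child(doc, "model",
    id = sbml_sid(model$id), "fbc:strict" = "true"
  )

  comps <- unique(model$metabolites$compartment)
  lc <- xml2::xml_add_child(mdl, "listOfCompartments")
  for (cp in comps) {
    xml2::xml_add_child(lc, "compartment", id = sbml_sid(cp), constant = "true")
  }

  ls <- xml2::xml_add_child(mdl, "listOfSpecies")
  for (i in seq_len(nrow(model$metabolites))) {
    m <- model$metabolites[i, ]
    sp <- xml2::xml_add_child(ls, "species",
      id = paste0("M_", sbml_sid(m$id)), name = m$name,
      compartment = sbml_sid(m$compartment),
      hasOnlySubstanceUnits = "false", boundaryCondition = "false",
      constant = "false"
    )
    if (!is.na(m$formula)) xml2::xml_set_attr(sp, "fbc:chemicalFormula", m$formula)
  }

  # one shared parameter per distinct bound value
  bound_vals <- sort(unique(c(model$reactions$lb, model$reactions$ub)))
  bkey <- vapply(bound_vals, function(v) format(v, digits = 17), character(1))
  bound_ids <- stats::setNames(sprintf("fs_bnd_%d", seq_along(bound_vals)), bkey)
  lp <- xml2::xml_add_child(mdl, "listOfParameters")
  for (i in seq_along(bound_vals)) {
    xml2::xml_add_child(lp, "parameter",
      id = bound_ids[[i]],
      value = bkey[i], constant = "true",
      sboTerm = "SBO:0000626"
    )
  }

  if (length(model$genes)) {
    lg <- xml2::xml_add_child(mdl, "fbc:listOfGeneProducts")
    for (g in model$genes) {
      xml2::xml_add_child(lg, "fbc:geneProduct",
        "fbc:id" = paste0("G_", sbml_sid(g)), "fbc:label" = g
      )
    }
  }

  if (!is.na(model$objective_id)) {
    lo <- xml2::xml_add_child(mdl, "fbc:listOfObjectives", "fbc:activeObjective" = "obj")
    ob <- xml2::xml_add_child(lo, "fbc:objective", "fbc:id" = "obj", "fbc:type" = "maximize")
    lfo <- xml2::xml_add_child(ob, "fbc:listOfFluxObjectives")
    xml2::xml_add_child(lfo, "fbc:fluxObjective",
      "fbc:reaction" = paste0("R_", sbml_sid(model$objective_id)),
      "fbc:coefficient" = "1"
    )
  }

  add_assoc <- function(parent, expr) {
    if (expr$op == "gene") {
      xml2::xml_add_child(parent, "fbc:geneProductRef",
        "fbc:geneProduct" = paste0("G_", sbml_sid(expr$gene))
      )
    } else if (expr$op %in% c("and", "or")) {
      node <- xml2::xml_add_child(parent, paste0("fbc:", expr$op))
      for (a in expr$args) add_assoc(node, a)
    }
  }

  lr <- xml2::xml_add_child(mdl, "listOfReactions")
  for (i in seq_len(nrow(model$reactions))) {
    r <- model$reactions[i, ]
    rn <- xml2::xml_add_child(lr, "reaction",
      id = paste0("R_", sbml_sid(r$id)), name = r$name,
      reversible = if (r$lb < 0) "true" else "false", fast = "false",
      "fbc:lowerFluxBound" = bound_ids[[format(r$lb, digits = 17)]],
      "fbc:upperFluxBound" = bound_ids[[format(r$ub, digits = 17)]]
    )
    if (nzchar(r$subsystem)) {
      notes <- xml2::xml_add_child(rn, "notes")
      body <- xml2::xml_add_child(notes, "body", xmlns = "http://www.w3.org/1999/xhtml")
      p <- xml2::xml_add_child(body, "p")
      xml2::xml_set_text(p, paste0("SUBSYSTEM: ", r$subsystem))
    }
    st <- r$stoichiometry[[1]]
    reac <- st[st < 0]
    prod <- st[st > 0]
    if (length(reac)) {
      lre <- xml2::xml_add_child(rn, "listOfReactants")
      for (mid in names(reac)) {
        xml2::xml_add_child(lre, "speciesReference",
          species = paste0("M_", sbml_sid(mid)),
          stoichiometry = format(-reac[[mid]], digits = 17), constant = "true"
        )
      }
    }
    if (length(prod)) {
      lpr <- xml2::xml_add_child(rn, "listOfProducts")
      for (mid in names(prod)) {
        xml2::xml_add_child(lpr, "speciesReference",
          species = paste0("M_", sbml_sid(mid)),
          stoichiometry = format(prod[[mid]], digits = 17), constant = "true"
        )
      }
    }
    expr <- parse_gpr(r$gpr)
    if (expr$op != "true") {
      assoc <- xml2::xml_add_child(rn, "fbc:geneProductAssociation")
      add_assoc(assoc, expr)
    }
  }

  xml2::write_xml(doc, path)
}
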