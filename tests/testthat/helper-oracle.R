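# Cross-language oracle: evaluate FBA/FVA requests with cobrapy + GLPK.
# Each request is list(model = <metabolic_model>, op = "fba"|"fva", and for
# fva: reaction =, fraction =; objective = optional). Models are passed
# through write_model(), so this also exercises the COBRA-JSON writer.
cobra_oracle <- function(requests) {
  reqs <- lapply(requests, function(r) {
    if (!is.null(r$model)) {
      stopifnot(inherits(r$model, "metabolic_model"))
      p <- tempfile(fileext = ".json")
      write_model(r$model, p, dialect = "cobra-json")
      r$model <- NULL
      r$path <- p
    }
    r
  })
  inp <- tempfile(fileext = ".json")
  outp <- tempfile(fileext = ".json")
  jsonlite::write_json(reqs, inp, auto_unbox = TRUE, digits = NA)
  status <- system2("python",
    c(testthat::test_path("oracle.py"), inp, outp),
    stdout = FALSE, stderr = ""
  )
  if (!identical(status, 0L)) {
    stop("cobrapy oracle failed with exit status ", status)
  }
  jsonlite::fromJSON(outp, simplifyVector = FALSE)
}

# The conditioned (minimal-medium) model a given simulation would solve;
# lets the oracle see exactly the LP the package solves.
conditioned <- function(model, config = sim_config(), objective_id = NULL) {
  cm <- fluxscan:::fba_condition_model(model, config)
  if (!is.null(objective_id)) cm$objective_id <- objective_id
  cm
}

# Independent brute-force GPR evaluator: rewrites the rule into an R
# logical expression and evaluates it directly, with no shared code with
# parse_gpr(). Gene ids must be syntactic R names (the tests ensure this).
brute_gpr_eval <- function(rule, assignment) {
  if (!nzchar(trimws(rule))) {
    return(TRUE)
  }
  txt <- gsub("\\bor\\b", "||", gsub("\\band\\b", "&&", rule, ignore.case = TRUE),
    ignore.case = TRUE
  )
  eval(parse(text = txt), envir = as.list(assignment))
}

# Reproducible random GPR rule over the given gene names.
random_gpr_rule <- function(genes, depth = 3) {
  build <- function(d) {
    if (d == 0 || stats::runif(1) < 0.35) {
      return(sample(genes, 1))
    }
    op <- sample(c("and", "or"), 1)
    n <- sample(2:3, 1)
    args <- vapply(seq_len(n), function(i) build(d - 1), character(1))
    paste0("(", paste(args, collapse = paste0(" ", op, " ")), ")")
  }
  build(depth)
}
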