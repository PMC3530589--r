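#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers stating which gene
#' combinations sustain a reaction: isozymes combine with `or`, enzyme
#' complexes with `and`. The grammar is the common COBRA one: identifiers,
#' `and`, `or` (case-insensitive; `&`/`|` accepted as synonyms) and
#' parentheses, with `and` binding tighter than `or`.
#'
#' An empty or blank rule parses to the trivial expression that evaluates
#' `TRUE` under any assignment: the reaction is not gene-associated and no
#' deletion can disable it.
#'
#' @param rule a single GPR string, e.g. `"YPL262W"` or `"A and (B or C)"`.
#' @return an object of class `gpr_expression`: a tree of nodes with
#'   `op` one of `"and"`, `"or"`, `"gene"`, `"true"`.
#' @export
#' @examples
#' e <- parse_gpr("A and (B or C)")
#' gpr_eval(e, c(A = TRUE, B = FALSE, C = TRUE))
parse_gpr <- function(rule) {
  if (is.null(rule) || length(rule) == 0 || is.na(rule) || !nzchar(trimws(rule))) {
    return(structure(list(op = "true"), class = "gpr_expression"))
  }
  stopifnot(is.character(rule), length(rule) == 1)
  toks <- regmatches(rule, gregexpr("\\(|\\)|&&?|\\|\\|?|[^()&|[:space:]]+", rule))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() {
    tk <- peek()
    pos <<- pos + 1L
    tk
  }
  fail <- function(msg) stop("GPR syntax error in rule '", rule, "': ", msg, call. = FALSE)
  is_and <- function(tk) !is.na(tk) && (tolower(tk) == "and" || tk %in% c("&", "&&"))
  is_or <- function(tk) !is.na(tk) && (tolower(tk) == "or" || tk %in% c("|", "||"))

  parse_or <- function() {
    left <- parse_and()
    args <- list(left)
    while (is_or(peek())) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1) args[[1]] else structure(list(op = "or", args = args), class = "gpr_expression")
  }
  parse_and <- function() {
    left <- parse_atom()
    args <- list(left)
    while (is_and(peek())) {
      advance()
      args <- c(args, list(parse_atom()))
    }
    if (length(args) == 1) args[[1]] else structure(list(op = "and", args = args), class = "gpr_expression")
  }
  parse_atom <- function() {
    tk <- peek()
    if (is.na(tk)) fail("unexpected end of rule (dangling operator?)")
    if (tk == "(") {
      advance()
      inner <- parse_or()
      if (is.na(peek()) || peek() != ")") fail("unbalanced parentheses")
      advance()
      return(inner)
    }
    if (tk == ")" || is_and(tk) || is_or(tk)) fail(paste0("unexpected token '", tk, "'"))
    advance()
    structure(list(op = "gene", gene = tk), class = "gpr_expression")
  }

  out <- parse_or()
  if (!is.na(peek())) fail(paste0("trailing token '", peek(), "'"))
  out
}

#' Evaluate a GPR expression against a gene activity assignment
#'
#' @param expr a `gpr_expression` from [parse_gpr()].
#' @param assignment named logical vector, gene id -> active?
#' @param default activity assumed for genes absent from `assignment`
#'   (default `TRUE`: genes not under study are considered present).
#' @return logical scalar: can the reaction carry flux?
#' @export
gpr_eval <- function(expr, assignment = logical(0), default = TRUE) {
  stopifnot(inherits(expr, "gpr_expression"))
  rec <- function(e) {
    switch(e$op,
      "true" = TRUE,
      "gene" = {
        v <- assignment[e$gene]
        if (length(v) == 0 || is.na(v)) default else unname(v)
      },
      "and" = all(vapply(e$args, rec, logical(1))),
      "or" = any(vapply(e$args, rec, logical(1))),
      stop("corrupt GPR expression node: ", e$op)
    )
  }
  rec(expr)
}

#' List the gene ids appearing in a GPR expression
#'
#' @param expr a `gpr_expression`.
#' @return character vector of unique gene ids (empty for the trivial rule).
#' @export
gpr_genes <- function(expr) {
  stopifnot(inherits(expr, "gpr_expression"))
  rec <- function(e) {
    switch(e$op,
      "true" = character(0),
      "gene" = e$gene,
      unlist(lapply(e$args, rec))
    )
  }
  unique(rec(expr))
}

#' Render a GPR expression back to rule-string form
#'
#' Produces the canonical `and`/`or`/parenthesis form understood by
#' [parse_gpr()] and by COBRA-dialect files.
#'
#' @param expr a `gpr_expression`.
#' @return a single string; `""` for the trivial rule.
#' @export
gpr_to_string <- function(expr) {
  stopifnot(inherits(expr, "gpr_expression"))
  rec <- function(e, parent_op) {
    switch(e$op,
      "true" = "",
      "gene" = e$gene,
      {
        s <- paste(vapply(e$args, rec, character(1), parent_op = e$op),
          collapse = paste0(" ", e$op, " ")
        )
        # parenthesize an 'or' nested under an 'and' to keep precedence
        if (e$op == "or" && identical(parent_op, "and")) paste0("(", s, ")") else s
      }
    )
  }
  rec(expr, NA_character_)
}

#' @export
print.gpr_expression <- function(x, ...) {
  s <- gpr_to_string(x)
  cat("<GPR> ", if (nzchar(s)) s else "(always active)", "\n", sep = "")
  invisible(x)
}
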