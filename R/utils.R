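`%||%` <- function(x, y) if (is.null(x)) y else x

#' Count atoms of one element in a chemical formula
#'
#' Parses a Hill-style formula string (e.g. `"C6H12O6"`) into element counts
#' and returns the count for one element. Pseudo-formulas used for
#' carbon-free carrier metabolites (e.g. `"R"`, `"X"`) simply contain no `C`
#' token and return 0. An empty or `NA` formula returns `NA_real_` (unknown
#' composition), which callers must treat as "composition unknown", not zero.
#'
#' @param formula character vector of formula strings.
#' @param element element symbol, default `"C"`.
#' @return numeric vector of atom counts (`NA` where the formula is unknown).
#' @export
#' @examples
#' element_count(c("C6H12O6", "CO2", "O2", "R"))
element_count <- function(formula, element = "C") {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    if (m[1] == -1) return(0)
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    total <- 0
    for (tk in toks) {
      sym <- sub("[0-9]*$", "", tk)
      if (sym == element) {
        num <- sub("^[A-Za-z]+", "", tk)
        total <- total + if (nzchar(num)) as.numeric(num) else 1
      }
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}
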