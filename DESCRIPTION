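Package: fluxscan
Title: Constraint-Based Strain Design for Fumarate Overproduction in Yeast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flux balance analysis (FBA) tools for in silico metabolic
    engineering of Saccharomyces cerevisiae towards fumaric acid secretion.
    Reads and writes metabolic models in SBML Level-3 FBC and COBRA-JSON
    dialects, simulates single-gene deletions through gene-protein-reaction
    (GPR) rule evaluation, resolves degenerate optima by flux variability
    analysis, sweeps substrate uptake against growth (robustness analysis),
    and nominates overexpression candidates by scanning enforced
    product-secretion levels and classifying each reaction's flux trajectory
    (FSEOF-style). Ships a deterministic yeast-core model generator with
    analytically known optima so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    xml2,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr
Config/testthat/edition: 3
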