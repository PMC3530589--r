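---
title: "Constraint-based strain design for fumarate overproduction in yeast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based strain design for fumarate overproduction in yeast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxscan)
```

## The model and its assumptions

Flux balance analysis (FBA) treats a metabolic network as a linear program:
find a flux vector $v$ maximizing an objective $c^\top v$ subject to the
steady-state constraint $S v = 0$ (with $S$ the stoichiometric matrix) and
per-reaction bounds $l \le v \le u$. The biomass pseudo-reaction drains
precursors in growth proportions, so its flux is the predicted specific
growth rate $\mu$ (h$^{-1}$); every other flux is in mmol gDCW$^{-1}$
h$^{-1}$. Exchange reactions follow the sign convention negative = uptake,
positive = secretion.

`fluxscan` chains four constraint-based analyses into one strain-design
workflow for fumaric-acid (FA) production in *Saccharomyces cerevisiae*:

1. **Single-gene deletion** (`delete_gene()`, `simulate_deletion()`): a
   knockout disables exactly the reactions whose gene–protein–reaction
   (GPR) boolean rule evaluates false with the gene absent and all others
   present — isozymes (`or`) survive, complexes (`and`) fail — by zeroing
   both flux bounds, then re-optimizing growth.
2. **Degenerate-optimum resolution** (`flux_variability()`): FBA optima are
   generally non-unique, so any single-number secretion rate is a choice.
   The package reports the flux variability interval at fraction 1.0 of
   the optimum and uses its midpoint as the headline number; the interval
   itself is always available. For the fumarase knockout the interval is
   pinched (secretion is stoichiometrically forced), so the policy choice
   is immaterial there — but it is stated, because published single
   numbers rarely say how uniqueness was obtained.
3. **Robustness analysis** (`robustness_scan()`): the glucose uptake rate
   is fixed point-by-point and growth re-optimized, giving the
   uptake-vs-growth curves whose ordering (knockout at or below wild type
   everywhere) is the visual signature of a "benign" deletion.
4. **Enforced-production scan** (`enforced_production_scan()`, an
   FSEOF-style procedure): on the knockout model, the product exchange is
   clamped (both bounds) to each of a grid of secretion levels from a
   control level up to the theoretical maximum, growth is re-optimized,
   and each reaction's flux trajectory is classified as `increased`,
   `decreased` or `irregular`. Reactions whose growth-optimal flux rises
   with forced production are overexpression candidates, ranked by the
   endpoint fold `|flux at max| / |flux at control|` (`rank_targets()`).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `substrate_uptake` | 10 | mmol gDCW$^{-1}$ h$^{-1}$ | standard aerobic glucose-limited setting for yeast genome-scale simulations |
| `oxygen_policy` | `"unbounded-uptake"` | — | aerobic batch culture; the O2 bound is rarely stated in publications, so it is explicit and echoed in the run manifest |
| `control_level` | 0.4 | mmol gDCW$^{-1}$ h$^{-1}$ | first enforced FA level; sits just above the knockout's natural secretion rate, which makes growth monotone along the scan |
| `steps` | 10 | — | enforcement grid; trajectories here are piecewise linear, so 10 levels resolves them comfortably |
| `classification_tolerance` | 0.01 | relative | absorbs solver noise without masking few-percent flux changes |
| `atp_maintenance` | 0 | mmol gDCW$^{-1}$ h$^{-1}$ | the reductive FA route is energetically neutral, so any forced ATP drain would cut its theoretical yield below 2 mol/mol |

Design choices that were genuinely open, and how they were settled:

* **Enforcement by equality.** The scan clamps the product flux with both
  bounds rather than a lower bound only; "production successively
  increased" describes controlled levels, and equality makes the
  clamp-fidelity invariant exact.
* **Fold = endpoint ratio.** A fold per reaction needs one scalar; the
  endpoint ratio is the only definition consistent with that. The full
  trajectory is kept in the output so any alternative (slope, regression)
  can be recomputed.
* **Monotonicity of growth in the enforced level.** Tightening a binding
  constraint cannot improve an optimum — *provided the clamp sits at or
  above the knockout's natural secretion rate*. Below it, the equality
  clamp binds from above and growth *rises* toward the unconstrained
  optimum. The default control level is chosen above the natural rate;
  scans started below it are legal (and tested for feasibility and clamp
  fidelity) but their growth profile is expected to be unimodal, not
  monotone.
* **Gene naming.** The fumarase gene is `FUM1` (systematic locus
  `YPL262W`); genome-scale files key genes by locus, the core model by
  standard name. Functions take whichever id the model uses.

## The synthetic core model

`build_core_model()` emits a deterministic ~40-reaction central-carbon
model of yeast: stepwise glycolysis (ENO, GAPD, PGK, PGM, PYK, TPI, …), a
lumped oxidative pentose-phosphate reaction (the sole NADPH source),
pyruvate decarboxylase/alcohol dehydrogenase, mitochondrial pyruvate
oxidation, an oxidative TCA cycle with aconitase and a `FUM1`-associated
fumarase, the reductive anaplerotic branch — pyruvate carboxylase (PC),
cytosolic malate dehydrogenase, reversible cytosolic fumarase — fixing
CO2, lumped oxidative phosphorylation at P/O = 2, exchanges for
glucose/O2/CO2/ethanol/fumarate, and a biomass pseudo-reaction draining
pyruvate, oxaloacetate, ATP and NADPH in 3 : 1 : 12 : 4 proportions
(scaled ×10 so optima land in a realistic growth range).

The point of the generator is that every pipeline stage has an
analytically known answer. With glucose uptake $g$ and growth $B$
(in the unscaled 3 : 1 : 12 : 4 units), NADPH demand pins the PPP flux,
carbon balance pins glycolytic flux, and the ATP balance closes the
system. At $g = 10$:

* wild type: $\mu^\* = 280/66.33 \cdot g/100 = 0.42211$ h$^{-1}$, with a
  small TCA flux ($T = 0.299$) burning the carbon left over from precursor
  demand;
* `FUM1` knockout: the TCA cycle cannot regenerate oxaloacetate past
  fumarate, so every respiratory turn ends in one secreted fumarate and
  one pyruvate-carboxylase-supplied oxaloacetate. Solving the coupled
  pyruvate/ATP balances gives $\mu = 0.41585$ h$^{-1}$ (1.49% below wild
  type) and a *forced* secretion of 0.297 mmol gDCW$^{-1}$ h$^{-1}$ — the
  flux-variability interval at the optimum is pinched at that value,
  while the wild-type interval is pinched at zero;
* reductive yield: glucose → 2 pyruvate → (PC, +2 CO2) → 2 oxaloacetate →
  2 malate → 2 fumarate balances ATP (+2 glycolysis, −2 PC) and NADH
  (+2 glycolysis, −2 malate dehydrogenase) exactly, so the maximum yield
  is exactly 2 mol FA per mol glucose — an LP vertex with small rational
  coordinates, reproduced by the solver to machine precision;
* with the reductive branch removed and fumarase forced
  fumarate → malate, the only oxaloacetate source sits downstream of
  fumarase, so sustained FA export is exactly 0.

All of these numbers are asserted in the test suite, and the FBA/FVA
optima are cross-checked against an independent constraint-based
implementation (cobrapy with GLPK) on the canonical model and on twenty
seeded bound-jittered variants (`make_variant()`).

What the toy does *not* emulate: compartmented cofactor pools (ATP/NADH
are shared across cytosol and mitochondrion), FAD-linked succinate
dehydrogenase (lumped to NAD), proton/charge balancing, a realistic
biomass composition, and alternative fumarate sinks or shuttles present
in genome-scale models. Consequently the knockout's quantitative growth
deficit and secretion rate are designed to be *qualitatively* comparable
to genome-scale predictions (a few percent; a few tenths of a unit), and
passing the toy-based tests validates the algorithms, not any particular
genome-scale number. One visible artifact: because one lumped PPP
reaction carries the whole NADPH demand, the hexose isomerase (PGI)
baseline flux is small at the control level, which inflates its endpoint
fold in the scan; fold rankings are therefore read within the classical
amplification panel (lower glycolysis + anaplerosis), where PC leads by a
wide margin.

## Numerical choices

The LP engine is a dense, two-phase, bounded-variable primal simplex
(`R/lp.R`) with Dantzig pricing and a Bland-rule fallback that guarantees
termination under degeneracy; the basis is refactorized every iteration,
which is robust and ample at core-model scale. Nonbasic variables sit at
finite bounds (true infinities are clamped to ±10^6; model files use the
±1000 convention anyway), so phase 2 cannot be unbounded. Reduced-cost
and pivot tolerances are 10^-9-scale; feasibility of a reported optimum
is checked in the tests as $\lVert S v\rVert_\infty \le 10^{-6}$.
Flux-variability subproblems re-solve with the objective's lower bound
set to the optimum minus a 10^-9-relative slack; this slack is why a
"pinned" interval can show widths of order 10^-8. Infeasible robustness
grid points are recorded as objective 0 with a flag rather than dropped,
so profiles keep their grid. Ties in `rank_targets()` break
alphabetically; undefined folds (zero control flux) rank after defined
ones, by absolute change.

Problem sizes throughout the examples and tests — a ~40-reaction model,
10-21 grid points, full-table FVA at 10 levels — were chosen so that
every stage, including the all-reaction scan, completes in seconds on a
single CPU.

## The worked pipeline

```{r pipeline, eval = FALSE}
dir <- tempdir()
write_model(build_core_model(), file.path(dir, "core.json"))
cfg <- pipeline_config(
  model_path = file.path(dir, "core.json"),
  output_dir = file.path(dir, "out"),
  deletion_gene = "FUM1",
  product_exchange_id = "EX_fum_e"
)
paths <- run_pipeline(cfg)
```

This writes `fba.tsv` (wild-type vs knockout fluxes, also normalized to a
glucose uptake of 100 — a pure output transform), `robustness.tsv` and its
plot, `scan.tsv`, `targets.tsv`, and `manifest.json` (model checksum,
configuration echo, solver and tolerance — enough to re-run the pipeline
bit-identically).

## Known limitations

* Only single-gene deletions; no combinatorial knockout search and no
  MOMA/ROOM-style quadratic reoptimization.
* The simplex is dense: fine for core-scale models, not tuned for
  genome-scale FVA (a genome-scale run works but is slow; the published
  genome-scale reproduction targets are wired into the acceptance tests
  and activate when an iND750 file is supplied).
* SBML support covers Level 3 + FBC v2 as used by constraint-based model
  distributions; kinetic SBML Level 2 models are out of scope.
* Transporter engineering (the succinate–fumarate carrier step that
  follows target amplification in practice) is an experimental follow-up,
  not something FBA models here.
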