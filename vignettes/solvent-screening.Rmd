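---
title: "Screening green solvents for seed-oil extraction: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening green solvents for seed-oil extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvscreen)
library(dplyr)
```

Replacing petroleum-derived *n*-hexane in edible-oil extraction is one of the
standing problems of green chemistry: candidate bio-based solvents
(2-methyltetrahydrofuran, cyclopentyl methyl ether, terpenes, ethanol) must
dissolve the oil's major lipids at least as well as hexane before any
wet-lab work is worth doing. `solvscreen` implements the computational side
of that decision: Hansen-solubility-parameter (HSP) affinity scoring,
inverse estimation of solute solubility spheres, COSMO-RS-style relative
solubility ranking, oil-quality composition indices, and a report that
quantifies how well the in-silico ranking agrees with experimental
extraction outcomes. This vignette explains each model, its assumptions,
the tunable parameters and the design decisions taken where the problem is
genuinely open.

## The Hansen solubility model

Every liquid is summarized by three cohesive-energy-density components, in
MPa^1/2^: dispersion (`delta_d`), polar (`delta_p`) and hydrogen bonding
(`delta_h`). Their Euclidean norm is the total (Hildebrand) parameter,
`hsp_total()`. Affinity between a solute and a solvent is the anisotropic
distance in this space,

$$R_{solv} = \sqrt{4(\delta_{d,u}-\delta_{d,v})^2 + (\delta_{p,u}-\delta_{p,v})^2 + (\delta_{h,u}-\delta_{h,v})^2},$$

where the conventional factor 4 reflects the empirically narrower tolerance
of solubility to dispersion mismatch. A solute carries a *Hansen sphere*: a
center in HSP space plus an interaction radius $R_{spher}$. The relative
energy difference

$$\mathrm{RED} = R_{solv} / R_{spher}$$

is dimensionless; RED < 1 places the solvent inside the sphere and predicts
dissolution. Conventions fixed in this package:

* **Boundary**: RED exactly 1 is classified *unsuitable* — the suitable
  class is defined strictly as RED < 1, so the boundary goes to the
  complementary class.
* **Units**: MPa^1/2^ throughout; no conversion layer. Components equal to
  (or near) zero are legal — *n*-hexane's polar and hydrogen-bonding
  parameters are 0.1.
* **Ranking ties** are broken by solvent input order, so screening output is
  reproducible without hidden randomness.
* **Display** follows the 2-decimal precision of published RED tables;
  internal computation is full precision.

`screen_solvents()` evaluates the full solute-by-solvent grid and returns a
tidy tibble (value, suitability label, within-solute rank). When only a
published RED table is available — without the spheres that generated it —
`as_red_screen()` classifies and ranks it directly.

## Inverse sphere estimation

Published screening tables often print RED values but not the solute
spheres behind them. `fit_hansen_sphere()` recovers a sphere (4 parameters)
from one RED row over solvents with known HSPs by minimizing
$\sum_j (\mathrm{RED}_{pred,j} - \mathrm{RED}_{obs,j})^2$.

The problem is deliberately fitted inside a box —
`delta_d` in [10, 25], `delta_p` in [0, 20], `delta_h` in [0, 25],
`r_spher` in [0.5, 25] MPa^1/2^ — because the objective has a scale
degeneracy: a center drifting far from all solvents with a proportionally
huge radius reproduces almost any smooth RED row. The box brackets the HSP
region of lipid-relevant solutes and common extraction solvents with
margin. The objective is also non-convex in the center/radius trade-off, so
the bounded Levenberg–Marquardt optimizer is restarted from 16 points of a
4-dimensional Halton sequence spread over the box (deterministic, so fits
are bit-reproducible); the best terminal objective wins. With at least 5
solvents in general position a noise-free row is recovered exactly
(objective below 1e-10); fewer than 5 solvents, or coincident solvent
HSPs, raise explicit errors.

Two diagnostics accompany every fit: per-solvent signed residuals and their
RMS (`augment()`, `glance()`), and `loo_predict_red()`, which refits with
one solvent held out and predicts its RED — a self-consistency check of a
published row. `grid_fit_sphere()` provides an independent derivative-free
reference: an exhaustive 0.25-step grid over the center box with the radius
profiled out analytically (for a fixed center the optimal inverse radius is
$\sum d_j \cdot \mathrm{RED}_{obs,j} / \sum d_j^2$, clamped to the radius
bounds). The test suite requires the optimizer never to return a worse
objective than this reference.

Fitting the packaged sesame RED rows is reported as a diagnostic, not
asserted against truth: the original spheres came from proprietary
group-contribution software and were never printed, and whether each row
used an independently estimated radius is unknowable from the table alone
(the fit treats `r_spher` as free per solute). Residual RMS on the order of
0.1 RED units is typical for those rows.

## Relative solubility

The second screening route consumes chemical potentials (typically from
COSMO-RS calculations, which are upstream of this package):

$$\log_{10} x_j = \frac{\mu_j^{pure} - \mu_j^{solvent} - \Delta G_{j,fusion}}{R\,T\,\ln 10},$$

with $R = 8.314$ J/(mol·K). The composition "log10 of exp of an
energy/RT" that appears in thermodynamics texts is read as converting the
natural-log-scale quantity to base 10 — dividing by $RT \ln 10$ — which is
the standard relative-solubility expression and the only dimensionally
coherent reading. Defaults: temperature 298.15 K, fusion term 0 (liquid
solute at working temperature); both are per-record overridable.

Because only *relative* solubility is meaningful at infinite dilution, each
solute row is normalized by `normalize_best_to_zero()` (subtract the row
maximum; idempotent, order-preserving) and ranked by
`rank_relative_solubility()`, where every solvent at 0 shares the top rank
band. A row whose maximum is not 0 (beyond 1e-9) is rejected as
unnormalized rather than silently re-normalized. The packaged reference
matrix is carried as data — the quantum chemistry that produced it is
explicitly out of scope.

## Oil-quality analytics

Fatty acids are classified purely by their `Cx:y` code — `y = 0` saturated,
`y = 1` monounsaturated, `y >= 2` polyunsaturated — never by trivial name
(an optional code-to-name lookup ships separately, because prose around
published tables occasionally swaps names while the codes stay correct).
`fatty_acid_class_sums()` returns the three class totals and the PUFA/SFA
ratio; because classes partition the acid list, SFA + MUFA + PUFA equals
the table total exactly.

Two tolerance decisions matter when validating published composition
tables:

* A sample's fatty-acid total is accepted within **100 ± 3** percentage
  points (`validate_fatty_acid_profile()`): published columns rarely close
  on 100 exactly because of rounding and minor unreported peaks. Violations
  are reported, not fatal.
* Printed "Total" rows of sterol/tocopherol tables are treated as
  *annotations*, checked against the recomputed component sum within
  **± 2 mg/100 g** (`component_totals()`). The recomputed value is always
  reported; disagreements beyond tolerance raise a classed warning and a
  flag, never a silent correction. The packaged sesame table contains three
  such internal inconsistencies (the *n*-hexane and ethanol sterol totals,
  and a CPME α-tocopherol entry incompatible with its own printed total),
  which the tests pin down as *expected* flags.

The packaged fatty-acid summary block itself contains arithmetic quirks
worth knowing about: one SFA total omits one of its own components, and
several printed PUFA/SFA ratios were truncated rather than rounded to two
decimals. The package computes full-precision sums and rounds half-up for
display; the acceptance tests assert exact agreement on every
arithmetically self-consistent printed cell and assert the known
discrepancies at their verified magnitudes.

`extraction_yield()` is the gravimetric definition: oil mass per 100 g dry
seeds.

## The screening report

`build_screening_report()` inner-joins four per-solvent tables (RED
screening, relative-solubility ranking, class summaries, bioactivity +
yields) by solvent name; fewer than 3 shared solvents is an error, and
unmatched names are listed in the result. Design choices:

* **Aggregation**: a solvent's single in-silico score is the mean RED
  across solutes by default; `median` and `worst` (max) are available
  because the aggregation is genuinely a modelling choice — global solvent
  rankings in the literature rarely state one.
* **Direction metadata**: IC50/EC50-type endpoints (lower = stronger) are
  correlated on their raw values with an explicit direction flag attached,
  so a negative coefficient against a beneficial component reads correctly
  instead of being silently sign-flipped.
* **Published coefficients** ship as reference metadata
  (`sesame_reported_correlations()`) and are compared informationally —
  the report prints the recomputed and reported values and their absolute
  difference. They are not test-asserted: recomputation from the published
  per-solvent means does not reproduce them, which is expected when the
  original analysis used replicate-level (unpublished) measurements.
* **No multiple-testing correction**: with six solvents this is a
  descriptive analysis; p-values are reported unadjusted and labelled as
  such. Both the solvent-mean mode (n = 6) and any replicate-level data a
  user supplies flow through the same interface.
* Rank agreement uses Spearman's rho with average-rank ties
  (`spearman_concordance()`), aligned by solvent name.

## Synthetic data: what it emulates and what it does not

Every pipeline input can be generated with known truth (`synth_spec()` and
the `gen_*` functions), which is how recovery and calibration are tested
without any external data:

* **Solvents**: HSPs uniform over `delta_d` 13–16, `delta_p` 0–10,
  `delta_h` 0–16 MPa^1/2^ — ranges chosen to bracket the packaged
  six-solvent reference set.
* **RED rows**: exact forward model plus additive Gaussian noise truncated
  at 0 (RED is non-negative by definition; no published error model
  exists, and additive noise at sd 0–0.1 spans the plausible rounding and
  estimation error of 2-decimal tables). Default truth sphere
  (17, 3, 5, radius 8): a lipid-like solute inside the fitting box.
* **Compositions**: symmetric-Dirichlet simplex draws scaled to 100, so
  closure and the class partition hold exactly by construction —
  independent Gaussian percentages would not close.
* **Bioactivity**: endpoints are affine in a standardized driver plus
  Gaussian noise sized so the population correlation equals the target;
  lower-is-stronger endpoints take the negative sign. Locations and scales
  are on the order of published seed-oil endpoint tables.

Defaults mirror the reference study's scale: 6 solvents, 10 fatty acids,
endpoints of realistic magnitude. Every generator takes an explicit seed
(default: the spec's seed) so single calls are bit-reproducible while
replicate studies can vary the seed; serialized fixtures round-trip through
the package's readers.

What the generators do *not* emulate: correlated measurement error between
endpoints, replicate structure, chromatographic artifacts, or any
relationship between a solvent's HSPs and its generated bioactivity.
Passing the synthetic recovery tests therefore demonstrates correctness of
the estimators under the stated noise model, not that real assay data meet
that model.

## Problem sizes and numerical conventions

The test suite's simulation studies use sizes chosen to make the checks
sharp while staying light: 50 random spheres for exact noise-free recovery
(each checked against the grid reference), 100 replicates per noise level
for the monotone-degradation study over RED noise sd {0, 0.02, 0.05, 0.1},
500 replicates at n = 200 for correlation calibration (mean recovered r
within ±0.02 of the 0.9 target), and 100 random instances for the
nested-loop oracle equivalence of `screen_solvents()` at 1e-12. All
stochastic tests run under fixed seeds.

Numerical conventions: screening equality is exact floating point (the
forward model is a handful of arithmetic operations); optimizer convergence
is accepted at `nls.lm` information codes 1–3; the grid reference must not
beat the optimizer by more than 1e-6; normalization tolerance for
"already-normalized" relative-solubility rows is 1e-9.

## Known limitations

* HSPs are treated as temperature-independent; no estimation of HSPs from
  molecular structure is provided (group-contribution methods are
  proprietary), so solute spheres must come from data via the inverse fit
  or from the user.
* The classical Hansen fit from binary good/poor solubility labels is not
  implemented — the package inverts *quantitative* RED rows.
* Inverse-fitted spheres from a single 6-solvent row are weakly
  identified in the radius direction when all observed REDs are far from
  1; treat the fitted radius as conditional on the box.
* With n = 6 solvents all correlation and concordance statistics are
  descriptive; the report deliberately carries n alongside every
  statistic.
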