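---
title: "Desirability-based response surface optimization of an herbal extraction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Desirability-based response surface optimization of an herbal extraction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytoqc)
```

## The problem

Ultrasound-assisted extraction (UAE) of a multi-compound herbal material —
here Clinopodii herba, whose markers span triterpenoid saponins, flavonoids
and phenylpropanoids — has several interacting process factors: the
methanol–water proportion of the solvent, the liquid-to-solid ratio, and
the sonication time. Because eleven marker compounds respond differently to
these factors, no single compound's yield defines "the best" conditions.
`phytoqc` implements the standard statistical workflow for this situation:

1. collapse the per-compound yields of each experimental run into a single
   **overall desirability** (OD) score;
2. model OD over the factor space with a **second-order polynomial** fitted
   to a **Box–Behnken design** (BBD);
3. judge the fit with the designed-experiment **ANOVA** including the
   lack-of-fit / pure-error split;
4. **maximize** the fitted surface inside the design region, and snap the
   optimum to operable settings;
5. support the surrounding chromatographic assay: calibration, LOD/LOQ,
   precision/recovery statistics, and peak-area → content conversion.

A seeded synthetic-data module generates every input with known ground
truth, so the whole pipeline is verifiable end to end.

## Overall desirability

Each quality index \(Y_i\) is rescaled linearly onto \([0,1]\),

\[ d_i = \frac{Y_i - Y_{\min}}{Y_{\max} - Y_{\min}} \]

for a larger-is-better index, with the mirrored form
\((Y_{\max}-Y_i)/(Y_{\max}-Y_{\min})\) for smaller-is-better. The bounds
are the minimum and maximum observed **within the experiment table being
scored** — not across experiments — unless fixed bounds are supplied. The
overall desirability of a run with \(n\) indices is the unweighted
geometric mean

\[ \mathrm{OD} = \left(\prod_{i=1}^n d_i\right)^{1/n}. \]

Two consequences are deliberate. First, a run at the observed worst level
of *any* index has OD exactly 0 — no epsilon floor is applied, which is why
two runs of the packaged 17-run experiment carry OD 0.0000. Second, the
geometric mean never exceeds the arithmetic mean, so OD is a conservative
aggregate; both properties are asserted in the test suite. Weighted or
two-sided (target-is-best) desirabilities are out of scope.

## The design and the model

`bbd_design()` builds the three-factor Box–Behnken layout: 12 edge points
(every factor pair at the four ±1 sign combinations, the third factor at
its center) plus replicated center runs, 17 runs in total with the default
5 centers. Coded levels are stored as exact integers −1/0/+1, which keeps
the orthogonality of the coded columns exact and makes replicate-group
detection (identical coded rows) safe. Runs are emitted in a fixed
canonical order — pairs (1,2), (1,3), (2,3); signs (−,−), (+,−), (−,+),
(+,+); centers last. Execution order in the laboratory is randomized in
practice, but every analysis in this package is order-invariant, and a
canonical order makes results reproducible and testable. Only the
three-factor design is implemented; other factor counts are rejected
rather than approximated.

Coding maps an actual level \(X\) to \(x = (X - X_0) / \delta\) where
\(X_0\) is the center and \(\delta\) the half-range. The fitted model is

\[ Y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j
     + \sum_i \beta_{ii} x_i^2 , \]

estimated by ordinary least squares **on the coded scale** — the magnitudes
of published coefficient sets for such designs are only consistent with
coding, and coded fitting keeps the columns well conditioned. Predictions
accept actual units and code internally.

## The ANOVA

`rsm_anova()` reports, per term, the *drop-one* (partial, Type-III-style)
sum of squares — the increase in residual SS when that single column is
removed and the model refitted. This matches the output of the commercial
DOE software such tables are usually produced with. On the orthogonal
coded columns the partial SS of a linear or interaction term reduces to
the closed form \(8\beta^2\) (column sum of squares 8), which the tests
exploit as an independent oracle. The quadratic columns are not orthogonal
to the intercept, so the per-term partial SS need not sum to the model SS;
the identity that *is* asserted is
\(SS_\text{total} = SS_\text{model} + SS_\text{residual}\).

With 17 runs and 10 parameters the residual has 7 df; the five center
replicates give pure error 4 df and leave 3 df for lack of fit. Lack-of-fit
F uses the pure-error mean square; all other F ratios use the residual mean
square; p-values come from the F survival function. With no replicated
runs the lack-of-fit split is omitted with a warning, never fabricated.
Formatted output rounds SS to 4 decimals and F to 2, matching the
conventional precision of published tables.

## Optimization

`maximize_surface()` maximizes the fitted quadratic inside a coded box,
default \([-1,1]^3\). The optimum of real surfaces frequently sits on a
face of the cube (in the packaged example the liquid-to-solid ratio lands
exactly on its +1 bound), so the search is boundary-aware by construction:
bounded L-BFGS-B from all 27 points of the \(\{-1,0,1\}^3\) lattice, a
derivative-free shrinking-grid coordinate refinement, the interior
stationary point \(-\tfrac12 A^{-1}b\) when it falls inside the box, and a
final exact active-set polish (with bound-active coordinates pinned, the
free coordinates solve a linear system). Near-ties are broken by the
coded-lexicographically smallest point, so the result is deterministic.
Requesting an unbounded maximization of a non-concave surface is an error.
Each factor is flagged when its optimum lies on a bound — important
scientifically, because a boundary optimum means the true optimum may lie
outside the studied region.

`round_to_practice()` snaps the actual-unit optimum to operable quanta
(e.g. nearest 5% solvent, nearest 5 min) and re-predicts; the snap never
moves a coordinate by more than half its quantum.

## Validation and quantification statistics

Calibration is unweighted OLS of peak area on concentration (a 1/x
weighting is available but off by default, since published curves of this
kind are typically unweighted). LOD and LOQ are `k * noise_sd / |slope|`
with explicit multipliers defaulting to the ICH values 3.3 and 10; they
are parameters because reported limits in the literature follow several
conventions (published LOQ:LOD ratios near 2:1 imply k ratios of 2, not
10/3.3). RSD is `100 * sd / mean` with the n−1 standard deviation;
recovery is `100 * (found − original) / added`, aggregated over the usual
3 spike levels × 3 replicates.

Contents follow
`mg/g = C(µg/mL) × volume(mL) × dilution / mass(g) / 1000`; concentrations
outside a curve's linear range are flagged, not dropped — silently nulling
a near-range analyte would corrupt batch totals. Batch ids follow the
`<site>/<Month>` convention of the packaged 24-batch table; totals per
batch and the best harvest period per site are computed by plain sums and
argmax, with replicate summaries as mean ± (n−1) sd over the three
injections.

## Synthetic data: what it emulates, and what it does not

`simulate_bbd_responses()` draws designed-experiment responses from a
stated coefficient vector plus homoscedastic Gaussian noise; seeds are
mandatory, and every generator is bit-reproducible given its seed. The
chromatogram simulator builds signals as sums of pure Gaussian peaks on a
uniform time grid (default step 0.01 min over the six-segment,
0–28 min variable-wavelength schedule: 348, 284, 330, 270, 250, 280 nm
switching at 7.3, 9.0, 13.0, 23.3 and 24.7 min), each peak carrying one
response factor per detection wavelength so that the segment switches have
observable consequences. Integration is baseline-subtracted trapezoidal
quadrature over user windows.

These choices emulate the *structure* of the real data — not its physics.
Real peaks tail; real noise is not white; real UV response factors per
analyte per wavelength are not tabulated here, so the synthetic ones are
declared values, never claimed to match real analytes. Passing tests
therefore demonstrate the correctness of the statistical machinery, not
instrument-level fidelity. Gaussian-peak areas integrate to within 0.1%
of the closed form at a 0.001 min step, and the parameter-recovery tests
(200 seeded simulations at noise sd 0.02 on the 17-run design) confirm the
fit is unbiased to within Monte-Carlo error and the recovered optimum
stays within 0.05 coded units of truth.

## Numerical choices and problem sizes

* Coding round-trips are exact to 1e−12; OLS is checked against a
  normal-equation solve at 1e−9 on random instances.
* Optimizer tolerances: gradient-based stage `pgtol = 1e-10`, position
  agreement with the closed form at 1e−6; the dense-grid cross-check uses
  a 101³ lattice (grid spacing 0.02).
* Test problem sizes are desk-scale throughout — 17-run designs, 200-draw
  Monte-Carlo recovery, 101³ grid oracles — chosen so the full suite runs
  in well under five minutes on one CPU while still exercising every code
  path.
* Degenerate inputs fail loudly: constant desirability indices without
  fixed bounds, rank-deficient model matrices, designs without replicates
  (warning + omitted lack of fit), two-point calibrations, zero slopes,
  overlapping integration windows.

## Known limitations

Only the 3-factor Box–Behnken design is generated. Desirabilities are
linear and unweighted. The optimizer handles a single response surface —
no Pareto multi-objective trade-offs, no ridge analysis. The published
validation summaries shipped as fixtures (calibration parameters, RSDs,
recoveries, contents) are reference values for format and consistency
checks; their raw replicate data are not public, so they cannot be
regenerated from first principles, and the package does not pretend to.
The `run_pipeline()` driver and the exported readers/writers are the
programmatic interface; the acceptance script under `scripts/` shows a
complete shell-level invocation.
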