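---
title: "Methods: whole-grain intake and healthcare cost savings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: whole-grain intake and healthcare cost savings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(grainCOI)
```

## The model and its assumptions

grainCOI implements a deterministic cost-of-illness (COI) model that turns a
population dietary change — closing the gap between current and recommended
whole-grain intake — into direct healthcare expenditure savings. It is a
desk-scale model: every input is a published summary statistic (a pooled
relative risk, a survey median intake, a national expenditure table), and
the output is an arithmetic consequence of those inputs. Three structural
assumptions do all the work:

1. **Linear dose–response.** The pooled relative risk RR per reference dose
   *d* of whole-grain food is scaled to an intake gap *g* as
   reduction = (1 − RR) · *g*/*d*. Meta-analytic dose–response curves for
   whole grains are close to linear over the doses of interest, and the
   linear form keeps confidence-interval propagation exact: each CI bound
   is scaled by the same factor, with the bounds swapping roles (a higher
   RR means a smaller reduction). An optional log-linear mode,
   1 − RR^(g/d), treats the RR as multiplicative per dose unit instead; for
   RR near 1 and g/d ≤ 0.5 the two agree to about half a percentage point
   (the worst case on that domain, at RR = 0.8 and g/d = 0.5, is 0.56
   points), and at the default inputs (RR 0.83–0.85, g/d = 0.3) they differ
   by under 0.2 points.

2. **Proportional cost response.** A 1% reduction in disease risk is
   assumed to save 1% of each expenditure category, uniformly. This ignores
   fixed costs, capacity effects and lags between incidence and spending;
   it is the standard simplification in this literature and makes savings
   exactly linear in the uptake fraction, which is why `predict()` can
   evaluate arbitrary uptakes.

3. **Step-function adoption.** Population uptake is a constant fraction per
   scenario, not a diffusion curve. The staged incremental path simply lets
   each successively more optimistic scenario occupy the next 5-year block.

CI propagation is deterministic throughout: lower and upper bounds flow
through the same linear maps as the central value. No Monte Carlo layer is
needed because every operation is monotone and linear in the uncertain
input.

## Parameters, units, defaults

| Parameter | Unit | Default | Why |
|---|---|---|---|
| current intake | g/day whole-grain content | 21 | adult median from national survey data |
| target intake | g/day content | 48 | the Australian Daily Target Intake |
| product:content ratio | — | 30/16 | 30 g of whole-grain food carries ≈ 16 g whole grain |
| reference dose | g/day product | 90 | dose the pooled RRs are expressed per (3 servings) |
| RR, CRC | — | 0.83 (0.78–0.89) | pooled over 6 prospective studies |
| RR, total cancer mortality | — | 0.85 (0.80–0.91) | pooled over 6 studies |
| uptake scenarios | fraction | 0.05, 0.15, 0.50, 1.00 | very pessimistic → universal |
| discount rate | per year | 0.07 | the conservative real rate used across Australian jurisdictions |
| block length / horizon | years | 5 / 20 | staged adoption at 5-year increments after year 0 (2020) |

A unit subtlety deserves its own paragraph. The 27 g gap is measured in
whole-grain *content*, while the 90 g reference dose is in grams of
*product* (90 g product ≈ 48 g content at the 30:16 ratio). The default
scaling divides the content gap by the product dose (27/90 = 0.3), which is
the convention of the published analyses this package reproduces and yields
the 5.1%/4.5% reductions exactly. Dimensional purists can set
`strict_content_units = TRUE` to divide by the 48 g content equivalent
(27/48 = 0.5625), which nearly doubles every downstream saving. The package
implements both and defaults to the published convention; we do not guess
which the original meta-analyses "really" meant, since the choice is a
property of the source RRs' exposure definition, not of this model.

## Expenditure inputs and inflation

The bundled expenditure fixtures carry both the 2015–16 base-year column
and the 2020 current-year column of the Australian (AIHW) cancer
expenditure tables; the pipeline uses the printed current-year column
directly rather than re-inflating the base year. The implied aggregate CPI
(Health) factor is 728.9/640.3 ≈ 1.1384, and `inflate()` reproduces each
current-year CRC category from its base value to within display rounding —
both columns are printed to 0.1, so up to 0.05·(1 + factor) ≈ 0.11 of
drift per category is attributable to rounding alone, and the per-category
implied ratios genuinely vary (≈ 1.136–1.152), suggesting per-category CPI
application upstream. Avoiding re-inflation avoids compounding that
rounding drift into the savings tables.

## Numerical choices

* All monetary arithmetic is double precision and unrounded end to end;
  rounding is a display concern. Display rounding is half-away-from-zero
  (the convention of financial tables, unlike R's banker's rounding), and
  values whose rounded magnitude would print as zero show as `<0.01`
  (or `<0.1` at one decimal).
* Discounting uses closed integer year ranges with year 0 undiscounted;
  the 20-year horizon is years 0–19. Block present values are computed
  from unrounded annual savings; discounting pre-rounded annuals would
  perturb the first decimal of several block cells.
* Degenerate inputs are legal where they are meaningful: zero gaps, zero
  uptake and zero-amount categories all propagate to zero savings; a
  zero-width CI collapses the savings CI. Harmful exposures (RR > 1) are
  accepted for generality but flagged with a warning, as is linear
  extrapolation beyond the reference dose.
* Config validation is exhaustive: every problem in a file is reported in
  one error, not just the first.

## The synthetic-data generator

`synthetic_spec()` + `generate_*()` emulate the *structure* of the real
inputs: log-normal (sdlog 1.5) category amounts reproduce the heavy-tailed
spread of expenditure tables, where two hospital categories dominate and
the smallest category is three orders of magnitude below the largest; RR
draws with independent CI half-widths per side guarantee the bound
ordering; uptakes, gaps and rates are uniform over realistic ranges. One
global seed drives everything, with per-generator sub-seeds derived
deterministically so streams do not shift when a generator is added.

What the generator does *not* emulate: correlation between category size
and inflation rate, skewed (asymmetric, log-scale) RR confidence intervals
as produced by actual meta-analysis, or individual-level intake
distributions. Property tests passing on synthetic data therefore
establish the model's algebraic invariants (linearity, homogeneity,
additivity, discounting identities, bound ordering) — not that the bundled
Australian inputs are themselves correct; those are asserted separately
against the printed values they came from. The test suite runs 1000
randomized invariant cases plus the full printed-table reproduction, and
completes in seconds.

## Known limitations

* Direct healthcare costs only; productivity and mortality-related
  (indirect) costs are out of scope, so totals are conservative.
* The proportional cost response assumes savings materialise in the same
  year as the risk reduction, with no latency — optimistic for cancers
  with decade-scale latency; the discounted staged path partially offsets
  this by deferring the larger uptakes.
* RR inputs are taken as given; the package never re-pools primary
  studies, and heterogeneity statistics are metadata only.
* One printed cell of the reference discounted table (total cancer,
  optimistic scenario, years 5–9) is internally inconsistent with its own
  universal-scenario column (633.3 vs 1267.2/2 = 633.6); the package
  reproduces the self-consistent value.
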