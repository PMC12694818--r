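---
title: "Models and methods: mtDNA heteroplasmy transmission under drift and selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: mtDNA heteroplasmy transmission under drift and selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitodrift)
```

# The scientific problem

A cell carries hundreds to thousands of mtDNA copies, a mature oocyte on
the order of 100,000. A variant is therefore described by its
*heteroplasmy* `h`, the mutant copy fraction. Two population-genetic forces
shape `h` across a mother-to-offspring transmission:

* **Drift through the germline bottleneck.** Only a small effective number
  of mtDNA segregating units founds each oocyte lineage, so offspring `h`
  scatters widely around the mother's value even without selection.
* **Purifying selection.** Some pathogenic variants are preferentially
  removed during oogenesis, shifting the offspring distribution downward
  beyond what drift alone predicts.

Distinguishing the two requires an explicit neutral-drift reference
distribution; that reference is the Kimura distribution implemented here.

# Shift statistics

For mother `h0` and offspring/oocyte `h`:

\[ R = \frac{h(1-h_0)}{h_0(1-h)}, \qquad L = \ln R = \mathrm{logit}(h) - \mathrm{logit}(h_0). \]

`R` is the mutant-carriage odds ratio; `L` is antisymmetric under swapping
mother and offspring and additive along chained transmissions, which makes
it the natural scale for pooling pairs with different starting
heteroplasmies. Mother-offspring analyses default to `L`; per-stage
follicle summaries report the arithmetic mean of `R` (with medians
alongside), matching how stage-wise shifts are usually quoted. Bootstrap
CIs (1000 seeded resamples) accompany stage means because single-stage
sample sizes are small.

**Boundary policy.** `h = 0` (variant lost) or `h = 1` (fixed) has no
finite logit. The default policy excludes such records and reports the
count; an optional clamp to `[eps, 1-eps]` with
`eps = 1/(2 * assay_copies)` (half a copy at assay resolution) is provided.
Published analyses of this kind do not state how boundary offspring were
handled, so the package makes the choice explicit, applies the *same*
policy to observed and simulated values, and never hides the excluded
count. The simulation-calibrated p-value of the null test is computed under
the identical policy, so the test stays calibrated even though exclusion
truncates the lower tail.

# The Kimura pure-drift distribution

Parameterised by the initial fraction `p` and drift parameter
`b in [0, 1)` with

\[ E[X] = p, \qquad \mathrm{Var}[X] = p(1-p)(1-b), \qquad b = (1 - 1/N)^t \]

for a haploid Wright-Fisher bottleneck of `N` copies over `t` generations.
With `F_i(x) = {}_2F_1(1-i, i+2; 2; x)` and `q = 1 - p`, the classical
eigenfunction series gives the loss mass, fixation mass and interior
density:

\[ f(x) = pq \sum_{i \ge 1} i(i+1)(2i+1) F_i(p) F_i(x)\, b^{i(i+1)/2}, \]
\[ P_1 = p + \sum_{i \ge 1} (2i+1)pq(-1)^i F_i(p)\, b^{i(i+1)/2}, \qquad
   P_0 = q - \sum_{i \ge 1} (2i+1)pq F_i(p)\, b^{i(i+1)/2}. \]

## Numerical choices

* `F_i(x) = P_{i-1}^{(1,1)}(1-2x)/i` links the hypergeometric terms to
  Jacobi polynomials, generated by their stable three-term recurrence; no
  special-function library is needed.
* Truncation is adaptive: `|F_i| <= 1` on `[0,1]`, so the i-th density term
  is bounded by `i(i+1)(2i+1) pq |F_i(p)| b^{i(i+1)/2}`; terms are added
  until that bound drops below `tolerance * 1e-3` (hard cap 500). Drift
  factors below `1e-300` are dropped to avoid underflow. At construction
  the mass residual `|P0 + P1 + \int f - 1|` must be below `tolerance`
  (default `1e-6`) or construction aborts with the achieved residual.
* The truncated density is a polynomial, so moments are computed *exactly*
  with Gauss-Legendre quadrature of sufficient order (Golub-Welsch nodes);
  the moment identities in the tests are checked to `1e-6` without
  quadrature slop.
* Sampling: boundary atoms first as a discrete mixture, then inverse-CDF on
  a 2001-point uniform grid with linear interpolation — O(1) per draw and
  reproducible from a seed.
* `b` within `1e-12` of 1 is treated as the degenerate no-drift limit
  (point mass at `p`, flagged, sampling warns).

## Validation against a Wright-Fisher oracle

The test suite compares Kimura samples with end-state frequencies of a
literal Wright-Fisher simulation (binomial resampling of `N` copies for
`t` generations). One subtlety: for `N = 20` the WF end state lives on a
21-point lattice, so a total-variation distance on 50 equal-width bins
measures the binning mismatch (most bins are empty), not model fit. The
equivalence check therefore uses *lattice-aligned* bins — `N + 1` bins
centred at `k/N` with the boundary atoms merged into the end bins — for
`N` in {20, 50, 100}; observed TV distances are below 0.016 everywhere
(threshold 0.03). The single 50-equal-bin check is run at `N = 100`, where
the lattice is finer than the bins (TV < 0.02).

# The neutral-null test

`neutral_null_test()` implements the simulation recipe: estimate `b` from
the observed pairs, draw `multiplier = 1000` neutral values per observed
pair from Kimura(`h0`, `b_hat`), transform both sides to log shifts under
the shared boundary policy, and compare densities.

Design choices made where the published procedure is silent:

* **`b` by variance matching** (`b_hat = 1 - sum((h-h0)^2)/sum(h0(1-h0))`).
  Matching the dispersion makes the comparison sensitive to the
  location/shape signature of selection rather than to bottleneck size,
  which is the scientifically interesting contrast. The estimate is
  reported in every result object.
* **A formal statistic.** Published figures overlay density curves without
  a test; the package computes the two-sample Kolmogorov-Smirnov distance
  and calibrates it by parametric re-simulation (199 replicates of the
  observed sample size drawn from the fitted null; p = (1 + #{D_rep >=
  D_obs})/200). Density-curve coordinates are still exported for plotting
  parity.
* **Stream seeding.** All randomness derives from one master seed via a
  fixed linear scheme with per-mother offsets (mothers ordered by `h0`),
  so results are reproducible and invariant to input row order.

Calibration is itself tested: across 200 neutral pedigrees the rejection
rate at nominal 0.05 stays at or below 0.10, and with selection
`s = -0.05` the test rejects with a negative mean difference in at least
90% of runs.

# Transmission analyses

* **Regression** of `pup_h` on `mother_h` defaults to OLS *with*
  intercept; a through-origin fit is always computable (and the CLI
  reports both) because published "fitted curves" rarely state the choice.
  Slope below 1 indicates selection; CI coverage is verified by parameter
  recovery at n = 500.
* **Normality-gated testing policy**: Shapiro-Wilk at alpha = 0.05 selects
  t-test vs Wilcoxon/Mann-Whitney, and the test actually used is always
  recorded. Vectors longer than Shapiro-Wilk's 5000-value limit are
  thinned deterministically (every k-th value) so the gate is
  reproducible.
* **Stage summaries** order stages canonically (primordial, primary, early
  secondary, late secondary, antral, MII, offspring) and compare
  consecutive stages by Mann-Whitney U, reporting raw p-values (the
  convention in this literature) plus Holm-adjusted ones.
* **Maternal-age analysis** aggregates per delivery (mean shift of a
  litter) before correlating with age, because pups within a litter share
  their transmission event; a pup-level variant exists behind a flag.
* **Tissue stability** is the per-mouse CV (sd/mean, %) of `h` across
  tissues, averaged over mice; scale invariance is property-tested.

# ddPCR quantification

Per channel (FAM = wild-type, HEX = mutant), `lambda = -ln(1 - k/N)`
molecules per droplet and `lambda * N` copies per reaction. Heteroplasmy is
the lambda ratio, not the positive-droplet ratio — the two differ once
droplets hold multiple molecules, and the lambda ratio is the statistically
correct choice under Poisson partitioning. Droplet volume (default 0.85 nL,
QX200 convention) is used only for the optional copies/uL column.
Saturated channels (`k = N`) are a hard error; double-blank wells are
flagged `empty` rather than given a fabricated heteroplasmy. The round-trip
test (simulate partitioning, re-quantify) recovers true copies within 2%
over 1000 wells.

# Off-target calling

At reference C positions the conversion rate is `T/depth` (at G, `A/depth`
— the same edit read on the other strand); sites at or *above* the 1%
threshold are flagged, the inclusive comparison matching the ">= 1%" rule
this assay family uses. Counts are pooled across strands (the per-strand
split is not published). A/T reference sites are never evaluated;
zero-depth sites are skipped with a warning; known on-target positions are
excluded from flagging but still reported. Coordinates are 1-based
mitochondrial positions, matching "m.3177 G > A"-style nomenclature.

# What the synthetic generators emulate — and what they do not

`simulate_pedigree()` produces a five-generation colony founded at
`h = 0.067` (44 mothers x ~18 pups by default, the scale of a real
transmission study): each transmission is `t = 15` Wright-Fisher
generations at `N = 200` copies (`b = (1-1/200)^15 ~ 0.93`, putting the
pup standard deviation around a 6.7% mother at ~5 percentage points, the
wide dispersion a germline bottleneck produces), optional per-replication
selection `p' = p(1+s)/(1+ps)` (s < 0 purifying), and binomial measurement
noise at 5000 assay copies. Litter sizes are truncated-Poisson(7) and ages
increase across deliveries, independent of heteroplasmy by default (the
published null findings for litter size and the default for age); an
`age_slope` knob injects an age-dependent selection trend for power
studies. Mothers whose lineage fixes or loses the variant are re-drawn
from the founder — a real colony cannot breed from homoplasmic-wild-type
females either.

`simulate_follicle_timecourse()` models 7 culture days: mutant copies are
removed with per-day per-copy probability `delta` (default 0.3, chosen to
reproduce the qualitative mutant-decline/wild-type-rise crossing over a
7-day culture; no quantitative elimination rate is published), and
replication fills 55% of the remaining deficit toward 100,000 copies per
day, which brings unedited oocytes to >= 90% of target by day 3 (the
published expansion tempo). Only wild-type copies replicate by default —
the strictest reading of compensatory replication — with a switch
re-admitting mutant copies at reduced rate for sensitivity analysis.

Not emulated: mitophagy mechanism, follicular atresia, nuclear-background
modifiers, PGC-stage bottleneck timing, sequencing-error structure on
heteroplasmy measurements (separate from the site-count fixture). A green
test therefore establishes that the *analysis* behaves correctly on data
with the stated drift/selection/noise structure — not that real follicle
biology has these parameter values.

# Known limitations

* The neutral null's published counterpart does not report its drift
  parameter or boundary handling, so its exact density curves are not
  reproducible; the package's null is calibrated by construction instead
  and states its choices in every report.
* The variance-matching `b_hat` absorbs any selection-induced variance
  change into the null; strong variance-shifting selection would be
  detected with reduced power.
* Reproducing the published headline numbers (regression slope 0.69,
  stage means 0.93/0.79/0.74, tissue CV 8.35%, generation means) requires
  the study's numerical datasheet mapped to the package schemas
  (`?load_study_datasheet`); the workbook cannot be shipped with the
  package, so the corresponding acceptance test fails visibly — by design
  — when the datasheet is absent.
* `estimate_b` assumes all offspring of a mother share one transmission
  depth; pedigrees with per-pair `t` need external stratification.
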