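# mitodrift

Transmission genetics of mitochondrial DNA (mtDNA) heteroplasmy through the
maternal germline.

Pathogenic mtDNA variants are present as a mixture of mutant and wild-type
copies; the mutant fraction is the *heteroplasmy* `h` (0 = pure wild-type,
1 = homoplasmic mutant). During oogenesis a germline bottleneck makes
offspring heteroplasmy scatter widely around the mother's value, and on top
of that random drift some pathogenic variants are actively eliminated
(*purifying selection*). `mitodrift` is for researchers who breed
heteroplasmic animal models (or culture follicles carrying base-edited
mtDNA) and need to decide: **is a variant transmitted neutrally, or is it
under selection — and at which stage of oocyte development does the
selection act?**

## The statistics at the core

* **Heteroplasmy shift.** For a mother at `h0` and an offspring/oocyte at
  `h`, the shift ratio is the mutant-carriage odds ratio
  `R = h(1 - h0) / (h0(1 - h))` and its natural log
  `L = ln R = logit(h) - logit(h0)`. `R = 1` (`L = 0`) is unbiased
  transmission; `R < 1` is a reduction in the offspring. `L` is
  antisymmetric and additive across chained transmissions.
* **Kimura pure-drift distribution.** Under neutral drift from initial
  fraction `p`, the end-state distribution of heteroplasmy is a mixture of
  atoms at 0 (loss) and 1 (fixation) plus a continuous density on (0, 1),
  parameterised by `b` with `E[X] = p` and `Var[X] = p(1-p)(1-b)`;
  `b = (1 - 1/N)^t` for a Wright–Fisher bottleneck of `N` copies over `t`
  generations. `kimura_distribution()` evaluates the classical
  hypergeometric series; `kimura_sample()` draws from it.
* **Neutral-null test.** `neutral_null_test()` estimates `b` from the data
  by variance matching, simulates 1000 neutral draws per observed pair,
  compares observed vs simulated log-shift distributions with a two-sample
  Kolmogorov–Smirnov distance, and calibrates its p-value by parametric
  re-simulation. A negative mean difference with a small p-value is the
  signature of purifying selection.
* **Supporting analyses.** Mother–offspring regression (slope < 1 =
  selection), normality-gated testing (Shapiro–Wilk chooses t-test vs
  Mann–Whitney/Wilcoxon), follicle-stage shift summaries, maternal-age and
  litter-size associations, cross-tissue stability CVs, ddPCR Poisson copy
  quantification (`lambda = -ln(1 - k/N)` per channel), and a >= 1%
  conversion-rate off-target caller for base-editing pileups.
* **Synthetic data.** Seeded generators emulate the experiments: a
  bottlenecked pedigree with optional per-replication selection `s`, a
  follicle-culture copy-number time course (mutant elimination plus
  compensatory wild-type replication toward ~100,000 copies), ddPCR droplet
  partitioning, and per-site base counts.

## Worked example

Simulate a colony the size of a typical transmission study (44 mothers,
~18 pups each, founder heteroplasmy 6.7%) with purifying selection
`s = -0.05` per copy replication, then ask the analysis stack whether it
sees the selection:

```r
library(mitodrift)

pairs <- simulate_pedigree(n_mothers = 44, pups_per_mother = 18,
                           selection_s = -0.05, seed = 42)

fit_transmission_regression(pairs)
#> Transmission regression (with intercept), n = 792
#>   slope = 0.5321 [0.4742, 0.5900], p = 4.03e-61, r^2 = 0.291
#>   intercept = -0.0014

ms <- mean_shift_test(pairs)
#> mean log shift -0.516 [-0.626, -0.405], p = 1.5e-17 (Wilcoxon signed-rank)

neutral_null_test(pairs, seed = 42)
#> Neutral-drift null test (Kimura simulation)
#>   n observed = 374, n simulated = 568772 (multiplier 1000), b_hat = 0.9511
#>   KS = 0.2057, p = 0.005, mean log-shift difference = -0.4031
#>   boundary exclusions: 418 observed, 223228 simulated
```

Read-out: the regression slope 0.53 sits well below the unbiased slope of
1; the mean log shift is negative (offspring carry less mutant than their
mothers); and the observed shift distribution differs from the simulated
neutral-drift null (KS p = 0.005) with a negative mean difference — all
three agree the variant is being purged. The large boundary-exclusion
count records pups in which the variant was lost outright (`h = 0`), which
have no finite log shift; exclusion is the default policy and the counts
are always reported. With `selection_s = 0` the same pipeline returns a
slope near 1 and a non-significant KS p-value.

The same stages are scriptable from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "mitodrift", package = "mitodrift"))')
Rscript $CLI simulate-pedigree --seed 7 --out out/
Rscript $CLI transmit --pairs out/pairs.tsv --out out/
Rscript $CLI kimura-null --pairs out/pairs.tsv --out out/ --seed 7
```

Each command validates its TSV inputs against a schema, then writes result
tables plus a JSON report (command echo, resolved config, input
fingerprints, warnings, results) atomically.

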