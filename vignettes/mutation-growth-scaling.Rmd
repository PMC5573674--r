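---
title: "Methods: mutation-rate and growth-rate scaling under genome reduction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mutation-rate and growth-rate scaling under genome reduction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mutscale)
```

## The scientific problem

Engineered genome reduction in *Escherichia coli* -- the stepwise removal of
nonessential genomic segments from the W3110 chromosome -- lowers the growth
rate and, strikingly, raises the spontaneous mutation rate. Across a series
of one wild-type and nine increasingly reduced genomes, both effects follow
simple scaling laws whose coefficients depend on the growth medium. This
package implements the full quantitative pipeline behind that observation:

1. **Fluctuation assays** give per-strain mutation rates: parallel cultures
   grown from small inocula are plated on selective medium, and the
   heavy-tailed distribution of resistant-colony counts identifies the
   expected number of mutational events per culture, `m`.
2. **OD600 curves** give per-strain exponential growth rates `mu` (h^-1^).
3. Two **scaling-law fits** relate the per-bp per-division mutation rate
   `M` to genome size `G` (Mb) and to growth rate:

   * genome-size law: `log10(M_i) = r * log10(G_i) + b`
   * growth-rate law: `log10(M_i) = log10(M0) + alpha * mu_i`

   where `M0`, the *mutation capacity*, is the extrapolated mutation rate of
   a non-growing culture.
4. **Gene-category correlation** asks which functional classes of deleted
   genes track the rising mutation rate along the reduction series.
5. A **serial-transfer simulator** reproduces the daily dilution-and-regrowth
   protocol used to evolve a reduced genome back toward faster growth and a
   lower mutation rate.
6. A **synthetic-data generator** emulates every input, so the entire
   pipeline is testable end to end without any external data.

The per-medium coefficient presets used by the generator are `r = -14.6`
(M63), `-10.1` (MAA), `-5.1` (LB); `alpha = -4.9` (M63), `-4.8` (MAA),
`-2.4` (LB); and `log10(M0) = -6.1` (M63), `-4.3` (MAA), `-5.4` (LB).

## Fluctuation-assay inference

The mutant-count distribution is computed in the Lea-Coulson
parameterisation by the MSS recursion,

```
p0 = exp(-m),   p_n = (m / n) * sum_{k < n} p_k / (n - k + 1),
```

and `estimate_m_mle()` maximises the resulting log-likelihood over `log(m)`
(1-D bounded search, explicit boundary at `m = 0` for all-zero samples).
The confidence interval is the likelihood-ratio interval (chi-squared with
1 df) rather than a Wald interval, because `m` estimates routinely sit near
the zero boundary. The classical P0 estimator
(`m = -log(zero-class fraction)`) is provided as a fallback and diagnostic;
on moderate `m` the two agree within a few percent.

Numerical choices:

* The pmf is truncated at a cap (`n_max`, default 10,000); counts at or
  above the cap fall into a single `>= n_max` tail cell of probability
  `1 - sum(pmf)`. Jackpot cultures are an expected feature of the
  distribution, so tail-binning is the default; disabling it
  (`tail_bin = FALSE`) turns an over-cap count into an explicit error.
* The recursion is O(n^2) and implemented in C++; a likelihood evaluation
  at the default cap costs tens of milliseconds, which keeps
  dozens-of-strain panels tractable.
* CFU-based population sizes use only plates with 10-500 colonies (the
  countable range of the plating protocol); the mean of reliable plates is
  scaled by one configurable dilution factor and the plated volume.

The per-bp per-division rate is `M = m / (N_t * target_size_bp)`. The
effective target size of nalidixic-acid resistance (how many genomic sites
confer the selected phenotype) is not identifiable from colony counts
alone, so it is a configuration parameter defaulting to 1 bp-equivalent --
i.e. rates are per-target unless the user supplies a size. The synthetic
round trip uses the same value on both sides, so recovery results are
unit-consistent.

### The branching oracle and its known gap

`sample_ld_counts()` is an independent implementation path used to check
the estimator: a discrete branching process with `n_generations`
synchronous doublings, Poisson mutation events proportional to each
generation's divisions, and deterministic clone growth (`2^(G-g)` final
mutants for a generation-`g` event). Its zero class is exactly `exp(-m)`
and its one-mutant class matches the Lea-Coulson `p1`; beyond that the
discrete model concentrates clone sizes on powers of two while the
continuous formulation spreads them smoothly (`P(clone >= s)` roughly
`1/s`). The two distributions therefore differ structurally: measured
total-variation distance is about 0.08-0.10 at `m` between 0.5 and 2
(e.g. `p2`: 0.136 discrete vs 0.107 continuous), independent of the number
of generations. Fitting the continuous likelihood to branching-simulated
counts consequently carries a small negative bias in `m` (about -4% at
`m <= 5`, saturating near -17% for `m` in the hundreds). On the log scale
this is a nearly uniform offset across a strain panel, so fitted scaling
*slopes* are affected only at the few-percent level; recovered intercepts
absorb the offset. The acceptance suite reports the measured
total-variation distances and recovery errors rather than hiding them.

## Growth-rate estimation

`growth_rate()` is the slope of `ln(OD)` against time over a selected
early-exponential window -- the multi-point generalisation of
`mu = ln(Cj/Ci) / (tj - ti)`, to which it reduces for a two-point window.
The default window policy scans contiguous runs of at least `min_points`
readings with OD inside `od_range` (default 0.01-0.1) and picks the
maximum-slope window among those with r^2^ >= 0.99, falling back to the
best-r^2^ window (flagged) when none qualifies.

Two analysis-side caveats, quantified by simulation during design:

* With additive reader noise of ~0.003 OD, the bottom of the default OD
  decade carries 30% relative noise in log space. Short (5-point)
  max-slope windows are then upward-biased -- severely so for slow
  growers (about +30% mean bias at `mu = 0.126` h^-1^ with sd comparable
  to the estimate). The panel analysis (`analyze_strain_panel()`, and the
  pipeline growth stage) therefore requires the window to span at least
  70% of the in-range readings (`min_frac = 0.7`) and fits over
  `od_range = c(0.02, 0.2)`, where relative noise stays below ~15%. This
  brings the single-curve sd down by an order of magnitude at the cost of
  a mild logistic-curvature compression (about -4 to -7% in `mu`,
  approximately uniform across strains, so it largely cancels in the
  growth-rate-law slope and exactly cancels in its intercept).
* Growth assays are averaged over 24 replicate curves per strain,
  matching the 12-24-fold replication typical of microplate growth
  surveys.

Blank handling is the caller's: curves are expected blank-subtracted, and
non-positive readings are dropped on construction.

## Scaling fits and statistics

Both laws are fitted by ordinary least squares on `log10(M)` (base 10
throughout, matching how the laws are written). OLS is used deliberately
despite measurement error in both variables -- the fits describe the
printed regression convention, not an errors-in-variables model; the
residual attenuation this induces under the generator's default noise is
below 4% of the slope.

Because panels have ~10 strains, p-values are computed by permutation:
exhaustive enumeration of all `n!` permutations for `n <= 8` (exact
fractions), otherwise seeded Monte-Carlo with the add-one correction
`(b + 1)/(n_perm + 1)`, which also floors the p-value. Spearman's rho is
the Pearson correlation of mid-ranks (ties averaged). Two-sided p-values
are the default; the direction-specific tests state their sidedness.

The nutrition-shift test (`media_shift_test()`) is a one-sided exact
Wilcoxon signed-rank test on paired per-strain `log10` rates -- chosen
because the same strains are measured in each medium, making a paired
design the natural reading; all-tied input returns `p = 1`, flagged.

## Gene-category analysis

Deleted genes are classified into a 23-code functional vocabulary (a
configurable default in the style of the classical *E. coli* annotation,
including transporter `t`, predicted transporter `pt`, predicted membrane
`pm`, and partial-information `d` classes). Deletions are nested along the
reduction series, so `cumulative_deletion_counts()` counts distinct genes
from the first strain that deletes them, producing a monotone strains x
categories table. Categories with **more than 10** cumulative deletions in
the most-reduced strain (strict inequality) enter the correlation stage:
Pearson correlation between `log10(M)` and the cumulative count across the
series (Spearman available), permutation p-values, and `-log10(p)` as the
heat-map quantity. The zero-deletion wild-type row is included by default
(it is one of the strains of the panel); this is configurable.

## Serial-transfer simulator

The protocol model: each day the selected culture is diluted by factors
10^1^..10^8^ into eight wells, grown `incubation_h` hours, and the single
well inside the OD 0.001-0.05 early-exponential window is carried forward;
several in-window wells are resolved toward the geometric midpoint
`sqrt(0.001 * 0.05)` of the window in log OD (a scale-appropriate rule; the
wet protocol does not need one because real overnight densities rarely
produce ties). Generations accumulate as
`log2(od_selected * dilution / od_previous)`, which telescopes exactly.

The default deterministic regrowth is exponential growth capped at the
carrying capacity with `mu_start = 8 * log(2) / 24` h^-1^, calibrated so an
unsaturated well regrows 256-fold in 24 h: the steady-state protocol then
yields exactly 8 generations/day and 400 generations over the 50-day
default -- the generation count implied by the protocol's published scale.
Adaptation is a saturating (hyperbolic) rise of `mu` with cumulative
generations, the minimal monotone model consistent with a single
before/after observation, and the mutation rate is tied to `mu` through the
growth-rate law at every step, so the simulated trajectory lies exactly on
that law by construction -- an intentional idealisation of the observation
that evolved strains track it only roughly.

## The synthetic-data generator

`gen_strain_panel()` draws, per strain, a true `log10 M` on the
genome-size law plus `Normal(0, 0.1)` strain noise, then derives the true
growth rate from the growth-rate law plus `Normal(0, 0.02)` noise. This
latent chain G -> M -> mu makes all three pairwise correlations (genome
size-mutation rate, mutation rate-growth rate, genome size-growth rate)
hold simultaneously, which is exactly the structure the analysis assumes.
With both noise terms at zero every downstream fit returns the preset
coefficients to machine precision -- the end-to-end identity check.

Design constants chosen once, and why:

* **Genome series**: wild type 4.65 Mb plus nine reduced genomes evenly
  spaced 4.561 down to 3.62 Mb -- the published span of the deletion
  series (deletions from ~89 kb up to ~1 Mb).
* **Wild-type growth anchors** `mu_wt` = 1.4 (LB), 0.88 (MAA), 0.45 (M63)
  h^-1^: microplate-realistic rates that fix the genome-law intercept via
  `b = log10(M0) + alpha * mu_wt - r * log10(4.65)`. The anchors are
  chosen so per-strain rates order M63 > MAA > LB (the nutrition-shift
  direction) *and* the implied mutations-per-culture stay in the
  estimable fluctuation-assay range (`m` from ~0.3 to ~200 at
  `N_t = 1e9`, 96 cultures).
* **Fluctuation scale**: 96 cultures per strain, `N_t = 1e9` -- a
  realistic assay with runtimes in seconds.
* **Growth curves**: logistic with `K = 1.0` OD, inoculum 0.001, 15-min
  sampling, additive reader noise 0.003 OD floored at 1e-4; horizons are
  extended for slow strains so the exponential window is always sampled.
* **Deletion table**: nested deletions with 14 of 23 categories
  constructed to exceed the >10-deletions filter in the final strain
  (major categories receive at least 11 genes, the rest at most 10), so
  the retention count is stable across seeds.
* **Expression compendium**: 75 samples with per-sample growth rates and
  planted gene-growth correlations (defaults 0.39, -0.06, -0.26 for the
  three mismatch-repair-like genes); per-sample offsets give unequal raw
  column means so global normalization is exercised.

What the generator does **not** emulate: mutant-fitness differences and
phenotypic lag in fluctuation assays, plating efficiency below 1, lag
phases and diauxie in growth curves, probe-level microarray artefacts, and
any sequence-level realism in the deletion table. Passing recovery tests
on this generator therefore demonstrates correctness of the estimators and
fits under the stated statistical model, not robustness to those
real-data complications.

## Problem sizes and reproducibility

Recovery checks average 20 panel seeds per medium (about 5-10 minutes for
all six coefficient targets on one CPU, dominated by the high-`m` M63
likelihoods); oracle-equivalence checks use 1e5 simulated cultures;
estimator checks use 50 replicates of 1000 cultures and 200 replicates of
100 cultures. Every stochastic stage takes an explicit seed, generators
are pure functions of (parameters, seed), and the pipeline summary embeds
all parameters and seeds so each figure-style table can be regenerated
without re-running estimation.

```{r example, eval = FALSE}
panel <- gen_strain_panel(scaling_scenario("M63", seed = 1))
est <- analyze_strain_panel(panel)
fit_genome_scaling(est)
fit_growth_mutation(est)
```
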