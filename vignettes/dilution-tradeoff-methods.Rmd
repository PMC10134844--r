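---
title: "Methods: dilution-experiment inference of growth, mortality, and the kill-the-winner trade-off"
author: "killwinner maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dilution-experiment inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(killwinner)
```

## The experimental design and its model

A top-down-control dilution experiment manipulates the mortality that
predators impose on marine bacteria while leaving their growth machinery
untouched. Source seawater is diluted with either 0.22-µm-filtered water
(removes protists and bacteria but **passes viruses**) or 30-kDa-filtered
water (removes viruses too), creating a gradient in which a fraction
*d* ∈ {0.25, 0.50, 0.75, 1.00} of the original top-down-control effect
remains. Bottles are incubated for 12 h; total bacterial density is counted
by flow cytometry at both ends, and community composition is sequenced (16S
amplicons) once at T0 from the shared source water and per bottle at T12.

The package's inference rests on three assumptions:

1. **Exponential, density-independent growth** over the short incubation:
   each taxon's population obeys `N(t) = N(0) exp(r t)`, so the per-capita
   net growth rate (PNGR) is `R = ln(N12 / N0) / 12 h`.
2. **Mortality scales linearly with predator encounter rate**, hence with
   the dilution factor *d*. Under protists+viruses dilution
   `r = g − d (m_P + m_V)`; under protists-only dilution the viruses in the
   diluent keep lysing at full strength, `r = g − d m_P − m_V`.
3. **Relative abundance × total density = absolute abundance.** Reads are
   converted to cells/mL with the duplicate-mean density of the matching
   treatment × dilution cell.

Ordinary least squares of `R` on `d` per taxon × treatment then identifies
the traits: the protists+viruses intercept is the **top-down-control-free
growth rate** (competitiveness, `a = g`), the protists slope is the
**resistance to grazing** (`b = −m_P`), the protists+viruses slope the
**resistance to the combined control** (`c = −(m_P + m_V)`), and the
difference `c − b = −m_V` the resistance to viruses alone. More negative
slopes mean more mortality per unit of control, i.e. less resistance.

On the viral-resistance difference we deliberately use `c − b`: the
mortality algebra above makes `c − b = −m_V ≤ 0`, which keeps the sign
convention of the other two resistances (more negative = more susceptible).
The opposite order is available via
`estimateTraits(..., subtraction_order = "p_minus_pv")` for users who
prefer the difference stated the other way round.

## The kill-the-winner question

The kill-the-winner hypothesis predicts a **competition–resistance
trade-off**: taxa that grow fastest when predation is removed suffer the
highest predator- and virus-imposed mortality, so no taxon can win
permanently and diversity is maintained. The package tests it at three
levels:

* per experiment, Pearson correlation and OLS of resistance on
  competitiveness (`tradeoffPerExperiment()`);
* across experiments, a random-intercept linear mixed model with
  experiment as the grouping factor, fitted by REML through `nlme`
  (`tradeoffLmm()`); the fixed-slope p uses the Wald normal
  approximation — a deliberate simplification over Satterthwaite degrees
  of freedom, adequate at the hundreds of observations the design yields;
* a **permutation null** (`permutationNull()`).

The permutation null deserves explanation. Competitiveness and resistance
come from the *same* regression (protists+viruses) or two closely related
ones, so OLS estimation error couples them mechanically: an overestimated
slope forces an underestimated intercept (`intercept = ȳ − slope·d̄`). A
naive correlation test would mistake this coupling for biology. The null
therefore shuffles each taxon's PNGR values across (dilution factor,
replicate) positions *within the taxon's series*, refits every regression,
re-derives traits, and recomputes the trade-off slope — 1000 times by
default. Because series means are invariant under the shuffle, the
permuted intercept remains `ȳ − slope·d̄`: the null preserves exactly the
mechanical coupling while destroying any real dependence of rate on
dilution. The observed slope is then scored as
`z = (observed − null mean)/null sd`, with a Shapiro–Wilk check that the
null is near-normal (the normal two-sided p is reported alongside an
empirical one). An alternative mode (`perm_mode = "taxa"`) shuffles
resistance values across taxa instead.

One behaviour of the within-taxon null is worth knowing: it destroys *any*
structure of rate over dilution, including mortality that is common to all
taxa. If every taxon carries a large identical mortality (no trade-off,
but strong top-down control), the observed trade-off slope sits near zero
while the null centres on the coupling value, and the test will flag the
difference. The test is therefore calibrated for the hypothesis it is
designed for — distinguishing a *trait-level* trade-off from the
estimation artifact — under generative nulls where mortality carries no
systematic component, which is how the type-I checks in the test suite are
constructed (trade-off slopes `beta_P = beta_V = 0` with only truncated
Gaussian noise on mortality).

## Diversity and composition consequences

Three indices are computed per sample after rarefaction (without
replacement, `vegan::rrarefy`) to a common depth, 3188 reads by default:

* **richness** — the post-rarefaction ASV count;
* **rank-normalised RAD**: `n_norm = 1000` random subsets of
  `target_richness` present taxa (default: the lowest post-rarefaction T12
  richness in the experiment) are renormalised, sorted, and averaged
  rank-wise, making RAD shape comparable across communities;
* **Zipf decay coefficient** — minus the slope of `log p_r` on `log r` of
  the normalised RAD, so larger = steeper dominance. Log–log OLS is the
  default because the averaged RAD is strictly positive and the fit is
  deterministic and exact on pure power laws (the test suite checks decay
  1 on `p_r ∝ 1/r` and 0 on uniform to 1e-10); a nonlinear least-squares
  mode refits on the raw scale when the log transform's weighting is a
  concern. The raw (negative) exponent is always emitted beside the
  positive decay so either sign convention can be read off.
* **Pielou evenness** — Shannon entropy of the normalised RAD over
  `log(ranks)`.

Each index is regressed on the dilution factor per treatment with the same
random-intercept machinery as the trade-off. Composition maintenance is
quantified as the Aitchison distance (Euclidean distance between centred
log-ratio vectors, integer pseudocount 1 on rarefied counts) between every
T12 sample and its experiment's T0, averaged over `n_sub = 100` paired
rarefactions drawn from one reproducible substream; slopes of distance on
dilution are compared between treatments by a pooled interaction ANCOVA
(`distance ~ d × treatment`).

## The synthetic-data generator

`drawTraits()` + `simulateExperiment()` generate complete experiments with
known ground truth. Defaults describe a productive coastal community:
growth `g ~ N(0.10, 0.05²) h⁻¹` truncated at zero; mortalities linear in
growth, `m = α + β g + ε`, with `β_P = β_V = 0.4` (grazing and lysis each
removing ~40 % of production at full strength), `ε ~ N(0, 0.01²)`
truncated at zero rather than resampled (simpler, and the induced atom at
zero mimics genuinely immune taxa); initial abundances lognormal with
sdlog 1.5; read depth 3188; flow-cytometry noise lognormal with CV 0.05.
Initial bottle densities default to 10⁶ cells/mL and are *not* scaled by
the dilution factor — the inoculum is diluted in the real protocol, but
the per-capita formulation cancels the initial density, so the option
(`dilute_inoculum`) exists only for visual realism of the density tables.

Two switches matter for testing. `exact_proportions = TRUE` replaces
multinomial read sampling with exact relative abundances, and
`density_cv = 0` removes density noise; together they make every
downstream estimate a closed-form function of the traits, and the test
suite requires recovery of `(g, −m_P, −(m_P+m_V), −m_V)` to 1e-8 (observed
agreement is at machine precision). All randomness descends from one
master seed through deterministic substreams (`childSeed()`), one per
sample/bottle, so datasets are pure functions of (design, traits) and
independent of evaluation order.

What the generator does **not** emulate: 16S copy-number variation,
compositional bias of PCR/sequencing, density-dependent growth or nutrient
exhaustion within the incubation, predator/virus population dynamics
(mortality pressure is a fixed rate, not a dynamic consumer), and bottle
effects beyond measurement noise. Passing parameter-recovery tests
therefore demonstrates the correctness of the estimation chain under the
stated model, not robustness to these real-data features.

A note on the in-silico kill-the-winner consequence: stronger top-down
control flattening the RAD (evenness rising, decay falling with *d*) is
predicted when growth differentiation outweighs the initial-abundance
heterogeneity. With the default sdlog 1.5 initial abundances the initial
structure can dominate the 12-h signal and the trend direction becomes
seed-dependent; the consequence checks therefore simulate a more even
source community (sdlog 0.5) with a virus-dominated trade-off
(`β_P = 0.15, β_V = 0.65`), where the pattern is robust across seeds.

## Numerical and procedural choices

* **Zero-read filter**: a taxon is dropped from a taxon × experiment ×
  treatment series when *any* constituent sample (T0 or any of the
  treatment's T12 samples) has zero reads for it; retained series have
  strictly positive abundances everywhere, so `ln(N12/N0)` is always
  finite. Series-level filtering keeps regressions balanced across the
  dilution gradient.
* **Replicate handling**: PNGR is computed per replicate bottle (up to 8
  points per regression); `replicate_mode = "mean"` averages duplicates
  first (4 points) for users who prefer cell means.
* **Degenerate regressions**: series with fewer than 3 points or fewer
  than 3 distinct dilution factors are skipped and logged; a perfectly
  flat series reports slope 0 with p = 1 (non-significant by convention),
  a perfect non-flat line p = 0.
* **Mixed-model edge cases**: a single experiment reduces to OLS (flagged
  `single_group_ols`); convergence failures fall back to OLS (flagged);
  fits whose between-experiment sd collapses below 1e-6 of the residual
  sd are flagged `singular` but still reported.
* **Significance**: per-ASV slope p-values are two-sided t-tests,
  uncorrected by default to match the counting style of field reports;
  Benjamini–Hochberg is one flag away.
* **Problem sizes**: the shipped fixture and the test suite use 40-taxon
  communities, the full 2 × 4 × 2 design, and scaled-down repetition
  counts (200 permutations, 100–300 RAD normalisations, 10–50 distance
  subsamples) chosen so the whole suite runs in a few minutes on a
  laptop; the package defaults (1000/1000/100) are what an analysis of a
  real study should use.

## Known limitations

Estimates inherit the detection floor of amplicon sequencing: rare taxa
with zero reads in any required sample are excluded, biasing the retained
set toward abundant organisms. Relative-abundance conversion assumes the
duplicate-mean density represents both bottles. The permutation null's
behaviour under strong common mortality (above) means a significant z is
evidence against "artifact only", not an isolated estimate of trade-off
strength. And the mixed model treats experiments as exchangeable random
intercepts; systematic between-experiment differences in slope are out of
scope (no random-slope variant is provided).
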