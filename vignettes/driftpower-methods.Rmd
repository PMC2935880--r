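---
title: "Methods: two-phase multiethnic GWAS power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-phase multiethnic GWAS power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftpower)
```

## The disease model and the test

`driftpower` works at the level of allele frequencies. A biallelic SNP
with risk-allele frequency $p$ in some population is tested by the 1-df
allelic (allele-count) chi-square comparing case and control risk-allele
frequencies. Under a multiplicative model, carrying $g$ copies of the risk
allele multiplies disease risk by $\mathrm{GRR}^g$; Bayes' rule then gives
the case frequency

$$p_\text{case} = \frac{p\,\mathrm{GRR}}{p\,\mathrm{GRR} + 1 - p},$$

and, under the rare-disease approximation used by default, controls keep
the population frequency, $p_\text{control} = p$. A useful fact about the
multiplicative model is that case genotypes remain in Hardy–Weinberg
proportions at $p_\text{case}$, so the allelic test's $2N$ alleles are
exchangeable and the familiar two-proportion non-centrality applies:

$$\mathrm{NCP} \;=\; \frac{(p_\text{case} - p_\text{control})^2}
 {\bar p(1-\bar p)\left(\tfrac{1}{2N_\text{case}} +
 \tfrac{1}{2N_\text{control}}\right)},$$

with $\bar p$ the sample-size-weighted pooled frequency *under the
alternative*. That pooling choice is the common NCP approximation and is
exactly what the package's Monte-Carlo oracle validates
(`monte_carlo_power()` simulates genotypes and computes the Pearson
allelic chi-square per replicate). Power is the upper-tail mass of the
noncentral chi-square beyond the central upper-$\alpha$ quantile.

Two properties carry the whole design machinery:

* **Additivity.** NCP is exactly linear in sample size at fixed
  frequencies, so the evidence of every (phase, panel) arm of a two-phase
  study adds: $\mathrm{NCP}_\text{total} = \sum_\text{arms}
  \mathrm{NCP}_\text{arm}$, each arm evaluated at its own population's
  frequency. This models collaborative designs where genome-wide data
  from both phases are *combined* — deliberately not a thresholded
  two-stage replication design, which would carry only a subset of SNPs
  into phase 2.
* **Orientation averaging.** `snp_power()` averages the power obtained by
  treating each allele in turn as risk-increasing, which removes the
  arbitrary choice of which allele "is" the risk allele when scanning a
  whole frequency table.

### Assumptions worth keeping in mind

* The effect (GRR) is **fixed across populations**. Heterogeneous or
  population-specific effects would erode the computed gains.
* **No linkage disequilibrium** between tag and causal variants is
  modelled: frequencies refer to the tested variant itself. If tagging
  differs strongly between populations, realized power will be lower than
  computed.
* Cases and controls are drawn from the same population (no
  stratification artefacts), and HWE holds within each population.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `grr` | — | genotype relative risk per allele copy (unitless, > 0; values < 1 are equivalent to re-orienting the allele) |
| `prevalence` | `NULL` | disease prevalence; when supplied, controls are the population minus cases at that prevalence instead of the rare-disease shortcut |
| `alpha` | 5e-8 discovery, 0.05 replication | significance threshold of the chi-square test |
| `df` | 1 | test degrees of freedom (the allelic test) |
| `target`, `n_cap` | 0.80, 150 000 | replication power target and the largest total N searched |
| `divergence` (F) | — | Balding–Nichols drift of a synthetic panel from the ancestral pool; an $F_{ST}$ analogue. 0.005–0.02 behaves like closely related panels, 0.10–0.15 like continental separation |
| `chromosomes` | 0 (exact) | founder chromosomes per panel for finite-sample frequency estimates; 100 mimics 50 founders |
| `min_maf` | — | array-like ascertainment cut on the reference panel's MAF; 0.01 mimics genotyping arrays, 0 mimics sequencing |

MAF strata default to monomorphic / (0, 1%) / [1%, 5%] / (5%, 10%] /
(10%, 50%], anchored to a reference panel (CEU by convention); "1–5%" is
the low-frequency band the package's summaries emphasise.

## What the synthetic generator emulates — and what it does not

`simulate_panels()` draws an ancestral frequency $q$ per SNP (by default
from a $1/x$ density on $[0.001, 0.999]$, a neutral-like spectrum with an
excess of rare alleles) and drifts each panel independently
(star topology) through
$\mathrm{Beta}\!\left(q\tfrac{1-F}{F},\,(1-q)\tfrac{1-F}{F}\right)$,
which is mean-preserving with variance $F\,q(1-q)$. On top of that,
`apply_ascertainment()` imposes the array bias toward variants common in
the reference panel, and `estimate_from_founders()` replaces true
frequencies by binomial draws on a fixed chromosome count, reproducing
both the discreteness of real frequency estimates and the loss of rare
alleles (a $p = 0.005$ allele is missed entirely with probability
$(1-0.005)^{100} \approx 0.606$ on 100 chromosomes).

This captures the mechanism that drives multiethnic power gains:
conditioning on a *low observed* frequency in panel A selects alleles
whose ancestral frequency is higher than the observation suggests, so an
independently drifted panel B shows them, on average, at higher frequency
— and power rises steeply with frequency in the 1–5% band. Passing tests
on this generator therefore demonstrate the frequency arithmetic, not
realistic human genetics: there is no site frequency spectrum fitted to
data, no shared drift topology (real continental panels are correlated),
no admixture (a mixture extension is deliberately left out of the
defaults), no LD, and no allele-calling error. Results on real frequency
tables are obtained by supplying them via `read_frequency_table()`
(native TSV or VCF plus a sample-to-panel map).

## Numerical choices

* **Tails via survival functions.** Power is always computed as
  `pchisq(..., lower.tail = FALSE)`, never `1 - CDF`, so genome-wide
  $\alpha = 5\times10^{-8}$ keeps full relative precision. At
  $\mathrm{NCP} = 0$ the size $\alpha$ is returned exactly rather than
  through the quantile round trip.
* **Approximation accuracy.** The noncentral chi-square tail matches the
  1-df normal decomposition $\Phi(\sqrt{\mathrm{NCP}} - z) +
  \Phi(-\sqrt{\mathrm{NCP}} - z)$ to better than $10^{-10}$. Against the
  genotype-level oracle the analytic power is accurate to a few parts in
  $10^{3}$ at the design grid; the residual is the known $O(1/N)$
  conservativeness of the chi-square approximation at small minor-allele
  counts and extreme tails, which is why the acceptance check pools
  several independent 50,000-replicate oracle runs — it sharpens the
  comparison onto the approximation error itself instead of simulation
  noise.
* **Replication solver.** `required_sample_size()` brackets and bisects
  the monotone power-in-N function over even totals (1:1
  cases:controls), returning the minimal even N with
  $\text{power}(N) \ge 0.8 > \text{power}(N-2)$; p ∈ {0, 1} is reported
  as monomorphic (no N exists) and targets unreachable at the 150,000 cap
  report the power at the cap instead.
* **Tie-breaks and conventions.** The minor allele is defined in the
  reference panel with ties at exactly 0.5 broken toward `allele_a`;
  cross-panel frequency comparisons track that *anchored* allele in both
  panels, which operationalises "ignoring allele flips". The "equal"
  frequency class uses exact equality by default (finite-chromosome
  estimates make exact ties common); a tolerance knob exists.
  `split_equal()` distributes phase-2 totals evenly with remainders to
  the earliest panels — the equal split is a documented default, since a
  multiethnic phase's proportions are a free design choice. Difference
  histograms use half-open bins $[lo, hi)$ of width 0.05.
* **Degenerate inputs.** Monomorphic SNPs contribute NCP 0 (power =
  $\alpha$); empty arms contribute 0; a zero-size phase 2 reduces the
  scenario to phase 1; multiallelic VCF records are rejected with a
  counted warning rather than split, keeping the two-allele invariant
  (`freq_b = 1 - freq_a`) global.

## Design choices where the design was open

* **Test parameterisation.** The allele-count chi-square with the
  rare-disease control approximation is the default; an exact-prevalence
  mode exposes the one unobservable (`effect_model(grr, prevalence = K)`).
  The two agree in the small-K limit and the prevalence mode enforces
  penetrance ≤ 1.
* **Reference study conditions.** The packaged synthetic study uses
  50,000 SNPs, two panels at F = 0.15, ascertainment at 1% reference MAF,
  GRR 1.2 and a 20,000-sample two-phase design (5,000/5,000 per phase) —
  sizes at which stratum means are stable to well under a percentage
  point while the whole pipeline (and its acceptance script) runs in
  seconds. The fabricated replication catalog uses 189 records over 182
  unique SNPs (7 reported for two traits), odds ratios uniform on
  [1.1, 1.3] and risk-allele frequencies uniform on [0.05, 0.5], the
  typical reported-association regime.
* **Gain attribution.** The positive-gain claim in the package's
  acceptance checks is asserted for frequency elevations between +15% and
  +40% of the anchored minor allele. Beyond +0.40 the anchored allele has
  usually drifted past 0.5 in the other panel (allele-flip territory),
  bins are sparse, and the sign of the mean change is not stable — so no
  claim is made there.

## Known limitations

* Power for *rare* variants (MAF < 1%) inherits both the chi-square
  approximation's small-count bias and, with 100-chromosome estimation,
  severe frequency-estimation noise; treat those strata qualitatively.
* The NCP sum assumes independent arms; overlapping samples or shared
  controls would require an explicit covariance treatment.
* `gain_by_difference()` attributes power change to frequency difference
  alone; with heterogeneous effects or differential tagging the
  attribution would be confounded.
* The CLI writes frequencies at 6 decimals; round-tripping through TSV
  is exact at that printed precision, not at full binary precision.
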