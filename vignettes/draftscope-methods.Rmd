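---
title: "Null variances, genetic draft, and SNP outlier tests: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null variances, genetic draft, and SNP outlier tests: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

`draftscope` analyses short-term evolve-and-resequence experiments in
which replicate plant populations descend from one outbred ancestor and
evolve for a handful of generations under different mating regimes —
obligate self-fertilization after pollinator loss versus bee-mediated
outcrossing — before each population is pooled (here, 100 plants) and
sequenced. The central quantity is the **null variance** $v$ of a
lineage: the variance of the change in angular-transformed allele
frequency,

$$x = 2 \sin^{-1}\sqrt{p},$$

accumulated over the experiment. On this scale the binomial sampling
variance of a frequency estimated from $m$ reads is $\approx 1/m$
independent of $p$, and neutral Wright–Fisher change over $t$
generations has variance

$$\mathrm{Var}(\Delta x) \approx \frac{t}{2N_e} + \frac{1}{2n} + \frac{1}{m},$$

where $n$ is the number of diploids bulked into the pool and
$N_e = N/(1+F)$ shrinks with the inbreeding coefficient $F$. The null
variance aggregates genetic drift, genetic *draft* (stochastic change at
neutral sites dragged by selection at linked loci — greatly amplified
when selfing suppresses effective recombination), and the pool-bulking
sampling round.

# Estimating null variances from pooled counts

Without an ancestral sample, per-lineage variances are identified from
the six pairwise divergences of four populations: under independent
evolution, $\mathrm{Var}(x_A - x_B) = v_A + v_B$. The pipeline
(`estimate_null_variances()`):

1. **Robust pairwise dispersion.** Per pair, the dispersion of
   $d = x_A - x_B$ across SNPs is estimated by a robust Gaussian scale
   statistic, by default $(\mathrm{IQR}/1.349)^2$, so that a minority of
   loci responding to selection does not inflate the estimate; the mean
   read-depth term $\overline{1/m_A + 1/m_B}$ is subtracted and the
   result floored at zero. A MAD-based alternative is selectable; the
   cited antecedent procedure is not specified at formula level, so the
   estimator is a configurable design choice.
2. **Block bootstrap.** The genome is cut into consecutive 500-SNP
   windows (final short window kept); resampling windows with
   replacement 1000 times yields the $6\times 6$ covariance $V$ of the
   pairwise divergences, which respects local linkage.
3. **Generalized least squares.** With $X$ the $6\times4$
   pair–population incidence matrix,
   $\hat v = (X^\top V^{-1} X)^{-1} X^\top V^{-1} y$. (The transpose
   appears in both factors — the standard GLS estimator; negative
   components are floored at zero with a warning.) $X$ has full column
   rank, so any consistent $y = Xv$ is recovered exactly.
4. **Intragenomic variability.** The same pipeline run per chromosome
   gives a matrix of per-chromosome $\hat v$; their coefficient of
   variation ($100\,\mathrm{sd}/\mathrm{mean}$) measures heterogeneity
   that chromosome-specific linked selection inflates above the neutral
   expectation. Chromosomes with fewer than 500 usable SNPs are
   excluded.

`typical_delta_p()` translates $v$ into an interpretable frequency
change by adding $\sqrt v$ on the angular scale and back-transforming;
with the package defaults this reproduces, from the four published null
variances, typical changes of 0.24, 0.40, 0.06 and 0.08 from
$p_0 = 0.5$.

# Filtering and diversity

`filter_snps()` applies the published rules sequentially: at least 50
reads in every population; total depth (summed over pools) at or below
the 95th percentile of the post-depth-filter distribution; minor allele
frequency at least 5% in at least one population; optional site
whitelist. Each SNP is tallied at the first rule that removes it. The
quantile rule is relative, so strict re-application always trims again;
the computed absolute cap is therefore reported and can be passed back
(`depth_cap=`) for reproducible re-filtering.

`windowed_pi()` sums per-SNP read heterozygosity
$\frac{m}{m-1}\,2\hat p(1-\hat p)$ over 50-kb windows and divides by the
window width; the $m/(m-1)$ factor unbiases sampling reads with
replacement (the reference analysis does not state its correction; this is
the package's choice). `pairwise_fst()` is a ratio-of-averages
identity-based estimator with both pool-seq sampling stages corrected
($m/(m-1)$ for reads, $2n/(2n-1)$ for the finite pool); it is validated
by property tests (0 for identical pools, 1 for fixed opposite alleles,
symmetry, agreement with a per-locus oracle), not against any published
empirical value, which would require the archived raw reads.

# The forward simulator

`run_replicate()` evolves diploid individuals at
$14 \times 2000 = 28{,}000$ linked SNPs (the karyotype of the study
species; both dimensions configurable). Founders are drawn at linkage
equilibrium from the ancestor frequencies (one Bernoulli draw per allele
copy). Each meiosis places, per chromosome, a single obligate crossover
at a uniformly chosen internal inter-SNP interval, with a random
starting haplotype. Note a consequence of the obligate crossover: the
two ends of a chromosome always derive from different parental
haplotypes (recombinant fraction 1 between the ends, $1/(L-1)$ between
adjacent SNPs). Seed parents are sampled proportional to relative
fitness (uniformly when neutral); pollen parents equal the seed parent
under selfing or are sampled independently under outcrossing. Selection
uses genotype fitnesses $1$, $1+hs$, $1+s$ multiplied across loci, with
defaults $s = 0.8$, $p_0 = 0.02$, and $h = 0.5$ — the dominance is not
stated in the reference analysis and matters little under full selfing, where
homozygotes dominate after the first generations. Runs with selection
are conditioned on every favored allele exceeding frequency 0.5 at
generation $t$ by whole-replicate rejection. A pooled-sequencing layer
grows `pool_n` offspring from the final generation (the bulked-seed
round), then draws Poisson($\bar m = 75$) read depths and binomial read
counts.

## Measuring the null variance of a replicate

Within a replicate the package computes the dispersion of
$\Delta x = x_{\text{final}} - x_{\text{ancestor}}$ across SNPs. For
simulation summaries the default estimator is the **plain variance**,
not the robust IQR scale, for two reasons. First, a neutral replicate
contains no selected outliers, so robustness buys nothing. Second,
under strong selfing at small $N$ the distribution of $\Delta x$ across
SNPs is strongly multimodal (few surviving lineages), and the
IQR-implied Gaussian scale overstates the variance by ~50% there; the
plain variance is the statistic whose replicate mean matches the
analytic drift accumulation and — decisively — back-computes the four
published calibration anchors (population sizes 43 and 13 for the
selfing null variances 0.2554 and 0.8545; 366 and 219 for the
outcrossing 0.0138 and 0.0235) from this package's own simulations.
Measured against the input ancestor frequencies, the replicate variance
includes the founder-sampling round $1/(2N)$, which those anchors also
require.

## Calibration

`calibrate_N()` grid-searches the census size whose mean replicate null
variance is closest to an observed target (ties toward smaller $N$).
The default mode measures population frequencies **without** the pool
and read-depth layers: the published outcrossing anchors equal
$(t+1)/(2N)$ with no $1/(2n)$ term, indicating that the original
calibration compared population-level simulated frequencies to the
observed null variances. The pooled mode (`use_pool = TRUE`) remains
available and is reported alongside in the acceptance suite.

# The nine-model outlier framework

Each SNP is scored under nine Gaussian models on the angular scale that
partition the four populations into groups sharing a frequency
parameter: drift (one group); adaptation in each single population
(four models); treatment parallelism; two three-group refinements; and
full independence. Group MLEs are inverse-variance weighted means
clipped to $[0, \pi]$ (a bounded numerical optimizer is unnecessary —
the closed form is checked against a grid-search oracle in the tests).
The per-population variance is $v_i + 1/m_i + 1/(2n)$: including the
pool term reproduces the published neutral model-support profile
(~59% drift support, ~1.5% for the three most complex models) in this
package's own neutral simulations, resolving the reference analysis's ambiguity
about the likelihood's ingredients. Support is compared by
$\mathrm{AIC} = 2k - 2\mathrm{LL}$ with ties toward the simpler model;
where drift is not the AIC-best model, a likelihood-ratio test against
drift with $k-1$ degrees of freedom is evaluated against the Sidak
threshold $1 - (1-\alpha)^{1/M}$ at $\alpha = 0.05$ (the reference analysis labels
this FDR; the formula is family-wise, and a Benjamini–Hochberg option
is provided for users who want an actual FDR).

# The synthetic-data generator

`generate_experiment()` emulates the experiment's statistical
structure: an ancestor built from three F1 families — every SNP carried
by 12 grandparental haplotypes, so ancestor frequencies sit on the
lattice $\{1/12, \dots, 11/12\}$ conditioned on polymorphism, with
per-SNP base frequencies drawn uniformly on $[0.1, 0.9]$ (the true
founder spectrum of the experiment depends on unpublished genotypes;
this is a stated assumption, not a reconstruction) — then four
independently evolving populations (defaults: selfing at $N = 43$ and
13, outcrossing at 366 and 219, nine generations), pooled sequencing,
and a truth record of seeds and realized parameters sufficient for
bit-identical regeneration. What it does **not** emulate: founder
linkage disequilibrium (founders are drawn at linkage equilibrium;
real founders carry six generations of selection-line history),
background selection from deleterious load, partial selfing, mutation,
or seed-mass evolution. A green end-to-end test therefore establishes
internal consistency of the estimators with the simulator's
assumptions, not faithfulness to every feature of the real data.

# Numerical and design notes

* $t = 9$ generations everywhere; the extra generation grown only for
  sequencing is treated as the pool-sampling round, not drift.
* Negative variance estimates are floored at zero and logged, never
  propagated.
* Bootstrap windows are consecutive 500-SNP runs in genome order; the
  final short window is kept.
* AIC ties break toward the lower model id; GLS falls back to a
  pseudo-inverse with a warning when $V$ is singular.
* Coordinates are 1-based; diversity windows are half-open
  `[start, start + 50000)` starting at 1; BED export is 0-based
  half-open.
* All randomness flows through R's RNG (including the C++ kernel, which
  uses the R generator), so a single `set.seed()` reproduces any result
  bit-identically; the pipeline derives and records per-stage sub-seeds.
* The acceptance suite runs reduced replicate ensembles (documented in
  `scripts/acceptance.R`) to fit a single-CPU budget; grid resolution
  and genome structure are kept at full scale except where noted.

# Known limitations

* Pool-seq FST uses a two-stage identity-based estimator; exact
  agreement with other pool-seq FST software is not a goal.
* The robust pairwise divergence assumes a mostly neutral genome; in a
  genome where a large fraction of SNPs respond to selection the
  subtraction logic underestimates nothing but the "null" label becomes
  moot.
* With very small selfing populations the GLS null variances inherit
  the IQR estimator's bias under multimodality (the same effect that
  motivates the plain-variance default for simulation summaries); the
  outlier tests remain internally consistent because the same estimate
  enters the likelihood.
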