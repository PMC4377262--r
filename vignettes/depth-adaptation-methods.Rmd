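---
title: "Methods: inferring local adaptation between shallow and mesophotic populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: inferring local adaptation between shallow and mesophotic populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific question

Sessile marine invertebrates such as the Mediterranean red coral occupy
depth gradients along which temperature regimes differ sharply: shallow
(~20 m) habitats are warmer and more variable than mesophotic (~40 m) ones.
Whether populations a hundred metres apart along such a gradient are
interchangeable — so that deep populations could replenish disturbed shallow
ones — or locally adapted is a quantitative question with two sides:

* **Neutral differentiation.** How much allele-frequency divergence do
  neutral markers (microsatellites) show between depth samples? This is
  summarised by Weir–Cockerham's $\theta$, an estimator of $F_{ST}$.
* **Phenotypic differentiation.** How much of the variance of a
  fitness-related trait (growth, thermal necrosis) lies among samples?
  This is summarised by $P_{ST}$, the phenotypic analogue of $Q_{ST}$.

Divergent selection is suggested where $P_{ST}$ significantly exceeds the
neutral reference. `margadapt` implements both sides plus the supporting
statistics (diversity tables, differentiation tests, distance phenograms,
linkage-disequilibrium effective population size, permutational ANOVA of
transplant designs) and a synthetic-data module that generates data with
the same structure so that every estimator can be validated end to end.

# Genetic statistics

## Diversity

Per sample and locus the package reports observed heterozygosity $H_o$
(fraction of heterozygous individuals among those typed) and Nei's
unbiased gene diversity
$$H_e = \frac{2n}{2n-1}\Bigl(1 - \sum_u p_u^2\Bigr),$$
with $n$ the typed diploids. The unbiased small-sample factor is used
because microsatellite tables are routinely reported that way; the plug-in
version is never larger, and the two agree as $n \to \infty$.

Allelic richness is rarefied hypergeometrically to a standard number of
gene copies $g$:
$$Ar(g) = \sum_u \Bigl[1 - \binom{N - N_u}{g} \Big/ \binom{N}{g}\Bigr],$$
the expected number of distinct alleles in a random subsample of $g$ of
the $N$ typed copies. $g$ is a count of genes (64 genes = 32 diploids);
the default is twice the smallest per-locus diploid count over samples so
every locus qualifies.

Departure from panmixia is measured by the Weir–Cockerham within-sample
$f$ ($F_{IS}$), a ratio of sums of the within-sample variance components
over loci and alleles. Its null distribution is obtained by re-pairing the
pooled gene copies within sample and locus, which enforces Hardy–Weinberg
proportions at fixed allele frequencies; the two-sided p-value uses $|f|$
with the add-one rule $p = (1 + \#\{|f^*| \ge |f|\})/(1 + n_{perm})$.
The classical software for these tests uses a Markov-chain exact approach;
this package deliberately substitutes seed-reproducible Monte-Carlo
permutation against the same null, and says so here rather than claiming
numerical identity with that software.

Batteries of Hardy–Weinberg and linkage tests are corrected with the
Benjamini–Hochberg step-up FDR (`fdr_adjust()`, backed by
`stats::p.adjust`), the default meaning of "FDR correction" in this
literature.

## Differentiation

`wc_theta()` computes the Weir–Cockerham (1984) estimator from the
hierarchical variance components $a$ (among populations), $b$ (among
individuals within populations) and $c$ (within individuals), per locus
and allele, with locus-specific sample sizes (missing genotypes reduce
$n_i$ only where they occur). The multilocus estimate is the ratio of
summed components $\sum a / \sum(a+b+c)$ — never an average of per-locus
ratios — which is the convention of the standard $F$-statistics programs.
The 95% CI resamples loci with replacement (percentile 2.5/97.5 bounds,
default 1000 replicates); per-locus components are computed once and only
re-summed, so the CI is cheap. A single informative locus yields a
degenerate CI with a warning. No null-allele (ENA-style) correction is
applied: the intended workflow is to pre-filter loci with suspected null
alleles, and the output therefore describes observed genotypes; this is a
documented limitation, and the synthetic-data module can generate null
alleles to study the resulting bias (they depress $H_o$ and inflate $f$).

Genotypic differentiation uses a per-locus log-likelihood-ratio $G$
statistic on the genotype-by-population table, combined over loci by
summing $G$ (a Fisher combination of per-locus permutation p-values is
available), with individuals permuted among populations.

Among-sample distances use Nei et al.'s (1983)
$D_a = 1 - \tfrac{1}{L}\sum_l \sum_u \sqrt{x_u y_u}$, and the phenogram is
Saitou–Nei neighbor joining (via **ape**). Negative NJ branch lengths —
possible on non-additive distances — are clamped to zero with the deficit
transferred to the adjacent branch, preserving total tree length; raw
branches are available with `clamp_negative = FALSE`. Node support is a
bootstrap over loci.

## Effective population size

`ldne_estimate()` implements the linkage-disequilibrium method under
random mating: Burrows' composite disequilibrium $\hat\Delta$ between
allele pairs at different loci (no phase assumed), squared correlation
$$\hat r^2 = \hat\Delta^2 \big/ \bigl[(p(1-p) + D_A)\,(q(1-q) + D_B)\bigr],$$
with $D_A$ the within-locus Hardy–Weinberg disequilibrium and the
$n/(n-1)$ small-sample factor on $\hat\Delta$. The composite denominator
makes the self-correlation of a duplicated locus exactly one (up to that
factor), and the factor itself is required for the estimator to match the
published sampling expectation below — both points are verified in the
test suite. Alleles rarer than the screening cutoff (default 0.02) are
dropped; when no allele of a locus is dropped, the most frequent one is
removed instead because its comparisons are linearly redundant (a
biallelic locus contributes one comparison). The weighted mean $r^2$
(weights = comparisons per locus pair; an unweighted mean is available for
sensitivity checks) is corrected by the sampling expectation
$E[r^2] = 1/S + 3.19/S^2$ for $S \ge 30$ (and the published $S < 30$
variant), at the weighted harmonic-mean sample size $S$, and mapped to
$$\hat N_e = \frac{1/3 + \sqrt{1/9 - 2.76\,\hat r^2_{drift}}}{2\,\hat r^2_{drift}}.$$
A non-positive drift component gives a negative estimate, reported as-is:
it means no drift signal is detectable at this sample size, and the upper
confidence bound is infinite. The 95% CI is a delete-one jackknife over
locus pairs on the weighted mean $r^2$, mapped through the same formula
(the upper $r^2$ bound gives the lower $N_e$ bound). The original LDNe
program's pair weighting has undocumented edge cases; this package
documents its own weighting exactly as above instead of claiming numeric
identity. Under the null (very large parental populations) the mean drift
component of this implementation is zero to within Monte-Carlo error, and
on one-generation Wright–Fisher cohorts bred from 50 parents the median
estimate over replicates sits in the correct range (both are acceptance
properties of the test suite).

# Phenotype statistics

## Permutational ANOVA

Transplant designs are analysed with univariate PERMANOVA on Euclidean
distance. For a univariate response the pseudo-$F$ of every term equals
the classical ANOVA $F$ exactly (this identity is an oracle test), but
p-values come from permutation (default 9999), avoiding normality
assumptions. Main effects permute raw observations; the interaction
permutes residuals of the reduced additive model (fitted additive values
held fixed), a standard scheme chosen because the original analysis
software does not document its own. Sums of squares are Type I on
balanced data; unbalanced crossed designs are refused rather than silently
re-weighted, because crossed-factor sums of squares lose order-invariance
without balance and the designs this analysis targets are balanced by
construction. Experimental plates are not modelled as a nested random
factor — a listed limitation. The trait analysed per colony is the mean
of the $k$ largest growth distances (default $k = 10$) from the calcein
mark to the section periphery; for necrosis series, the final level.

## P_ST versus F_ST

The core comparison. With among- and within-sample variance components
$\sigma^2_B$ and $\sigma^2_W$ (one-way method-of-moments estimates;
$\sigma^2_B = \max(0, (MS_B - MS_W)/n_0)$ with the standard unbalanced
$n_0$; negative moment estimates truncated so $P_{ST} \in [0,1]$):
$$P_{ST}(r) = \frac{r\,\sigma^2_B}{r\,\sigma^2_B + 2\sigma^2_W},
  \qquad r = c/h^2,$$
where $h^2$ is the assumed within-population narrow-sense heritability
and $c$ the assumed additive-genetic proportion of among-population
variance. At the null assumption $r = 1$, $P_{ST}$ plays the role of
$Q_{ST}$. Because $c$ and $h^2$ are unknowable for wild, slow-maturing
species, the whole curve over the conservative range $0 < r \le 1$ is
reported (200 log-spaced grid points on $(0.001, 1]$, always containing
$r = 1$).

Confidence bands resample individuals with replacement within each sample
(sizes preserved; default 1000 replicates; percentile bounds — the
simplest interval given that nothing more specific is prescribed for this
analysis). Replicates with zero within-sample variance everywhere are
degenerate ($P_{ST} \equiv 1$), counted, and flagged if above 1% of
draws. Since every bootstrap draw of the curve is monotone in $r$, the
percentile band is monotone too, which keeps the sensitivity analysis
well-behaved.

"Significantly higher than $F_{ST}$" is operationalised as the lower 95%
bound of $P_{ST}(1)$ exceeding the reference point value — the upper 95%
bootstrap bound of $\theta$, or an external low-polymorphism $F_{ST}$
anchor (default 0.1) used as a conservative upper neutral reference. This
is the conservative reading of comparing intervals. The sensitivity
statistic $(c/h^2)_{crit}$ is the smallest $r$ whose lower bound clears
the reference, linearly interpolated between bracketing grid points;
comparisons with $(c/h^2)_{crit} < 0.2$ are flagged robust, following the
published guideline that small critical ratios make the inference of
divergent selection insensitive to the unknown genetic architecture.
$(c/h^2)_{crit}$ is monotone in the reference by construction.

# The synthetic-data module

The generators exist so every stage is testable without any download, and
their defaults are fixed at the study design the package targets:

* **Genotypes**: 4 populations of 43, 43, 42 and 45 diploids at 7
  microsatellite loci, 12 alleles per locus, island-model differentiation
  at $F = 0.1$. Frequencies follow the Balding–Nichols construction
  (ancestral simplex from a symmetric Dirichlet; population frequencies
  from $\mathrm{Dir}(p_{anc}(1-F)/F)$), chosen because the pipeline needs
  a controllable $\theta$, not demographic realism. Optional inbreeding
  (autozygosity probability) and null alleles (hidden allele whose
  carriers look homozygous and whose homozygotes are missing) exercise
  the diversity statistics. Microsatellite mutation is not modelled.
* **Wright–Fisher cohorts** for $N_e$ recovery: a parental pool of
  `true_ne` diploids, each offspring from a freshly drawn random parent
  pair.
* **Transplant growth**: balanced 2×2 origin-by-treatment design, 10
  colonies per cell, cell means (mm) implementing a local-vs-foreign
  pattern with residual variance 4.1e-4, matching the scale of
  calcein-derived growth increments.
* **Common-garden necrosis**: hourly temperature series (seasonal
  sinusoid plus anomaly); necrosis begins once cumulative degree-hours
  above 24 °C exceed an origin-specific lag and then grows with an
  origin-specific slope (lognormal colony-level heterogeneity), capped at
  100%; survival is final necrosis below 100%. This is a phenomenological
  threshold model, not a physiological one; its default contrast between
  origins is sharper than field outcomes (the default mesophotic cohort
  loses essentially all colonies), which is sufficient for exercising the
  one-way analysis and survival summaries but should not be read as a
  calibrated mortality model.

What passing tests on these generators show — and do not show: they
validate the estimators against known generating parameters under clean
island-model and normal-error assumptions. Real microsatellite data add
null alleles, allele-size homoplasy and departures from the island model;
real phenotypes add plate effects, measurement error and non-normal
errors. The statistical machinery is agnostic to these, but parameter
recovery rates quoted here should not be extrapolated to field data.

# Numerical and design choices

* Permutation p-values always use the add-one rule, so $p \ge
  1/(n_{perm}+1)$ and a fixed seed reproduces every p-value exactly.
* One global seed is expanded into fixed per-stage child seeds
  (`child_seed()`, a linear-congruential fold kept below $2^{31}$), so
  pipeline stages can be rerun in isolation and a rerun with the same
  inputs and seed is bit-identical.
* GENEPOP parsing auto-detects 2- versus 3-digit allele codes from the
  genotype field width (overridable), treats `00`/`000` as a whole-call
  missing (no half-missing calls), accepts `pop` in any capitalisation,
  and is insensitive to line-ending style. Individual ids need not be
  unique; the internal key is (population, row). No file encoding is
  assumed beyond ASCII-compatible text.
* Degenerate inputs are explicit: all-monomorphic loci give an
  undefined-$\theta$/-$f$ error; a constant PERMANOVA response reports
  $F = 0$, $p = 1$; both variance components zero is an undefined-$P_{ST}$
  error; $S < 10$ refuses the $N_e$ estimate.
* Validation problem sizes (the package's own choice of simulation
  scale): theta recovery uses 2×50 diploids × 20 loci × 100 replicates
  per $F$; PERMANOVA calibration 1000 null datasets × 999 permutations;
  component recovery 500 datasets of 10×40 observations; $N_e$ recovery
  50 cohorts of 50 at 30 loci. The full suite runs in a few minutes on
  one core.

# Known limitations

* $\theta$ is computed on observed genotypes; null-allele bias must be
  handled by locus filtering upstream.
* Only univariate (single-trait) PERMANOVA; no dispersion (PERMDISP)
  test; no repeated-measures model for necrosis series.
* $c$ and $h^2$ are not estimated from data — the sensitivity analysis
  over $c/h^2$ is the honest substitute.
* The jackknife for $N_e$ is over locus pairs only (no
  individual-resampling interval).
* Bayesian clustering (STRUCTURE-style connectivity) is out of scope.
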