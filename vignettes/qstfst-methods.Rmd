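---
title: "Comparing quantitative-trait and neutral-marker differentiation: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing quantitative-trait and neutral-marker differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qstfst)
```

## The question and the model

Populations drift apart even without selection. A quantitative trait whose
among-population differentiation (Q~ST~) exceeds what neutral markers show
(F~ST~) is a candidate for divergent selection; one that diverges less is a
candidate for stabilizing (uniform) selection. This package implements that
comparison for a full-sib common-garden design: plants from many wild
populations, grown as two sibs per family in randomized containers, with a
panel of neutral multi-allelic markers genotyped on the same material.

Three models carry the analysis:

1. **Marker differentiation.** The Weir–Cockerham (1984) estimator treats
   each allele of each locus as a binary character and partitions its
   variance into among-population ($a$), between-individual-within-population
   ($b$) and within-individual ($c$) components from allele frequencies,
   observed heterozygote frequencies, and per-locus sample sizes.
   The multi-locus estimate is the ratio of sums
   $\hat\theta = \sum a / \sum (a+b+c)$ over loci and alleles, which weighs
   loci by their information content and is the field's standard. Monomorphic
   loci contribute $0/0$ and are skipped; negative estimates (sampling noise
   around zero) are reported as computed. Missing calls are dropped per locus,
   so sample sizes are per-locus. Significance comes from permuting
   *individuals* (both alleles together, preserving within-individual
   disequilibrium) among populations, with the add-one estimator
   $p = (1+\#\{\theta^* \ge \hat\theta\})/(n_{perm}+1)$.

2. **Trait variance components.** Per trait,
   $$y = \mu + \mathrm{pop} + \mathrm{family(pop)} + \mathrm{block} + \varepsilon,$$
   all random effects independent, zero-mean, homoscedastic; fitted by REML
   with non-negativity at the boundary. Because families are full sibs, the
   family variance estimates half the additive variance, giving
   $h^2 = 2V_w/(V_w+V_{res})$ and Spitze's
   $Q_{ST} = V_b/(V_b + 2h^2(V_w+V_{res}))$. When $h^2$ comes from the same
   fit this reduces algebraically to $V_b/(V_b+4V_w)$; the package checks the
   two forms against each other. $h^2$ is estimated once per subspecies from
   all families — the same shared value enters every pairwise $Q_{ST}$ — and
   estimates above 1 (possible with noisy full-sib components) are reported
   with a warning rather than clamped, because clamping would silently change
   $Q_{ST}$.

3. **The neutral null.** Under neutrality with deme-level drift, the expected
   among-population additive variance is $2F/(1-F)\,V_A$ with
   $V_A = 2V_w$, which makes $E[Q_{ST}] = F_{ST}$. The null distribution of
   the observed difference $Q_{ST}-F_{ST}$ is simulated per trait:
   resample loci with replacement and recompute $\hat\theta$ ($F_{sim}$);
   simulate a trait dataset on the *observed design* with among-population
   variance $2F_{sim}/(1-F_{sim})\,\hat V_A$ and the fitted within-population
   components; re-estimate the components of the simulated values by the same
   REML machinery; record $Q_{sim}-F_{sim}$. Drawing only $n_{pops}$
   population effects makes the realized among-deme variance fluctuate as
   $\chi^2_{d}/d$ with $d = n_{pops}-1$, so deme sampling is represented
   without an explicit scaling term. The two-tailed add-one p-value
   compares the observed difference against this sample.

## Why the null re-estimates components

A tempting shortcut evaluates $Q_{sim} = V_b^{neutral}/(V_b^{neutral}+2V_A)$
algebraically from the drawn $V_A$. But $V_A$ then cancels:
the null reduces to a function of $F_{sim}$ and the $\chi^2$ draw alone, and
carries none of the estimation noise that the observed $\hat Q_{ST}$ has.
In our fully neutral end-to-end simulations (8 populations × 10 families ×
2 sibs) that shortcut produced a null about three times too narrow and a
42% rejection rate at $\alpha=0.05$. Re-estimating the components of each
simulated dataset — the modification this package adopts — restores nominal
behaviour: at the study's scale (8 populations × 25 families × 2 sibs) the
measured type-I error is 0.05–0.06. The costly refits are cached
(default 1,000) and the cache resampled to the requested null size
(default 10,000; a paper-faithful 100,000 is just a larger `n_rep`).

With weakly informative designs (few families, large residual variance) the
re-estimated $Q_{sim}$ honestly piles up at the boundaries 0 and 1, exactly
as the observed estimator would; the null is then wide and the test
conservative. That is a property of the design, not of the test.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `n_perm` (F~ST~ test) | 999 | individual-level permutations |
| `n_boot` (CIs) | 1,000 | parametric-bootstrap refits; percentile 2.5/97.5 bounds |
| `n_rep` (neutral null) | 10,000 | null sample size (resampled from `cache_size` refits, default 1,000) |
| `alpha` (zeroing + verdicts) | 0.05 | boundary-LRT threshold for treating a component as null, and verdict significance |
| `tail` (Mantel) | `"greater"` | one-tailed positive association, the convention for distance-matrix tests |
| optimizer tolerances | 1e-12 | REML convergence; tight enough that balanced-design fits match closed-form ANOVA to ~1e-7 |

The zeroing rule (a variance component whose boundary ½χ²₀+½χ²₁ LRT p ≥ α is
set to 0 in further calculations) is applied inside pairwise Q~ST~; the LRT
and threshold are this package's concrete choice for a rule usually stated
only informally. Pairwise Q~ST~ first square-root-normalizes the trait
(shifting the minimum to zero if negatives exist — a sign-preserving
convention chosen here because the transform is usually stated without one);
overall Q~ST~ uses untransformed data. Whether pairwise refits should use
the pair's own residual variance or the global one is genuinely open; the
pair's own is used, keeping each pair's model self-contained.

## Distance-matrix inference

Mantel statistics are Pearson correlations over the $n(n-1)/2$ upper-triangle
entries; the null permutes rows and columns of one matrix jointly. With
$n \le 7$ populations the full $n!$ permutation set is enumerated and the
p-value is the exact proportion of relabelings at least as extreme
(identity included) — with five populations the finest attainable one-tailed
p is $1/120 \approx 0.008$, which is worth knowing before interpreting any
"significant" small-n Mantel result. The partial Mantel statistic is the
first-order partial correlation
$(r_{AB}-r_{AC}r_{BC})/\sqrt{(1-r_{AC}^2)(1-r_{BC}^2)}$ with A permuted.
Geographic distances are haversine great circles (Earth radius 6,371 km);
isolation by distance uses $F/(1-F)$ against log distance, with negative
$F$ clamped to 0 (with a warning) because the linearization is undefined
below zero.

## The synthetic-data generator

`study_design()` defaults encode the emulated study: 13 populations in two
subspecies (8 + 5), family counts uniform on 9–42, two sibs per family,
40 containers × 24 plants filled at random, 23 loci with 3–12 alleles, and
altitudes of origin uniform on 61–1,564 m. Genotypes follow the
Balding–Nichols model — population allele frequencies
Dirichlet-distributed around Dirichlet(1,…,1) ancestral frequencies with
concentration $(1-F)/F$ — chosen over coalescent simulation because it is
parameterized directly by the quantity the estimator targets. Phenotypes add
independent Gaussian population, family, block and residual effects plus an
optional linear altitude cline. The seven default traits span the
heritability (≈0.3–0.9) and Q~ST~ regimes (stabilizing ≈0.02 to divergent
≈0.7) a study of this kind reports, with cline slopes 0.00125 and −0.00048
per metre on the two count traits.

What the generator deliberately omits: marker–trait linkage (traits and
genotypes are independent, matching the neutral-marker assumption),
stepwise-mutation structure in the microsatellites, spatial genetic
autocorrelation, genotype-by-environment interaction, and non-Gaussian
trait distributions. Passing tests therefore validate the estimators and
their calibration under the stated model — they do not certify robustness
to, e.g., null alleles or maternal effects in real data.

## Numerical choices and degenerate inputs

- REML fits go through lme4's modular interface; bootstrap replicates swap
  the response in place and re-optimize from a fixed starting point derived
  from the generating components, so replicates are independent of each
  other's solutions (a warm start carried across replicates would anchor
  later fits at any boundary the previous one reached).
- NLopt is bounded at 3,000 evaluations per fit: with very tight tolerances
  the optimizer can otherwise cycle at machine-precision plateaus.
- Random terms whose factor has a single level in scope are dropped and
  reported as zero variance; fits with all loci monomorphic, traits with
  fewer than 10 observations, or a single family are errors, not guesses.
- Negative LRTs within 0.01 of zero are clipped to 0 (optimizer noise);
  larger ones raise an error.
- Bootstrap replicates that fail to converge are dropped and counted; more
  than 10% failures attaches a warning to the interval.
- Null replicates where the resampled $F_{sim} \ge 1$, the refit fails, or
  both re-estimated components are 0 (Q undefined) are redrawn and counted.

## Problem sizes used in the tests

The suite validates recovery and calibration at these scales, chosen to
mirror the emulated study while keeping a laptop run comfortable:
θ recovery at 23 loci × 8 populations × 30 diploids (20 replicates);
Q~ST~ recovery and null calibration at 8 populations × 25 families × 2 sibs
(100 and 200 replicates; null cache 120, `n_rep` 2,000); bootstrap coverage
at 6 populations × 12 families (100 outer replicates, `n_boot` 200).
Production defaults are larger (see the table above).

## Known limitations

- Full-sib $h^2$ conflates additive variance with dominance and maternal
  components; the package reports what the design identifies.
- The neutral null conditions on the fitted within-population components
  and the observed marker panel; uncertainty in $\hat V_A$ enters through
  the re-estimation step, not through an outer prior.
- CI-overlap verdicts use the point F~ST~, ignoring its (small) sampling
  variance, as is conventional.
- Exhaustive Mantel enumeration stops at $n = 7$ ($5040$ relabelings);
  beyond that, sampled permutations with the add-one correction are used.
- No support for variable ploidy, dominance markers, pedigrees beyond
  full sibs, or multivariate (genetic-correlation) extensions.
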