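---
title: "Identifying actual disease variants by genotypic likelihood-ratio tests"
author: "varident"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying actual disease variants by genotypic likelihood-ratio tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A case–control association signal at a variant does not mean the variant is
causal.  Variants in linkage disequilibrium (LD) with one or several causal
variants — often rare alleles riding on a common haplotype background — can
carry an equally strong or stronger marginal signal, a phenomenon known as
synthetic association.  `varident` implements a genotype-level method for
deciding, within a gene region of phased case–control data, *which* set of
variants is the actual disease-variant set: every candidate model (each
single variant, then each pair, and so on) is tested against the observed
genotype frequencies of *all* variants in the region, and a model is
accepted only when it explains the whole regional pattern.

## Disease model: sufficient causal components

The epidemiological backbone is the sufficient-causal-component (SCC)
model.  Disease occurs when any one sufficient cause is completed; the
studied gene contributes one component of one such cause (a gene–gene or
gene–environment combination), so its disease genotypes are neither
necessary nor sufficient.  Writing PLI for the population lifetime
incidence and $y$ for the proportion of the PLI attributable to the focal
cause, the case population mixes two sources: a fraction $1-y$ mirrors the
population genotype distribution, and a fraction $y$ is drawn entirely from
disease genotypes (DD and Dd for a dominant variant, DD alone for a
recessive one), apportioned by their population shares among disease
genotypes:

$$P'_g = (1-y)\,P_g + y\,\frac{P_g}{S} \;\; (g \text{ a disease genotype}),
\qquad P'_g = (1-y)\,P_g \;\; (g \text{ normal}),$$

with $S$ the total mass of disease genotypes.  Controls are treated as the
population (PLI is small, 1% by default).  All effect-size conversions
follow from this mixing:

* `or_from_y()` / `y_from_or()` map between $y$ and the allelic odds ratio
  $\mathrm{OR} = \frac{p'/(1-p')}{p/(1-p)}$, where $p, p'$ are the
  control/case disease-allele frequencies implied by the genotype triples.
  At HWE with allele frequency 0.3 and $y = 0.2$, the dominant OR is 1.3 —
  common alleles cannot carry large dominant odds ratios.
* For a dominant variant $y = 1$ is reached at
  $\mathrm{OR} = 2(1-P_{DD})/P_{Dd} - 1$; larger odds ratios are
  infeasible for those genotype frequencies (`max_dominant_or()`).
* `penetrance()` combines the focal risk $y \cdot \mathrm{PLI}/S$ with the
  background risk $(1-y)\mathrm{PLI}$ as a union of independent mechanisms;
  penetrance falls quickly as the disease allele becomes common, which is
  how genes with incomplete penetrance and extreme odds ratios fit the
  same framework.

One boundary convention: for a recessive variant whose homozygote class is
absent from the finite control panel ($P_{DD} = 0$) the mixing still places
mass $y$ on case homozygotes — those individuals arise by random union of
two disease haplotypes, which is also how the simulation machinery
constructs them.

## The virtual disease variant

The method assumes all disease variants in the gene have the *same*
defective effect.  A haplotype is then a disease haplotype as soon as it
carries a minor allele at any member of the candidate set; carrying two
counts once.  `collapse_variants()` performs this union on haplotypes and
derives individual genotypes (0, 1, 2 disease haplotypes) from the phased
pairs.  This is why phased input is required: the virtual genotype of a
compound heterozygote depends on phase.  Weighted collapsing (unequal
per-variant effects) is deliberately out of scope — it belongs to the
complementary allele-based method for independent effects.

## The genotypic likelihood-ratio test

Testing a model $D$ (the virtual variant of a member set) proceeds in three
steps.

**Expected case frequencies.**  The case genotype frequencies of the
virtual variant, $P(D'_j)$, are taken from the case sample itself — the
test conditions on them and assumes no effect size, which is what makes it
independent of the dominance model.  Every candidate variant $i$ in the
region then has expected case genotype frequencies
$$\pi_i = \sum_j \frac{P(G_i D_j)}{P(D_j)}\, P(D'_j),$$
where the joint table $P(G_i D_j)$ is estimated at the *genotype* level
from control individuals, so the sample's natural deviation from
Hardy–Weinberg proportions (random sampling of gametes) propagates into the
expectation instead of being idealised away.  A disease-genotype class with
no control carriers (typically the rare homozygote) is reconstructed by
random union of gametes from the control haplotype pool.  A genotype
category with zero expected frequency — a rare homozygote class invisible
to a few hundred controls — is merged into its adjacent category, giving
rare variants their natural two-category (1 df) test; declaring the model
impossible on such cells instead would reject true models in a fifth of
simulated samples, which we considered unacceptable for a test whose
selling point is calibration.

**Per-variant corrected statistic.**  For candidate $i$ with $k$ genotype
categories the multinomial log-likelihood ratio
$G_i = 2\sum_g o_g \log\{o_g/(n\pi_g)\}$ is corrected by the determinant
ratio $(|\Sigma_i|/|\sigma_i|)^{1/(k-1)}$: $|\Sigma_i|$ is the model-based
multinomial covariance determinant over the first $k-1$ categories and
$|\sigma_i|$ a resampling estimate of the same determinant that includes
the sampling error of the finite control panel.  For bi-allelic rare
variants ($k = 2$) this is the scalar variance ratio.

**The resampling null.**  The resampler rebuilds pseudo-case samples from
the controls: the observed disease-genotype classes are refilled with
genotype-matched control individuals (haplotype pairing when a class has no
control carrier — every pseudo-case is genotype-matched, so any
same-genotype quota between 0 and 1 is satisfied by construction), holding
the disease-genotype counts at their observed values because the statistic
conditions on them.  Crucially, each replicate also redraws a
pseudo-control sample of the same size and recomputes the expectations from
it.  Without that step the resampled counts are exactly multinomial and the
correction collapses to 1, while the real statistic carries the extra
variance of estimating conditionals from a few hundred controls — roughly a
doubling at equal case and control sizes.

**The region total.**  The per-variant statistics of LD partners are
strongly positively correlated (near-duplicate pairs in a region share
almost the same signal), so the *sum* of per-variant statistics has heavier
tails than a chi-square even when every term is perfectly calibrated, and
the model's own members — whose expectations are conditioned on their own
case frequencies — would contribute deterministic zeros.  The package
therefore (i) excludes member variants from the total and its degrees of
freedom $\mathrm{df} = \sum_{i \notin D}(k_i - 1)$, and (ii) calibrates the
member-excluded G-sum against the resampler's own pseudo-totals — the same
machinery used for the variance correction, used for its full distribution —
reporting `p_lower` as the rank of the observed total in that null and
`total_statistic` as its chi-square-scale equivalent
$F^{-1}_{\chi^2_\mathrm{df}}(p_\mathrm{lower})$.  During development we
measured the alternatives on the built-in panel (400 true-model
replicates): the plain member-inclusive sum kept the rejection rate near
nominal but its distribution sat visibly below $\chi^2$; the
member-excluded sum matched the mean but inherited the LD-correlation
variance; only the resampling-calibrated total met both the nominal
rejection rate and the chi-square shape.  The dedicated calibration tests
in the test suite lock this choice.

## The exhaustive search

`identify_variants()` tests all $M$ one-variant models, accepting those
with `p_lower < 1 - alpha` (the 0.95 rule at the default
$\alpha = 0.05$); if any are accepted the one with the smallest `p_lower`
wins (ties broken by enumeration order, which is lexicographic), otherwise
all $\binom{M}{2}$ two-variant models are tested, and so on up to
`max_model_size`.  On a 10-variant region that is 10 tests, then 45.
Variants monomorphic in the control sample cannot be conditioned on and are
excluded from candidacy for that data set (reported in the result); a rare
true variant absent from the controls is therefore undiscoverable in that
sample — a Type II, not a crash.

## The synthetic panel

`apoe_like_config()` encodes the study population as an explicit haplotype
pool of 13 variants emulating the APOE-region panel of 1092 individuals
used as the reference population: allele frequencies from 0.004 to 0.51
(including 0.00412, 0.00592, 0.00870, 0.082, 0.149, 0.325, 0.510),
designated strong-LD pairs with $r^2$ of 0.446, 0.502, 0.410, 0.768 and
0.77, and rare alleles fully nested on common haplotype backgrounds
($D' = 1$, $r^2 \approx 0$).  Encoding LD through an explicit pool rather
than a coalescent simulation makes every target an analytic function of the
pool (`pool_freqs()`, `pool_ld_stats()`), so the generator is verifiable
exactly; the cost is realism — no recombination gradient, no mutation, no
demography, and only as many haplotype classes as were designed in.  The
five quoted $r^2$ values and the frequency spectrum are reproduced exactly
at the pool level; the remaining pairwise structure is unconstrained.
`synth_panel()` draws haplotypes multinomially and pairs them at random, so
sampled panels deviate from Hardy–Weinberg proportions exactly as random
union of gametes implies — the deviation the test is built to respect.  A
draw that leaves a variant monomorphic is redrawn wholesale (the variant
set stays stable; rare alleles at frequency 0.004 are lost from a
1092-individual panel in roughly one draw in ten thousand).

Passing tests on this generator show that the method behaves as designed
under its own assumptions — random mating, a fixed haplotype pool, controls
representative of the population.  They do not show robustness to
population structure, genotyping error, unphased or missing data (rejected
at input), or LD patterns unlike the designed ones.

## Simulation machinery and study conditions

`generate_case_control()` draws controls from the panel with replacement
(an option disables replacement when the panel is large enough) and fills
case disease-genotype classes by sampling panel individuals conditional on
the virtual genotype, pairing two sampled disease haplotypes when a class
(rare homozygotes) is absent from the panel.  `type1_error()` is the
rejection rate of the true model; `type2_error()` runs the full search and
splits failures into partial identifications (a proper subset of the true
set — in practice the frequent member of a rare/common pair), wrong
identifications (an LD partner accepted instead), and no acceptance.
Clopper–Pearson intervals accompany all rates.

Defaults follow the reference study design: 500 cases, 500 controls, 1000
simulations, 1000 resampling replicates.  The shipped tests scale down to
stay fast while keeping the conditions recognisable: the calibration tests
use 500 simulated data sets with 200 resampling replicates on the
1092-individual panel; the Type II trend tests use 40–60 searches per cell.
The acceptance script uses 400 calibration replicates and 40 searches per
Type II cell.

## Numerical choices and edge cases

* Genotype categories are merged (never smoothed) when their expected
  frequency is exactly zero; `0 log 0 = 0` for observed zeros; a direct
  call to `lrt_statistic()` with a positive count on a zero-expectation
  category still returns the infinite-statistic sentinel.
* A non-positive resampled determinant (degenerate covariance) disables
  the per-variant correction for that variant and is flagged.
* The bootstrap `p_lower` uses mid-ranks, `(r + 0.5)/(R + 1)`, so it never
  returns exactly 0 or 1; with the default 1000 replicates its granularity
  is about 0.001.
* A pseudo-control redraw can lose a small stratum or every disease
  haplotype; those replicates fall back to the full-control conditionals
  (frequencies), and zero-probability groups in the pseudo-total are
  floored at the full-sample group probability.
* All entry points take a `seed`; identical seeds give identical results,
  and sub-draws are length-safe (a one-individual stratum is sampled as
  that individual, not as an index range).
* Ties at allele frequency 0.5 keep the ALT allele as the coded allele;
  the coded allele is otherwise the minor allele of the full panel, fixed
  before any case/control split.

## Known limitations

* Cases and controls must be phased; phase errors masquerade as compound
  heterozygotes and shift virtual genotypes.
* The test conditions on the case frequencies of the virtual variant, so a
  one-variant region carries no discriminating information (`total_df`
  is 0 and the model is trivially accepted).
* Strong LD through $r^2$ between a true variant and a more frequent
  partner produces wrong identifications at high odds ratios; strong LD
  within a candidate pair makes the pair nearly indistinguishable.  Both
  are properties of the inference problem, not of the implementation, and
  both are reproduced by the Type II machinery.
* Monomorphic-in-controls variants are invisible to the search.
* The resampling null treats the control sample as the population; with
  very few controls the calibration degrades.
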