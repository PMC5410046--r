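---
title: "Models and methods: genomic selection in a partial-diallel breeding population"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: genomic selection in a partial-diallel breeding population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the simulator that generates its study populations, the numerical
choices, and the limits of what the synthetic experiments can show.

## The two prediction models

**Pedigree model (individual-tree / "animal" model).** Raw phenotypes are
modelled as

$$y = X\beta + Sp + Tu + e, \qquad u \sim N(0, A\sigma^2_u),\;
p \sim N(0, I\sigma^2_p),\; e \sim N(0, I\sigma^2_e),$$

with fixed overall mean and site effect, a random permanent
block-within-site effect, and additive genetic effects for *every*
pedigree member. $A$ is the numerator relationship matrix from the tabular
method ($A_{ii} = 1 + \tfrac12 A_{sd}$,
$A_{ij} = \tfrac12 (A_{j,s(i)} + A_{j,d(i)})$, absent parents contribute
zero; founders unrelated and non-inbred). Fitting this model on all
sampled trees defines the reference ("true") breeding values: every
validation scheme correlates its out-of-sample genomic predictions against
these full-data EBVs, so accuracy measures agreement with the best
pedigree-based estimate, not with the unobservable genotypic value.
Unphenotyped individuals (parents; masked validation trees) receive EBVs
through $A$ — for a two-generation diallel this is the parental-average
projection, and the package tests verify it equals the exact
$A$-projection of the phenotyped individuals' BLUPs.

**Marker model (ridge-regression BLUP).** Phenotypes standardized by
block-within-site mean and site SD are modelled as

$$y = X\beta + Z\alpha + e, \qquad \alpha \sim N(0, I\sigma^2_a),$$

all marker effects sharing one variance, i.e. ridge regression; the only
fixed effect is the overall mean because site scale and block location are
removed by standardization. Genotypes are coded as minor-allele counts
0/1/2 (orientation fixed once on the full panel so signs are stable across
subset scenarios), missing calls imputed as the marker mean rounded
half-up, and covariates centered to $Z' = g - 1 \in \{-1, 0, +1\}$ —
equivalent to valuing the two alleles $\pm 0.5 a_j$. GEBVs are
$\hat g_i = \sum_j Z'_{ij} \hat a_j$. The marker-based additive variance is
$V_A = \sigma^2_a \sum_k 2 p_k q_k$, and heritabilities are
$\sigma^2_u / (\sigma^2_u + \sigma^2_e)$ (pedigree) and
$V_A / (V_A + \sigma^2_e)$ (marker); block variance is excluded from the
denominator, a choice consistent with the variance-component tables this
analysis is patterned on.

## Estimation: Gibbs sampling over a Gauss-Seidel core

Both models are estimated by single-site Gibbs sampling. Location
parameters are updated one coordinate at a time with a residual update —
each update costs one dot product and one residual adjustment, which is
exactly a Gauss-Seidel sweep when the noise is switched off. Variances use
flat (improper) priors implemented as scaled-inverse-chi-square draws with
$\nu = -2$, scale 0: e.g.
$\sigma^2_a \mid \cdot \sim \alpha'\alpha / \chi^2_{m-2}$. The animal
sampler keeps $w = A^{-1}u$ updated incrementally, so an iteration costs
$O(q^2)$; $A^{-1}$ is computed once per fit by direct inversion (dense $A$
is adequate at desk scale; a $10^{-8}$ jitter guards rank problems).

Defaults follow the reference configuration: 100,000 iterations, 20,000
burn-in, one variance sample retained every 1,000 iterations; posterior
means of location effects accumulate over every post-burn-in iteration.
The package's tests and the acceptance script run reduced chains
(10,000 / 2,000, and 4,000–6,000 for per-fold refits), which parameter-
recovery checks show are sufficient at these problem sizes. Convergence is
checked by a Geweke-style z-score on the variance traces (|z| < 3), which
replaces visual trace inspection; traces are exported for offline
inspection anyway. Chains draw from R's RNG, so a seed makes every fit
bit-reproducible; rescaling the response by $c$ rescales the same draws,
making scale equivariance exact rather than merely distributional (a
property the tests exploit).

**Deterministic refits.** Cross-validation refits models dozens of times.
With variance ratios fixed (estimated once on the full data), the refit is
a linear solve. Two design choices here: the marker-model refit uses the
exact ridge closed form — profiling out the unpenalized intercept by
centering, then solving the dual $n \times n$ system when $n < m$ — and
the animal-model refit a direct dense MME solve. Gauss-Seidel iteration,
though implemented and exported (`gauss_seidel_blup()`,
`gauss_seidel_ridge()`), converges too slowly at tight tolerance on the
strongly coupled full-panel systems to be the production path; the tests
verify on well-conditioned systems that the iterative and direct routes
agree to $10^{-8}$, and that ridge GEBVs equal GBLUP predictions from
$G \propto Z_c Z_c'$ on the same data.

## The synthetic population

The simulator emulates the study conditions end to end: 27 parents from
10 labelled provenances (round-robin, solely to support the unrelated
scenario), 34 full-sib families from a partial diallel (distinct non-self
pairs; a first pairing round over a shuffled parent order guarantees every
parent mates), 22 progeny per family trimmed at random to 734 trees —
balance simplifies stratified fold construction relative to the unbalanced
real design — planted on 2 sites with 4 blocks each, with each family
split evenly across sites (per-site allocation is a config knob; the real
split was uneven). 4,993 SNPs are placed uniformly at random on 12 linkage
groups totalling 1,850 cM (≈2.7 markers/cM); founder minor-allele
frequencies are drawn from a Beta(2, 2) scaled onto (0, 0.5], which puts
≈3% of markers below 5% MAF — matching the observed rarity of
low-frequency alleles. Meiosis uses the Haldane map function with no
interference (closed-form testable: the package verifies recombination
fractions of 0 at 0 cM, 0.316 at 50 cM, 0.5 across linkage groups).
Genotype calls go missing completely at random at rate 0.018.

Traits are controlled by 200 of the genotyped markers carrying additive
effects drawn from a normal distribution ("many genes of small effect");
the rest are neutral. Effects are rescaled so the **base-population**
additive variance $\sum_k 2 p_k q_k a_k^2$ (founder frequencies, linkage
equilibrium) equals the trait's genetic variance. This anchoring matters:
the animal model's $\sigma^2_u$ estimates base-population variance, so
anchoring realized progeny variance instead biases recovered heritability
upward by ~0.1 under family structure. Phenotypes are
$y = \mu + \text{site} + \text{block} + TBV + e$ with
$\sigma^2_e = \sigma^2_g (1 - h^2) / h^2$, so the within-site individual
heritability equals its target by construction ($h^2 = 1$ is allowed and
gives a noiseless trait). Default traits mirror mature growth and wood
traits: height (cm, $h^2$ 0.68), wood density (kg/m³, 0.41), diameter
(mm, 0.57) and microfibril angle (degrees, 0.74, lower is better), with
genetic variances at the magnitudes reported for such trials.

What the simulator does **not** emulate: genotype-by-environment
interaction (none is generated, consistent with the low G×E the emulated
study reports — so cross-site accuracy checks are construction checks, not
tests of G×E robustness), dominance/epistasis, unbalanced families,
genotyping error, ascertainment bias of the SNP panel, and QTL outside the
genotyped panel. The last point matters most for interpretation: with all
causal loci genotyped, marker models can only do *better* here than on
real data at equal relatedness, so passing regime checks demonstrates the
machinery's behaviour, not field-trial accuracy levels.

## Validation schemes and their numerical choices

Folds are family-stratified: members shuffled within family and dealt
round-robin into $k = 10$ folds from a random offset, so each fold takes
≈10% of every family and each tree validates exactly once. Standardization
parameters, variance ratios (in Gibbs mode) and marker effects are learned
from training trees only — permuting validation phenotypes provably leaves
validation GEBVs unchanged, and a test asserts this. Fold errors are
reported as the SD of the per-fold correlations (the error definition is
otherwise unstated in the source material); pooled correlations are also
reported.

The half-sib split partitions families (greedy, seeded order, balancing
sides) so every multi-family parent has families on both sides and no
full-sib family spans the split; parents with a single family go to
training, flagged. The unrelated split holds out whole provenances and
keeps only families with both parents inside (validation) or outside
(training) the held-out set, guaranteeing zero cross-set additive
relationship — straddling families are dropped. Marker subsets: random-k,
top-k by |effect| from the full-data fit (ties by marker id),
complement, or one linkage group. The training-size ladder re-estimates
variance components **per fold** by default: reusing full-data ratios
shields small training sets from variance-estimation noise and flattens
the accuracy decay that is precisely the phenomenon of interest at small
$n$ (fast modes exist and are documented). The site-mean scheme averages
5 replicate models on random 359-tree subsets, matching the mean per-site
sample size.

Genetic gain selects the top $\lceil 0.05 n \rceil$ candidates by
predicted phenotype (fixed-effect estimate plus predicted breeding value,
de-standardized to trait units for marker models; ties broken by id) in
the trait's favorable direction; gain is the selection differential
against the candidate-population mean (grand mean, not site means), and
per-year ratios use 28- versus 9-year cycles, factorizing exactly as
gain ratio × cycle ratio.

## Degenerate inputs and tie rules

Imputation rounds half up (mean 0.5 → 1). Markers with all calls missing
fail QC (call rate 0) rather than impute. A site with zero phenotypic SD
standardizes to all zeros, flagged; single-tree blocks center by the site
mean, flagged; sites unseen in training (cross-site prediction) fall back
to pooled training mean/SD. QC rules are conjunctive — call rate ≥ 0.85,
MAF ≥ 0.0055, minor-allele carriers ≥ 10, |F_IS| ≤ 0.5 — with drop
attribution in that order; a GenTrain-style chip score is accepted only as
optional metadata, never computed. `k = 1` cross-validation (training =
validation) is allowed but warns. Gauss-Seidel stops when the largest
coordinate update falls below 1e-8 (1,000-sweep budget); non-convergence
is an error, never silent.

## Problem sizes used by tests and acceptance runs

Unit tests run populations of 110–480 trees with 300–1,500 markers and
chains of 2,000–6,000 iterations. The acceptance suite runs the emulated
design at 544–734 trees with 1,500–4,993 markers: parameter recovery at
2,000 markers and chain 10,000/2,000 over 5 seeds per heritability level;
relatedness ordering over 5 seeds; marker subsets over 3 seeds at the full
4,993-marker panel; the training-size ladder over 2 seeds at 2,000 markers
with per-fold re-estimation. These sizes are the package's choice of
desk-scale experiment: large enough for the regime properties to be
stable averages, small enough to iterate on.

## Known limitations

Heritability estimates from ~30 families have large sampling spread (REML
on matched data ranges ±0.15 across seeds); recovery claims hold for
seed-averages, not single runs. The Gibbs posterior mean under flat priors
carries a small upward bias (~+0.05 on $h^2$) relative to REML at these
sizes. The magnitude of the training-size accuracy decay is strongly
seed-dependent. Accuracy against full-data EBVs (the reference definition)
partially rewards family-mean agreement; against true breeding values it
is typically a few points lower. None of these affect the orderings the
scenario suite tests, which hold on seed-averages throughout.
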