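---
title: "Separating genetic nurture from genetic transmission with nurtureR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separating genetic nurture from genetic transmission with nurtureR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimand

Offspring resemble their parents for two distinct reasons: they inherit half
of each parent's genome, and they grow up in an environment those parents
shape. "Genetic nurture" is the second channel expressed in genetic terms —
parental alleles that influence the offspring through parental behavior
rather than through inheritance. The clean way to separate the channels is
the transmission experiment nature runs in every family: each parent passes
exactly one of two haplotypes. A polygenic score built on the transmitted
haplotypes (`PGS_T`) carries both channels; the same score on the
non-transmitted haplotypes (`PGS_NT`) can only act through the environment,
because those alleles are in the parent but not the child. Jointly,

```
outcome ~ beta_T * PGS_T + beta_NT * PGS_NT + sex + age + (1 | family)
```

identifies `beta_NT` as genetic nurture and `beta_DGT = beta_T - beta_NT` as
direct genetic transmission.

This rests on assumptions worth stating: parents are the rearing parents;
population structure is controlled (scores are residualized on principal
components and standardized within genotyping batch); and mate choice is
either random or explicitly modeled — under genetic assortative mating the
non-transmitted score of one parent proxies the other parent's genotype, so
the parent-of-origin models estimate all pairwise covariances among the four
parent-specific scores rather than assuming them zero.

## Transmission inference by tile matching

With phased genotypes, an offspring haplotype is a mosaic of one parent's two
haplotypes, switching at recombination breakpoints. The inference proceeds:

1. **Tiles.** Each chromosome's markers are cut into consecutive tiles of
   150 adjacent markers (configurable). A trailing remainder shorter than
   half a tile merges into the previous tile; longer remainders stand alone.
2. **Assignment.** Per offspring haplotype and candidate parent, the
   genome-wide sum of per-tile minimum mismatches is computed. In trios the
   2×2 haplotype-to-parent assignment minimizing the total is taken; in pairs
   the offspring haplotype with the smaller genome-wide mismatch belongs to
   the genotyped parent. Zero margin falls back to a fixed rule (haplotype 1
   to the mother) and is flagged ambiguous.
3. **Tile sources.** Per tile the parental haplotype with fewer mismatches is
   the source. Ties keep the previous tile's source — continuity minimizes
   spurious breakpoints — with a flagged haplotype-1 default on a
   chromosome's first tile. Tiles with fewer than 10 informative markers
   (parent heterozygous, non-missing) inherit their neighbor's source.
4. **Breakpoint refinement.** Where adjacent tiles disagree, the union of the
   two tiles is scanned for the change point minimizing total mismatches.
   The true crossover is identifiable only up to the uninformative gap
   between flanking heterozygous markers; any point inside that gap yields
   identical transmitted and non-transmitted datasets, so the argmin is
   taken deterministically (first minimum).
5. **Marker-wise correction.** The transmitted allele must equal the
   offspring's allele, so any marker where the assigned source mismatches a
   heterozygous parent has its source flipped. This repairs events the tile
   scan cannot see (e.g. double crossovers inside one tile) and guarantees
   two exact identities: transmitted + non-transmitted alleles are a
   permutation of the parent's genotype at every marker, and the combined
   transmitted score equals scoring the offspring genome directly.

For a genotyped parent the non-transmitted allele is the unchosen haplotype's
allele. For an ungenotyped parent the transmitted alleles are the unassigned
offspring haplotype (so `PGS_T` is always complete) and the non-transmitted
alleles are missing.

Under error-free phase this recovers the simulator's ground truth exactly at
every marker we have tested; with phase switch errors accuracy degrades
smoothly with the switch rate, which the test suite checks as a monotone
trend. Residual risk concentrates where parents are uninformative
(homozygous runs) — there the non-transmitted allele equals the transmitted
one and no error is possible, which is why concordance stays high even when
breakpoints wander within gaps.

## Scores

Scores are plain weighted allele sums (`sum_j w_j * allele_j`), with the
weight table aligned to the dataset's coded allele: when a weight's effect
allele is the reference allele the contribution is `w * (1 - code)`. Missing
alleles contribute the marker's mean haplotype dosage. Scores are computed on
raw allele counts and standardized only afterwards (per batch, after
residualizing on the leading principal components — ten by default; the
simulator emits no PCs, so this reduces to a within-batch z-score). Keeping
raw counts through the component stage preserves the conservation identity
(transmitted + non-transmitted = the parent's diploid score) to machine
precision.

A pair's missing non-transmitted score is imputed with the mean of observed
parents. The observed-parent average is ambiguous between a cohort-wide and
a role-specific mean; the default is role-specific (missing fathers get the
observed-father mean), with the overall mean and no-imputation available by
argument. Imputation is used only for the combined-score mixed models; the
parent-of-origin and mediation path models leave the scores missing and let
FIML use all available data.

## FIML path models

The parent-of-origin and mediation analyses are linear path models over
observed variables. No installed package provides observed-variable FIML
SEM, so the estimator is implemented here: the model implies a mean vector
and covariance matrix via the recursive-system inverse `(I - A)^{-1}`;
rows are grouped by missingness pattern and each pattern contributes its
observed subvector's multivariate-normal likelihood through per-pattern
sufficient statistics (so cost scales with the number of patterns, not
rows). Exogenous covariances are parameterized by a Cholesky factor with
log-diagonal and residual SDs on the log scale, keeping the implied
covariance positive definite throughout. With complete data the maximum is
closed-form (equation-wise OLS with ML variance scaling and sample moments
for the exogenous block) and is used directly — this is also why the
complete-data bootstrap is fast. With missingness, BFGS with
central-difference gradients runs from pairwise-moment starting values, with
a PORT fallback; convergence requires a relative objective change below
1e-12 (optimizer tolerance) and a gradient norm below 1e-3 relative to the
objective, else an error carrying the last parameter vector.

Standardized coefficients are derived from the implied variances
(`b * sd(x) / sd(y)`); the binary sex covariate is deliberately left on its
raw 0/1 scale in the standardized solution. Wald equality tests compare two
standardized coefficients via the delta method on the observed-information
covariance (numeric Hessian), df = 1. Bootstrap confidence intervals resample
family clusters by default — respecting sibling dependence; the resampling
unit is switchable to individuals — with percentile intervals and failed
replicates excluded up to a 10% ceiling. Fit indices use
`chisq = 2 * (loglik_saturated - loglik_model)` with the `n` (not `n-1`)
multiplier convention in `RMSEA = sqrt(max(0, (chisq - df) / (df * n)))`;
CFI uses an all-covariances-zero independence baseline. Note that a
mediation model with all paths present is saturated (df = 0, exact-fit
constants); df > 0 arises only when paths are constrained away.

The mediation decomposition reports `a*b` (indirect), `c' + a*b` (total) and
the proportion mediated `100 * indirect / total`, the latter only when the
two share sign — a ratio of opposite-signed effects is not a proportion and
is returned as NA.

## What the simulator emulates — and what it does not

`simulateDataset()` draws founder haplotypes independently per marker from
allele frequencies (uniform on [0.05, 0.95] by default), pairs mates by a
noisy rank interleave whose realized mate-score correlation tracks `rho_am`,
generates gametes under the Haldane model (Poisson crossover counts,
`length_cM / 100` expected per chromosome, uniform positions, no
interference), and reduces a configurable fraction of families to pairs.
Phenotypes follow a liability model: parental phenotype
`P = gamma * Z(G_parent) + e` (unit variance), offspring linear predictor

```
delta * Z(G_o) + eta_m * Z(P_m) + eta_f * Z(P_f)
  + nu_m * Z(G_m) + nu_f * Z(G_f) + beta_sex * sex + beta_age * Z(age)
```

with `nu` a small direct-nurture path bypassing the measured parental
phenotype, so that mediation through parental phenotype is partial rather
than total — matching the qualitative structure of real mediation findings.
Binary traits threshold the liability at the empirical quantile matching the
target prevalence (smoking initiation 0.414, lifetime cannabis 0.227);
smoking-quantity traits are emitted only for initiators, for parents and
offspring alike; continuous outcomes are rescaled to cohort-like units
(cigarettes/day 10.24 ± 6.00; pack-years 7.03 ± 6.73; alcohol 6.74 ± 8.46
g/day). Age is uniform on 18–67, sex Bernoulli(1/2), sibling counts uniform
on 1–3 when not fixed. A master seed feeds named substreams (frequencies,
founders, weights, mating, meiosis, phenotypes, switch errors), so one seed
fixes the dataset byte for byte.

Deliberately absent: linkage disequilibrium between markers (the tile
matcher must not depend on it), genotyping error beyond optional phase
switch errors, X-chromosome and sex-specific maps, multi-generation
pedigrees, and zero-inflation or skew in the continuous outcomes. Passing
tests on this generator therefore demonstrates the *algorithmic* correctness
of inference, scoring and estimation — transmitted/non-transmitted recovery
against ground truth, unbiased path recovery, calibrated type-I error — not
robustness to LD structure, genotyping artifacts or questionnaire
measurement quirks in real cohorts. The quantity gating also makes
missingness depend on the underlying liability (as in real initiation-gated
measures); FIML assumes ignorable missingness, so mediation estimates under
gating inherit the same caveat as the original design.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `tileSize` | 150 | markers | the method's validated tile length |
| `minInformative` | 10 | markers/tile | below this, mismatch counts are noise; inherit the neighbor |
| `refine` | TRUE | — | sub-tile breakpoint placement; off = tile-boundary breakpoints |
| `nPcs` | 10 | components | population-structure residualization |
| `imputeStrategy` | "role" | — | role-specific observed-parent mean |
| `bootstrapB` | 1000 | replicates | CI stability; tests use smaller B |
| FDR family | 5 | tests | the five outcomes, NT and T adjusted separately |
| `rho_am` | 0 | correlation | assortative mating off unless studied |
| `delta, eta_m, eta_f, gamma, nu_*` | 0.12, 0.05, 0.05, 0.4, 0.01 | per SD | modest transmitted effect, small equal nurture, realistic parent heritability, small unmediated nurture |

Marker density defaults to 3,000 per chromosome on a 100 cM map — chosen for
desk-scale runtime while keeping tiles at 5 cM, where double crossovers
within a tile are rare; it is not a claim about post-QC marker density in
any cohort.

## Numerical choices and degenerate inputs

Zero-length maps give deterministic no-recombination meioses. Zero-variance
variables are an error wherever standardization is required; residualization
reports degenerate variance when a score is exactly linear in the PCs.
Singleton families make the mixed-model variance split unidentified — the
fitter allows it (point estimates then coincide with OLS) and flags singular
fits. Identical parents make haplotype assignment ambiguous; the fixed rule
plus flag keeps the output deterministic. The bootstrap refuses fewer than
two clusters. Ties in tile matching and change-point scans resolve
deterministically (continuity, then first minimum), so repeated runs are
identical.

## Problem sizes used by the test suite

The suite validates calibration properties at sizes chosen for a desk-scale
run: transmission concordance on 200 simulated pairs of 2 × 3,000 markers;
parameter recovery (`delta`, `eta_m`, `eta_f`, indirect effect) at n = 4,000
over 8 seeds against 3 Monte-Carlo-SE bands; type-I error of the
non-transmitted test over 40 null-generator replicates; bootstrap coverage
of a null indirect effect over 40 replicates at B = 100; likelihood-ratio
p-value uniformity over 60 replicates. The bands are computed at the sizes
actually run, so the checks remain exact statements at those sizes.

## Known limitations

The estimator suite assumes linear, recursive structure with multivariate
normal errors for FIML; ordinal/probit path models and latent measurement
models are out of scope, as are statistical phasing, GWAS weight estimation
(weights are an input), PCA computation, and survival or gene-environment
interaction models. Proportion-mediated is undefined under inconsistent
mediation. Real-cohort effect sizes are not reproducible from synthetic
data; the package reproduces the *method* and its validation logic, not the
cohort's point estimates.
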