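---
title: "Methods: quantifying parallel ecotype divergence"
author: "ecoparallel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying parallel ecotype divergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models, the decisions behind
them, and what its synthetic-data tests do and do not demonstrate.

## The study design the package assumes

The unit of replication is the *sympatric ecotype pair*: within one lake, a
planktivorous reference form and a derived form (benthivorous, and in
three-ecotype lakes also piscivorous). Lakes are nested in glacial
lineages. Parallelism questions are always questions about pairs of pairs:
do two pairs diverge in the same direction (small angle θ), by the same
amount (small ΔL), at the same loci (sharing tests), with the same
transcripts (DEG/RDA sharing), and does lake ecosystem size explain the
residual heterogeneity?

## Size correction

Linear traits scale allometrically with body size, so raw values conflate
size and shape. Each measured value is mapped to its expected value at the
lineage mean fork length:

log10 Y = log10 M + b (log10 Lm − log10 L).

The slope b is estimated per trait and lineage from an ANCOVA of log10 M on
log10 L with lake and ecotype as additive covariates (a common slope).
The covariate reading of the procedure was adopted over fitting separate
slopes per lake-and-ecotype group: with 20–40 fish per group, per-group
slopes are noisy, and a common slope makes the correction exactly
invertible, which the generator exploits (it builds measured values by
running the formula backwards, so zero-noise data are corrected perfectly —
one of the acceptance checks). When fork length carries no variance the
slope is undefined and set to zero, making the correction the identity.
The correction is idempotent: re-correcting corrected traits re-estimates
b ≈ 0 and changes nothing.

## Variance partitioning

Each response is fit as
`trait ~ ecotype + lake + lineage + ecotype:lake + ecotype:lineage` with
partial η² = SS/(SS + SS_res) per term. Type-II sums of squares are used
because lake sample sizes are unbalanced in this kind of field design;
Type II is computed in-package by residual-sum-of-squares comparisons
(each term tested against the model of all terms not containing it), which
remains defined when the residual SS is exactly zero. When lakes are fully
nested in lineages, the lineage main effect and the ecotype:lineage
interaction are aliased; they are dropped with a message and reported as
NA rather than silently absorbed. A response is "parallel-dominant" when
the ecotype η² exceeds both interaction η².

## Trajectory analysis

All trajectories are two-point: the paired-ecotype design makes trajectory
direction the centroid-difference vector, oriented planktivorous → derived
so angles are comparable across lakes. θ is reported in degrees on
[0, 180]; ΔL is the absolute length difference. Zero-length vectors leave
θ undefined (NA with a warning), never 0.

Significance uses residual randomization. The permuted datasets are built
from the *pair-only* model's fitted values plus permuted residuals of the
*full group-centroid* model: under this null, divergence vectors have
random directions and noise-scale lengths, while pair location and
residual spread are preserved. This choice is deliberate. Keeping the
ecotype term in the fitted values leaves shared overfit noise in both
permuted vectors and makes null θ p-values anticonservative; keeping the
ecotype-divergence structure in the residuals instead lets planted signal
leak into the null and destroys power in the strong-signal limit. The
implemented scheme passes both checks: θ p-values are uniform across
synthetic null studies (KS test), and an extreme planted signal attains
the minimum p of 1/(n_perm + 1). Permutations that produce an undefined
angle (possible only in degenerate noise-free data) are counted as
extreme, so a degenerate comparison is conservatively non-significant.

Trajectory analyses default to size-corrected traits for phenotypes; any
score matrix can be supplied, and PCA inputs are truncated at the smallest
number of components cumulatively explaining more than half the variance
(k50), the retention rule used throughout.

## Fst scans and outliers

Per-locus differentiation is the Weir–Cockerham (1984) θ̂ from the
variance components a, b, c computed from genotype counts with observed
heterozygote frequencies; the genome-wide value is the ratio of sums
Σa/Σ(a+b+c). Negative per-locus estimates are retained: clipping would
bias the scan mean, the standard deviation behind ZFst, and the 95th
percentile.

Two outlier rules are provided. The empirical rule flags loci strictly
above the per-pair 95th percentile (always ≈5% of loci, by construction).
The permuted-panmixia rule reshuffles ecotype labels within lakes,
recomputes the scan each time, pools all permuted per-locus values into
one null distribution, and flags empirical values above the pooled null's
95th percentile (a per-locus null is available behind a flag). On a
panmictic pair both rules flag ≈5%; when real background differentiation
exists, the permuted rule flags more — which is why sharing analyses based
on it find more overlap.

HWE filtering uses a chi-square test (1 df) per population rather than an
exact test; at the 0.05 threshold and the moderate allele frequencies that
survive the MAF filter the decisions coincide, and the chi-square is
simple and vectorizable. The QC defaults — presence in ≥66% of individuals
in ≥2/3 of populations, MAF ≥ 0.05, observed heterozygosity ≤ 0.5, HWE
P > 0.05 in ≥2/3 of populations, one SNP per contig — follow standard
RAD-seq practice.

The D statistic uses the frequency form with a leave-one-block-out
jackknife (default 200 loci per block; fewer than 5 blocks yields the
estimate without a Z, with a warning). f3(C; A, B) subtracts a within-C
sampling-bias term h_c/(2 n_c) with unbiased heterozygosity; a strongly
negative Z signals admixture of C.

## RDA association

Partial RDA residualizes both the response and the ecotype predictor on
condition dummies (lake, optionally lineage), regresses residual response
on residual predictor, and takes the principal axes of the fitted values
as constrained axes. Two-ecotype designs use a 0/1 predictor and give one
axis. Three-ecotype designs use two indicator contrasts
(benthivorous-vs-rest, piscivorous-vs-rest): a single ordinal 0/1/2
predictor can only ever produce one constrained axis, so the two-contrast
coding is the reconstruction that yields the two-axis geometry in which
the first axis separates benthivorous from planktivorous and the second
isolates the piscivorous form. Candidates are features with
|z-standardized loading| > 2 on a constrained axis (a two-tailed 5% rule).
Significance is a permutation pseudo-F obtained by permuting rows of the
residualized predictor. Genotypes are centred but not variance-scaled
(dosages share a scale); missing dosages are mean-imputed per population
first. The constrained solution is verified against `vegan::rda` with a
`Condition()` term in the test suite.

## Expression

Counts are normalized by median-of-ratios size factors (rescaled to
geometric mean one) and transformed as log2(count/sf + 1) — a deliberate,
self-contained stand-in for regularized-log transforms whose behaviour is
easy to test. Differential expression is a per-gene Welch t-test on the
normalized values within a lake with BH correction per lake; its realized
false-positive behaviour under the null is part of the acceptance
calibration, and planted log2FC = 2 signals at n = 4+4 are recovered at
≥70%. Genes enter network construction when ecotype explains more than 10%
of their total variance in a fixed-effects `expr ~ ecotype + lake`
decomposition. Modules are found on the |r|^6 adjacency (unsigned network,
soft power 6 as the conventional default), 1 − adjacency dissimilarity,
average-linkage clustering with a static cut at 0.992, minimum size 25,
then iterative merging of modules whose eigengenes are closer than 0.25 in
correlation distance. A static cut replaces dynamic tree-cutting while
keeping the printed parameters; module labels are ordered by size so the
output is invariant to gene input order. The module eigengene is the
unit-norm first principal component of the standardized member expression,
oriented to a positive mean loading. cis-eQTL mapping tests every
gene–SNP pair within 1 Mb (gene position = annotated start) by least
squares of expression on additive dosage plus lake and lineage dummies,
with BH correction across all tested pairs and reporting at FDR 0.1 and
0.05; the covariate residualization is done once, which makes the t-test
per pair a vectorized one-variable regression with the correct residual
degrees of freedom.

## Integration

Ecosystem size is PC1 of z-standardized lake maximum depth and surface
area, oriented so larger lakes score higher; pairwise lake distances are
absolute PC1 differences. Mantel tests correlate lower-triangle entries
and permute object labels of the second matrix with a one-sided
(positive-association) p by default — matching the directional hypotheses
— with 999 permutations as the conventional default; a two-sided option
exists. Regressions are ordinary least squares. The predictability report
always contains its twelve pre-registered rows (four Mantel tests among
divergence axes, three regressions, five Mantel tests against ecosystem
distance); analyses whose inputs are missing are flagged "not computed"
rather than dropped. "Mean trait variance" per lake is the within-ecotype
pooled variance of each corrected trait, averaged over traits.

## The synthetic generator

The generator is the package's study-design stand-in, not a fixture: every
downstream stage is tested against the signals it plants.

* **Design**: 2 lineages × 3 lakes × 2 ecotypes × 20 fish by default (the
  demo scale, chosen so a full pipeline run takes seconds), with 2,000
  SNPs and 3,000 genes; all counts are tunable.
* **Genotypes**: ancestral frequencies ~ Uniform(0.05, 0.95); each
  population drifts by a Balding–Nichols Beta draw with one parameter F
  (default 0.05, a typical within-lineage differentiation scale).
  Ecotype-associated SNPs shift the two ecotypes' frequencies ±Δ/2 around
  the lake frequency, clipped to [0.01, 0.99]. Missingness is completely
  at random (default 5%).
* **Traits**: log10-scale baseline + a lineage-shared ecotype effect
  vector + a lake-specific deviation + Gaussian noise (default sd 0.02,
  i.e. ≈5% proportional trait noise, a realistic measurement scale),
  pushed through the allometric formula in reverse. Gaussian residuals are
  an assumption of convenience, not a claim about real fish.
* **Ecosystem coupling**: each lake's effect vector is rotated by an angle
  proportional to a mix of the lake's ecosystem-size score and noise, with
  mixing weight `ecosystemCoupling`; at 0 rotations are independent of
  ecosystem size, at 1 fully determined by it. The rotation magnitude is
  tied to `lakeNoiseScale` so that zero lake noise means perfectly
  identical effect vectors.
* **Expression**: negative-binomial counts (var = μ + αμ²) with lognormal
  library size factors; DE genes get a shared ecotype log2 fold change;
  eQTL genes get an additive dosage term on the log2 mean, and their gene
  positions are placed within the cis window of their SNP.

What passing tests on this generator show: the estimators are correct
(oracle equivalence), calibrated (uniform null p-values, nominal FDR), and
powered at the planted effect sizes (recall bounds). What they do not
show: robustness to linkage structure (loci are independent given
population frequencies), to non-Gaussian trait residuals, to
coverage-driven missingness, or to expression confounders beyond lake,
lineage and library size — real data carry all of these.

## Numerical choices and degenerate inputs

Angles are clamped into [−1, 1] before arccos (precision near the
boundaries is ~10⁻⁶ degrees). PCA fixes each component's sign by making
its largest-magnitude loading positive. Per-locus Fst with an (a+b+c)
denominator of zero is NA and excluded from ratio-of-sums and quantiles.
Sharing tests with observed = expected report p = 1 without calling the
proportion test. All stochastic stages require an explicit seed; the
pipeline derives per-stage seeds deterministically from one global seed,
and two runs with the same seed are byte-identical (hash-verified).

## Problem sizes used in tests

Oracle checks run on ≤10-sample hand inputs. Calibration uses 100–300
replicates of small designs (and 1,000 loci × 1,000 permutations for the
panmixia null). Recovery uses the effect sizes quoted above. The
end-to-end determinism check runs the default demo study twice; one run
takes on the order of ten seconds on one CPU.

## Known limitations

Two-point trajectories only; composite-genotype LD (no phasing); no
forward selection or variance partitioning beyond the single conditioned
RDA model; the DE and network procedures are defined stand-ins whose
outputs are not numerically comparable to shrinkage-based or
topological-overlap pipelines, although their thresholds keep the same
interface; cis-eQTL assumes the expression and genotype samples coincide.
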