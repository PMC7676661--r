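---
title: "Methods: paired-wing morphometrics, asymmetry and admixture in wingmorph"
author: "wingmorph authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired-wing morphometrics, asymmetry and admixture in wingmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models implemented in `wingmorph`,
the assumptions behind them, the tunable parameters and their defaults, and
the design decisions that were genuinely open.

## Data model

A dataset couples three tables: landmark configurations (19 ordered 2-D
vein-intersection landmarks per wing, left and right per individual,
optionally replicated over imaging and digitization sessions; coordinates
held internally in micrometers), per-individual metadata (site, maternal
mtDNA lineage A/C/M, hybrid index HI in [0, 1] with 0 = African and 1 =
European ancestry, allowed missing), and a genotype matrix of
within-individual allele frequencies over 14 microsatellite loci (each
entry 0, 0.5 or 1; per-locus rows sum to 1 for a diploid).  Readers exist
for TPS (`LM=`/`SCALE=`/`ID=` blocks, with the identifier convention
`individual_side_imagingrep_digitizationrep`, since TPS has no native
replicate fields) and for a long-format CSV keyed by `landmark_index`,
which is authoritative — the reader never reorders landmarks.  A missing
`SCALE=` is an error when physical units are requested rather than a
silent factor of 1: centroid sizes are reported in micrometers and a
silently unscaled file would corrupt them.

## Superimposition

Generalized Procrustes analysis follows the standard three steps: center
each configuration on its centroid, scale to unit centroid size, and
iteratively rotate (rotations only, no reflections) to minimize the summed
squared distances to the consensus, which is recomputed as the arithmetic
mean after every sweep and rescaled to unit size.  Left wings are
reflected about the y-axis *before* the fit and all wings and replicates
enter one joint superimposition — the matching-symmetry protocol for
paired separate structures.  Convergence is declared when the relative
decrease of the objective falls below 1e-10 (at most 100 sweeps; wing
data converge in 3–5).  Two numerical choices deserve note:

* **Initial consensus.**  The initial consensus is the plain mean of the
  centered, scaled configurations (falling back to the first configuration
  if raw orientations nearly cancel).  This keeps the algorithm
  deterministic and order-independent, and makes the fit a fixed point:
  re-running GPA on its own output converges immediately with a consensus
  change at the tolerance level.  Initializing from the first configuration
  instead would leave the whole fit in the arbitrary digitization
  orientation of specimen 1.  The output orientation is still a gauge:
  analyses that compare fitted vector fields against external references
  must first rotate the fit frame onto that reference.
* **Tangent projection.**  By default distances are taken directly in
  Procrustes shape space; an orthogonal tangent-space projection at the
  consensus is available as a flag.  At within-population wing scales
  (Procrustes radii around 1e-2) the projection moves coordinates by about
  the squared radius (~1e-5 — quadratically small) and changes relative
  pairwise distances by well under 0.1%, which is why it is off by
  default.

## Asymmetry decomposition

For a rectangular design of n individuals × 2 sides × r1 imaging × r2
digitization replicates, sums of squares are computed from marginal means:
individuals from side-and-replicate means, sides (directional asymmetry)
from the mean left-right difference, the individual × side interaction
(fluctuating asymmetry) from individual-specific left-right deviations,
ME1 from variation across imaging sessions within individual × side, and
ME2 as the digitization residual.  For shape, squared deviations are
summed over all 38 Procrustes coordinates and every conventional degree of
freedom is multiplied by the shape dimension 34; this is exactly
equivalent to summing 38 per-coordinate conventional ANOVAs, and the test
suite verifies that equivalence against `stats::aov` on random designs.
Goodall's F ratios use the mixed-model denominators (individuals and sides
over the interaction; the interaction over ME1; ME1 over ME2) with
parametric F reference distributions on the multiplied degrees of freedom.
The isotropy assumption behind Goodall's F is strong; under the
generator's isotropic noise the type-I error of the sides and interaction
tests is within half a percentage point of nominal (verified over 800
simulated null datasets), but real wing covariance is anisotropic and the
F tests should be read as the original analysis chain's convention, not as
exact.

Percent-variance columns are computed from SS, not variance components, so
they sum to 100 across the table's rows.

Per-individual FA scores average replicates first, then take the
individual left-minus-right shape vector `a_i`, estimate directional
asymmetry as `DA = mean(a_i)`, and report `||a_i − DA||` (Procrustes FA
score) and the analogous Mahalanobis score in the metric of the sample
covariance of the `a_i`, restricted to its non-null eigenspace (the
covariance of n individuals in 34 informative dimensions is rank-deficient
whenever n ≤ 35; the retained rank is recorded in a warning attribute).
Mahalanobis scores are kept even though their repeatability is typically
poor — reproducing that exclusion decision is part of the analysis chain.
Size FA is the signed difference `CS_left − CS_right`; downstream
regressions use its absolute value by default (FA is a magnitude), with
the signed version retained and a toggle provided, since either convention
appears in the literature.

Repeatability is ICC(2,1) — two-way random effects, absolute agreement,
single measure — computed from mean squares with the Shrout–Fleiss F-based
confidence interval, applied to the individuals × measurements table of FA
scores from the replicated subset.

## Covariation

Two-block PLS takes the SVD of the cross-covariance matrix (n − 1
denominator) of the two column-centered blocks.  Blocks are centered but
never scaled — allele-frequency columns keep their natural variance, and
no per-locus standardization is applied.  Permutation tests shuffle the
rows of one block only (10,000 iterations by default), which destroys the
between-block covariance while preserving each block's internal
covariance; p-values use the `(exceedances + 1) / (n_perm + 1)`
convention, upper tail, for singular values, score correlations and the
RV coefficient alike (larger = stronger association).  Axis comparisons
use the absolute cosine (axes are sign-indeterminate) and an analytic
null: for uniformly random directions in dimension p, the squared cosine
is Beta(1/2, (p − 1)/2) distributed.

## Hybrid morphology

HI classes use strict thresholds — African below 0.1, European above 0.9,
boundary values hybrids — matching the verbal rule "smaller than 0.1".
The between-group PCA uses *unweighted* group means: with one 170-strong
hybrid class and a 27-strong parental class, weighting would let the
hybrid class drag the grand mean and axes; a weighted variant is exposed
as an option.  Leave-one-out classification recomputes group means (and,
by default, the between-group axes) with the focal individual excluded and
assigns to the nearest mean; ties break deterministically to the lowest
factor level.  Pairwise mean-shape distances are tested by shuffling class
labels within the pair (30,000 iterations by default).

The trajectory analysis measures the angle at the African vertex between
the vectors to the hybrid and European means.  Its p-value permutes class
labels and counts larger-or-equal angles (upper tail: a large angle means
transgressive hybrid morphology).  Under genuine intermediacy the observed
angle is *smaller* than label-permuted angles, so the test reports p near
1 — non-significant, as it should.  Label permutation was chosen over
residual randomization as the simplest null consistent with testing
"different from 0°"; this is a known point of divergence among
implementations and is the main reason trajectory p-values are only
qualitatively comparable across software.

FA–HI regressions fit linear and quadratic models and compare
`AIC = n log(RSS/n) + 2k`, its small-sample correction AICc, and BIC, with
k counting intercept, slope(s) and the error variance (3 and 4).  The
lower AICc wins; ties go to the linear model.  Shape FA is first
size-corrected by regressing on mean centroid size and keeping residuals
whenever size and FA covary.

## The synthetic-data generator

The generator emulates the study conditions end to end, with every
parameter echoed in the ground truth so downstream stages can be validated
against known quantities.  Defaults, with units and origin:

* **Hybrid-index mixture**: 26% Beta(2, 30) (African spike, mean ≈ 0.06),
  62% Uniform(0.1, 0.9), 12% Beta(30, 2) — a convenience matching the
  published category balance, not a demographic model.
* **Size model**: per-ancestry-class Normals, African 6453 ± 145 μm,
  hybrid 6560 ± 176 μm, European 6778 ± 195 μm.  The class-based model
  reproduces the published per-class moments exactly by construction; the
  cost is that size is flat in HI *within* the hybrid class, so the
  continuous size–HI correlation is weaker than a continuous cline would
  give.  That trade-off was chosen deliberately: the per-class moments
  are the stated calibration targets, the within-class dose-response is
  not.
* **Shape cline**: a fixed unit direction in shape space (deterministic
  construction, orthogonalized against translation, rotation and scaling
  at the template so it is a genuine shape change), traversed linearly in
  HI with total length 0.02 Procrustes units — the published
  African–European mean-shape distance.
* **Individual shape scatter**: isotropic, 0.0037 per coordinate; **shape
  FA**: a per-individual vector with sd 0.0021 per coordinate, drawn once
  and split half to each side; **shape DA**: a fixed vector of length
  0.003.  These three come from inverting the published mean-square
  partition of the full-sample and replicated ANOVA tables under the
  balanced-design expectations (e.g. `E[MS_int] = σ_ME² + r σ_FA²/2`).
* **Size FA** 30 μm (sd of the signed left−right CS difference, from the
  full-sample interaction mean square); size DA 0 (no directional size
  asymmetry was detectable).
* **Measurement error**: per-coordinate Gaussian noise of 3 μm per
  imaging session (ME1) and 2 μm per digitization (ME2), plus a 0.15%
  relative scale jitter per imaging session.  The jitter models slide
  remounting changing the effective magnification: it perturbs measured
  size but cancels in shape, which is exactly the pattern of the published
  error strata (imaging error two orders of magnitude larger for size than
  its shape footprint would imply).
* **Genotypes**: 14 loci × 4 alleles; deterministic ancestral profiles
  whose dominant allele rotates across loci, mixed per individual as
  `(1 − HI)·p_A + HI·p_E`, two draws per locus, encoded 0/0.5/1.
* **Transgression**: an optional hybrid-specific offset along a direction
  orthogonal to the cline, scaled by `4·HI·(1 − HI)`; 0 by default (pure
  intermediacy), nonzero only to exercise the trajectory test's
  alternative regime.
* **Replicates**: the first `n_replicated` (default 36) individuals get
  the 2 × 2 imaging × digitization grid; everyone else one measurement
  per wing.  Requesting replicated error strata with r1 or r2 = 1 is an
  error — they would be inestimable.

Each stored measurement receives a random nuisance rotation (±30°) and
translation, and left wings are stored mirrored, as a digitizer would
record them.  Regeneration from the same seed is bit-identical.

What the generator does **not** emulate: anisotropic within-class shape
covariance (no published covariance structure exists to calibrate one, so
noise is isotropic — real wing variation is strongly structured by the
venation), colony/pedigree structure (workers are treated as independent,
though real samples are clustered within hives), linkage between loci,
genotyping error, and any size–shape allometry beyond the isometric
component removed by scaling.  Passing tests on synthetic data therefore
demonstrate correctness of the computations and calibration of the tests
under the generator's assumptions, not robustness to the full structure of
real wing data.

## Problem sizes and test design

The test suite exercises: the replicated 36 × 2 × 2 × 2 design for
degrees-of-freedom bookkeeping; 100 random small designs (3–5 individuals)
for the per-coordinate ANOVA equivalence; 800 null datasets for the
Goodall F calibration; 1000 planted-null datasets per permutation test
(PLS RV, pairwise distances, trajectory angle, regression slopes) at 99
permutations each, with a 3–7% acceptance band around the nominal 5%;
populations of 120–300 individuals for recovery checks (DA direction,
FA-variance ordering, PLS1/bgPC1–HI correlations above 0.6, regression
slope 2.0 recovered within 0.05); and ten replicate populations of 300
individuals for the size-calibration coverage check (each class mean
within 2 standard errors of its target, at nominal coverage).  The
acceptance
script uses the full default population (283 individuals, 36 replicated)
at 10,000/30,000 permutations and completes in about a minute.

## Known limitations

* Goodall's F assumes isotropic, equal-variance shape noise; no
  permutation-based Procrustes ANOVA is provided.
* Only matching symmetry for paired 2-D structures is implemented — no
  object symmetry, semilandmarks or 3-D support.
* The Mahalanobis FA metric is estimated from the same sample it scores,
  which is rank-deficient below 36 individuals and noisy near that
  boundary; its scores are reported for protocol fidelity, not
  recommended for inference.
* Between-group PCA is a descriptive ordination; with few groups and many
  dimensions its axes are sensitive to group-mean sampling error, which is
  why classification is cross-validated and mean differences are
  permutation-tested.
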