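---
title: "Quantifying digitization and device error in 3D geometric morphometrics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying digitization and device error in 3D geometric morphometrics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gmerror)
```

## The problem

Landmark-based geometric morphometrics quantifies biological shape from
Cartesian coordinates of homologous points after removing size, position and
orientation. When the same specimens are imaged on different devices (for
example a high-resolution µCT scanner versus a cheaper, lower-resolution
structured-light surface scanner) and digitized repeatedly, the interesting
question is how much of the total shape variation is biological signal —
differences between individuals, bilateral asymmetry, sexual dimorphism —
and how much is measurement error: random digitization noise and systematic
device signatures. `gmerror` implements the full repeated-measure analysis
chain for this question and a synthetic-data generator with known variance
components so every stage can be validated end to end.

## The model and procedure

**Superimposition.** Configurations of $p$ points in 3D are centered, scaled
to unit centroid size ($\mathrm{CS} = \sqrt{\sum_i \lVert x_i - \bar x
\rVert^2}$), and rotated to a consensus by generalized Procrustes analysis
(GPA): rotations are the SVD solution with determinant $+1$ enforced, the
consensus is the coordinate-wise mean renormalized to unit size, and the
loop stops when the consensus moves less than `tol` (default $10^{-10}$,
`max_iter` 100). The aligned sample is finally rotated to the consensus'
principal axes with a skewness-based sign convention, so results do not
depend on the arbitrary common orientation of the input. Aligned shapes are
projected orthogonally to the tangent space at the consensus,
$t = (I - cc^\top)(x - c)$ with $c$ the flattened unit consensus; these
$3p$-dimensional tangent coordinates are the shape variables for all
statistics. Orthogonal rather than stereographic projection is used; for
the small shape variation typical of intraspecific data the difference is
far below the measurement error quantified here.

**Sliding semilandmarks.** Curve semilandmarks carry one degree of freedom
(along the unit chord between their two neighbors) and surface patch points
two (the top-2 principal directions of their neighbor set centered on the
point). `slide_gpa()` alternates GPA with moving every sliding point by the
orthogonal projection of its deviation from the consensus onto its tangent
basis — the Procrustes-distance criterion, not bending energy. Tangent
frames are estimated on the consensus (stable across specimens; a
per-specimen option exists). Three cycles (`n_cycles = 3`) are the default;
the objective is monitored and non-increasing. Because only point data are
available at analysis time, a patch point's "surface" is approximated by
its 6 nearest sliding/patch neighbors on the template — a point-set
analogue of sliding on a mesh, and the one modelling step users should be
aware of when importing mesh-derived patch definitions.

**Object symmetry.** Each configuration is paired with its mirrored copy
(one coordinate negated, bilateral pair rows swapped, midline rows kept)
and the doubled sample is superimposed jointly. The consensus is
symmetrized about the mirror plane at every iteration, which makes the
reference exactly bilaterally symmetric; a consequence is that the aligned
mirrored copy equals `mirror_relabel()` of the aligned original to
numerical precision, so the decomposition
$\text{symmetric} = \tfrac12(\text{orig} + \text{mirrored})$,
$\text{asymmetric} = \text{orig} - \text{symmetric}$ is exact and midline
asymmetry is confined to the mirror-normal direction. All copies are
aligned with proper rotations: `mirror_relabel()` already returns a
non-reflected configuration, and permitting reflections during alignment
could undo the relabelling and silently collapse true asymmetry. The mirror
axis defaults to `x`; `"auto"` picks the axis along which bilateral-pair
midpoints of the first configuration spread least, which assumes the data
are roughly oriented with the symmetry plane near a coordinate plane (after
alignment the choice is only an orientation convention, because mirroring
about different axes differs by a proper rotation).

**Variance partitioning.** `procrustes_anova()` decomposes the summed
squared variation of the tangent coordinates over an ordered factor
sequence with sequential (Type I) sums of squares; $F = \mathrm{MS}_
\text{factor}/\mathrm{MS}_\text{residual}$. Degrees of freedom follow the
standard linear model on specimen counts (18/19/76 for the 19-individual,
two-device, three-replicate design), not the shape-dimension-multiplied
bookkeeping some desktop programs print; percent variance
($100 \cdot \mathrm{SS}/\sum \mathrm{SS}$) is unaffected by that choice.
Significance uses residual randomization under the reduced model: the
residuals of the model without the tested term are permuted across
specimens, the statistic recomputed, and $p = (b+1)/(n_\text{perm}+1)$
(999 permutations by default, seed mandatory, never zero). The effect size
$Z$ is the standardized position of $\log F$ in the permutation
distribution, observed value included — a convention documented here
because published tables rarely define it. An `exact` mode enumerates all
$n!$ permutations for $n \le 8$ and is used by the test suite against an
enumeration oracle. `symmetry_anova()` applies the engine to the doubled
sample with the classical sequence Individual, Side (directional
asymmetry), Ind:Side (fluctuating asymmetry), Device, Residuals (replicate
digitization).

**Error metrics.** Repeatability is the intraclass-correlation analogue
from a balanced one-factor (individual) Procrustes ANOVA:
$s^2 = (\mathrm{MS}_\text{among} - \mathrm{MS}_\text{within})/r$ and
$R = s^2 / (s^2 + \mathrm{MS}_\text{within})$ with $r$ replicates per
individual. Negative values are reported with a warning, not clamped —
clamping hides degenerate designs. `repeatability()` re-runs the entire
superimposition (and symmetric-component extraction when a bilateral map is
given) on each requested subset — per device, and for `all`,
`fixed_curves` or `fixed_only` landmarks — because repeatability of a
subset is a property of that subset's own alignment. Per-cell Procrustes
variance (one cell = the replicates of one individual on one device) is the
mean squared deviation from the cell mean with denominator $n$, following
the trace-of-covariance definition (an $n-1$ option exists and is off by
default); the device-level value is the unweighted mean over cells, and two
devices are compared by permuting device labels within individuals.

**Classification.** Between-group PCA takes the principal components of the
group mean shapes (groups weighted equally) and projects all specimens onto
those $\le g-1$ axes. Leave-one-out cross-validation drops one specimen,
refits means *and axes* by default (refitting only means is an option),
projects the held-out specimen and assigns it to the nearest group mean by
Euclidean distance in score space — Mahalanobis would be poorly conditioned
in a $\le g-1$-dimensional space estimated from tiny samples. Ties break
deterministically toward the first group in label order, with a warning.
Replicates are averaged per individual and device before classification
(`average_replicates()`), keeping devices separate, while the dimorphism
ANOVA uses all replicates — mirroring standard practice for this design.
Accuracy, row-normalized rates and Cohen's $\kappa$ come from the confusion
matrix.

## The synthetic generator

`simulate_landmarks()` emulates a repeated-measure two-device study on a
deterministic template: points on a hemiellipsoid (semi-axes 10, 14, 8 mm —
about the proportions of a small rodent cranium) with exact mirror pairs
about $x = 0$; the default budget is 58 fixed landmarks, 145 curve
semilandmarks in chains anchored by fixed points, and 86 patch points, 289
in total, for 19 individuals × 2 devices × 3 replicates = 114
configurations. Effects are Gaussian displacement fields, each rescaled so
its realized mean per-coordinate variance equals its stated $\sigma^2$
exactly (this makes analytical expectations exact rather than asymptotic):

* symmetric individual fields (`sigma_individual`, default 0.110 mm),
* one shared anti-symmetric directional-asymmetry field (`da_magnitude`,
  0.068),
* per-individual anti-symmetric fluctuating asymmetry (`sigma_fa`, 0.032),
* a fixed smooth systematic field added to the second device
  (`device_offset_scale`, 0.128): a pure-quadratic polynomial in the
  template coordinates, symmetrized and projected onto the orthocomplement
  of the translation/rotation/scale directions so superimposition cannot
  absorb it — device error is a coherent shape shift, visible in PCA, not
  extra noise,
* per-replicate digitization noise (`sigma_digitization`, 0.070 / 0.042 mm
  — the first device noisier, variance ratio ≈ 2.8),
* a symmetric dimorphism field added to males (`sex_effect`, 0.090), with
  11 of 19 individuals sexed (7 female),
* nuisance: a uniform random rotation, translation up to one template
  diameter, and scale in [0.5, 2] per configuration.

The defaults were chosen once so the per-coordinate variance shares
reproduce the study regime this design targets — individual ≈ 48%,
directional asymmetry ≈ 18%, device ≈ 16%, digitization ≈ 13%, fluctuating
asymmetry ≈ 4% (the device field enters at a quarter of its squared scale
because only half the sample is displaced by it). Realized sequential-SS
shares differ from these naive ratios in the classical way (each fitted
factor absorbs a df-proportional slice of the noise), which the test suite
accounts for by testing orderings and recoveries, not exact shares. The
expected repeatability is the plain per-coordinate ICC
$\sigma^2_\text{ind}/(\sigma^2_\text{ind} + \sigma^2_\text{dig})$, exact up
to the seven degrees of freedom absorbed by superimposition; it refers to
the analysis *without* symmetric-component extraction, which halves the
noise term. A `tangential` digitization mode puts noise only at sliding
points, along their template tangent directions — used to verify that
sliding removes what it is supposed to remove (>90% of such noise in the
tests; in practice ~99.9%).

What the generator does **not** emulate: landmark-to-landmark noise
covariance (noise is independent per point), mesh-level artifacts
(smoothing, holes), operator-specific biases, and — importantly — the
anisotropy of real biological variation. Real within-species variation
concentrates in few directions that overlap dimorphism; the generator's
isotropic individual fields make group means more separable at a given
variance share than real data would be, so between-group-PCA accuracy on
synthetic data is optimistic even when the dimorphism *variance share*
matches a real study (the `sex_effect` default is calibrated to a ~0.095
R² share, not to a target accuracy). Passing tests therefore demonstrate
correctness of the algorithms and calibration of the tests, not
field-realistic classification rates.

## Numerical choices and degenerate inputs

Unit-centroid-size scaling (not mean-size) is used throughout; all reported
statistics are ratios and insensitive to the convention. Rotations come
from the SVD of the 3×3 cross-product matrix with the smallest singular
vector's sign corrected to enforce $\det = +1$; reflections are permitted
only where requested. Zero centroid size, coincident slider neighbors,
collinear patch neighborhoods, confounded factors, saturated designs,
singleton variance cells, unbalanced replicate counts (the ICC formula
assumes balance) and single-member classification groups are all rejected
with messages naming the offending point, specimen or factor. Missing
coordinates are rejected, never imputed — imputation would contaminate the
error estimates this package exists to measure. Landmark files use 1-based
point indices, matching the package's internal indexing.

## Problem sizes in the tests

The test suite exercises the full 289-point, 114-configuration design where
the design itself is under test, and smaller templates (e.g. 31 points, 6
individuals) for statistical recovery loops that repeat over many seeds:
20-seed recovery runs for repeatability and device-variance ratios, 200
simulated null datasets with 499 permutations each for type-I-error
calibration, and 200 null classification runs. These sizes give standard
errors comfortably below the tested tolerances while keeping the suite
quick to run.
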