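---
title: "Methods: radiomics test-retest repeatability with radstab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: radiomics test-retest repeatability with radstab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radstab)
```

## The problem

A radiomics feature is only usable as an imaging biomarker if it is
*repeatable*: scanned twice under unchanged conditions, the same subject
should yield (nearly) the same value. radstab implements a complete
test-retest repeatability analysis for features extracted from volumetric MR
images — prostate mpMRI being the motivating setting — and makes it testable
end to end by pairing it with a synthetic phantom cohort whose
between-subject and within-subject variance structure is known exactly.

The pipeline is: intensity normalization → image pre-filtering →
fixed-bin-width grey-level discretization → feature extraction (first-order,
shape, GLCM, GLRLM, GLSZM) → per-feature ICC(1,1) → study-level summaries.

## The repeatability model

With one measurement pair per subject, both the between-subject and the
within-subject (scan-to-scan) variability are modelled as independent random
effects, which leads to the one-way random-effects intraclass correlation

$$\mathrm{ICC}(1,1) = \frac{\mathrm{BMS} - \mathrm{WMS}}
                           {\mathrm{BMS} + \mathrm{WMS}},$$

where BMS and WMS are the between- and within-subject mean squares of a
one-way ANOVA with $k = 2$ replicates. BMS estimates the population
heterogeneity, WMS the scan-to-scan noise. The estimator is affine-invariant
(`icc(a x + b) = icc(x)`) and ranges over $[-1, 1]$; negative estimates are
*retained*, because truncation at zero would bias the rank-based summaries
built on top.

Confidence intervals use the classical F-based construction: with
$F = \mathrm{BMS}/\mathrm{WMS}$,
$F_L = F / F_{1-\alpha/2}(n-1,\, n)$ and
$F_U = F \cdot F_{1-\alpha/2}(n,\, n-1)$, each bound mapping through
$(F^\ast - 1)/(F^\ast + 1)$ for $k = 2$. The default `alpha = 0.1` gives the
90% intervals that repeatability plots conventionally show. Other interval
constructions exist and differ slightly in width; they never change the
point estimate. Subjects missing a value at either timepoint are dropped
pairwise per feature, and the retained `n` is recorded in every result row.
When all $2n$ values are identical both mean squares vanish and the ICC is
undefined: such features are flagged missing rather than forced to a value.

## Preprocessing

**Normalization.** MR intensities are relative, so two affine schemes are
provided. *Whole-image*: shift/scale all voxels to mean 300 / SD 100, which
puts most intensities in 0–600 for roughly Gaussian histograms.
*Reference-region*: fit the affine map on a muscle reference ROI so that the
ROI reaches mean 100 / SD 10, then apply that single map to every voxel;
muscle is used because it is more homogeneous than prostate tissue and
assumed stable across subjects and timepoints. Both are pure affine maps:
they preserve intensity rank order, and leave Skewness and Kurtosis of any
ROI untouched. The SD is the population (divide-by-N) convention — at image
scale the distinction from the sample convention is negligible, but fixing
it makes the contracts exact. No outlier clipping is applied before the
statistics are computed, and background voxels are not excluded.

**Filter bank.** Eighteen derived images per input by default: the original;
Laplacian-of-Gaussian at sigmas 1–5 mm; the eight sub-bands of a single-level
*undecimated* 3-D wavelet transform; and four single-voxel transforms
(square, square root, logarithm, exponential). Choices a practitioner may
care about:

* LoG sigmas are interpreted in millimetres: the per-axis Gaussian SD in
  voxels is `sigma_mm / spacing`, so anisotropic voxels are honoured. The
  second-derivative kernel shares the sampled Gaussian's normalizer and is
  projected to exact zero sum, so constants map to exactly zero. Boundaries
  are handled by mirror reflection.
* The wavelet family defaults to Coiflet-1 (configurable, `haar` also
  built in); the transform is stationary (no decimation) with symmetric
  padding, so geometry is preserved and no sub-band alignment ambiguity
  arises beyond the even-filter half-sample convention, which is fixed to
  the left-of-centre tap.
* The intensity transforms rescale transformed magnitudes so the maximum
  absolute intensity equals the pre-transform maximum, then restore the
  original sign. The exponential is computed as `exp(x - max(x)) * max|x|`,
  which is algebraically the same contract and cannot overflow.

Shape features depend only on the mask, so they are computed once per ROI
and are bit-identical across all filters — a property the test suite
asserts rather than assumes.

## Discretization and texture matrices

Grey levels use fixed-bin-*width* discretization anchored at the ROI
minimum: `level(x) = floor((x - min)/w) + 1`, computed from the intensities
*inside* the ROI only. The study grid is w ∈ {10, 15, 20, 40}; after
whole-image normalization (range ≈ 0–600) any w ≥ 5 keeps the level count
under 128, and w = 40 does so for ranges up to 5120. An alternative mode
aligning bin edges to multiples of w is available (`aligned = TRUE`) for
compatibility with implementations that anchor bins at zero.

Texture matrices and their conventions (all chosen once and recorded in the
matrix objects, since the field's tools differ silently on them):

* **GLCM** — distance 1, symmetric accumulation, 13 unique directions in 3D
  and the 4 in-plane directions in 2D (which merges slices); matrices are
  summed over directions *before* normalization ("merged" aggregation), so
  each configuration yields one feature value.
* **GLRLM** — maximal same-level runs along the same direction sets, broken
  by the ROI boundary; the run-length-weighted mass equals
  `n_voxels * n_directions`. Under merged aggregation `RunPercentage` is
  defined as `N_runs / (n_voxels * n_directions)` so it stays in (0, 1].
* **GLSZM** — connected components of constant level with 26-connectivity
  in 3D and 8-connectivity in 2D; the zone-size-weighted mass equals the
  ROI voxel count.

Each builder is verified against an independent brute-force oracle
(exhaustive pair enumeration, a run scanner, a flood fill) on hundreds of
random small grids.

## Feature definitions

First-order moments use the population convention; Kurtosis is reported
non-excess (a Gaussian scores 3); percentiles interpolate linearly between
order statistics (R's type 7); Entropy is the base-2 Shannon entropy of the
discretized ROI intensities with `0 log 0 = 0`. Volume is voxel-count
volume (count × voxel volume) rather than mesh volume — deterministic on
tiny fixtures, and immaterial to ICC comparisons because the ICC is
scale-invariant. Surface area counts exposed voxel faces; diameters are
measured between voxel centres (restricted to surface voxels for speed);
axis lengths come from the eigenvalues of the voxel-coordinate covariance.

Features that are deterministic functions of retained features are excluded
from the roster (`Compactness1/2` and `SphericalDisproportion` vs
`Sphericity`; `SumAverage` vs `JointAverage`; `Homogeneity1/2` vs `Idm`), as
are `Flatness` and `LeastAxis`, which are meaningless for single-slice ROIs.
`SumAverage` is still computed internally so the identity
`SumAverage = 2 * JointAverage` can be tested. Features undefined on
degenerate inputs (e.g. `Correlation` on a constant ROI) are emitted with a
missing value — never dropped — and excluded pairwise from the ICC.

## The phantom generator

`phantom_spec()` defines a cohort of prostate-like volumes imaged twice.
What it emulates, and how the variance budget is split:

| source | mechanism | default |
|---|---|---|
| between subjects | additive tissue-intensity shift | `sigma_b = 20` |
| between subjects | lesion radius ~ N(5, 1) mm, centre jitter 1 mm | |
| between subjects | gland axes scaled by `exp(N(0, 0.08))` | |
| between subjects | Gaussian-random-field texture, correlation length 2 mm, SD 15 | shared by both scans |
| within subject | i.i.d. voxel noise | `sigma_w = 10` |
| within subject | global gain ~ N(1, 0.05), offset ~ N(0, 10) per scan | exercises normalization |
| within subject | tumor contour jitter: one-voxel in-plane dilation/erosion with probability 0.15 per scan | emulates re-contouring |

The anatomy is a gland ellipsoid with a posterior peripheral-zone band, a
darker spherical lesion, and a homogeneous low-intensity muscle cylinder
placed outside the prostate (the reference region). Labels are
hierarchical — tumor ⊂ peripheral zone ⊂ whole gland — with an ROI being a
union of label codes. The default grid is 40×40×16 voxels at 1×1×3 mm,
axial-T2w-like. Contour-jitter magnitude is a free parameter: real studies
do not quantify segmentation inconsistency between timepoints, so it is a
modelling choice, not a calibration.

Seeding uses one master seed with per-subject sub-streams, so the first
*k* subjects are unchanged when the cohort grows, and the whole cohort is a
pure function of the spec — byte-for-byte through the image writer.

For a restricted spec (texture amplitude 0, no contour jitter, fixed lesion
geometry, gain/offset fixed) the ROI-mean feature has the closed-form ICC
$\sigma_b^2 / (\sigma_b^2 + \sigma_w^2/N)$, where $N$ is the lesion voxel
count: scan noise averages down over the ROI. `calibrate_phantom_icc()`
inverts this to target a chosen true ICC, which is how parameter-recovery
simulations are built. Outside the restricted regime (texture on, jitter
on) no closed form exists and the generator is validated by its empirical
variance structure instead.

What the phantom does *not* emulate: MR physics (no k-space, bias fields or
distortions), inter-scanner or inter-protocol variation, anatomically
realistic texture, or reader variability beyond the one-voxel jitter model.
Passing tests therefore demonstrate correctness of the *pipeline* under a
known generative model, not repeatability magnitudes of any clinical
dataset: reproducing a clinical study's ICC values requires its images.

## Study-level summaries

* **Volume reference** — the ICC of `Volume` per ROI/image type is the
  within-study threshold for calling a feature repeatable; being a shape
  feature it is identical under every filter fingerprint.
* **Bin-width sensitivity** — per (feature, filter), the max–min ICC range
  across bin widths, and a rank histogram (rank 1 = best ICC per key; ties
  share the minimum rank; each width's counts sum to the key count).
* **Top-k per class** — features ranked by their best-configuration ICC,
  i.e. the maximum over the filter grid at the reporting bin width
  (default 15); ties break lexicographically by feature name so reports are
  reproducible.
* **Filter frequency** — how often each pre-filter carries a feature above
  the Volume reference; a feature exceeding under several filters counts for
  each of them.
* **Normalization delta** — per-feature ICC change between two
  normalization modes, plus the union of both modes' top-k sets (up to 2k
  features per class).

`build_report()` is a pure function of the ICC table, so a report can be
reproduced exactly from a persisted `icc.csv`. Plots (`autoplot()`,
`plot_icc_panel()`, ...) are presentation only; the CSV tables are the
contract.

## Problem sizes used by the test suite

The suite validates the texture builders on 200+ random grids up to 6³
voxels against brute-force oracles; parameter recovery runs 500 phantom
cohorts of 15 subjects on a 16×16×8 grid (mean recovered ICC within ±0.05
of the generating 0.7, 90% CI coverage within 90% ± 4%); the end-to-end
demonstration study uses 5 subjects with a reduced grid (2 normalizations ×
3 filters × 2 bin widths, 2D) and is checked to be byte-identical across
reruns. These sizes were chosen so the full suite completes in minutes on a
single CPU while leaving every statistical check adequately powered.

## Known limitations

* The hierarchical label model cannot represent overlapping ROIs that are
  not nested.
* Contour jitter can push single tumor voxels beyond the anatomical
  peripheral zone; the hierarchical codes absorb this, mirroring how
  expert re-contouring can disagree with anatomy.
* First-order features are replicated across the 2D/3D grid axis (their
  values do not depend on texture dimensionality); consumers should expect
  identical values there by design.
* Exact numerical agreement with any particular third-party radiomics
  implementation is not a goal; conventions above are documented precisely
  so that differences are explainable.
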