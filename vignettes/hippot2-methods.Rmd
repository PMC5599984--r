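---
title: "Automated hippocampal T2 relaxometry: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated hippocampal T2 relaxometry: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hippot2)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and their defaults, what the synthetic
data emulate (and what they do not), and the design decisions taken where
the underlying methodology leaves choices open.

## The measurement problem

Hippocampal sclerosis produces two quantitative MRI signatures: volume
loss, measurable once the hippocampus is segmented, and elevated T2
relaxation time, measurable from a T2 map. The obstacle to automating the
T2 half is cerebrospinal fluid: the hippocampus borders CSF (temporal
horn, choroidal fissure), CSF has a T2 on the order of seconds against
~80–130 msec for brain tissue, and any voxel that mixes the two is pulled
sharply upward. Manual practice handles this by keeping hand-drawn ROIs
small (~20 mm² per slice) and away from fluid — at the cost of sampling a
small fraction of the structure, rater dependence, and poor scan-rescan
reproducibility. The automated chain here instead measures the whole
structure and removes the contaminated shell explicitly.

## Voxelwise T2 from two echoes

With two echo times the monoexponential model `S(TE) = A·exp(−TE/T2)` is
exactly identified and the fit is closed-form per voxel:

$$T2 = \frac{TE_2 - TE_1}{\ln(S_1 / S_2)}$$

There is no least-squares choice to make — that would only arise with
three or more echoes, which are out of scope. Defaults `te1 = 30`,
`te2 = 119` msec correspond to a typical clinical 3T dual-echo fast
recovery fast spin echo protocol.

Numerical policy (the model itself is silent on these, so they are
package decisions):

* voxels with `S1 ≤ 0`, `S2 ≤ 0` or `S1 ≤ S2` (no decay) have no physical
  solution and are **masked invalid** rather than clamped; all downstream
  statistics skip them;
* a configurable validity ceiling (`t2_max = 3000` msec) also invalidates
  near-equal echo pairs whose implied T2 diverges, keeping maps finite;
* computation is double precision; maps are written as float32 NIfTI with
  a uint8 validity companion.

At the late-echo SNR of 50 that the phantom simulates, Rician noise
biases the estimator upward by well under 1% for tissue-range T2, which
the suite verifies by Monte-Carlo.

## The ROI chain: resample, erode, threshold, pool

Order of operations is fixed: the segmentation is (1) resampled onto the
T2-map grid through the supplied rigid transform, (2) eroded, (3)
stripped of voxels with T2 above the CSF cutoff, then (4) summarized as a
voxel-pooled mean. Erosion before thresholding matters: erosion removes
the geometric partial-volume shell, the threshold catches whatever
contaminated voxels survive it.

Decisions taken where the procedure is conventionally underspecified:

* **Resampling** is nearest-neighbour pull-back (each reference voxel's
  world center mapped through the inverse transform to the nearest source
  voxel). Labels are never interpolated, so no fractional labels can
  appear. The transform convention is source-world → target-world, with
  an `invert` flag for tools that store the opposite direction.
* **Erosion element**: one iteration of a 3×3 *in-plane* square. With
  4 mm coronal slices over ~0.4 mm in-plane voxels, a 3-D element would
  eat a 4 mm shell from both through-plane faces and destroy the
  structure; in-plane erosion removes the boundary where partial volume
  actually lives. A `full-3D` 6-connected mode exists for isotropic data.
* **Threshold comparison is strict**: a voxel at exactly 170 msec is
  retained; only `T2 > 170` is removed.
* **The mean is voxel-pooled** over the whole ROI, not slice-averaged;
  the slice-wise view is exposed separately as `slice_profile()`, ordered
  anterior→posterior by the world y direction of the affine (anterior T2
  tends to run higher, and anteroposterior profiles are a natural
  extension of the single-number summary).
* `min_voxels = 20` flags degenerate ROIs as unreliable rather than
  erroring — a measurement from a handful of voxels is reported but not
  trusted.

On a noiseless phantom whose segmentation overreaches one voxel into an
abutting ventricle, the unprocessed mean is ~39 msec above truth while
the eroded-and-thresholded mean equals truth exactly; the acceptance
suite pins both facts.

## Calibrating the CSF cutoff

The shipped cutoff of 170 msec is the operating value for the default
protocol. For other scanners or sequences, `calibrate_cutoff()` re-derives
it from pooled control gray-matter and CSF T2 samples. The conventional
procedure — "inspect the two distributions and pick the crossing" — is
operationalized as an explicit, reproducible loss: a 1 msec grid search
over `[median(GM), median(CSF)]` minimizing
`P(GM > c) + P(CSF ≤ c)`, ties broken toward the lower candidate
(pooled across control subjects; a per-subject cutoff would couple the
measurement to per-subject segmentation quality).

One property worth stating honestly: with *subject-level* GM statistics
(SD ~4 msec) the equal-weight optimum sits near 129 msec, not 170. The
operating value of 170 msec is consistent with the *voxel-level* spread
of GM T2 in the partial-volume shell (SD of order 15–20 msec), which is
what a voxelwise calibration actually sees; the suite demonstrates both
regimes. Tissue labels taken from probability maps should be thresholded
hard (p > 0.9) so that partial-volume voxels do not blur the classes.

## Volume correction and reference ranges

Head-size correction uses the regression-residual ("covariance") method:
an OLS slope of hippocampal volume on intracranial volume fitted in
controls, then `corrected = raw − b·(ICV − mean ICV_controls)`. Centering
at the control ICV mean keeps corrected volumes in natural cm³ units,
preserves the control-group mean exactly, and makes corrected control
volumes orthogonal to ICV. Left and right hippocampi share a single
pooled model (controls show no volume laterality).

Reference ranges are `mean ± 1.96 SD` in controls. Bilateral ranges pool
the two sides with the exact concatenation moments

$$s^2_{pool} = \frac{(n-1)(s_L^2+s_R^2) + n\left[(m_L-m)^2+(m_R-m)^2\right]}{2n-1}$$

— the only pooling consistent with treating the 2n per-side measurements
as one sample (note it is *not* the average of the side SDs, and for
identical sides it is smaller than either SD by the Bessel factor
$\sqrt{2(n-1)/(2n-1)}$). For the shipped control statistics this yields
108.5–123.8 msec (T2) and 2.51–3.55 cm³ (volume), with per-side T2
upper bounds 123.6 (left) and 123.9 msec (right).

## Classification

Side-wise binary logistic regression on (corrected volume, mean T2),
fitted by IRLS (tolerance 1e-8, ≤100 iterations) with perfect separation
reported via a flag rather than an error. The labeling convention — not
uniquely determined by the study design — is: for the left-side model,
left-HS and bilateral-HS hippocampi are pathologic; controls and the left
hippocampi of right-HS subjects are non-pathologic (mirrored on the
right). Contralateral hippocampi are deliberately kept in the negative
class even though contralateral T2 runs ~2–3 msec high, because that is
the clinically relevant contrast. The decision threshold is fixed at 0.5.
Reported rates are training classification (no cross-validation), matching
how such models are conventionally summarized for this cohort size; all
three models (volume-only, T2-only, combined) can be fitted via the
`features` argument.

## The digital phantom and synthetic cohorts

The phantom emulates the *measurement physics*, not anatomy: a GM shell
over a WM core, two ~3 cm³ hippocampal ellipsoids with CSF ventricle
compartments 6-adjacent to them (so the partial-volume hazard is present
by construction), dual-echo images from the forward model plus Rician
noise `sqrt((S+σZ₁)² + (σZ₂)²)`, on a 128×128×32 grid of
0.43×0.43×4 mm voxels — a 4× in-plane downscale of a 512×512 clinical
matrix, chosen so a full phantom generates in well under a second.
Compartment T2 defaults are WM 80, GM 110, hippocampus 115, CSF 2000
msec; proton densities 70/85/90/100. The default noise level sets the
late-echo hippocampal SNR to 50, typical of the targeted acquisitions;
σ is freely configurable and σ = 0 gives the exact-inversion regime.
`hippo_scale` shrinks the hippocampi (~0.87 ≈ 2 cm³) to simulate
atrophy, and per-side T2 can be raised to simulate sclerosis.

Synthetic cohorts draw per-hippocampus (corrected volume, mean T2) from
group-level bivariate Gaussians (controls n = 50, left HS n = 27, right
HS n = 18, bilateral HS n = 5 by default). Left-right values of a
measure correlate at 0.3 within subject — a realism choice, not an
estimated quantity; volume and T2 are drawn independently.

The scan-rescan study generates two scans per subject with independent
noise and ±1 voxel whole-head repositioning, measuring each hippocampus
with the automated chain and with simulated manual 20 mm² elliptical
ROIs (aspect 2:1, centered on the per-slice centroid with 1 mm Gaussian
placement jitter, no erosion or threshold — faithful to manual
practice). Automated whole-ROI measurement averages thousands of voxels
and is insensitive to repositioning; jittered small ellipses are not, and
occasionally clip CSF. The suite asserts the direction (automated SD of
differences < manual), not magnitudes: the simulated SDs depend on σ and
jitter choices and are far tighter for the automated method than real
scans, where physiological and positioning variability dominate
thermal noise.

What passing phantom tests does *not* show about real data: no real
anatomy or segmentation error model, no B1/stimulated-echo effects, no
motion beyond rigid repositioning, no k-space artifacts, and Gaussian
group features with assumed cross-side correlation. The phantom validates
the *algorithmic* chain — fit, geometry, exclusion, statistics — not
scanner fidelity.

## Problem sizes and determinism

Every generator is a pure function of its seed. The suite and the
acceptance script use: noiseless phantoms on the default grid for
exactness checks; a 64×64×24 grid for unit tests of ROI logic; 100
subjects (200 hippocampus pairs) for the reproducibility study; 200
cohort replicates for classification rates; 10⁴ replicates for t-test
type-I calibration; brute-force oracles on ≤ 32³ grids. These sizes give
sampling error comfortably below the asserted margins while keeping the
full suite in the minutes range.

## Known limitations

* Dual-echo T2 assumes monoexponential decay in mixed voxels and is
  noisier than multiecho CPMG fitting; multiecho, multicomponent T2 and
  stimulated-echo correction are out of scope.
* Rigid-transform *estimation* and hippocampal/tissue *segmentation* are
  external: the package applies supplied transforms and masks.
* Subfield-level measurement (CA1/CA3/dentate) is not attempted at 4 mm
  slice thickness.
* The shipped normative ranges describe one acquisition protocol; T2
  values are not transferable across protocols, and recalibration of both
  cutoff and ranges is expected for other scanners.
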