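---
title: "Methods: localizing the subcortical auditory system with subcortaud"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: localizing the subcortical auditory system with subcortaud}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(subcortaud)
```

## The problem

The ascending auditory pathway passes through four pairs of small, deep
nuclei — the cochlear nucleus (CN), superior olivary complex (SOC), inferior
colliculus (IC) and medial geniculate body (MGB). They are hard to see with
in vivo anatomical MRI, but they respond vigorously to sound, so they can be
*functionally* localized: present many natural sounds in a sparse
event-related design, fit a voxelwise GLM for sound versus silence, threshold
each subject's map, and aggregate the binarized maps across subjects into a
probabilistic atlas. `subcortaud` implements that analysis chain, the
validation machinery around it (leave-one-out atlases, overlap and
centroid-distance scoring, Dice and average Hausdorff agreement), and the
companion diffusion side: ODF peak extraction, deterministic peak-following
tractography, and ROI-constrained connectivity fingerprints. Because the
package is meant to be testable without scanner data, a synthetic-data module
generates every input with known ground truth.

## The single-subject GLM

The signal model for run $r$, voxel $v$ is

$$ y_{rv}(t) = \beta_v\, (s_r * h)(t) + \sum_{c=1}^{k} \gamma_{cv}\, n_{rc}(t)
   + \mu_{rv} + \varepsilon_{rv}(t), $$

where $s_r$ is the onset indicator, $h$ a 9-tap FIR hemodynamic response
sampled at the volume interval, $n_{rc}$ data-driven noise regressors and
$\mu$ a run intercept. Catch trials (stimulus repetitions the participants
respond to) are modelled by a separate regressor of no interest and never
enter the contrast.

Everything data-driven is estimated under cross-validation so the test-run
fits are unbiased. Each run serves once as the test set of an outer fold; on
the fold's training runs the package:

1. **Selects the noise pool** (`select_noise_pool()`): an F test of the
   9-stick stimulus model against intercept-only, per voxel; the pool is
   every brain voxel below the critical value at `f_alpha` (default 0.05,
   i.e. voxels *not* significant at the uncorrected 5% level). The level is
   configurable because only the existence of a threshold, not its value, is
   prescribed by the design.
2. **Deconvolves the HRF** (`deconvolve_hrf()`): per-voxel 9-tap FIR least
   squares on the concatenated training runs; the subject-level HRF is the
   peak-normalized average over the top-decile most responsive voxels
   (stick-model F), which stabilizes the small test-run fits. A per-voxel
   variant is available (`per_voxel = TRUE`). When no voxel survives a
   Bonferroni-corrected F test the aggregation is refused rather than
   returning a normalized noise vector.
3. **Chooses k** (`optimize_k()`): for each candidate number of
   principal-component noise regressors, an inner leave-one-run-out
   cross-validation fits the stimulus-plus-noise model on the inner-training
   runs and scores variance explained on the held-out run. The noise
   regressors share one spatial basis (principal components of the
   concatenated inner-training pool); their per-voxel loadings, learned on
   the training runs, transfer to the held-out run whose regressors are
   obtained by projecting that basis onto its own pool time courses. The
   median score across voxels is maximized, with ties within `tol` (0.005
   variance-explained units) resolving to the smallest k.

The test run is then fitted by OLS with the HRF-convolved stimulus regressor
plus its own pool-derived principal-component regressors
(`compute_noise_regressors()`, orthonormal per run), and the per-run
estimates are pooled by inverse-variance fixed effects
(`fixed_effects_combine()`): $\hat\beta = \sum_i \beta_i/s_i^2 \big/ \sum_i
1/s_i^2$, $\mathrm{Var} = 1/\sum_i 1/s_i^2$, degrees of freedom summed.
P-values are one-sided positive by default — activation mapping of sound
versus silence — with a two-sided option (`sided = "two"`), since sidedness
is a convention rather than a derived fact.

### Why the k-selection score includes the pool voxels

The synthetic cohort plants its structured noise strictly outside the
responsive nuclei, so that the noise-pool selection step has an exactly
recoverable truth. A consequence is that the voxels *outside* the estimated
pool carry almost no structured variance, and a cross-validated score
restricted to them is flat in k: the number of components would be decided by
noise. The default score therefore spans all brain voxels. There is no
leakage: the loadings applied to the held-out run are estimated on the
training runs only, and a spurious (beyond-rank) component adds
training-noise loadings multiplied by an independent held-out time course,
which strictly worsens the score. `score_voxels = "nonpool"` restores the
restricted variant for data whose responsive voxels do share the structured
noise. With brain-wide scoring, ten seeded replicates recover a planted
3-component process as $k^\* = 3$ in all ten, and pure-white-noise
replicates select $k^\* = 0$.

### Fold layout

The acquisition design this emulates — 12 runs per session, four stimulus
sets, so each of four folds holds 9 training and 3 testing runs and 126/42
training/testing sounds (72/24 in the 8-run follow-up experiment) — is
arithmetic the package reproduces in `cv_fold_plan()` and asserts in its
tests. Desk-scale
simulations use 4 runs with leave-one-run-out outer folds; the fold machinery
is identical, only the run count differs.

## Thresholding and the group atlas

Single-subject p maps are thresholded by Benjamini–Hochberg FDR at `q = 0.05`
intersected with an uncorrected `p < 0.001` (`fdr_mask()`; BH is the field's
default FDR procedure, and the extra p threshold curbs the false positives
FDR admits when many voxels are active), then cluster-filtered at
3.37 mm³ — 27 voxels on the 0.5 mm grid — with 26-connectivity
(`cluster_filter()`; the connectivity is configurable since volumetric
clustering conventions differ). The order is fixed: threshold, binarize,
cluster-filter, then sum across subjects into a `probabilistic_map()`, whose
value at a voxel is the number of subjects significant there.
`leave_one_out_maps()` rebuilds the atlas once per left-out subject, and
`loo_validation()` scores, per structure: the overlap
$100 \cdot |LOO \cap subject| / |LOO|$ (the leave-one-out map is the
denominator — the question being how much of the atlas's claim is confirmed
in the new subject) and the Euclidean distance between the two restricted
centroids. Cells whose restricted leave-one-out region is empty are reported
missing, not zero. Structure assignment uses a reference label volume; the
synthetic truth provides it in simulations.

## Agreement metrics

`dice()` is $2|A\cap B|/(|A|+|B|)$, defined as 1 when both masks are empty.
`average_hausdorff()` is the symmetric average of directed mean
nearest-neighbour distances between member-voxel world centers — the standard
"average Hausdorff distance" of the segmentation literature; the classical
maximum variant and a boundary-voxels-only mode sit behind flags. All member
voxels are used by default because one-voxel-thick structures (the dorsal CN
wrapping the cerebellar peduncle is about 0.5 mm thin) leave boundary
extraction degenerate. `label_volumes()` turns label counts into mm³ for
volumetry tables across sources and probabilistic-map thresholds.

## Tractography

`extract_peaks()` finds local maxima of per-voxel ODF amplitudes on a sampled
sphere (antipodally symmetric directions, antipodal pairs identified),
greedily keeps them in descending amplitude subject to a minimum separation
angle (10° for the postmortem protocol, 25° in vivo), a relative amplitude
floor, and at most 5 peaks per voxel. `track()` is a deterministic
peak-following tracker: seeds uniform inside seed voxels, bidirectional
propagation, trilinear FA interpolation with termination below `fa_stop`
(0.001 postmortem — the specimen outside is masked to zero — and 0.023 in
vivo), nearest-voxel peak lookup with sign alignment, and a per-step turning
limit (75° postmortem, 45° in vivo). The step defaults to half the smallest
voxel dimension (Nyquist-style sampling of the grid) and streamlines shorter
than three steps are discarded as seed fragments; both are configurable and
neither is prescribed by the protocol. A nominal "1,000,000 seeds per voxel"
taken literally would imply more than 10¹² seeds for a postmortem-resolution
volume, so the seed budget is exposed as a configurable total (`n_seeds`,
default 10⁴-scale) with a literal per-voxel mode (`seeds_per_voxel`).

`dilate_mask()` grows ROIs by a Euclidean ball in voxel units (2.5 voxels =
500 µm at the 200 µm postmortem resolution) to admit the white matter
adjacent to grey-matter nuclei. `filter_streamlines()` keeps streamlines
seeded in a seed ROI that intersect at least one waypoint ROI (half-open
voxel boxes, so each point belongs to exactly one voxel), and
`connectivity_matrix()` reports, as percentages of the total streamline
count, the unordered ROI pairs each streamline touches, with
touch-exactly-one counts on the diagonal. The package reproduces
qualitatively the resolution effects seen in the source analyses: dilating
ROIs or downsampling the grid (partial voluming) monotonically grows the
off-diagonal connectivity of a tube passing near, but not through, the
undilated ROIs.

## The synthetic cohort

`make_cohort_rois()` plants eight spherical nuclei (radius 2 mm) at
anatomically inspired bilateral positions in a brainstem-sized field of view,
jittered per subject and per nucleus with isotropic Gaussian SD 0.5 mm — the
jitter stands in for residual inter-subject registration error, and applying
it per nucleus rather than as one rigid per-subject shift is the stricter
test of atlas generalization. `simulate_subject_runs()` adds, on top of a
baseline of 100 (so amplitudes read as percent signal change): the stimulus
response (effect size 3, i.e. three times the white-noise SD of 1) convolved
with a difference-of-gammas HRF sampled at the volume interval; three shared
structured-noise components (per-run Gaussian time courses times fixed
spatial loadings of SD 2, supported strictly outside the nuclei — the planted
noise pool); and white noise everywhere. Event designs draw inter-stimulus
gaps uniformly from {3,4,5} volumes, matching a mean ISI of four volumes
with minimum three and maximum five. All generators are bit-reproducible
given their seed and return the planted truth alongside the data.

What the simulation does *not* emulate: physiological (cardiac/respiratory)
noise spectra, draining-vein displacement of activation toward the brainstem
surface, inter-subject anatomical variability beyond center jitter,
registration and distortion artifacts, and T2*-contrast anatomy. Passing
tests therefore demonstrate the correctness of the estimators and their
cross-validation plumbing, not robustness to every property of real 7T data.

The fiber phantoms (`make_peak_field()`) are straight, bent (configurable
angle) or crossing tubes with unit tangent peaks and FA contrast, standing in
for tracts like the lateral lemniscus; `make_odf_samples()` renders them as
ODF amplitude fields through a symmetric axial kernel
$\exp(\kappa\,(d\cdot\mu)^2)$ so the peak-extraction stage can be tested
against an exhaustive sphere-scan oracle.

## Numerical choices

- Voxel convention: 0-based indices, affine maps index to RAS+ mm, the world
  point of a voxel is its center; point-in-voxel tests use half-open boxes.
- Smoothing: separable Gaussian, `sigma = FWHM / (2*sqrt(2*log(2)))` per axis in
  voxel units, reflective boundaries (mass-conserving near edges). The 1.5 mm
  FWHM smoothing of upsampled maps is available and applied after upsampling
  when enabled, following the stated order of operations; it is off by
  default in simulations because the synthetic grid is already the analysis
  grid.
- Resampling: output shape `ceiling(extent / target)` so the field of view is
  never cropped; trilinear interpolation is refused on integer label volumes.
- Minimum-intensity projection: slabs of `floor(slab_mm / spacing)` slices; a
  trailing partial slab is kept when it holds at least half the nominal
  slice count (flag to always keep or always drop).
- optimize_k caps the PCA basis at 20,000 pool voxels and the score median at
  10,000 voxels, subsampled with a fixed internal seed; both are principal
  subspaces/medians and insensitive to the subsample, and both caps are
  parameters.
- Degenerate inputs fail with named conditions (`subcortaud_empty_pool`,
  `subcortaud_no_responsive_voxels`, `subcortaud_empty_mask`, ...) rather
  than propagating NaN.

## Problem sizes used by the tests and the acceptance script

The cohort evaluation runs 10 subjects on a 40³ grid at 0.5 mm (a 20 mm cube
around the brainstem nuclei layout), 4 runs of 120 volumes with 23 events
each, `k_max = 4`, leave-one-run-out outer folds. These sizes are the
package's desk-scale study conditions: large enough that every nucleus is
recovered in every subject and the leave-one-out validation is
well-conditioned, small enough to run in minutes. At those conditions the
median leave-one-out centroid distance is well under the 2 mm that the
analysis is expected to achieve, and the median is computed — never assumed —
each time the suite runs.

## Known limitations

- No inter-subject registration: the synthetic cohort shares one grid, so
  the leave-one-out "back-projection" step of a real study is an external
  concern here.
- The tracker follows nearest-voxel peaks with trilinear FA only; it does not
  interpolate orientations between voxels, which EuDX-family trackers also
  avoid, but which limits sub-voxel smoothness.
- `fdr_mask()` assumes exchangeable voxels under BH; spatial correlation from
  smoothing makes the procedure conservative rather than invalid.
- The per-voxel HRF option exists but the subject-level aggregate is the
  tested default; strongly voxel-varying hemodynamics would favour the
  former.
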