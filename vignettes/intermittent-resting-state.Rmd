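---
title: "Validating intermittent resting-state connectivity: models and methods"
author: "interRest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating intermittent resting-state connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(interRest)
```

## The problem

Blocked task fMRI — the kind acquired routinely for clinical language
lateralization — alternates task blocks with rest blocks. During the rest
blocks the brain's intrinsic network activity is present just as it is in a
dedicated resting-state scan, provided one waits for the haemodynamic
response of the preceding task block to decay. The "intermittent resting
state" approach extracts exactly those volumes and treats them as
resting-state data, so functional connectivity can be studied in cohorts for
whom only task fMRI exists.

interRest implements that extraction together with the three-level validation
one runs to trust it: does the intermittent arm reproduce the *topography* of
canonical networks, their *within-network connectivity*, and *group-level*
seed-based differences, when the same subjects also have a continuous rest
scan? Because no clinical data ship with the package, a synthetic BOLD
generator with known ground truth stands in for the cohort, and the entire
pipeline is exercised on it.

## Rest-volume extraction

The scan has alternating rest/task blocks; at TR 3 s a 30-s block is 10
volumes. The extraction scheme has three counts, all in volumes:

* `nDiscardScanStart` (default 3, i.e. 9 s): dropped from the scan's *first*
  rest block while the longitudinal magnetisation reaches steady state. This
  replaces — it is not added to — the per-rest-block discard below; with the
  default protocol that is the only reading that yields the documented 72
  retained volumes (7 + 10·2 + 9·5).
* `nKeepTaskStart` (default 2, 6 s): the first volumes of every task block are
  *kept as rest*, because the canonical haemodynamic response has barely risen
  6 s after task onset.
* `nDiscardRestStart` (default 5, 15 s): dropped from every non-initial rest
  block while the previous task block's response decays back to baseline.

Those lags are exactly the arithmetic of the canonical double-gamma HRF used
by the generator (peak near 5 s, decayed to under 1% of peak by ~30 s).
Volume indices are 0-based throughout — volume 0 is the first acquired
volume — matching the sidecar files the extraction writes; the R accessors
document this prominently.

Extracted scans keep their *original* acquisition times. The temporal spacing
of interleaved rest volumes is non-uniform, and any frequency-domain
operation (the DCT high-pass in particular) refuses such scans with an error
telling the user to filter before extraction.

## Denoising model and ordering

Denoising follows the component-based noise-correction recipe: a 0.01 Hz
discrete-cosine high-pass basis, CompCor principal components from noise
tissue (smallest count explaining at least 50% of variance), optional
Friston-24 motion expansion, all regressed out in a single least-squares fit
with z-standardization, then 6 mm FWHM Gaussian smoothing.

Two ordering decisions were genuinely open:

* **Denoise before extraction.** The DCT filter needs uniform sampling, so
  filtering and confound regression run on the full continuous series and
  extraction afterwards. Purely per-volume operations (smoothing,
  standardized residuals) commute with extraction, which the test suite
  asserts.
* **Smooth last.** Whether standardization preceded or followed smoothing is
  not fixed by the recipe; the package standardizes residuals and smooths
  last. The choice is localized in `denoiseScan()` for sensitivity analyses.

The 24-parameter motion expansion is the Friston set: parameters, backward
differences, and both squared. (Six parameters plus derivatives alone would
be 12; the printed total of 24 implies the squared terms.) The synthetic
cohort plants no motion, so the pipeline run uses only DCT + CompCor
regressors; `motionExpansion()` is exercised by its own tests and available
for real confound tables (fMRIPrep-style TSV naming).

Numerical details: smoothing uses separable 1-D Gaussian kernels with sigma =
FWHM / (2·sqrt(2·ln 2) · voxel size), truncated at 4 sigma and renormalized
where the kernel overhangs the grid edge, so constant volumes are preserved
exactly and an interior impulse keeps unit mass. Rank-deficient confound
designs fall back to the pseudoinverse with a warning rather than failing.
Zero-variance voxels stay zero under standardization, and tSNR maps assign
such voxels 0 rather than NaN so QC maps remain plottable.

## Group spatial ICA and template matching

Both arms are decomposed with group spatial ICA: subjects' in-mask series are
voxelwise demeaned, scaled to unit total variance per subject (so no subject
dominates), and concatenated along time; the concatenation is doubly centred,
PCA-whitened to 20 components (the conventional order for resting-state
networks), and unmixed with the symmetric fixed-point algorithm under the
logcosh contrast. Maps are z-scored over in-mask voxels; signs follow two
conventions — non-negative skewness for storage, and non-negative template
correlation during matching, which makes matching invariant to component sign
and order.

The fixed-point iteration is restarted from a new seeded initialisation (up
to 5 times) if the alignment criterion does not reach 1e-4 within 2000
iterations, and errors if all restarts fail. That failure mode is real, not
hypothetical: a model order far above the data's non-Gaussian rank leaves
whitened directions that are essentially Gaussian, for which the fixed point
has no attractor. The tests therefore size their fixtures so the requested
order is supported (e.g. the reduced smoke-test cohort uses 4 components for
its 4 planted latent networks, while the full-size runs use the default 20).

Matching against the template atlas uses Pearson correlation between each
component map and the *binary* network template over in-mask voxels — the
template is a label volume, and binary-template Pearson is the assumed
variant. Thresholding matched maps at z > 2 and the minimum ROI size of 5
voxels are defaults exposed in the configuration: no principled value is
dictated by the method, and both are reported in every resolved
configuration. Spatially distinct ROIs use 26-connectivity by default (also
configurable); the intersection of the two arms' thresholded maps is labelled
into ROIs ordered by size.

## Connectivity and similarity statistics

ROI series are unweighted voxel means (an eigenvariate option is deliberately
out of scope). Correlations are Fisher z-transformed with |r| clipped at
1 − 1e-7, keeping z finite (≈ 8.4) for degenerate identical series; matrices
store 0 on the undefined diagonal.

Between-arm similarity of the group-mean matrices is Spearman's rho over the
upper triangle. Its null distribution permutes ROI *labels* — rows and
columns jointly, Mantel-style — never individual cells: cells of a symmetric
matrix are not exchangeable, labels are. Tests are one-sided (similarity
exceeding the null) since similarity is the hypothesis; a two-sided flag
exists. The sampled test uses 5000 iterations with the +1 correction,
p = (1 + #{rho_perm ≥ rho_obs}) / (1 + n_iter), so p is never 0 and has
granularity 1/(n_iter + 1). For small matrices all K! label permutations are
enumerated exactly (K ≤ 7; 3 ROIs gives the coarsest possible p of k/6). The
pipeline picks the exact test for K ≤ 4 and the sampled test above that.

Whether the two arms' template correlations differ is assessed with Steiger's
test for two dependent correlations sharing one variable (the template). The
underlying method was an open choice; Steiger's z with the mean correlation
in the covariance term is the standard option. Spatial autocorrelation makes
the voxel count a serious overestimate of the effective sample size, so the
caller must supply `nEff`; the pipeline uses in-mask voxels / 10, a
documented stand-in rather than an estimate.

## Group inference

Second-level comparisons use pooled-variance two-sample t-tests on subjects'
seed-based Fisher-z maps (pooled rather than Welch, configurable), cluster
forming at two-sided voxel p < 0.001 with positive and negative excursions
labelled separately, and cluster-level FDR at q < 0.05. Cluster p-values come
from a *permutation* null of maximum cluster extents over group-label
shuffles rather than parametric random-field theory: smoothness estimation is
brittle on toy-sized grids, while permutation is exact under group
exchangeability. This is a deliberate, documented substitute. Benjamini-
Hochberg is applied across observed clusters; swapping group labels negates
the t-map exactly, which the tests assert.

## The synthetic generator

The generator emulates the paired acquisitions: a 200-volume blocked task
scan (TR 3 s, ten 30-s rest + ten 30-s task blocks, rest first) and a
170-volume continuous rest scan (8.5 min), already in a common space — no
motion, slice-timing or distortion effects are simulated, so fMRIPrep-style
spatial preprocessing is out of scope by construction.

Each network has a latent Gaussian time series with a specified network
covariance; ROI spheres add `loading × latent` to their voxels; task scans
add the block design convolved with the canonical HRF in the designated task
networks; every voxel receives AR(1) noise (marginal sd `whiteSd`,
lag-1 correlation 0.3), a low-rank drift (shared linear + 128-s cosine shapes
with per-voxel Gaussian amplitudes, total sd 1.2) and a baseline of 100.
Making the drift low-rank is what gives CompCor something real to find: its
two structured directions carry most noise-tissue variance, so the 50%
threshold yields two components instead of half the scan's rank.

No generative parameters exist to copy from clinical data, so the defaults
are chosen once as realistic for 3 T BOLD and surfaced in
`defaultNetworkSpec()` / `NoiseModel()` rather than hard-coded: ten radius-2
ROI spheres on a 24 × 24 × 18 voxel grid at 3 mm (small enough for desk-scale
tests, large enough for spatially distinct spheres ≥ 7 voxels apart), five
DMN-like regions, three SMN-like regions (task-activated), and left/right
hippocampus-like single-ROI networks used as seeds. Loadings within a network
are deliberately heterogeneous (1.3 down to 0.3) so the true within-network
correlation matrix has distinct, rankable entries — with one latent per
network and equal loadings, all within-network correlations would be equal
and rank-based similarity between arms would be undefined in principle.
Resulting ROI-level Fisher-z values span roughly 0.2–1.8, the range seen in
practice.

The planted group effect shifts one network-covariance entry in group B. One
latent drives each network, so an effect on a multi-ROI network would move
all of its ROIs at once and leave "the planted target ROI" ill-defined; the
default designated pair is therefore the two single-ROI hippocampal networks,
and recovery is scored as Dice overlap between significant clusters and the
contralateral hippocampal sphere. Any pair of networks can be designated
instead.

Determinism: one master seed spawns per-subject streams such that subject k
is bit-reproducible regardless of cohort size; every stochastic stage
(simulation, ICA initialisation, permutation nulls) takes an explicit seed,
and rerunning a configuration reproduces the report byte for byte.

### What the generator does and does not show

Passing tests on this generator demonstrate that the *pipeline* is correct
and calibrated: extraction selects the right volumes, ICA recovers planted
topography from both arms, similarity statistics are valid (null rejection
rates at their nominal level) and group inference detects planted effects
while controlling false positives. They do not demonstrate clinical
performance: the generator has no motion, no physiological cycles, no
inter-subject anatomical variability, stationary noise, and networks that are
geometrically simpler than real ones. Real-data template correlations of
~0.5–0.6 are therefore not targets here; the synthetic runs sit higher
(~0.8) because the world they live in is cleaner.

## Problem sizes in the shipped experiments

The demonstration cohort runs 6 subjects per group at the full acquisition
lengths (200/170 volumes); one validation run takes about a minute. The
statistical-calibration experiments use 500 independent matrix pairs with
199-permutation tests (the rejection rule p ≤ 0.05 is exact at that count),
and 100 null cohorts of 6 subjects per group with 199-permutation cluster
nulls; the planted-effect recovery experiment uses 20 subjects per group with
499 permutations. The group-inference experiments omit CompCor (and, for the
null cohorts, smoothing): permutation inference is exact under group
exchangeability regardless of the per-subject map pipeline, and those stages
are exercised by their own tests and the demonstration run.

## Known limitations

* Unweighted ROI means only; no first-eigenvariate extraction.
* The task-regression alternative to interleaved extraction is not
  implemented.
* No covariate adjustment (age/sex) in the group model; pooled-variance t
  only.
* The dependent-correlation test relies on a caller-supplied effective sample
  size; no spatial-autocorrelation estimator is provided.
* The synthetic "noise tissue" for CompCor is the complement of the planted
  ROIs eroded by one voxel — a stand-in for white-matter/CSF masks, labelled
  as such.
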