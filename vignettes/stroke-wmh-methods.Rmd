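---
title: "Methods: stroke-aware WMH segmentation with strokewmh"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stroke-aware WMH segmentation with strokewmh}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

White matter hyperintensities (WMH) are FLAIR-bright white-matter lesions of
presumed vascular origin, common in aging and ubiquitous after stroke.
Automated WMH segmentation tools are typically developed and validated in
stroke-free cohorts; in stroke patients two things break. First, the
infarcted tissue itself is often FLAIR-hyperintense, so a voxel classifier
confuses stroke with WMH unless the stroke lesion is handled explicitly.
Second, supervised voxel classifiers are trained on one scanner and applied
to another, and systematic acquisition differences (gain, offset, noise)
degrade them badly, while unsupervised intensity-model segmenters refit each
scan and are largely immune.

`strokewmh` implements the full experimental apparatus for studying both
problems: a supervised k-nearest-neighbour (k-NN) voxel classifier with the
complete user-settings space and stroke-lesion handling on classifier input
or output; a distance-band adaptive-thresholding surrogate; an unsupervised
Gaussian-mixture baseline; the complete voxel-, cluster- and volume-level
scoring suite; a phased one-factor-at-a-time settings optimizer scored by
leave-one-out cross-validation; a same-site/cross-site/mixed-sample
validation experiment; and a synthetic multi-site brain phantom generator
that makes all of it runnable and testable without MRI data.

## The supervised model

Each in-brain voxel is represented by a feature vector holding, per
modality (FLAIR required, T1/T2 optional):

* the normalized intensity,
* optionally the mean intensity over a cubic patch of side $p$ voxels
  (tested values $p \in \{0, 3, 6, 9\}$), which buffers against residual
  misregistration, and
* optionally spatially weighted template coordinates
  $sw \cdot (x, y, z)$ (tested $sw \in \{0, 1, 5, 10\}$), which encode the
  strong spatial prior that WMH cluster periventricularly.

Labelled training vectors are sampled from gold-standard WMH masks (lesion
points) and from the rest of the brain (non-lesion points) under three
location policies: `any` (anywhere outside the WMH mask), `noborder`
(additionally excluding the 1-voxel 26-neighbourhood border of the mask,
whose labels are least trustworthy), and `surround` (only that border). The
classifier is exact k-NN (default $k = 40$): a query voxel's WMH
probability is the fraction of WMH labels among its $k$ Euclidean-nearest
training vectors, so probabilities are exact multiples of $1/k$. The
probability map is binarized at a fixed threshold $\tau$ (tested grid
$\{0.8, 0.85, 0.9, 0.95, 0.99\}$; $0.85$ recommended) or by the adaptive
band thresholds below.

Stroke lesions are handled in one of two modes. **Input masking** removes
the stroke from the brain mask before feature extraction and sampling, so
the classifier never sees infarcted tissue; stroke voxels get probability
zero. **Output masking** predicts over the full brain and afterwards
deletes the stroke mask — optionally dilated by 1–5 mm to also remove
boundary false positives — from the output. In both modes the final mask
never intersects the stroke mask; the difference is that output masking
leaves WMH-mimicking stroke voxels in the *training* pool labelled
non-WMH, which contaminates the feature space and costs sensitivity.

### Numerical and design choices

* **Spatial coordinate scale.** Spatial features are
  $sw \cdot (\mathbf{w} - \mathbf{c}) / L$ where $\mathbf{w}$ is the
  voxel's world-mm position, $\mathbf{c}$ the grid centre and $L$ the grid
  half-extent. With intensities normalized to $[0,1]$, raw mm coordinates
  (range tens of mm) would make $sw = 1$ location-dominant and every
  $sw > 0$ setting degenerate to a location-only classifier. Normalizing
  by the half-extent puts coordinates on the intensity scale, so $sw = 1$
  balances intensity and location and $sw = 5, 10$ increasingly
  prioritize location — reproducing the empirically observed ordering in
  which moderate spatial weighting helps and heavy weighting hurts.
* **Intensity normalization.** Default percentile mapping: clip to the
  within-brain 1st/99th percentiles and map to $[0,1]$; z-scoring and
  `none` are available. A constant image maps to 0 rather than erroring.
* **Threshold comparison** is inclusive (`p >= tau`).
* **Distance ties** in the k-NN are broken by lower training-row index, so
  results are independent of training-row permutation and reproducible
  across platforms; the implementation is exact exhaustive search (no
  approximate index).
* **Patch windows** of even side place the shorter half toward the origin
  (`lo = floor((p-1)/2)`); patch means are taken over the window
  intersected with the effective brain mask.
* **Cluster connectivity** defaults to 26-adjacency (standard for lesion
  clusters) and is configurable everywhere it matters.
* **Dilation** is physical: the structuring element is the set of voxel
  centres within the mm radius, honouring anisotropic voxel sizes (an
  exact Euclidean distance transform thresholded at the radius).
* **Grid compatibility** (shape, affine within $10^{-4}$) is an error,
  never a silent resample; masks resample with nearest interpolation so
  binarity survives, intensities trilinearly.

## Adaptive thresholding surrogate

The adaptive path is a deliberately simplified, clearly-labelled surrogate
of locally adaptive threshold estimation: voxels are assigned to
distance-from-ventricle bands (default two bands split at 10 mm, a common
periventricular cutoff) and each band gets the threshold from a candidate
grid (default $\{0.50, 0.55, \dots, 0.95, 0.99\}$) that maximizes the mean
within-band Dice over training subjects, ties resolved toward the larger
(more conservative) threshold. With one band this reduces bitwise to the
fixed threshold. The original method instead regresses local thresholds on
local features; nothing here claims to reproduce it — the surrogate exists
so fixed-vs-adaptive comparisons have a concrete, inspectable adaptive arm.

## The unsupervised baseline

The baseline segmenter fits a diagonal-covariance Gaussian mixture
(default $K = 4$) to the in-brain multimodal intensity vectors of each
subject independently: k-means initialization from a seed, EM to a relative
log-likelihood tolerance of $10^{-6}$, variance floor at $10^{-6}$ of the
per-dimension data variance to prevent component collapse. The lesion class
is the component with the highest FLAIR mean — WMH are FLAIR-hyperintense
by definition, and keeping the rule transparent makes failure modes (e.g. a
bright non-lesion structure capturing the class) inspectable. The lesion
posterior is thresholded at $\tau \in \{0.1, 0.3, 0.5, 0.7, 0.9\}$ (default
0.1, the empirically best setting) and the stroke mask is removed from the
*output* only, mirroring how unsupervised tools are used in practice. This
is an intensity-clustering baseline, not a reimplementation of any specific
atlas-based generative segmenter: there is no deformable atlas, no mesh
prior, no scan-adaptive hyperparameter model.

## Scoring

With gold mask $G$ and automated mask $A$: Dice $SI = 2|G \cap A| /
(|G| + |A|)$, $FDR = |A \setminus G| / |A|$, $FNR = |G \setminus A| /
|G|$. At cluster level (connected components, 26-adjacency), $FDR_c$ is
the fraction of automated clusters with no gold overlap and $FNR_c$ the
fraction of gold clusters with no automated overlap; with
$MTA = (|G| + |A|)/2$, the detection error rate $DER$ counts voxels of all
unmatched clusters and the outline error rate $OER$ the disagreement
voxels within matched clusters, each divided by $MTA$ (so
$DER + OER = (FP + FN)/MTA$). Volume agreement across subjects is
ICC(A,1): two-way random effects, absolute agreement, single measure, from
the ANOVA mean squares. Metrics undefined for a subject (empty $A$ or $G$)
are recorded as `NaN` and excluded from cohort means with counts reported;
scoring them as zero would bias the means. Whether report cells are
per-subject means (implemented) or pooled-voxel metrics is a genuine
convention choice; per-subject means follow the established scoring
convention for this metric suite.

## Optimization and validation experiments

`phased_optimize()` performs one-factor-at-a-time search: each phase varies
one dimension at a time (modalities, spatial weighting, patch, sampling
location, point counts, then threshold) around the phase-start
configuration and picks per-dimension winners by the 2-of-3 rule on
(mean SI ↑, volume ICC ↑, mean FNR$_c$ ↓), all scored by leave-one-out
cross-validation. Because the pairwise rule admits preference cycles, a
cycle falls back to highest SI (logged); a candidate configuration is
adopted only if it wins the 2-of-3 comparison against the incumbent
*without lowering mean SI*, which yields an improvement-or-equal guarantee
on the lead overlap metric. Threshold sweeps reuse the LOO probability
maps (thresholding is the only difference), and every evaluated
configuration is cached, so later phases mostly re-read scores.

`cross_site_experiment()` splits each per-site cohort 80/20 (seeded simple
random split) and scores four supervised arms with identical settings —
train-A/test-A, train-B/test-B, train-A/test-B, and mixed training — plus
an unsupervised GMM arm on each test sample.

## The phantom generator

Real multi-site MRI with expert WMH masks cannot ship with a package, so
every experiment runs on a synthetic phantom designed to exercise exactly
the mechanisms above: an ellipsoidal head (semi-axes 26/30/24 mm), two
ellipsoidal lateral ventricles, spherical WMH clusters (default 10–20 per
subject, radii 1.5–4.5 mm) seeded periventricularly with probability 0.7
(within 10 mm of the ventricles), and an optional spherical stroke lesion
(default radius 10 mm, a mid-sized chronic infarct) placed away from the
ventricles. The default grid is 64³ voxels at 1 mm isotropic — small
enough for desk-scale experiments, large enough for ≈ 2,000 WMH voxels per
subject. Intensities are class means (arbitrary units) with additive
Gaussian noise: on FLAIR, parenchyma 100, WMH 140, CSF 50; on T1 the WMH
are iso-intense (100) and CSF dark (40); noise SD 10. **The stroke lesion
defaults to the WMH means in every modality** — maximal confusability, the
stress case the stroke-handling machinery exists for. A site effect is an
affine intensity map `gain * v + offset` plus a noise multiplier; the
studied shift is gain 1.4, offset +20, noise ×1.5. One cohort seed fans
out additively to per-subject seeds; there is no hidden global RNG state,
and every stage is bit-reproducible from its seeds.

What the phantom does *not* model: gyral anatomy, bias fields beyond the
affine site effect, partial-volume edges (smoothing is available but off
by default so class means stay exact), non-spherical lesion shapes, and
nonlinear scanner effects. Consequences worth stating plainly:

* Phantom contrasts are cleaner than real FLAIR, so absolute Dice values
  here (≈ 0.85–0.95 same-site) exceed what any tool achieves on real
  stroke cohorts (≈ 0.5–0.65); only *directions and contrasts* of effects
  transfer, not absolute levels.
* Because the site effect is exactly affine, per-site percentile
  normalization would cancel it *exactly* — an artifact of the phantom's
  simplicity, not a property of real scanners, where normalization leaves
  residual domain shift. The cross-site experiment therefore feeds
  unnormalized intensities (`intensity_normalization = "none"`), letting
  acquisition-scale differences reach the feature space as they do in
  real multi-site data.

## Problem sizes used in the shipped experiments

The package's own test suite and the reproduction script run, as their
standing study conditions: 200 random 16³ mask pairs and 100 random k-NN
problems (≤ 500 training, ≤ 200 query rows) for the oracle checks; 20
test phantoms at 64³ for the stroke-masking contrast (3 training subjects,
1000 lesion + 4000 non-lesion points each); 20 + 20 phantoms for the
cross-site experiment (300 + 900 points per training subject, within-cohort
80/20 splits); and a 6-subject leave-one-out cohort for the optimizer
demonstration with a deliberately planted spatial prior: every WMH cluster
seeds within 3 mm of the ventricles (a tight periventricular collar), and
the noise (SD 60) is smoothed with a 3 mm FWHM kernel *after* being added,
making it spatially correlated. Correlated noise matters: patch averaging
removes independent voxel noise, so with iid noise the patch dimension
alone restores intensity separability and location adds nothing; smooth
noise blobs survive patch averaging, so intensity stays ambiguous at any
patch size and the planted location prior is genuinely informative — the
conditions under which a spatial weighting of zero is suboptimal by
construction. The reproduction script uses 15 subjects per
site so each 20% test split still supports a volume ICC.

## Known limitations

* The adaptive-threshold arm is a surrogate (distance bands, not learned
  local regression); conclusions about "adaptive thresholding" from this
  package are conclusions about the band surrogate.
* The GMM baseline shares only the *unsupervised refit-per-scan* property
  with atlas-based generative segmenters; no numerical correspondence with
  any external tool's output is claimed.
* Registration is application-only: the package applies given affines
  (FLIRT-style text matrices) but never estimates them.
* The k-NN is exact and single-threaded; cohorts beyond desk scale would
  want an approximate index, which is deliberately out of scope because
  settings comparisons require bit-stable probabilities.
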