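---
title: "Surface-based lesion detection and its guessing-null evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based lesion detection and its guessing-null evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

surflesion implements a complete surface-based morphometry (SBM) pipeline
for detecting focal cortical lesions — the kind of subtle malformation
(focal cortical dysplasia, FCD) sought in presurgical epilepsy imaging —
together with the statistical machinery needed to decide whether a
detector's apparent localisation performance beats blind guessing. Because
clinical MRI cannot be redistributed, the package ships a synthetic-cohort
generator that reproduces the statistical structure the analysis relies on;
every stage downstream of image segmentation is then exercised end to end
on data the user can regenerate from a seed.

## The detection problem and the evaluation paradigm

Per-vertex measures (cortical thickness, curvature, sulcal depth, area,
volume, intrinsic curvature, white/grey contrast, and normalized T1/FLAIR
intensities sampled at six cortical/subcortical depths — 19 base measures in
all) live on a symmetric two-hemisphere template mesh. A detector converts
them into a per-vertex statistic for one subject: either a univariate GLM
z-score against the control population, or a multivariate novelty score
(robust Mahalanobis distance, isolation forest) or supervised
random-forest probability.

Maps are thresholded over a sweep, suprathreshold vertices are clustered
into connected components, and each cluster is reduced to a mark at its
area-weighted centroid vertex. A ground-truth label (a manually traced
lesion, or a lobar hypothesis region for MRI-negative patients) counts as
detected only when a mark centroid falls inside it — deliberately stricter
than overlap criteria, because point marks admit an exact chance model. Over
the sweep this yields, per threshold,

* TPF — fraction of ground-truth labels detected (at that or any stricter
  threshold),
* FPF — fraction of control subjects with at least one cluster,
* FPR — mean cluster count per control subject,

and the alternative free-response ROC (AFROC) curve TPF(FPF), whose area
(AUC, in [0, 1]) summarises detection performance. False positives are
counted in controls only: patients may harbour true lesions beyond their
labels.

## The guessing null

The null hypothesis is a process that places lesion marks uniformly at
random over the cortical vertices. For a label whose relative size is
$\varphi$ (label area over total surface area), the large-cohort AFROC
curve of this process is

$$\mathrm{TPF} = 1 - (1 - \mathrm{FPF})^{\varphi}, \qquad
  \mathrm{AUC} = \frac{\varphi}{\varphi + 1},$$

so guessing attains 0.5 when labels cover the whole surface (the task
degenerates to plain ROC classification) and tends to 0 as labels shrink.
Finite cohorts scatter around this curve; the null distribution of the AUC
is therefore obtained by Monte Carlo: every subject receives
$N \sim \mathrm{Poisson}(\lambda_{\max})$ marks with independent activation
levels $u \sim U(0,1)$, and the operating point at level $\ell$ uses marks
with $u \le \ell$. This coupling makes each simulated curve monotone and
gives exactly the closed form in expectation: active marks at level $\ell$
are Poisson with rate $\ell\lambda_{\max}$, so
$\mathrm{FPF} = 1 - e^{-\ell\lambda_{\max}}$ and
$\mathrm{TPF} = 1 - e^{-\ell\lambda_{\max}\varphi_v} =
1 - (1-\mathrm{FPF})^{\varphi_v}$. Defaults are $\lambda_{\max} = 20$
(truncation error $e^{-20}$ in the FPF endpoint) and 256 activation levels;
the null mean is insensitive to both beyond $\lambda_{\max} \ge 10$ and 128
levels (tested).

An observed AUC is tested one-sidedly with the permutation-style estimate
$p = (b+1)/(m+1)$, where $b$ counts null samples greater than or equal to
the observation (ties count against it). Bonferroni adjustment
$\min(1, kp)$ controls the family-wise error over the $k$ detection
conditions of an experiment. Per lesion, the FPF at the strictest detecting
threshold feeds the same closed form,
$P = 1 - (1-\mathrm{FPF}_{\mathrm{detection}})^{\varphi}$, as a
per-lesion significance.

Two conventions deliberately coexist: $\varphi$ is defined as an *area*
ratio, while marks are *vertex*-uniform. On the quasi-uniform icosphere
template the two differ by well under a percent for generic labels (a few
percent for labels of only a handful of vertices, where area quantisation
bites); tests that compare simulated means against the closed form use the
realized vertex fraction of the label, which is the exact size parameter of
the vertex-uniform process.

## The template and its geometry

The template is a pair of mirrored icosphere meshes ("hemispheres", each a
closed 2-manifold) with index correspondence $i \leftrightarrow i$ between
sides, radius 100 mm by default so that the total area ($\approx 2.5\times
10^5\,\mathrm{mm}^2$) is of the same order as a human cortex and
millimetre-valued kernels and lesion radii keep their physical meaning.
Subdivision level 4 (2,562 vertices per hemisphere) is the default working
resolution; level 3 is used for the heavier simulation suites and level 2
for brute-force comparisons.

Smoothing uses explicit heat-kernel iterations with the combinatorial graph
Laplacian, $f \leftarrow f + \tau L f$ with $\tau = 1/(2\,\mathrm{deg}_{\max})$.
This operator is linear, preserves constants and the global vertex mean
exactly, and conserves the area-weighted integral to about a percent on the
quasi-uniform mesh. The number of iterations for a requested FWHM comes
from a per-template calibration: the variance growth per iteration is
fitted once from a point-source response (using exact great-circle
distances), stored with the mesh, and inverted for the target
$\sigma^2 = \mathrm{FWHM}^2 / (8\ln 2)$, with a fractional final step for
the remainder. Point-source responses recover requested FWHMs of 8 and
32 mm within the 15% contract at level 4. FWHMs below the mesh edge length
cannot be realised exactly; the kernel then degenerates gracefully towards
the identity (relevant for 4 mm post-smoothing on coarse test meshes —
harmless, since it only weakens the false-positive suppression it exists
for).

Cluster centroids are the area-weighted mean coordinate snapped to the
nearest cluster member (ties to the lowest vertex index): an off-surface
mean has no "inside the label" semantics, and snapping makes the criterion
exact and deterministic. The synthetic template has a single geometry;
with real data the choice of surface (white, inflated, spherical) on which
centroids are computed would matter and is up to the user.

## The synthetic cohort

For each measure, a subject's map is

> smooth population mean field + linear covariate effects + subject-level
> random intercept + spatially correlated vertex noise,

with per-measure natural units (thickness 0.25 mm per SD unit, intensities
0.06 normalized units, and so on). Covariates are age, sex, scanner site
and an intracranial-volume analog; the ICV effect applies only to area,
volume and thickness, matching the GLM design downstream. Noise fields are
white noise smoothed at 15 mm FWHM and restandardized — this is what gives
controls realistic smooth false-positive clusters rather than speckle.
Defaults (noise SD 1, intercept SD 0.3, covariate effects 0.2–0.3 SD per
covariate SD) were chosen once as plausible SBM magnitudes and are not
tuned; the default cohort sizes mirror the reference study conditions (94
controls, 5 MRI-positive subjects carrying 6 lesions, 27 MRI-negative
subjects).

T1 and FLAIR are sampled at 75%, 50%, 25% of cortical thickness, at the
white-grey interface, and 1 and 2 mm subcortically (12 maps). Depth means
rise monotonically towards white matter for T1; a shared per-modality noise
component guarantees adjacent-depth correlations of at least 0.5. The maps
are pushed through an arbitrary per-subject scanner gain and re-normalized
with a two-point affine map (median mid-cortical intensity to 0, median
intensity at −1 mm to 1), which exactly cancels the gain — the package's
normalized-signal-intensity analog. White/grey contrast is derived
deterministically from the normalized T1 maps as a percent-contrast,
$100\,(T1_{-1\mathrm{mm}} - T1_{50\%}) / \tfrac12 (T1_{-1\mathrm{mm}} +
T1_{50\%})$ (denominator floored at 0.05 to keep the measure finite under
extreme noise); consequently lesion effects are never set on the contrast
directly — its characteristic decrease emerges from the subcortical T1
drop.

MRI-positive subjects receive geodesic-disc lesions (radii drawn from a
configurable range; the defaults give relative areas in roughly
0.002–0.016) with an FCD-like effect profile in control-SD units: thickness
up, subcortical T1 down, subcortical FLAIR up. MRI-negative subjects get
the same profile scaled by `negative_effect_scale` (default 0.25) inside a
random sub-patch of their hypothesis label, which is a union of 1–3
adjacent parcels from a synthetic flood-fill parcellation (8 parcels per
hemisphere by default, a lobar-atlas analog); with these defaults the
hypothesis sizes land inside the configured 0.02–0.36 range without
trimming.

What the generator does *not* emulate: reconstruction and registration
error, curvature-dependent thickness bias, non-Gaussian intensity tails,
spatially varying noise, multiple lesion types, or any coupling between
morphometric measures beyond the intensity-depth family. Passing tests
therefore validate the statistical machinery — calibration of the GLM and
of the guessing-null p-values, effect recovery, detector power under a
known implanted signal — not clinical detection performance on real MRI.

## Features, standardization and detectors

Each base measure expands into four features: 8 mm smoothed, 32 mm
smoothed, their difference (difference-of-Gaussians, a spatial band-pass
with exactly zero global mean under this smoothing operator), and
hemispheric asymmetry (raw inter-hemisphere difference, then 8 mm
smoothing — in that order). 19 measures give 76 features; the six named
subsets are `all` (76), `base8` (19), `reduced` (24: thickness, white/grey
contrast, T1 and FLAIR at −1 mm and 50% at all four variants), and each
without FLAIR-derived features (52/13/16).

Classifier inputs are z-scored in two stages: per subject (each feature
centred/scaled by its own across-vertex moments, pooling both hemispheres)
and then per vertex across controls. When the evaluated subject is itself a
control, the vertex-level reference excludes it, so specificity estimates
are not self-contaminated. The GLM consumes raw 8 mm-smoothed measures with
covariates instead — z-scoring is the simpler alternative to covariate
modelling and is reserved for the classifiers.

The GLM compares one subject against the controls per vertex by OLS with
the prediction-residual z
$z = (y_0 - x_0^\top\hat\beta)\,/\,(\hat\sigma\sqrt{1 + x_0^\top (X^\top
X)^{-1} x_0})$, which makes leave-one-out control z-values t-distributed
with $n - p$ degrees of freedom (no t-to-z conversion is applied; at
realistic control counts the difference is negligible, and the pooled
control z SD contract of [0.9, 1.1] absorbs it). Positive z means above the
covariate-adjusted control expectation; maps are used two-tailed.
Numerically zero residual variances yield z = 0 with a warning.

Mahalanobis novelty uses a minimum-covariance-determinant location/scatter
(support fraction 0.75 by default) with an explicit median-$\chi^2$
consistency rescaling so that squared distances of Gaussian controls are
$\chi^2_p$-calibrated; the MCD itself is fitted on a capped, seeded row
subsample (20,000 rows) for tractability while scoring uses all vertices.
The isolation forest follows the original algorithm ($t = 100$ trees,
subsample $\psi = 2048$, depth limit $\lceil \log_2 \psi \rceil$,
path-length normalisation $c(n)$), implemented in C++ and driven by R's
RNG so fits are seed-reproducible; $\psi$ is lowered with a warning when
the training set is smaller. The supervised random-forest comparator uses
100 trees, $\sqrt{p}$ feature sampling, minimum leaf size 1 and Gini
splitting, trained on strict-label lesional vertices against a 1:10
control subsample. Training schedules are leave-one-out throughout: all
controls for patients, all *other* controls for each control; the
random forest additionally pools lesional vertices of the other
MRI-positive subjects. All vertices of both hemispheres are pooled into one
observation matrix. Score maps are post-smoothed at 4 mm FWHM (averaging
preserves the range contracts).

## Numerical choices in the AFROC sweep

Thresholds are type-1 empirical quantiles (hence always observed map
values). Half of the grid covers the pooled statistic above its floor value
(the floor is dropped so zero-inflated sparse maps do not collapse the
sweep), and half covers the upper tail from the smallest per-subject map
maximum upwards — operating points only move when a threshold crosses a
subject's maximum, so that is where resolution matters. With this design
the AUC at 512 thresholds agrees with 4,096 thresholds to better than 0.01
on smooth maps, and AFROC evaluation of maps that *are* realisations of
the guessing process (Poisson-many uniform-height spikes) recovers
$\varphi/(\varphi+1)$ within Monte-Carlo error.

A label's detection is cumulative over the sweep (detected at a threshold
if detected at it or any stricter one), which makes TPF monotone even
though merging clusters can move a centroid out of a label, and which is
exactly the "strictest threshold that allowed detection" convention used
for the per-lesion analysis. Curves are closed by prepending (0, 0) and
extending horizontally at the final TPF to FPF = 1, the completion under
which the closed-form null AUC integrates to $\varphi/(\varphi+1)$ over
the full FPF range. Two-tailed z-maps are thresholded on |z|, so adjacent
positive and negative patches merge only if edge-connected after masking.
Wide lesion labels (strict labels dilated by 4 vertices) are the evaluation
ground truth; strict labels are used only for random-forest training. The
TPF denominator is the number of labels, not of subjects.

## Experiment orchestration and problem sizes

`run_experiment()` evaluates every requested condition on two arms — the
MRI-positive cohort against wide lesion labels and the MRI-negative cohort
against hypothesis labels — each against its own Monte-Carlo null, and
writes CSV/JSON reports that are fully regenerable from the config and
seed. As an R package the interface is the documented functions plus
`scripts/acceptance.R`; no shell CLI is shipped.

The simulation suites run at sizes chosen to make their statistical
contracts sharp while keeping the whole test run desk-scale: null-mean
agreement uses 200 labels × 200 controls × 500 runs per $\varphi$;
pipeline p-value calibration uses 400 zero-effect cohorts of 30 controls
and 2 hypothesis subjects on a level-3 mesh with 99 null runs each (the
0.05-level rejection rate is required to stay below 0.07); the power suite
implants +4 SD multi-measure lesions in 3 of 23 subjects; the
reference-cohort null (six labels, sizes 0.002–0.016 averaging 0.007, 94
controls) uses $10^4$ runs. Exact mark/curve/AUC equivalence against a
brute-force reference (igraph components, first-principles bookkeeping) is
checked on a 162-vertex-per-hemisphere template with 5 thresholds.

## Known limitations

* The guessing null models marks as independent points; real detector maps
  produce spatially extended, threshold-coupled clusters whose centroids
  drift along the sweep. On zero-effect synthetic cohorts the resulting
  p-values are calibrated at the 5% level (tested), but mild
  anti-conservatism for other map types or very coarse meshes cannot be
  excluded — inspecting the per-lesion table guards against significance
  carried by a single subject.
* Sub-edge-length smoothing requests (e.g. 4 mm on the level-2 test mesh)
  are honoured only approximately, as on any discrete surface.
* The MCD support-fraction default (0.75) and the isolation-forest
  defaults follow standard practice and are configurable but not tuned.
* Synthetic parcels approximate lobar hypothesis labels topologically
  (contiguous, exhaustive), not anatomically.
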