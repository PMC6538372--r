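---
title: "Depth-resolved BOLD modulation analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved BOLD modulation analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamod)
```

## The scientific problem

Sub-millimetre fMRI can resolve BOLD signal at different cortical depths.
Because feedforward (bottom-up) input targets the granular layer (layer 4)
while feedback (top-down) input targets agranular (deep and superficial)
layers, the laminar profile of a response modulation carries information
about its origin.  `lamod` implements a complete analysis chain for
block-design laminar BOLD data in which two modulations are crossed: the
stimulus contrast (bottom-up) and feature-based attention to one of two
overlaid orientations (top-down).  Voxel populations preferring clockwise
and counter-clockwise orientations are identified from an independent
localizer, their time courses are unmixed into depth bins, and per-bin
modulation effects are summarized by an agranular–granular score.  A
synthetic cohort generator with known ground truth makes every stage
testable without any scanner data, and a QUEST adaptive staircase with
simulated observers covers the behavioral-control arm of such experiments.

## The forward model behind the simulator

For each gray-matter bin $b \in \{\text{deep}, \text{middle},
\text{superficial}\}$ and voxel population $p \in \{\text{CW},
\text{CCW}\}$, the neural drive during a block is

$$a_{b,p} = \beta_b + c_b \,[\text{high contrast}] + \alpha_b\,[\text{cue} = p],$$

with baseline $\beta_b$, contrast amplitude $c_b$ and attention amplitude
$\alpha_b$.  The block boxcar (5 volumes of cue + stimulus, 5 volumes of
rest) is convolved with a canonical double-gamma HRF.  Two vascular
distortions are then applied: an ascending-vein leak, where bin $b$ receives
a fraction $\lambda$ of the summed neural signal of all deeper bins, and a
multiplicative gain non-decreasing towards the pial surface.  Both mimic the
well-known superficial bias of gradient-echo BOLD; they are a deliberately
minimal caricature (a one-parameter leak plus a gain profile), not a
biophysical vascular model.  Each voxel's signal is its partial-volume
depth-weight row times the bin signals of its population, on a DC offset of
100 scanner units, plus a per-voxel linear drift and AR(1) noise.  The
white-matter and CSF bins carry attenuated (0.1) copies of the nearest
gray-matter signal so that the full 5-column weight matrix is exercised by
the regression.

Default amplitudes encode the laminar physiology the analysis is designed to
detect: contrast peaked in the middle bin (`c = (0.4, 0.8, 0.5)` signal
units, i.e. percent-scale changes on the DC offset), attention broad with a
superficial peak (`alpha = (0.25, 0.30, 0.45)`), baseline 2.0 everywhere,
leak $\lambda = 0.3$, gain $(1, 1.3, 1.6)$, noise SD 1.0 (1% of the DC
level, typical of high-field block designs after averaging considerations),
AR(1) $\rho = 0.3$, drift-slope SD 0.01 per volume.  A cohort draws one
subject-level ground truth per subject by adding independent
$\mathcal{N}(0, 0.15)$ jitter to each attention and contrast bin amplitude —
enough between-subject variability that a minority of subjects can show a
reversed agranular–granular difference, as observed in real cohorts, while
the group direction is preserved.

The geometry is a flat slab: a gray-matter sheet of constant 2 mm thickness
with a sinusoidally perturbed lower boundary between white-matter and CSF
margins, sampled by 0.8 mm voxels.  With constant thickness the equivolume
rule for the three gray-matter bins reduces to equal-thickness thirds.  The
analysis consumes only the resulting weight matrix, so no folded-cortex mesh
machinery is needed; partial-volume rows arise naturally from voxels
straddling the perturbed boundaries.  What the simulator does *not* emulate:
folded anatomy, discrete vessels, motion, physiological noise, or spatial
correlation of noise across voxels.  Passing tests therefore demonstrate
correctness of the analysis chain and its statistical calibration, not
robustness to those real-data complications.

## Protocol constants

All timing is volume-locked at TR 3.408 s.  A main-task run is 3 dummy
volumes plus 16 blocks of 10 volumes — `compute_run_duration(16, 10)` gives
555.5 s — with exactly 4 blocks per condition in seeded random order
(balance per run is assumed; only random interleaving is specified by the
protocol).  The localizer alternates single-orientation blocks of 4 volumes
with equal rests: `compute_run_duration(16, 8)` gives 446.4 s.

## Analysis chain and numerical choices

**Drift removal.** High-pass filtering projects out discrete-cosine
components with period above the 55 s cutoff.  The projection preserves the
temporal mean, is idempotent, and attenuates a 200 s sinusoid to under 5%
while passing a 20 s sinusoid above 95%.

**Voxel selection.** A GLM on the localizer (condition regressors plus
intercept and centered linear trend) yields an all-stimuli activity contrast
and a CW−CCW orientation contrast.  Activity is thresholded voxelwise at
z > 2.3 after converting t to z by matching tail probabilities.  The
original criterion involved cluster-level correction inside FSL; a plain
voxelwise threshold is used here because the cluster-forming internals are
not reproducible from the published description, and the threshold is
configurable.  Orientation masks take up to 500 voxels with the most
positive t (clockwise-preferring) and most negative t
(counter-clockwise-preferring) among active voxels; when fewer qualify, all
qualifying voxels are taken, and ties break by ascending voxel id so the
selection is order-invariant.

**Layer unmixing.** The depth-weight matrix `W` (voxel × 5 bins) is
regressed against the voxel × time data `Y` by per-time-point ordinary least
squares, `L = (WᵀW)⁻¹WᵀY`, which equals the pseudo-inverse solution on every
full-rank instance; a condition-number guard (10⁸) rejects degenerate voxel
populations.  A joint spatiotemporal solve would be mathematically identical
for this formulation, so the per-time-point form is used.  Unmixing is done
separately for the clockwise- and counter-clockwise-preferring populations;
all five bins enter the regression, and the three gray-matter bins are
carried forward.

**Normalization.** Each gray-matter bin's full-run time course is z-scored
(mean 0, SD 1) within layer and within run, across all conditions.  This
removes the superficial amplitude gradient injected by the drainage model
while leaving within-layer condition differences intact; the pipeline can
run with normalization disabled (`normalize = FALSE`) and the sign structure
of condition effects is unchanged.

**Segmentation and effects.** Layer time courses are cut into 10-volume
segments aligned to the attention cue (5 stimulus + 5 interval volumes).
The attended average takes, for each block, the segment from the population
whose preferred orientation was cued; the unattended average takes the
crossed pairing; contrast averages pool both populations across high and low
blocks.  Effects are the condition differences averaged over segment volumes
3–6, whose onset-relative times are 6.8, 10.2, 13.6 and 17.0 s — the peak of
the block response (cue 1.04 s + 16 s stimulus = exactly 5 volumes, so the
cue onset anchors the segment).  The agranular–granular score is
(deep + superficial)/2 − middle; positive means agranular-dominant.
Averaging proceeds blocks-within-run, then runs, then subjects; with the
balanced design these orders are equivalent.

One boundary property worth knowing: the first block of a run has no
predecessor, so its segment lacks the HRF tail every later segment inherits.
In a noiseless simulation the attended−unattended effects are still
*exactly* proportional to the injected attention amplitudes (each block
contributes one attended and one unattended segment, cancelling
block-unspecific terms identically), while the high−low effects carry a
small baseline-scaled boundary term.  The recovery tests therefore check
attention proportionality directly and validate both profiles against an
independent bin-level forward-model computation.

**Percent signal change.** Condition betas from the main-task GLM are scaled
by the regressor peak height and divided by the fitted intercept (the
baseline level), times 100 — the convention used by the common GLM packages
when regressors are convolved boxcars.

## Statistics

`rm_anova()` implements fully within-subject factorial ANOVA (1–3 factors)
by projecting the subjects × cells matrix onto orthonormal contrast spaces
(Kronecker products of per-factor contrasts), which reproduces the classical
cell-mean sums of squares exactly; each effect is tested against its
subject-interaction error term.  Sphericity is handled per effect:
Greenhouse–Geisser $\hat\varepsilon = \mathrm{tr}(S)^2/(d\,\mathrm{tr}(S^2))$
from the covariance $S$ of the contrast scores, and Huynh–Feldt
$\tilde\varepsilon = (n d \hat\varepsilon - 2)/(d(n - 1 - d\hat\varepsilon))$
clipped to 1.  Both are always reported; the p value uses the Huynh–Feldt
correction by default for every effect with more than one numerator df
(rather than conditioning on a sphericity test), and the policy is
configurable (`epsilon = "greenhouse-geisser"` or `"none"`).  Two-level
effects have $\varepsilon = 1$ exactly.  Under a simulated Gaussian null the
interaction test's type-I error is 0.05 ± 0.01 (checked over 10⁴ datasets).
Degrees of freedom are reported as (df_effect, df_error).

`paired_t()` is the standard two-sided paired t test with explicit guards
for degenerate differences (all-zero → t = 0, p = 1; nonzero constant →
error instead of an infinite statistic).  Within-subject error bars use the
Cousineau normalization (subtract the subject mean, add the grand mean) with
the Morey $\sqrt{k/(k-1)}$ correction; the underlying figure legend
convention ("within-subjects standard error") does not pin down a method, so
this common choice is documented rather than inferred.

## QUEST staircase

The staircase maintains a posterior over log threshold on a grid (Gaussian
prior, grain 0.01 log units, ±5 prior SDs).  The psychometric is a Weibull
in stimulus intensity with fixed slope 3.5, guess 0.5 (2AFC) and lapse 0.02
— standard QUEST conventions; the experimental protocol states only the 80%
target and trial-by-trial updating, so these shape parameters are package
defaults, not inferred values.  Each trial is placed at the intensity where
the posterior-mean threshold's psychometric predicts the target accuracy
(posterior mean rather than mode or a quantile; configurable at the level of
the placement computation).  Scanner sessions start the staircase at the
previously measured threshold plus 20%.  The session runner balances the
sign of the width increment within blocks of 8 trials (4 positive, 4
negative, random order), mirroring the task's pseudo-randomization; the
observer responds to the magnitude.  Against a well-specified simulated
observer, 2000+ trials converge to the target accuracy within 2 percentage
points and recover the threshold within 5%.

## Problem sizes used by the test suite

Unit tests run on reduced instances chosen to keep the suite quick while
preserving every structural property: 120–200-voxel slabs, 8-block runs,
2-run subjects, and 4-subject pipelines for determinism checks.  The
cohort-level claims (laminar profile directions, the share of subjects with
attention more agranular than contrast, interaction power) use the full
default cohort — 24 subjects, 3 runs of 16 blocks, 1000 voxels — and the
null-calibration check uses 10⁴ simulated datasets.  These sizes are the
package's chosen study conditions, matching the experimental design the
simulator emulates.

## Known limitations

- The slab geometry cannot produce the depth-weight correlations of folded
  cortex (e.g. voxels spanning opposite sulcal banks).
- The drainage model is qualitative; no claim is made that $\lambda$ and the
  gain profile match measured vascular physics.
- `rm_anova()` requires complete crossed designs; unbalanced or missing-cell
  data need a mixed-model approach outside this package's scope.
- No spatial smoothing, registration, cluster-level inference, or
  deconvolution of the drainage bias is provided.
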