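---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hypovis)
```

hypovis implements the quantitative procedures used to characterise
visually responsive neurons in retinorecipient hypothalamus (and similar
subcortical targets), the accompanying anatomical quantification, and a
3D-pose behavioural analysis. This vignette documents the models, their
assumptions, the tunable parameters, and the choices made where the
procedures were genuinely open.

## Photoreceptor-effective stimulus quantification

Light stimuli are quantified per photopigment as
$\int S(\lambda)\,f(\lambda)\,p(\lambda)\,d\lambda$, where $S$ is the
spectral photon flux density (photons/cm²/s/nm), $p$ the pigment's relative
spectral sensitivity (peak 1) and $f$ a prereceptoral transmission term.
Integration is trapezoidal on the spectrum's native grid; templates are
resampled by linear interpolation and set to zero outside their support.

Sensitivity templates use the standard vitamin-A1 nomogram (alpha band plus
the short-wavelength beta band), parameterised only by the peak wavelength;
a pure-Gaussian form is available for analytic checks. Because the beta
band is a genuine secondary shoulder, the strict "single local maximum"
property holds for the alpha band alone (`beta_band = FALSE`). Default peak
wavelengths (rod 498, S-opsin 365, human L-opsin 556, melanopsin 480 nm)
live in `default_lambda_max()` — configuration, not code. The
prereceptoral filter defaults to identity: the appropriate lens/media
correction is species- and preparation-specific and is supplied by the
user as a transmission curve.

`design_isoluminant_pair()` constructs the "melanopsin high vs low"
stimulus pair: two non-negative LED weight vectors whose mixtures agree in
effective flux for every matched opsin (relative error < 1e-6) while
maximising Michelson contrast for the target pigment. With one more LED
than matched opsins the admissible set for a fixed matched-flux target is
a line segment and the contrast extremes are found exactly; the target is
fixed at the flux of the half-power mixture, a deterministic choice that
does not affect the Michelson contrast (which is scale-invariant in the
unbounded problem). Larger LED sets fall back to penalised optimisation.

## Full-field response classification

All trial-resolved tests are paired two-tailed t-tests across trials at
$\alpha = 0.05$ (configurable throughout).

* **Responsiveness**: firing rate in the first 250 ms after light ON (and
  after light OFF) against an equal-length window immediately before
  onset. The comparison window is not dictated by the protocol, so the
  immediately pre-onset window of matching length is used; an "increase"
  additionally requires a positive mean difference, which keeps the
  two-tailed false-positive rate near $\alpha$ overall (verified by the
  null-calibration test at 1,000 homogeneous-Poisson cells).
* **Sustained vs transient**: rate over the last 500 ms of the step against
  the 2 s pre-onset baseline; significant positive difference = sustained.
* **Step measures**: ON and OFF peaks are the largest absolute
  baseline-subtracted change in any 50 ms bin within a 1 s search window
  after each transition (signed, so suppression is representable); "tonic"
  is the baseline-subtracted mean over the last 500 ms of light ON.
* **Latency**: spikes are pooled, binned at 1 ms and smoothed with a
  Gaussian kernel window ($\sigma$ = 5 ms); latency is the first
  post-onset sample beyond the 95% confidence limits of the 1 s
  pre-stimulus smoothed rate (mean ± 1.96 SD; a 2.5/97.5-percentile
  option exists). Two numerical choices matter here and are deliberate:
  the kernel window **trails** the evaluation time (causal half-Gaussian),
  because a centred kernel attributes stimulus-evoked spikes to times
  ~2$\sigma$ *before* the first evoked spike and therefore biases onsets
  early; and the crossing must be sustained for 10 consecutive samples
  (10 ms, two kernel widths), which suppresses the skewed single-cluster
  noise crossings that otherwise dominate sparse baselines. With these
  choices, a simulated 5→80 spikes/s step at 100 ms is detected at a
  median of ~100 ms over 50 trials.

**Irradiance-response curves** are 4-parameter sigmoids
$r(I) = \mathrm{lower} + (\mathrm{upper}-\mathrm{lower})/(1 +
10^{\,\mathrm{slope}\,(\log EC_{50} - I)})$ in log10 irradiance, fitted by
Levenberg–Marquardt with five quantile-based starts; the fit is reported
in the canonical orientation (positive slope). Curves are compared by the
extra-sum-of-squares F-test; the parameters under test (default
$\{\log EC_{50}, \mathrm{slope}\}$, giving $F_{2,\,n-8}$) are shared in the
null model while the remaining parameters stay free per dataset. The
"two-tailed" phrasing common in biology software corresponds to the
standard upper-tail F probability, which is what is computed.

**Melanopsin contrast** compares baseline-subtracted mean rates over the
first 250 ms and the last 5 s of long (10 s) cone-matched steps that
differ in melanopsin excitation; a melanopsin contribution appears as a
high-vs-low difference confined to the late window.

**Cone opponency**: responses to 0.25 Hz square-wave opsin-isolating
stimuli are folded by cycle; the signed amplitude per opsin is the rate on
excitation increments minus decrements, tested across cycles. Opponency
requires opposite signs with both opsins individually significant. The
preference index $(|r_L| - |r_S|)/(|r_L| + |r_S|)$ (positive toward L) is
this package's operationalisation — the original metric is defined in
earlier literature and not reproduced here.

## Spatial and motion tuning

**Receptive fields** from flashing bars (~7°, 250 ms): per-position
responses are baseline-subtracted 250 ms window rates; detectability
requires at least two positions surviving Benjamini–Hochberg control
across all conditions, plus a non-flat profile (the fitted width must be
narrower than the stimulated span — a cell that responds equally
everywhere has no spatial RF). A 1-D Gaussian is fitted per axis to the
dominant-polarity profile; centre = fitted means, diameter = mean FWHM
(2.355σ), polarity from the sign convention that ON cells are excited by
luminance increments. Surround suppression is flagged when significant
opposite-sign responses occur within three bar widths of the centre.
These analysis details (window, fit form, multiplicity control) are this
package's declared choices for a procedure whose original description
lives in prior work.

**Chi-square periodogram**: firing is binned at 100 bins per stimulus
cycle and folded over complete cycles;
$\%\mathrm{Var} = 100\,\mathrm{Var}(\text{cycle-mean waveform}) /
\mathrm{Var}(\text{full series})$ (population variances), and the
cycle-folded statistic $Q = K N \cdot \%\mathrm{Var}/100$ is referred to
$\chi^2_{N-1}$. The null rejection rate at $\alpha=0.05$ was verified by
simulation at the protocol's cycle counts. %Var is exactly invariant to
shifting all spikes by whole periods.

**Grating battery** (5 spatial frequencies 8–64°/cycle × 5 speeds
30–240°/s × 8 directions; temporal frequency = speed ÷ spatial period):
the optimal stimulus is the %Var argmax, ties broken toward lower spatial
frequency, lower speed, then smaller angle. A cell counts as grating
responsive when any stimulus survives BH across the 200 tests — with 200
periodograms a raw $\alpha$ would make nearly every silent cell
"responsive". Cutoffs are the highest temporal frequency (Hz) and highest
spatial frequency (cycles/°) with %Var at least half its maximum,
interpolated linearly in log2 frequency between bracketing tested values;
boundary values are returned when there is no crossing, and no
interpolation is attempted into a frequency with no detectable response.

**Direction/orientation selectivity** uses peak-trough amplitudes of the
cycle-folded waveform (100 bins/cycle, circular 5-point boxcar) at the
optimal spatial frequency and speed: preferred direction = amplitude
argmax, null = opposite, $DSI = (D_{pref}-D_{null})/(D_{pref}+D_{null})$;
orientations average opposing pairs, with the orthogonal pair as null.
Cells with an index above 0.33 are labelled DS/OS. Note that the
peak-trough estimator is noise-inflated in both preferred and null
directions, so measured DSI understates the generative tuning depth — a
property shared with the experimental analysis, and the reason the
synthetic direction-tuned cells target a generative DSI of 0.6.

**Motion selectivity** (expanding/contracting light or dark spots, 2–60°,
0.5 or 0.1 s, with luminance-matched static controls): the response is the
largest 50 ms-binned baseline-subtracted rate within 650 ms of delivery
(500 ms baseline). A cell is motion selective when its overall best
response is to a motion stimulus and beats that stimulus's control in an
unpaired t-test at $P < 0.0065$ (an $\alpha$ incorporating a conservative
multiplicity correction);
$MSI = (S_{motion}-S_{control})/(S_{motion}+S_{control})$ with amplitudes
floored at 0 so the index stays in $[-1, 1]$. Detection of *any* spot
response (for the luminance ON/OFF and "none" classes) compares the peak
statistic against the identical statistic computed on the pre-stimulus
window — a bias-matched null, since a maximum over bins exceeds the mean
baseline rate even without a response — with BH control across the
stimulus set.

**Taxonomy**: precedence direction-tuned (V: DSI > 0.33, including the
occasional orientation-selective cell that crosses it) → complex-motion
(VI) → full-field classes (I sustained; II/III ON- vs OFF-biased transient
by the larger absolute peak) → spatial-contrast (IV: no full-field
response but a bar, grating or spot response) → unresponsive.

## Anatomical quantification

**Sector asymmetry**: a 90° window swept in 1° steps about the soma within
the dendritic-field radius; the index compares the densest placement with
the one 180° opposite, $(I_{max}-I_{opp})/(I_{max}+I_{opp})$. Works on
point sets (counts) or intensity images (sums); rotation-equivariant by
construction.

**Retinal quadrants**: boundaries lie on the anatomical axes (dorsal,
nasal, ventral, temporal), so the quadrants are the corner sectors
(dorsonasal … ventrotemporal) that anatomical reports name; a configurable
`boundary_offset` (45°) instead centres quadrants on the axes. Boundary
points are assigned half-open (inclusive lower angle). The densest
rotating window covering 25% of the retinal area is implemented as a 90°
sector of the retinal disk (the retina is treated as the disk of the
stated area centred on the optic disc; margin effects beyond that are out
of scope and documented at the interface).

**Colocalization with a rotation null**: stacks are tiled into 70 × 70 µm
× 40 µm subfields (square in voxels, so the in-plane 90° rotation is
lossless); the 10 subfields richest in label-positive voxels are analysed.
Voxel positivity uses per-channel Otsu thresholds by default (a fixed
threshold can be supplied — whether the original analysis thresholded
manually or automatically is unknown, so both exist). For each subfield
the fraction of label-positive voxels that are marker-positive is computed
before and after rotating that subfield's marker channel by 90°, and the
two sets of fractions are compared by paired two-tailed t-test. Subfields
with no label-positive voxels are excluded (warned); fewer than three
usable subfields yields an undefined p. The ratio of mean original to mean
rotated fraction is reported as colocalization relative to chance and is
`NA` when the rotated mean is zero.

**Label density** is count-in-polygon over polygon area per section,
averaged across sections. Point-in-polygon uses an even-odd crossing rule
with half-open edges, so a point on a boundary shared by two adjacent
regions is counted exactly once (left/lower boundaries inside).

## Pose decomposition and behavioural features

The statistical shape model writes the landmark configuration of frame
$t$ as $X(t) = (\bar X + \sum_i P_i b_i(t))\,R(t) + T(t)$: a mean pose,
orthonormal deformation eigenposes with per-frame coefficients, and a
rigid transform. Fitting uses generalised Procrustes alignment
(rotation + translation, no scaling) followed by PCA of the aligned
residuals. Alignment rotations are restricted to yaw by default: arena
landmark data have a physical vertical, and keeping it fixed preserves the
meaning of the XZ (sagittal) and XY (horizontal) planes used by the
elongation and bend features; the fitted model is put in a canonical
orientation with the mean body axis along +x. Full 3-D alignment is
available (`align = "full"`).

Per-frame decomposition alternates a rigid Procrustes step and a
shape-projection step to convergence (change in squared error below
1e-15, warm-started from the previous frame); on model-generated data the
landmark RMSE reaches ~1e-8 mm. Frames whose reconstruction error is
grossly out of line can be re-imputed from the model reconstruction — the
mechanism used for outlier landmark correction.

The nine features: rear (neck z − tail-base z, mm); elongation and bend
(projections of the rigid-aligned shape residual onto the leading
principal deformation mode computed within the XZ and XY planes
respectively, sign-fixed so that growing nose–tail distance is positive —
an explicit stand-in for definitions that live in prior work); their
first differences (padded with 0 at frame 1, no smoothing, 15 Hz);
locomotion (per-frame XY displacement of the rigid translation $T(t)$,
mm/frame); rotation (Frobenius distance between consecutive rotation
matrices, equal to $2\sqrt2\,|\sin(\Delta\theta/2)|$ for a pure yaw step);
and the binary freeze series.

Freezing: the summed 3-D displacement of all landmarks between
consecutive frames, scored 1 when strictly below 2 mm (exactly 2 mm is
not a freeze; the boundary convention is documented because the original
rule does not state it). Stimulus-evoked responses average each feature
over a 1 s window starting exactly 2 frames after onset, minus the mean
of the 2 s immediately pre-stimulus; freeze events start at the first
freeze frame in that window and end only at two consecutive non-freeze
frames, continuing past the window if freezing is ongoing.

## Synthetic data: what it emulates and what it does not

The generators produce seed-deterministic, ground-truth-labelled inputs
under the recording protocols: inhomogeneous-Poisson spike trains (by
thinning of a rate upper bound at 1 ms resolution) whose rate functions
implement each group's defining structure; 15 Hz landmark trajectories
with AR(1) locomotion/heading/posture dynamics and stimulus-locked
injected effects (flash → locomotion, loom → freeze of known duration,
sound → bend/rotation); two-channel puncta volumes with a programmed
colocalized fraction over independent background; and quadrant-weighted
retinal point patterns.

Default conditions follow the protocols: 2 s and 10 s steps with 2 s
baselines and 10 repeats, 0.25 Hz cone square waves, ~7° bars at 0.25 s
over a contiguous 1–2° position grid with 8 repeats, the full 5 × 5 × 8
grating grid, and the 8-spot looming set at two transition speeds with 20
repeats. Grating trials span a whole number of stimulus cycles (8 by
default) so the periodogram folds cleanly, and the labelled 240-cell
population uses 4 repeats per grating stimulus — a desk-scale size chosen
once (below the 13 repeats of the recording protocol, which would only
improve the signal-to-noise). Rates: baseline 5 spikes/s; sustained steps
to 30 spikes/s with a slow saturating melanopsin term (τ = 2 s) active
only under the melanopsin-high stimulus; ON/OFF transients decaying with
τ = 0.3 s; direction-tuned cells use a cosine kernel
$A(θ) = A\,(1+k\cos(θ-θ_p))/(1+k)$ whose noiseless DSI equals $k$ exactly
(targets above 1 are rejected as infeasible); looming cells respond with a
transient peaking at the end of the expansion. Volume defaults (2,000
label puncta, 15% independent marker density in a 70 × 56 × 8-voxel stack
at 5 µm) put the chance colocalization level in a regime where the paired
test is well calibrated and the ratio-to-chance estimator is stable.

What the synthetic data do **not** emulate: spike-sorting artefacts,
bursting and refractoriness, adaptation across trials, eye movements,
correlated noise across cells, landmark-tracking outliers beyond isotropic
jitter, realistic confocal point-spread functions, or retinal flattening
geometry. Passing tests therefore certify the *analysis* under the stated
statistical structure, not robustness to every failure mode of real
recordings.

## Numerical choices and limitations

Window membership is half-open `(from, to]` everywhere; argmax ties break
deterministically (first/lowest coordinate). PSTH smoothing renormalises
the kernel at the series edges so constants are preserved. The latency
fallback for silent baselines requires the smoothed rate to exceed half a
single spike's kernel contribution (flagged). Sigmoid fits report
`converged` honestly and return the best candidate otherwise. The
alternating pose decomposition converges linearly (rate ~0.76 on the toy
model), so tolerances are set on the error change rather than iteration
counts. Problem sizes in the test-suite calibrations (1,000-cell nulls,
240-cell taxonomy, 50-field RF recovery, 100-run latency/sigmoid
recoveries, 500–1,000-stack colocalization nulls) are the package's
stated desk-scale study conditions.

Known limitations: the cone-preference index and the elongation/bend
operationalisations stand in for definitions published elsewhere; the
chi-square periodogram's χ² reference is asymptotic (calibration verified
at the protocol's cycle counts, not guaranteed for very sparse trains);
group-level statistics across animals/experimental groups are
deliberately out of scope — the pipeline emits tidy per-unit and per-trial
tables for external modelling.
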