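---
title: "Quantifying blood-brain-barrier leakage with MP2RAGE delta-T1 maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying blood-brain-barrier leakage with MP2RAGE delta-T1 maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deltaT1)
```

## The measurement problem

Gadolinium-based contrast agents shorten the longitudinal relaxation time
T1 wherever they accumulate. In multiple sclerosis, visible enhancement on
post-contrast T1-weighted images marks acute blood-brain-barrier (BBB)
breakdown, but most lesions do not enhance visibly even though their BBB
may still leak at a low level. Quantitative T1 mapping offers a more
sensitive readout: subtract a pre-contrast T1 map from a post-contrast T1
map acquired in the same session and examine the difference,

$$\Delta T_1 = T_1^{\text{post}} - T_1^{\text{pre}},$$

inside non-enhancing white matter lesions (NELs). Negative values mean
gadolinium reached the tissue. The magnitude is small — on the order of
0.1 s against a lesion T1 near 1.9 s at 7T — so everything hinges on the
accuracy of the T1 maps and the subtraction chain. This package implements
that chain end to end, together with a synthetic ground-truth generator
that makes every stage testable.

## The MP2RAGE signal model

MP2RAGE acquires two gradient-echo (GRE) readout trains in a single
inversion-recovery cycle: inversion (efficiency $\eta$), a train of
`n_exc` small-flip-angle excitations centred at TI1, a second train
centred at TI2, and free recovery until the next inversion. Only
longitudinal magnetisation needs to be tracked: each excitation with flip
angle $\alpha$ maps $M_z \mapsto M_z\cos\alpha$ followed by recovery over
the echo spacing, each gap relaxes $M_z$ toward $M_0$, and the inversion
maps $M_z \mapsto -\eta M_z$. Every stage is affine in $M_z$, so the
periodic steady state is obtained in closed form by composing the affine
maps over one cycle and solving the fixed point. The reported signals are
$\sin\alpha \cdot M_z$ just before the centre excitation of each train
(centre of k-space under linear encoding).

`simulate_signals()` implements the closed form; `simulate_signals_bloch()`
advances $M_z$ pulse by pulse through repeated cycles until periodicity and
serves as the independent check. The two agree to better than $10^{-8}
M_0$ over T1 from 0.3 to 5 s and transmit scales 0.8-1.2 (a test asserts
this).

The two readouts are combined into the uniform (UNI) ratio image

$$\mathrm{UNI} = \frac{\mathrm{Re}(S_1 S_2^*)}{|S_1|^2 + |S_2|^2} \in
[-0.5, +0.5],$$

which cancels $M_0$, receive-field and $T_2^*$ weighting, leaving a pure
function of T1 for a given protocol. T1 estimation inverts this function
through a lookup table (`build_lookup()`, default 1 ms grid over
0.3-5.0 s): the largest strictly monotone branch of the UNI(T1) curve is
retained, inverted by linear interpolation, and UNI values outside the
branch are clamped to the nearest bound and flagged rather than silently
extrapolated. For the study protocol (cycle TR 8.5 s, TI 1.0/3.0 s, flips
5°/5°, 252 excitations at 6.9 ms spacing) the branch covers roughly
0.3-4.2 s and is strictly decreasing; very long T1 (CSF-like) falls
outside and is excluded by the QC flag, which is the correct behaviour for
a white-matter-focused analysis.

The default inversion efficiency is 1.0. It is configurable, but since it
affects only absolute calibration — and the validation suite is built on
self-consistent recovery — no claim is made about absolute agreement with
any particular scanner implementation.

## The processing chain

`reconstruct_t1_map()` mirrors the clinical pipeline: the denoised
T1-weighted product `inv2 * (uni + 0.5)` (which suppresses the amplified
background noise of the raw UNI image) is thresholded at 5% of its robust
maximum (99th percentile) to form a brain mask, and the lookup inversion is
applied inside it. `register_post_to_pre()` aligns the post-contrast volume
rigidly (6 degrees of freedom): a supplied transform is inverted exactly
when the misalignment is known, or estimated by maximising normalised
cross-correlation over a 3-level multi-resolution pyramid. The estimator
optimises translations before rotations at every level (translations carry
most of a same-session head misalignment and are far better conditioned),
scans the final level at quarter-voxel resolution to step over the local
NCC maxima that trilinear interpolation creates near the voxel lattice, and
finally prefers the simplest transform (rounded translations, zero
rotations) among near-ties — integer translations reproduce same-grid
voxels exactly, and near-spherically-symmetric anatomy leaves rotations
weakly constrained. Registration success is judged by the achieved NCC
(threshold 0.8), not by the optimiser's iteration flag; failure falls back
to the identity with a warning.

`compute_delta_t1()` subtracts pre from aligned post (the sign convention
is post − pre, so gadolinium shortening is negative) and voxels flagged by
either reconstruction are set to missing — excluded, never imputed or
clipped. `derive_masks()` encodes the mask algebra: NEL = WML ∖ EL and
NAWM = cerebral WM ∖ WML, with EL forced into WML by intersection (with a
warning) if the inputs violate the subset relation.

## The synthetic ground truth

`build_phantom()` generates a concentric-shell head — CSF rim, cortical-GM
ribbon, WM core — with non-overlapping spherical lesions placed wholly
inside the WM core, a configurable fraction of which enhance. Geometry is
deliberately schematic: the mathematics under test (signal model, lookup
inversion, registration, mask algebra, ROI statistics) is indifferent to
anatomical realism, and a geometry this simple makes every mask and every
median exactly known. Default tissue values are the cohort medians of the
7T study: pre-contrast T1 of 1.300 s (NAWM), 1.898 s (cGM), 1.912 s (NEL),
2.430 s (EL), with CSF at 4.3 s, and delta-T1 of −0.004, −0.096, −0.134
and −1.100 s respectively (zero in CSF). Per-voxel spread defaults to
zero so that configured medians are exact ground truth; a Gaussian spread
can be switched on per tissue. `apply_gadolinium()` supports the direct
shift used for recovery testing and a relaxivity model
$1/T_1^{\text{post}} = 1/T_1^{\text{pre}} + r_1 C$ for
concentration-driven simulations.

`simulate_acquisition()` forward-simulates both readouts voxelwise.
Noise is circular complex Gaussian per readout channel, so stored
magnitudes are Rician (Rayleigh in the background with mean
$\sigma\sqrt{\pi/2}$, asserted by a test) and the UNI image is formed from
the complex combination exactly as on-scanner. An earlier design that
added magnitude noise to signed real signals was rejected: the NEL T1 of
1.912 s happens to sit near the zero crossing of the first readout under
this protocol, and restoring the sign from a noisy sample inflates
$|S_1|$ asymmetrically, biasing the NEL delta-T1 median by about
−0.03 s at realistic noise levels. The complex-channel model is both more
faithful to how MP2RAGE data are actually combined and free of that
artefact. `noise_sigma` is expressed as a fraction of $M_0$;
`snr_to_sigma()` converts a tissue SNR defined on the noiseless
second-inversion white-matter signal (the conventional reference image)
into that scale. Optional degradations: a linear left-right B1+ gradient
scaling both flip angles, and a rigid 6-parameter misalignment of the
post-contrast acquisition.

The simulated cohort (`simulate_cohort()`) draws demographics and clinical
scores from the study population's per-phenotype means and spreads (47
subjects, 34 relapsing-remitting and 13 progressive, 72% treated, EDSS
median 3) and generates each subject's NEL median delta-T1 from an
additive model: a treated-RRMS baseline of −0.110 s, −0.055 s for
progressive phenotype, −0.040 s for being untreated, −0.012 s per EDSS
point above 3, plus between-subject noise of SD 0.045 s. The baseline and
group offsets are set from the reported group medians (RRMS −0.110 vs PMS
−0.177; treated −0.122 vs untreated −0.162; EDSS ≤ median −0.109 vs >
median −0.168); the between-subject SD is chosen so the generated ranges
are comparable to the reported ones. What passing cohort tests show is
that the statistics layer recovers the configured orderings and effect
directions — not that real patients behave this way, since the generative
model is itself built from the reported summaries.

## Statistics layer

Per-ROI distribution metrics (`roi_metrics()`) follow stated conventions:
sample variance with the $n-1$ denominator, quartiles by linear
interpolation (type 7; configurable, since the convention matters at small
n), and Pearson kurtosis ($m_4/m_2^2$, normal = 3; the excess convention
is available but non-excess is the default because the reported NEL
kurtosis values of roughly 5-6 sit above 3). Group summaries follow the
median-of-medians convention: per-subject medians first, never pooled
voxels. Pooled voxel vectors are available separately
(`pooled_voxel_values()`) for the per-voxel correlation and KDE overlay
analyses.

Hypothesis tests delegate to the standard R machinery behind stable
surfaces: paired t plus matched-pairs Wilcoxon (`compare_paired()`),
Mann-Whitney U (`compare_groups()`), Spearman/Pearson with partial
variants by rank-then-residual (`correlate()`), logistic treatment models
with Wald p-values and explicit separation detection
(`fit_treatment_logistic()`, with `tidy()`/`glance()` methods), and
Benjamini-Hochberg FDR (`fdr_adjust()`). Exact enumeration is used for the
rank tests up to a combined n of 12 without ties, the normal approximation
with continuity correction above; the test suite carries independent
enumeration oracles (explicit sums over sign patterns and group
assignments) and a 2000-replicate null calibration of the Mann-Whitney
rejection rate. All tests are two-sided. One spec-level invariant was
found to be false and is deliberately not asserted: the BH step-up is not
idempotent on its own output (re-adjusting multiplies each order statistic
by $m/j$ again); the suite asserts the true properties instead — adjusted
values never decrease, order statistics are preserved, constant vectors
are fixed points.

## Numerical choices and problem sizes

* Lookup grid 1 ms: an order of magnitude finer than the smallest
  delta-T1 of interest (4 ms in NAWM); inversion error is bounded by one
  grid step and in practice is far below it.
* Noiseless recovery tolerance 2 ms per tissue median (3 ms for
  subtraction maps), i.e. the grid step.
* Validation phantoms are 64^3 for the recovery targets (about 1-2 s per
  phase) and 48^3 or 32^3 for property suites; these sizes were chosen
  because recovery is already exact at the grid step there, so larger
  grids add nothing but runtime.
* Registration pyramid factors 4/2/1 with strided downsampling and a
  1-2-1 binomial pre-smooth of the metric images; Nelder-Mead with 300
  iterations per stage.
* Degenerate inputs are contracts, not accidents: empty ROIs error,
  constant ROIs report missing kurtosis, all-tied paired differences flag
  the Wilcoxon test, perfect separation withholds logistic coefficients.

## Known limitations

* The phantom's geometry is schematic; partial-volume behaviour at real
  cortical folds and confluent periventricular lesions is not emulated.
* Within-lesion delta-T1 structure is uniform (optionally with iid
  spread); the scattered spatial pattern seen in real lesions is not
  modelled, and no claim about its spatial statistics is made.
* Gadolinium is static — one post-contrast time point, no
  pharmacokinetics.
* B1+ correction is not implemented (only forward simulation of B1+
  bias); absolute T1 calibration against any particular scanner is out of
  scope.
* The registration estimator is designed for small same-session rigid
  misalignments; it is not a general-purpose registration tool.
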