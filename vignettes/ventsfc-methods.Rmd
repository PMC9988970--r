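---
title: "Methods: from bedside fNIRS and ventricle volumes to |sFC|/VV slopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from bedside fNIRS and ventricle volumes to |sFC|/VV slopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them. Preterm neonates with germinal
matrix–intraventricular hemorrhage can develop posthemorrhagic ventricular
dilatation; the analysis implemented here asks whether enlarged lateral
ventricles (VV, mL, from 3D cranial-ultrasound segmentations) go along with
disrupted spontaneous functional connectivity (sFC) in bedside fNIRS, and
whether CSF-diversion procedures (which abruptly reduce VV) are followed by
connectivity rebounds.

## The synthetic cohort generator

No patient recordings ship with the package, so all quantitative claims are
made against a generator whose defaults encode the study conditions: two
arms (23 patients without CSF diversion with 2–8 sessions; 7 with diversion
with 3–15 sessions), gestational age at birth ~26.6 ± 2.6 weeks, roughly
weekly sessions, 408-s recordings (the mean session length) at 10.17 Hz on
a 20-channel cap (10 per hemisphere, 22 mm separation, 760/850 nm).

A recording's log-attenuation is the sum of:

* a **hemodynamic component**: latent band-limited (0.01–0.08 Hz) Gaussian
  series mixed through an eigenfactor of the target correlation matrix and
  pushed through the Beer–Lambert forward model (ΔHbO with antiphase ΔHbR,
  HbO SD 0.01 mM). The spectral coefficients of the latent series are
  orthogonalized across channels, so the realized correlation of the latent
  block equals the target *exactly* at any duration — at 6.8 min the slow
  band has only ~30 effective degrees of freedom, and without this the
  empirical correlations of even a "null" session would wander by ±0.2;
* a **cardiac oscillation** shared by both wavelengths, with slowly
  drifting rate inside 90–210 bpm, amplitude 0.5× the hemodynamic OD SD
  per channel (15% of channels are cardiac-free by default, emulating the
  observed exclusion fraction);
* **polynomial drift**, **motion spikes** (Poisson, 0.5/min; step plus
  decaying transient, 5–20× the hemodynamic SD), **dropout intervals**
  (intensity collapses below 1% of baseline) and white sensor noise
  (2×10⁻⁴ OD).

The default target correlation is a quadrant factor model: channels load
(0.75) on their hemisphere × region factor; factors of one hemisphere
correlate +0.3, factors across hemispheres −0.5 — giving within-cluster
correlations ≈ 0.56 and interhemispheric anti-correlations ≈ −0.28,
positive semidefinite by construction.

**Coupling to VV.** Per session, each pair's target magnitude is attenuated
as `|rho| = max(0, |rho0| − beta · VV)` with signs preserved
(`beta = 0.002 /mL` by default), using the hemisphere's own volume for
within-hemisphere pairs. For interhemispheric pairs the study protocol is
only defined per hemisphere; we default to the mean of left and right
(configurable: left/right/total). Attenuated matrices are projected back to
the PSD cone (eigenvalue clamping + diagonal renormalization) when needed.

VV trajectories are linear in GA per side with Gaussian session noise,
truncated at 0.5 mL; diversion events subtract a step (default
19.93 ± 8 mL total, floor 2 mL) split across sides in proportion to the
current volumes, with pre/post sessions placed on the same day. Diversion
baselines (10–25 mL per side) and growth (1–3.5 mL/week) reflect
progressive PHVD; the no-diversion arm is mild (1.5–8 mL per side, −0.3 to
1 mL/week). `simulate_sfc_cohort()` skips the optics and draws each
session's connectivity directly from the attenuation model plus Gaussian
estimation noise (SD 0.1, matching the sampling error of a robust
correlation on ~150 one-second samples).

What the generator does *not* emulate: spatially structured optode
coupling, systemic physiology (respiration, blood-pressure waves),
developmental nonstationarity within a session, or any relation between
artifacts and clinical state. Passing tests therefore demonstrate that the
pipeline recovers what it assumes — not that the assumptions hold in real
neonates.

## Signal quality and subsample selection

SCI and PSP are computed in 5-s windows with 50% overlap; window and hop
lengths are `floor(window_s * fs)` and `floor(window_s * fs * (1−overlap))`
samples — deterministic and never exceeding the requested duration. Per
window both wavelengths are linearly detrended (slow hemodynamics would
otherwise leak through a 50-sample band-pass and correlate across
wavelengths), filtered to 1.5–3.5 Hz with a zero-phase forward–backward
order-3 Butterworth, and amplitude-normalized. SCI is their Pearson
correlation; PSP is the peak of `|FFT|²/L` of the coeff-normalized
cross-correlation inside the cardiac band. Detrend + filtfilt is linear, so
its action on fixed-length windows is precomputed once as a matrix — the
tests verify bit-level equivalence with filtering each window separately.

The 2.5-min subsample maximizes the mean over covered windows and channels
of rank-normalized SCI + rank-normalized PSP over hop-aligned candidate
starts; any span overlapping a dropout interval (intensity below 1% of the
channel median for >0.5 s) scores −Inf, with a least-contaminated fallback
(and warning) when no clean span exists. Ties break to the earliest start.

Channel validity requires both a sufficient fraction (0.6) of windows
passing SCI ≥ 0.7 and PSP ≥ 0.1, and a local spectral peak inside the
cardiac band exceeding 2× the band's median power. The exact thresholds of
the study's detector are not public; these are declared reconstructions,
all exposed in `pipeline_config()`.

## Motion correction

Detection works on a running-median high-passed copy of each OD series (the
median filter is edge-preserving, so baseline steps do not inflate the
scale estimate): a sample is flagged when the moving-window (1 s) SD
exceeds 13.5× the robust SD, or the window peak-to-peak exceeds 5× it
*while the window SD is also elevated* (≥3×; a lone extreme of clean noise
raises peak-to-peak but not the SD), or the first difference jumps by more
than 5× the robust SD of the differences (steps are invisible to the
median high-pass but maximal in the first difference). Flags are dilated by
±0.5 s and merged.

Correction fits a smoothing spline inside each segment and subtracts it;
the `smoothing` parameter (default 0.99) is the fidelity weight, mapped to
the spline's roughness penalty as `(1−p)/p × 1e−8` on the normalized
abscissa — tight enough to track step artifacts to a few percent. The
residual segment is re-leveled onto a linear ramp between the mean of up to
one second of clean data on each side, which keeps both boundaries
continuous even when an unflagged baseline shift abuts the segment. Samples
outside dilated segments are returned unchanged — by construction, not by
approximation. If a segment covers the whole series there is no clean
anchor; the series is linearly de-trended with a warning, leaving genuine
signal intact. Correction operates on optical density (artifacts are
multiplicative in intensity, additive in OD), after subsample selection.

## Hemoglobin conversion

ΔOD = −ln(I/Ī) with Ī the subsample mean (non-positive samples are replaced
by the channel's minimum positive value and flagged; all-non-positive
channels become invalid). The 2×2 Beer–Lambert system is solved per channel
and sample with the Gratzer/Kollias extinction compilation at 760/850 nm
(embedded as versioned constants, table id `"gratzer"`; the study does not
name its table) and the stated partial pathlength factors 0.1063/0.0845
used verbatim as multiplicative pathlength terms. Whether these are on the
conventional DPF scale is unknown; their absolute scale only rescales
concentration units and cancels in all correlation-based results. Channel
distances are the montage separations (scaled to cap size) in cm.

## Nuisance regression and resampling

The design holds Fourier sine/cosine pairs at every frequency `m/T`
strictly between 0.09 Hz and the Nyquist rate (T is the session length —
the selected subsample — rather than a fixed constant), plus polynomial
drift terms of orders 0–4. "Orders 0–4" includes the constant, which a
well-posed residual needs. The polynomials are discrete orthogonal (Gram)
polynomials from `stats::poly`: continuous Legendre polynomials are only
O(1/n²) orthogonal on a finite grid, whereas the discrete family is exactly
orthogonal (and converges to Legendre), so residual orthogonality can be
asserted at 1e−10. On the uniform grid the Fourier block is an orthonormal
subset of the DFT basis; the regression exploits this for an exact fast
path (project onto the Fourier block, orthonormalize the remaining ~6
columns against it, project again), making the near-square OLS (~1500
regressors on ~1500 samples) cost milliseconds instead of a dense QR. The
global regressor is the mean over valid channels, per chromophore; HbO and
HbR are cleaned independently and HbT is recomputed afterwards. No
pre-whitening is applied anywhere.

Resampling to 1 Hz uses a zero-phase order-4 Butterworth low-pass at
0.45 Hz (odd-reflection padding tames edge transients) followed by
interpolation on the integer-second grid; output length is `floor(n/fs)`,
DC is exact, and the 0.01–0.08 Hz passband is flat to well under 2%.

## Robust correlation

Both series are standardized by median/MAD. Bisquare weights (tuning
4.685) are computed from each sample's joint standardized residual distance
to the current weighted fit — the bivariate Mahalanobis distance, symmetric
in the two series — and iterated to convergence. A weighted Pearson with
weights from one-directional line-fit residuals is *not* used: downweighting
exactly the points that dilute the correlation inflates it (population value
≈ 0.54 at ρ = 0.5), which would defeat the purpose of a correlation
estimate. The returned value applies the standard reweighting step of
robust covariance estimation: plain Pearson over the samples whose
converged weight is positive. On clean data nothing is trimmed and the
result equals classical Pearson exactly; gross outliers fall beyond the
redescending cutoff and are excluded. Zero-MAD inputs fall back to Pearson
with a warning; results are clamped to [−1, 1].

## Group maps and |sFC|/VV slopes

Group t-maps average raw session correlations (not Fisher-z; a z-transform
average is available but off by default) to one value per patient per pair,
then test against zero; pairs with fewer contributing patients than the
minimum-sample threshold (defaults 10 of 23 and 5 of 7 per arm) are flagged
low-confidence and excluded. Missingness always propagates as missing.

|sFC| (absolute connectivity, polarity-free disruption measure) is related
to VV per channel pair, using the pair's own hemisphere's ventricle volume
(interhemispheric rule as above), via three estimators:

1. **Per-patient OLS** — slope per patient (≥2 sessions; constant-VV
   patients dropped with a warning), one-sample t-test of patient slopes;
2. **LME** — `|sFC| ~ 1 + VV` with a per-patient random intercept; a random
   VV slope is attempted first and dropped on convergence failure or
   singular fit (recorded per pair). Estimation is REML; p-values are Wald
   normal approximations on the fixed-effect t (the study's tool is
   unspecified; with these design sizes Satterthwaite corrections change
   nothing material);
3. **LME + GA** — adds gestational age at session as a fixed effect,
   adjusting both |sFC| and VV for their common developmental trend.

Hemisphere-level pooled tests are one-sample t-tests over the group-level
slopes of all *within-hemisphere* pairs (an interhemispheric pair has no
unique hemisphere; its pair-level slope is still reported). How the study
extracted "group-level slopes" from LME fits is ambiguous; we use the
per-pair fixed effects. No multiplicity correction is applied across
channel pairs, matching the single-hypothesis stance (an FDR option exists
but is off by default). GA post-hoc models (`VV ~ GA`, mean `|sFC| ~ GA`,
random intercepts) provide the context check.

Diversion paired tests match, per event, the nearest sessions before and
after within 0.15 weeks (≈ one day, the same-day protocol; widening is a
parameter) and compare ΔVV (left/right/total) and Δ of the four
cluster-mean |sFC| values with paired t-tests, pooling events across
patients.

## Problem sizes and numerical choices in the tests

The test suite and acceptance checks run the full default cohort once
(23 + 7 patients, 408-s sessions for the acceptance script, 300-s for the
t-map check) and use reduced designs where many replicates are needed: the
slope sign-recovery and null-calibration experiments use a 6-channel
montage (within-hemisphere pairs only) with 14 patients × 8–12 sessions at
100 and 200 replicates — chosen so each replicate's hemisphere test has
non-trivial power while three estimators × hundreds of replicates stay
within minutes. Subsample-optimality checks use 200-s sessions at 8 Hz so
every candidate span can be enumerated. Determinism is asserted byte-for-byte
on written slope tables from two identically seeded runs.

Known limitations: the cardiac-presence detector and motion thresholds are
reconstructions with documented defaults, not the study's (unpublished)
values; the hemisphere assignment of interhemispheric pairs in the slope
analysis is a configuration choice; LME p-values are asymptotic; and all
calibration statements are with respect to the generator's assumptions
listed above.
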