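# ventsfc

Bedside multimodal monitoring analysis for preterm neonates with germinal
matrix–intraventricular hemorrhage (GMH-IVH): links lateral-ventricle
volumes (VV, from 3D cranial ultrasound segmentations) to spontaneous
functional connectivity (sFC) measured with multichannel functional
near-infrared spectroscopy (fNIRS). It is written for researchers studying
posthemorrhagic ventricular dilatation (PHVD) who need a tested, fully
reproducible version of this analysis chain, exercised end-to-end on a
synthetic-cohort generator that emulates the statistical structure of such
bedside data.

## What it computes

**Signal chain (per session).** Two-wavelength (760/850 nm) intensity
recordings at 10.17 Hz from a 20-channel neonatal cap (10 per hemisphere,
22 mm separation) pass through:

1. windowed quality metrics — scalp coupling index (SCI) and peak spectral
   power (PSP) in 5-s windows with 50% overlap for a cardiac range of
   90–210 bpm;
2. selection of the contiguous 2.5-min subsample maximizing rank-combined
   SCI + PSP while avoiding signal dropout;
3. channel exclusion where cardiac pulsation is absent (SCI/PSP thresholds
   plus a cardiac-band spectral-peak test), with manual/hardware exclusions;
4. spline interpolation of abrupt motion artifacts on optical density;
5. modified Beer–Lambert conversion to ΔHbO/ΔHbR with partial pathlength
   factors 0.1063 (760 nm) and 0.0845 (850 nm), channel lengths scaled to
   cap size; ΔHbT = ΔHbO + ΔHbR;
6. nuisance regression: Fourier terms above 0.09 Hz, polynomial drift terms
   (orders 0–4) and the global mean signal, fit by OLS per chromophore (no
   pre-whitening), then resampling to 1 Hz;
7. robust-correlation connectivity between all valid channel pairs.

**Statistics (per cohort).** Group t-maps (session correlations averaged to
one value per patient, one-sample t-test per channel pair, minimum-sample
thresholds); and the |sFC|/VV relation estimated per channel pair with three
incremental methods — per-patient simple linear regression, linear
mixed-effects (LME) with patient random effects, and LME additionally
adjusting for gestational age (GA) — each pair using the volume of the
corresponding hemisphere's ventricle, with hemisphere-level pooled t-tests.
For patients undergoing CSF diversion, pre/post same-day paired comparisons
of VV and of four functional-cluster |sFC| summaries, plus longitudinal
case-study tables.

**Synthetic cohort.** `simulate_cohort()` generates both study arms
(defaults: 23 patients without CSF diversion, 2–8 sessions; 7 with
diversion, 3–15 sessions, step volume decreases at events, mean −19.93 mL)
with per-session recordings whose latent correlation magnitudes are
attenuated as `|rho| = max(0, |rho0| − beta · VV)` (default
`beta = 0.002 /mL`), signs preserved — so every estimate has a known ground
truth. `simulate_sfc_cohort()` is the faster connectivity-level variant for
statistics-layer experiments.

## Worked example

```r
library(ventsfc)

cohort <- simulate_cohort(cohort_spec(), seed = 1)   # 30 patients, ~190 sessions
res    <- run_pipeline(cohort, pipeline_config(), out_dir = "results/pipeline")

res$slopes$diversion$lme$hemispheres
```

```
 hemisphere     slope      t df      p n_pairs
       left -0.001354 -2.552 44 0.0143      45
      right -0.000475 -0.993 44 0.3264      45
```

The hemisphere-level LME slope in the diversion arm is negative
(−0.00135 per mL, p = 0.014 on the left): |sFC| falls as the ventricles
enlarge, recovering the generator's planted coupling of −0.002 per mL from
the raw optical signals. The paired diversion tests show the volume steps:

```r
run <- diversion_paired_tests(res$cohort)
run$tests[run$tests$variable == "d_vv_total", ]
#    variable  mean    sd     t df       p  n
#  d_vv_total -19.9 7.495 -9.92 13 1.98e-07 14
```

i.e. total VV drops by ~20 mL across CSF-diversion events (the generator's
configured mean step is 19.93 mL).

The same workflow is laid out as numbered drivers under `analysis/`
(`01_simulate_cohort.R` … `05_diversion_case_studies.R`), each a thin script
over the package functions that prints what it found and writes its tables
under `results/`.

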