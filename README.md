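# laryngotopo

Laryngotopographic analysis of high-speed videolaryngoscopy (HSV)
recordings in R: per-pixel Fourier mapping of vocal-fold vibration and the
**Stiffness Asymmetry Index (SAI)** that quantifies left/right vibratory
asymmetry.

## The problem

During phonation the vocal folds oscillate at a common fundamental
frequency F0 (roughly 90–370 Hz). Vocal-fold tissue stiffened by an
infiltrative lesion — early glottic carcinoma in particular — loses its
mucosal wave and stops vibrating, while benign masses such as polyps
usually keep oscillating. HSV captures individual vibratory cycles at
2400–3200 frames per second, so the brightness of every pixel over time is
a periodic signal wherever tissue vibrates. This package is for voice
scientists and laryngology researchers who want to turn such recordings
into quantitative vibration maps and a single asymmetry score per
recording.

## The method

For each pixel inside a B-spline region of interest drawn around the
folds, the discrete Fourier transform of the mean-removed brightness
function b(t) ∈ [0, 255] yields, at the bin nearest the global F0, an
amplitude (normalized to [0, 1] by the ROI-wide maximum) and a phase in
(−π, π]. Pixels whose normalized amplitude reaches 0.1 are *vibrating*.
With the ROI split at the glottal axis into the affected (AVF) and
non-affected (NAVF) fold and vibrating areas AVF_F0, NAVF_F0:

```
SAI = 1 − (AVF_F0 / AVF) / (NAVF_F0 / NAVF)
```

SAI = 0 means symmetric vibration; SAI → 1 means the affected fold barely
vibrates — the signature of a stiff, malignancy-suspect fold. The full
chain (`run_single()`) is: read → channel extraction (red for fold/gap
contrast, blue for glare flagging) → inter-frame offset estimation by
cross-correlation and integer-shift stabilization → maximum-glottic-opening
frame selection → rotation to a vertical glottal axis → B-spline ROI and
left/right split → per-pixel spectra → global F0 → maps → SAI, plus an
independent kymographic F0 cross-check from the glottal-width waveform
(GWW). Group-level Mann-Whitney comparisons (`compare_groups()`) use the
exact small-sample null distribution.

No clinical data ship with the package; a synthetic scene generator
(`scene_config()` / `generate_recording()` / `generate_cohort()`) renders
fold-shaped vibrating regions with full ground truth for validation.

## Worked example

Generate a synthetic recording in which the entire left fold vibrates at
150 Hz but only a quarter of the right fold does (expected
SAI = 1 − 0.25/1 = 0.75), then run the full pipeline:

```r
library(laryngotopo)

cfg   <- scene_config(vib_frac = c(left = 1, right = 0.25))
scene <- generate_recording(cfg)
scene$recording
#> <hsv_recording> 480 frames, 128 x 128 px, 2400 fps (synthetic-seed1)

res <- run_single(run_config(scene$recording, scene$landmarks,
                             affected_side = "right"))
res
#> <ltg_run> global F0 = 150.0 Hz (GWW 150.0 Hz), SAI = 0.73
res$sai
#> <sai_result> SAI = 0.73 (affected: right)
#>   affected fold: 870 / 4136 px vibrating; non-affected: 3200 / 4138 px
res$maps
#> <ltg_maps> global F0 = 150.0 Hz (bin 5.00 Hz), 8274 ROI px, 4070 vibrating (threshold 0.10)
```

The detected global F0 (150 Hz) matches the planted modulation frequency
and the independent kymographic estimate; the recovered SAI (0.73) sits
within 0.05 of the configured 0.75 — the residual comes from the one
column of gap-edge pixels per side swept by the oscillating glottal gap,
which vibrates on both folds alike. Maps export as headerless CSV grids
and pseudocolor PNGs via `write_maps()`; real recordings are read from
lossless PNG/TIFF frame directories with `read_recording()`, with axis and
fold-edge nodes supplied by a JSON/YAML landmark file
(`read_landmarks()`).

A thin command-line front end ships at `inst/cli/ltg`
(`ltg run`, `ltg cohort`, `ltg synth`).

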