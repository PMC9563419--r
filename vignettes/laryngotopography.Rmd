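---
title: "Laryngotopographic mapping and the Stiffness Asymmetry Index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Laryngotopographic mapping and the Stiffness Asymmetry Index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laryngotopo)
```

## The problem and the method

During phonation the two vocal folds oscillate at a common fundamental
frequency $F_0$, typically 90--370 Hz. Tissue stiffened by an infiltrative
lesion — early glottic carcinoma in particular — loses its mucosal wave and
stops vibrating, while benign polypoid masses usually add bulk without
stiffness and keep oscillating. High-speed videolaryngoscopy (HSV) at
2400--3200 frames per second resolves individual vibratory cycles, so each
pixel of the image sequence carries a *brightness function* $b_{x,y}(t) \in
[0, 255]$ whose periodicity reflects the motion of the tissue imaged at
that location.

Laryngotopography turns this observation into maps. For every pixel inside
a region of interest (ROI) around the folds, the package computes the
discrete Fourier transform of the mean-removed brightness function and
reads, at the spectral bin nearest the global fundamental frequency:

* the **amplitude**, normalized by the maximum over all analyzed pixels so
  the map lives in $[0, 1]$;
* the **phase**, in radians in $(-\pi, \pi]$;
* in addition, each pixel's own spectral peak within the analysis band
  (70--400 Hz by default) forms the per-pixel $F_0$ map.

A pixel is **vibrating** when its normalized amplitude reaches a threshold
of 0.1 — the clinically validated cutoff separating clear harmonic
oscillation from spectral noise — and it is not flagged as glare.

The left and right fold masks (the ROI split at the glottal axis) and the
vibrating mask define the **Stiffness Asymmetry Index**:

$$\mathrm{SAI} \;=\; 1 \;-\;
\frac{\mathrm{AVF}_{F_0} / \mathrm{AVF}}
     {\mathrm{NAVF}_{F_0} / \mathrm{NAVF}},$$

where $\mathrm{AVF}$ ($\mathrm{NAVF}$) is the pixel area of the affected
(non-affected) fold and $\mathrm{AVF}_{F_0}$ ($\mathrm{NAVF}_{F_0}$) the
vibrating pixel count within it. SAI $= 0$ means symmetric vibration; SAI
$\to 1$ means the affected fold barely vibrates: a stiff,
malignancy-suspect fold. A value of 0.75, for instance, means the affected
fold's vibrating fraction is only a quarter of the healthy fold's.

## The processing chain

`run_single()` executes the stages in a fixed order, each a pure function
of its inputs:

1. **Channel extraction.** The blue RGB component serves glare detection
   (specular reflections of the light source saturate it); the red
   component maximizes fold/gap brightness contrast and feeds all spectral
   analysis.
2. **Offset reduction.** Consecutive frames are registered by integer
   cross-correlation (FFT-based, linear via zero padding) within a
   ±15 px search window; cumulative offsets are removed by integer
   translation with zero-filled borders. Offsets are integer-valued:
   clinical inter-frame motion is on the order of a dozen pixels, and
   sub-pixel registration would resample the very brightness signals the
   method analyzes.
3. **Maximum-opening frame.** The frame maximizing the count of dark
   pixels (below the 25th intensity percentile of the stack) in the
   central image half is the reference for landmark annotation. Ties take
   the smallest index. A landmark file may override the choice.
4. **Rotation.** The user-marked glottal axis defines an inclination from
   the image vertical (degrees, $(-90, 90]$); frames are rotated about the
   image center with bilinear interpolation and zero fill so the axis
   becomes vertical.
5. **ROI geometry.** Up to 20 nodes marked along the outer fold edges are
   interpolated by a periodic cubic spline with chord-length
   parameterization — the curve passes through every node, matching how
   the nodes are placed on the visible fold edges. The curve is rasterized
   by the even-odd rule on pixel centers and split at the axis column
   (pixels exactly on an integer axis column go left, a fixed tie rule).
6. **Spectral maps and SAI** as above. Normalization uses the maximum over
   ROI pixels rather than the whole frame: out-of-ROI anatomy and glare
   would otherwise set the denominator.
7. **Kymographic cross-check.** A one-row glottal width waveform (GWW) —
   the run length of dark pixels containing the axis column at the ROI
   centroid row — provides an independent $F_0$ estimate by the same
   spectral peak contract. The two routes share no intermediate
   quantities beyond the stabilized stack, so their agreement (within one
   frequency bin on clean scenes) is a genuine cross-method check.

The global $F_0$ itself is the amplitude-weighted mode of the per-pixel
spectral peaks over the ROI, at bin resolution with lowest-frequency tie
breaking. This keeps the estimator deterministic and robust to a minority
of off-frequency pixels.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `band` | 70--400 | Hz | brackets the observed phonation range 90--370 Hz with margin |
| `amp_threshold` | 0.1 | — | clinically validated vibrating cutoff |
| `peak_floor` | 1.0 | intensity units | separates "no harmonic" from a weak harmonic; spectral noise on 8-bit data stays well below it |
| `search_radius` | 15 | px | above the "dozen pixels" of clinical inter-frame motion |
| `window` | none | — | spectra are read at bin resolution; an optional Hann taper is available for off-bin content |
| `dark_quantile` | 0.25 | — | the glottal gap is the darkest structure; a quartile threshold tracks it across exposure levels |
| glare rule | blue ≥ 250 in ≥ 50% of frames | — | conservative reading of the blue channel's role |

## The synthetic scene generator

No clinical recordings ship with the package; `scene_config()` /
`generate_recording()` produce fully specified stand-ins with ground
truth. The reference scene is 128 × 128 px, 480 frames at 2400 fps — 5 Hz
frequency bins and second-scale runtimes. Two mirrored elliptical folds
(semi-axes 22 × 45 px) flank a dark glottal gap of half-width 4.5 px whose
width modulates by ±0.5 px at $F_0$; with this geometry the
integer-quantized kymographic width toggles its medial column at 50% duty,
a square wave whose fundamental (≈1.3 px) is reliably detectable, while
the band of gap-edge pixels swept by the moving edge stays one column per
side. Vibration is brightness modulation
$A \sin(2\pi F_0 t / \mathrm{fps} + \varphi_{\text{fold}})$ over a
*medial band* of each fold — the pixels nearest the axis, where the
mucosal wave lives — covering an exact pixel-count fraction of the fold
area. That fraction is the single knob controlling the expected SAI:
declaring the affected side, $\mathrm{SAI}_{\text{expected}} = 1 -
f_{\text{aff}} / f_{\text{non}}$.

The generator emulates: fold/gap red-channel contrast, blue-channel glare
spots (saturated discs), whole-frame integer jitter as a clipped random
walk (steps and excursion bounded, matching inter-frame offsets of up to a
dozen pixels), axis tilt, and clipped additive Gaussian noise. It does
*not* emulate photorealistic laryngeal texture, aperiodic or chaotic
vibration, mucosal-wave propagation (phase varies between folds but not
within one), non-rigid deformation, or lossy-codec artifacts. Passing
tests therefore establish the correctness of the computational chain under
its stated model, not clinical performance on real tissue.

`generate_cohort()` draws subject-level SAI values from per-group Beta
distributions matched by moments to the reported clinical structure
(normophonic 0.10 ± 0.07, benign 0.16 ± 0.13, malignant 0.65 ± 0.18),
sets the affected fold's vibrating fraction to $1 - \mathrm{SAI}$, and
optionally renders a full recording per subject.

## Numerical choices and degenerate inputs

* All argmax ties resolve to the smallest index (frames, spectral bins,
  histogram modes); the on-axis pixel column joins the left fold. This
  makes every output bit-reproducible.
* Spectral amplitudes are one-sided DFT magnitudes scaled by $2/T$ after
  per-pixel DC removal, so a bin-centered sinusoid of amplitude $A$ reads
  exactly $A$. Phases are `Arg` of the DFT coefficient; only phase
  *differences* between regions are interpreted.
* The amplitude-map maximum is exactly 1 by construction, and the map is
  invariant to uniform brightness rescaling.
* A uniform stack (no opening), an ROI without any detectable harmonic,
  and an all-zero amplitude map raise classed degenerate-input errors
  rather than returning numbers.
* A non-affected fold with zero vibrating pixels makes the SAI ratio
  undefined: the index presumes unilateral disease, and the package raises
  a degeneracy error instead of reporting a value. With
  `affected_side = "auto"` the stiffer side (smaller vibrating fraction)
  is taken as affected, guaranteeing SAI $\in [0, 1]$; a declared side can
  yield a negative value, which is flagged as sign-inverted.
* Mann-Whitney comparisons are two-sided and exact in the small-sample
  regime: `wilcox.test`'s exact path for untied data, full enumeration
  with midranks when ties are present and the pooled size allows it
  (≤ 18), and the tie-corrected normal approximation beyond.

## Design choices where the field leaves room

* **Interpolating, not approximating, contour.** A B-spline with the nodes
  as control points would pass well inside points marked *on* the fold
  edges (for 8 nodes on a circle of radius 50 px the curve would miss by
  ≈5 px). The periodic interpolating cubic runs through the marks. The
  price is that a node perturbation has (exponentially decaying) global
  influence rather than strictly local support.
* **Global $F_0$ from the map itself.** The amplitude-weighted mode makes
  the mapping self-contained; the kymographic GWW estimate is kept as an
  independent verification, mirroring how the method is validated
  clinically, and may be substituted via the `global_f0` argument of
  `build_ltg_maps()`.
* **Frame directories, not video containers.** Analysis operates on
  per-pixel intensities; lossy codecs perturb exactly the quantity under
  study. The package reads lexicographically ordered PNG/TIFF frame
  directories (zero-padded numbering required) and writes the same format.
* **Strict-$F_0$ mask option.** Whether a vibrating pixel must also have
  its own spectral peak at the global $F_0$ is left configurable
  (`strict_f0`, off by default): the amplitude-at-$F_0$-bin criterion
  alone already suppresses off-frequency pixels, whose amplitude at the
  $F_0$ bin is near zero.

## Problem sizes used in validation

The packaged checks run the full pipeline on reference scenes
(128 × 128 × 480) for the graded-asymmetry SAI values (vibrating fractions
1, 0.75, 0.5, 0.25 → SAI 0, 0.25, 0.5, 0.75 within ±0.05), the 280 Hz
$F_0$ identification, threshold semantics at normalized amplitudes 0.08
and 0.12, exact recovery of ≤ 12 px planted jitter, and the
laryngotopography-vs-kymography $F_0$ agreement at 90/150/280/370 Hz.
Unit tests use reduced scenes (96 × 96 × 240 and 64 × 64 × 32) with the
same geometry. Cohort discrimination is assessed on 200 replicate cohorts
of n = (10, 10, 11) drawn from the group model (ground-truth SAI draws;
rendered recordings back a smaller end-to-end recovery check). Under the
group means and SDs above, the malignant-vs-normal and
malignant-vs-benign exact tests are significant in every replicate; the
benign-vs-normal pair — whose population means genuinely differ by 0.06 —
still rejects in ~15% of replicates, which is the expected power of an
exact rank test at these sample sizes, not an implementation artifact.

## Known limitations

* Landmarks (axis endpoints, fold-edge nodes) come from a file; no
  automatic fold-edge detection or glottis segmentation is attempted.
* One stabilization pass with whole-frame integer translations; no
  deformable registration.
* Stationary-spectrum analysis only: a single DFT over the whole
  recording, no time-frequency decomposition, no harmonic-to-noise or
  mucosal-wave-velocity measures.
* The kymographic module is deliberately minimal (dark-run width at one
  row) — sufficient as an $F_0$ cross-check, not a clinical kymography
  replacement.
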