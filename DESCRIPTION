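Package: laryngotopo
Title: Laryngotopographic Analysis of High-Speed Videolaryngoscopy Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Per-pixel spectral mapping ("laryngotopography") of vocal-fold
    vibration in high-speed videolaryngoscopy recordings. Implements the full
    processing chain: frame-directory video I/O, colour-channel extraction,
    inter-frame offset estimation by cross-correlation and integer-shift
    stabilization, maximum-glottic-opening frame selection, rotation to a
    vertical glottal axis, closed B-spline region-of-interest delineation with
    left/right fold splitting, per-pixel Fourier analysis yielding fundamental
    frequency, normalized amplitude and phase maps with a vibrating-pixel
    mask, a simplified glottal-width-waveform (kymographic) fundamental
    frequency cross-check, and the Stiffness Asymmetry Index (SAI) that
    quantifies left/right vibratory asymmetry, together with Mann-Whitney
    group comparisons. A synthetic scene generator produces fully specified
    recordings with ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    mgcv,
    png,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
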