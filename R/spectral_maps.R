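# Per-pixel spectral analysis: brightness functions, Fourier spectra, the
# global fundamental frequency and the laryngotopographic maps (F0,
# normalized amplitude, phase) with the vibrating-pixel mask.
#
# Amplitude convention: the one-sided DFT magnitude scaled by 2/T after
# per-pixel mean (DC) removal, so a unit-amplitude sinusoid at a bin center
# yields amplitude 1 before map normalization. Phase convention: Arg of the
# DFT coefficient at the bin, radians in (-pi, pi] (a pure sine
# A*sin(2*pi*f*t) therefore reads -pi/2 at its bin); only phase
# *differences* between regions are interpreted.

#' Brightness function of one pixel
#'
#' The time series of the fold-contrast channel at a pixel, untransformed,
#' values in 0..255.
#'
#' @param stack a [channel_stack()].
#' @param pixel `c(x, y)` pixel coordinates (column, row).
#' @return Object of class `brightness_signal`: `values`, `fps`, `pixel`.
#' @export
pixel_brightness_series <- function(stack, pixel) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$data)
  x <- pixel[1]; y <- pixel[2]
  if (x < 1 || x > d[2] || y < 1 || y > d[1])
    ltg_input_error("pixel lies outside the image")
  structure(list(values = stack$data[y, x, ], fps = stack$fps,
                 pixel = c(x = x, y = y)),
            class = "brightness_signal")
}

# Shared DFT core: signals in columns of an T x P matrix, mean-removed,
# optional Hann taper (amplitude-corrected). Returns complex T x P matrix
# and the amplitude scale factor per bin.
dft_matrix <- function(M, window = c("none", "hann")) {
  window <- match.arg(window)
  T_ <- nrow(M)
  M <- sweep(M, 2, colMeans(M))
  w <- if (window == "hann") 0.5 * (1 - cos(2 * pi * (seq_len(T_) - 1) / T_))
       else rep(1, T_)
  list(coef = stats::mvfft(M * w), scale = 2 / sum(w))
}

#' Fourier spectrum of a brightness signal
#'
#' DC (mean) is removed, no taper is applied by default; an optional Hann
#' window is available for leakage control. One-sided frequencies
#' `k * fps / T`, `k = 0 .. floor(T/2)`.
#'
#' @param sig a [pixel_brightness_series()] (or any list with `values`,
#'   `fps`).
#' @param window `"none"` (default) or `"hann"`.
#' @return Object of class `pixel_spectrum`: `freqs` (Hz), `amplitudes`,
#'   `phases` (radians in `(-pi, pi]`), `fps`.
#' @export
compute_spectrum <- function(sig, window = c("none", "hann")) {
  v <- sig$values
  T_ <- length(v)
  if (T_ < 16L)
    ltg_input_error("at least 16 samples are required for a spectrum")
  ft <- dft_matrix(matrix(v, ncol = 1), window)
  k <- 0:(T_ %/% 2)
  coef <- ft$coef[k + 1L, 1]
  structure(list(freqs = k * sig$fps / T_,
                 amplitudes = ft$scale * Mod(coef),
                 phases = Arg(coef),
                 fps = sig$fps),
            class = "pixel_spectrum")
}

#' Detect the fundamental-frequency peak of one spectrum
#'
#' Returns the frequency of the maximal amplitude bin within the analysis
#' band, or `NA` when that maximum falls below `peak_floor` -- the "no
#' harmonic at the fundamental frequency" case of non-vibrating tissue.
#' Ties resolve to the lowest frequency.
#'
#' @param spec a [compute_spectrum()] result.
#' @param band `c(f_lo, f_hi)` Hz; default 70--400 Hz covers phonation
#'   fundamentals (observed clinical range 90--370 Hz).
#' @param peak_floor absolute amplitude floor (intensity units, default 1).
#' @return Peak frequency in Hz, or `NA_real_`.
#' @export
detect_pixel_f0 <- function(spec, band = c(70, 400), peak_floor = 1.0) {
  if (length(band) != 2L || band[2] <= band[1])
    ltg_config_error("band must be c(f_lo, f_hi) with f_lo < f_hi")
  sel <- which(spec$freqs >= band[1] & spec$freqs <= band[2] & spec$freqs > 0)
  if (length(sel) == 0L)
    ltg_config_error("no spectral bins fall inside the band")
  k <- sel[which.max(spec$amplitudes[sel])]
  if (spec$amplitudes[k] < peak_floor) return(NA_real_)
  spec$freqs[k]
}

# Internal: brightness series of all mask pixels as a T x P matrix, plus
# the (y, x) index of each column.
stack_matrix <- function(stack, mask) {
  d <- dim(stack$data)
  idx <- which(mask)
  T_ <- d[3]
  M <- matrix(stack$data, d[1] * d[2], T_)[idx, , drop = FALSE]
  list(M = t(M), idx = idx)
}

# Internal: per-pixel spectral summary over a mask. Returns band-peak
# frequency/amplitude per pixel and the complex coefficient at a given bin.
roi_spectra <- function(stack, mask, band, window) {
  sm <- stack_matrix(stack, mask)
  T_ <- nrow(sm$M)
  if (T_ < 16L) ltg_input_error("at least 16 frames are required")
  ft <- dft_matrix(sm$M, window)
  freqs <- (0:(T_ %/% 2)) * stack$fps / T_
  bins <- which(freqs >= band[1] & freqs <= band[2] & freqs > 0)
  if (length(bins) == 0L) ltg_config_error("no spectral bins inside band")
  A <- ft$scale * Mod(ft$coef[bins, , drop = FALSE])
  pk <- max.col(t(A), ties.method = "first")  # ties -> lowest frequency
  list(idx = sm$idx, freqs = freqs, bins = bins, coef = ft$coef,
       scale = ft$scale,
       peak_freq = freqs[bins][pk],
       peak_amp = A[cbind(pk, seq_along(pk))])
}

#' Estimate the global fundamental frequency over the ROI
#'
#' Each ROI pixel votes for its own detected spectral peak with a weight
#' equal to the peak amplitude; the global F0 is the amplitude-weighted mode
#' of these votes at frequency-bin resolution. Pixels whose peak falls below
#' `peak_floor` abstain. Deterministic: ties resolve to the lowest
#' frequency.
#'
#' @param stack `fold_contrast` [channel_stack()] (stabilized, rotated).
#' @param roi a [fold_roi()] (or logical mask).
#' @param band analysis band in Hz.
#' @param peak_floor amplitude floor below which a pixel abstains.
#' @param window taper passed to the DFT (default none).
#' @return Global F0 in Hz.
#' @export
estimate_global_f0 <- function(stack, roi, band = c(70, 400),
                               peak_floor = 1.0,
                               window = c("none", "hann")) {
  mask <- if (inherits(roi, "fold_roi")) roi$roi_mask else roi
  if (!any(mask)) ltg_input_error("empty ROI")
  rs <- roi_spectra(stack, mask, band, match.arg(window))
  keep <- rs$peak_amp >= peak_floor
  if (!any(keep))
    ltg_degenerate_error("no ROI pixel shows a detectable harmonic peak")
  wsum <- tapply(rs$peak_amp[keep], rs$peak_freq[keep], sum)
  f <- as.numeric(names(wsum))
  f[order(-wsum, f)][1]
}

#' Build the laryngotopographic maps
#'
#' For every ROI pixel the amplitude and phase of the DFT bin nearest the
#' global F0 are read; amplitudes are normalized by their maximum over the
#' analyzed (non-glare) pixels, so the map maximum is exactly 1. A pixel is
#' "vibrating" when its normalized amplitude reaches `amp_threshold` and it
#' is not glare-flagged (optionally also when its own peak frequency matches
#' the global F0 within one bin, `strict_f0 = TRUE`). The per-pixel F0 map
#' stores each pixel's own detected peak.
#'
#' @param stack `fold_contrast` [channel_stack()].
#' @param roi a [fold_roi()] or logical mask.
#' @param global_f0 global fundamental frequency (Hz), from
#'   [estimate_global_f0()] or kymographic analysis.
#' @param amp_threshold normalized-amplitude cutoff in (0, 1); default 0.1,
#'   the clinically validated value separating clear harmonic oscillation
#'   from spectral noise.
#' @param band per-pixel F0 search band (Hz).
#' @param peak_floor absolute amplitude floor for the per-pixel F0 map.
#' @param glare logical matrix of glare-flagged pixels ([glare_mask()]), or
#'   `NULL`.
#' @param window DFT taper.
#' @param strict_f0 additionally require the pixel's own peak to lie within
#'   one bin of `global_f0` for vibrating-mask membership.
#' @return Object of class `ltg_maps`: `f0_map`, `amp_map`, `phase_map`
#'   (`H x W`, `NA` outside the ROI), `vibrating_mask` (logical),
#'   `global_f0`, `amp_threshold`, `bin_width_hz`, `fps`.
#' @export
build_ltg_maps <- function(stack, roi, global_f0, amp_threshold = 0.1,
                           band = c(70, 400), peak_floor = 1.0,
                           glare = NULL, window = c("none", "hann"),
                           strict_f0 = FALSE) {
  if (amp_threshold <= 0 || amp_threshold >= 1)
    ltg_config_error("amp_threshold must lie in (0, 1)")
  mask <- if (inherits(roi, "fold_roi")) roi$roi_mask else roi
  if (!any(mask)) ltg_input_error("empty ROI")
  d <- dim(stack$data)
  T_ <- d[3]
  rs <- roi_spectra(stack, mask, band, match.arg(window))
  kbin <- round(global_f0 * T_ / stack$fps)  # nearest bin, no interpolation
  if (kbin < 1 || kbin > T_ %/% 2)
    ltg_config_error("global_f0 falls outside the spectrum")
  coef_f0 <- rs$coef[kbin + 1L, ]
  amp_raw <- rs$scale * Mod(coef_f0)
  phase <- Arg(coef_f0)

  glare_v <- if (is.null(glare)) rep(FALSE, length(rs$idx))
             else glare[rs$idx]
  analyzed <- !glare_v
  amax <- if (any(analyzed)) max(amp_raw[analyzed]) else 0
  if (amax == 0)
    ltg_degenerate_error("all amplitudes at the F0 bin are zero")
  amp_norm <- amp_raw / amax

  vib <- amp_norm >= amp_threshold & !glare_v
  if (strict_f0) {
    bw <- stack$fps / T_
    vib <- vib & !is.na(rs$peak_freq) &
      abs(rs$peak_freq - global_f0) <= bw + 1e-9
  }

  grid <- function(values, default = NA_real_) {
    m <- matrix(default, d[1], d[2])
    m[rs$idx] <- values
    m
  }
  f0_pix <- ifelse(rs$peak_amp >= peak_floor, rs$peak_freq, NA_real_)
  vib_m <- grid(vib, default = FALSE)
  storage.mode(vib_m) <- "logical"
  structure(list(f0_map = grid(f0_pix), amp_map = grid(amp_norm),
                 phase_map = grid(phase), vibrating_mask = vib_m,
                 global_f0 = global_f0, amp_threshold = amp_threshold,
                 bin_width_hz = stack$fps / T_, fps = stack$fps),
            class = "ltg_maps")
}

#' @export
print.ltg_maps <- function(x, ...) {
  n_roi <- sum(!is.na(x$amp_map))
  cat(sprintf(
    "<ltg_maps> global F0 = %.1f Hz (bin %.2f Hz), %d ROI px, %d vibrating (threshold %.2f)\n",
    x$global_f0, x$bin_width_hz, n_roi, sum(x$vibrating_mask),
    x$amp_threshold))
  invisible(x)
}
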