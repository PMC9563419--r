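# Simplified kymographic analysis: glottal width waveform (GWW) at one
# cross-section row and its spectral F0. This is the independent
# cross-check route for the laryngotopographic global F0: the two
# estimators share no intermediate quantities beyond the stabilized stack.

#' Extract the glottal width waveform
#'
#' At the chosen cross-section row, the glottal width per frame is the run
#' length of contiguous "dark" pixels (intensity below the stack's
#' `dark_quantile` quantile) containing the glottal-axis column -- the open
#' gap between the two folds. A closed glottis yields width 0.
#' `row = "mid-axis"` picks the row of the ROI centroid.
#'
#' @param stack stabilized, rotated `fold_contrast` [channel_stack()].
#' @param roi a [fold_roi()].
#' @param row cross-section row (integer) or `"mid-axis"`.
#' @param dark_quantile stack intensity quantile defining "dark"
#'   (default 0.25).
#' @return Object of class `gww`: `widths` (length T, pixels), `row`,
#'   `fps`.
#' @export
extract_gww <- function(stack, roi, row = "mid-axis", dark_quantile = 0.25) {
  stopifnot(inherits(stack, "channel_stack"), inherits(roi, "fold_roi"))
  d <- dim(stack$data)
  if (identical(row, "mid-axis")) {
    rows_in <- which(roi$roi_mask, arr.ind = TRUE)[, 1]
    row <- round(mean(rows_in))
  }
  row <- as.integer(row)
  if (row < 1L || row > d[1] || !any(roi$roi_mask[row, ]))
    ltg_input_error("cross-section row does not intersect the ROI")
  thr <- stats::quantile(stack$data, dark_quantile, names = FALSE)
  c0 <- as.integer(round(roi$axis_x))
  w <- d[2]
  widths <- numeric(d[3])
  for (t in seq_len(d[3])) {
    dark <- stack$data[row, , t] < thr
    if (!dark[c0]) { widths[t] <- 0; next }
    l <- c0
    while (l > 1L && dark[l - 1L]) l <- l - 1L
    r <- c0
    while (r < w && dark[r + 1L]) r <- r + 1L
    widths[t] <- r - l + 1L
  }
  structure(list(widths = widths, row = row, fps = stack$fps),
            class = "gww")
}

#' @export
print.gww <- function(x, ...) {
  cat(sprintf("<gww> row %d, %d frames, width range %g-%g px\n",
              x$row, length(x$widths), min(x$widths), max(x$widths)))
  invisible(x)
}

#' Fundamental frequency from a glottal width waveform
#'
#' Same estimator contract as [detect_pixel_f0()]: DC-removed spectral peak
#' of the width series within the band, `NA` when no peak reaches the
#' floor.
#'
#' @param gww a [extract_gww()] result.
#' @param band analysis band, Hz.
#' @param peak_floor amplitude floor (pixels of width oscillation,
#'   default 1).
#' @param window DFT taper.
#' @return F0 in Hz, or `NA_real_`.
#' @export
f0_from_gww <- function(gww, band = c(70, 400), peak_floor = 1.0,
                        window = c("none", "hann")) {
  if (length(gww$widths) < 16L)
    ltg_input_error("at least 16 samples are required")
  spec <- compute_spectrum(list(values = gww$widths, fps = gww$fps),
                           window = match.arg(window))
  detect_pixel_f0(spec, band = band, peak_floor = peak_floor)
}

#' Export a GWW as CSV
#'
#' @param gww a [extract_gww()] result.
#' @param file output path; columns `frame,width`.
#' @return `file`, invisibly.
#' @export
write_gww_csv <- function(gww, file) {
  utils::write.csv(data.frame(frame = seq_along(gww$widths),
                              width = gww$widths),
                   file, row.names = FALSE)
  invisible(file)
}
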