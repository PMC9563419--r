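# Small synthetic channel stacks with known spectral content.
sine_stack <- function(h, w, T_, fps, amp, f, phase = 0, base = 100,
                       mask = NULL) {
  t <- seq_len(T_) - 1
  data <- array(base, c(h, w, T_))
  if (is.null(mask)) mask <- matrix(TRUE, h, w)
  s <- amp * sin(2 * pi * f * t / fps + phase)
  for (k in which(mask)) data[k + (t) * h * w] <- base + s
  channel_stack(data, "fold_contrast", fps)
}

test_that("brightness series reproduces the generator's closed form", {
  g <- tiny_sym()$g
  red <- extract_channel(g$recording, "fold_contrast")
  px <- which(g$truth$vib_left, arr.ind = TRUE)[1, ]
  sig <- pixel_brightness_series(red, c(px[2], px[1]))
  t <- seq_len(32) - 1
  want <- 170 + 50 * sin(2 * pi * 150 * t / 2400)
  expect_lt(max(abs(sig$values - want)), 0.51)  # rounding only
  expect_length(sig$values, 32)

  const <- channel_stack(array(100, c(4, 4, 20)), "fold_contrast", 2400)
  expect_equal(pixel_brightness_series(const, c(2, 3))$values, rep(100, 20))
  expect_error(pixel_brightness_series(const, c(9, 1)),
               class = "ltg_input_error")
})

test_that("spectrum of a bin-centered sinusoid peaks at its amplitude", {
  t <- seq_len(480) - 1
  sig <- list(values = 120 + 50 * sin(2 * pi * 280 * t / 2400), fps = 2400)
  spec <- compute_spectrum(sig)
  k <- which.max(spec$amplitudes)
  expect_equal(spec$freqs[k], 280)
  expect_equal(spec$amplitudes[k], 50, tolerance = 1e-9)
  expect_equal(spec$freqs[2] - spec$freqs[1], 5)  # bin width fps/T

  flat <- compute_spectrum(list(values = rep(42, 64), fps = 2400))
  expect_lt(max(flat$amplitudes), 1e-9)

  expect_error(compute_spectrum(list(values = rep(1, 8), fps = 2400)),
               class = "ltg_input_error")
})

test_that("spectrum matches a direct DFT-summation oracle", {
  t <- seq_len(96) - 1
  v <- 7 * sin(2 * pi * 250 * t / 2400) + 3 * cos(2 * pi * 500 * t / 2400)
  spec <- compute_spectrum(list(values = v, fps = 2400))
  want <- dft_sum_oracle(v, 2400)
  expect_equal(spec$freqs, want$freqs)
  expect_equal(spec$amplitudes, want$amplitudes, tolerance = 1e-9)
  # phases are only meaningful where the coefficient is non-negligible
  sig_bins <- want$amplitudes > 1e-6
  expect_equal(spec$phases[sig_bins], want$phases[sig_bins],
               tolerance = 1e-9)
  # two planted components recovered with their coefficients
  expect_equal(spec$amplitudes[spec$freqs == 250], 7, tolerance = 1e-6)
  expect_equal(spec$amplitudes[spec$freqs == 500], 3, tolerance = 1e-6)
})

test_that("total spectral power equals time-domain variance (Parseval)", {
  set.seed(3)
  v <- rnorm(33, 100, 20)  # odd length: no Nyquist bin subtlety
  spec <- compute_spectrum(list(values = v, fps = 2400))
  power <- sum(spec$amplitudes^2) / 2
  expect_equal(power, mean((v - mean(v))^2), tolerance = 1e-6)
})

test_that("per-pixel F0 detection scans the band with an amplitude floor", {
  t <- seq_len(480) - 1
  mk <- function(v) compute_spectrum(list(values = v, fps = 2400))
  expect_equal(detect_pixel_f0(mk(100 + 50 * sin(2 * pi * 280 * t / 2400))),
               280)
  expect_true(is.na(detect_pixel_f0(mk(rep(100, 480)))))
  two <- 100 + 40 * sin(2 * pi * 150 * t / 2400) +
    4 * sin(2 * pi * 300 * t / 2400)
  expect_equal(detect_pixel_f0(mk(two)), 150)
  # exhaustive scan oracle over the band
  spec <- mk(two)
  sel <- spec$freqs >= 70 & spec$freqs <= 400
  expect_equal(detect_pixel_f0(spec),
               spec$freqs[sel][which.max(spec$amplitudes[sel])])
  expect_error(detect_pixel_f0(spec, band = c(400, 70)),
               class = "ltg_config_error")
})

test_that("global F0 is the amplitude-weighted mode of pixel peaks", {
  # half the pixels strong at 150 Hz, half weak at 300 Hz
  h <- 6; w <- 6; T_ <- 240
  m1 <- matrix(FALSE, h, w); m1[, 1:3] <- TRUE
  stack <- sine_stack(h, w, T_, 2400, 50, 150, mask = m1)
  t <- seq_len(T_) - 1
  weak <- 100 + 5 * sin(2 * pi * 300 * t / 2400)
  for (k in which(!m1)) stack$data[k + t * h * w] <- weak
  roi <- matrix(TRUE, h, w)
  expect_equal(estimate_global_f0(stack, roi), 150)

  # weighted-histogram oracle from per-pixel spectra
  votes <- sapply(seq_len(h * w), function(k) {
    spec <- compute_spectrum(pixel_brightness_series(
      stack, c((k - 1) %/% h + 1, (k - 1) %% h + 1)))
    sel <- spec$freqs >= 70 & spec$freqs <= 400
    i <- which.max(spec$amplitudes[sel])
    c(spec$freqs[sel][i], spec$amplitudes[sel][i])
  })
  wsum <- tapply(votes[2, ], votes[1, ], sum)
  expect_equal(estimate_global_f0(stack, roi),
               as.numeric(names(wsum)[which.max(wsum)]))

  const <- channel_stack(array(100, c(4, 4, 64)), "fold_contrast", 2400)
  expect_error(estimate_global_f0(const, matrix(TRUE, 4, 4)),
               class = "ltg_degenerate_error")
})

test_that("amplitude maps are max-normalized and scale-invariant", {
  g <- quick_asym()
  maps <- g$run$maps
  expect_equal(max(maps$amp_map, na.rm = TRUE), 1)
  expect_true(all(maps$amp_map >= 0 & maps$amp_map <= 1, na.rm = TRUE))
  expect_true(all(maps$phase_map > -pi & maps$phase_map <= pi + 1e-12,
                  na.rm = TRUE))
  # vibrating mask is exactly the thresholded amplitude map (no glare here)
  expect_equal(maps$vibrating_mask,
               !is.na(maps$amp_map) & maps$amp_map >= maps$amp_threshold)

  # uniform brightness rescaling leaves the normalized map unchanged
  red <- extract_channel(g$g$recording, "fold_contrast")
  half <- channel_stack(red$data * 0.5, red$channel_role, red$fps)
  roi <- g$run$roi
  m1 <- build_ltg_maps(red, roi, g$run$global_f0)
  m2 <- build_ltg_maps(half, roi, g$run$global_f0)
  expect_equal(m1$amp_map, m2$amp_map, tolerance = 1e-12)
})

test_that("threshold semantics: normalized amplitude 0.08 excluded, 0.12 included", {
  h <- 8; w <- 8; T_ <- 240
  strong <- matrix(FALSE, h, w); strong[, 1:4] <- TRUE
  stack <- sine_stack(h, w, T_, 2400, 50, 150, mask = strong)
  t <- seq_len(T_) - 1
  for (k in which(!strong))
    stack$data[k + t * h * w] <- 100 + 4 * sin(2 * pi * 150 * t / 2400)
  roi <- matrix(TRUE, h, w)
  maps <- build_ltg_maps(stack, roi, 150, amp_threshold = 0.1)
  expect_equal(unique(round(maps$amp_map[!strong], 6)), 0.08)
  expect_false(any(maps$vibrating_mask[!strong]))
  expect_true(all(maps$vibrating_mask[strong]))

  for (k in which(!strong))
    stack$data[k + t * h * w] <- 100 + 6 * sin(2 * pi * 150 * t / 2400)
  maps12 <- build_ltg_maps(stack, roi, 150, amp_threshold = 0.1)
  expect_equal(unique(round(maps12$amp_map[!strong], 6)), 0.12)
  expect_true(all(maps12$vibrating_mask))
})

test_that("phase map separates regions by their planted phase offset", {
  h <- 8; w <- 8; T_ <- 240
  left <- matrix(FALSE, h, w); left[, 1:4] <- TRUE
  stack <- sine_stack(h, w, T_, 2400, 50, 150, phase = 0, mask = left)
  t <- seq_len(T_) - 1
  for (k in which(!left))
    stack$data[k + t * h * w] <- 100 + 50 * sin(2 * pi * 150 * t / 2400 + pi / 2)
  maps <- build_ltg_maps(stack, matrix(TRUE, h, w), 150)
  dphi <- maps$phase_map[1, 8] - maps$phase_map[1, 1]
  expect_equal(dphi, pi / 2, tolerance = 1e-9)
})

test_that("per-pixel F0 map and the strict-F0 mask option behave as documented", {
  h <- 8; w <- 8; T_ <- 240
  left <- matrix(FALSE, h, w); left[, 1:4] <- TRUE
  stack <- sine_stack(h, w, T_, 2400, 50, 150, mask = left)
  t <- seq_len(T_) - 1
  for (k in which(!left))  # off-F0 region at 90 Hz, same amplitude
    stack$data[k + t * h * w] <- 100 + 50 * sin(2 * pi * 90 * t / 2400)
  roi <- matrix(TRUE, h, w)
  maps <- build_ltg_maps(stack, roi, 150)
  expect_true(all(maps$f0_map[left] == 150))
  expect_true(all(maps$f0_map[!left] == 90))
  # at the 150 Hz bin the 90 Hz region has ~zero amplitude -> not vibrating
  expect_false(any(maps$vibrating_mask[!left]))
  strict <- build_ltg_maps(stack, roi, 150, strict_f0 = TRUE)
  expect_true(all(strict$vibrating_mask[left]))
  expect_false(any(strict$vibrating_mask[!left]))

  # glare-flagged pixels are excluded from mask and normalization
  glare <- matrix(FALSE, h, w); glare[1:2, 1] <- TRUE
  mg <- build_ltg_maps(stack, roi, 150, glare = glare)
  expect_false(any(mg$vibrating_mask[glare]))

  expect_error(build_ltg_maps(stack, roi, 150, amp_threshold = 1.2),
               class = "ltg_config_error")
})
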