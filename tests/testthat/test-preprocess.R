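rgb_frame <- function(r, g, b, h = 8, w = 8) {
  f <- array(0, c(h, w, 3))
  f[, , 1] <- r; f[, , 2] <- g; f[, , 3] <- b
  f
}

test_that("channel extraction maps roles to RGB components", {
  rec <- hsv_recording(list(rgb_frame(255, 0, 0), rgb_frame(255, 0, 0)), 2400)
  expect_true(all(extract_channel(rec, "fold_contrast")$data == 255))
  expect_true(all(extract_channel(rec, "glare_reduction")$data == 0))
  expect_error(extract_channel(rec, "saturation"),
               class = "ltg_config_error")
})

test_that("saturated glare spots are flagged and excluded from analysis", {
  g <- generate_recording(tiny_scene(glare = list(c(20, 32, 3))))
  blue <- extract_channel(g$recording, "glare_reduction")
  gm <- glare_mask(blue)
  expect_true(gm[32, 20])                    # spot center
  expect_setequal(which(gm), g$truth$glare_idx)
  # glare pixels never enter the vibrating mask
  r <- run_scene(g)
  expect_equal(sum(r$maps$vibrating_mask & r$glare), 0)
})

test_that("planted integer shifts are recovered as cumulative offsets", {
  base <- generate_recording(tiny_scene())$recording$frames[[1]][, , 1]
  mk <- function(...) channel_stack(simplify2array(list(...)),
                                    "fold_contrast", 2400)
  sh <- function(dx, dy) laryngotopo:::shift_image(base, dx, dy)

  off <- estimate_offsets(mk(base, sh(3, -2)), 15)
  expect_equal(off$dx, c(0, 3))
  expect_equal(off$dy, c(0, -2))

  off <- estimate_offsets(mk(base, base, base), 15)
  expect_true(all(off$dx == 0 & off$dy == 0))

  # consecutive shifts (2,1) then (-1,0): cumulative (0,0),(2,1),(1,1)
  stack <- mk(base, sh(2, 1), sh(1, 1))
  off <- estimate_offsets(stack, 6)
  expect_equal(off$dx, c(0, 2, 1))
  expect_equal(off$dy, c(0, 1, 1))
  # every pairwise estimate matches the brute-force correlation oracle
  for (t in 2:3) {
    expect_equal(unname(laryngotopo:::xcorr_shift(
      stack$data[, , t - 1], stack$data[, , t], 6)),
      brute_shift(stack$data[, , t - 1], stack$data[, , t], 6))
  }

  expect_error(estimate_offsets(mk(base, base), search_radius = 40),
               class = "ltg_config_error")
})

test_that("offset recovery tolerates additive noise within one pixel", {
  set.seed(42)
  base <- generate_recording(tiny_scene())$recording$frames[[1]][, , 1]
  noisy <- function(m) pmin(pmax(m + rnorm(length(m), 0, 10), 0), 255)
  stack <- channel_stack(
    simplify2array(list(noisy(base),
                        noisy(laryngotopo:::shift_image(base, 4, -3)))),
    "fold_contrast", 2400)
  off <- estimate_offsets(stack, 10)
  expect_lte(abs(off$dx[2] - 4), 1)
  expect_lte(abs(off$dy[2] - (-3)), 1)
})

test_that("stabilization is the identity for zero offsets and a fixed point otherwise", {
  g <- generate_recording(tiny_scene(jitter_max = 5, seed = 9))
  red <- extract_channel(g$recording, "fold_contrast")
  off <- estimate_offsets(red)
  rec_st <- stabilize(g$recording, off)
  # re-estimating on the stabilized recording yields all-zero offsets
  off2 <- estimate_offsets(extract_channel(rec_st, "fold_contrast"))
  expect_true(all(off2$dx == 0 & off2$dy == 0))

  zero <- off; zero$dx[] <- 0L; zero$dy[] <- 0L
  expect_identical(stabilize(g$recording, zero)$frames, g$recording$frames)

  # translated pair becomes identical on the overlap
  a <- g$recording$frames[[1]][, , 1]
  b <- laryngotopo:::shift_image(a, 3, 2)
  st <- stabilize(channel_stack(simplify2array(list(a, b)),
                                "fold_contrast", 2400),
                  estimate_offsets(channel_stack(
                    simplify2array(list(a, b)), "fold_contrast", 2400)))
  expect_equal(st$data[10:50, 10:50, 2], a[10:50, 10:50])
})

test_that("maximum-opening frame is the dark-pixel-count argmax with smallest-index ties", {
  g <- generate_recording(quick_scene(gap_halfwidth = 3, gap_mod = 3))
  red <- extract_channel(g$recording, "fold_contrast")
  idx <- select_max_opening_frame(red)
  # oracle: dark columns are the half-integer offsets inside the gap, so
  # the opening area argmax is that of the rasterized column count
  cols <- vapply(g$truth$gap_halfwidth_series,
                 function(gw) 2 * sum((0:9 + 0.5) < gw), 0)
  expect_equal(idx, which.max(cols))  # which.max takes the smallest index

  # monotone closing gap: widest dark block in frame 1
  mk_dark <- function(wd) {
    m <- matrix(200, 20, 20)
    if (wd > 0) m[6:15, 10:(9 + wd)] <- 0
    m
  }
  stack <- channel_stack(simplify2array(lapply(c(5, 3, 1), mk_dark)),
                         "fold_contrast", 2400)
  expect_equal(select_max_opening_frame(stack), 1)

  # two equal maxima: smaller index wins
  stack2 <- channel_stack(simplify2array(lapply(c(3, 5, 5), mk_dark)),
                          "fold_contrast", 2400)
  expect_equal(select_max_opening_frame(stack2), 2)

  uniform <- channel_stack(array(100, c(20, 20, 3)), "fold_contrast", 2400)
  expect_error(select_max_opening_frame(uniform),
               class = "ltg_degenerate_error")
})

test_that("glottal axis angle is the inclination from vertical in (-90, 90]", {
  expect_equal(glottal_axis(c(10, 10), c(10, 40))$angle, 0)
  expect_equal(glottal_axis(c(10, 10), c(40, 40))$angle, 45)
  expect_equal(glottal_axis(c(10, 10), c(40, 10))$angle, 90)
  # direction-independent up to the (-90, 90] normalization
  expect_equal(glottal_axis(c(40, 40), c(10, 10))$angle, 45)
  expect_error(glottal_axis(c(5, 5), c(5, 5)), class = "ltg_input_error")
})

test_that("rotation to vertical aligns the axis and is invertible", {
  g <- generate_recording(tiny_scene())
  rec <- g$recording

  # already vertical: identity
  ax0 <- glottal_axis(c(32.5, 10), c(32.5, 50))
  out0 <- rotate_to_vertical(rec, ax0)
  expect_identical(out0$recording$frames, rec$frames)
  expect_equal(out0$axis$angle, 0)

  # 45 degrees: returned axis vertical, old endpoints land on one column
  ax <- glottal_axis(c(22, 22), c(42, 42))
  out <- rotate_to_vertical(rec, ax)
  expect_lt(abs(out$axis$angle), 1e-6)
  expect_lt(abs(out$axis$a[1] - out$axis$b[1]), 0.5)
  # analytic check: transform_point matches the rotation matrix
  th <- 45 * pi / 180
  c0 <- c((64 + 1) / 2, (64 + 1) / 2)
  p <- c(22, 22) - c0
  expect_equal(out$transform_point(rbind(c(22, 22)))[1, ],
               c(cos(th) * p[1] - sin(th) * p[2],
                 sin(th) * p[1] + cos(th) * p[2]) + c0)

  # rotate by angle then back: a smooth image is recovered within
  # interpolation blur on the interior
  f <- 127 + 120 * outer(sin(seq(0, 3, length.out = 64)),
                         cos(seq(0, 2, length.out = 64)))
  back <- laryngotopo:::rotate_image(laryngotopo:::rotate_image(f, 17), -17)
  interior <- 16:48
  expect_lt(mean(abs(back[interior, interior] - f[interior, interior])), 2)

  expect_error(rotate_to_vertical(rec, glottal_axis(c(500, 5), c(10, 50))),
               class = "ltg_input_error")
})

test_that("landmark files round-trip through JSON and YAML", {
  lm <- list(axis = rbind(c(32.5, 10), c(34.5, 50)),
             reference_frame = 17,
             nodes = cbind(x = c(10, 20, 30, 20), y = c(20, 10, 20, 30)))
  f <- withr::local_tempfile(fileext = ".json")
  write_landmarks(lm, f)
  got <- read_landmarks(f)
  expect_s3_class(got$axis, "glottal_axis")
  expect_equal(got$axis$a, c(32.5, 10))
  expect_equal(got$reference_frame, 17L)
  expect_equal(unname(got$nodes), unname(lm$nodes))

  fy <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(axis = list(c(1, 2), c(3, 40)),
                        reference_frame = "auto",
                        nodes = list(c(1, 1), c(5, 1), c(5, 5), c(1, 5))), fy)
  goty <- read_landmarks(fy)
  expect_true(is.na(goty$reference_frame))
  expect_equal(nrow(goty$nodes), 4)

  expect_error(read_landmarks(withr::local_tempfile(fileext = ".json")),
               class = "ltg_config_error")
})
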