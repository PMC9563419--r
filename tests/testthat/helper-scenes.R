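# Shared synthetic fixtures. Two reduced scene scales keep the unit tests
# fast; the acceptance tests use the full reference scene. Expensive scenes
# and pipeline runs are cached per session.

# 96 x 96, 240 frames @ 2400 fps: 10 Hz bins, 150 = 15 bins.
quick_scene <- function(...) {
  scene_config(shape = c(96, 96), n_frames = 240,
               fold_rx = 16, fold_ry = 32, ...)
}

# 64 x 64, 32 frames @ 2400 fps: 75 Hz bins, 150 = 2 bins.
tiny_scene <- function(...) {
  scene_config(shape = c(64, 64), n_frames = 32,
               fold_rx = 10, fold_ry = 20, ...)
}

run_scene <- function(g, ...) {
  suppressMessages(run_single(run_config(g$recording, g$landmarks, ...)))
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A quick asymmetric scene (right fold 25% vibrating) and its pipeline run.
quick_asym <- function() cached("quick_asym", {
  g <- generate_recording(quick_scene(vib_frac = c(left = 1, right = 0.25)))
  list(g = g, run = run_scene(g, affected_side = "right"))
})

# A tiny symmetric scene and its run (cheap maps for I/O tests).
tiny_sym <- function() cached("tiny_sym", {
  g <- generate_recording(tiny_scene())
  list(g = g, run = run_scene(g))
})

# Brute-force pairwise shift oracle: maximize the plain correlation of the
# mean-removed frames over all integer shifts in the window (independent of
# the FFT path it checks).
brute_shift <- function(a, b, r) {
  best <- c(0, 0); bv <- -Inf
  am <- a - mean(a)
  for (dy in -r:r) for (dx in -r:r) {
    bs <- laryngotopo:::shift_image(b - mean(b), -dx, -dy)
    v <- sum(am * bs)
    if (v > bv) { bv <- v; best <- c(dx, dy) }
  }
  best
}

# Even-odd point-in-polygon oracle (ray casting), independent of mgcv.
pip_even_odd <- function(poly, px, py) {
  n <- nrow(poly) - 1  # closed polygon
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    j <- i
  }
  inside
}

# Direct DFT-by-summation oracle for a single signal (no fft()).
dft_sum_oracle <- function(v, fps) {
  T_ <- length(v)
  v <- v - mean(v)
  k <- 0:(T_ %/% 2)
  coef <- vapply(k, function(kk)
    sum(v * exp(-2i * pi * kk * (seq_len(T_) - 1) / T_)), complex(1))
  list(freqs = k * fps / T_, amplitudes = 2 * Mod(coef) / T_,
       phases = Arg(coef))
}

# Exhaustive Mann-Whitney oracle: enumerate every assignment of the pooled
# observations to group 1, compute U from midranks, two-sided tail doubling.
mw_enum_oracle <- function(x, y) {
  m <- length(x); n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[1:m]) - m * (m + 1) / 2
  us <- apply(utils::combn(m + n, m), 2,
              function(ix) sum(r[ix]) - m * (m + 1) / 2)
  min(1, 2 * min(mean(us <= u_obs + 1e-9), mean(us >= u_obs - 1e-9)))
}

# Direct evaluation of the SAI definition from the four counts.
sai_oracle <- function(AVF, AVF_F0, NAVF, NAVF_F0) {
  1 - (AVF_F0 / AVF) / (NAVF_F0 / NAVF)
}
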