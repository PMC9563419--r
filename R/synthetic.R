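# Synthetic high-speed recordings with known ground truth. The scene
# emulates the observables the method analyzes: two fold-shaped regions
# flanking a dark glottal gap, per-pixel sinusoidal brightness modulation at
# a common F0 inside designated vibrating sub-regions, a gap whose width
# modulates at the same F0 (so kymography sees a signal), optional static
# glare spots, whole-frame translation jitter, axis tilt and additive
# Gaussian noise. Vibration is modelled as brightness modulation -- the
# quantity the method observes -- not as biomechanical displacement.

#' Synthetic scene configuration
#'
#' Defaults define the reference desk-scale scene: 128 x 128 px, 480 frames
#' at 2400 fps (5 Hz frequency bins), F0 = 150 Hz, elliptical folds of
#' semi-axes 22 x 45 px flanking a glottal gap of half-width 4.5 px
#' modulated by +/- 0.5 px (so the integer-quantized kymographic width
#' toggles at 50% duty, a detectable square wave at F0),
#' red-channel baselines 170 (fold) / 20 (gap) / 90
#' (surrounding tissue), modulation amplitude 50 intensity units. The
#' vibrating sub-region of each fold is the medial band (pixels nearest the
#' glottal axis, where the mucosal wave lives) covering `vib_frac` of the
#' fold's area; this fraction is the single knob controlling the expected
#' SAI.
#'
#' @param shape `c(H, W)` in pixels.
#' @param fps frame rate (Hz).
#' @param n_frames number of frames T.
#' @param f0 common fundamental frequency (Hz), must be below Nyquist.
#' @param vib_frac `c(left =, right =)` vibrating fraction of each fold's
#'   area, in `[0, 1]`.
#' @param amplitude `c(left =, right =)` modulation amplitude (intensity
#'   units).
#' @param phase `c(left =, right =)` modulation phase offset (radians).
#' @param axis_angle glottal-axis tilt from vertical (degrees).
#' @param fold_rx,fold_ry fold ellipse semi-axes (px).
#' @param gap_halfwidth mean glottal gap half-width (px).
#' @param gap_mod gap half-width modulation amplitude (px) at `f0`.
#' @param baseline_fold,baseline_gap,background red-channel baselines.
#' @param glare list of `c(x, y, radius)` saturated glare spots.
#' @param jitter `T x 2` integer matrix of per-frame `(dx, dy)` translations
#'   (first row must be `(0, 0)`), or `NULL`.
#' @param jitter_max if `jitter` is `NULL` and this is positive, draw an
#'   integer random-walk jitter: per-frame steps uniform in
#'   `[-jitter_max, jitter_max]`, positions clipped to the same range
#'   (frame 1 fixed at zero) -- camera drift with bounded inter-frame
#'   offsets, the motion regime the stabilizer is built for.
#' @param noise_sd additive Gaussian noise SD (intensity units).
#' @param seed RNG seed for jitter and noise.
#' @return Object of class `scene_config`.
#' @export
scene_config <- function(shape = c(128, 128), fps = 2400, n_frames = 480,
                         f0 = 150,
                         vib_frac = c(left = 1, right = 1),
                         amplitude = c(left = 50, right = 50),
                         phase = c(left = 0, right = 0),
                         axis_angle = 0,
                         fold_rx = 22, fold_ry = 45,
                         gap_halfwidth = 4.5, gap_mod = 0.5,
                         baseline_fold = 170, baseline_gap = 20,
                         background = 90,
                         glare = list(),
                         jitter = NULL, jitter_max = 0,
                         noise_sd = 0, seed = 1) {
  pair <- function(v) {
    if (length(v) == 1L) v <- c(v, v)
    if (is.null(names(v))) names(v) <- c("left", "right")
    v[c("left", "right")]
  }
  cfg <- list(shape = shape, fps = fps, n_frames = as.integer(n_frames),
              f0 = f0, vib_frac = pair(vib_frac),
              amplitude = pair(amplitude), phase = pair(phase),
              axis_angle = axis_angle, fold_rx = fold_rx, fold_ry = fold_ry,
              gap_halfwidth = gap_halfwidth, gap_mod = gap_mod,
              baseline_fold = baseline_fold, baseline_gap = baseline_gap,
              background = background, glare = glare,
              jitter = jitter, jitter_max = jitter_max,
              noise_sd = noise_sd, seed = seed)
  if (cfg$f0 >= cfg$fps / 2)
    ltg_config_error("f0 must be below the Nyquist frequency")
  if (any(cfg$vib_frac < 0 | cfg$vib_frac > 1))
    ltg_config_error("vib_frac must lie in [0, 1]")
  h <- shape[1]; w <- shape[2]
  axis_x <- (w + 1) / 2
  gmax <- gap_halfwidth + gap_mod
  cy <- (h + 1) / 2
  if (axis_x - gmax - 2 * fold_rx < 2 || cy - fold_ry < 2 ||
      cy + fold_ry > h - 1)
    ltg_config_error("fold geometry does not fit inside the frame")
  if (!is.null(jitter)) {
    jitter <- as.matrix(jitter)
    if (nrow(jitter) != n_frames || any(jitter[1, ] != 0))
      ltg_config_error("jitter must have one row per frame, first row (0,0)")
    cfg$jitter <- jitter
  }
  cfg$axis_x <- axis_x
  cfg$center_y <- cy
  structure(cfg, class = "scene_config")
}

# Fold geometry on the pixel grid: ellipse masks and medial-band vibrating
# sub-masks of exact pixel-count fractions.
scene_geometry <- function(cfg) {
  h <- cfg$shape[1]; w <- cfg$shape[2]
  xg <- matrix(rep(seq_len(w), each = h), h)
  yg <- matrix(rep(seq_len(h), times = w), h)
  gmax <- cfg$gap_halfwidth + cfg$gap_mod
  cxl <- cfg$axis_x - gmax - cfg$fold_rx
  cxr <- cfg$axis_x + gmax + cfg$fold_rx
  ell <- function(cx) ((xg - cx) / cfg$fold_rx)^2 +
    ((yg - cfg$center_y) / cfg$fold_ry)^2 <= 1
  left <- ell(cxl); right <- ell(cxr)
  # medial band: the round(frac * n) fold pixels nearest the axis
  medial_band <- function(mask, frac) {
    n <- sum(mask)
    k <- round(frac * n)
    out <- matrix(FALSE, h, w)
    if (k == 0) return(out)
    idx <- which(mask)
    dist <- abs(xg[idx] - cfg$axis_x)
    ord <- order(dist, yg[idx], xg[idx])
    out[idx[ord[seq_len(k)]]] <- TRUE
    out
  }
  gap_zone <- abs(xg - cfg$axis_x) < gmax + 1 &
    abs(yg - cfg$center_y) <= cfg$fold_ry
  list(left = left, right = right,
       vib_left = medial_band(left, cfg$vib_frac["left"]),
       vib_right = medial_band(right, cfg$vib_frac["right"]),
       gap_zone = gap_zone, xg = xg, yg = yg,
       cx_left = cxl, cx_right = cxr)
}

#' Generate a synthetic recording with ground truth
#'
#' Deterministic given the config seed. Vibrating pixels follow
#' `baseline + A * sin(2*pi*f0*t/fps + phase_fold)`; the glottal gap
#' half-width modulates at the same F0; glare spots saturate all channels;
#' the folds are rendered red-dominant so the red channel carries the
#' fold/gap contrast and the blue channel stays dark except at glare;
#' jitter is applied as whole-frame integer translations (zero-filled
#' borders) and Gaussian noise is clipped to `[0, 255]`.
#'
#' @param cfg a [scene_config()].
#' @return List with `recording` (an [hsv_recording()]), `truth` (ground
#'   truth: fold and vibrating masks, true f0 and phases, configured
#'   fractions, `expected_sai` by the SAI definition, `affected_side`,
#'   planted `jitter`) and `landmarks` (axis endpoints, reference frame,
#'   fold-edge nodes in the rendered frame's coordinates, ready for
#'   [run_single()]).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  geo <- scene_geometry(cfg)
  h <- cfg$shape[1]; w <- cfg$shape[2]; T_ <- cfg$n_frames
  set.seed(cfg$seed)

  # static red-channel base: folds over background (gap carved per frame)
  red0 <- matrix(cfg$background, h, w)
  red0[geo$left | geo$right] <- cfg$baseline_fold
  red0[geo$gap_zone] <- cfg$baseline_fold  # medial tissue between folds

  vib_idx <- c(which(geo$vib_left), which(geo$vib_right))
  vib_amp <- c(rep(cfg$amplitude["left"], sum(geo$vib_left)),
               rep(cfg$amplitude["right"], sum(geo$vib_right)))
  vib_ph <- c(rep(cfg$phase["left"], sum(geo$vib_left)),
              rep(cfg$phase["right"], sum(geo$vib_right)))

  zone_idx <- which(geo$gap_zone)
  zone_dx <- abs(geo$xg[zone_idx] - cfg$axis_x)

  glare_idx <- integer(0)
  for (g in cfg$glare) {
    spot <- (geo$xg - g[1])^2 + (geo$yg - g[2])^2 <= g[3]^2
    glare_idx <- union(glare_idx, which(spot))
  }

  jit <- cfg$jitter
  if (is.null(jit)) {
    jit <- matrix(0L, T_, 2)
    if (cfg$jitter_max > 0) {
      m <- cfg$jitter_max
      steps <- matrix(sample(seq.int(-m, m), 2L * (T_ - 1L),
                             replace = TRUE), ncol = 2)
      for (t in 2:T_)
        jit[t, ] <- pmin(pmax(jit[t - 1, ] + steps[t - 1, ], -m), m)
    }
  }

  omega <- 2 * pi * cfg$f0 / cfg$fps
  frames <- vector("list", T_)
  gap_w <- numeric(T_)
  for (t in seq_len(T_)) {
    ph <- omega * (t - 1)
    red <- red0
    red[vib_idx] <- red[vib_idx] + vib_amp * sin(ph + vib_ph)
    g_t <- cfg$gap_halfwidth + cfg$gap_mod * sin(ph)
    gap_w[t] <- g_t
    red[zone_idx[zone_dx < g_t]] <- cfg$baseline_gap
    green <- 0.6 * red
    blue <- matrix(30, h, w)
    if (length(glare_idx)) {
      red[glare_idx] <- 255; green[glare_idx] <- 255; blue[glare_idx] <- 255
    }
    f <- array(0, c(h, w, 3L))
    f[, , 1] <- red; f[, , 2] <- green; f[, , 3] <- blue
    if (cfg$axis_angle != 0)
      for (ch in 1:3) f[, , ch] <- rotate_image(f[, , ch], -cfg$axis_angle)
    if (any(jit[t, ] != 0))
      for (ch in 1:3) f[, , ch] <- shift_image(f[, , ch], jit[t, 1], jit[t, 2])
    if (cfg$noise_sd > 0)
      f <- f + stats::rnorm(length(f), 0, cfg$noise_sd)
    f <- round(pmin(pmax(f, 0), 255))
    storage.mode(f) <- "integer"
    frames[[t]] <- f
  }
  rec <- hsv_recording(frames, cfg$fps,
                       source_id = sprintf("synthetic-seed%d", cfg$seed))

  frac <- cfg$vib_frac
  affected <- if (frac["right"] < frac["left"]) "right" else "left"
  nonaff <- setdiff(c("left", "right"), affected)
  expected_sai <- if (frac[nonaff] == 0) NA_real_
                  else 1 - frac[affected] / frac[nonaff]

  center <- c((w + 1) / 2, (h + 1) / 2)
  tilt <- function(p) rot_point(p, -cfg$axis_angle, center)
  cy <- cfg$center_y; ry <- cfg$fold_ry; rx <- cfg$fold_rx
  epts <- function(ts, cx) t(vapply(ts, function(a)
    c(cx + rx * cos(a * pi / 180), cy + ry * sin(a * pi / 180)),
    numeric(2)))
  nodes <- rbind(
    c(cfg$axis_x, cy - ry - 3),
    epts(seq(250, 110, length.out = 6), geo$cx_left),
    c(cfg$axis_x, cy + ry + 3),
    epts(c(seq(70, 0, length.out = 4), seq(342, 290, length.out = 3)),
         geo$cx_right))
  axis_pts <- rbind(c(cfg$axis_x, cy - ry - 6), c(cfg$axis_x, cy + ry + 6))
  landmarks <- list(axis = glottal_axis(tilt(axis_pts)[1, ],
                                        tilt(axis_pts)[2, ]),
                    reference_frame = NA_integer_,
                    nodes = tilt(nodes))

  truth <- list(left_fold = geo$left, right_fold = geo$right,
                vib_left = geo$vib_left, vib_right = geo$vib_right,
                f0 = cfg$f0, phase = cfg$phase, vib_frac = frac,
                expected_sai = unname(expected_sai),
                affected_side = affected, axis_x = cfg$axis_x,
                gap_halfwidth_series = gap_w, jitter = jit,
                glare_idx = glare_idx)
  list(recording = rec, truth = truth, landmarks = landmarks, config = cfg)
}

# Beta shape parameters from mean/sd (method of moments).
beta_shapes <- function(m, s) {
  k <- m * (1 - m) / s^2 - 1
  if (k <= 0) ltg_config_error("sd too large for a Beta distribution")
  c(a = m * k, b = (1 - m) * k)
}

#' Default cohort group model
#'
#' Per-group distributions of the subject-level SAI (equivalently of the
#' affected fold's vibrating fraction, `1 - SAI`, with the non-affected fold
#' fully vibrating), chosen as Beta distributions matching the clinically
#' reported group structure: normophonic 0.10 +/- 0.07, benign glottal
#' lesions 0.16 +/- 0.13, malignant lesions 0.65 +/- 0.18.
#'
#' @return Named list of `c(a, b)` Beta shape pairs.
#' @export
default_group_model <- function() {
  list(normophonic = beta_shapes(0.10, 0.07),
       benign      = beta_shapes(0.16, 0.13),
       malignant   = beta_shapes(0.65, 0.18))
}

#' Generate a synthetic subject cohort
#'
#' Draws one subject-level SAI per subject from the group's Beta
#' distribution, sets the affected fold's vibrating fraction to `1 - SAI`
#' (non-affected fold fully vibrating, affected side random), and -- when
#' `render = TRUE` -- renders a full recording per subject. Reproducible:
#' the same seed yields bit-identical cohorts.
#'
#' @param n named integer vector of group sizes, e.g.
#'   `c(normophonic = 10, benign = 10, malignant = 11)`.
#' @param seed RNG seed.
#' @param group_model named list of Beta `c(a, b)` pairs per group
#'   (default [default_group_model()]).
#' @param render render recordings (`TRUE`) or return only the sampled
#'   ground truth (`FALSE`, cheap; used for large replicate studies).
#' @param ... scene parameters forwarded to [scene_config()] for rendered
#'   subjects (e.g. a smaller `shape`/`n_frames` for speed).
#' @return A data frame with one row per subject (`subject`, `group`,
#'   `affected_side`, `vib_frac_affected`, `expected_sai`, `seed`); when
#'   `render = TRUE` it carries a list-column `scene` holding each
#'   [generate_recording()] result.
#' @export
generate_cohort <- function(n = c(normophonic = 10, benign = 10,
                                  malignant = 11),
                            seed = 1, group_model = default_group_model(),
                            render = FALSE, ...) {
  if (any(n < 1L) || is.null(names(n)))
    ltg_input_error("n must be a named vector of positive group sizes")
  if (!all(names(n) %in% names(group_model)))
    ltg_config_error("every group needs an entry in group_model")
  set.seed(seed)
  rows <- list()
  for (g in names(n)) {
    sh <- group_model[[g]]
    sai <- stats::rbeta(n[[g]], sh["a"], sh["b"])
    side <- sample(c("left", "right"), n[[g]], replace = TRUE)
    rows[[g]] <- data.frame(
      subject = sprintf("%s_%02d", substr(g, 1, 1), seq_len(n[[g]])),
      group = g, affected_side = side,
      vib_frac_affected = 1 - sai, expected_sai = sai)
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df$seed <- seed * 1000L + seq_len(nrow(df))
  if (render) {
    df$scene <- lapply(seq_len(nrow(df)), function(i) {
      vf <- c(left = 1, right = 1)
      vf[df$affected_side[i]] <- df$vib_frac_affected[i]
      generate_recording(scene_config(vib_frac = vf, seed = df$seed[i], ...))
    })
  }
  df
}
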