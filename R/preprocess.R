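# Pre-processing chain: channel extraction, inter-frame offset reduction,
# maximum-glottic-opening frame selection, rotation to a vertical glottal
# axis. Each stage is a pure function of its inputs; the pipeline module
# enforces their order.

#' Single-channel frame stack
#'
#' @param data `H x W x T` numeric array of intensities in 0..255.
#' @param channel_role one of `"glare_reduction"`, `"fold_contrast"`,
#'   `"luminance"`.
#' @param fps inherited frame rate.
#' @return Object of class `channel_stack`.
#' @export
channel_stack <- function(data, channel_role, fps) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  structure(list(data = data, channel_role = channel_role, fps = fps),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<channel_stack> role=%s, %d frames, %d x %d px, %.0f fps\n",
              x$channel_role, d[3], d[1], d[2], x$fps))
  invisible(x)
}

#' Extract a colour channel by analysis role
#'
#' The blue component of the endoscopic RGB images is used to reduce glare
#' caused by the laser light source (specular reflections saturate blue),
#' while the red component maximizes the brightness contrast between the
#' vocal folds and the dark glottal gap; all downstream brightness analysis
#' runs on the `fold_contrast` (red) stack and glare flagging on the
#' `glare_reduction` (blue) stack.
#'
#' @param rec an [hsv_recording()].
#' @param role `"glare_reduction"` (blue), `"fold_contrast"` (red) or
#'   `"luminance"` (Rec. 601 weights).
#' @return A [channel_stack()].
#' @export
extract_channel <- function(rec, role = c("fold_contrast", "glare_reduction",
                                          "luminance")) {
  stopifnot(inherits(rec, "hsv_recording"))
  if (!is.character(role) || !role[1] %in%
      c("fold_contrast", "glare_reduction", "luminance"))
    ltg_config_error(paste0("unknown channel role: ", role[1]))
  role <- role[1]
  T_ <- n_frames(rec); h <- rec$dim[1]; w <- rec$dim[2]
  data <- array(0, c(h, w, T_))
  for (t in seq_len(T_)) {
    f <- rec$frames[[t]]
    data[, , t] <- switch(role,
      fold_contrast   = f[, , 1],
      glare_reduction = f[, , 3],
      luminance       = 0.299 * f[, , 1] + 0.587 * f[, , 2] + 0.114 * f[, , 3])
  }
  channel_stack(data, role, rec$fps)
}

#' Flag glare-contaminated pixels
#'
#' Pixels whose glare-reduction (blue) channel is saturated in at least half
#' of the frames are specular reflections of the light source, not tissue;
#' they are excluded from spectral analysis.
#'
#' @param stack a `glare_reduction` [channel_stack()].
#' @param sat_level saturation level (intensity units, default 250).
#' @param min_frac minimum fraction of frames saturated (default 0.5).
#' @return Logical `H x W` matrix, `TRUE` where glare is flagged.
#' @export
glare_mask <- function(stack, sat_level = 250, min_frac = 0.5) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$data)
  sat <- rowMeans(matrix(stack$data >= sat_level, d[1] * d[2], d[3]))
  matrix(sat >= min_frac, d[1], d[2])
}

# FFT cross-correlation between two mean-removed frames; returns the
# integer (dx, dy) within +/- r maximizing the correlation. Frames are
# zero-padded by r on each side so the correlation is linear (no circular
# wraparound within the search window). Ties break towards the first
# candidate in (dy, dx) ascending scan order.
xcorr_shift <- function(a, b, r) {
  h <- nrow(a); w <- ncol(a)
  ph <- h + 2L * r; pw <- w + 2L * r
  A <- matrix(0, ph, pw); B <- matrix(0, ph, pw)
  A[seq_len(h), seq_len(w)] <- a - mean(a)
  B[seq_len(h), seq_len(w)] <- b - mean(b)
  cc <- Re(stats::fft(Conj(stats::fft(A)) * stats::fft(B), inverse = TRUE))
  # cc[1 + (dy mod ph), 1 + (dx mod pw)] = sum_{y,x} A[y,x] B[y+dy, x+dx]
  dys <- -r:r; dxs <- -r:r
  sub <- cc[(dys %% ph) + 1L, (dxs %% pw) + 1L, drop = FALSE]
  best <- arrayInd(which.max(t(sub)), c(length(dxs), length(dys)))
  c(dx = dxs[best[1]], dy = dys[best[2]])
}

#' Estimate inter-frame offsets by cross-correlation
#'
#' Camera and endoscope motion introduces whole-frame offsets of up to a
#' dozen pixels between consecutive images. For every consecutive pair the
#' integer displacement maximizing the cross-correlation of the mean-removed
#' frames within `+/- search_radius` is found; cumulative offsets relative
#' to frame 1 are returned (frame 1 has offset (0, 0) by definition).
#'
#' @param stack a [channel_stack()] (typically `fold_contrast`).
#' @param search_radius maximum displacement considered, pixels (default 15).
#' @return Object of class `frame_offsets`: data frame with columns
#'   `frame`, `dx`, `dy` plus attribute `search_radius`.
#' @export
estimate_offsets <- function(stack, search_radius = 15L) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$data)
  if (d[3] < 2L) ltg_input_error("need at least 2 frames")
  if (search_radius < 1L || search_radius >= min(d[1], d[2]) / 2)
    ltg_config_error("search_radius must be in [1, min(H, W)/2)")
  T_ <- d[3]
  dx <- dy <- integer(T_)
  for (t in 2:T_) {
    s <- xcorr_shift(stack$data[, , t - 1], stack$data[, , t], search_radius)
    dx[t] <- dx[t - 1] + s["dx"]
    dy[t] <- dy[t - 1] + s["dy"]
  }
  structure(data.frame(frame = seq_len(T_), dx = dx, dy = dy),
            search_radius = search_radius, class = c("frame_offsets",
                                                     "data.frame"))
}

#' Remove inter-frame offsets
#'
#' Translates every frame by the negated cumulative offset (integer shift,
#' zero-filled borders, dimensions unchanged), aligning all frames with
#' frame 1. Works on an [hsv_recording()] (all three channels) or a
#' [channel_stack()].
#'
#' @param x recording or channel stack.
#' @param offsets a `frame_offsets` object from [estimate_offsets()].
#' @return Object of the same class as `x`.
#' @export
stabilize <- function(x, offsets) UseMethod("stabilize")

#' @export
stabilize.hsv_recording <- function(x, offsets) {
  stopifnot(inherits(offsets, "frame_offsets"),
            nrow(offsets) == n_frames(x))
  frames <- x$frames
  for (t in seq_along(frames)) {
    if (offsets$dx[t] == 0 && offsets$dy[t] == 0) next
    f <- frames[[t]]
    for (ch in 1:3)
      f[, , ch] <- shift_image(f[, , ch], -offsets$dx[t], -offsets$dy[t])
    frames[[t]] <- f
  }
  hsv_recording(frames, x$fps, x$source_id)
}

#' @export
stabilize.channel_stack <- function(x, offsets) {
  stopifnot(inherits(offsets, "frame_offsets"),
            nrow(offsets) == dim(x$data)[3])
  data <- x$data
  for (t in seq_len(dim(data)[3])) {
    if (offsets$dx[t] == 0 && offsets$dy[t] == 0) next
    data[, , t] <- shift_image(data[, , t], -offsets$dx[t], -offsets$dy[t])
  }
  channel_stack(data, x$channel_role, x$fps)
}

#' Select the frame with the largest glottic opening
#'
#' The glottal gap is the darkest structure in the fold-contrast channel, so
#' the opening area is proxied by the count of "dark" pixels -- intensity
#' below a quantile threshold of the whole stack's intensity distribution --
#' inside the central half of the image (the glottis is centered after
#' stabilization; the image periphery holds unrelated dark anatomy). Ties
#' resolve to the smallest frame index.
#'
#' @param stack stabilized `fold_contrast` [channel_stack()].
#' @param dark_quantile stack intensity quantile defining "dark"
#'   (default 0.25).
#' @return Frame index (1-based).
#' @export
select_max_opening_frame <- function(stack, dark_quantile = 0.25) {
  stopifnot(inherits(stack, "channel_stack"))
  d <- dim(stack$data)
  if (diff(range(stack$data)) == 0)
    ltg_degenerate_error("uniform stack: no glottic opening detectable")
  thr <- stats::quantile(stack$data, dark_quantile, names = FALSE)
  rows <- seq.int(floor(d[1] / 4) + 1L, floor(3 * d[1] / 4))
  cols <- seq.int(floor(d[2] / 4) + 1L, floor(3 * d[2] / 4))
  central <- stack$data[rows, cols, , drop = FALSE]
  counts <- colSums(matrix(central < thr, length(rows) * length(cols), d[3]))
  which.max(counts)  # ties -> smallest index
}

#' Glottal axis
#'
#' Two endpoints delineating the main axis of the glottal area, marked on
#' the maximum-opening frame. The inclination is measured from the image
#' vertical in degrees, normalized to `(-90, 90]`.
#'
#' @param endpoint_a,endpoint_b `(x, y)` pixel coordinates.
#' @return Object of class `glottal_axis` with `a`, `b`, `angle`.
#' @export
glottal_axis <- function(endpoint_a, endpoint_b) {
  a <- as.numeric(endpoint_a); b <- as.numeric(endpoint_b)
  if (isTRUE(all.equal(a, b)))
    ltg_input_error("axis endpoints must be distinct")
  structure(list(a = a, b = b, angle = axis_angle(a, b)),
            class = "glottal_axis")
}

# Inclination of segment a->b from the image vertical, degrees in (-90, 90].
axis_angle <- function(a, b) {
  ang <- atan2(b[1] - a[1], b[2] - a[2]) * 180 / pi
  if (ang > 90) ang <- ang - 180
  if (ang <= -90) ang <- ang + 180
  ang
}

#' Rotate a recording so the glottal axis is vertical
#'
#' Every frame is rotated by the axis inclination about the image center
#' (bilinear interpolation, zero-filled corners, dimensions unchanged); the
#' transformed axis is returned and is vertical to numerical precision.
#'
#' @param rec an [hsv_recording()].
#' @param axis a [glottal_axis()] in the recording's pixel coordinates.
#' @return List with elements `recording`, `axis` (rotated) and
#'   `transform_point`, a function mapping original `(x, y)` points (n x 2
#'   matrix) into the rotated frame -- used to carry ROI nodes along.
#' @export
rotate_to_vertical <- function(rec, axis) {
  stopifnot(inherits(rec, "hsv_recording"), inherits(axis, "glottal_axis"))
  h <- rec$dim[1]; w <- rec$dim[2]
  inb <- function(p) p[1] >= 1 && p[1] <= w && p[2] >= 1 && p[2] <= h
  if (!inb(axis$a) || !inb(axis$b))
    ltg_input_error("axis endpoints must lie inside the frame")
  ang <- axis$angle
  center <- c((w + 1) / 2, (h + 1) / 2)
  tp <- function(p) rot_point(p, ang, center)
  if (abs(ang) < 1e-9) {
    return(list(recording = rec, axis = axis, transform_point = tp))
  }
  frames <- lapply(rec$frames, function(f) {
    out <- f
    for (ch in 1:3) out[, , ch] <- rotate_image(f[, , ch], ang)
    out
  })
  new_axis <- glottal_axis(tp(rbind(axis$a))[1, ], tp(rbind(axis$b))[1, ])
  list(recording = hsv_recording(frames, rec$fps, rec$source_id),
       axis = new_axis, transform_point = tp)
}

#' Read a landmark file
#'
#' Landmarks carry the interactively collected annotations: the two glottal
#' axis endpoints, an optional reference frame index and up to 20 fold-edge
#' nodes. JSON and YAML are accepted:
#' `{"axis": [[x,y],[x,y]], "reference_frame": 17 | "auto",
#'   "nodes": [[x,y], ...]}`.
#'
#' @param path JSON or YAML file.
#' @return List with `axis` (a [glottal_axis()]), `reference_frame`
#'   (integer or `NA` for automatic selection) and `nodes` (n x 2 matrix or
#'   `NULL`).
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    ltg_config_error(paste0("landmark file not found: ", path))
  lm <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(lm$axis) || length(lm$axis) < 2)
    ltg_format_error("landmark file lacks an 'axis' entry with two points")
  to_mat <- function(x) {
    if (is.matrix(x)) return(matrix(as.numeric(x), ncol = 2))
    if (is.data.frame(x)) return(matrix(as.numeric(as.matrix(x)), ncol = 2))
    do.call(rbind, lapply(x, function(p) as.numeric(unlist(p))))
  }
  ax <- to_mat(lm$axis)
  nodes <- if (is.null(lm$nodes)) NULL else to_mat(lm$nodes)
  if (!is.null(nodes) && nrow(nodes) > 20L)
    ltg_input_error("at most 20 fold-edge nodes are supported")
  rf <- lm$reference_frame
  rf <- if (is.null(rf) || is.na(rf) || identical(rf, "auto")) NA_integer_
        else as.integer(rf)
  list(axis = glottal_axis(ax[1, ], ax[2, ]), reference_frame = rf,
       nodes = nodes)
}

#' Write a landmark file (JSON)
#'
#' @param landmarks list with `axis` (`glottal_axis` or 2 x 2 matrix),
#'   optional `reference_frame`, optional `nodes` matrix.
#' @param path output `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  ax <- landmarks$axis
  if (inherits(ax, "glottal_axis")) ax <- rbind(ax$a, ax$b)
  rf <- landmarks$reference_frame
  if (is.null(rf) || is.na(rf)) rf <- "auto"
  out <- list(axis = unname(lapply(seq_len(nrow(ax)), function(i) ax[i, ])),
              reference_frame = rf)
  if (!is.null(landmarks$nodes)) {
    nd <- landmarks$nodes
    out$nodes <- unname(lapply(seq_len(nrow(nd)), function(i) nd[i, ]))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
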