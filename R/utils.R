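# Internal helpers shared across modules.

# Classed error conditions so callers (and tests) can dispatch on failure kind.
ltg_stop <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "ltg_error", "error", "condition")))
}

ltg_input_error  <- function(msg) ltg_stop("ltg_input_error", msg)
ltg_config_error <- function(msg) ltg_stop("ltg_config_error", msg)
ltg_format_error <- function(msg) ltg_stop("ltg_format_error", msg)
ltg_io_error     <- function(msg) ltg_stop("ltg_io_error", msg)
# degenerate input: structurally valid but carries no analyzable signal
ltg_degenerate_error <- function(msg) ltg_stop("ltg_degenerate_error", msg)

# Coordinate convention (used everywhere): origin at the top-left pixel
# center, x = column index, y = row index, both starting at 1. A matrix m
# holding an image is addressed m[y, x]. Angles are measured from the image
# vertical, in degrees, with the sign fixed by axis_angle(): the angle a
# satisfies direction = (sin a, cos a) in (x, y).

# Translate a single-channel image by an integer (dx, dy), vacated border
# filled with `fill`. Positive dx moves content towards larger x.
shift_image <- function(m, dx, dy, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  src_x <- seq_len(w) - dx
  src_y <- seq_len(h) - dy
  ok_x <- src_x >= 1L & src_x <= w
  ok_y <- src_y >= 1L & src_y <= h
  if (any(ok_x) && any(ok_y)) {
    out[which(ok_y), which(ok_x)] <- m[src_y[ok_y], src_x[ok_x], drop = FALSE]
  }
  out
}

# Bilinear sampling of image m at real coordinates (xs, ys); outside the
# image the value is `fill`. Vectorized over coordinates.
bilinear_sample <- function(m, xs, ys, fill = 0) {
  h <- nrow(m); w <- ncol(m)
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0;   fy <- ys - y0
  v <- function(xi, yi) {
    inside <- xi >= 1 & xi <= w & yi >= 1 & yi <= h
    out <- rep(fill, length(xi))
    out[inside] <- m[cbind(yi[inside], xi[inside])]
    out
  }
  (1 - fx) * (1 - fy) * v(x0,     y0) +
    fx     * (1 - fy) * v(x0 + 1, y0) +
    (1 - fx) * fy     * v(x0,     y0 + 1) +
    fx     * fy       * v(x0 + 1, y0 + 1)
}

# Rotate a single-channel image by `angle_deg` about the image center using
# bilinear interpolation, zero fill, output dimensions unchanged. The point
# transform applied to content is rot_point(p, angle_deg).
rotate_image <- function(m, angle_deg, fill = 0) {
  if (angle_deg == 0) return(m)
  h <- nrow(m); w <- ncol(m)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  th <- angle_deg * pi / 180
  gx <- rep(seq_len(w), each = h) - cx
  gy <- rep(seq_len(h), times = w) - cy
  # inverse map: output pixel -> source location
  sx <- cos(th) * gx + sin(th) * gy + cx
  sy <- -sin(th) * gx + cos(th) * gy + cy
  matrix(bilinear_sample(m, sx, sy, fill = fill), h, w)
}

# Forward point transform matching rotate_image: where content at p lands.
rot_point <- function(p, angle_deg, center) {
  th <- angle_deg * pi / 180
  dx <- p[, 1] - center[1]; dy <- p[, 2] - center[2]
  cbind(cos(th) * dx - sin(th) * dy + center[1],
        sin(th) * dx + cos(th) * dy + center[2])
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

`%||%` <- function(a, b) if (is.null(a)) b else a
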