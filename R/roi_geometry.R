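# Region-of-interest geometry: a closed cubic spline through the user's
# fold-edge nodes, rasterized to a pixel mask and split into left/right
# fold masks by the (vertical) glottal axis.

#' Fit a closed cubic spline contour through fold-edge nodes
#'
#' The up-to-20 nodes marked along the outer edges of the vocal folds are
#' interpolated by a periodic cubic spline (chord-length parameterization),
#' i.e. the curve passes through every node and is C2-continuous across the
#' closure. Sampled densely, the result is a closed polyline whose first and
#' last points coincide.
#'
#' @param nodes n x 2 matrix of `(x, y)` points ordered around the region
#'   perimeter, `n >= 4`, not all collinear.
#' @param samples_per_segment dense samples per node-to-node span
#'   (default 20, sub-pixel at clinical image scales).
#' @return (m+1) x 2 matrix of curve points, closed (first row == last row).
#' @export
fit_bspline_contour <- function(nodes, samples_per_segment = 20L) {
  nodes <- as.matrix(nodes)
  if (nrow(nodes) < 4L)
    ltg_input_error("at least 4 nodes are required for a closed contour")
  # collinear nodes span a rank-1 point cloud
  sv <- svd(sweep(nodes, 2, colMeans(nodes)), nu = 0, nv = 0)$d
  if (sv[2] < 1e-9 * max(sv[1], 1))
    ltg_input_error("nodes are collinear; cannot enclose a region")
  closed <- rbind(nodes, nodes[1, ])
  seg <- sqrt(rowSums(diff(closed)^2))
  if (any(seg == 0))
    ltg_input_error("duplicate consecutive nodes")
  tt <- c(0, cumsum(seg))
  dense_t <- unlist(lapply(seq_len(nrow(nodes)), function(i)
    seq(tt[i], tt[i + 1], length.out = samples_per_segment + 1L)[-(samples_per_segment + 1L)]))
  dense_t <- c(dense_t, tt[length(tt)])
  x <- stats::spline(tt, closed[, 1], method = "periodic", xout = dense_t)$y
  y <- stats::spline(tt, closed[, 2], method = "periodic", xout = dense_t)$y
  cbind(x = x, y = y)
}

# Signed polygon area (shoelace); contour closed or not.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  n <- nrow(p)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}

#' Rasterize a closed contour to a pixel mask
#'
#' A pixel belongs to the region iff its center `(x, y)` (integer column,
#' row) lies inside the polygonal approximation of the curve under the
#' even-odd rule. Contours extending beyond the image are clipped with a
#' warning.
#'
#' @param contour closed curve ((m+1) x 2, first point = last point).
#' @param shape image dimensions `c(H, W)`.
#' @return Logical `H x W` matrix.
#' @export
rasterize_roi <- function(contour, shape) {
  contour <- as.matrix(contour)
  if (!isTRUE(all.equal(contour[1, ], contour[nrow(contour), ],
                        check.attributes = FALSE)))
    ltg_input_error("contour must be closed (first point == last point)")
  h <- shape[1]; w <- shape[2]
  if (any(contour[, 1] < 0.5 | contour[, 1] > w + 0.5 |
          contour[, 2] < 0.5 | contour[, 2] > h + 0.5))
    warning("contour extends outside the image; clipping to bounds")
  if (abs(polygon_area(contour)) < 1e-9)
    return(matrix(FALSE, h, w))
  px <- rep(seq_len(w), each = h)
  py <- rep(seq_len(h), times = w)
  inside <- mgcv::in.out(contour, cbind(px, py))
  matrix(inside, h, w)
}

#' Split an ROI into left and right fold masks at the glottal axis
#'
#' After rotation to a vertical axis, pixels with center strictly left of
#' the axis column go to the left fold, strictly right to the right fold;
#' pixels exactly on the axis (integer `axis_x`) join the left fold. The two
#' masks partition the ROI for every input.
#'
#' @param roi_mask logical `H x W` matrix.
#' @param axis_x axis column (real).
#' @return List `left`, `right` of logical matrices.
#' @export
split_folds <- function(roi_mask, axis_x) {
  stopifnot(is.matrix(roi_mask), is.logical(roi_mask))
  cols <- which(roi_mask, arr.ind = TRUE)
  if (nrow(cols) > 0) {
    bb <- range(cols[, 2])
    if (axis_x < bb[1] || axis_x > bb[2])
      warning("axis column lies outside the ROI bounding box")
  }
  xg <- matrix(rep(seq_len(ncol(roi_mask)), each = nrow(roi_mask)),
               nrow(roi_mask))
  list(left = roi_mask & xg <= axis_x,
       right = roi_mask & xg > axis_x)
}

#' Build a complete fold ROI
#'
#' Convenience constructor running [fit_bspline_contour()],
#' [rasterize_roi()] and [split_folds()].
#'
#' @param nodes n x 2 node matrix (ordered around the perimeter).
#' @param shape image dimensions `c(H, W)`.
#' @param axis_x vertical glottal-axis column.
#' @param samples_per_segment passed to [fit_bspline_contour()].
#' @return Object of class `fold_roi` with `nodes`, `contour`, `roi_mask`,
#'   `left_mask`, `right_mask`, `axis_x`.
#' @export
fold_roi <- function(nodes, shape, axis_x, samples_per_segment = 20L) {
  contour <- fit_bspline_contour(nodes, samples_per_segment)
  roi_mask <- rasterize_roi(contour, shape)
  lr <- split_folds(roi_mask, axis_x)
  structure(list(nodes = as.matrix(nodes), contour = contour,
                 roi_mask = roi_mask, left_mask = lr$left,
                 right_mask = lr$right, axis_x = axis_x),
            class = "fold_roi")
}

#' @export
print.fold_roi <- function(x, ...) {
  cat(sprintf(
    "<fold_roi> %d nodes, ROI %d px (left %d / right %d), axis x = %.1f\n",
    nrow(x$nodes), sum(x$roi_mask), sum(x$left_mask), sum(x$right_mask),
    x$axis_x))
  invisible(x)
}
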