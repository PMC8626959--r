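#' Construct a centerline from 3D points
#'
#' A centerline is an ordered polyline through the lumen center of a tubular
#' vessel, stored as a tibble with columns `x`, `y`, `z` (mm) and the cumulative
#' arc length `arclength` (mm, starting at 0). Orientation is tracked with the
#' `proximal_first` attribute: all landmarking algorithms assume the first point
#' is the proximal (inlet-side) end.
#'
#' @param points A data frame or matrix with columns/column-triplet `x`, `y`,
#'   `z` in mm, ordered along the vessel.
#' @param proximal_first Logical; whether the first point is the proximal end.
#' @param merge_duplicates Merge consecutive duplicate points (zero-length
#'   segments break derivative stencils) with a warning instead of erroring.
#' @return A `centerline` tibble with columns `x`, `y`, `z`, `arclength`.
#' @examples
#' cl <- centerline(data.frame(x = 0:5, y = 0, z = 0))
#' total_length(cl)
#' @export
centerline <- function(points, proximal_first = TRUE, merge_duplicates = TRUE) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 3)
    points <- tibble::tibble(x = points[, 1], y = points[, 2], z = points[, 3])
  }
  if (!all(c("x", "y", "z") %in% names(points))) {
    abort_config("`points` must have columns x, y, z")
  }
  pts <- tibble::tibble(
    x = as.numeric(points$x), y = as.numeric(points$y), z = as.numeric(points$z)
  )
  if (anyNA(pts) || !all(is.finite(as.matrix(pts)))) {
    abort_config("centerline coordinates must be finite numbers")
  }
  if (nrow(pts) < 2) abort_config("a centerline needs at least 2 points")
  seg <- segment_lengths(pts)
  if (any(seg == 0)) {
    if (!merge_duplicates) abort_config("centerline contains duplicate consecutive points")
    rlang::warn(sprintf("merged %d duplicate consecutive point(s)", sum(seg == 0)))
    pts <- pts[c(TRUE, seg > 0), ]
    if (nrow(pts) < 2) abort_config("a centerline needs at least 2 distinct points")
    seg <- segment_lengths(pts)
  }
  out <- pts
  out$arclength <- c(0, cumsum(seg))
  new_centerline(out, proximal_first = proximal_first)
}

new_centerline <- function(df, proximal_first = TRUE) {
  structure(
    tibble::new_tibble(df, nrow = nrow(df)),
    class = c("centerline", class(tibble::tibble())),
    proximal_first = isTRUE(proximal_first)
  )
}

segment_lengths <- function(pts) {
  m <- as.matrix(pts[, c("x", "y", "z")])
  sqrt(rowSums((m[-1, , drop = FALSE] - m[-nrow(m), , drop = FALSE])^2))
}

#' Coordinate matrix of a centerline
#' @param c A `centerline`.
#' @return An n-by-3 numeric matrix of xyz coordinates (mm).
#' @export
as_points <- function(c) {
  unname(as.matrix(as.data.frame(c)[, c("x", "y", "z")]))
}

#' Total arc length of a centerline (mm)
#' @param c A `centerline`.
#' @export
total_length <- function(c) {
  c$arclength[nrow(c)]
}

#' Is the centerline stored proximal-end first?
#' @param c A `centerline`.
#' @export
is_proximal_first <- function(c) {
  isTRUE(attr(c, "proximal_first"))
}

#' Reverse the point order of a centerline
#'
#' Arc lengths are recomputed from the reversed points; total length is
#' preserved.
#'
#' @param c A `centerline`.
#' @param proximal_first Orientation flag to record on the reversed curve.
#' @export
reverse_centerline <- function(c, proximal_first = is_proximal_first(c)) {
  centerline(as.data.frame(c)[rev(seq_len(nrow(c))), c("x", "y", "z")],
             proximal_first = proximal_first)
}

#' Orient a centerline proximal-end first using an inlet point
#'
#' The landmarking algorithms traverse the vessel from proximal to distal, so
#' the stored point order must start at the inlet. The point order is reversed
#' when the last point is nearer to the given inlet than the first point.
#'
#' @param c A `centerline`.
#' @param inlet Numeric xyz (mm) of the vessel inlet (proximal end).
#' @return A `centerline` with `proximal_first = TRUE`. Applying the operation
#'   twice with the same inlet is a no-op.
#' @export
orient_centerline <- function(c, inlet) {
  inlet <- as.numeric(inlet)
  if (length(inlet) != 3 || anyNA(inlet)) abort_config("`inlet` must be a numeric xyz triplet")
  p <- as_points(c)
  d_first <- sqrt(sum((p[1, ] - inlet)^2))
  d_last <- sqrt(sum((p[nrow(p), ] - inlet)^2))
  if (abs(d_first - d_last) < 1e-6) {
    abort_config("inlet is equidistant from both endpoints; orientation is ambiguous")
  }
  if (d_last < d_first) {
    reverse_centerline(c, proximal_first = TRUE)
  } else {
    new_centerline(tibble::as_tibble(as.data.frame(c)), proximal_first = TRUE)
  }
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf(
    "# A centerline: %d points, total length %.3f mm, %s\n",
    nrow(x), total_length(x),
    if (is_proximal_first(x)) "proximal-first" else "orientation unverified"
  ))
  print(tibble::as_tibble(as.data.frame(x)), ...)
  invisible(x)
}

# Rigid transform helper used by tests and examples.

#' Apply a rigid motion (rotation + translation) to a centerline
#' @param c A `centerline`.
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 numeric offset (mm).
#' @export
transform_centerline <- function(c, rotation = diag(3), translation = c(0, 0, 0)) {
  p <- as_points(c) %*% t(rotation)
  p <- sweep(p, 2, as.numeric(translation), "+")
  centerline(p, proximal_first = is_proximal_first(c))
}
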