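# Discrete differential geometry of uniformly sampled 3D curves.
#
# All derivatives are 2nd-order central finite differences with respect to the
# (uniform) arc-length parameter; one-sided stencils of the same order are used
# at the ends. The curvature formula kappa = |r' x r''| / |r'|^3 and the
# torsion formula tau = r''' . (r' x r'') / |r' x r''|^2 are invariant to the
# parametrization speed, so small deviations of the discrete spacing from true
# arc length cancel to leading order.

check_uniform <- function(c, min_points, tol = 0.05) {
  if (nrow(c) < min_points) {
    abort_config(sprintf("at least %d points are required", min_points))
  }
  seg <- diff(c$arclength)
  h <- stats::median(seg)
  # The final segment may be shorter (resampling lands on the endpoint); the
  # end stencils are one-sided and end points are excluded from peak
  # detection, so it is exempt from the uniformity requirement.
  if (max(abs(seg[-length(seg)] - h)) > tol * h) {
    abort_config("point spacing is non-uniform (> 5% deviation); resample the centerline first (see resample_centerline)")
  }
  h
}

# First derivative wrt parameter index*h, 2nd order, one-sided at ends.
deriv1 <- function(p, h) {
  n <- nrow(p)
  d <- (p[c(2:n, n), , drop = FALSE] - p[c(1, 1:(n - 1)), , drop = FALSE]) / (2 * h)
  d[1, ] <- (-3 * p[1, ] + 4 * p[2, ] - p[3, ]) / (2 * h)
  d[n, ] <- (3 * p[n, ] - 4 * p[n - 1, ] + p[n - 2, ]) / (2 * h)
  d
}

deriv2 <- function(p, h) {
  n <- nrow(p)
  d <- (p[c(2:n, n), , drop = FALSE] - 2 * p + p[c(1, 1:(n - 1)), , drop = FALSE]) / h^2
  d[1, ] <- (2 * p[1, ] - 5 * p[2, ] + 4 * p[3, ] - p[4, ]) / h^2
  d[n, ] <- (2 * p[n, ] - 5 * p[n - 1, ] + 4 * p[n - 2, ] - p[n - 3, ]) / h^2
  d
}

# Third derivative: 5-point central stencil; the two points at each end
# replicate the nearest interior value (they are excluded from peak detection
# downstream).
deriv3 <- function(p, h) {
  n <- nrow(p)
  d <- matrix(0, n, 3)
  i <- 3:(n - 2)
  d[i, ] <- (p[i + 2, , drop = FALSE] - 2 * p[i + 1, , drop = FALSE] +
               2 * p[i - 1, , drop = FALSE] - p[i - 2, , drop = FALSE]) / (2 * h^3)
  d[1, ] <- d[2, ] <- d[3, ]
  d[n, ] <- d[n - 1, ] <- d[n - 2, ]
  d
}

#' Curvature and torsion profile of a centerline
#'
#' Computes the scalar curvature `kappa = |r' x r''| / |r'|^3` (1/mm) and the
#' torsion `tau = r''' . (r' x r'') / |r' x r''|^2` (1/mm, signed) per point
#' along arc length. Torsion is set to 0 where `|r' x r''|^2 < 1e-12`
#' (locally straight segments, where torsion is undefined).
#'
#' @param c A uniformly resampled [centerline()] (>= 7 points; spacing within
#'   5% of uniform, otherwise an error asks for resampling).
#' @return A tibble with columns `arclength`, `curvature`, `torsion`.
#' @examples
#' helix <- make_helix(a = 10, b = 3, n_turns = 2, spacing = 0.1)
#' prof <- compute_geometry(helix)
#' summary(prof$curvature)  # ~ 10 / 109
#' @export
compute_geometry <- function(c) {
  h <- check_uniform(c, min_points = 7)
  p <- as_points(c)
  d1 <- deriv1(p, h)
  d2 <- deriv2(p, h)
  d3 <- deriv3(p, h)
  cr <- cross_rows(d1, d2)
  cr2 <- rowSums(cr * cr)
  speed <- row_norms(d1)
  curvature <- sqrt(cr2) / speed^3
  torsion <- ifelse(cr2 < 1e-12, 0, rowSums(d3 * cr) / cr2)
  tibble::tibble(arclength = c$arclength, curvature = curvature, torsion = torsion)
}

#' Curvature profile only
#'
#' Like [compute_geometry()] but requires only 5 points (second derivatives)
#' and returns curvature alone.
#'
#' @inheritParams compute_geometry
#' @return A tibble with columns `arclength`, `curvature`.
#' @export
compute_curvature <- function(c) {
  h <- check_uniform(c, min_points = 5)
  p <- as_points(c)
  d1 <- deriv1(p, h)
  d2 <- deriv2(p, h)
  curvature <- row_norms(cross_rows(d1, d2)) / row_norms(d1)^3
  tibble::tibble(arclength = c$arclength, curvature = curvature)
}

#' Torsion profile only
#' @inheritParams compute_geometry
#' @return A tibble with columns `arclength`, `torsion`.
#' @export
compute_torsion <- function(c) {
  compute_geometry(c)[, c("arclength", "torsion")]
}

#' Frenet-Serret frame along a centerline
#'
#' Tangent `T = r'/|r'|`, normal `N` pointing toward the center of the
#' osculating circle, binormal `B = T x N`. The normal is undefined where the
#' curve is locally straight; such points are flagged.
#'
#' @inheritParams compute_geometry
#' @param kappa_min Curvature below which the normal is flagged undefined
#'   (1/mm).
#' @return A tibble with `arclength`, `curvature`, matrix columns `tangent`,
#'   `normal`, `binormal`, and logical `flagged`.
#' @export
compute_frenet_frame <- function(c, kappa_min = 1e-8) {
  h <- check_uniform(c, min_points = 5)
  p <- as_points(c)
  d1 <- deriv1(p, h)
  d2 <- deriv2(p, h)
  speed <- row_norms(d1)
  tangent <- d1 / speed
  cr <- cross_rows(d1, d2)
  curvature <- row_norms(cr) / speed^3
  # (r' x r'') x r' is orthogonal to r' and points toward the circle center.
  nvec <- cross_rows(cr, d1)
  nn <- row_norms(nvec)
  flagged <- curvature <= kappa_min | nn == 0
  nn[nn == 0] <- 1
  normal <- nvec / nn
  binormal <- cross_rows(tangent, normal)
  tibble::tibble(
    arclength = c$arclength, curvature = curvature,
    tangent = tangent, normal = normal, binormal = binormal,
    flagged = flagged
  )
}

#' Parallel-transport frame and curvature components
#'
#' Builds a minimally rotating (parallel-transport) orthonormal frame
#' `(T, E1, E2)` along the curve and expresses the curvature vector in it:
#' `T' = k1 E1 + k2 E2`. `E1` at the first point is the component of a fixed
#' reference direction (the global z-axis by default) orthogonal to the first
#' tangent; successive frames are propagated by the double-reflection method,
#' the standard minimal-twist discretization. The curvature vector is computed
#' as `(r' x r'') x r' / |r'|^4`, whose norm equals the scalar curvature
#' exactly, so `k1^2 + k2^2 = kappa^2` holds to frame orthonormality
#' precision. Unlike the Frenet frame, `E1`/`E2` stay stable through straight
#' segments, which is what makes the curvature-vector trajectory usable for
#' landmarking.
#'
#' @inheritParams compute_geometry
#' @param reference Reference direction used to seed `E1` at the first point.
#'   If it is near-parallel to the first tangent (within 1e-6), a fallback
#'   axis is used automatically (with a message).
#' @return A tibble with `arclength`, `curvature`, matrix columns `tangent`,
#'   `e1`, `e2`, and numeric `k1`, `k2` (1/mm).
#' @export
compute_parallel_transport <- function(c, reference = c(0, 0, 1)) {
  h <- check_uniform(c, min_points = 5)
  p <- as_points(c)
  d1 <- deriv1(p, h)
  d2 <- deriv2(p, h)
  speed <- row_norms(d1)
  tangent <- d1 / speed
  cr <- cross_rows(d1, d2)
  curv_vec <- cross_rows(cr, d1) / speed^4
  curvature <- row_norms(cr) / speed^3

  n <- nrow(p)
  e1 <- matrix(0, n, 3)
  t1 <- tangent[1, ]
  ref <- as.numeric(reference) / norm3(as.numeric(reference))
  proj <- ref - sum(ref * t1) * t1
  if (norm3(proj) < 1e-6) {
    for (axis in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      proj <- axis - sum(axis * t1) * t1
      if (norm3(proj) >= 1e-6) {
        rlang::inform("reference direction parallel to the first tangent; using a fallback axis")
        break
      }
    }
  }
  e1[1, ] <- proj / norm3(proj)
  # Double-reflection propagation of E1 along the tangent sequence.
  for (i in 1:(n - 1)) {
    v1 <- p[i + 1, ] - p[i, ]
    c1 <- sum(v1 * v1)
    eL <- e1[i, ] - (2 / c1) * sum(v1 * e1[i, ]) * v1
    tL <- tangent[i, ] - (2 / c1) * sum(v1 * tangent[i, ]) * v1
    v2 <- tangent[i + 1, ] - tL
    c2 <- sum(v2 * v2)
    if (c2 < 1e-30) {
      e1[i + 1, ] <- eL
    } else {
      e1[i + 1, ] <- eL - (2 / c2) * sum(v2 * eL) * v2
    }
    # Re-orthonormalize against accumulated rounding.
    e1[i + 1, ] <- e1[i + 1, ] - sum(e1[i + 1, ] * tangent[i + 1, ]) * tangent[i + 1, ]
    e1[i + 1, ] <- e1[i + 1, ] / norm3(e1[i + 1, ])
  }
  e2 <- cross_rows(tangent, e1)
  k1 <- rowSums(curv_vec * e1)
  k2 <- rowSums(curv_vec * e2)
  tibble::tibble(
    arclength = c$arclength, curvature = curvature,
    tangent = tangent, e1 = e1, e2 = e2, k1 = k1, k2 = k2
  )
}

#' Export the geometric profile of a centerline as CSV
#'
#' Writes `(arclength, curvature, torsion, k1, k2)` per point, convenient for
#' plotting curvature/torsion profiles.
#'
#' @inheritParams compute_geometry
#' @param path Output CSV path.
#' @export
export_profile <- function(c, path) {
  geo <- compute_geometry(c)
  pt <- compute_parallel_transport(c)
  geo$k1 <- pt$k1
  geo$k2 <- pt$k2
  readr::write_csv(geo, path)
  invisible(geo)
}
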