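# Seeded, deterministic generators of analytic and ICA-like test centerlines.
# All generators emit points exactly on the designed geometry at uniform arc
# spacing, so closed-form curvature/torsion and designed bend boundaries serve
# as ground truth for the estimators and the landmarking algorithms.

#' Circular helix centerline
#'
#' Points on `(a cos u, a sin u, b u)` at uniform arc spacing. The closed-form
#' curvature and torsion, `a / (a^2 + b^2)` and `b / (a^2 + b^2)`, make the
#' helix the standard oracle for the discrete estimators. `b = 0` gives a
#' planar circle (zero torsion).
#'
#' @param a Radius (mm, > 0).
#' @param b Pitch parameter (mm per radian; may be negative for the mirrored,
#'   opposite-chirality helix).
#' @param n_turns Number of full turns (> 0).
#' @param spacing Arc-length spacing of the emitted points (mm).
#' @return A [centerline()].
#' @export
make_helix <- function(a, b = 0, n_turns = 1, spacing = 0.1) {
  if (a <= 0 || n_turns <= 0 || spacing <= 0) abort_config("invalid helix parameters")
  speed <- sqrt(a^2 + b^2)   # |dr/du|
  if (spacing >= 2 * pi * a) abort_config("`spacing` must be smaller than the circumference")
  L <- n_turns * 2 * pi * speed
  s <- seq(0, L, length.out = max(2L, ceiling(L / spacing) + 1L))
  u <- s / speed
  centerline(cbind(a * cos(u), a * sin(u), b * u))
}

#' Planar sinusoidal wave centerline
#'
#' `y = A sin(2 pi x / period)`, `z = 0`, emitted at uniform arc spacing. A
#' planar curve has exactly zero torsion, and the curvature peaks sit at the
#' crests and troughs (2 per period), which makes the wave the oracle for
#' torsion sign/zero tests and for peak counting. `amplitude = 0` degenerates
#' to a straight line.
#'
#' @param amplitude Amplitude A (mm, >= 0).
#' @param period Spatial period (mm, > 0).
#' @param n_periods Number of periods (> 0).
#' @param spacing Arc-length spacing (mm).
#' @return A [centerline()].
#' @export
make_planar_wave <- function(amplitude, period, n_periods = 2, spacing = 0.1) {
  if (amplitude < 0 || period <= 0 || n_periods <= 0 || spacing <= 0) {
    abort_config("invalid planar wave parameters")
  }
  x_end <- n_periods * period
  # March x at steps that produce uniform arc spacing.
  xs <- numeric(ceiling(4 * x_end * (1 + amplitude / period) / spacing))
  xs[1] <- 0
  i <- 1L
  k <- 2 * pi / period
  while (xs[i] < x_end) {
    slope <- amplitude * k * cos(k * xs[i])
    xs[i + 1L] <- xs[i] + spacing / sqrt(1 + slope^2)
    i <- i + 1L
  }
  xs <- xs[1:i]
  centerline(cbind(xs, amplitude * sin(k * xs), 0))
}

#' Specification of a synthetic siphon-like centerline
#'
#' Describes an ICA-siphon-scale test vessel built from constant-radius
#' circular arcs joined by short straight blends, with each successive bend
#' plane rotated about the local tangent. A proximal lead-in arc and a distal
#' lead-out arc flank the `n_bends` labeled bends so that every designed bend
#' has both a proximal and a distal plane-rotation joint (the joints carry the
#' torsion spikes and angle jumps the landmarking algorithms key on).
#' Arc radii, arc angles and rotations default to the canonical 4-bend siphon
#' whose inter-segment rotations (50, 70, 50, 120 degrees) exceed the ICA
#' threshold sequence (45, 60, 45, 110).
#'
#' @param n_bends Number of designed bends (>= 1).
#' @param bend_rotations_deg Rotation of each bend's plane about the local
#'   tangent, relative to the previous segment (length `n_bends`; the first
#'   entry is the rotation between the lead-in and bend 1).
#' @param bend_radii Arc radius per bend (mm, length `n_bends` or scalar).
#' @param bend_angles_deg Tangent turning angle per bend (degrees, length
#'   `n_bends` or scalar).
#' @param lead_radius,lead_angle_deg Geometry of the lead-in and lead-out arcs.
#' @param lead_out_rotation_deg Plane rotation between the last bend and the
#'   lead-out (creates the distal torsion joint).
#' @param blend_length Straight blend length between segments (mm).
#' @param spacing Arc-length spacing of emitted points (mm).
#' @param target_length Approximate total length (mm); arc angles are scaled
#'   so the siphon lands near the ICA scale (60-70 mm) unless `NULL`.
#' @param seed Seed recorded in the spec (generation itself is deterministic).
#' @return A `siphon_spec` list.
#' @export
siphon_spec <- function(n_bends = 4,
                        bend_rotations_deg = c(50, 70, 50, 120),
                        bend_radii = c(6, 4.5, 5.5, 4),
                        bend_angles_deg = c(95, 110, 100, 115),
                        lead_radius = 8, lead_angle_deg = 45,
                        lead_out_rotation_deg = 75,
                        blend_length = 3, spacing = 0.1,
                        target_length = 65, seed = 1L) {
  if (n_bends < 1) abort_config("`n_bends` must be >= 1")
  bend_radii <- rep_len(bend_radii, n_bends)
  bend_angles_deg <- rep_len(bend_angles_deg, n_bends)
  if (length(bend_rotations_deg) != n_bends) {
    abort_config("`bend_rotations_deg` must have one rotation per bend")
  }
  if (any(bend_radii <= 0) || any(bend_angles_deg <= 0) || blend_length <= 0 ||
      spacing <= 0 || lead_radius <= 0 || lead_angle_deg <= 0) {
    abort_config("siphon dimensions must be positive")
  }
  if (any(bend_angles_deg > 175) || lead_angle_deg > 175) {
    abort_config("arc angles above 175 degrees make the arcs overlap")
  }
  spec <- list(
    n_bends = as.integer(n_bends),
    bend_rotations_deg = bend_rotations_deg,
    bend_radii = bend_radii,
    bend_angles_deg = bend_angles_deg,
    lead_radius = lead_radius, lead_angle_deg = lead_angle_deg,
    lead_out_rotation_deg = lead_out_rotation_deg,
    blend_length = blend_length, spacing = spacing,
    target_length = target_length, seed = as.integer(seed)
  )
  structure(spec, class = "siphon_spec")
}

#' Random siphon specification
#'
#' Draws a valid [siphon_spec()] with 4-8 bends, radii 3.5-7 mm, arc angles
#' 80-130 degrees and plane rotations 25-150 degrees, mirroring the spread of
#' ICA siphon morphologies. Deterministic given the seed.
#'
#' @param seed Integer seed.
#' @return A `siphon_spec`.
#' @export
random_siphon_spec <- function(seed) {
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  n <- sample(4:8, 1)
  siphon_spec(
    n_bends = n,
    bend_rotations_deg = stats::runif(n, 25, 150),
    bend_radii = stats::runif(n, 3.5, 7),
    bend_angles_deg = stats::runif(n, 80, 130),
    lead_out_rotation_deg = stats::runif(1, 40, 140),
    seed = seed
  )
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Generate a siphon-like centerline with designed ground truth
#'
#' Builds the arc-and-blend curve described by a [siphon_spec()]: a lead-in
#' arc, `n_bends` circular arcs with rotated bend planes, and a lead-out arc,
#' all joined by straight blends. Because the construction is piecewise
#' analytic, the designed curvature-peak positions (arc midpoints), bend
#' boundaries (blend midpoints) and inter-segment rotations are exact and
#' returned as ground truth.
#'
#' @param spec A [siphon_spec()].
#' @return A list with elements `centerline` (a [centerline()]) and
#'   `ground_truth`, a list holding the per-segment table `segments`
#'   (`segment`, `type`, `start`, `end`, `peak`, `radius`, `rotation_deg`),
#'   the designed `interfaces` (blend midpoints flanking the labeled bends,
#'   mm) and `peaks` (labeled-bend curvature peak positions, mm).
#' @export
make_siphon <- function(spec = siphon_spec()) {
  stopifnot(inherits(spec, "siphon_spec"))
  radii <- c(spec$lead_radius, spec$bend_radii, spec$lead_radius)
  angles <- c(spec$lead_angle_deg, spec$bend_angles_deg, spec$lead_angle_deg) * pi / 180
  rotations <- c(0, spec$bend_rotations_deg, spec$lead_out_rotation_deg) * pi / 180
  types <- c("lead_in", rep("bend", spec$n_bends), "lead_out")
  n_seg <- length(radii)

  arc_lengths <- radii * angles
  if (!is.null(spec$target_length)) {
    scale_ang <- (spec$target_length - (n_seg - 1) * spec$blend_length) / sum(arc_lengths)
    if (scale_ang <= 0) abort_config("`target_length` too short for the requested segments")
    angles <- angles * scale_ang
    if (any(angles > 175 * pi / 180)) {
      abort_config("`target_length` requires arc angles above 175 degrees (overlapping arcs)")
    }
    arc_lengths <- radii * angles
  }

  # Walk the curve: position p, tangent t, in-plane normal m (toward each
  # arc's center). Plane rotations about t happen at blend midpoints.
  pieces <- list()
  seg_table <- vector("list", n_seg)
  p <- c(0, 0, 0); tg <- c(0, 0, 1); m <- c(1, 0, 0)
  s0 <- 0
  for (j in seq_len(n_seg)) {
    if (j > 1) {
      # Straight blend; the bend-plane rotation is applied about the tangent.
      pieces[[length(pieces) + 1L]] <- list(
        type = "line", p0 = p, dir = tg, len = spec$blend_length
      )
      p <- p + spec$blend_length * tg
      s0 <- s0 + spec$blend_length
      m <- rotate_about(m, tg, rotations[j])
    }
    R <- radii[j]; phi <- angles[j]
    center <- p + R * m
    pieces[[length(pieces) + 1L]] <- list(
      type = "arc", center = center, radius = R,
      u = -m, v = tg, phi = phi
    )
    seg_table[[j]] <- tibble::tibble(
      segment = j, type = types[j], start = s0, end = s0 + R * phi,
      peak = s0 + R * phi / 2, radius = R,
      rotation_deg = rotations[j] * 180 / pi
    )
    # End state of the arc.
    ev <- arc_eval(pieces[[length(pieces)]], R * phi)
    p <- ev$p; tg <- ev$t
    m <- (center - p); m <- m / norm3(m)
    s0 <- s0 + R * phi
  }

  total <- s0
  s_grid <- seq(0, total, by = spec$spacing)
  pts <- matrix(0, length(s_grid), 3)
  piece_len <- vapply(pieces, function(pc) if (pc$type == "line") pc$len else pc$radius * pc$phi, numeric(1))
  piece_end <- cumsum(piece_len)
  piece_start <- c(0, piece_end[-length(piece_end)])
  idx <- findInterval(s_grid, piece_end, left.open = TRUE) + 1L
  idx[idx > length(pieces)] <- length(pieces)
  for (i in seq_along(s_grid)) {
    pc <- pieces[[idx[i]]]
    ds <- s_grid[i] - piece_start[idx[i]]
    pts[i, ] <- if (pc$type == "line") pc$p0 + ds * pc$dir else arc_eval(pc, ds)$p
  }

  seg_table <- dplyr::bind_rows(seg_table)
  bend_rows <- seg_table[seg_table$type == "bend", ]
  interfaces <- (bend_rows$start - spec$blend_length / 2)
  interfaces <- c(interfaces, bend_rows$end[nrow(bend_rows)] + spec$blend_length / 2)
  list(
    centerline = centerline(pts),
    ground_truth = list(
      segments = seg_table,
      interfaces = interfaces,
      peaks = bend_rows$peak,
      rotations_deg = spec$bend_rotations_deg,
      total_length = total
    )
  )
}

# Evaluate a circular arc piece at arc-length ds from its start.
# The arc starts at center + R*u with start tangent v; u,v orthonormal.
arc_eval <- function(pc, ds) {
  ang <- ds / pc$radius
  p <- pc$center + pc$radius * (cos(ang) * pc$u + sin(ang) * pc$v)
  t <- -sin(ang) * pc$u + cos(ang) * pc$v
  list(p = p, t = t / norm3(t))
}

# Rodrigues rotation of vector v about unit axis k by angle ang.
rotate_about <- function(v, k, ang) {
  k <- k / norm3(k)
  v * cos(ang) + cross3(k, v) * sin(ang) + k * sum(k * v) * (1 - cos(ang))
}

#' Add seeded Gaussian jitter to interior centerline points
#'
#' Models operator/segmentation variability: independent zero-mean Gaussian
#' displacement with per-axis standard deviation `sigma` added to every
#' interior point (endpoints stay fixed). Deterministic given the seed; the
#' caller's random-number state is left untouched.
#'
#' @param c A [centerline()].
#' @param sigma Per-axis displacement SD (mm, >= 0).
#' @param seed Integer seed.
#' @return A jittered [centerline()].
#' @export
add_noise <- function(c, sigma, seed = 1L) {
  if (sigma < 0) abort_config("`sigma` must be >= 0")
  if (sigma == 0) return(c)
  old <- .Random.seed_exists()
  on.exit(restore_seed(old), add = TRUE)
  set.seed(seed)
  p <- as_points(c)
  n <- nrow(p)
  noise <- matrix(stats::rnorm(3 * n, sd = sigma), n, 3)
  noise[1, ] <- 0
  noise[n, ] <- 0
  centerline(p + noise, proximal_first = is_proximal_first(c))
}
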