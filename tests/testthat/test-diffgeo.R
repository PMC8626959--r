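# Closed-form oracles: a circular helix (a cos u, a sin u, b u) has
# kappa = a/(a^2+b^2), tau = b/(a^2+b^2), and binormal z-component
# a/sqrt(a^2+b^2); a circle of radius R has kappa = 1/R; planar curves have
# exactly zero torsion.

test_that("curvature matches the circle and straight-line closed forms", {
  circ <- make_helix(a = 5, b = 0, n_turns = 1, spacing = 0.1)
  g <- compute_geometry(circ)
  expect_lt(max(abs(g$curvature - 0.2)) / 0.2, 0.005)
  line <- centerline(cbind(seq(0, 10, 0.1), 0, 0))
  expect_lt(max(compute_curvature(line)$curvature), 1e-9)
})

test_that("curvature and torsion match the helix closed forms within 0.5%", {
  h <- helix_10_3()
  g <- compute_geometry(h)
  i <- interior(h)
  expect_lt(max(abs(g$curvature[i] - 10 / 109)) * 109 / 10, 0.005)
  expect_lt(max(abs(g$torsion[i] - 3 / 109)) * 109 / 3, 0.005)
})

test_that("planar curves have zero torsion and mirrored helices negated torsion", {
  w <- make_planar_wave(5, 20, 2, 0.1)
  g <- compute_geometry(w)
  expect_lt(max(abs(g$torsion)), 1e-6 * max(g$curvature))
  h <- helix_10_3()
  hm <- make_helix(a = 10, b = -3, n_turns = 2, spacing = 0.1)
  expect_equal(compute_geometry(hm)$torsion, -compute_geometry(h)$torsion,
               tolerance = 1e-9)
})

test_that("geometry requires enough uniformly spaced points", {
  irregular <- centerline(cbind(c(0, 1, 1.5, 3, 3.2, 5, 7, 7.5), 0, 0))
  expect_error(compute_geometry(irregular), class = "bendmark_config_error")
  expect_error(compute_geometry(centerline(cbind(c(0, 1, 2), 0, 0))),
               class = "bendmark_config_error")
})

test_that("the Frenet frame is orthonormal with N toward the circle center", {
  circ <- make_helix(a = 5, b = 0, n_turns = 1, spacing = 0.1)
  fr <- compute_frenet_frame(circ)
  # N must point from each point toward the origin (circle center).
  to_center <- -as_points(circ) / 5
  expect_lt(max(abs(fr$normal - to_center)), 1e-4)
  h <- helix_10_3()
  fh <- compute_frenet_frame(h)
  for (pair in list(c("tangent", "normal"), c("tangent", "binormal"),
                    c("normal", "binormal"))) {
    expect_lt(max(abs(rowSums(fh[[pair[1]]] * fh[[pair[2]]]))), 1e-6)
  }
  for (v in c("tangent", "normal", "binormal")) {
    expect_lt(max(abs(sqrt(rowSums(fh[[v]]^2)) - 1)), 1e-6)
  }
  # Binormal z-component is constant at a/sqrt(a^2+b^2) for the helix.
  i <- interior(h)
  expect_lt(max(abs(fh$binormal[i, 3] - 10 / sqrt(109))) * sqrt(109) / 10, 0.005)
  expect_lt(diff(range(fh$binormal[i, 3])), 1e-4)
})

test_that("straight regions are flagged in the Frenet frame", {
  line <- centerline(cbind(seq(0, 10, 0.1), 0, 0))
  fr <- compute_frenet_frame(line)
  expect_true(all(fr$flagged))
})

test_that("parallel-transport frames are orthonormal and satisfy k1^2+k2^2 = kappa^2", {
  for (cl in list(helix_10_3(), canonical_siphon()$centerline)) {
    cp <- resample_centerline(cl, 0.1)
    pt <- compute_parallel_transport(cp)
    expect_lt(max(abs(rowSums(pt$tangent * pt$e1))), 1e-6)
    expect_lt(max(abs(rowSums(pt$tangent * pt$e2))), 1e-6)
    expect_lt(max(abs(rowSums(pt$e1 * pt$e2))), 1e-6)
    expect_lt(max(abs(sqrt(rowSums(pt$e1^2)) - 1)), 1e-6)
    ok <- pt$curvature > 1e-6
    expect_lt(max(abs(pt$k1[ok]^2 + pt$k2[ok]^2 - pt$curvature[ok]^2) /
                    pt$curvature[ok]^2), 1e-6)
    # The parallel-transport curvature magnitude agrees with the
    # Frenet/profile estimator.
    geo <- compute_geometry(cp)
    expect_lt(max(abs(pt$curvature - geo$curvature) / pmax(geo$curvature, 1e-3)), 1e-6)
  }
})

test_that("a reference direction parallel to the first tangent falls back automatically", {
  # Straight lead along +z (the default reference direction) into a bend.
  lead <- cbind(0, 0, seq(0, 2, by = 0.1))
  u <- seq(0.02, pi / 2, by = 0.02)
  arc <- cbind(0, 5 - 5 * cos(u), 2 + 5 * sin(u))
  cl <- centerline(rbind(lead, arc))
  expect_message(compute_parallel_transport(cl), "fallback")
})

test_that("the curvature-vector direction advances at the torsion rate on a helix", {
  h <- helix_10_3()
  pt <- compute_parallel_transport(resample_centerline(h, 0.1))
  tr <- curvature_vector_trace(pt)
  i <- interior(h)
  slope <- stats::coef(stats::lm(tr$theta[i] ~ tr$arclength[i]))[[2]]
  expect_lt(abs(slope - 3 / 109) * 109 / 3, 0.01)
})

test_that("theta is constant on a single planar bend and steps by ~180 deg at an inflection", {
  cbend <- make_planar_wave(8, 60, 0.5, 0.1)  # half period: one bend, no inflection
  trc <- curvature_vector_trace(compute_parallel_transport(cbend))
  i <- interior(cbend, 20)
  expect_lt(diff(range(trc$theta[i])) * 180 / pi, 1)
  scurve <- make_planar_wave(8, 30, 1, 0.1)   # full period: crest then trough
  pts <- compute_parallel_transport(scurve)
  trs <- curvature_vector_trace(pts)
  kp <- find_peaks(pts$curvature, 0.05, exclude_ends = 2)
  expect_equal(nrow(kp), 2)
  jump <- abs(diff(trs$theta[kp$index])) * 180 / pi
  expect_equal(jump, 180, tolerance = 0.02)
})

test_that("kappa and tau are scale-covariant and rigid-motion invariant", {
  sip <- resample_centerline(canonical_siphon()$centerline, 0.1)
  g <- compute_geometry(sip)
  scaled <- centerline(as_points(sip) * 2)
  gs <- compute_geometry(scaled)
  # Torsion is compared where the curve is genuinely curved; on straight
  # blends it is a 0/0 ratio whose floating-point noise is not covariant.
  curved <- g$curvature > 1e-3
  expect_equal(gs$curvature, g$curvature / 2, tolerance = 1e-9)
  expect_equal(gs$torsion[curved], g$torsion[curved] / 2, tolerance = 1e-9)
  ang <- c(0.3, 1.1, 2.2)
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]), 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  moved <- transform_centerline(sip, rotation = rz %*% rx, translation = c(4, -7, 13))
  gm <- compute_geometry(moved)
  expect_equal(gm$curvature, g$curvature, tolerance = 1e-9)
  expect_equal(gm$torsion[curved], g$torsion[curved], tolerance = 1e-9)
  ptm <- compute_parallel_transport(moved)
  pt <- compute_parallel_transport(sip)
  expect_equal(ptm$k1^2 + ptm$k2^2, pt$k1^2 + pt$k2^2, tolerance = 1e-9)
})

test_that("reversal keeps kappa and flips the sign of tau", {
  sip <- resample_centerline(canonical_siphon()$centerline, 0.1)
  g <- compute_geometry(sip)
  gr <- compute_geometry(reverse_centerline(sip))
  i <- interior(sip)
  i_curved <- i[g$curvature[i] > 1e-3]  # torsion is defined only off the straight blends
  expect_lt(max(abs(g$curvature[i] - rev(gr$curvature)[i])), 1e-9)
  expect_lt(max(abs(g$torsion[i_curved] + rev(gr$torsion)[i_curved])), 1e-6)
})

test_that("export_profile writes the per-point geometry table", {
  f <- withr::local_tempfile(fileext = ".csv")
  h <- make_helix(5, 1, 1, 0.1)
  export_profile(h, f)
  tab <- readr::read_csv(f, show_col_types = FALSE)
  expect_named(tab, c("arclength", "curvature", "torsion", "k1", "k2"))
  expect_equal(nrow(tab), nrow(h))
})
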