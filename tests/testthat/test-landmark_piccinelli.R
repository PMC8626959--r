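test_that("bends span nearest enclosing torsion peaks on a designed profile", {
  # Profile positions in mm with 1 mm sampling: curvature peaks at 10, 30, 50;
  # |torsion| peaks at 5, 20, 40, 60.
  arcl <- 0:65
  kappa <- 0.1 +
    0.5 * exp(-(arcl - 10)^2 / 8) +
    0.6 * exp(-(arcl - 30)^2 / 8) +
    0.4 * exp(-(arcl - 50)^2 / 8)
  b <- pair_curvature_bends(
    kappa_peaks = c(11L, 31L, 51L),   # 1-based indices of s = 10, 30, 50
    tau_peaks = c(6L, 21L, 41L, 61L), # s = 5, 20, 40, 60
    curvature = kappa, arclengths = arcl
  )
  expect_equal(b$start_arclength, c(5, 20, 40))
  expect_equal(b$end_arclength, c(20, 40, 60))
  expect_equal(b$peak_arclength, c(10, 30, 50))
})

test_that("curvature peaks without both flanking torsion peaks yield no bend", {
  arcl <- 0:65
  kappa <- rep(0.1, 66)
  # Curvature peak proximal to the first torsion peak: no proximal flank.
  b <- pair_curvature_bends(3L, c(10L, 30L), kappa, arcl)
  expect_equal(nrow(b), 0)
  # Fewer than two torsion peaks can never enclose anything.
  expect_equal(nrow(pair_curvature_bends(c(10L, 20L), 15L, kappa, arcl)), 0)
})

test_that("curvature peaks sharing a torsion interval split at the curvature minimum", {
  arcl <- 0:65
  kappa <- 0.1 + 0.5 * exp(-(arcl - 20)^2 / 8) + 0.5 * exp(-(arcl - 40)^2 / 8)
  b <- pair_curvature_bends(c(21L, 41L), c(6L, 61L), kappa, arcl)
  expect_equal(nrow(b), 2)
  # Boundary at the curvature minimum between the peaks (s = 30 by symmetry).
  expect_equal(b$end_arclength[1], b$start_arclength[2])
  expect_equal(b$end_arclength[1], 30, tolerance = 1)
})

test_that("bend assignment matches the exhaustive pairing oracle on random profiles", {
  for (seed in 1:20) {
    pr <- random_profile(seed)
    got <- pair_curvature_bends(pr$k_peaks, pr$t_peaks, pr$kappa, pr$arclengths)
    want <- oracle_pairing(pr$k_peaks, pr$t_peaks, pr$kappa, pr$arclengths)
    expect_equal(got$start_arclength, want$start, info = paste("seed", seed))
    expect_equal(got$peak_arclength, want$peak, info = paste("seed", seed))
    expect_equal(got$end_arclength, want$end, info = paste("seed", seed))
  }
})

test_that("returned bends are ordered, non-overlapping, one curvature peak each", {
  res <- canonical_piccinelli()
  b <- tidy(res)
  expect_gt(nrow(b), 0)
  expect_true(all(b$start_arclength <= b$peak_arclength))
  expect_true(all(b$peak_arclength <= b$end_arclength))
  expect_true(!is.unsorted(b$start_arclength))
  expect_true(all(b$start_arclength[-1] >= b$end_arclength[-nrow(b)] - 1e-9))
  expect_equal(b$length, b$end_arclength - b$start_arclength)
  # Interfaces coincide with |torsion| peaks or inter-peak curvature minima.
  geo <- compute_geometry(res$centerline)
  tp <- geo$arclength[find_peaks(abs(geo$torsion), 0.05, exclude_ends = 2)$index]
  on_tau <- vapply(res$interfaces, function(x) min(abs(tp - x)) < 1e-9, logical(1))
  expect_true(all(on_tau | res$interfaces %in% c(b$start_arclength, b$end_arclength)))
})

test_that("the designed siphon recovers one geometric bend per designed bend", {
  res <- canonical_piccinelli()
  expect_equal(nrow(res$bends), 4)
  gt <- canonical_siphon()$ground_truth
  expect_lt(max(abs(sort(res$bends$peak_arclength) - gt$peaks)), 1.5)
  # Also for a different bend count with distinct torsion-spike joints.
  sp3 <- siphon_spec(n_bends = 3, bend_rotations_deg = c(60, 90, 75),
                     bend_radii = c(6, 4.5, 5), bend_angles_deg = c(100, 110, 105))
  r3 <- landmark_piccinelli(make_siphon(sp3)$centerline)
  expect_equal(nrow(r3$bends), 3)
})

test_that("a centerline without torsion extrema yields an empty result with a warning", {
  h <- make_helix(a = 10, b = 3, n_turns = 1.5, spacing = 0.05)
  expect_warning(
    res <- landmark_piccinelli(h, piccinelli_config(preprocess_config(lam = 0, n_iter = 0))),
    "torsion"
  )
  expect_equal(nrow(res$bends), 0)
  expect_false(res$failed)
})

test_that("bend count does not increase with coarser resampling on a fixed noisy model", {
  noisy <- add_noise(canonical_siphon()$centerline, 0.1, seed = 5)
  counts <- vapply(c(0.05, 0.1, 0.25), function(r) {
    nrow(suppressWarnings(
      landmark_piccinelli(noisy, piccinelli_config(preprocess_config(r = r)))
    )$bends)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})
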