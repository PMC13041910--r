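test_that("circle ground truth has the exact analytic properties", {
  ct <- fx_circle10()
  expect_equal(ct$writhe_truth, 0)
  expect_length(ct$apex_positions, 0)
  kappa <- curvature_profile(ct$curve)
  expect_true(all(abs(kappa - 0.1) < 1e-6))
  d <- sqrt(rowSums(sweep(curve_points(ct$curve), 2L, c(0, 0, 0))^2))
  expect_true(all(abs(d - 10) < 1e-9))
  expect_equal(radius_of_gyration(fx_circle100()$curve)$rg, 100,
               tolerance = 1e-6)
  expect_error(make_circle(-1), "positive")
  expect_error(make_circle(10, n_points = 4), "at least 8")
})

test_that("interwound plectoneme writhe matches the fine-discretization oracle", {
  p <- fx_plectoneme()
  # oracle = Gauss double integral on the 0.25 nm resampling (stored truth)
  expect_gte(p$writhe_truth, -6.8)
  expect_lte(p$writhe_truth, -5.2)
  # near-planar racket: two straight strands with wide caps, no interwinding
  racket <- make_plectoneme(660, 0, 20, 20, seed = 1)
  expect_lt(abs(racket$writhe_truth), 0.2)
})

test_that("mirror reflection negates plectoneme writhe exactly", {
  p <- fx_plectoneme()
  wr <- compute_writhe(p$curve)
  expect_equal(compute_writhe(reflect_curve(p$curve)), -wr, tolerance = 1e-12)
})

test_that("generators are deterministic and self-avoiding", {
  a <- make_plectoneme(660, -6, 8, 5, seed = 42)
  b <- make_plectoneme(660, -6, 8, 5, seed = 42)
  expect_identical(a$curve$points, b$curve$points)
  c_ <- make_plectoneme(660, -6, 8, 5, seed = 43)
  expect_false(identical(a$curve$points, c_$curve$points))
  pts <- curve_points(a$curve)
  expect_gt(.min_nonadjacent_dist_cpp(pts, 3L), 2)
})

test_that("infeasible plectoneme geometry is rejected with explanation", {
  expect_error(make_plectoneme(100, -20, 8, 5, seed = 1), "infeasible")
  expect_error(make_branched_plectoneme(200, c(-6, -6, -6), 8, 5, seed = 1),
               "infeasible")
})

test_that("branched generator builds the requested arms and apices", {
  b <- fx_branched3()
  expect_identical(b$branch_count, 3L)
  expect_length(b$apex_positions, 3)
  expect_setequal(unique(b$arm_label), 1:3)
  expect_error(make_branched_plectoneme(660, numeric(0)), "1 and 5")
})

test_that("composite branched writhe is consistent with per-arm closures", {
  b <- fx_branched2()
  # oracle: close each arm's points through a straight chord and sum
  per_arm <- vapply(1:2, function(arm) {
    pts <- curve_points(b$curve)[b$arm_label == arm, , drop = FALSE]
    compute_writhe(closed_curve(pts, validate = FALSE), touch_tol = 0)
  }, numeric(1))
  expect_lt(abs(b$writhe_truth - sum(per_arm)), 0.8)
})

test_that("single-arm branched request delegates to the unbranched generator", {
  a <- make_branched_plectoneme(660, -6, 8, 5, seed = 9)
  b <- make_plectoneme(660, -6, 8, 5, seed = 9)
  expect_identical(a$curve$points, b$curve$points)
})

test_that("noiseless rendering puts maximum density on the curve", {
  ct <- make_circle(40, 150)
  vol <- render_density(ct, voxel_size = 1.5, duplex_sigma = 2, noise_sd = 0)
  d <- dim(vol$values)
  peak <- arrayInd(which.max(vol$values), d)
  ctr <- vol$origin + (as.numeric(peak) - 0.5) * vol$voxel_size
  dmin <- sqrt(min(rowSums(sweep(curve_points(ct$curve), 2L, ctr)^2)))
  expect_lte(dmin, vol$voxel_size)
})

test_that("rendering is seed-deterministic and mass-linear in curve points", {
  p <- fx_plectoneme()
  v1 <- render_density(p, 1.5, 2, noise_sd = 0.3, seed = 5)
  v2 <- render_density(p, 1.5, 2, noise_sd = 0.3, seed = 5)
  expect_identical(v1$values, v2$values)
  v3 <- render_density(p, 1.5, 2, noise_sd = 0.3, seed = 6)
  expect_false(identical(v1$values, v3$values))
  # integrated density = n_points * analytic kernel mass, within 1%
  v0 <- render_density(p, 1.5, 2, noise_sd = 0)
  mass <- sum(v0$values) * v0$voxel_size^3
  expected <- length(p$curve) * (2 * pi)^(3 / 2) * 2^3
  expect_lt(abs(mass - expected) / expected, 0.01)
})

test_that("coarse voxels raise an undersampling warning recorded in provenance", {
  p <- fx_plectoneme()
  expect_warning(v <- render_density(p, voxel_size = 4, duplex_sigma = 2),
                 "undersampled")
  expect_true(length(v$provenance$warnings) > 0)
})

test_that("particle placement follows the construction geometry", {
  p <- fx_plectoneme()
  spacing <- p$curve$spacing
  on_curve <- place_particles(p, bp_positions = c(100, 700, 1500),
                              offset = 0)$centers
  d0 <- vapply(seq_len(nrow(on_curve)), function(i) {
    sqrt(min(rowSums(sweep(curve_points(p$curve), 2L,
                           as.numeric(on_curve[i, c("x", "y", "z")]))^2)))
  }, numeric(1))
  expect_true(all(d0 <= spacing / 2))
  off <- place_particles(p, bp_positions = c(100, 700, 1500),
                         offset = 5)$centers
  d5 <- vapply(seq_len(nrow(off)), function(i) {
    sqrt(min(rowSums(sweep(curve_points(p$curve), 2L,
                           as.numeric(off[i, c("x", "y", "z")]))^2)))
  }, numeric(1))
  expect_true(all(abs(d5 - 5) <= spacing / 2))
  expect_error(place_particles(p, bp_positions = p$total_bp + 5), "bp")
  expect_error(place_particles(p, bp_positions = 10, offset = -1), "offset")
})

test_that("opposite-bp particles sit half a plasmid apart in angle", {
  p <- fx_plectoneme()
  placed <- place_particles(p, bp_positions = c(0, p$total_bp / 2))$centers
  sep <- pairwise_angular_separation(placed$bp, p$total_bp)
  expect_equal(sep$radians, pi, tolerance = 1e-9)
})
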