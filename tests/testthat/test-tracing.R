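vol_cache <- new.env(parent = emptyenv())

noiseless_volume <- function() {
  if (is.null(vol_cache$p)) {
    vol_cache$p <- render_density(fx_plectoneme(), voxel_size = 1.5,
                                  duplex_sigma = 2, noise_sd = 0)
  }
  vol_cache$p
}

test_that("spine of a rendered ring is a single loop of the right length", {
  ring <- make_circle(100, 400)
  vol <- render_density(ring, voxel_size = 2, duplex_sigma = 2, noise_sd = 0)
  sp <- compute_spine(vol)
  expect_identical(spine_junctions(sp), 0L)
  expect_lt(abs(spine_length(sp) - 2 * pi * 100) / (2 * pi * 100), 0.10)
  # the loop closes: one cycle path
  expect_identical(length(sp$paths), 1L)
  expect_true(sp$paths[[1]][1] == sp$paths[[1]][length(sp$paths[[1]])])
})

test_that("spine of an unbranched plectoneme is a junction-free path", {
  sp <- compute_spine(noiseless_volume())
  expect_identical(spine_junctions(sp), 0L)
  expect_identical(length(sp$paths), 1L)
})

test_that("empty or fragmented volumes raise particle-isolation errors", {
  empty <- density_volume(array(0, c(20, 20, 20)), voxel_size = 2)
  expect_error(compute_spine(empty), "particle isolation")
  two <- array(0, c(40, 20, 20))
  two[5:10, 8:12, 8:12] <- 1
  two[30:35, 8:12, 8:12] <- 1
  expect_error(compute_spine(density_volume(two, voxel_size = 2)),
               "particle isolation")
})

test_that("duplex centers recover two parallel rods at their spacing", {
  # two straight rods 10 nm apart, spine along the midline
  z <- seq(5, 95, by = 1)
  rodA <- cbind(30, 25, z)
  rodB <- cbind(40, 25, z)
  truthless <- closed_curve(rbind(rodA, rodB[rev(seq_len(nrow(rodB))), ]),
                            validate = FALSE)
  dims <- c(48, 34, 67)
  vol <- density_volume(
    .splat_gaussians_cpp(array(0, dims), as.integer(dims), c(0, 0, 0), 1.5,
                         rbind(rodA, rodB), 2, 1),
    voxel_size = 1.5)
  spine <- structure(list(
    points = cbind(35, 25, seq(15, 85, by = 2)),
    edges = cbind(seq_len(35), c(seq_len(35)[-1], 35)),
    degree = c(1L, rep(2L, 34L)),
    paths = list(seq_len(36)[-36]),
    voxel_size = 1.5), class = "spine_line")
  spine$paths <- list(seq_len(36 - 1L))
  cs <- sample_duplex_centers(vol, spine, end_extension = 0)
  ok <- !cs$degenerate & !cs$empty
  sep <- sqrt((cs$x1 - cs$x2)^2 + (cs$y1 - cs$y2)^2 + (cs$z1 - cs$z2)^2)[ok]
  expect_true(all(abs(sep - 10) <= 1.5))
})

test_that("duplex centers on a plectoneme sit on the strands", {
  vol <- noiseless_volume()
  sp <- compute_spine(vol)
  cs <- sample_duplex_centers(vol, sp)
  pts <- curve_points(fx_plectoneme()$curve)
  ok <- which(!cs$degenerate & !cs$empty)
  centers <- rbind(as.matrix(cs[ok, c("x1", "y1", "z1")]),
                   as.matrix(cs[ok, c("x2", "y2", "z2")]))
  d <- vapply(seq_len(nrow(centers)), function(i) {
    sqrt(min(rowSums(sweep(pts, 2L, centers[i, ])^2)))
  }, numeric(1))
  expect_lt(sqrt(mean(d^2)), 2)
})

test_that("greedy linking recovers a shuffled circle ordering", {
  theta <- seq(0, 2 * pi, length.out = 61)[-61]
  pts <- cbind(50 * cos(theta), 50 * sin(theta), 0)
  set.seed(4)
  shuffled <- pts[sample(nrow(pts)), ]
  tour <- link_centers(shuffled, max_gap = 12)
  expect_identical(nrow(tour), nrow(pts))
  # correct cyclic order: consecutive tour points are circle neighbours
  ang <- atan2(tour[, 2], tour[, 1])
  d_ang <- diff(c(ang, ang[1]))
  d_ang <- (d_ang + pi) %% (2 * pi) - pi
  expect_true(all(abs(abs(d_ang) - 2 * pi / 60) < 1e-6))
  # gap bridging: delete 3 consecutive points, tour still closes
  gappy <- pts[-(10:12), ]
  set.seed(5)
  gappy <- gappy[sample(nrow(gappy)), ]
  tour2 <- link_centers(gappy, max_gap = 21)
  expect_identical(nrow(tour2), nrow(pts) - 3L)
})

test_that("structured linking yields a closed tour over both strands", {
  vol <- noiseless_volume()
  sp <- compute_spine(vol)
  cs <- sample_duplex_centers(vol, sp)
  tour <- link_centers(cs, volume = vol)
  expect_identical(nrow(attr(tour, "unresolved")), 0L)
  # closed: last point near first
  expect_lt(sqrt(sum((tour[1, ] - tour[nrow(tour), ])^2)), 25)
  # the tour length approximates the full contour (both strands + caps)
  len <- sum(sqrt(rowSums((tour[c(2:nrow(tour), 1), ] - tour)^2)))
  expect_lt(abs(len - 662) / 662, 0.1)
})

test_that("refine_curve resamples at the target spacing and is idempotent", {
  vol <- noiseless_volume()
  sp <- compute_spine(vol)
  tour <- link_centers(sample_duplex_centers(vol, sp), volume = vol)
  cv <- refine_curve(tour, target_spacing = 2)
  seg <- sqrt(rowSums((curve_points(cv)[c(2:length(cv), 1), ] -
                         curve_points(cv))^2))
  expect_true(all(abs(seg - 2) <= 0.2))
  # circle: smoothing cannot create curvature structure
  ring <- resample_curve(fx_circle10()$curve, spacing = 1)
  rv <- refine_curve(curve_points(ring), target_spacing = 2)
  kap <- as.numeric(curvature_profile(rv))
  expect_lt((max(kap) - min(kap)) / mean(kap), 0.05)
  # idempotence: a second refinement barely moves the points
  cv2 <- refine_curve(cv, target_spacing = 2)
  n <- min(length(cv), length(cv2))
  rms <- sqrt(mean(rowSums((curve_points(cv)[seq_len(n), ] -
                              curve_points(cv2)[seq_len(n), ])^2)))
  expect_lt(rms, 0.2)
  expect_error(refine_curve(tour[1:5, ]), ">= 8")
})

test_that("full tracing recovers contour and writhe of a noiseless particle", {
  p <- fx_plectoneme()
  cv <- trace_plasmid(noiseless_volume())
  expect_lt(abs(contour_length(cv) - p$contour_length) / p$contour_length,
            0.05)
  expect_lt(abs(compute_writhe(cv) - p$writhe_truth), 1.0)
  # determinism: identical volume and config give bit-identical curves
  cv2 <- trace_plasmid(noiseless_volume())
  expect_identical(cv$points, cv2$points)
})

test_that("tracing is equivariant under axis-aligned rotation", {
  vol <- noiseless_volume()
  cv <- trace_plasmid(vol)
  # rotate the volume 90 degrees about z: (x, y) -> (-y, x)
  d <- dim(vol$values)
  rot <- aperm(vol$values, c(2, 1, 3))[d[2]:1, , , drop = FALSE]
  vol_rot <- density_volume(rot, voxel_size = vol$voxel_size,
                            origin = c(-(vol$origin[2] +
                                           d[2] * vol$voxel_size),
                                       vol$origin[1], vol$origin[3]))
  cv_rot <- trace_plasmid(vol_rot)
  back <- cbind(cv_rot$points[, 2], -cv_rot$points[, 1], cv_rot$points[, 3])
  # compare as point sets (the tour may start elsewhere / reverse)
  d_ab <- vapply(seq_len(nrow(back)), function(i) {
    sqrt(min(rowSums(sweep(cv$points, 2L, back[i, ])^2)))
  }, numeric(1))
  expect_lt(max(d_ab), 2 * vol$voxel_size)
  expect_equal(compute_writhe(cv_rot), compute_writhe(cv), tolerance = 0.05)
})
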