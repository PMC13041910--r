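test_that("binding assignment honours the distance threshold strictly", {
  p <- fx_plectoneme()
  pts <- curve_points(p$curve)
  obs <- data.frame(kind = c("RNAP", "RNAP", "RNAP"),
                    x = c(pts[10, 1] + 0.5, pts[50, 1] + 5, pts[80, 1]),
                    y = c(pts[10, 2], pts[50, 2], pts[80, 2]),
                    z = c(pts[10, 3], pts[50, 3], pts[80, 3]))
  b <- assign_binding(obs, p$curve) # default 1 nm
  expect_identical(b$bound, c(TRUE, FALSE, TRUE))
  expect_identical(b$nearest_index[1], 10L)
  # blob-rendered synthetic particles at offset 5 need a matched threshold
  placed <- place_particles(p, bp_positions = c(200, 900, 1600), offset = 5)
  obs2 <- data.frame(x = placed$centers$x, y = placed$centers$y,
                     z = placed$centers$z)
  b2 <- assign_binding(obs2, p$curve, distance_threshold = 8)
  expect_true(all(b2$bound))
})

test_that("binding is invariant under joint rigid motion", {
  p <- fx_plectoneme()
  pts <- curve_points(p$curve)
  obs <- data.frame(x = pts[c(5, 60), 1] + 0.4, y = pts[c(5, 60), 2],
                    z = pts[c(5, 60), 3])
  b0 <- assign_binding(obs, p$curve)
  R <- random_rotation(7)
  moved_curve <- transform_curve(p$curve, rotation = R,
                                 translation = c(11, -3, 40))
  moved_obs <- as.data.frame(sweep(as.matrix(obs) %*% t(R), 2L,
                                   c(11, -3, 40), "+"))
  names(moved_obs) <- c("x", "y", "z")
  b1 <- assign_binding(moved_obs, moved_curve)
  expect_identical(b1$bound, b0$bound)
  expect_identical(b1$nearest_index, b0$nearest_index)
})

test_that("apex proximity classes follow the arc-window rule", {
  p <- fx_plectoneme()
  ap <- detect_apices(p$curve)
  pts <- curve_points(p$curve)
  arc <- arc_lengths(p$curve)
  at_apex <- ap$index[1]
  # index at twice the window from any apex
  far <- which.max(vapply(seq_len(nrow(pts)), function(i) {
    min(circ <- pmin(abs(arc[i] - ap$arc), contour_length(p$curve) -
                       abs(arc[i] - ap$arc)))
  }, numeric(1)))
  obs <- data.frame(x = pts[c(at_apex, far), 1], y = pts[c(at_apex, far), 2],
                    z = pts[c(at_apex, far), 3])
  b <- assign_binding(obs, p$curve)
  cls <- classify_apex_proximity(b, ap, p$curve, apex_window = 20)
  expect_identical(cls$apical_class, c("apical", "off_apex"))
  # unbound input errors unless allowed
  obs$x[1] <- obs$x[1] + 50
  bu <- assign_binding(obs, p$curve)
  expect_error(classify_apex_proximity(bu, ap, p$curve), "unbound")
})

test_that("planted apical and mid-arm particles are classified exactly", {
  p <- fx_plectoneme()
  ap <- detect_apices(p$curve)
  arc <- arc_lengths(p$curve)
  total_bp <- p$total_bp
  L <- p$contour_length
  apex_bp <- round(p$apex_positions / L * total_bp)
  mid_bp <- round(((p$apex_positions[1] + p$apex_positions[2]) / 2) /
                    L * total_bp)
  placed <- place_particles(p, bp_positions = c(apex_bp, mid_bp), offset = 0)
  obs <- data.frame(x = placed$centers$x, y = placed$centers$y,
                    z = placed$centers$z)
  b <- assign_binding(obs, p$curve, distance_threshold = 2)
  cls <- classify_apex_proximity(b, ap, p$curve, apex_window = 20)
  expect_identical(cls$apical_class, c("apical", "apical", "off_apex"))
})

test_that("bp mapping anchors at the fiducial and wraps consistently", {
  p <- fx_plectoneme()
  pts <- curve_points(p$curve)
  fid_idx <- 25L
  obs <- data.frame(x = pts[fid_idx, 1] + 0.3, y = pts[fid_idx, 2],
                    z = pts[fid_idx, 3])
  fid <- assign_binding(obs, p$curve)
  bp <- map_bp_coordinates(p$curve, fid, total_bp = 1950, fiducial_bp = 1090,
                           direction = "forward")
  expect_equal(bp[fid_idx], 1090, tolerance = 1e-9)
  # half a loop forward: (1090 + 975) mod 1950 = 115
  arc <- arc_lengths(p$curve)
  total <- contour_length(p$curve)
  half <- which.min(abs(((arc - arc[fid_idx]) %% total) - total / 2))
  expect_lt(abs(bp[half] - 115), 1950 / length(p$curve) + 1e-9)
  # consecutive increments sum to total_bp exactly (modular consistency)
  inc <- diff(c(bp, bp[1])) %% 1950
  expect_equal(sum(inc), 1950, tolerance = 1e-6)
  # reverse direction mirrors the coordinate
  bp_rev <- map_bp_coordinates(p$curve, fid, direction = "reverse")
  expect_equal(bp_rev[fid_idx], 1090, tolerance = 1e-9)
  # unbound fiducial is rejected
  obs$x <- obs$x + 50
  expect_error(map_bp_coordinates(p$curve, assign_binding(obs, p$curve),
                                  direction = "forward"), "not bound")
})

test_that("angular separations are symmetric, bounded and complete", {
  sep <- pairwise_angular_separation(c(0, 1400), 2800)
  expect_equal(sep$radians, pi)
  # printed worked conversion: 2.7 rad on 2.8 kb is ~1.2 kbp
  bp_d <- 2.7 / (2 * pi) * 2800
  sep2 <- pairwise_angular_separation(c(100, 100 + bp_d), 2800)
  expect_equal(sep2$radians, 2.7, tolerance = 1e-9)
  expect_equal(round(sep2$bp_distance / 100) * 100, 1200)
  four <- pairwise_angular_separation(c(0, 700, 1400, 2100), 2800)
  expect_identical(nrow(four), 6L)
  expect_true(all(four$radians > 0 & four$radians <= pi + 1e-12))
  # invariant to relabeling
  sep_a <- sort(pairwise_angular_separation(c(5, 900, 2000), 2800)$radians)
  sep_b <- sort(pairwise_angular_separation(c(2000, 5, 900), 2800)$radians)
  expect_equal(sep_a, sep_b)
  expect_error(pairwise_angular_separation(5, 2800), "at least 2")
})

test_that("localization report aggregates planted fractions exactly", {
  p <- fx_plectoneme()
  ap <- detect_apices(p$curve)
  make_set <- function(bps, thresh = 2) {
    placed <- place_particles(p, bp_positions = bps, offset = 0)
    obs <- data.frame(x = placed$centers$x, y = placed$centers$y,
                      z = placed$centers$z)
    classify_apex_proximity(assign_binding(obs, p$curve, thresh), ap,
                            p$curve, apex_window = 20)
  }
  total_bp <- p$total_bp
  L <- p$contour_length
  apex_bp <- round(p$apex_positions / L * total_bp)
  mid_bp <- round(mean(p$apex_positions) / L * total_bp)
  sets <- list(make_set(apex_bp[1]),                 # 1 apical
               make_set(c(apex_bp[1], mid_bp)),      # apical + off-apex
               make_set(c(apex_bp[2], mid_bp)))      # apical + off-apex
  rep_ <- localization_report(sets)
  expect_identical(rep_$n_plasmids, 3L)
  expect_identical(rep_$n_bound, 5L)
  expect_equal(rep_$off_apex_fraction, 2 / 5)
  expect_equal(rep_$multi_particle_fraction, 2 / 3)
  # single apical particle: off-apex fraction 0
  solo <- localization_report(sets[1])
  expect_equal(solo$off_apex_fraction, 0)
  # empty input: empty report, no division by zero
  empty <- localization_report(list())
  expect_identical(empty$n_plasmids, 0L)
  expect_true(is.na(empty$off_apex_fraction))
})
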