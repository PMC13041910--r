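test_that("planar closed curves have zero writhe", {
  expect_lt(abs(compute_writhe(fx_circle10()$curve)), 1e-6)
  # irregular planar polygon, still planar
  set.seed(3)
  theta <- sort(stats::runif(60, 0, 2 * pi))
  r <- 20 + 5 * sin(3 * theta)
  planar <- closed_curve(cbind(r * cos(theta), r * sin(theta), 0))
  expect_lt(abs(compute_writhe(planar, touch_tol = 0)), 1e-6)
})

test_that("writhe is invariant under rigid motion and scale, odd under mirror", {
  p <- fx_plectoneme()
  wr <- compute_writhe(p$curve)
  for (seed in 1:3) {
    moved <- transform_curve(p$curve, rotation = random_rotation(seed),
                             translation = c(100, -40, 7) * seed,
                             scale = c(0.5, 1, 3.7)[seed])
    expect_lt(abs(compute_writhe(moved) - wr), 1e-9)
  }
  expect_equal(compute_writhe(reflect_curve(p$curve)), -wr,
               tolerance = 1e-12)
})

test_that("exact segment-pair writhe agrees with midpoint quadrature", {
  p <- fx_plectoneme()
  expect_equal(compute_writhe(p$curve), writhe_midpoint(p$curve),
               tolerance = 0.02)
  b <- fx_branched3()
  expect_equal(compute_writhe(b$curve), writhe_midpoint(b$curve),
               tolerance = 0.02)
})

test_that("writhe errors and warnings follow the contract", {
  expect_error(compute_writhe(matrix(rnorm(9), 3, 3)), ">= 4 points")
  # near-touching segments trigger a warning naming pair indices
  sq <- rbind(c(0, 0, 0), c(10, 0, 0), c(10, 10, 0), c(5, 10, 0.05),
              c(5, 0.02, 0.02), c(0, 10, 0))
  expect_warning(compute_writhe(closed_curve(sq)), "near-touching")
})

test_that("circumscribed-circle curvature matches closed forms", {
  kappa <- curvature_profile(resample_curve(fx_circle10()$curve, spacing = 2))
  expect_true(all(abs(kappa - 0.1) < 0.001))
  # collinear triple
  line3 <- closed_curve(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(1, 5, 0)))
  expect_equal(as.numeric(curvature_profile(line3))[2], 0)
  # circular helix: kappa = a / (a^2 + c^2), c = pitch / (2 pi)
  a <- 4; pitch <- 12; cc <- pitch / (2 * pi)
  t_ <- seq(0, 6 * pi, length.out = 400)
  helix <- cbind(a * cos(t_), a * sin(t_), cc * t_)
  closed <- closed_curve(rbind(helix, c(60, 0, mean(helix[, 3]))),
                         validate = FALSE)
  kap <- as.numeric(curvature_profile(closed))
  interior <- 10:380
  expect_true(all(abs(kap[interior] - a / (a^2 + cc^2)) <
                    0.02 * a / (a^2 + cc^2)))
  dup <- rbind(c(0, 0, 0), c(0, 0, 0), c(1, 1, 1))
  expect_error(curvature_profile(closed_curve(dup, validate = FALSE)),
               "duplicate")
})

test_that("apex detection finds caps, not uniform or junction curvature", {
  expect_identical(detect_apices(fx_circle10()$curve)$count, 0L)
  p <- fx_plectoneme()
  ap <- detect_apices(p$curve)
  expect_identical(ap$count, 2L)
  # detected apices sit at the generator's cap midpoints (within the
  # smoothing window)
  d <- vapply(ap$arc, function(s) min(abs(p$apex_positions - s)), numeric(1))
  expect_true(all(d <= 10))
  expect_identical(detect_apices(fx_branched3()$curve)$count, 3L)
  # sorted by descending curvature
  expect_true(all(diff(ap$curvature) <= 0))
})

test_that("radius of gyration equals the direct-formula oracle", {
  expect_equal(radius_of_gyration(fx_circle100()$curve)$rg, 100,
               tolerance = 0.005)
  same <- closed_curve(matrix(1, 5, 3), validate = FALSE)
  expect_equal(radius_of_gyration(same)$rg, 0)
  set.seed(11)
  cloud <- matrix(stats::rnorm(1500), 500, 3)
  rg <- radius_of_gyration(cloud)
  direct <- sqrt(mean(rowSums(sweep(cloud, 2L, colMeans(cloud))^2)))
  expect_lt(abs(rg$rg - direct), 1e-9)
  expect_true(all(diff(rg$eigenvalues) <= 0))
  # rigid-motion invariance; Rg scales linearly, curvature inversely
  p <- fx_plectoneme()
  moved <- transform_curve(p$curve, rotation = random_rotation(5),
                           translation = c(3, 4, 5))
  expect_equal(radius_of_gyration(moved)$rg, radius_of_gyration(p$curve)$rg,
               tolerance = 1e-9)
  scaled <- transform_curve(p$curve, scale = 2)
  expect_equal(radius_of_gyration(scaled)$rg,
               2 * radius_of_gyration(p$curve)$rg, tolerance = 1e-9)
  expect_equal(as.numeric(curvature_profile(scaled)),
               as.numeric(curvature_profile(p$curve)) / 2, tolerance = 1e-9)
})

test_that("superhelical axis recovers the strand spacing", {
  p <- fx_plectoneme()
  ap <- detect_apices(p$curve)
  ax <- superhelical_axis(p$curve, ap)
  # away from the apical caps the inter-strand spacing is the generated one
  mid <- ax$spacing[ax$arc_from_apex > 40 & ax$arc_from_apex < 280]
  expect_true(all(abs(mid - 8) < 0.5))
  # spacing rises toward the cap diameter near the apices
  near_cap <- ax$spacing[ax$arc_from_apex < 8]
  expect_gt(max(near_cap), 8.5)
  # a circle has no interwound region
  expect_error(superhelical_axis(fx_circle10()$curve,
                                 detect_apices(fx_circle10()$curve)),
               "no interwound region|at least")
})

test_that("branch decomposition partitions points and matches arm labels", {
  p <- fx_plectoneme()
  ax <- superhelical_axis(p$curve, detect_apices(p$curve))
  dec <- segment_branches(ax, p$curve)
  expect_identical(dec$n_branches, 1L)
  expect_true(all(dec$branch == 1L))
  b <- fx_branched3()
  axb <- superhelical_axis(b$curve, detect_apices(b$curve))
  decb <- segment_branches(axb, b$curve)
  expect_identical(decb$n_branches, 3L)
  # partition: every curve point in exactly one branch
  expect_length(decb$branch, length(b$curve))
  expect_true(all(decb$branch %in% 1:3))
  expect_gte(branch_agreement(b$arm_label, decb$branch), 0.95)
  # a two-armed V splits at its corner
  v <- fx_branched2()
  axv <- superhelical_axis(v$curve, detect_apices(v$curve))
  decv <- segment_branches(axv, v$curve)
  expect_identical(decv$n_branches, 2L)
  expect_gte(branch_agreement(v$arm_label, decv$branch), 0.95)
})

test_that("writhe density units reconstruct the branch writhe", {
  # relaxed near-planar loop: densities all near zero
  ring <- fx_circle100()
  ax_err <- tryCatch(superhelical_axis(ring$curve, detect_apices(ring$curve)),
                     error = function(e) NULL)
  expect_null(ax_err)
  p <- fx_plectoneme()
  ap <- detect_apices(p$curve)
  dec <- segment_branches(superhelical_axis(p$curve, ap), p$curve)
  dens <- branch_writhe_density(p$curve, dec, unit_length = 100)
  wr <- compute_writhe(p$curve)
  L <- sum(dec$branch_length_nm)
  # uniform ideal plectoneme: each unit density = Wr/L within 20%
  expect_true(all(abs(dens$density - wr / L) <= 0.2 * abs(wr / L)))
  # length-weighted density total reconstructs Wr within the chord bound
  expect_lt(abs(sum(dens$writhe) - wr), 0.1 * abs(wr) + 0.3)
  # a branch shorter than the unit stays unsegmented
  dec80 <- dec
  dec80$branch_length_nm <- 80
  d80 <- branch_writhe_density(p$curve, dec80, unit_length = 100)
  expect_identical(nrow(d80), 1L)
})

test_that("linking-number bookkeeping reproduces printed arithmetic", {
  expect_equal(round(supercoiling_density(-15, 186), 2), -0.08)
  expect_equal(round(supercoiling_density(-8, 186), 2), -0.04)
  expect_equal(supercoiling_density(0, 186), 0)
  expect_identical(lk0_from_size(1950, 10.5), 186)
  expect_error(supercoiling_density(-15, 0), "positive")
  st <- linking_state(dLk = -15, Lk0 = 186, Wr = -10)
  expect_equal(delta_twist(st), -5)
  expect_error(delta_twist(linking_state(-15, 186)), "Wr")
})

test_that("topology summary composes consistently and survives JSON", {
  ct <- fx_circle100()
  s <- summarize_topology(ct$curve)
  expect_equal(s$writhe, 0, tolerance = 1e-6)
  expect_identical(s$apex_count, 0L)
  expect_equal(s$rg, 100, tolerance = 0.5)
  p <- fx_plectoneme()
  sp <- summarize_topology(p$curve)
  expect_equal(sp$writhe, p$writhe_truth, tolerance = 0.05)
  expect_identical(sp$apex_count, 2L)
  expect_identical(sp$n_branches, 1L)
  tf <- tempfile(fileext = ".json")
  write_summary_json(sp, tf)
  back <- read_summary_json(tf)
  expect_equal(back$writhe, sp$writhe, tolerance = 1e-12)
  expect_equal(back$curvature, sp$curvature, tolerance = 1e-12)
  expect_identical(as.integer(back$apex_count), sp$apex_count)
  unlink(tf)
})

test_that("oracle equivalence: 2 nm writhe tracks the 0.25 nm oracle", {
  # seeded battery of synthetic curves, both discretizations
  cases <- list(
    make_plectoneme(660, -6, 8, 5, seed = 21),
    make_plectoneme(660, -9, 8, 5, seed = 22),
    make_branched_plectoneme(660, c(-3, -3, -3), 8, 5, seed = 23))
  for (cs in cases) {
    expect_lt(abs(compute_writhe(cs$curve) - cs$writhe_truth), 0.05)
  }
})
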