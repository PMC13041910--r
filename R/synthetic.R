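#' Synthetic ground-truth plasmid conformations
#'
#' Generators for closed-curve plasmid models with known geometry and
#' topology: planar circles, unbranched interwound plectonemes, and
#' star-like branched plectonemes. Each returns a `synthetic_truth` object
#' carrying the curve plus the ground-truth quantities downstream estimators
#' are tested against. The reference writhe (`writhe_truth`) is always
#' evaluated by the Gauss double integral on a 0.25 nm resampling of the
#' generated geometry, independent of the curve spacing requested.
#'
#' @name synthetic_truth
#' @keywords internal
NULL

ORACLE_SPACING <- 0.25   # nm; discretization of the writhe reference
BP_PER_NM <- 1950 / 660  # ~2 kbp construct: 0.338 nm/bp

new_synthetic_truth <- function(curve, writhe_truth, apex_arc, branch_count,
                                strand_spacing, arm_label, params,
                                total_bp = NULL) {
  arc <- arc_lengths(curve)
  apex_index <- if (length(apex_arc) > 0) {
    vapply(apex_arc, function(s) which.min(abs(arc - s)), integer(1))
  } else integer(0)
  if (is.null(total_bp)) total_bp <- round(contour_length(curve) * BP_PER_NM)
  structure(list(
    curve = curve,
    contour_length = contour_length(curve),
    writhe_truth = writhe_truth,
    apex_positions = apex_arc,
    apex_index = apex_index,
    branch_count = branch_count,
    strand_spacing = strand_spacing,
    arm_label = arm_label,
    total_bp = total_bp,
    particle_truth = NULL,
    params = params
  ), class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf(paste0("synthetic_truth: contour %.0f nm, Wr = %.2f, ",
                     "%d branch(es), %d apices\n"),
              x$contour_length, x$writhe_truth, x$branch_count,
              length(x$apex_positions)))
  invisible(x)
}

# enforce the self-avoidance invariant at the rendered duplex diameter
check_self_avoidance <- function(curve, duplex_diameter = 2) {
  pts <- curve_points(curve)
  spacing <- mean(segment_lengths(pts))
  skip <- max(2L, as.integer(ceiling(6 / spacing)))
  dmin <- .min_nonadjacent_dist_cpp(pts, skip)
  if (dmin <= duplex_diameter) {
    stop(sprintf(paste0("generated curve is not self-avoiding: minimum ",
                        "non-adjacent distance %.2f nm <= duplex diameter ",
                        "%.2f nm"), dmin, duplex_diameter))
  }
  invisible(dmin)
}

#' Planar circle ground truth
#'
#' @param radius circle radius in nm (> 0).
#' @param n_points number of points (>= 8).
#' @return a `synthetic_truth` with zero writhe and no apices.
#' @export
make_circle <- function(radius, n_points = 500) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be positive")
  if (n_points < 8) stop("n_points must be at least 8")
  theta <- seq(0, 2 * pi, length.out = n_points + 1L)[seq_len(n_points)]
  pts <- cbind(radius * cos(theta), radius * sin(theta), 0)
  curve <- closed_curve(pts, provenance = list(generator = "make_circle"))
  new_synthetic_truth(curve, writhe_truth = 0, apex_arc = numeric(0),
                      branch_count = 1L, strand_spacing = NA_real_,
                      arm_label = rep(1L, n_points),
                      params = list(radius = radius, n_points = n_points))
}

# cubic Hermite arc between (p0, t0) and (p1, t1); tangents are unit vectors,
# `scale` sets their magnitude; returns n interior samples (endpoints excluded)
hermite_arc <- function(p0, t0, p1, t1, scale, n) {
  u <- seq(0, 1, length.out = n + 2L)[2:(n + 1L)]
  h00 <- 2 * u^3 - 3 * u^2 + 1
  h10 <- u^3 - 2 * u^2 + u
  h01 <- -2 * u^3 + 3 * u^2
  h11 <- u^3 - u^2
  outer(h00, p0) + outer(h10, t0 * scale) +
    outer(h01, p1) + outer(h11, t1 * scale)
}

# polyline length
poly_len <- function(P) {
  if (nrow(P) < 2L) return(0)
  sum(sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2)))
}

# One interwound arm along axis direction u (unit), starting at `base`,
# height H, with m signed turns, strand radius a, distal Hermite cap of
# nominal radius r_a. e1, e2 are unit vectors completing the frame.
# Returns list of point blocks in traversal order: out-strand (base->tip),
# cap, back-strand (tip->base), plus endpoint tangents at the base for
# connector construction.
build_arm <- function(base, u, e1, e2, H, m, a, r_a, phi0, ds) {
  n_s <- max(8L, as.integer(round(sqrt(H^2 + (pi * abs(m) * a)^2) / ds)))
  t_par <- seq(0, 1, length.out = n_s)
  # one interwound turn = one inter-strand crossing = half a strand
  # revolution; negative m winds so that crossings are right-handed and
  # the writhe comes out negative
  phi <- phi0 - pi * m * t_par
  circ <- function(ph) outer(cos(ph), e1) + outer(sin(ph), e2)
  axis_pts <- outer(t_par * H, u) + matrix(base, n_s, 3, byrow = TRUE)
  s_out <- axis_pts + a * circ(phi)             # base -> tip
  s_back_up <- axis_pts + a * circ(phi + pi)    # base -> tip on other strand
  s_back <- s_back_up[n_s:1L, , drop = FALSE]   # traversed tip -> base

  tangent_at <- function(P, at_end) {
    v <- if (at_end) P[nrow(P), ] - P[nrow(P) - 1L, ] else P[2L, ] - P[1L, ]
    v / sqrt(sum(v^2))
  }
  p_tip_out <- s_out[n_s, ]
  t_tip_out <- tangent_at(s_out, TRUE)
  p_tip_back <- s_back[1L, ]
  t_tip_back <- tangent_at(s_back, FALSE)
  n_cap <- max(6L, as.integer(round(pi * r_a / ds)))
  cap <- hermite_arc(p_tip_out, t_tip_out, p_tip_back, t_tip_back,
                     scale = 4 * r_a, n = n_cap)
  list(
    blocks = list(out = s_out, cap = cap, back = s_back),
    base_in = list(p = s_back[nrow(s_back), ], t = tangent_at(s_back, TRUE)),
    base_out = list(p = s_out[1L, ], t = tangent_at(s_out, FALSE)),
    cap_mid_block_offset = nrow(s_out) + ceiling(n_cap / 2)
  )
}

sign_or_pos <- function(m) if (m < 0) -1 else 1

# assemble blocks into one closed polyline with labels; returns fine curve,
# per-point arm labels, and apex arc positions
assemble_truth <- function(blocks, labels_per_block, apex_block_flags, spacing,
                           generator, params, strand_spacing, branch_count,
                           seed) {
  P <- do.call(rbind, blocks)
  lab <- rep.int(labels_per_block, vapply(blocks, nrow, integer(1)))
  # cumulative arc of the raw assembly, to locate apex (cap midpoint) arcs
  seg <- sqrt(rowSums((P[c(2:nrow(P), 1L), ] - P)^2))
  arc <- c(0, cumsum(seg))[seq_len(nrow(P))]
  apex_arc <- numeric(0)
  off <- 0L
  for (b in seq_along(blocks)) {
    if (apex_block_flags[b]) {
      mid <- off + ceiling(nrow(blocks[[b]]) / 2)
      apex_arc <- c(apex_arc, arc[mid])
    }
    off <- off + nrow(blocks[[b]])
  }

  raw <- closed_curve(P, validate = FALSE)
  fine <- resample_curve(raw, spacing = ORACLE_SPACING)
  wr <- compute_writhe(fine, touch_tol = 0)
  curve <- resample_curve(raw, spacing = spacing)
  curve$provenance <- list(generator = generator, params = params, seed = seed)
  # transfer labels to the resampled curve by arc position
  lab_out <- lab[vapply(arc_lengths(curve), function(s)
    which.min(abs(arc - s)), integer(1))]
  truth <- new_synthetic_truth(curve, writhe_truth = wr, apex_arc = apex_arc,
                               branch_count = branch_count,
                               strand_spacing = strand_spacing,
                               arm_label = lab_out, params = params)
  check_self_avoidance(curve)
  truth
}

#' Unbranched interwound plectoneme ground truth
#'
#' Two antiparallel duplex strands helically interwound about a straight
#' superhelical axis, capped at both ends by smooth (tangent-continuous)
#' apical loops. Negative `n_interwound_turns` produces right-handed
#' crossings and hence negative writhe.
#'
#' @param contour_length total curve length in nm.
#' @param n_interwound_turns signed number of interwound turns.
#' @param strand_spacing inter-strand distance in nm (twice the wrapping
#'   radius).
#' @param apex_radius nominal apical loop radius in nm.
#' @param seed integer seed (sets the azimuthal phase).
#' @param spacing point spacing of the returned curve, nm.
#' @return a `synthetic_truth`.
#' @export
make_plectoneme <- function(contour_length = 660, n_interwound_turns = -6,
                            strand_spacing = 8, apex_radius = 5, seed = 1,
                            spacing = 2) {
  m <- n_interwound_turns
  a <- strand_spacing / 2
  r_a <- apex_radius
  if (a <= 0 || r_a <= 0) stop("strand_spacing and apex_radius must be positive")
  set.seed(seed)
  phi0 <- stats::runif(1, 0, 2 * pi)

  turn_len <- pi * abs(m) * a
  cap_len <- pi * r_a # initial estimate, refined below
  H <- NA_real_
  arm <- NULL
  for (iter in 1:4) {
    strand_len <- (contour_length - 2 * cap_len) / 2
    if (strand_len^2 <= turn_len^2 + 1) {
      stop(sprintf(paste0("infeasible plectoneme geometry: %g nm contour ",
                          "cannot accommodate %g interwound turns at ",
                          "spacing %g nm with apex radius %g nm"),
                   contour_length, m, strand_spacing, apex_radius))
    }
    H <- sqrt(strand_len^2 - turn_len^2)
    arm <- build_arm(base = c(0, 0, -H / 2), u = c(0, 0, 1),
                     e1 = c(1, 0, 0), e2 = c(0, 1, 0),
                     H = H, m = m, a = a, r_a = r_a, phi0 = phi0, ds = 0.5)
    cap_len <- poly_len(arm$blocks$cap)
  }
  # closing cap at the base (second apex)
  n_cap <- max(6L, as.integer(round(pi * r_a / 0.5)))
  cap2 <- hermite_arc(arm$base_in$p, arm$base_in$t,
                      arm$base_out$p, arm$base_out$t,
                      scale = 4 * r_a, n = n_cap)
  blocks <- list(arm$blocks$out, arm$blocks$cap, arm$blocks$back, cap2)
  assemble_truth(blocks, labels_per_block = rep(1L, 4),
                 apex_block_flags = c(FALSE, TRUE, FALSE, TRUE),
                 spacing = spacing, generator = "make_plectoneme",
                 params = list(contour_length = contour_length,
                               n_interwound_turns = m,
                               strand_spacing = strand_spacing,
                               apex_radius = apex_radius, seed = seed),
                 strand_spacing = strand_spacing, branch_count = 1L,
                 seed = seed)
}

#' Branched (star-like) plectoneme ground truth
#'
#' Interwound arms radiating from a central junction region, each capped by
#' an apical loop, joined by smooth connectors. Two arms are placed at 90
#' degrees; three or more are spread evenly. Arms are staggered slightly in
#' z so the junction transits stay self-avoiding.
#'
#' @param contour_length total curve length in nm.
#' @param branch_turn_counts signed interwound turns per arm (length = number
#'   of arms, 1 to 5; a single arm delegates to [make_plectoneme()]).
#' @param strand_spacing inter-strand distance in nm.
#' @param apex_radius apical loop radius in nm.
#' @param seed integer seed (azimuthal phases).
#' @param spacing point spacing of the returned curve, nm.
#' @return a `synthetic_truth` with `branch_count = length(branch_turn_counts)`.
#' @export
make_branched_plectoneme <- function(contour_length = 660,
                                     branch_turn_counts = c(-3, -3, -3),
                                     strand_spacing = 8, apex_radius = 5,
                                     seed = 1, spacing = 2) {
  k <- length(branch_turn_counts)
  if (k < 1L || k > 5L) stop("between 1 and 5 branches are supported")
  if (k == 1L) {
    return(make_plectoneme(contour_length, branch_turn_counts[1L],
                           strand_spacing, apex_radius, seed, spacing))
  }
  a <- strand_spacing / 2
  r_a <- apex_radius
  set.seed(seed)
  # strand endpoints at the junction stay near-horizontal (phase pi/2 puts
  # them perpendicular to the arm, in the star plane) so the connector
  # transits are tame; the seed jitters the phase moderately
  phis <- pi / 2 + stats::runif(k, -0.3, 0.3)

  angles <- if (k == 2L) c(0, pi / 2) else 2 * pi * (seq_len(k) - 1L) / k
  # arm start offset from the center, sized so junction transits bend far
  # more gently than apical loops; a two-armed V gets an extra-wide bend
  # (radius ~50 nm) that reads as a corner, not an apex
  r0 <- c(0, 24, 22, 30, 30)[k]
  z_off <- 4 * (seq_len(k) - (k + 1) / 2) # stagger transits vertically

  turn_len <- pi * abs(branch_turn_counts) * a
  conn_total <- k * 1.2 * r0 # initial estimate
  cap_total <- k * pi * r_a
  arms <- NULL
  conns <- NULL
  for (iter in 1:4) {
    strand_budget <- (contour_length - cap_total - conn_total) / (2 * k)
    if (any(strand_budget^2 <= turn_len^2 + 1)) {
      stop(sprintf(paste0("infeasible branched geometry: %g nm contour ",
                          "cannot accommodate arms with turns (%s) at ",
                          "spacing %g nm"),
                   contour_length,
                   paste(branch_turn_counts, collapse = ", "), strand_spacing))
    }
    H <- sqrt(strand_budget^2 - turn_len^2)
    arms <- lapply(seq_len(k), function(j) {
      u <- c(cos(angles[j]), sin(angles[j]), 0)
      e1 <- c(0, 0, 1)                            # phase 0 points up
      e2 <- c(sin(angles[j]), -cos(angles[j]), 0) # right-handed (u, e1, e2)
      build_arm(base = r0 * u + c(0, 0, z_off[j]), u = u, e1 = e1, e2 = e2,
                H = H[j], m = branch_turn_counts[j], a = a, r_a = r_a,
                phi0 = phis[j], ds = 0.5)
    })
    conns <- lapply(seq_len(k), function(j) {
      jn <- if (j == k) 1L else j + 1L
      p0 <- arms[[j]]$base_in$p
      t0 <- arms[[j]]$base_in$t
      p1 <- arms[[jn]]$base_out$p
      t1 <- arms[[jn]]$base_out$t
      d <- sqrt(sum((p1 - p0)^2))
      n_conn <- max(6L, as.integer(round(1.3 * d / 0.5)))
      hermite_arc(p0, t0, p1, t1, scale = 1.2 * d, n = n_conn)
    })
    cap_total <- sum(vapply(arms, function(A) poly_len(A$blocks$cap),
                            numeric(1)))
    conn_total <- sum(vapply(conns, poly_len, numeric(1)))
  }

  blocks <- list()
  labels <- integer(0)
  apex_flags <- logical(0)
  for (j in seq_len(k)) {
    jn <- if (j == k) 1L else j + 1L
    blocks <- c(blocks, arms[[j]]$blocks["out"], arms[[j]]$blocks["cap"],
                arms[[j]]$blocks["back"])
    labels <- c(labels, j, j, j)
    apex_flags <- c(apex_flags, FALSE, TRUE, FALSE)
    # split each connector between the two arms it joins
    cn <- conns[[j]]
    h <- nrow(cn) %/% 2L
    blocks <- c(blocks, list(cn[seq_len(h), , drop = FALSE]),
                list(cn[(h + 1L):nrow(cn), , drop = FALSE]))
    labels <- c(labels, j, jn)
    apex_flags <- c(apex_flags, FALSE, FALSE)
  }
  assemble_truth(blocks, labels_per_block = labels,
                 apex_block_flags = apex_flags, spacing = spacing,
                 generator = "make_branched_plectoneme",
                 params = list(contour_length = contour_length,
                               branch_turn_counts = branch_turn_counts,
                               strand_spacing = strand_spacing,
                               apex_radius = apex_radius, seed = seed),
                 strand_spacing = strand_spacing, branch_count = as.integer(k),
                 seed = seed)
}

#' Standard synthetic recovery battery
#'
#' The fixed set of ground-truth conformations used to validate end-to-end
#' tracing recovery: four unbranched plectonemes (5 to 8 interwound turns),
#' two two-armed and four three-armed stars, all at the ~2 kbp scale
#' (660 nm contour, 8 nm strand spacing, 5 nm apical radius). Geometry
#' seeds are fixed (they are the study conditions); only the rendering
#' noise varies with the caller's seed.
#'
#' @param noise_seed_base integer; case `i` renders its noise with seed
#'   `noise_seed_base * 1000 + i`.
#' @param voxel_size,duplex_sigma,noise_sd rendering parameters; the
#'   defaults give a peak signal-to-noise ratio of 5.
#' @return list of cases, each with `truth` (a `synthetic_truth`) and
#'   `volume` (a `density_volume`).
#' @export
recovery_battery <- function(noise_seed_base = 1, voxel_size = 1.5,
                             duplex_sigma = 2, noise_sd = 0.5) {
  specs <- list(
    list(turns = -6, seed = 1), list(turns = -7, seed = 2),
    list(turns = -5, seed = 3), list(turns = -8, seed = 4),
    list(turns = c(-4, -4), seed = 5), list(turns = c(-3, -4), seed = 6),
    list(turns = c(-3, -3, -3), seed = 7),
    list(turns = c(-2, -3, -3), seed = 8),
    list(turns = c(-3, -3, -2), seed = 9), list(turns = -6, seed = 10))
  lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    truth <- if (length(sp$turns) == 1L) {
      make_plectoneme(660, sp$turns, 8, 5, seed = sp$seed)
    } else {
      make_branched_plectoneme(660, sp$turns, 8, 5, seed = sp$seed)
    }
    vol <- render_density(truth, voxel_size = voxel_size,
                          duplex_sigma = duplex_sigma, noise_sd = noise_sd,
                          seed = noise_seed_base * 1000 + i)
    list(truth = truth, volume = vol)
  })
}

#' Render a ground-truth curve into a density volume
#'
#' Sums one isotropic Gaussian kernel (sd `duplex_sigma`, peak 1) per curve
#' point onto a voxel grid enclosing the particle, then adds i.i.d. Gaussian
#' noise. Emulates a low-pass-filtered per-particle tomographic map.
#'
#' @param truth a `synthetic_truth`.
#' @param voxel_size voxel edge in nm; should be at most strand_spacing / 3
#'   (coarser sampling sets a provenance warning flag).
#' @param duplex_sigma Gaussian sd of the rendered duplex cross-section, nm.
#' @param noise_sd sd of the additive Gaussian noise (ridge peak is about
#'   2.5 for the default 2 nm curve spacing, so noise_sd = 0.25 gives
#'   signal-to-noise near 10).
#' @param seed noise seed; identical seeds give bit-identical volumes.
#' @return a `density_volume`.
#' @export
render_density <- function(truth, voxel_size = 1.5, duplex_sigma = 2,
                           noise_sd = 0, seed = 1) {
  pts <- curve_points(truth$curve)
  flags <- character(0)
  if (is.finite(truth$strand_spacing) &&
      voxel_size > truth$strand_spacing / 3) {
    flags <- c(flags, sprintf(
      "voxel_size %.2f nm exceeds strand_spacing/3 = %.2f nm: undersampled",
      voxel_size, truth$strand_spacing / 3))
    warning(flags[[1L]])
  }
  pad <- 4 * duplex_sigma + 2 * voxel_size
  lo <- apply(pts, 2L, min) - pad
  hi <- apply(pts, 2L, max) + pad
  dims <- as.integer(ceiling((hi - lo) / voxel_size))
  vol <- array(0, dim = dims)
  vol <- .splat_gaussians_cpp(vol, dims, lo, voxel_size, pts,
                              duplex_sigma, 1.0)
  if (noise_sd > 0) {
    set.seed(seed)
    vol <- vol + stats::rnorm(length(vol), 0, noise_sd)
    dim(vol) <- dims
  }
  density_volume(vol, voxel_size = voxel_size, origin = lo,
                 provenance = list(generator = "render_density",
                                   duplex_sigma = duplex_sigma,
                                   noise_sd = noise_sd, seed = seed,
                                   warnings = flags))
}

#' Place protein particles on a ground-truth plasmid
#'
#' Maps base-pair positions to curve points (arc-proportional), displaces
#' each center outward along the local normal by `offset`, and optionally
#' renders spherical Gaussian blobs into a supplied volume.
#'
#' @param truth a `synthetic_truth`.
#' @param bp_positions base-pair coordinates in `[0, total_bp)`.
#' @param particle_radius blob radius in nm (rendered sd = radius / 2).
#' @param offset outward displacement of the particle center from the curve,
#'   nm.
#' @param seed reserved for stochastic placement variants; recorded in the
#'   output for provenance.
#' @param volume optional `density_volume` to add the blobs to.
#' @param amplitude peak blob density when rendering.
#' @return list with `centers` (data.frame: bp, x, y, z, curve_index,
#'   arc_nm) and `volume` (updated `density_volume`, or NULL).
#' @export
place_particles <- function(truth, bp_positions, particle_radius = 5,
                            offset = 0, seed = 1, volume = NULL,
                            amplitude = 3) {
  total_bp <- truth$total_bp
  if (any(bp_positions < 0 | bp_positions >= total_bp)) {
    stop(sprintf("bp positions must lie in [0, %d)", total_bp))
  }
  if (offset < 0) stop("offset must be non-negative")
  pts <- curve_points(truth$curve)
  n <- nrow(pts)
  arc <- arc_lengths(truth$curve)
  total <- truth$contour_length
  centers <- matrix(0, length(bp_positions), 3L)
  idx <- integer(length(bp_positions))
  for (p in seq_along(bp_positions)) {
    s <- bp_positions[p] / total_bp * total
    i <- which.min(abs(arc - s))
    idx[p] <- i
    ctr <- pts[i, ]
    if (offset > 0) {
      prv <- pts[if (i == 1L) n else i - 1L, ]
      nxt <- pts[if (i == n) 1L else i + 1L, ]
      inward <- prv + nxt - 2 * ctr
      nrm <- sqrt(sum(inward^2))
      outward <- if (nrm > 1e-9) -inward / nrm else {
        t_ <- nxt - prv
        perp <- c(-t_[2L], t_[1L], 0)
        if (sqrt(sum(perp^2)) < 1e-9) perp <- c(0, -t_[3L], t_[2L])
        perp / sqrt(sum(perp^2))
      }
      ctr <- ctr + offset * outward
    }
    centers[p, ] <- ctr
  }
  df <- data.frame(bp = bp_positions, x = centers[, 1], y = centers[, 2],
                   z = centers[, 3], curve_index = idx,
                   arc_nm = arc[idx])
  if (!is.null(volume)) {
    volume$values <- .splat_gaussians_cpp(
      volume$values, dim(volume$values), volume$origin, volume$voxel_size,
      centers, particle_radius / 2, amplitude)
    volume$provenance$particles <- list(bp = bp_positions,
                                        radius = particle_radius,
                                        offset = offset, seed = seed)
  }
  list(centers = df, volume = volume)
}
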