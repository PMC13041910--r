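#' Spine line of a density volume
#'
#' Recovers the superhelical-axis skeleton of a single plasmid particle:
#' the volume is smoothed with a strong Gaussian kernel, binarized at a
#' quantile of its positive voxel densities, reduced to its largest
#' connected component, and thinned to a one-voxel-wide curve skeleton
#' (topology-preserving (26,6) thinning). Short spurs are pruned and the
#' skeleton returned as a graph of physical-coordinate points.
#'
#' @param volume a `density_volume`.
#' @param smoothing_sigma Gaussian sd in nm (strong: of the order of the
#'   plectoneme width, so the two duplex strands merge into one tube).
#' @param threshold_quantile binarization quantile of the positive voxel
#'   densities of the smoothed map.
#' @param prune_length spurs shorter than this (nm) are removed.
#' @return object of class `spine_line`: list with `points` (n x 3 nm),
#'   `edges` (2-column index matrix), `degree` (per point) and `paths`
#'   (list of index vectors: simple paths/cycles between junctions/endpoints).
#' @export
compute_spine <- function(volume, smoothing_sigma = 8,
                          threshold_quantile = 0.90, prune_length = 15) {
  vx <- volume$voxel_size
  sm <- .blur3d_cpp(volume$values, dim(volume$values), smoothing_sigma / vx)
  pos <- sm[sm > 0]
  if (length(pos) == 0L) {
    stop("particle isolation error: no positive density after smoothing")
  }
  thr <- stats::quantile(pos, threshold_quantile, names = FALSE)
  mask <- sm >= thr
  lab <- .label_components_cpp(mask, dim(volume$values))
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0L) {
    stop("particle isolation error: empty volume above threshold")
  }
  main <- which.max(sizes)
  if (length(sizes) > 1L && sort(sizes, decreasing = TRUE)[2L] >
      0.25 * sizes[main]) {
    stop("particle isolation error: multiple large components above threshold")
  }
  mask <- lab == main
  skel <- .thin3d_cpp(mask, dim(volume$values))
  skeleton_to_spine(skel, volume, prune_length)
}

# Build a spine_line graph from a thinned voxel mask, prune short spurs,
# decompose into simple paths.
skeleton_to_spine <- function(skel, volume, prune_length) {
  vx <- volume$voxel_size
  idx <- which(skel)
  if (length(idx) < 3L) {
    stop("particle isolation error: skeleton too small to trace")
  }
  d <- dim(skel)
  ijk <- cbind((idx - 1L) %% d[1L] + 1L,
               ((idx - 1L) %/% d[1L]) %% d[2L] + 1L,
               (idx - 1L) %/% (d[1L] * d[2L]) + 1L)
  pts <- voxel_centers(volume, ijk)
  n <- nrow(pts)

  # 26-neighbour edges among skeleton voxels
  key <- (ijk[, 1L] - 1L) + d[1L] * ((ijk[, 2L] - 1L) +
                                       d[2L] * (ijk[, 3L] - 1L))
  lookup <- new.env(hash = TRUE, size = n)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = lookup)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, ]
  edges <- list()
  for (o in seq_len(nrow(offs))) {
    nb <- ijk + matrix(offs[o, ], n, 3L, byrow = TRUE)
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= d[1L] &
      nb[, 2L] >= 1L & nb[, 2L] <= d[2L] &
      nb[, 3L] >= 1L & nb[, 3L] <= d[3L]
    nk <- (nb[, 1L] - 1L) + d[1L] * ((nb[, 2L] - 1L) + d[2L] * (nb[, 3L] - 1L))
    for (i in which(ok)) {
      j <- lookup[[as.character(nk[i])]]
      if (!is.null(j) && j > i) edges[[length(edges) + 1L]] <- c(i, j)
    }
  }
  edges <- do.call(rbind, edges)
  # drop diagonal shortcut edges where a shorter 2-edge path exists:
  # keep edge (i,j) only if no common neighbour connects them with two
  # strictly shorter steps (avoids doubled edges along staircase skeletons)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  elen <- sqrt(rowSums((pts[edges[, 1L], , drop = FALSE] -
                          pts[edges[, 2L], , drop = FALSE])^2))
  keep <- rep(TRUE, nrow(edges))
  for (e in order(elen, decreasing = TRUE)) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    common <- intersect(adj[[i]], adj[[j]])
    common <- setdiff(common, c(i, j))
    if (length(common) > 0L) {
      li <- sqrt(rowSums(sweep(pts[common, , drop = FALSE], 2L, pts[i, ])^2))
      lj <- sqrt(rowSums(sweep(pts[common, , drop = FALSE], 2L, pts[j, ])^2))
      if (any(li < elen[e] & lj < elen[e])) {
        keep[e] <- FALSE
        adj[[i]] <- setdiff(adj[[i]], j)
        adj[[j]] <- setdiff(adj[[j]], i)
      }
    }
  }
  edges <- edges[keep, , drop = FALSE]

  # iterative spur pruning
  repeat {
    deg <- tabulate(edges, nbins = n)
    paths <- graph_paths(edges, deg, n)
    spur <- FALSE
    for (p in paths) {
      if (length(p) < 2L) next
      ends_deg <- deg[c(p[1L], p[length(p)])]
      plen <- poly_len(pts[p, , drop = FALSE])
      if (any(ends_deg == 1L) && plen < prune_length) {
        # delete interior + the degree-1 end(s) of this path
        drop_nodes <- p[-c(if (ends_deg[1L] > 1L) 1L,
                           if (ends_deg[2L] > 1L) length(p))]
        edges <- edges[!(edges[, 1L] %in% drop_nodes |
                           edges[, 2L] %in% drop_nodes), , drop = FALSE]
        spur <- TRUE
        break
      }
    }
    if (!spur) break
  }
  deg <- tabulate(edges, nbins = n)
  paths <- graph_paths(edges, deg, n)
  structure(list(points = pts, edges = edges, degree = deg, paths = paths,
                 voxel_size = vx),
            class = "spine_line")
}

#' @export
print.spine_line <- function(x, ...) {
  cat(sprintf("spine_line: %d skeleton points, %d path(s), %d junction(s)\n",
              sum(x$degree > 0), length(x$paths), sum(x$degree >= 3L)))
  invisible(x)
}

#' Total length of a spine line (nm)
#'
#' Skeleton voxel paths zigzag at the voxel scale, which inflates raw
#' polyline length; each path is lightly smoothed (three passes of a
#' three-point mean) before measuring.
#'
#' @param spine a `spine_line`.
#' @return summed smoothed polyline length of its paths.
#' @export
spine_length <- function(spine) {
  sum(vapply(spine$paths, function(p) {
    P <- spine$points[p, , drop = FALSE]
    if (nrow(P) >= 5L) {
      for (pass in 1:3) {
        P <- apply(rbind(P[1L, ], P, P[nrow(P), ]), 2L, function(col) {
          as.numeric(stats::filter(col, rep(1 / 3, 3), sides = 2))[
            2:(length(col) - 1L)]
        })
      }
    }
    poly_len(P)
  }, numeric(1)))
}

#' Number of junction nodes (degree >= 3) in a spine line
#' @param spine a `spine_line`.
#' @return integer count.
#' @export
spine_junctions <- function(spine) sum(spine$degree >= 3L)

# Decompose an undirected graph into simple paths between nodes of degree
# != 2, plus pure cycles. Returns a list of node-index vectors; a cycle is
# returned with its first node repeated at the end.
graph_paths <- function(edges, deg, n) {
  if (is.null(edges) || nrow(edges) == 0L) return(list())
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  used <- new.env(hash = TRUE)
  ekey <- function(i, j) paste0(min(i, j), "_", max(i, j))
  paths <- list()
  walk <- function(start, nxt) {
    p <- c(start, nxt)
    assign(ekey(start, nxt), TRUE, envir = used)
    prev <- start
    cur <- nxt
    while (deg[cur] == 2L) {
      nb <- setdiff(adj[[cur]], prev)
      if (length(nb) == 0L) break
      nb <- nb[1L]
      if (!is.null(used[[ekey(cur, nb)]])) break
      assign(ekey(cur, nb), TRUE, envir = used)
      p <- c(p, nb)
      prev <- cur
      cur <- nb
    }
    p
  }
  terminals <- which(deg > 0L & deg != 2L)
  for (t in terminals) {
    for (nb in adj[[t]]) {
      if (is.null(used[[ekey(t, nb)]])) {
        paths[[length(paths) + 1L]] <- walk(t, nb)
      }
    }
  }
  # remaining unused edges belong to pure cycles
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    if (is.null(used[[ekey(i, j)]])) {
      paths[[length(paths) + 1L]] <- walk(i, j)
    }
  }
  paths
}

#' Sample duplex weight centers along a spine line
#'
#' Steps along each spine path at `step` nm. At each step a sampling
#' cylinder (axis = local spine tangent) collects voxels above a density
#' threshold; their positions, projected onto the plane perpendicular to
#' the axis, are split into two regions by the sign of the first principal
#' component (a planar cut through the cylinder axis maximizing separation),
#' and each region's density-weighted centroid is recorded. Steps where the
#' split is degenerate (single strand, e.g. apical caps) are flagged and a
#' single centroid recorded, never dropped silently.
#'
#' @param volume a `density_volume`.
#' @param spine a `spine_line` from [compute_spine()].
#' @param cylinder_diameter cylinder diameter in nm.
#' @param cylinder_height cylinder height in nm.
#' @param step spacing of sampling positions along the spine, nm.
#' @param threshold_quantile density threshold: quantile of the positive
#'   voxel values of the raw volume.
#' @param min_center_separation centroids closer than this (nm) flag the
#'   record as degenerate.
#' @param end_extension open spine paths are extrapolated along their end
#'   tangents by this many nm, so apical caps beyond the skeleton ends are
#'   still sampled (overshoot yields flagged empty records, which are
#'   reported, not dropped).
#' @return object of class `center_samples`: data.frame with step position
#'   (`sx`, `sy`, `sz`), the two centers (`x1..z1`, `x2..z2`; center 2 is NA
#'   when degenerate), `degenerate` and `empty` flags, `path` and `step_index`.
#' @export
sample_duplex_centers <- function(volume, spine, cylinder_diameter = 60,
                                  cylinder_height = 15, step = 5,
                                  threshold_quantile = 0.90,
                                  min_center_separation = 3,
                                  end_extension = 20) {
  if (length(spine$paths) == 0L) stop("spine is empty")
  v <- volume$values
  vx <- volume$voxel_size
  thr <- dna_threshold(volume, threshold_quantile)
  d <- dim(v)
  rad <- cylinder_diameter / 2
  hh <- cylinder_height / 2
  reach <- sqrt(rad^2 + hh^2)

  # ignore short internal fragments of the skeleton (junction-cluster
  # debris); a lone path is always kept
  path_lens <- vapply(spine$paths, function(p)
    poly_len(spine$points[p, , drop = FALSE]), numeric(1))
  keep_paths <- if (length(spine$paths) > 1L) which(path_lens >= 30) else 1L
  if (length(keep_paths) == 0L) keep_paths <- which.max(path_lens)

  rows <- list()
  for (pi_ in keep_paths) {
    path <- spine$paths[[pi_]]
    P <- spine$points[path, , drop = FALSE]
    if (nrow(P) < 2L) next
    # light smoothing of the voxel path, then arc-length stepping
    if (nrow(P) >= 5L) {
      P <- apply(rbind(P[1L, ], P, P[nrow(P), ]), 2L, function(col) {
        as.numeric(stats::filter(col, rep(1 / 3, 3), sides = 2))[
          2:(length(col) - 1L)]
      })
    }
    # extrapolate free (degree <= 1) path ends to reach the apical caps;
    # junction-side ends are left alone so cylinders do not wander into
    # neighbouring arms
    is_cycle <- path[1L] == path[length(path)]
    start_free <- !is_cycle && spine$degree[path[1L]] <= 1L
    end_free <- !is_cycle && spine$degree[path[length(path)]] <= 1L
    if (end_extension > 0 && nrow(P) >= 3L) {
      if (start_free) {
        t_head <- P[1L, ] - P[3L, ]
        t_head <- t_head / max(sqrt(sum(t_head^2)), 1e-9)
        P <- rbind(P[1L, ] + end_extension * t_head, P)
      }
      if (end_free) {
        t_tail <- P[nrow(P), ] - P[nrow(P) - 2L, ]
        t_tail <- t_tail / max(sqrt(sum(t_tail^2)), 1e-9)
        P <- rbind(P, P[nrow(P), ] + end_extension * t_tail)
      }
    }
    seg <- sqrt(rowSums((P[-1L, , drop = FALSE] - P[-nrow(P), , drop = FALSE])^2))
    arc <- c(0, cumsum(seg))
    total <- arc[length(arc)]
    if (total < step) next
    s_steps <- seq(0, total, by = step)
    for (si in seq_along(s_steps)) {
      s <- s_steps[si]
      k <- findInterval(s, arc, rightmost.closed = TRUE)
      k <- min(max(k, 1L), nrow(P) - 1L)
      f <- if (seg[k] > 0) (s - arc[k]) / seg[k] else 0
      c0 <- P[k, ] + f * (P[k + 1L, ] - P[k, ])
      tangent <- P[min(k + 1L, nrow(P)), ] - P[max(k - 1L, 1L), ]
      tn <- sqrt(sum(tangent^2))
      if (tn < 1e-9) next
      tangent <- tangent / tn

      # voxel bounding box around the cylinder
      lo <- pmax(1L, as.integer(floor((c0 - reach - volume$origin) / vx + 0.5)))
      hi <- pmin(d, as.integer(ceiling((c0 + reach - volume$origin) / vx + 0.5)))
      if (any(lo > hi)) next
      ii <- lo[1L]:hi[1L]; jj <- lo[2L]:hi[2L]; kk <- lo[3L]:hi[3L]
      sub <- v[ii, jj, kk, drop = FALSE]
      sel <- which(sub >= thr)
      rec <- list(sx = c0[1L], sy = c0[2L], sz = c0[3L],
                  x1 = NA_real_, y1 = NA_real_, z1 = NA_real_,
                  x2 = NA_real_, y2 = NA_real_, z2 = NA_real_,
                  degenerate = FALSE, empty = FALSE,
                  path = pi_, step_index = si)
      if (length(sel) == 0L) {
        rec$empty <- TRUE
        rows[[length(rows) + 1L]] <- rec
        next
      }
      aidx <- arrayInd(sel, dim(sub))
      coords <- voxel_centers(volume, cbind(ii[aidx[, 1L]], jj[aidx[, 2L]],
                                            kk[aidx[, 3L]]))
      rel <- sweep(coords, 2L, c0)
      axial <- as.numeric(rel %*% tangent)
      radial2 <- rowSums(rel^2) - axial^2
      inside <- abs(axial) <= hh & radial2 <= rad^2
      if (!any(inside)) {
        rec$empty <- TRUE
        rows[[length(rows) + 1L]] <- rec
        next
      }
      if (sum(inside) < 20L) {
        # a real duplex strand leaves tens of voxels above threshold in the
        # cylinder; a handful is residual noise, not signal
        rec$empty <- TRUE
        rows[[length(rows) + 1L]] <- rec
        next
      }
      coords <- coords[inside, , drop = FALSE]
      w <- sub[sel][inside]
      rel <- rel[inside, , drop = FALSE]
      axial <- axial[inside]
      # taper weights along the cylinder axis: the strands rotate about the
      # spine, so distant slices smear each strand into an arc and defeat
      # the two-region split
      w <- w * exp(-0.5 * (axial / (cylinder_height / 4))^2)
      # in-plane coordinates
      perp <- rel - outer(axial, tangent)
      wsum <- sum(w)
      mu <- colSums(perp * w) / wsum
      pc <- sweep(perp, 2L, mu)
      covw <- crossprod(pc * sqrt(w / wsum))
      e1 <- eigen(covw, symmetric = TRUE)$vectors[, 1L]
      score <- as.numeric(pc %*% e1)
      side <- score >= 0
      m1 <- sum(w[side]); m2 <- sum(w[!side])
      if (m1 < 0.1 * wsum || m2 < 0.1 * wsum ||
          sum(side) < 10L || sum(!side) < 10L) {
        ctr <- colSums(coords * w) / wsum
        rec[c("x1", "y1", "z1")] <- as.list(ctr)
        rec$degenerate <- TRUE
      } else {
        c1 <- colSums(coords[side, , drop = FALSE] * w[side]) / m1
        c2 <- colSums(coords[!side, , drop = FALSE] * w[!side]) / m2
        if (sqrt(sum((c1 - c2)^2)) < min_center_separation) {
          ctr <- colSums(coords * w) / wsum
          rec[c("x1", "y1", "z1")] <- as.list(ctr)
          rec$degenerate <- TRUE
        } else {
          rec[c("x1", "y1", "z1")] <- as.list(c1)
          rec[c("x2", "y2", "z2")] <- as.list(c2)
        }
      }
      rows[[length(rows) + 1L]] <- rec
    }
  }
  if (length(rows) == 0L) stop("no usable sampling positions along the spine")
  out <- do.call(rbind, lapply(rows, as.data.frame))
  term_coord <- function(first) {
    t(vapply(spine$paths, function(p) {
      spine$points[if (first) p[1L] else p[length(p)], ]
    }, numeric(3)))
  }
  sc <- term_coord(TRUE)
  ec <- term_coord(FALSE)
  info <- data.frame(
    path = seq_along(spine$paths),
    start_degree = vapply(spine$paths, function(p) spine$degree[p[1L]],
                          integer(1)),
    end_degree = vapply(spine$paths, function(p) spine$degree[p[length(p)]],
                        integer(1)),
    cycle = vapply(spine$paths, function(p) p[1L] == p[length(p)], logical(1)),
    s_x = sc[, 1L], s_y = sc[, 2L], s_z = sc[, 3L],
    e_x = ec[, 1L], e_y = ec[, 2L], e_z = ec[, 3L])
  attr(out, "path_info") <- info
  class(out) <- c("center_samples", "data.frame")
  out
}

# Density threshold separating duplex signal from background: the requested
# quantile of the positive voxel values, floored at 3.5 robust background
# standard deviations (MAD) so additive noise cannot pull it into the noise
# tail. On a noiseless rendering the MAD is ~0 and the quantile rules.
dna_threshold <- function(volume, threshold_quantile = 0.90) {
  v <- volume$values
  pos <- v[v > 0]
  if (length(pos) == 0L) stop("volume has no positive density")
  max(stats::quantile(pos, threshold_quantile, names = FALSE),
      3.5 * stats::mad(v))
}

# flatten center samples into a point matrix (2 points per clean record,
# 1 per degenerate record), dropping empties and merging near-duplicates
centers_to_points <- function(samples, dedup_dist = 3) {
  keep <- !samples$empty
  p1 <- as.matrix(samples[keep, c("x1", "y1", "z1")])
  p2 <- as.matrix(samples[keep & !samples$degenerate, c("x2", "y2", "z2")])
  pts <- rbind(p1, p2)
  pts <- pts[stats::complete.cases(pts), , drop = FALSE]
  if (nrow(pts) == 0L) return(pts)
  # greedy dedup: keep a point only if no kept point is within dedup_dist
  kept <- matrix(numeric(0), 0L, 3L)
  for (i in seq_len(nrow(pts))) {
    if (nrow(kept) == 0L ||
        min(rowSums(sweep(kept, 2L, pts[i, ])^2)) > dedup_dist^2) {
      kept <- rbind(kept, pts[i, ])
    }
  }
  unname(kept)
}

#' Link duplex centers into a closed path
#'
#' Orders the sampled weight centers into one cyclic tour that traverses
#' both strands and every apex. When the input is a `center_samples`
#' data.frame the step structure is exploited: at each sampling step the two
#' weight centers are assigned to two strand rails by distance to the rail
#' ends (rotation resolves ties), rails are joined across apical caps
#' through the degenerate (single-center) records, and junction-side rail
#' ends are paired by the minimal-distance matching that yields a single
#' closed cycle. A bare n x 3 matrix (e.g. an edited center list after
#' manual intervention) is linked greedily: candidate successors within
#' `max_gap`, smallest turning angle first. Centers that cannot be placed
#' are reported in the `unresolved` attribute, not guessed; if no closed
#' tour exists a linking-failure error lists the break.
#'
#' @param samples a `center_samples` data.frame (or an n x 3 matrix of
#'   centers).
#' @param max_gap maximal distance between consecutive tour points, nm.
#' @param max_turn turning angles above this (degrees) are taken only when
#'   no gentler continuation exists (apex turnarounds legitimately turn
#'   sharply).
#' @param dedup_dist centers closer than this are merged before greedy
#'   linking, nm.
#' @param volume the source `density_volume`; when supplied, junction
#'   transits are recovered by following the density ridge between strand
#'   ends.
#' @return n x 3 matrix of ordered points forming a closed path, with
#'   attribute `unresolved` (matrix of centers left out of the tour).
#' @export
link_centers <- function(samples, max_gap = 25, max_turn = 130,
                         dedup_dist = 3, volume = NULL) {
  if (!is.matrix(samples) && !is.null(attr(samples, "path_info"))) {
    return(link_center_rails(samples, max_gap, volume = volume))
  }
  pts <- if (is.matrix(samples)) samples else centers_to_points(samples, dedup_dist)
  n <- nrow(pts)
  if (n < 8L) stop("linking failure: fewer than 8 usable centers")
  cos_soft <- cos(max_turn * pi / 180)

  # pick the next point: smallest turning angle among unvisited candidates
  # within `gap`; candidates turning more than max_turn are only taken when
  # nothing better exists (apex turnarounds legitimately turn sharply)
  next_point <- function(cur, prev_dir, visited, excluded, gap) {
    d2 <- rowSums(sweep(pts, 2L, pts[cur, ])^2)
    cand <- which(!visited & !excluded & d2 <= gap^2 & d2 > 1e-12)
    if (length(cand) == 0L) return(NA_integer_)
    if (is.null(prev_dir)) return(cand[which.min(d2[cand])])
    vecs <- sweep(pts[cand, , drop = FALSE], 2L, pts[cur, ])
    lens <- sqrt(rowSums(vecs^2))
    cosang <- as.numeric(vecs %*% prev_dir) / pmax(lens, 1e-12)
    soft <- cosang >= cos_soft
    if (any(soft)) cand[soft][which.max(cosang[soft])]
    else cand[which.max(cosang)]
  }

  visited <- logical(n)
  excluded <- logical(n)
  order_idx <- integer(0)
  cur <- 1L
  visited[cur] <- TRUE
  order_idx <- cur
  prev_dir <- NULL
  backtracks <- 0L
  max_backtracks <- max(10L, as.integer(0.25 * n))
  repeat {
    if (sum(visited) + sum(excluded & !visited) >= n) break
    nxt <- next_point(cur, prev_dir, visited, excluded, max_gap)
    if (is.na(nxt)) {
      # try a longer bridge before giving up on this position
      nxt <- next_point(cur, prev_dir, visited, excluded, 2 * max_gap)
    }
    if (is.na(nxt)) {
      # dead end: drop the current point from the tour (likely a spurious
      # center) and resume from its predecessor
      if (length(order_idx) <= 2L || backtracks >= max_backtracks) break
      excluded[cur] <- TRUE
      visited[cur] <- FALSE
      order_idx <- order_idx[-length(order_idx)]
      backtracks <- backtracks + 1L
      cur <- order_idx[length(order_idx)]
      prev_dir <- if (length(order_idx) >= 2L) {
        v <- pts[cur, ] - pts[order_idx[length(order_idx) - 1L], ]
        v / sqrt(sum(v^2))
      } else NULL
      next
    }
    dir <- pts[nxt, ] - pts[cur, ]
    prev_dir <- dir / sqrt(sum(dir^2))
    visited[nxt] <- TRUE
    order_idx <- c(order_idx, nxt)
    cur <- nxt
  }
  count <- length(order_idx)
  unresolved <- pts[!visited, , drop = FALSE]
  gap_close <- sqrt(sum((pts[order_idx[count], ] - pts[order_idx[1L], ])^2))
  if (gap_close > 2 * max_gap || count < 0.7 * n) {
    stop(sprintf(paste0("linking failure: tour covers %d of %d centers and ",
                        "ends %.1f nm from its start; broken segment near ",
                        "(%.1f, %.1f, %.1f)"),
                 count, n, gap_close,
                 pts[order_idx[count], 1L], pts[order_idx[count], 2L],
                 pts[order_idx[count], 3L]))
  }
  out <- pts[order_idx, , drop = FALSE]
  attr(out, "unresolved") <- unresolved
  out
}

# ---- rail-based linking of structured center samples ------------------------

# Assign the two centers of each step to two strand rails per spine path;
# returns per-path rails plus cap (degenerate) points at the free ends.
build_rails <- function(samples) {
  info <- attr(samples, "path_info")
  out <- list()
  for (p in info$path) {
    rec <- samples[samples$path == p & !samples$empty, , drop = FALSE]
    rec <- rec[order(rec$step_index), , drop = FALSE]
    if (nrow(rec) == 0L) next
    A <- NULL
    B <- NULL
    caps_head <- NULL
    caps_tail <- NULL
    seen_pair <- FALSE
    for (r in seq_len(nrow(rec))) {
      if (rec$degenerate[r]) {
        cpt <- as.numeric(rec[r, c("x1", "y1", "z1")])
        if (!seen_pair) caps_head <- rbind(caps_head, cpt)
        else caps_tail <- rbind(caps_tail, cpt)
        next
      }
      c1 <- as.numeric(rec[r, c("x1", "y1", "z1")])
      c2 <- as.numeric(rec[r, c("x2", "y2", "z2")])
      if (!seen_pair) {
        A <- rbind(A, c1)
        B <- rbind(B, c2)
        seen_pair <- TRUE
      } else {
        ea <- A[nrow(A), ]
        eb <- B[nrow(B), ]
        straight <- sum((c1 - ea)^2) + sum((c2 - eb)^2)
        swapped <- sum((c2 - ea)^2) + sum((c1 - eb)^2)
        if (swapped < straight) {
          tmp <- c1
          c1 <- c2
          c2 <- tmp
        }
        A <- rbind(A, c1)
        B <- rbind(B, c2)
      }
    }
    row <- info[info$path == p, ]
    out[[length(out) + 1L]] <- list(
      path = p, A = A, B = B, caps_head = caps_head, caps_tail = caps_tail,
      start_degree = row$start_degree,
      end_degree = row$end_degree,
      cycle = row$cycle,
      s_node = as.numeric(row[c("s_x", "s_y", "s_z")]),
      e_node = as.numeric(row[c("e_x", "e_y", "e_z")]))
  }
  out
}

# Order cap points into a chain from `from` to `to`: the apical loop is
# close to a semicircle over the chord between the two rail ends, so points
# are sorted by their angle in the plane spanned by the chord and the
# outward bulge direction. Points duplicating the rail ends are dropped.
chain_points <- function(pts, from, to) {
  if (is.null(pts) || nrow(pts) == 0L) return(NULL)
  keep <- vapply(seq_len(nrow(pts)), function(r) {
    min(sum((pts[r, ] - from)^2), sum((pts[r, ] - to)^2)) > 16
  }, logical(1))
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) == 0L) return(NULL)
  ctr <- (from + to) / 2
  xhat <- to - from
  xn <- sqrt(sum(xhat^2))
  if (xn < 1e-9) {
    # rail ends coincide: fall back to distance-from-center ordering
    return(pts[order(rowSums(sweep(pts, 2L, ctr)^2)), , drop = FALSE])
  }
  xhat <- xhat / xn
  rel <- sweep(pts, 2L, ctr)
  out_dir <- colMeans(rel)
  out_dir <- out_dir - sum(out_dir * xhat) * xhat
  on <- sqrt(sum(out_dir^2))
  if (on < 1e-9) {
    return(pts[order(as.numeric(rel %*% xhat)), , drop = FALSE])
  }
  out_dir <- out_dir / on
  theta <- atan2(as.numeric(rel %*% out_dir), as.numeric(rel %*% xhat))
  pts[order(theta, decreasing = TRUE), , drop = FALSE]
}

# all perfect matchings of the integers 1..n (n even), as lists of 2-col pairs
perfect_matchings <- function(ids) {
  if (length(ids) == 0L) return(list(matrix(integer(0), 0L, 2L)))
  first <- ids[1L]
  rest <- ids[-1L]
  out <- list()
  for (j in seq_along(rest)) {
    partner <- rest[j]
    for (sub in perfect_matchings(rest[-j])) {
      out[[length(out) + 1L]] <- rbind(c(first, partner), sub)
    }
  }
  out
}

# Drop gross outlier points from a strand rail: a weight center whose
# distance from the midpoint of its two neighbours far exceeds what strand
# curvature can produce is a corrupted split (e.g. cross-talk from a
# neighbouring strand), not geometry.
clean_rail <- function(P, max_resid = 4.5) {
  if (is.null(P) || nrow(P) < 3L) return(P)
  repeat {
    n <- nrow(P)
    mid <- (P[c(1L, 1:(n - 1L)), , drop = FALSE] +
              P[c(2:n, n), , drop = FALSE]) / 2
    resid <- sqrt(rowSums((P - mid)^2))
    resid[c(1L, n)] <- 0
    worst <- which.max(resid)
    if (resid[worst] <= max_resid || n <= 3L) break
    P <- P[-worst, , drop = FALSE]
  }
  P
}

# Follow the density ridge from a rail end into the junction region.
# Steps along the local tube by cone-weighted centroids until it comes
# within `capture` nm of one of the `targets` (n x 3), loses density, or
# exceeds max_steps. Returns list(target = index or NA, via = points).
follow_transit <- function(volume, start, dir, targets, threshold,
                           step = 4, radius = 5, capture = 6,
                           max_steps = 40, self = 0L, min_walk = 12) {
  v <- volume$values
  d <- dim(v)
  vx <- volume$voxel_size
  pos <- start
  via <- NULL
  for (k in seq_len(max_steps)) {
    pred <- pos + step * dir
    lo <- pmax(1L, as.integer(floor((pred - radius - volume$origin) / vx + 0.5)))
    hi <- pmin(d, as.integer(ceiling((pred + radius - volume$origin) / vx + 0.5)))
    if (any(lo > hi)) return(list(target = NA_integer_, via = via))
    ii <- lo[1L]:hi[1L]; jj <- lo[2L]:hi[2L]; kk <- lo[3L]:hi[3L]
    sub <- v[ii, jj, kk, drop = FALSE]
    sel <- which(sub >= threshold)
    if (length(sel) == 0L) return(list(target = NA_integer_, via = via))
    aidx <- arrayInd(sel, dim(sub))
    coords <- voxel_centers(volume, cbind(ii[aidx[, 1L]], jj[aidx[, 2L]],
                                          kk[aidx[, 3L]]))
    rel <- sweep(coords, 2L, pos)
    dist_ <- sqrt(rowSums(rel^2))
    keep <- dist_ > 1e-9 & sqrt(rowSums(sweep(coords, 2L, pred)^2)) <= radius
    if (!any(keep)) return(list(target = NA_integer_, via = via))
    coords <- coords[keep, , drop = FALSE]
    rel <- rel[keep, , drop = FALSE]
    dist_ <- dist_[keep]
    cosang <- as.numeric(rel %*% dir) / dist_
    w <- sub[sel][keep] * pmax(cosang, 0)^2
    if (sum(w) <= 0) return(list(target = NA_integer_, via = via))
    nxt <- colSums(coords * w) / sum(w)
    ndir <- nxt - pos
    nn <- sqrt(sum(ndir^2))
    if (nn < 0.25 * step) return(list(target = NA_integer_, via = via))
    # momentum on the walking direction damps centroid jitter so the
    # recovered transit stays smooth
    dir <- 0.5 * dir + 0.5 * ndir / nn
    dir <- dir / sqrt(sum(dir^2))
    pos <- nxt
    via <- rbind(via, pos)
    td <- sqrt(rowSums(sweep(targets, 2L, pos)^2))
    if (self >= 1L) td[self] <- Inf
    hit <- which(td <= capture)
    if (length(hit) > 0L && k * step >= min_walk) {
      return(list(target = hit[which.min(td[hit])], via = via))
    }
  }
  list(target = NA_integer_, via = via)
}

# Link structured center samples: rails per path, apex joins at free ends,
# minimal-distance single-cycle matching of junction-side rail ends.
link_center_rails <- function(samples, max_gap, volume = NULL,
                              junction_trim = 20) {
  rails_by_path <- build_rails(samples)
  if (length(rails_by_path) == 0L) {
    stop("linking failure: no usable centers on any spine path")
  }

  # A path end is a true junction only if another kept path terminates
  # nearby; a skeleton artifact (e.g. a tiny cycle at an apical cap whose
  # fragments were discarded) leaves a high-degree node with no counterpart
  # and is treated as a free (apex) end.
  n_rb <- length(rails_by_path)
  for (ri in seq_len(n_rb)) {
    rb <- rails_by_path[[ri]]
    others <- do.call(rbind, lapply(rails_by_path[-ri], function(o)
      rbind(o$s_node, o$e_node)))
    near_other <- function(node) {
      !is.null(others) &&
        min(sqrt(rowSums(sweep(others, 2L, node)^2))) <= 30
    }
    if (rb$start_degree >= 3L && !near_other(rb$s_node)) {
      rb$start_degree <- 1L
    }
    if (rb$end_degree >= 3L && !near_other(rb$e_node)) {
      rb$end_degree <- 1L
    }
    rails_by_path[[ri]] <- rb
  }

  # centers sampled close to a junction mix density from several arms and
  # are unreliable; trim rail tails inside the junction ball and let the
  # ridge-following transit walks bridge the gap
  for (ri in seq_len(n_rb)) {
    rb <- rails_by_path[[ri]]
    if (is.null(rb$A)) next
    for (rail in c("A", "B")) {
      P <- rb[[rail]]
      if (rb$start_degree >= 3L) {
        bad <- sqrt(rowSums(sweep(P, 2L, rb$s_node)^2)) <= junction_trim
        k <- which(!bad)[1L]
        if (!is.na(k) && k > 1L) P <- P[k:nrow(P), , drop = FALSE]
      }
      if (rb$end_degree >= 3L) {
        bad <- sqrt(rowSums(sweep(P, 2L, rb$e_node)^2)) <= junction_trim
        k <- rev(which(!bad))[1L]
        if (!is.na(k) && k < nrow(P)) P <- P[seq_len(k), , drop = FALSE]
      }
      rb[[rail]] <- P
    }
    rails_by_path[[ri]] <- rb
  }

  # single circular path with (almost) no paired records: a lone duplex ring,
  # the tour is just the single-center chain in step order
  if (length(rails_by_path) == 1L) {
    rb <- rails_by_path[[1L]]
    n_pair <- if (is.null(rb$A)) 0L else nrow(rb$A)
    if (rb$cycle && n_pair < 4L) {
      rec <- samples[samples$path == rb$path & !samples$empty &
                       samples$degenerate, , drop = FALSE]
      rec <- rec[order(rec$step_index), , drop = FALSE]
      pts <- as.matrix(rec[, c("x1", "y1", "z1")])
      if (nrow(pts) >= 8L &&
          sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2)) < max_gap) {
        # drop a duplicated closure point if the cycle sampled it twice
        if (sqrt(sum((pts[1L, ] - pts[nrow(pts), ])^2)) < 1e-6) {
          pts <- pts[-nrow(pts), , drop = FALSE]
        }
        attr(pts, "unresolved") <- matrix(numeric(0), 0L, 3L)
        return(pts)
      }
      stop("linking failure: circular spine with too few centers")
    }
  }

  # build segment list: each rail is a segment with two ends; paths whose
  # sampling produced no usable strand pairs carry no information and are
  # dropped (reported, not guessed) — the transit walks bridge past them
  usable <- vapply(rails_by_path, function(rb)
    !is.null(rb$A) && nrow(rb$A) >= 2L, logical(1))
  if (!all(usable)) {
    warning(sprintf("dropping %d spine path(s) without usable strand pairs",
                    sum(!usable)))
    rails_by_path <- rails_by_path[usable]
  }
  if (length(rails_by_path) == 0L) {
    stop("linking failure: no spine path yielded usable strand pairs")
  }
  segs <- list()
  for (rb in rails_by_path) {
    segs[[length(segs) + 1L]] <- list(path = rb$path, rail = "A",
                                      pts = clean_rail(rb$A))
    segs[[length(segs) + 1L]] <- list(path = rb$path, rail = "B",
                                      pts = clean_rail(rb$B))
  }
  # ends: (segment, side) with side 1 = first row (path start side),
  # side 2 = last row (path end side)
  end_pt <- function(s, side) {
    P <- segs[[s]]$pts
    if (side == 1L) P[1L, ] else P[nrow(P), ]
  }

  joins <- list() # each: list(a = c(seg, side), b = c(seg, side), via = pts)
  free_ends <- list()
  for (rb in rails_by_path) {
    sA <- which(vapply(segs, function(s) s$path == rb$path && s$rail == "A",
                       logical(1)))
    sB <- which(vapply(segs, function(s) s$path == rb$path && s$rail == "B",
                       logical(1)))
    # apex joins at free ends of the path; junction-side ends go to the pool
    if (rb$start_degree <= 1L && !rb$cycle) {
      via <- chain_points(rb$caps_head, end_pt(sA, 1L), end_pt(sB, 1L))
      joins[[length(joins) + 1L]] <- list(a = c(sA, 1L), b = c(sB, 1L),
                                          via = via)
    } else {
      free_ends[[length(free_ends) + 1L]] <- c(sA, 1L)
      free_ends[[length(free_ends) + 1L]] <- c(sB, 1L)
    }
    if (rb$end_degree <= 1L && !rb$cycle) {
      via <- chain_points(rb$caps_tail, end_pt(sA, 2L), end_pt(sB, 2L))
      joins[[length(joins) + 1L]] <- list(a = c(sA, 2L), b = c(sB, 2L),
                                          via = via)
    } else {
      free_ends[[length(free_ends) + 1L]] <- c(sA, 2L)
      free_ends[[length(free_ends) + 1L]] <- c(sB, 2L)
    }
  }

  if (length(free_ends) > 0L) {
    if (length(free_ends) %% 2L == 1L) {
      stop("linking failure: odd number of junction-side strand ends")
    }
    coords <- t(vapply(free_ends, function(e) end_pt(e[1L], e[2L]),
                       numeric(3)))
    # outward tangent at each free end (averaged over a few rail points)
    tangents <- t(vapply(free_ends, function(e) {
      P <- segs[[e[1L]]]$pts
      k <- min(4L, nrow(P) - 1L)
      v <- if (e[2L] == 1L) P[1L, ] - P[1L + k, ] else
        P[nrow(P), ] - P[nrow(P) - k, ]
      v / max(sqrt(sum(v^2)), 1e-12)
    }, numeric(3)))
    seg_of <- vapply(free_ends, `[`, integer(1), 1L)
    path_of <- vapply(seg_of, function(s) segs[[s]]$path, integer(1))

    # ridge-following walks through the junction density decide which
    # strand ends are joined by a real transit, and recover its points
    walk_partner <- rep(NA_integer_, length(free_ends))
    walk_via <- vector("list", length(free_ends))
    if (!is.null(volume)) {
      thr <- dna_threshold(volume)
      for (i in seq_along(free_ends)) {
        res <- follow_transit(volume, coords[i, ], tangents[i, ],
                              coords, thr, self = i)
        if (!is.na(res$target) && res$target != i &&
            path_of[res$target] != path_of[i]) {
          walk_partner[i] <- res$target
          walk_via[[i]] <- res$via
        }
      }
    }
    # mutually confirmed walks become fixed joins
    fixed <- list()
    fixed_ends <- integer(0)
    for (i in seq_along(free_ends)) {
      j <- walk_partner[i]
      if (!is.na(j) && i < j && identical(walk_partner[j], i) &&
          !(i %in% fixed_ends) && !(j %in% fixed_ends)) {
        via <- walk_via[[i]]
        # trim walk points that overshoot into the partner rail
        if (!is.null(via) && nrow(via) > 1L) {
          dj <- sqrt(rowSums(sweep(via, 2L, coords[j, ])^2))
          via <- via[seq_len(max(1L, which.min(dj) - 1L)), , drop = FALSE]
        }
        # smooth the seam (rail tail + transit + partner head) so the
        # junction crossing carries no artificial curvature spike
        via <- smooth_transit_seam(segs, free_ends[[i]], free_ends[[j]], via)
        fixed[[length(fixed) + 1L]] <- list(a = free_ends[[i]],
                                            b = free_ends[[j]], via = via)
        fixed_ends <- c(fixed_ends, i, j)
      }
    }
    joins <- c(joins, fixed)
    open_ids <- setdiff(seq_along(free_ends), fixed_ends)
    free_sub <- free_ends[open_ids]

    # pair cost: transit length plus misalignment of the strand tangents
    # with the transit chord (a real junction transit leaves one strand
    # roughly along its tangent and enters the other against its tangent)
    pair_cost <- function(i, j) {
      u <- coords[j, ] - coords[i, ]
      d <- sqrt(sum(u^2))
      if (d < 1e-9) return(0)
      u <- u / d
      d + 15 * ((1 - sum(tangents[i, ] * u)) + (1 + sum(tangents[j, ] * u)))
    }
    if (length(open_ids) > 0L) {
      if (length(open_ids) > 10L) {
        stop(sprintf(paste0("linking failure: %d unresolved junction-side ",
                            "strand ends; too many to match"),
                     length(open_ids)))
      }
      best <- NULL
      best_cost <- Inf
      for (m in perfect_matchings(open_ids)) {
        # transits connect strands of different spine paths
        if (any(path_of[m[, 1L]] == path_of[m[, 2L]])) next
        cand_joins <- c(joins, lapply(seq_len(nrow(m)), function(r) {
          list(a = free_ends[[m[r, 1L]]], b = free_ends[[m[r, 2L]]],
               via = NULL)
        }))
        if (!is_single_cycle(segs, cand_joins)) next
        cost <- sum(vapply(seq_len(nrow(m)), function(r)
          pair_cost(m[r, 1L], m[r, 2L]), numeric(1)))
        if (cost < best_cost) {
          best_cost <- cost
          best <- m
        }
      }
      if (is.null(best)) {
        stop("linking failure: no junction matching closes the tour")
      }
      for (r in seq_len(nrow(best))) {
        joins[[length(joins) + 1L]] <- list(a = free_ends[[best[r, 1L]]],
                                            b = free_ends[[best[r, 2L]]],
                                            via = NULL)
      }
    }
  }

  assemble_tour(segs, joins)
}

# Smooth a junction transit in the context of the rails it joins: local
# quadratic regression over the open polyline (rail tail, via points,
# partner rail head), returning the smoothed via block only.
smooth_transit_seam <- function(segs, end_a, end_b, via, context = 4L,
                                window = 12) {
  if (is.null(via) || nrow(via) < 1L) return(via)
  tail_of <- function(e) {
    P <- segs[[e[1L]]]$pts
    k <- min(context, nrow(P))
    if (e[2L] == 1L) P[k:1L, , drop = FALSE] else
      P[(nrow(P) - k + 1L):nrow(P), , drop = FALSE]
  }
  head_of <- function(e) {
    P <- segs[[e[1L]]]$pts
    k <- min(context, nrow(P))
    if (e[2L] == 1L) P[1L:k, , drop = FALSE] else
      P[nrow(P):(nrow(P) - k + 1L), , drop = FALSE]
  }
  pre <- tail_of(end_a)
  post <- head_of(end_b)
  comb <- rbind(pre, via, post)
  n <- nrow(comb)
  seg_l <- sqrt(rowSums((comb[-1L, , drop = FALSE] -
                           comb[-n, , drop = FALSE])^2))
  arc <- c(0, cumsum(seg_l))
  sm <- comb
  for (i in seq(2L, n - 1L)) {
    nb <- which(abs(arc - arc[i]) <= window)
    if (length(nb) < 5L) next
    ds <- arc[nb] - arc[i]
    X <- cbind(1, ds, ds^2)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, comb[nb, , drop = FALSE])),
                     error = function(e) NULL)
    if (!is.null(beta)) sm[i, ] <- beta[1L, ]
  }
  sm[(nrow(pre) + 1L):(nrow(pre) + nrow(via)), , drop = FALSE]
}

# does the segment/join structure form one cycle covering every segment?
is_single_cycle <- function(segs, joins) {
  n <- length(segs)
  # union-find over segments through joins
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  deg <- matrix(0L, n, 2L)
  for (j in joins) {
    deg[j$a[1L], j$a[2L]] <- deg[j$a[1L], j$a[2L]] + 1L
    deg[j$b[1L], j$b[2L]] <- deg[j$b[1L], j$b[2L]] + 1L
    ra <- find(j$a[1L])
    rb <- find(j$b[1L])
    if (ra != rb) parent[rb] <- ra
  }
  if (any(deg != 1L)) return(FALSE)
  length(unique(vapply(seq_len(n), find, integer(1)))) == 1L
}

# walk segments and joins into one ordered closed point path
assemble_tour <- function(segs, joins) {
  if (!is_single_cycle(segs, joins)) {
    stop("linking failure: strand segments do not close into a single tour")
  }
  join_at <- vector("list", length(segs))
  for (s in seq_along(segs)) join_at[[s]] <- vector("list", 2L)
  for (ji in seq_along(joins)) {
    j <- joins[[ji]]
    join_at[[j$a[1L]]][[j$a[2L]]] <- ji
    join_at[[j$b[1L]]][[j$b[2L]]] <- ji
  }
  used_seg <- logical(length(segs))
  tour <- NULL
  seg <- 1L
  enter_side <- 1L
  repeat {
    P <- segs[[seg]]$pts
    if (enter_side == 2L) P <- P[nrow(P):1L, , drop = FALSE]
    tour <- rbind(tour, P)
    used_seg[seg] <- TRUE
    exit_side <- if (enter_side == 1L) 2L else 1L
    ji <- join_at[[seg]][[exit_side]]
    j <- joins[[ji]]
    if (j$a[1L] == seg && j$a[2L] == exit_side) {
      nxt <- j$b
      via <- j$via
    } else {
      nxt <- j$a
      via <- if (is.null(j$via)) NULL else j$via[nrow(j$via):1L, , drop = FALSE]
    }
    if (!is.null(via)) tour <- rbind(tour, via)
    if (nxt[1L] == 1L && nxt[2L] == 1L) break # back at the starting end
    if (used_seg[nxt[1L]]) {
      stop("linking failure: tour revisits a strand segment")
    }
    seg <- nxt[1L]
    enter_side <- nxt[2L]
  }
  tour <- unname(as.matrix(tour))
  # merge near-duplicate consecutive points (walk/rail overlap)
  seg <- sqrt(rowSums((tour[c(2:nrow(tour), 1L), , drop = FALSE] - tour)^2))
  tour <- tour[seg > 0.5, , drop = FALSE]
  attr(tour, "unresolved") <- matrix(numeric(0), 0L, 3L)
  tour
}

#' Smooth and resample a closed path into the final curve
#'
#' Local-quadratic smoothing along arc length followed by periodic-spline
#' arc-length resampling at the target spacing. Closure is preserved and
#' total contour length stays within 2% of the smoothed path length.
#'
#' @param path ordered closed path: n x 3 matrix or `closed_curve` (>= 8
#'   points).
#' @param target_spacing output point spacing, nm.
#' @param smooth_window smoothing window along arc, nm (default three times
#'   the target spacing).
#' @return a `closed_curve` at the target spacing.
#' @export
refine_curve <- function(path, target_spacing = 2,
                         smooth_window = 3 * target_spacing) {
  pts <- curve_points(path)
  if (nrow(pts) < 8L) stop("refine_curve needs a closed path with >= 8 points")
  sm <- smooth_closed_curve(pts, window = smooth_window)
  out <- resample_curve(closed_curve(sm, validate = FALSE),
                        spacing = target_spacing)
  out$provenance <- c(if (inherits(path, "closed_curve")) path$provenance
                      else list(),
                      list(refine = list(target_spacing = target_spacing,
                                         smooth_window = smooth_window)))
  out
}

#' Trace a plasmid centerline from a density volume
#'
#' Full tracing pipeline: spine skeletonization, sampling-cylinder duplex
#' weight centers, linking into a closed tour, smoothing and resampling.
#' Deterministic given the volume and configuration.
#'
#' @param volume a `density_volume`.
#' @param config a `run_config` (see [run_config()]); all stage parameters
#'   are taken from it.
#' @param interventions optional edited center list (n x 3 matrix) that
#'   replaces the sampled centers before linking — the scriptable analogue
#'   of manual correction.
#' @return a `closed_curve` with full stage provenance.
#' @export
trace_plasmid <- function(volume, config = run_config(), interventions = NULL) {
  spine <- compute_spine(volume,
                         smoothing_sigma = config$spine_smoothing_sigma,
                         threshold_quantile = config$spine_threshold_quantile,
                         prune_length = config$spine_prune_length)
  samples <- sample_duplex_centers(
    volume, spine,
    cylinder_diameter = config$cylinder_diameter,
    cylinder_height = config$cylinder_height,
    step = config$cylinder_step,
    threshold_quantile = config$center_threshold_quantile,
    min_center_separation = config$min_center_separation,
    end_extension = config$sample_end_extension)
  source_pts <- if (is.null(interventions)) samples else interventions
  path <- link_centers(source_pts, max_gap = config$link_max_gap,
                       max_turn = config$link_max_turn,
                       dedup_dist = config$link_dedup_dist,
                       volume = volume)
  curve <- refine_curve(path, target_spacing = config$resample_spacing,
                        smooth_window = config$refine_smooth_window)
  curve$provenance <- list(
    stage = "trace_plasmid",
    config = unclass(config),
    config_hash = config_hash(config),
    n_spine_points = sum(spine$degree > 0),
    n_spine_junctions = spine_junctions(spine),
    n_centers = nrow(samples),
    n_degenerate = sum(samples$degenerate),
    n_empty = sum(samples$empty),
    n_unresolved = nrow(attr(path, "unresolved")))
  curve
}
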