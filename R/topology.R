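#' Writhe of a closed curve (Gauss double integral)
#'
#' Evaluates the discretized Gauss double integral over all non-adjacent
#' segment pairs of the closed polygonal curve, using the exact per-pair
#' solid-angle expression of Klenin & Langowski (method 1a). Right-handed
#' crossings contribute negatively, matching the sign convention in which
#' negatively supercoiled DNA has negative writhe.
#'
#' @param curve a `closed_curve` (or n x 3 point matrix, taken as closed).
#' @param touch_tol segment pairs closer than this (nm) trigger a warning
#'   listing the pair indices; set 0 to disable the check.
#' @return writhe (dimensionless scalar).
#' @export
compute_writhe <- function(curve, touch_tol = 0.1) {
  pts <- curve_points(curve)
  if (nrow(pts) < 4L) stop("writhe needs a closed curve with >= 4 points")
  if (any(!is.finite(pts))) stop("curve points must be finite")
  res <- .writhe_gauss_cpp(pts, touch_tol)
  if (length(res$touch_i) > 0) {
    warning(sprintf(
      "near-touching segments (< %.2f nm) at %d pair(s), e.g. (%d, %d)",
      touch_tol, length(res$touch_i), res$touch_i[1], res$touch_j[1]))
  }
  res$writhe
}

#' Per-point curvature of a closed curve
#'
#' Discrete curvature at each point i from its two cyclic neighbours via the
#' circumscribed-circle formula kappa = 1/R = 4S/(f g h), where S is the area
#' of the triangle (p[i-1], p[i], p[i+1]) and f, g, h are its side lengths.
#' Collinear triples give kappa = 0.
#'
#' @param curve a `closed_curve` with at least 3 points.
#' @return object of class `curvature_profile`: numeric vector of kappa
#'   (1/nm), aligned with curve indices.
#' @export
curvature_profile <- function(curve) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  if (n < 3L) stop("curvature needs at least 3 points")
  prv <- pts[c(n, 1:(n - 1L)), , drop = FALSE]
  nxt <- pts[c(2:n, 1L), , drop = FALSE]
  a <- pts - prv
  b <- nxt - pts
  c_ <- nxt - prv
  f <- sqrt(rowSums(a^2))
  g <- sqrt(rowSums(b^2))
  h <- sqrt(rowSums(c_^2))
  if (any(f < 1e-12) || any(g < 1e-12)) {
    stop("duplicate points in a curvature triple")
  }
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  S <- 0.5 * sqrt(cx^2 + cy^2 + cz^2)
  kappa <- 4 * S / (f * g * h)
  structure(kappa, class = "curvature_profile")
}

#' Detect plectoneme apices from a curvature profile
#'
#' Apices are the high-curvature distal loops capping plectoneme branches.
#' The curvature profile is smoothed along arc length, then strict local
#' maxima with at least `min_prominence` and pairwise arc separation of at
#' least `min_separation` are kept, sorted by descending curvature.
#'
#' @param curve a `closed_curve`.
#' @param profile its `curvature_profile` (computed if missing).
#' @param smooth_window arc-length smoothing window for the profile, nm.
#' @param min_prominence minimal peak prominence, 1/nm.
#' @param min_separation minimal pairwise arc separation between apices, nm.
#' @return object of class `apex_set`: list with `index` (curve indices),
#'   `curvature` (smoothed kappa at each apex), `arc` (arc-length positions,
#'   nm) and `count`.
#' @export
detect_apices <- function(curve, profile = NULL, smooth_window = 10,
                          min_prominence = 0.05, min_separation = 30) {
  if (is.null(profile)) profile <- curvature_profile(curve)
  pts <- curve_points(curve)
  n <- nrow(pts)
  arc <- arc_lengths(curve)
  total <- contour_length(curve)
  kappa <- circular_smooth(as.numeric(profile), arc, total, smooth_window)

  # strict local maxima on the circular profile
  prv <- kappa[c(n, 1:(n - 1L))]
  nxt <- kappa[c(2:n, 1L)]
  peaks <- which(kappa > prv & kappa >= nxt)
  if (length(peaks) == 0L) {
    return(structure(list(index = integer(0), curvature = numeric(0),
                          arc = numeric(0), count = 0L),
                     class = "apex_set"))
  }
  prom <- vapply(peaks, function(p) peak_prominence(kappa, p), numeric(1))
  keep <- peaks[prom >= min_prominence]
  keep <- keep[order(kappa[keep], decreasing = TRUE)]
  chosen <- integer(0)
  for (p in keep) {
    if (all(circ_arc_dist(arc, total, p, chosen) >= min_separation) ||
        length(chosen) == 0L) {
      chosen <- c(chosen, p)
    }
  }
  structure(list(index = chosen, curvature = kappa[chosen],
                 arc = arc[chosen], count = length(chosen)),
            class = "apex_set")
}

#' @export
print.apex_set <- function(x, ...) {
  cat(sprintf("apex_set: %d apices\n", x$count))
  if (x$count > 0) {
    print(data.frame(index = x$index, arc_nm = round(x$arc, 1),
                     curvature = signif(x$curvature, 3)))
  }
  invisible(x)
}

# Gaussian-weighted circular smoothing of a per-point profile along arc length.
circular_smooth <- function(values, arc, total, window) {
  if (window <= 0) return(values)
  n <- length(values)
  sd <- window / 2
  mean_seg <- total / n
  half_k <- min((n - 1L) %/% 2L, max(1L, as.integer(ceiling(3 * sd / mean_seg))))
  offs <- seq(-half_k, half_k)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- ((i - 1L + offs) %% n) + 1L
    ds <- arc[idx] - arc[i]
    ds <- ds - total * round(ds / total)
    w <- exp(-0.5 * (ds / sd)^2)
    out[i] <- sum(w * values[idx]) / sum(w)
  }
  out
}

# prominence of circular profile peak at index p: height above the higher of
# the two minima separating it from taller (or equal) terrain
peak_prominence <- function(values, p) {
  n <- length(values)
  h <- values[p]
  run_min <- function(step) {
    lo <- h
    i <- p
    for (k in seq_len(n - 1L)) {
      i <- ((i - 1L + step) %% n) + 1L
      if (values[i] > h) break
      if (values[i] < lo) lo <- values[i]
    }
    lo
  }
  h - max(run_min(1L), run_min(-1L))
}

#' Radius of gyration and gyration-tensor eigenvalues
#'
#' Gyration tensor of the curve points about their centroid; Rg is the square
#' root of the eigenvalue sum (equal to the root-mean-square distance of
#' points from the centroid). Eigenvalues are returned sorted descending
#' (r1 >= r2 >= r3).
#'
#' @param curve a `closed_curve` or point matrix.
#' @return list with `rg` (nm) and `eigenvalues` (length 3, nm^2).
#' @export
radius_of_gyration <- function(curve) {
  pts <- curve_points(curve)
  if (nrow(pts) < 2L) return(list(rg = 0, eigenvalues = c(0, 0, 0)))
  centered <- sweep(pts, 2L, colMeans(pts))
  gyr <- crossprod(centered) / nrow(pts)
  ev <- sort(eigen(gyr, symmetric = TRUE, only.values = TRUE)$values,
             decreasing = TRUE)
  ev[ev < 0] <- 0
  list(rg = sqrt(sum(ev)), eigenvalues = ev)
}

#' Superhelical axis trace and inter-strand spacing
#'
#' Cuts the curve at its apices into strand groups; each point is paired with
#' its nearest point in any other group (ignoring partners closer than
#' `min_arc_sep` along the curve, so a pairing cannot simply step across an
#' apex). The pair midpoint traces the superhelical axis and the pair
#' distance is the local inter-strand spacing. The first apex anchors the
#' zero of the arc coordinate.
#'
#' @param curve a `closed_curve`.
#' @param apices an `apex_set` with at least 2 apices.
#' @param min_arc_sep minimal along-curve separation of paired points, nm.
#' @return object of class `axis_trace`: data.frame with axis point
#'   coordinates (`x`, `y`, `z`), `spacing` (nm), `curve_index`,
#'   `partner_index`, `group`, and `arc_from_apex` (nm).
#' @export
superhelical_axis <- function(curve, apices, min_arc_sep = 20) {
  if (!inherits(apices, "apex_set")) stop("`apices` must be an apex_set")
  if (apices$count < 2L) stop("no interwound region: fewer than 2 apices")
  pts <- curve_points(curve)
  n <- nrow(pts)
  arc <- arc_lengths(curve)
  total <- contour_length(curve)

  cuts <- sort(apices$index)
  # group g covers indices cuts[g] .. cuts[g+1]-1 (cyclically)
  group <- integer(n)
  for (g in seq_along(cuts)) {
    from <- cuts[g]
    to <- if (g < length(cuts)) cuts[g + 1L] - 1L else cuts[1L] - 1L
    idx <- if (from <= to) from:to else c(from:n, seq_len(max(to, 0L)))
    group[idx] <- g
  }
  group[group == 0L] <- length(cuts) # indices before the first apex

  anchor <- apices$index[1L]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    other <- which(group != group[i])
    if (length(other) == 0L) next
    other <- other[circ_arc_dist(arc, total, i, other) >= min_arc_sep]
    if (length(other) == 0L) next
    d2 <- rowSums(sweep(pts[other, , drop = FALSE], 2L, pts[i, ])^2)
    j <- other[which.min(d2)]
    mid <- (pts[i, ] + pts[j, ]) / 2
    rows[[i]] <- c(mid, sqrt(min(d2)), i, j, group[i],
                   circ_arc_dist(arc, total, i, anchor))
  }
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  out <- as.data.frame(rows)
  names(out) <- c("x", "y", "z", "spacing", "curve_index", "partner_index",
                  "group", "arc_from_apex")
  out$curve_index <- as.integer(out$curve_index)
  out$partner_index <- as.integer(out$partner_index)
  out$group <- as.integer(out$group)
  class(out) <- c("axis_trace", "data.frame")
  out
}

#' Decompose a plasmid into plectoneme branches
#'
#' Builds a thinned polyline graph from the superhelical-axis point cloud
#' (grid snapping plus along-curve connectivity), marks junctions where
#' three or more axis chains meet or where at least three distinct strand
#' passes converge within `junction_radius`, splits chains there, and
#' assigns every curve point to the branch of its nearest non-junction axis
#' point.
#'
#' @param axis an `axis_trace`.
#' @param curve the `closed_curve` the axis was computed from.
#' @param junction_radius radius of the junction neighbourhood, nm.
#' @param corner_angle axis chains bending by more than this angle (degrees,
#'   measured over ~10 nm) are also split; catches two-armed junctions that
#'   leave the axis graph degree-2.
#' @return object of class `branch_decomposition`: list with `branch` (an
#'   integer label per curve point), `n_branches`, `branch_length_nm`
#'   (per-branch axis length), `junction_axis` (logical per axis row), and
#'   `axis_branch` (branch label per axis row, 0 = junction region).
#' @export
segment_branches <- function(axis, curve, junction_radius = 15,
                             corner_angle = 60) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  apts <- as.matrix(axis[, c("x", "y", "z")])
  na <- nrow(apts)

  # --- junction detection: >= 3 distinct strand passes within the radius ---
  # a "pass" is a contiguous run of source curve indices among the axis
  # points near a location; mid-arm there are exactly two (one per strand)
  spacing_est <- if (inherits(curve, "closed_curve")) curve$spacing else
    mean(segment_lengths(pts))
  gap_pts <- max(3L, as.integer(ceiling(junction_radius / spacing_est)))
  near_junction <- logical(na)
  for (t in seq_len(na)) {
    d2 <- rowSums(sweep(apts, 2L, apts[t, ])^2)
    nb <- which(d2 <= junction_radius^2)
    runs <- count_circular_runs(sort(axis$curve_index[nb]), n, gap_pts)
    if (runs >= 3L) near_junction[t] <- TRUE
  }

  # --- axis chains: order axis rows by source curve index (they already are)
  # and link consecutive rows when spatially close; snap to drop the
  # two-fold sampling duplication
  keep <- !near_junction
  labels <- integer(na) # 0 = junction region
  if (any(keep)) {
    labels[keep] <- cluster_points(apts[keep, , drop = FALSE],
                                   link_dist = max(4, 3 * spacing_est))
  }

  # --- split clusters at sharp corners (two-armed junctions) ---
  labels <- split_corner_clusters(apts, labels, axis$curve_index, axis$group,
                                  corner_angle, junction_radius)

  # drop tiny fragments into the junction pool: a genuine branch has many
  # axis points and a usable axis extent
  for (b in unique(labels[labels > 0])) {
    rows <- which(labels == b)
    if (length(rows) < 12L ||
        axis_path_length(apts[rows, , drop = FALSE],
                         axis$curve_index[rows], axis$group[rows]) < 25) {
      labels[rows] <- 0L
    }
  }
  # relabel 1..k
  lev <- sort(unique(labels[labels > 0]))
  relab <- integer(max(labels, 1L))
  relab[lev] <- seq_along(lev)
  labels[labels > 0] <- relab[labels[labels > 0]]
  k <- length(lev)

  if (k == 0L) {
    labels <- rep(1L, na)
    k <- 1L
  }

  # reference polyline per branch (its longest strand pass) and the arc
  # coordinate of every axis point along it; used for unit segmentation
  axis_arc <- rep(NA_real_, na)
  blen <- numeric(k)
  for (b in seq_len(k)) {
    rows <- which(labels == b)
    ref <- axis_reference_pass(apts[rows, , drop = FALSE],
                               axis$curve_index[rows], axis$group[rows])
    blen[b] <- ref$length
    if (nrow(ref$points) >= 2L) {
      for (r in rows) {
        d2 <- rowSums(sweep(ref$points, 2L, apts[r, ])^2)
        axis_arc[r] <- ref$arc[which.min(d2)]
      }
    } else {
      axis_arc[rows] <- 0
    }
  }

  # assign every curve point to the branch of its nearest labelled axis point
  lab_idx <- which(labels > 0)
  lab_pts <- apts[lab_idx, , drop = FALSE]
  branch <- integer(n)
  nearest_axis_row <- integer(n)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(lab_pts, 2L, pts[i, ])^2)
    row <- lab_idx[which.min(d2)]
    branch[i] <- labels[row]
    nearest_axis_row[i] <- row
  }

  structure(list(branch = branch, n_branches = k,
                 branch_length_nm = blen,
                 junction_axis = near_junction,
                 axis_branch = labels,
                 axis_arc = axis_arc,
                 nearest_axis_row = nearest_axis_row),
            class = "branch_decomposition")
}

# longest contiguous strand pass among a branch's axis points, with its
# cumulative arc coordinates: the branch's reference axis polyline. A pass
# ends where the source indices jump or the strand group changes (each
# group traverses the axis once; crossing a group boundary would fold the
# pass back on itself at an apex).
axis_reference_pass <- function(apts, curve_index, group) {
  ord <- order(curve_index)
  apts <- apts[ord, , drop = FALSE]
  ci <- curve_index[ord]
  gr <- group[ord]
  brk <- c(0L, which(diff(ci) > 10L | diff(gr) != 0L), length(ci))
  best <- NULL
  best_len <- -1
  for (s in seq_len(length(brk) - 1L)) {
    ix <- (brk[s] + 1L):brk[s + 1L]
    if (length(ix) < 2L) next
    P <- apts[ix, , drop = FALSE]
    len <- poly_len(P)
    if (len > best_len) {
      best_len <- len
      best <- P
    }
  }
  if (is.null(best)) {
    return(list(points = apts, arc = rep(0, nrow(apts)), length = 0))
  }
  seg <- sqrt(rowSums((best[-1L, , drop = FALSE] -
                         best[-nrow(best), , drop = FALSE])^2))
  list(points = best, arc = c(0, cumsum(seg)), length = best_len)
}

# number of runs of (sorted) curve indices, circular in 1..n, split at gaps
# larger than gap_pts
count_circular_runs <- function(idx, n, gap_pts) {
  if (length(idx) == 0L) return(0L)
  if (length(idx) == 1L) return(1L)
  gaps <- diff(idx)
  wrap_gap <- idx[1L] + n - idx[length(idx)]
  breaks <- sum(gaps > gap_pts) + (wrap_gap > gap_pts)
  max(1L, breaks)
}

# single-linkage spatial clustering via union on a kNN-style radius graph
cluster_points <- function(pts, link_dist) {
  m <- nrow(pts)
  if (m == 0L) return(integer(0))
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  d2max <- link_dist^2
  for (i in seq_len(m - 1L)) {
    d2 <- rowSums(sweep(pts[(i + 1L):m, , drop = FALSE], 2L, pts[i, ])^2)
    for (j in which(d2 <= d2max)) {
      ri <- find(i)
      rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(m), find, integer(1))
  match(roots, unique(roots))
}

# split clusters whose internal polyline turns sharply (V-shaped junctions):
# orders each cluster's axis points along the dominant strand pass, smooths,
# and cuts at direction changes above the angle threshold
split_corner_clusters <- function(apts, labels, curve_index, group,
                                  corner_angle, junction_radius) {
  if (corner_angle >= 180) return(labels)
  cos_thr <- cos(corner_angle * pi / 180)
  next_label <- max(labels) + 1L
  for (b in sort(unique(labels[labels > 0]))) {
    rows <- which(labels == b)
    if (length(rows) < 12L) next
    ord <- rows[order(curve_index[rows])]
    # use the longest single strand pass (pass = contiguous indices within
    # one group; a group change folds back at an apex)
    ci <- curve_index[ord]
    gr <- group[ord]
    brk <- c(0L, which(diff(ci) > 10L | diff(gr) != 0L), length(ci))
    seg_len <- diff(brk)
    s_best <- which.max(seg_len)
    pass <- ord[(brk[s_best] + 1L):brk[s_best + 1L]]
    if (length(pass) < 12L) next
    P <- apts[pass, , drop = FALSE]
    # smooth the pass so point noise cannot mimic a corner
    P <- apply(rbind(P[1L, ], P[1L, ], P, P[nrow(P), ], P[nrow(P), ]), 2L,
               function(col) as.numeric(stats::filter(col, rep(0.2, 5),
                                                      sides = 2))[
                 3:(length(col) - 2L)])
    mean_sp <- poly_len(P) / max(nrow(P) - 1L, 1L)
    # direction change across +- 30 nm, wide enough to integrate a gentle
    # junction bend; corners cannot sit in the distal cap region of an arm,
    # so exclude a zone near the pass ends
    w <- max(3L, as.integer(ceiling(30 / mean_sp)))
    excl <- max(w, as.integer(ceiling(25 / mean_sp)))
    if (nrow(P) <= 2L * excl + 1L) next
    cut_at <- integer(0)
    for (i in seq(excl + 1L, nrow(P) - excl)) {
      v1 <- P[i, ] - P[i - w, ]
      v2 <- P[i + w, ] - P[i, ]
      n1 <- sqrt(sum(v1^2))
      n2 <- sqrt(sum(v2^2))
      if (n1 < 1e-9 || n2 < 1e-9) next
      if (sum(v1 * v2) / (n1 * n2) < cos_thr) cut_at <- c(cut_at, i)
    }
    if (length(cut_at) == 0L) next
    # merge contiguous cut positions, take their centers as corners
    corners <- split(cut_at, cumsum(c(1, diff(cut_at) > w)))
    corner_pts <- t(vapply(corners, function(ix) P[ix[ceiling(length(ix) / 2)], ],
                           numeric(3)))
    # points within the junction ball of a corner go to label 0; the rest
    # split by which corner-free segment of the pass they are closest to
    bounds <- sort(vapply(corners, function(ix) ix[ceiling(length(ix) / 2)],
                          numeric(1)))
    pass_seg <- findInterval(seq_len(nrow(P)), bounds + 0.5) + 1L
    # map every row of the cluster to nearest pass point
    Pall <- apts[rows, , drop = FALSE]
    nearest <- vapply(seq_len(nrow(Pall)), function(r) {
      which.min(rowSums(sweep(P, 2L, Pall[r, ])^2))
    }, integer(1))
    newseg <- pass_seg[nearest]
    # junction ball: within junction_radius of any corner
    for (r in seq_along(rows)) {
      dmin <- min(sqrt(rowSums(sweep(corner_pts, 2L, Pall[r, ])^2)))
      if (dmin <= junction_radius) {
        labels[rows[r]] <- 0L
      } else {
        labels[rows[r]] <- if (newseg[r] == 1L) b else
          next_label + newseg[r] - 2L
      }
    }
    next_label <- max(labels) + 1L
  }
  labels
}

# axis length of one branch: polyline length of its reference strand pass
axis_path_length <- function(apts, curve_index, group) {
  axis_reference_pass(apts, curve_index, group)$length
}

#' Per-branch writhe density
#'
#' Treats each branch's curve points as a smaller closed curve (straight
#' chord closure between the arc endpoints) and computes its writhe. Branches
#' whose axis is longer than `unit_length` are split into consecutive
#' equal-length units along the curve, each scored as writhe per unit axis
#' length; shorter branches form single units.
#'
#' @param curve a `closed_curve`.
#' @param decomposition a `branch_decomposition` for `curve`.
#' @param unit_length segmentation unit along the branch axis, nm.
#' @return data.frame with `branch`, `unit`, `axis_length_nm`, `writhe`,
#'   and `density` (1/nm).
#' @export
branch_writhe_density <- function(curve, decomposition, unit_length = 100) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  out <- list()
  for (b in seq_len(decomposition$n_branches)) {
    idx <- which(decomposition$branch == b)
    if (length(idx) < 6L) {
      warning(sprintf("branch %d has < 6 points; skipped", b))
      next
    }
    blen <- decomposition$branch_length_nm[b]
    n_units <- max(1L, as.integer(floor(blen / unit_length)))
    # cut the branch into consecutive units along its axis; every curve
    # point carries the axis-arc coordinate of its nearest axis point
    coord <- decomposition$axis_arc[decomposition$nearest_axis_row[idx]]
    coord[!is.finite(coord)] <- 0
    breaks <- seq(0, max(blen, max(coord)), length.out = n_units + 1L)
    unit_of <- findInterval(coord, breaks, all.inside = TRUE)
    chunks <- lapply(seq_len(n_units), function(u)
      order_circular_indices(idx[unit_of == u], n))
    for (u in seq_along(chunks)) {
      ci <- chunks[[u]]
      if (length(ci) < 6L) {
        warning(sprintf("branch %d unit %d has < 6 points; skipped", b, u))
        next
      }
      sub <- pts[ci, , drop = FALSE]
      wr <- compute_writhe(closed_curve(sub, validate = FALSE), touch_tol = 0)
      ulen <- blen / n_units
      out[[length(out) + 1L]] <- data.frame(
        branch = b, unit = u, axis_length_nm = ulen, writhe = wr,
        density = wr / ulen)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(branch = integer(0), unit = integer(0),
                      axis_length_nm = numeric(0), writhe = numeric(0),
                      density = numeric(0)))
  }
  do.call(rbind, out)
}

# order a set of curve indices into a contiguous circular arc if possible:
# rotate so the largest gap is the break point
order_circular_indices <- function(idx, n) {
  idx <- sort(idx)
  if (length(idx) < 2L) return(idx)
  gaps <- c(diff(idx), idx[1L] + n - idx[length(idx)])
  cut <- which.max(gaps)
  if (cut == length(idx)) idx else c(idx[(cut + 1L):length(idx)], idx[1:cut])
}

#' Linking-number bookkeeping
#'
#' @param dLk linking-number difference from the relaxed state, turns.
#' @param Lk0 relaxed linking number, turns.
#' @param Wr writhe (optional).
#' @return object of class `linking_state` with fields `dLk`, `Lk0`, `Wr`
#'   plus derived `sigma` (= dLk/Lk0) and `dTw` (= dLk - Wr); the derived
#'   values are always recomputed, never stored independently.
#' @export
linking_state <- function(dLk, Lk0, Wr = NA_real_) {
  if (!is.finite(Lk0) || Lk0 <= 0) stop("Lk0 must be positive")
  structure(list(dLk = dLk, Lk0 = Lk0, Wr = Wr), class = "linking_state")
}

#' @export
print.linking_state <- function(x, ...) {
  cat(sprintf("linking_state: dLk = %g, Lk0 = %g, sigma = %.4f", x$dLk, x$Lk0,
              supercoiling_density(x$dLk, x$Lk0)))
  if (is.finite(x$Wr)) cat(sprintf(", Wr = %g, dTw = %g", x$Wr, delta_twist(x)))
  cat("\n")
  invisible(x)
}

#' Supercoiling density sigma = dLk / Lk0
#' @param dLk linking-number difference, turns.
#' @param Lk0 relaxed linking number, turns (> 0).
#' @return sigma (dimensionless).
#' @export
supercoiling_density <- function(dLk, Lk0) {
  if (any(!is.finite(Lk0)) || any(Lk0 <= 0)) stop("Lk0 must be positive")
  dLk / Lk0
}

#' Relaxed linking number from plasmid size
#' @param n_bp plasmid size in base pairs.
#' @param helical_repeat B-DNA helical repeat, bp per turn.
#' @return Lk0 in turns (rounded to the nearest integer).
#' @export
lk0_from_size <- function(n_bp, helical_repeat = 10.5) {
  if (any(n_bp <= 0) || helical_repeat <= 0) {
    stop("n_bp and helical_repeat must be positive")
  }
  round(n_bp / helical_repeat)
}

#' Twist change dTw = dLk - Wr (White's theorem bookkeeping)
#' @param state a `linking_state` with finite `Wr`.
#' @return dTw in turns.
#' @export
delta_twist <- function(state) {
  if (!inherits(state, "linking_state")) stop("expected a linking_state")
  if (!is.finite(state$Wr)) stop("Wr not set on this linking_state")
  state$dLk - state$Wr
}

#' Full topological summary of a traced plasmid
#'
#' Composes writhe, radius of gyration, curvature, apex detection,
#' superhelical-axis tracing, branch decomposition and per-branch writhe
#' densities into one serializable record.
#'
#' @param curve a `closed_curve`.
#' @param config a `run_config` (defaults taken from [run_config()]).
#' @return object of class `topology_summary` (a list; see fields).
#' @export
summarize_topology <- function(curve, config = run_config()) {
  profile <- curvature_profile(curve)
  apices <- detect_apices(curve, profile,
                          smooth_window = config$apex_smooth_window,
                          min_prominence = config$apex_min_prominence,
                          min_separation = config$apex_min_separation)
  wr <- compute_writhe(curve)
  rg <- radius_of_gyration(curve)
  total <- contour_length(curve)
  arc <- arc_lengths(curve)

  axis <- NULL
  decomposition <- NULL
  densities <- NULL
  mean_apical_spacing <- NA_real_
  if (apices$count >= 2L) {
    axis <- superhelical_axis(curve, apices, min_arc_sep = config$axis_min_arc_sep)
    decomposition <- segment_branches(axis, curve,
                                      junction_radius = config$junction_radius)
    densities <- branch_writhe_density(curve, decomposition,
                                       unit_length = config$writhe_density_unit)
    near_apex <- vapply(axis$curve_index, function(i) {
      min(circ_arc_dist(arc, total, i, apices$index)) <= config$apex_window
    }, logical(1))
    if (any(near_apex)) mean_apical_spacing <- mean(axis$spacing[near_apex])
  }

  structure(list(
    writhe = wr,
    rg = rg$rg,
    gyration_eigenvalues = rg$eigenvalues,
    contour_length_nm = total,
    n_points = length(curve),
    apex_count = apices$count,
    apex_arc_nm = apices$arc,
    apex_index = apices$index,
    mean_apex_curvature = if (apices$count > 0) mean(apices$curvature) else NA_real_,
    mean_apical_spacing_nm = mean_apical_spacing,
    n_branches = if (!is.null(decomposition)) decomposition$n_branches else 1L,
    branch_length_nm = if (!is.null(decomposition))
      decomposition$branch_length_nm else numeric(0),
    writhe_density = densities,
    branch = if (!is.null(decomposition)) decomposition$branch else
      rep(1L, length(curve)),
    curvature = as.numeric(profile),
    axis = axis,
    config_hash = config_hash(config)
  ), class = "topology_summary")
}

#' @export
print.topology_summary <- function(x, ...) {
  cat(sprintf(paste0(
    "topology_summary: Wr = %.2f, Rg = %.1f nm, contour = %.0f nm, ",
    "%d apices, %d branch(es)\n"),
    x$writhe, x$rg, x$contour_length_nm, x$apex_count, x$n_branches))
  invisible(x)
}

#' Serialize a topology summary to JSON (and back)
#'
#' @param summary a `topology_summary`.
#' @param path file to write; if NULL the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_summary_json <- function(summary, path = NULL) {
  x <- unclass(summary)
  x$axis <- if (!is.null(x$axis)) as.data.frame(unclass(x$axis)) else NULL
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_summary_json
#' @param json_or_path JSON string or path to a JSON file.
#' @export
read_summary_json <- function(json_or_path) {
  x <- jsonlite::fromJSON(json_or_path, simplifyVector = TRUE)
  if (!is.null(x$axis)) class(x$axis) <- c("axis_trace", "data.frame")
  class(x) <- "topology_summary"
  x
}
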