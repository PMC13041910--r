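#' Closed 3D curve
#'
#' Container for a traced DNA duplex centerline: an ordered, closed sequence
#' of 3D points in nanometres. The closure edge runs from the last point back
#' to the first; indices are reported 0-based in file output, 1-based inside
#' R as usual.
#'
#' @param points numeric matrix with 3 columns (x, y, z in nm), one row per
#'   point, ordered along the curve. The first point must not be repeated at
#'   the end.
#' @param spacing nominal point spacing in nm (defaults to the mean segment
#'   length including the closure edge).
#' @param provenance optional list recording how the curve was produced.
#' @param validate check closure sanity (no duplicate consecutive points).
#' @return an object of class `closed_curve`.
#' @export
closed_curve <- function(points, spacing = NULL, provenance = list(),
                         validate = TRUE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("`points` must have 3 columns (x, y, z)")
  if (nrow(points) < 3L) stop("a closed curve needs at least 3 points")
  dimnames(points) <- list(NULL, c("x", "y", "z"))
  seg <- segment_lengths(points)
  if (validate) {
    if (any(!is.finite(points))) stop("curve points must be finite")
    if (any(seg < 1e-9)) stop("duplicate consecutive points in curve")
  }
  if (is.null(spacing)) spacing <- mean(seg)
  structure(list(points = points, spacing = spacing, provenance = provenance),
            class = "closed_curve")
}

#' @export
print.closed_curve <- function(x, ...) {
  cat(sprintf("closed_curve: %d points, contour %.1f nm, spacing %.2f nm\n",
              nrow(x$points), contour_length(x), x$spacing))
  invisible(x)
}

#' @export
length.closed_curve <- function(x) nrow(x$points)

# per-segment lengths, including the closure edge (row i -> row i+1, last -> first)
segment_lengths <- function(points) {
  nxt <- points[c(2:nrow(points), 1L), , drop = FALSE]
  sqrt(rowSums((nxt - points)^2))
}

#' Total contour length of a closed curve (nm)
#' @param curve a `closed_curve`.
#' @return contour length in nm, including the closure edge.
#' @export
contour_length <- function(curve) {
  sum(segment_lengths(curve_points(curve)))
}

# Accept a closed_curve or a bare point matrix.
curve_points <- function(curve) {
  if (inherits(curve, "closed_curve")) curve$points
  else {
    m <- as.matrix(curve)
    if (ncol(m) != 3L) stop("expected a closed_curve or an n x 3 matrix")
    m
  }
}

#' Arc-length coordinate of each curve point (nm)
#'
#' @param curve a `closed_curve`.
#' @return numeric vector: arc length from point 1 to each point
#'   (first element 0).
#' @export
arc_lengths <- function(curve) {
  pts <- curve_points(curve)
  seg <- segment_lengths(pts)
  c(0, cumsum(seg))[seq_len(nrow(pts))]
}

# circular arc distance between two point indices
circ_arc_dist <- function(arc, total, i, j) {
  d <- abs(arc[i] - arc[j])
  pmin(d, total - d)
}

#' Resample a closed curve at uniform arc-length spacing
#'
#' Fits periodic cubic splines to x(s), y(s), z(s) over cumulative arc length
#' and evaluates them on a uniform grid, so the result is closed with
#' near-equal point spacing.
#'
#' @param curve a `closed_curve` (or n x 3 matrix, taken as closed).
#' @param spacing target point spacing in nm.
#' @param n_points alternatively, the exact number of output points.
#' @return a `closed_curve` at the requested spacing.
#' @export
resample_curve <- function(curve, spacing = 2, n_points = NULL) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  seg <- segment_lengths(pts)
  total <- sum(seg)
  s <- c(0, cumsum(seg)) # length n+1, periodic knots
  if (is.null(n_points)) n_points <- max(8L, as.integer(round(total / spacing)))
  s_new <- seq(0, total, length.out = n_points + 1L)[seq_len(n_points)]
  out <- matrix(0, n_points, 3L)
  for (c in 1:3) {
    vals <- c(pts[, c], pts[1L, c]) # periodic: repeat first point at s = total
    f <- stats::splinefun(s, vals, method = "periodic")
    out[, c] <- f(s_new)
  }
  prov <- if (inherits(curve, "closed_curve")) curve$provenance else list()
  closed_curve(out, spacing = total / n_points, provenance = prov)
}

#' Smooth a closed curve along arc length
#'
#' Local quadratic (Savitzky-Golay style) regression of each coordinate
#' against arc length over a circular window. Quadratic fits pass smooth
#' arcs nearly unchanged (no inward curvature bias) while averaging out
#' point noise.
#'
#' @param curve a `closed_curve` or n x 3 matrix.
#' @param window full window width in nm; at least 5 points are always used.
#' @return matrix of smoothed points (same row count).
#' @export
smooth_closed_curve <- function(curve, window) {
  pts <- curve_points(curve)
  n <- nrow(pts)
  seg <- segment_lengths(pts)
  mean_seg <- mean(seg)
  half_k <- max(2L, as.integer(ceiling((window / 2) / mean_seg)))
  if (2L * half_k + 1L >= n) half_k <- (n - 1L) %/% 2L
  arc <- c(0, cumsum(seg)) # arc[i] = arc length at point i (1-based), arc[n+1] = total
  total <- arc[n + 1L]
  out <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    idx <- ((i - 1L + seq(-half_k, half_k)) %% n) + 1L
    ds <- arc[idx] - arc[i]
    # unwrap circular arc offsets
    ds <- ds - total * round(ds / total)
    X <- cbind(1, ds, ds^2)
    # closed-form local quadratic: value at ds = 0 for each coordinate
    XtX <- crossprod(X)
    beta <- solve(XtX, crossprod(X, pts[idx, , drop = FALSE]))
    out[i, ] <- beta[1L, ]
  }
  out
}

#' Apply a rigid transform (and optional scaling) to a curve
#'
#' @param curve a `closed_curve`.
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 offset in nm.
#' @param scale uniform scale factor.
#' @return transformed `closed_curve`.
#' @export
transform_curve <- function(curve, rotation = diag(3), translation = c(0, 0, 0),
                            scale = 1) {
  pts <- curve_points(curve) * scale
  pts <- pts %*% t(rotation)
  pts <- sweep(pts, 2L, translation, "+")
  closed_curve(pts, provenance = if (inherits(curve, "closed_curve"))
    curve$provenance else list())
}

#' Mirror-reflect a curve through the yz plane
#' @param curve a `closed_curve`.
#' @return reflected `closed_curve` (x negated).
#' @export
reflect_curve <- function(curve) {
  pts <- curve_points(curve)
  pts[, 1] <- -pts[, 1]
  closed_curve(pts, provenance = if (inherits(curve, "closed_curve"))
    curve$provenance else list())
}
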