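# Shared fixtures, built once per test run. All geometry is generated in
# code; seeds are fixed so every run sees identical objects.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fx_circle10 <- function() fixture("circle10", function() make_circle(10, 500))
fx_circle100 <- function() fixture("circle100", function() make_circle(100, 500))
fx_plectoneme <- function() {
  fixture("plectoneme", function() make_plectoneme(660, -6, 8, 5, seed = 1))
}
fx_branched3 <- function() {
  fixture("branched3", function()
    make_branched_plectoneme(660, c(-3, -3, -3), 8, 5, seed = 2))
}
fx_branched2 <- function() {
  fixture("branched2", function()
    make_branched_plectoneme(660, c(-4, -4), 8, 5, seed = 3))
}

# independent writhe oracle: midpoint-quadrature Gauss double integral,
# pure R, a different numerical route from the exact segment-pair formula
writhe_midpoint <- function(points) {
  P <- curve_points(points)
  n <- nrow(P)
  nxt <- P[c(2:n, 1L), , drop = FALSE]
  seg <- nxt - P
  mid <- (P + nxt) / 2
  total <- 0
  for (i in seq_len(n - 2L)) {
    j <- (i + 2L):n
    if (i == 1L) j <- j[j != n]
    r <- sweep(mid[j, , drop = FALSE], 2L, mid[i, ])
    d3 <- (rowSums(r^2))^(3 / 2)
    cx <- seg[i, 2] * seg[j, 3] - seg[i, 3] * seg[j, 2]
    cy <- seg[i, 3] * seg[j, 1] - seg[i, 1] * seg[j, 3]
    cz <- seg[i, 1] * seg[j, 2] - seg[i, 2] * seg[j, 1]
    # r points from segment i to segment j, so the integrand needs r_i - r_j
    total <- total - sum((cx * r[, 1] + cy * r[, 2] + cz * r[, 3]) / d3)
  }
  total / (2 * pi)
}

# random rigid rotation matrix from a fixed seed
random_rotation <- function(seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_ <- qr(M)
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

# label-agreement between generator arm labels and a branch assignment:
# fraction of points whose estimated branch maps to their true arm under
# the best per-branch relabelling
branch_agreement <- function(true_label, est_label) {
  tab <- table(true_label, est_label)
  sum(apply(tab, 2L, max)) / length(true_label)
}
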