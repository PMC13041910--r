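#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline double clamp1(double x) {
  if (x > 1.0) return 1.0;
  if (x < -1.0) return -1.0;
  return x;
}

// Solid angle (signed) subtended by segment pair (p1->p2, p3->p4),
// exact per-pair expression of Klenin & Langowski (method 1a).
static double pair_omega(const double* p1, const double* p2,
                         const double* p3, const double* p4) {
  double r12[3], r34[3], r13[3], r14[3], r23[3], r24[3];
  for (int c = 0; c < 3; ++c) {
    r12[c] = p2[c] - p1[c];
    r34[c] = p4[c] - p3[c];
    r13[c] = p3[c] - p1[c];
    r14[c] = p4[c] - p1[c];
    r23[c] = p3[c] - p2[c];
    r24[c] = p4[c] - p2[c];
  }
  double n1[3], n2[3], n3[3], n4[3];
  cross3(r13, r14, n1);
  cross3(r14, r24, n2);
  cross3(r24, r23, n3);
  cross3(r23, r13, n4);
  const double eps = 1e-14;
  double l1 = std::sqrt(dot3(n1, n1));
  double l2 = std::sqrt(dot3(n2, n2));
  double l3 = std::sqrt(dot3(n3, n3));
  double l4 = std::sqrt(dot3(n4, n4));
  if (l1 < eps || l2 < eps || l3 < eps || l4 < eps) return 0.0; // coplanar
  for (int c = 0; c < 3; ++c) {
    n1[c] /= l1; n2[c] /= l2; n3[c] /= l3; n4[c] /= l4;
  }
  double omega = std::asin(clamp1(dot3(n1, n2))) +
                 std::asin(clamp1(dot3(n2, n3))) +
                 std::asin(clamp1(dot3(n3, n4))) +
                 std::asin(clamp1(dot3(n4, n1)));
  double cr[3];
  cross3(r34, r12, cr);
  double s = dot3(cr, r13);
  if (s > 0) return omega;
  if (s < 0) return -omega;
  return 0.0;
}

// Distance between two 3D segments (for the near-touch warning only).
static double seg_seg_dist(const double* p1, const double* p2,
                           const double* p3, const double* p4) {
  double d1[3], d2[3], r[3];
  for (int c = 0; c < 3; ++c) {
    d1[c] = p2[c] - p1[c];
    d2[c] = p4[c] - p3[c];
    r[c]  = p1[c] - p3[c];
  }
  double a = dot3(d1, d1), e = dot3(d2, d2), f = dot3(d2, r);
  double s = 0.0, t = 0.0;
  const double eps = 1e-12;
  if (a <= eps && e <= eps) {
    // both degenerate
  } else if (a <= eps) {
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = dot3(d1, r);
    if (e <= eps) {
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = dot3(d1, d2);
      double denom = a * e - b * b;
      if (denom > eps) s = std::min(1.0, std::max(0.0, (b * f - c * e) / denom));
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  double dx[3];
  for (int c = 0; c < 3; ++c) dx[c] = (p1[c] + s * d1[c]) - (p3[c] + t * d2[c]);
  return std::sqrt(dot3(dx, dx));
}

// [[Rcpp::export(name = ".writhe_gauss_cpp")]]
List writhe_gauss_cpp(NumericMatrix pts, double touch_tol) {
  int n = pts.nrow();
  std::vector<double> P(3 * n);
  for (int i = 0; i < n; ++i) {
    P[3 * i] = pts(i, 0);
    P[3 * i + 1] = pts(i, 1);
    P[3 * i + 2] = pts(i, 2);
  }
  double total = 0.0;
  std::vector<int> touch_i, touch_j;
  for (int i = 0; i < n; ++i) {
    const double* a1 = &P[3 * i];
    const double* a2 = &P[3 * ((i + 1) % n)];
    for (int j = i + 2; j < n; ++j) {
      if (i == 0 && j == n - 1) continue; // adjacent through closure
      const double* b1 = &P[3 * j];
      const double* b2 = &P[3 * ((j + 1) % n)];
      total += pair_omega(a1, a2, b1, b2);
      if (touch_tol > 0) {
        // cheap bound before the exact segment distance
        double dx = b1[0] - a1[0], dy = b1[1] - a1[1], dz = b1[2] - a1[2];
        double d2 = dx * dx + dy * dy + dz * dz;
        double va[3] = {a2[0]-a1[0], a2[1]-a1[1], a2[2]-a1[2]};
        double vb[3] = {b2[0]-b1[0], b2[1]-b1[1], b2[2]-b1[2]};
        double bound = touch_tol + std::sqrt(dot3(va, va)) + std::sqrt(dot3(vb, vb));
        if (d2 < bound * bound &&
            seg_seg_dist(a1, a2, b1, b2) < touch_tol) {
          touch_i.push_back(i + 1);
          touch_j.push_back(j + 1);
        }
      }
    }
  }
  double wr = total / (2.0 * M_PI); // unordered pairs counted once: 2x / 4pi
  return List::create(_["writhe"] = wr,
                      _["touch_i"] = wrap(touch_i),
                      _["touch_j"] = wrap(touch_j));
}

// Minimum distance between non-adjacent curve points (self-avoidance check).
// Points i, j compared only when their cyclic index separation exceeds skip.
// [[Rcpp::export(name = ".min_nonadjacent_dist_cpp")]]
double min_nonadjacent_dist_cpp(NumericMatrix pts, int skip) {
  int n = pts.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      int sep = j - i;
      int csep = std::min(sep, n - sep);
      if (csep <= skip) continue;
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < best) best = d;
    }
  }
  return best;
}
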