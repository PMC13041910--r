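#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ---- 3D topology-preserving thinning -------------------------------------
//
// Curve thinning of a binary volume under (26, 6) connectivity. A border
// voxel is deleted when it is a simple point (removal preserves both object
// and background topology) and not a curve endpoint. Simplicity is tested
// directly with the local characterization of Bertrand & Malandain:
//   * exactly one 26-connected object component in the 26-neighborhood,
//   * exactly one 6-connected background component in the 18-neighborhood
//     that touches a face neighbor of the voxel.
// Deletion proceeds in 6 directional subiterations for approximate
// medialness and is fully deterministic.

namespace {

int lx[27], ly[27], lz[27];
bool adj26tab[27][27];
bool adj6tab[27][27];
bool is18tab[27];
bool is6tab[27];
bool tables_ready = false;

void init_tables() {
  if (tables_ready) return;
  for (int L = 0; L < 27; ++L) {
    lx[L] = L % 3 - 1;
    ly[L] = (L / 3) % 3 - 1;
    lz[L] = L / 9 - 1;
    int s = std::abs(lx[L]) + std::abs(ly[L]) + std::abs(lz[L]);
    is18tab[L] = (L != 13) && s <= 2;
    is6tab[L] = (s == 1);
  }
  for (int a = 0; a < 27; ++a) {
    for (int b = 0; b < 27; ++b) {
      int dx = std::abs(lx[a] - lx[b]);
      int dy = std::abs(ly[a] - ly[b]);
      int dz = std::abs(lz[a] - lz[b]);
      adj26tab[a][b] = (a != b) && dx <= 1 && dy <= 1 && dz <= 1;
      adj6tab[a][b] = (dx + dy + dz == 1);
    }
  }
  tables_ready = true;
}

struct Grid {
  std::vector<unsigned char>* m;
  int nx, ny, nz;
  inline bool at(int x, int y, int z) const {
    if (x < 0 || y < 0 || z < 0 || x >= nx || y >= ny || z >= nz) return false;
    return (*m)[x + nx * (y + (size_t)ny * z)] != 0;
  }
};

// local 3x3x3 occupancy around (x,y,z), center at L=13
inline void local_occ(const Grid& g, int x, int y, int z, bool occ[27]) {
  for (int L = 0; L < 27; ++L)
    occ[L] = g.at(x + lx[L], y + ly[L], z + lz[L]);
}

inline int count26(const bool occ[27]) {
  int c = 0;
  for (int L = 0; L < 27; ++L)
    if (L != 13 && occ[L]) ++c;
  return c;
}

bool is_simple(const bool occ[27]) {
  // one 26-component of object voxels in N26
  int comp = 0;
  int label[27];
  for (int L = 0; L < 27; ++L) label[L] = -1;
  int stack[27];
  for (int L = 0; L < 27; ++L) {
    if (L == 13 || !occ[L] || label[L] >= 0) continue;
    if (comp == 1) return false; // second component found
    ++comp;
    int top = 0;
    stack[top++] = L;
    label[L] = comp;
    while (top > 0) {
      int c = stack[--top];
      for (int d = 0; d < 27; ++d) {
        if (d != 13 && occ[d] && label[d] < 0 && adj26tab[c][d]) {
          label[d] = comp;
          stack[top++] = d;
        }
      }
    }
  }
  if (comp != 1) return false;

  // one 6-component of background voxels in N18 touching a face neighbor
  int bcomp = 0;
  for (int L = 0; L < 27; ++L) label[L] = -1;
  for (int L = 0; L < 27; ++L) {
    if (!is6tab[L] || occ[L] || label[L] >= 0) continue;
    if (bcomp == 1) return false;
    ++bcomp;
    int top = 0;
    stack[top++] = L;
    label[L] = bcomp;
    while (top > 0) {
      int c = stack[--top];
      for (int d = 0; d < 27; ++d) {
        if (is18tab[d] && !occ[d] && label[d] < 0 && adj6tab[c][d]) {
          label[d] = bcomp;
          stack[top++] = d;
        }
      }
    }
  }
  return bcomp == 1;
}

} // namespace

// [[Rcpp::export(name = ".thin3d_cpp")]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dims) {
  init_tables();
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<unsigned char> m(n);
  for (size_t i = 0; i < n; ++i) m[i] = mask[i] ? 1 : 0;
  Grid g{&m, nx, ny, nz};

  const int dirs[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  bool occ[27];
  bool changed = true;
  std::vector<size_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            size_t idx = x + nx * (y + (size_t)ny * z);
            if (!m[idx]) continue;
            if (g.at(x + dirs[d][0], y + dirs[d][1], z + dirs[d][2])) continue;
            local_occ(g, x, y, z, occ);
            if (count26(occ) <= 1) continue; // endpoint: keep
            if (is_simple(occ)) cand.push_back(idx);
          }
      // sequential re-check so deletions stay topology-safe
      for (size_t k = 0; k < cand.size(); ++k) {
        size_t idx = cand[k];
        int x = idx % nx;
        int y = (idx / nx) % ny;
        int z = idx / ((size_t)nx * ny);
        local_occ(g, x, y, z, occ);
        if (count26(occ) <= 1) continue;
        if (is_simple(occ)) {
          m[idx] = 0;
          changed = true;
        }
      }
    }
  }
  LogicalVector out(n);
  for (size_t i = 0; i < n; ++i) out[i] = m[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---- separable Gaussian blur ----------------------------------------------

// [[Rcpp::export(name = ".blur3d_cpp")]]
NumericVector blur3d_cpp(NumericVector vol, IntegerVector dims, double sigma) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  if (sigma <= 0) return clone(vol);
  int rad = (int)std::ceil(3.0 * sigma);
  std::vector<double> ker(2 * rad + 1);
  double s = 0;
  for (int i = -rad; i <= rad; ++i) {
    ker[i + rad] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += ker[i + rad];
  }
  for (auto& k : ker) k /= s;

  std::vector<double> a(vol.begin(), vol.end()), b(n);
  const int nn[3] = {nx, ny, nz};
  const size_t stride[3] = {1, (size_t)nx, (size_t)nx * ny};
  for (int ax = 0; ax < 3; ++ax) {
    int len = nn[ax];
    size_t st = stride[ax];
    size_t nlines = n / len;
    // iterate all 1D lines along axis ax
    for (size_t line = 0; line < nlines; ++line) {
      // compute base index of this line
      size_t rem = line, base = 0;
      for (int o = 0; o < 3; ++o) {
        if (o == ax) continue;
        size_t dimo = nn[o];
        size_t coord = rem % dimo;
        rem /= dimo;
        base += coord * stride[o];
      }
      for (int i = 0; i < len; ++i) {
        double acc = 0;
        for (int k = -rad; k <= rad; ++k) {
          int j = i + k;
          if (j < 0) j = -j;               // reflect
          if (j >= len) j = 2 * len - 2 - j;
          if (j < 0) j = 0;
          acc += ker[k + rad] * a[base + (size_t)j * st];
        }
        b[base + (size_t)i * st] = acc;
      }
    }
    std::swap(a, b);
  }
  NumericVector out(a.begin(), a.end());
  out.attr("dim") = dims;
  return out;
}

// ---- Gaussian splatting ----------------------------------------------------

// Adds an isotropic Gaussian kernel (peak `amplitude`, sd `sigma` nm,
// truncated at 4 sigma) for every point (nm) into the volume grid.
// Voxel centers sit at origin + (index - 0.5) * voxel (1-based indices).
// [[Rcpp::export(name = ".splat_gaussians_cpp")]]
NumericVector splat_gaussians_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector origin, double voxel,
                                  NumericMatrix pts, double sigma,
                                  double amplitude) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out = clone(vol);
  double rad = 4.0 * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  for (int p = 0; p < pts.nrow(); ++p) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2);
    int x0 = std::max(0, (int)std::floor((px - rad - origin[0]) / voxel - 0.5));
    int x1 = std::min(nx - 1, (int)std::ceil((px + rad - origin[0]) / voxel - 0.5));
    int y0 = std::max(0, (int)std::floor((py - rad - origin[1]) / voxel - 0.5));
    int y1 = std::min(ny - 1, (int)std::ceil((py + rad - origin[1]) / voxel - 0.5));
    int z0 = std::max(0, (int)std::floor((pz - rad - origin[2]) / voxel - 0.5));
    int z1 = std::min(nz - 1, (int)std::ceil((pz + rad - origin[2]) / voxel - 0.5));
    for (int z = z0; z <= z1; ++z) {
      double dz = origin[2] + (z + 0.5) * voxel - pz;
      for (int y = y0; y <= y1; ++y) {
        double dy = origin[1] + (y + 0.5) * voxel - py;
        for (int x = x0; x <= x1; ++x) {
          double dx = origin[0] + (x + 0.5) * voxel - px;
          double d2 = dx * dx + dy * dy + dz * dz;
          if (d2 > rad * rad) continue;
          out[x + nx * (y + (size_t)ny * z)] += amplitude * std::exp(-d2 * inv2s2);
        }
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---- connected components (26-connectivity) --------------------------------

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] > 0) continue;
    ++next;
    stack.clear();
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      size_t c = stack.back();
      stack.pop_back();
      int x = c % nx, y = (c / nx) % ny, z = c / ((size_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int X = x + dx, Y = y + dy, Z = z + dz;
            if (X < 0 || Y < 0 || Z < 0 || X >= nx || Y >= ny || Z >= nz) continue;
            size_t j = X + nx * (Y + (size_t)ny * Z);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
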