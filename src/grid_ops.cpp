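// Voxel kernels for the packing-density engine.
//
// Conventions shared with the R side:
//   - column-major linear index v = i + nx*(j + ny*k), 0-based i/j/k
//   - voxel centre (i) = origin + (i + 0.5) * h   (0-based)
//   - flags byte: bits 0-1 label {0 solvent, 1 SE envelope, 2 inside vdW,
//     3 void}; bit 2 probe-feasible (min weighted distance >= probe);
//     bit 3 probe-accessible from the grid boundary.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstring>
using namespace Rcpp;

static const unsigned char LAB_MASK = 3;
static const unsigned char LAB_SOLVENT = 0;
static const unsigned char LAB_SE = 1;
static const unsigned char LAB_VDW = 2;
static const unsigned char LAB_VOID = 3;
static const unsigned char BIT_FEAS = 4;
static const unsigned char BIT_ACC = 8;

static const float F_INF = 1e30f;

// ---- 1D squared distance transform (lower envelope of parabolas) ----
static void dt1d(const float* f, float* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e300;
  z[1] = 1e300;
  for (int q = 1; q < n; q++) {
    double fq = (double)f[q] + (double)q * q;
    double s = (fq - ((double)f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
    while (s <= z[k]) {
      k--;
      s = (fq - ((double)f[v[k]] + (double)v[k] * v[k])) / (2.0 * (q - v[k]));
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e300;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    double val = dq * dq + f[v[k]];
    d[q] = (val > F_INF) ? F_INF : (float)val;
  }
}

// squared Euclidean distance transform, in voxel units, in place
static void edt3d(std::vector<float>& f, int nx, int ny, int nz) {
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<float> line(nmax), out(nmax);
  std::vector<int> vbuf(nmax);
  std::vector<double> zbuf(nmax + 1);
  // x pass
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++) {
      size_t base = (size_t)nx * (j + (size_t)ny * k);
      dt1d(&f[base], &out[0], nx, &vbuf[0], &zbuf[0]);
      std::memcpy(&f[base], &out[0], sizeof(float) * nx);
    }
  // y pass
  for (int k = 0; k < nz; k++)
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)i + (size_t)nx * (size_t)ny * k;
      for (int j = 0; j < ny; j++) line[j] = f[base + (size_t)nx * j];
      dt1d(&line[0], &out[0], ny, &vbuf[0], &zbuf[0]);
      for (int j = 0; j < ny; j++) f[base + (size_t)nx * j] = out[j];
    }
  // z pass
  size_t nxy = (size_t)nx * ny;
  for (int j = 0; j < ny; j++)
    for (int i = 0; i < nx; i++) {
      size_t base = (size_t)i + (size_t)nx * j;
      for (int k = 0; k < nz; k++) line[k] = f[base + nxy * k];
      dt1d(&line[0], &out[0], nz, &vbuf[0], &zbuf[0]);
      for (int k = 0; k < nz; k++) f[base + nxy * k] = out[k];
    }
}

// stamp min over atoms of (|v - c_i| - r_i) within reach r_i + extra
static void stamp_minwd(std::vector<float>& minwd,
                        const double* ox, double h, int nx, int ny, int nz,
                        const NumericMatrix& xyz, const NumericVector& rad,
                        double extra) {
  int na = xyz.nrow();
  for (int a = 0; a < na; a++) {
    double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
    double r = rad[a];
    double R = r + extra;
    int ilo = std::max(0, (int)std::ceil((cx - R - ox[0]) / h - 0.5));
    int ihi = std::min(nx - 1, (int)std::floor((cx + R - ox[0]) / h - 0.5));
    int jlo = std::max(0, (int)std::ceil((cy - R - ox[1]) / h - 0.5));
    int jhi = std::min(ny - 1, (int)std::floor((cy + R - ox[1]) / h - 0.5));
    int klo = std::max(0, (int)std::ceil((cz - R - ox[2]) / h - 0.5));
    int khi = std::min(nz - 1, (int)std::floor((cz + R - ox[2]) / h - 0.5));
    for (int k = klo; k <= khi; k++) {
      double dz = ox[2] + (k + 0.5) * h - cz;
      for (int j = jlo; j <= jhi; j++) {
        double dy = ox[1] + (j + 0.5) * h - cy;
        double dyz2 = dy * dy + dz * dz;
        size_t base = (size_t)nx * (j + (size_t)ny * k);
        for (int i = ilo; i <= ihi; i++) {
          double dx = ox[0] + (i + 0.5) * h - cx;
          double wd = std::sqrt(dx * dx + dyz2) - r;
          float fwd = (float)wd;
          if (fwd < minwd[base + i]) minwd[base + i] = fwd;
        }
      }
    }
  }
}

// 6-connected flood fill over feasible voxels from the grid boundary
static void flood_accessible(std::vector<unsigned char>& acc,
                             const std::vector<float>& minwd,
                             float probe, int nx, int ny, int nz) {
  size_t n = (size_t)nx * ny * nz;
  std::vector<int> stack;
  stack.reserve(1 << 20);
  size_t nxy = (size_t)nx * ny;
  // seed every boundary-face voxel that admits a probe centre
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        if (i > 0 && i < nx - 1 && j > 0 && j < ny - 1 && k > 0 && k < nz - 1)
          continue;
        size_t v = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        if (minwd[v] >= probe && !acc[v]) {
          acc[v] = 1;
          stack.push_back((int)v);
        }
      }
  while (!stack.empty()) {
    size_t v = (size_t)stack.back();
    stack.pop_back();
    int i = (int)(v % nx);
    size_t rest = v / nx;
    int j = (int)(rest % ny);
    int k = (int)(rest / ny);
    const int di[6] = {-1, 1, 0, 0, 0, 0};
    const int dj[6] = {0, 0, -1, 1, 0, 0};
    const int dk[6] = {0, 0, 0, 0, -1, 1};
    for (int t = 0; t < 6; t++) {
      int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      size_t w = (size_t)ii + (size_t)nx * (jj + (size_t)ny * kk);
      if (!acc[w] && minwd[w] >= probe) {
        acc[w] = 1;
        stack.push_back((int)w);
      }
    }
  }
  (void)n;
}

// Label the grid: solvent-excluded region by rolling-probe closure.
// dilate_slack is added to the probe radius when dilating the accessible
// set back over the surface (half-voxel boundary compensation).
// [[Rcpp::export]]
RawVector cpp_se_label(NumericVector origin, double h, IntegerVector dims,
                       NumericMatrix xyz, NumericVector rad,
                       double probe, double dilate_slack) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  std::vector<float> minwd(n, F_INF);
  stamp_minwd(minwd, &origin[0], h, nx, ny, nz, xyz, rad, probe + 2.0 * h);

  std::vector<unsigned char> acc(n, 0);
  flood_accessible(acc, minwd, (float)probe, nx, ny, nz);

  // squared distance (voxel units) to the accessible set
  std::vector<float> dist(n);
  for (size_t v = 0; v < n; v++) dist[v] = acc[v] ? 0.0f : F_INF;
  edt3d(dist, nx, ny, nz);

  double thr = (probe + dilate_slack) / h;
  float thr2 = (float)(thr * thr);
  RawVector flags(n);
  for (size_t v = 0; v < n; v++) {
    bool vdw = minwd[v] < 0.0f;
    bool feas = minwd[v] >= (float)probe;
    bool a = acc[v] != 0;
    unsigned char lab;
    if (!vdw && (a || dist[v] <= thr2)) lab = LAB_SOLVENT;
    else if (vdw) lab = LAB_VDW;
    else lab = LAB_SE;
    flags[v] = lab | (feas ? BIT_FEAS : 0) | (a ? BIT_ACC : 0);
  }
  return flags;
}

// Promote buried probe-swept space to VOID: seeds are probe-feasible,
// non-accessible SE voxels; the void is their dilation by
// probe + dilate_slack restricted to SE voxels.
// [[Rcpp::export]]
RawVector cpp_detect_voids(RawVector flags, IntegerVector dims,
                           double h, double probe, double dilate_slack) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  bool any_seed = false;
  for (size_t v = 0; v < n; v++) {
    unsigned char f = flags[v];
    if ((f & LAB_MASK) == LAB_SE && (f & BIT_FEAS) && !(f & BIT_ACC)) {
      any_seed = true;
      break;
    }
  }
  RawVector out = clone(flags);
  if (!any_seed) return out;
  std::vector<float> dist(n);
  for (size_t v = 0; v < n; v++) {
    unsigned char f = flags[v];
    bool seed = (f & LAB_MASK) == LAB_SE && (f & BIT_FEAS) && !(f & BIT_ACC);
    dist[v] = seed ? 0.0f : F_INF;
  }
  edt3d(dist, nx, ny, nz);
  double thr = (probe + dilate_slack) / h;
  float thr2 = (float)(thr * thr);
  for (size_t v = 0; v < n; v++) {
    unsigned char f = out[v];
    if ((f & LAB_MASK) == LAB_SE && dist[v] <= thr2)
      out[v] = (f & ~LAB_MASK) | LAB_VOID;
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_count_labels(RawVector flags) {
  IntegerVector counts(4);
  size_t n = flags.size();
  for (size_t v = 0; v < n; v++) counts[flags[v] & LAB_MASK]++;
  return counts;
}

// [[Rcpp::export]]
IntegerVector cpp_labels(RawVector flags) {
  size_t n = flags.size();
  IntegerVector lab(n);
  for (size_t v = 0; v < n; v++) lab[v] = flags[v] & LAB_MASK;
  return lab;
}

// Additively weighted Voronoi ownership for SE and inside-vdW voxels.
// Ties (equal weighted distance) go to the lowest atom serial. Stamped
// within r_i + probe + 2h; any voxel whose best stamped distance exceeds
// probe + 2h falls back to an exhaustive scan, so the result always equals
// the brute-force argmin.
// [[Rcpp::export]]
IntegerVector cpp_assign_owners(RawVector flags, NumericVector origin,
                                double h, IntegerVector dims,
                                NumericMatrix xyz, NumericVector rad,
                                IntegerVector serial, double probe,
                                bool brute_force) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  int na = xyz.nrow();
  IntegerVector owner(n);
  std::vector<double> best(n, 1e300);
  std::vector<int> own(n, 0);

  if (!brute_force) {
    double extra = probe + 2.0 * h;
    for (int a = 0; a < na; a++) {
      double cx = xyz(a, 0), cy = xyz(a, 1), cz = xyz(a, 2);
      double r = rad[a];
      double R = r + extra;
      int ilo = std::max(0, (int)std::ceil((cx - R - origin[0]) / h - 0.5));
      int ihi = std::min(nx - 1, (int)std::floor((cx + R - origin[0]) / h - 0.5));
      int jlo = std::max(0, (int)std::ceil((cy - R - origin[1]) / h - 0.5));
      int jhi = std::min(ny - 1, (int)std::floor((cy + R - origin[1]) / h - 0.5));
      int klo = std::max(0, (int)std::ceil((cz - R - origin[2]) / h - 0.5));
      int khi = std::min(nz - 1, (int)std::floor((cz + R - origin[2]) / h - 0.5));
      for (int k = klo; k <= khi; k++) {
        double dz = origin[2] + (k + 0.5) * h - cz;
        for (int j = jlo; j <= jhi; j++) {
          double dy = origin[1] + (j + 0.5) * h - cy;
          double dyz2 = dy * dy + dz * dz;
          size_t base = (size_t)nx * (j + (size_t)ny * k);
          for (int i = ilo; i <= ihi; i++) {
            size_t v = base + i;
            unsigned char lab = flags[v] & LAB_MASK;
            if (lab != LAB_SE && lab != LAB_VDW) continue;
            double dx = origin[0] + (i + 0.5) * h - cx;
            double wd = std::sqrt(dx * dx + dyz2) - r;
            if (wd < best[v] ||
                (wd == best[v] && own[v] > 0 && serial[a] < serial[own[v] - 1])) {
              best[v] = wd;
              own[v] = a + 1;
            }
          }
        }
      }
    }
  }

  double guarantee = probe + 2.0 * h;
  for (size_t v = 0; v < n; v++) {
    unsigned char lab = flags[v] & LAB_MASK;
    if (lab != LAB_SE && lab != LAB_VDW) {
      owner[v] = 0;
      continue;
    }
    if (!brute_force && own[v] > 0 && best[v] <= guarantee) {
      owner[v] = own[v];
      continue;
    }
    // exhaustive fallback
    int i = (int)(v % nx);
    size_t rest = v / nx;
    int j = (int)(rest % ny);
    int k = (int)(rest / ny);
    double px = origin[0] + (i + 0.5) * h;
    double py = origin[1] + (j + 0.5) * h;
    double pz = origin[2] + (k + 0.5) * h;
    double b = 1e300;
    int w = 0;
    for (int a = 0; a < na; a++) {
      double dx = px - xyz(a, 0), dy = py - xyz(a, 1), dz = pz - xyz(a, 2);
      double wd = std::sqrt(dx * dx + dy * dy + dz * dz) - rad[a];
      if (wd < b || (wd == b && w > 0 && serial[a] < serial[w - 1])) {
        b = wd;
        w = a + 1;
      }
    }
    owner[v] = w;
  }
  return owner;
}

// Per-atom voxel counts of owned inside-vdW and SE-envelope voxels.
// [[Rcpp::export]]
IntegerMatrix cpp_accumulate(RawVector flags, IntegerVector owner, int n_atoms) {
  IntegerMatrix counts(n_atoms, 2);
  size_t n = flags.size();
  for (size_t v = 0; v < n; v++) {
    int o = owner[v];
    if (o <= 0) continue;
    unsigned char lab = flags[v] & LAB_MASK;
    if (lab == LAB_VDW) counts(o - 1, 0)++;
    else if (lab == LAB_SE) counts(o - 1, 1)++;
  }
  return counts;
}

// Buried/exposed classification: an atom is exposed iff at least one voxel
// inside its vdW sphere is 6-adjacent to a solvent voxel. Also counts such
// surface-contact voxels per atom.
// [[Rcpp::export]]
List cpp_burial(RawVector flags, NumericVector origin, double h,
                IntegerVector dims, NumericMatrix xyz, NumericVector rad) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int na = xyz.nrow();
  LogicalVector exposed(na);
  IntegerVector contacts(na);
  // bin atoms into cells of edge maxr so containment queries scan 27 bins
  double maxr = 0.0;
  for (int a = 0; a < na; a++) maxr = std::max(maxr, (double)rad[a]);
  double L = std::max(maxr, h);
  double bx = origin[0], by = origin[1], bz = origin[2];
  int gx = std::max(1, (int)std::ceil(nx * h / L));
  int gy = std::max(1, (int)std::ceil(ny * h / L));
  int gz = std::max(1, (int)std::ceil(nz * h / L));
  std::vector<std::vector<int> > bins((size_t)gx * gy * gz);
  for (int a = 0; a < na; a++) {
    int ci = std::min(gx - 1, std::max(0, (int)((xyz(a, 0) - bx) / L)));
    int cj = std::min(gy - 1, std::max(0, (int)((xyz(a, 1) - by) / L)));
    int ck = std::min(gz - 1, std::max(0, (int)((xyz(a, 2) - bz) / L)));
    bins[(size_t)ci + (size_t)gx * (cj + (size_t)gy * ck)].push_back(a);
  }
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (int k = 0; k < nz; k++)
    for (int j = 0; j < ny; j++)
      for (int i = 0; i < nx; i++) {
        size_t v = (size_t)i + (size_t)nx * (j + (size_t)ny * k);
        if ((flags[v] & LAB_MASK) != LAB_VDW) continue;
        bool touch = false;
        for (int t = 0; t < 6 && !touch; t++) {
          int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
          if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) {
            touch = true;  // beyond the padded boundary is bulk solvent
            continue;
          }
          size_t w = (size_t)ii + (size_t)nx * (jj + (size_t)ny * kk);
          if ((flags[w] & LAB_MASK) == LAB_SOLVENT) touch = true;
        }
        if (!touch) continue;
        double px = bx + (i + 0.5) * h;
        double py = by + (j + 0.5) * h;
        double pz = bz + (k + 0.5) * h;
        int ci = std::min(gx - 1, std::max(0, (int)((px - bx) / L)));
        int cj = std::min(gy - 1, std::max(0, (int)((py - by) / L)));
        int ck = std::min(gz - 1, std::max(0, (int)((pz - bz) / L)));
        for (int ck2 = std::max(0, ck - 1); ck2 <= std::min(gz - 1, ck + 1); ck2++)
          for (int cj2 = std::max(0, cj - 1); cj2 <= std::min(gy - 1, cj + 1); cj2++)
            for (int ci2 = std::max(0, ci - 1); ci2 <= std::min(gx - 1, ci + 1); ci2++) {
              const std::vector<int>& bin =
                  bins[(size_t)ci2 + (size_t)gx * (cj2 + (size_t)gy * ck2)];
              for (size_t t = 0; t < bin.size(); t++) {
                int a = bin[t];
                double dx = px - xyz(a, 0), dy = py - xyz(a, 1), dz = pz - xyz(a, 2);
                if (dx * dx + dy * dy + dz * dz < rad[a] * rad[a]) {
                  exposed[a] = true;
                  contacts[a]++;
                }
              }
            }
      }
  return List::create(_["exposed"] = exposed, _["contacts"] = contacts);
}

// Connected components of VOID voxels (26-connectivity). Returns a
// component id per voxel (0 for non-void), ids in discovery order.
// [[Rcpp::export]]
IntegerVector cpp_void_components(RawVector flags, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  size_t n = (size_t)nx * ny * nz;
  IntegerVector comp(n);
  int next_id = 0;
  std::vector<int> stack;
  for (size_t v0 = 0; v0 < n; v0++) {
    if ((flags[v0] & LAB_MASK) != LAB_VOID || comp[v0] != 0) continue;
    next_id++;
    comp[v0] = next_id;
    stack.push_back((int)v0);
    while (!stack.empty()) {
      size_t v = (size_t)stack.back();
      stack.pop_back();
      int i = (int)(v % nx);
      size_t rest = v / nx;
      int j = (int)(rest % ny);
      int k = (int)(rest / ny);
      for (int dk = -1; dk <= 1; dk++)
        for (int dj = -1; dj <= 1; dj++)
          for (int di = -1; di <= 1; di++) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
              continue;
            size_t w = (size_t)ii + (size_t)nx * (jj + (size_t)ny * kk);
            if ((flags[w] & LAB_MASK) == LAB_VOID && comp[w] == 0) {
              comp[w] = next_id;
              stack.push_back((int)w);
            }
          }
    }
  }
  return comp;
}
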