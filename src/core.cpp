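#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Pack integer 3-D cell indices into one 64-bit key (each offset to >= 0,
// 21 bits per axis is ample for any molecular bounding box / cell size).
static inline long long cell_key(long long ix, long long iy, long long iz) {
  return ((ix + 1048576LL) << 42) | ((iy + 1048576LL) << 21) | (iz + 1048576LL);
}

typedef std::unordered_map<long long, std::vector<int> > CellMap;

static CellMap build_cells(const NumericMatrix& xyz, double cell) {
  CellMap cm;
  int n = xyz.nrow();
  cm.reserve(n);
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor(xyz(i, 0) / cell);
    long long iy = (long long)std::floor(xyz(i, 1) / cell);
    long long iz = (long long)std::floor(xyz(i, 2) / cell);
    cm[cell_key(ix, iy, iz)].push_back(i);
  }
  return cm;
}

// Count atom pairs closer than `cutoff` whose residue separation is at
// least `minsep` (bonded/adjacent residues are excluded from clashes).
// [[Rcpp::export]]
int cpp_clash_count(NumericMatrix xyz, IntegerVector resno,
                    double cutoff, int minsep) {
  int n = xyz.nrow();
  double c2 = cutoff * cutoff;
  CellMap cm = build_cells(xyz, cutoff);
  int count = 0;
  for (int i = 0; i < n; ++i) {
    long long ix = (long long)std::floor(xyz(i, 0) / cutoff);
    long long iy = (long long)std::floor(xyz(i, 1) / cutoff);
    long long iz = (long long)std::floor(xyz(i, 2) / cutoff);
    for (long long dx = -1; dx <= 1; ++dx)
      for (long long dy = -1; dy <= 1; ++dy)
        for (long long dz = -1; dz <= 1; ++dz) {
          CellMap::const_iterator it =
            cm.find(cell_key(ix + dx, iy + dy, iz + dz));
          if (it == cm.end()) continue;
          const std::vector<int>& v = it->second;
          for (size_t k = 0; k < v.size(); ++k) {
            int j = v[k];
            if (j <= i) continue;
            if (std::abs(resno[i] - resno[j]) < minsep) continue;
            double a = xyz(i, 0) - xyz(j, 0);
            double b = xyz(i, 1) - xyz(j, 1);
            double c = xyz(i, 2) - xyz(j, 2);
            if (a * a + b * b + c * c < c2) ++count;
          }
        }
  }
  return count;
}

// Exact Debye double sum: I(q) = sum_ij w_i w_j sinc(q r_ij).
// Coordinates and q must be in reciprocal units (nm and 1/nm here).
// [[Rcpp::export]]
NumericVector cpp_debye(NumericMatrix xyz, NumericVector w, NumericVector q) {
  int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  double wtot = 0.0;
  for (int i = 0; i < n; ++i) wtot += w[i];
  // self terms + q = 0 analytic limit handled via sinc(0) = 1
  std::vector<double> acc(nq, 0.0);
  for (int i = 0; i < n; ++i) {
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2), wi = w[i];
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ww = 2.0 * wi * w[j];
      for (int k = 0; k < nq; ++k) {
        double x = q[k] * r;
        acc[k] += ww * (x < 1e-12 ? 1.0 : std::sin(x) / x);
      }
    }
  }
  double self = 0.0;
  for (int i = 0; i < n; ++i) self += w[i] * w[i];
  for (int k = 0; k < nq; ++k) I[k] = acc[k] + self;
  return I;
}

// Orientationally averaged |sum_j w_j exp(i q u.r_j)|^2 over a spherical
// Fibonacci (golden-ratio) grid of directions u.
// [[Rcpp::export]]
NumericVector cpp_golden_curve(NumericMatrix xyz, NumericVector w,
                               NumericVector q, int n_orient) {
  int n = xyz.nrow(), nq = q.size();
  NumericVector I(nq);
  const double ga = M_PI * (3.0 - std::sqrt(5.0)); // golden angle
  std::vector<double> dot(n);
  // |F(u)|^2 = |F(-u)|^2 for real weights, so a hemispherical Fibonacci
  // grid of n points samples as finely as 2n full-sphere points.
  for (int m = 0; m < n_orient; ++m) {
    double z = 1.0 - (m + 0.5) / n_orient;
    double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
    double ph = ga * m;
    double ux = rxy * std::cos(ph), uy = rxy * std::sin(ph), uz = z;
    for (int j = 0; j < n; ++j)
      dot[j] = ux * xyz(j, 0) + uy * xyz(j, 1) + uz * xyz(j, 2);
    for (int k = 0; k < nq; ++k) {
      double re = 0.0, im = 0.0, qk = q[k];
      for (int j = 0; j < n; ++j) {
        double ph2 = qk * dot[j];
        re += w[j] * std::cos(ph2);
        im += w[j] * std::sin(ph2);
      }
      I[k] += re * re + im * im;
    }
  }
  for (int k = 0; k < nq; ++k) I[k] /= n_orient;
  return I;
}

// Sum over unordered pairs of 1/r_ij, for the Kirkwood friction double sum.
// [[Rcpp::export]]
double cpp_inv_dist_sum(NumericMatrix xyz) {
  int n = xyz.nrow();
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      double dx = xi - xyz(j, 0), dy = yi - xyz(j, 1), dz = zi - xyz(j, 2);
      s += 1.0 / std::sqrt(dx * dx + dy * dy + dz * dz);
    }
  }
  return s;
}

// Place shell beads of radius sigma on the boundary of the union of
// spheres of radius `aer` centred on the atoms. Candidate points are a
// Fibonacci grid on each atom sphere; points inside any other atom sphere
// are dropped; survivors are thinned to ~one per cubic cell of edge
// 1.6*sigma so neighbouring beads roughly touch.
// [[Rcpp::export]]
NumericMatrix cpp_shell_beads(NumericMatrix xyz, double aer, double sigma,
                              double thin = 1.0) {
  int n = xyz.nrow();
  double area = 4.0 * M_PI * aer * aer;
  int m = std::max(12, (int)std::ceil(1.3 * area / (sigma * sigma)));
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  double search = 2.0 * aer;
  CellMap cm = build_cells(xyz, search);
  double a2 = aer * aer * (1.0 - 1e-9);

  std::vector<double> px, py, pz;
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < m; ++k) {
      double z = 1.0 - 2.0 * (k + 0.5) / m;
      double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
      double ph = ga * k;
      double cx = xyz(i, 0) + aer * rxy * std::cos(ph);
      double cy = xyz(i, 1) + aer * rxy * std::sin(ph);
      double cz = xyz(i, 2) + aer * z;
      bool buried = false;
      long long ix = (long long)std::floor(xyz(i, 0) / search);
      long long iy = (long long)std::floor(xyz(i, 1) / search);
      long long iz = (long long)std::floor(xyz(i, 2) / search);
      for (long long dx = -1; dx <= 1 && !buried; ++dx)
        for (long long dy = -1; dy <= 1 && !buried; ++dy)
          for (long long dz = -1; dz <= 1 && !buried; ++dz) {
            CellMap::const_iterator it =
              cm.find(cell_key(ix + dx, iy + dy, iz + dz));
            if (it == cm.end()) continue;
            const std::vector<int>& v = it->second;
            for (size_t t = 0; t < v.size(); ++t) {
              int j = v[t];
              if (j == i) continue;
              double a = cx - xyz(j, 0), b = cy - xyz(j, 1), c = cz - xyz(j, 2);
              if (a * a + b * b + c * c < a2) { buried = true; break; }
            }
          }
      if (!buried) { px.push_back(cx); py.push_back(cy); pz.push_back(cz); }
    }
  }
  // thin to one bead per cell
  double cell = thin * sigma;
  std::unordered_map<long long, int> taken;
  std::vector<int> keep;
  for (size_t k = 0; k < px.size(); ++k) {
    long long ix = (long long)std::floor(px[k] / cell);
    long long iy = (long long)std::floor(py[k] / cell);
    long long iz = (long long)std::floor(pz[k] / cell);
    long long key = cell_key(ix, iy, iz);
    if (taken.find(key) == taken.end()) {
      taken[key] = 1;
      keep.push_back((int)k);
    }
  }
  NumericMatrix out(keep.size(), 3);
  for (size_t k = 0; k < keep.size(); ++k) {
    out(k, 0) = px[keep[k]];
    out(k, 1) = py[keep[k]];
    out(k, 2) = pz[keep[k]];
  }
  return out;
}

// Dense 3N x 3N Rotne-Prager-Yamakawa mobility matrix for equal beads of
// radius a (SI units). Overlapping bead pairs use the standard RPY
// overlap form, so thinned shells with spacing < 2a remain well-posed.
// [[Rcpp::export]]
NumericMatrix cpp_rpy_matrix(NumericMatrix xyz, double a, double eta) {
  int n = xyz.nrow();
  NumericMatrix M(3 * n, 3 * n);
  double mself = 1.0 / (6.0 * M_PI * eta * a);
  for (int i = 0; i < n; ++i) {
    for (int k = 0; k < 3; ++k) M(3 * i + k, 3 * i + k) = mself;
    for (int j = i + 1; j < n; ++j) {
      double d[3] = { xyz(i, 0) - xyz(j, 0), xyz(i, 1) - xyz(j, 1),
                      xyz(i, 2) - xyz(j, 2) };
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double r = std::sqrt(r2);
      double ci, cr; // coefficients of I and of rhat rhat^T
      if (r >= 2.0 * a) {
        double pre = 1.0 / (8.0 * M_PI * eta * r);
        double aa = 2.0 * a * a / (3.0 * r2);
        ci = pre * (1.0 + aa);
        cr = pre * (1.0 - 3.0 * aa);
      } else {
        ci = mself * (1.0 - 9.0 * r / (32.0 * a));
        cr = mself * (3.0 * r / (32.0 * a));
      }
      for (int k = 0; k < 3; ++k)
        for (int l = 0; l < 3; ++l) {
          double v = ci * (k == l ? 1.0 : 0.0) + cr * d[k] * d[l] / r2;
          M(3 * i + k, 3 * j + l) = v;
          M(3 * j + l, 3 * i + k) = v;
        }
    }
  }
  return M;
}

// Cubic-grid bead filling of the hydrated body: grid points of spacing h
// lying within `aer` of any atom centre.
// [[Rcpp::export]]
NumericMatrix cpp_fill_beads(NumericMatrix xyz, double aer, double h) {
  int n = xyz.nrow();
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) {
    lo[k] = xyz(0, k); hi[k] = xyz(0, k);
    for (int i = 1; i < n; ++i) {
      lo[k] = std::min(lo[k], xyz(i, k));
      hi[k] = std::max(hi[k], xyz(i, k));
    }
    lo[k] -= aer; hi[k] += aer;
  }
  double cellsz = std::max(aer, h);
  CellMap cm = build_cells(xyz, cellsz);
  double a2 = aer * aer;
  std::vector<double> px, py, pz;
  for (double x = lo[0]; x <= hi[0]; x += h)
    for (double y = lo[1]; y <= hi[1]; y += h)
      for (double z = lo[2]; z <= hi[2]; z += h) {
        long long ix = (long long)std::floor(x / cellsz);
        long long iy = (long long)std::floor(y / cellsz);
        long long iz = (long long)std::floor(z / cellsz);
        bool inside = false;
        for (long long dx = -1; dx <= 1 && !inside; ++dx)
          for (long long dy = -1; dy <= 1 && !inside; ++dy)
            for (long long dz = -1; dz <= 1 && !inside; ++dz) {
              CellMap::const_iterator it =
                cm.find(cell_key(ix + dx, iy + dy, iz + dz));
              if (it == cm.end()) continue;
              const std::vector<int>& v = it->second;
              for (size_t t = 0; t < v.size(); ++t) {
                double a = x - xyz(v[t], 0), b = y - xyz(v[t], 1),
                       c = z - xyz(v[t], 2);
                if (a * a + b * b + c * c <= a2) { inside = true; break; }
              }
            }
        if (inside) { px.push_back(x); py.push_back(y); pz.push_back(z); }
      }
  NumericMatrix out(px.size(), 3);
  for (size_t k = 0; k < px.size(); ++k) {
    out(k, 0) = px[k]; out(k, 1) = py[k]; out(k, 2) = pz[k];
  }
  return out;
}
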