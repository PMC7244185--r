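// Core numerics: pair interactions via cell-list neighbor search, explicit
// Euler time stepping, and union-find clustering. Positions live in the
// half-open periodic box [0, L)^d with minimum-image displacements.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double phi_val(double s) {
  // (1/s) exp(-1/(1-s)) on (0,1), 0 for s >= 1; caller guarantees s > 0
  if (s >= 1.0) return 0.0;
  return std::exp(-1.0 / (1.0 - s)) / s;
}

static inline double phi_deriv(double s) {
  if (s >= 1.0) return 0.0;
  const double u = 1.0 - s;
  return std::exp(-1.0 / u) * (-1.0 / (s * s) - 1.0 / (s * u * u));
}

static inline double wrap01(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;   // guard against floor rounding at the boundary
  if (x < 0.0) x += L;
  return x;
}

static inline double min_image(double dx, double L) {
  return dx - L * std::nearbyint(dx / L);
}

// Linked-cell grid over [0,L)^d with bin size >= cutoff; M < 3 bins per side
// would make the 3^d stencil visit a bin twice, so we fall back to all-pairs.
struct CellGrid {
  int M, d, ncell;
  double L, bin;
  std::vector<int> head, nxt;
  bool all_pairs;

  CellGrid(int N, int d_, double L_, double cutoff) : d(d_), L(L_) {
    M = (int)std::floor(L / cutoff);
    all_pairs = (M < 3);
    if (all_pairs) M = 1;
    bin = L / M;
    ncell = 1;
    for (int k = 0; k < d; ++k) ncell *= M;
    head.assign(ncell, -1);
    nxt.assign(N, -1);
  }

  int bin_index(const double* x) const {
    int idx = 0;
    for (int k = 0; k < d; ++k) {
      int c = (int)(x[k] / bin);
      if (c >= M) c = M - 1;
      if (c < 0) c = 0;
      idx = idx * M + c;
    }
    return idx;
  }

  void build(const double* pos, int N) {
    std::fill(head.begin(), head.end(), -1);
    for (int i = 0; i < N; ++i) {
      int c = bin_index(pos + (size_t)i * d);
      nxt[i] = head[c];
      head[c] = i;
    }
  }
};

// Per-cell tension V_i, spatial gradient of V_i wrt x_i, and orientation
// gradient wrt omega_i (free-vector convention; tangent projection is applied
// by the caller). Buffers are raw row-major [N x d].
static void fields(const double* pos, const double* ori, int N, int d,
                   double a, double b, double eps, double L,
                   CellGrid& grid, bool symmetrize,
                   double* V, double* gx, double* gw) {
  const double a2 = a * a, b2 = b * b;
  const double e2 = 1.0 - b2 / a2;
  grid.build(pos, N);
  std::fill(V, V + N, 0.0);
  std::fill(gx, gx + (size_t)N * d, 0.0);
  std::fill(gw, gw + (size_t)N * d, 0.0);

  std::vector<int> cand;
  cand.reserve(64);

  for (int i = 0; i < N; ++i) {
    const double* xi = pos + (size_t)i * d;
    const double* wi = ori + (size_t)i * d;
    cand.clear();
    if (grid.all_pairs) {
      for (int j = 0; j < N; ++j) if (j != i) cand.push_back(j);
    } else {
      int ci[3] = {0, 0, 0};
      for (int k = 0; k < d; ++k) {
        int c = (int)(xi[k] / grid.bin);
        if (c >= grid.M) c = grid.M - 1;
        ci[k] = c;
      }
      int noff = (d == 2) ? 9 : 27;
      for (int o = 0; o < noff; ++o) {
        int rem = o, idx = 0;
        for (int k = 0; k < d; ++k) {
          int off = rem % 3 - 1;
          rem /= 3;
          int c = ci[k] + off;
          if (c < 0) c += grid.M;
          if (c >= grid.M) c -= grid.M;
          idx = idx * grid.M + c;
        }
        for (int j = grid.head[idx]; j >= 0; j = grid.nxt[j])
          if (j != i) cand.push_back(j);
      }
    }

    double dd[3];
    for (size_t q = 0; q < cand.size(); ++q) {
      int j = cand[q];
      const double* xj = pos + (size_t)j * d;
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        dd[k] = min_image(xj[k] - xi[k], L);
        dist2 += dd[k] * dd[k];
      }
      if (dist2 >= a2) continue;   // r_ij^2 >= dist2/a^2 >= 1: no interaction
      double dw = 0.0;
      for (int k = 0; k < d; ++k) dw += dd[k] * wi[k];
      double s = (dist2 - e2 * dw * dw) / b2;
      if (s < eps) s = eps;        // singularity floor near coincident centers
      if (s < 1.0) {
        double ex = std::exp(-1.0 / (1.0 - s));
        V[i] += ex / s;
        double u = 1.0 - s;
        double fp = ex * (-1.0 / (s * s) - 1.0 / (s * u * u));
        double cx = fp * 2.0 / b2;
        double cw = fp * (-2.0 * e2 / b2) * dw;
        for (int k = 0; k < d; ++k) {
          gx[(size_t)i * d + k] += cx * (-dd[k] + e2 * dw * wi[k]);
          gw[(size_t)i * d + k] += cw * dd[k];
        }
      }
      if (symmetrize) {            // passive term of the total-potential force
        const double* wj = ori + (size_t)j * d;
        double dwj = 0.0;
        for (int k = 0; k < d; ++k) dwj += dd[k] * wj[k];
        double sj = (dist2 - e2 * dwj * dwj) / b2;
        if (sj < eps) sj = eps;
        if (sj < 1.0) {
          double exj = std::exp(-1.0 / (1.0 - sj));
          double uj = 1.0 - sj;
          double fpj = exj * (-1.0 / (sj * sj) - 1.0 / (sj * uj * uj));
          double cxj = fpj * 2.0 / b2;
          for (int k = 0; k < d; ++k)
            gx[(size_t)i * d + k] += cxj * (-dd[k] + e2 * dwj * wj[k]);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List interaction_fields_cpp(NumericMatrix pos, NumericMatrix ori,
                            double a, double b, double L, double eps,
                            bool symmetrize = false) {
  int N = pos.nrow(), d = pos.ncol();
  // row-major copies so cell i is contiguous
  std::vector<double> p((size_t)N * d), w((size_t)N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) {
      p[(size_t)i * d + k] = pos(i, k);
      w[(size_t)i * d + k] = ori(i, k);
    }
  std::vector<double> V(N), gx((size_t)N * d), gw((size_t)N * d);
  CellGrid grid(N, d, L, a);
  fields(p.data(), w.data(), N, d, a, b, eps, L, grid, symmetrize,
         V.data(), gx.data(), gw.data());
  NumericVector Vout(N);
  NumericMatrix gxout(N, d), gwout(N, d);
  for (int i = 0; i < N; ++i) {
    Vout[i] = V[i];
    for (int k = 0; k < d; ++k) {
      gxout(i, k) = gx[(size_t)i * d + k];
      gwout(i, k) = gw[(size_t)i * d + k];
    }
  }
  return List::create(_["tension"] = Vout, _["grad_x"] = gxout,
                      _["grad_omega"] = gwout);
}

// Verlet pair list: candidates within a + skin, rebuilt via the grid when the
// largest drift-corrected displacement since the last build exceeds skin/2
// (coherent transport of a flock does not trigger rebuilds).
struct VerletList {
  int N, d;
  double L, cutoff, skin;
  std::vector<int> start, idx;
  std::vector<double> ref;      // positions at last build
  CellGrid grid;

  VerletList(int N_, int d_, double L_, double cutoff_, double skin_)
    : N(N_), d(d_), L(L_), cutoff(cutoff_), skin(skin_),
      start(N_ + 1), ref((size_t)N_ * d_), grid(N_, d_, L_, cutoff_ + skin_) {}

  void build(const double* pos) {
    std::copy(pos, pos + (size_t)N * d, ref.begin());
    grid.build(pos, N);
    const double rc2 = (cutoff + skin) * (cutoff + skin);
    idx.clear();
    for (int i = 0; i < N; ++i) {
      start[i] = (int)idx.size();
      const double* xi = pos + (size_t)i * d;
      if (grid.all_pairs) {
        for (int j = 0; j < N; ++j) {
          if (j == i) continue;
          double dist2 = 0.0;
          for (int k = 0; k < d; ++k) {
            double dd = min_image(pos[(size_t)j * d + k] - xi[k], L);
            dist2 += dd * dd;
          }
          if (dist2 < rc2) idx.push_back(j);
        }
      } else {
        int ci[3] = {0, 0, 0};
        for (int k = 0; k < d; ++k) {
          int cb = (int)(xi[k] / grid.bin);
          if (cb >= grid.M) cb = grid.M - 1;
          ci[k] = cb;
        }
        int noff = (d == 2) ? 9 : 27;
        for (int o = 0; o < noff; ++o) {
          int rem = o, bidx = 0;
          for (int k = 0; k < d; ++k) {
            int off = rem % 3 - 1;
            rem /= 3;
            int cb = ci[k] + off;
            if (cb < 0) cb += grid.M;
            if (cb >= grid.M) cb -= grid.M;
            bidx = bidx * grid.M + cb;
          }
          for (int j = grid.head[bidx]; j >= 0; j = grid.nxt[j]) {
            if (j == i) continue;
            double dist2 = 0.0;
            for (int k = 0; k < d; ++k) {
              double dd = min_image(pos[(size_t)j * d + k] - xi[k], L);
              dist2 += dd * dd;
            }
            if (dist2 < rc2) idx.push_back(j);
          }
        }
      }
    }
    start[N] = (int)idx.size();
  }

  bool stale(const double* pos) const {
    // drift-corrected: subtract the mean displacement, so rigid transport of
    // the whole population never invalidates the list
    double mean[3] = {0, 0, 0};
    for (int i = 0; i < N; ++i)
      for (int k = 0; k < d; ++k)
        mean[k] += min_image(pos[(size_t)i * d + k] - ref[(size_t)i * d + k], L) / N;
    const double lim2 = 0.25 * skin * skin;
    for (int i = 0; i < N; ++i) {
      double r2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double dd = min_image(pos[(size_t)i * d + k] - ref[(size_t)i * d + k], L) - mean[k];
        r2 += dd * dd;
      }
      if (r2 > lim2) return true;
    }
    return false;
  }
};

// force pass over a Verlet pair list (same math as fields()); when
// symmetrize is true the spatial force also carries the passive term
// grad_{x_i} Phi(r_ji^2) = Phi'(r_ji^2) (2/b^2)(-d + e^2 (d.w_j) w_j),
// i.e. the dynamics descend the total potential sum_i V_i instead of each
// cell's own V_i (the orientation gradient is identical in both readings)
static void fields_verlet(const double* pos, const double* ori, int N, int d,
                          double a, double b, double eps, double L,
                          const VerletList& vl, bool symmetrize,
                          double* V, double* gx, double* gw) {
  const double a2 = a * a, b2 = b * b;
  const double e2 = 1.0 - b2 / a2;
  std::fill(V, V + N, 0.0);
  std::fill(gx, gx + (size_t)N * d, 0.0);
  std::fill(gw, gw + (size_t)N * d, 0.0);
  double dd[3];
  for (int i = 0; i < N; ++i) {
    const double* xi = pos + (size_t)i * d;
    const double* wi = ori + (size_t)i * d;
    for (int q = vl.start[i]; q < vl.start[i + 1]; ++q) {
      int j = vl.idx[q];
      const double* xj = pos + (size_t)j * d;
      double dist2 = 0.0;
      for (int k = 0; k < d; ++k) {
        dd[k] = min_image(xj[k] - xi[k], L);
        dist2 += dd[k] * dd[k];
      }
      if (dist2 >= a2) continue;
      double dw = 0.0;
      for (int k = 0; k < d; ++k) dw += dd[k] * wi[k];
      double s = (dist2 - e2 * dw * dw) / b2;
      if (s < eps) s = eps;
      if (s < 1.0) {
        double ex = std::exp(-1.0 / (1.0 - s));
        V[i] += ex / s;
        double u = 1.0 - s;
        double fp = ex * (-1.0 / (s * s) - 1.0 / (s * u * u));
        double cx = fp * 2.0 / b2;
        double cw = fp * (-2.0 * e2 / b2) * dw;
        for (int k = 0; k < d; ++k) {
          gx[(size_t)i * d + k] += cx * (-dd[k] + e2 * dw * wi[k]);
          gw[(size_t)i * d + k] += cw * dd[k];
        }
      }
      if (symmetrize) {
        const double* wj = ori + (size_t)j * d;
        double dwj = 0.0;
        for (int k = 0; k < d; ++k) dwj += dd[k] * wj[k];
        double sj = (dist2 - e2 * dwj * dwj) / b2;
        if (sj < eps) sj = eps;
        if (sj < 1.0) {
          double exj = std::exp(-1.0 / (1.0 - sj));
          double uj = 1.0 - sj;
          double fpj = exj * (-1.0 / (sj * sj) - 1.0 / (sj * uj * uj));
          double cxj = fpj * 2.0 / b2;
          for (int k = 0; k < d; ++k)
            gx[(size_t)i * d + k] += cxj * (-dd[k] + e2 * dwj * wj[k]);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List simulate_cpp(NumericMatrix pos0, NumericMatrix ori0,
                  double a, double b, double c, double alpha, double beta,
                  double L, double eps, double dt, int nsteps, int record_stride,
                  bool symmetrize = false) {
  int N = pos0.nrow(), d = pos0.ncol();
  std::vector<double> p((size_t)N * d), w((size_t)N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) {
      p[(size_t)i * d + k] = wrap01(pos0(i, k), L);
      w[(size_t)i * d + k] = ori0(i, k);
    }
  std::vector<double> V(N), gx((size_t)N * d), gw((size_t)N * d);
  VerletList vlist(N, d, L, a, 2.0);
  vlist.build(p.data());

  int nrec = nsteps / record_stride + 1;
  NumericVector times(nrec);
  NumericVector prec((size_t)nrec * N * d), wrec((size_t)nrec * N * d);
  prec.attr("dim") = IntegerVector::create(N, d, nrec);
  wrec.attr("dim") = IntegerVector::create(N, d, nrec);

  int irec = 0;
  auto record = [&](double t) {
    times[irec] = t;
    for (int k = 0; k < d; ++k)
      for (int i = 0; i < N; ++i) {
        size_t off = (size_t)irec * N * d + (size_t)k * N + i;  // column-major slab
        prec[off] = p[(size_t)i * d + k];
        wrec[off] = w[(size_t)i * d + k];
      }
    ++irec;
  };
  record(0.0);

  for (int step = 1; step <= nsteps; ++step) {
    if (vlist.stale(p.data())) vlist.build(p.data());
    fields_verlet(p.data(), w.data(), N, d, a, b, eps, L, vlist, symmetrize,
                  V.data(), gx.data(), gw.data());
    for (int i = 0; i < N; ++i) {
      double* xi = &p[(size_t)i * d];
      double* wi = &w[(size_t)i * d];
      const double* gxi = &gx[(size_t)i * d];
      const double* gwi = &gw[(size_t)i * d];
      // steering: tangential part of the orientation gradient
      double dotgw = 0.0;
      for (int k = 0; k < d; ++k) dotgw += gwi[k] * wi[k];
      double dw[3], any = 0.0;
      for (int k = 0; k < d; ++k) {
        dw[k] = -beta * (gwi[k] - dotgw * wi[k]);
        any += std::fabs(dw[k]);
      }
      for (int k = 0; k < d; ++k)
        xi[k] = wrap01(xi[k] + dt * (c * wi[k] - alpha * gxi[k]), L);
      if (any != 0.0) {   // exact conservation for beta = 0 or circular cells
        double nrm = 0.0;
        for (int k = 0; k < d; ++k) {
          wi[k] += dt * dw[k];
          nrm += wi[k] * wi[k];
        }
        nrm = std::sqrt(nrm);
        if (!(nrm > 0.0))
          stop("orientation of cell %d vanished at step %d (t = %g)",
               i + 1, step, step * dt);
        for (int k = 0; k < d; ++k) wi[k] /= nrm;
      }
      for (int k = 0; k < d; ++k)
        if (!std::isfinite(xi[k]) || !std::isfinite(wi[k]))
          stop("non-finite state for cell %d at step %d (t = %g)",
               i + 1, step, step * dt);
    }
    if (step % record_stride == 0) record(step * dt);
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = times, _["positions"] = prec,
                      _["orientations"] = wrec);
}

struct UnionFind {
  std::vector<int> parent;
  UnionFind(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int x, int y) {
    x = find(x); y = find(y);
    if (x != y) parent[y] = x;
  }
};

// [[Rcpp::export]]
IntegerVector cluster_labels_cpp(NumericMatrix pos, double R, double L) {
  int N = pos.nrow(), d = pos.ncol();
  std::vector<double> p((size_t)N * d);
  for (int i = 0; i < N; ++i)
    for (int k = 0; k < d; ++k) p[(size_t)i * d + k] = wrap01(pos(i, k), L);
  CellGrid grid(N, d, L, R);
  grid.build(p.data(), N);
  UnionFind uf(N);
  const double R2 = R * R;

  for (int i = 0; i < N; ++i) {
    const double* xi = &p[(size_t)i * d];
    if (grid.all_pairs) {
      for (int j = i + 1; j < N; ++j) {
        double dist2 = 0.0;
        for (int k = 0; k < d; ++k) {
          double dd = min_image(p[(size_t)j * d + k] - xi[k], L);
          dist2 += dd * dd;
        }
        if (dist2 <= R2) uf.unite(i, j);
      }
    } else {
      int ci[3] = {0, 0, 0};
      for (int k = 0; k < d; ++k) {
        int cbin = (int)(xi[k] / grid.bin);
        if (cbin >= grid.M) cbin = grid.M - 1;
        ci[k] = cbin;
      }
      int noff = (d == 2) ? 9 : 27;
      for (int o = 0; o < noff; ++o) {
        int rem = o, idx = 0;
        for (int k = 0; k < d; ++k) {
          int off = rem % 3 - 1;
          rem /= 3;
          int cb = ci[k] + off;
          if (cb < 0) cb += grid.M;
          if (cb >= grid.M) cb -= grid.M;
          idx = idx * grid.M + cb;
        }
        for (int j = grid.head[idx]; j >= 0; j = grid.nxt[j]) {
          if (j <= i) continue;
          double dist2 = 0.0;
          for (int k = 0; k < d; ++k) {
            double dd = min_image(p[(size_t)j * d + k] - xi[k], L);
            dist2 += dd * dd;
          }
          if (dist2 <= R2) uf.unite(i, j);
        }
      }
    }
  }

  IntegerVector labels(N);
  std::vector<int> relabel(N, 0);
  int next = 0;
  for (int i = 0; i < N; ++i) {
    int r = uf.find(i);
    if (relabel[r] == 0) relabel[r] = ++next;
    labels[i] = relabel[r];
  }
  return labels;
}
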