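#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Squared-distance values for "no feature voxel" use a large finite sentinel
// so the parabola arithmetic below stays well defined; anything at or above
// it maps back to +Inf on output.
static const double DT_LARGE = 1e20;

// 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// with physical sample spacing `h` (mm). f holds squared distances (mm^2)
// and is updated in place.
static void dt1d(std::vector<double>& f, int n, double h, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * h;
    double s;
    for (;;) {
      double vv = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + vv * vv)) / (2.0 * qq - 2.0 * vv);
      if (s <= z[k]) --k; else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double vv = (double)v[k] * h;
    d[q] = (qq - vv) * (qq - vv) + f[v[k]];
  }
  for (int q = 0; q < n; ++q) f[q] = d[q];
}

// Exact 3D Euclidean distance transform: distance (mm) from every voxel to the
// nearest voxel where mask != 0. Anisotropic spacing supported.
// [[Rcpp::export(name = ".cpp_edt")]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : DT_LARGE;

  int maxdim = std::max(nx, std::max(ny, nz));
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 2);
  std::vector<int> v(maxdim + 1);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, nx, spacing[0], d, v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = f[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
      dt1d(f, ny, spacing[1], d, v, z);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = f[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = g[base + (R_xlen_t)k * nx * ny];
      dt1d(f, nz, spacing[2], d, v, z);
      for (int k = 0; k < nz; ++k) g[base + (R_xlen_t)k * nx * ny] = f[k];
    }

  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (g[i] >= DT_LARGE) ? R_PosInf : std::sqrt(g[i]);
  return out;
}

// 6-connected component labelling. Components numbered 1.. in order of their
// lowest linear voxel index (deterministic tie-break contract).
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s]) continue;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t nb = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
        if (mask[nb] && !lab[nb]) { lab[nb] = next; stack.push_back(nb); }
      }
    }
  }
  return lab;
}

// Multi-source Dijkstra inside `domain`: each domain voxel gets the label of
// the geodesically nearest seed (6-neighbour graph, edge weights = physical
// spacing). Ties resolved toward the lower seed label (priority-queue order).
// [[Rcpp::export(name = ".cpp_geodesic_labels")]]
IntegerVector cpp_geodesic_labels(LogicalVector domain, IntegerVector dims,
                                  NumericVector spacing,
                                  IntegerVector seed_idx, IntegerVector seed_label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<double> dist(n, std::numeric_limits<double>::infinity());
  typedef std::pair<double, std::pair<R_xlen_t, int> > Node; // (dist, (idx, label))
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  for (int s = 0; s < seed_idx.size(); ++s) {
    R_xlen_t idx = (R_xlen_t)seed_idx[s] - 1; // 1-based from R
    if (idx < 0 || idx >= n || !domain[idx]) continue;
    if (0.0 < dist[idx]) {
      dist[idx] = 0.0;
      pq.push(Node(0.0, std::make_pair(idx, seed_label[s])));
    }
  }
  const int di[6] = { -1, 1, 0, 0, 0, 0 };
  const int dj[6] = { 0, 0, -1, 1, 0, 0 };
  const int dk[6] = { 0, 0, 0, 0, -1, 1 };
  const double w[6] = { spacing[0], spacing[0], spacing[1], spacing[1], spacing[2], spacing[2] };
  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double dcur = top.first;
    R_xlen_t cur = top.second.first;
    int lcur = top.second.second;
    if (lab[cur] != 0 || dcur > dist[cur]) continue;
    lab[cur] = lcur;
    int i = (int)(cur % nx);
    int j = (int)((cur / nx) % ny);
    int k = (int)(cur / ((R_xlen_t)nx * ny));
    for (int m = 0; m < 6; ++m) {
      int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
      if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
      R_xlen_t nb = (R_xlen_t)kk * nx * ny + (R_xlen_t)jj * nx + ii;
      if (!domain[nb] || lab[nb] != 0) continue;
      double nd = dcur + w[m];
      if (nd < dist[nb]) {
        dist[nb] = nd;
        pq.push(Node(nd, std::make_pair(nb, lcur)));
      }
    }
  }
  return lab;
}

// Two-tissue irreversible compartment model on a uniform fine grid.
// Exponential integrator, exact for piecewise-linear Ca; rates per minute,
// dt in minutes. Returns (1 - vb) (C1 + C2) + vb * Ca.
// [[Rcpp::export(name = ".cpp_two_tissue")]]
NumericVector cpp_two_tissue(NumericVector ca, double dt_min, double K1,
                             double k2, double k3, double vb) {
  const int n = ca.size();
  NumericVector out(n);
  const double k = k2 + k3;
  double E, phi1, psi;
  if (k > 0.0) {
    E = std::exp(-k * dt_min);
    phi1 = (1.0 - E) / k;
    psi = dt_min * phi1 - (1.0 - E * (1.0 + k * dt_min)) / (k * k);
  } else {
    E = 1.0;
    phi1 = dt_min;
    psi = dt_min * dt_min / 2.0;
  }
  double c1 = 0.0, c1prev = 0.0, c2 = 0.0;
  out[0] = vb * ca[0];
  for (int j = 1; j < n; ++j) {
    double u = K1 * (ca[j - 1] * phi1 + (ca[j] - ca[j - 1]) * psi / dt_min);
    c1 = E * c1prev + u;
    c2 += k3 * (c1prev + c1) / 2.0 * dt_min;
    out[j] = (1.0 - vb) * (c1 + c2) + vb * ca[j];
    c1prev = c1;
  }
  return out;
}
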