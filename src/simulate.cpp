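#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Piecewise pair interaction magnitude split into its attractive and
// repulsive parts. Distances at or below d_l, exactly at d_e, or outside
// every branch contribute nothing.
static inline void pair_magnitudes(double x, double d_l, double d_e, double d_h,
                                   double k1, double k2, double k3,
                                   double &attract, double &repulse) {
  attract = 0.0;
  repulse = 0.0;
  const double mid = 0.5 * (d_e + d_h);
  if (x > d_l && x < d_e) {
    repulse = k1 * (1.0 / x - 1.0 / d_e);
  } else if (x > d_e && x <= mid) {
    attract = k2 * std::sin((x - d_e) * M_PI / (d_h - d_e));
  } else if (x > mid) {
    attract = k3;
  }
}

// union-find for weak components of the K-nearest-neighbor digraph
struct DSU {
  std::vector<int> parent;
  DSU(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) { while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; } return x; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) parent[a] = b; }
};

static void knn_sets(const std::vector<double> &D, int n, int k,
                     std::vector<int> &nbrs) {
  // nbrs is n*k, neighbors of i sorted by (distance, index)
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      cand[m++] = std::make_pair(D[i * n + j], j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int r = 0; r < k; ++r) nbrs[i * k + r] = cand[r].second;
  }
}

// [[Rcpp::export(name = ".simulate_swarm_cpp")]]
List simulate_swarm_cpp(NumericMatrix init, int K,
                        double d_l, double d_e, double d_h,
                        double k1, double k2, double k3,
                        double a, double b, double c,
                        int t_max, double stability_tol, int stability_window,
                        int stride) {
  const int n = init.nrow();
  const int d = init.ncol();
  const int k = std::min(K, n - 1);

  std::vector<double> pos(init.begin(), init.end()); // column-major n x d
  std::vector<double> D(n * n, 0.0), Dnew(n * n, 0.0);
  std::vector<double> F(n * d, 0.0);
  std::vector<int> nbrs(std::max(1, n * k), 0);

  NumericMatrix centroid(t_max + 1, d);
  IntegerVector ncomp(t_max + 1, NA_INTEGER);
  NumericVector mean_nn(t_max + 1, NA_REAL);
  NumericVector max_change(t_max + 1, NA_REAL);

  std::vector<NumericMatrix> snaps;
  std::vector<int> snap_steps;

  const double abs_tol = stability_tol * d_e;
  int stationary_at = -1;
  int status = 0;       // 0 ok, 1 coincident agents, 2 non-finite blow-up
  int error_step = -1;
  int n_steps = 0;

  // per-state bookkeeping shared between step 0 and the loop
  auto dist_all = [&](const std::vector<double> &p, std::vector<double> &out) {
    for (int i = 0; i < n; ++i) {
      out[i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double s = 0.0;
        for (int q = 0; q < d; ++q) {
          double diff = p[q * n + i] - p[q * n + j];
          s += diff * diff;
        }
        s = std::sqrt(s);
        out[i * n + j] = s;
        out[j * n + i] = s;
      }
    }
  };
  auto record_state = [&](int t, const std::vector<double> &p,
                          const std::vector<double> &dist) {
    for (int q = 0; q < d; ++q) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += p[q * n + i];
      centroid(t, q) = s / n;
    }
    if (n > 1) {
      double acc = 0.0;
      for (int i = 0; i < n; ++i) {
        double mn = R_PosInf;
        for (int j = 0; j < n; ++j)
          if (j != i && dist[i * n + j] < mn) mn = dist[i * n + j];
        acc += mn;
      }
      mean_nn[t] = acc / n;
    }
    if (k > 0) {
      DSU dsu(n);
      for (int i = 0; i < n; ++i)
        for (int r = 0; r < k; ++r) dsu.unite(i, nbrs[i * k + r]);
      int comps = 0;
      for (int i = 0; i < n; ++i) if (dsu.find(i) == i) ++comps;
      ncomp[t] = comps;
    } else {
      ncomp[t] = n;
    }
  };
  auto snapshot = [&](int t, const std::vector<double> &p) {
    NumericMatrix m(n, d);
    std::copy(p.begin(), p.end(), m.begin());
    snaps.push_back(m);
    snap_steps.push_back(t);
  };

  dist_all(pos, D);
  if (k > 0) knn_sets(D, n, k, nbrs);
  record_state(0, pos, D);
  snapshot(0, pos);

  int quiet = 0;
  int t = 0;
  bool stored_last = true;
  for (t = 1; t <= t_max; ++t) {
    // forces from the state at t-1
    std::fill(F.begin(), F.end(), 0.0);
    for (int i = 0; i < n && status == 0; ++i) {
      for (int r = 0; r < k; ++r) {
        int j = nbrs[i * k + r];
        double x = D[i * n + j];
        if (x == 0.0) { status = 1; error_step = t; break; }
        double attract, repulse;
        pair_magnitudes(x, d_l, d_e, d_h, k1, k2, k3, attract, repulse);
        double s = (a * attract - b * repulse) / x;
        for (int q = 0; q < d; ++q)
          F[q * n + i] += s * (pos[q * n + j] - pos[q * n + i]);
      }
    }
    if (status != 0) { t -= 1; break; }

    bool finite = true;
    for (int q = 0; q < d; ++q)
      for (int i = 0; i < n; ++i) {
        pos[q * n + i] += c * F[q * n + i];
        if (!std::isfinite(pos[q * n + i])) finite = false;
      }
    if (!finite) { status = 2; error_step = t; break; }

    dist_all(pos, Dnew);
    double mc = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        double ch = std::fabs(Dnew[i * n + j] - D[i * n + j]);
        if (ch > mc) mc = ch;
      }
    max_change[t] = mc;
    if (k > 0) knn_sets(Dnew, n, k, nbrs);
    record_state(t, pos, Dnew);
    stored_last = false;
    if (t % stride == 0) { snapshot(t, pos); stored_last = true; }
    std::swap(D, Dnew);

    if (mc < abs_tol) ++quiet; else quiet = 0;
    if (quiet >= stability_window) {
      stationary_at = t - stability_window;
      break;
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  n_steps = std::min(t, t_max);
  if (status != 0 && error_step >= 0) n_steps = std::max(0, error_step - 1);
  if (!stored_last && status == 0) snapshot(n_steps, pos);

  List snaps_out(snaps.size());
  for (size_t s = 0; s < snaps.size(); ++s) snaps_out[s] = snaps[s];

  return List::create(
    _["snapshots"] = snaps_out,
    _["snapshot_steps"] = IntegerVector(snap_steps.begin(), snap_steps.end()),
    _["centroid"] = centroid,
    _["n_components"] = ncomp,
    _["mean_nn_dist"] = mean_nn,
    _["max_dist_change"] = max_change,
    _["stationary_at"] = stationary_at,
    _["n_steps"] = n_steps,
    _["status"] = status,
    _["error_step"] = error_step);
}
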