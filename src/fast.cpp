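// Bulk kernels for the window-resolved pipeline. These mirror the R
// reference implementations exactly (midrank Spearman; BFS distances;
// triangle counts; Brandes betweenness; finite-distance eccentricity;
// Newman assortativity; iterative k-core peeling) and are cross-checked
// against them in the test suite.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

// Midranks of v (ties averaged), as R's rank().
static void midranks(const double* v, int n, std::vector<double>& out,
                     std::vector<std::pair<double, int>>& buf) {
  buf.resize(n);
  out.resize(n);
  for (int i = 0; i < n; ++i) buf[i] = {v[i], i};
  std::sort(buf.begin(), buf.end());
  int i = 0;
  while (i < n) {
    int j = i;
    while (j + 1 < n && buf[j + 1].first == buf[i].first) ++j;
    double r = 0.5 * (i + j) + 1.0; // average of ranks i+1..j+1
    for (int k = i; k <= j; ++k) out[buf[k].second] = r;
    i = j + 1;
  }
}

// [[Rcpp::export]]
NumericVector cpp_fc_series(NumericMatrix x, IntegerVector starts,
                            int window_samples) {
  const int n_roi = x.nrow();
  const int n_win = starts.size();
  NumericVector fc(Dimension(n_roi, n_roi, n_win));
  std::vector<std::vector<double>> ranks(n_roi);
  std::vector<double> rbuf;
  std::vector<std::pair<double, int>> ibuf;
  std::vector<double> win(window_samples);
  std::vector<double> mu(n_roi), ss(n_roi);

  for (int w = 0; w < n_win; ++w) {
    const int s0 = starts[w];
    for (int r = 0; r < n_roi; ++r) {
      for (int t = 0; t < window_samples; ++t) win[t] = x(r, s0 + t);
      midranks(win.data(), window_samples, rbuf, ibuf);
      ranks[r] = rbuf;
      double m = 0;
      for (int t = 0; t < window_samples; ++t) m += rbuf[t];
      m /= window_samples;
      double s = 0;
      for (int t = 0; t < window_samples; ++t) {
        ranks[r][t] -= m;
        s += ranks[r][t] * ranks[r][t];
      }
      mu[r] = m;
      ss[r] = s;
    }
    double* slab = &fc[(size_t)w * n_roi * n_roi];
    for (int i = 0; i < n_roi; ++i) {
      slab[i * n_roi + i] = 1.0;
      for (int j = i + 1; j < n_roi; ++j) {
        double rho;
        if (ss[i] <= 0 || ss[j] <= 0) {
          rho = R_NaN;
        } else {
          double cp = 0;
          for (int t = 0; t < window_samples; ++t) {
            cp += ranks[i][t] * ranks[j][t];
          }
          rho = cp / std::sqrt(ss[i] * ss[j]);
        }
        slab[j * n_roi + i] = rho;
        slab[i * n_roi + j] = rho;
      }
    }
  }
  return fc;
}

struct GraphWork {
  int n;
  std::vector<int> adj;     // n x n 0/1, column-major
  std::vector<int> deg;
  std::vector<int> dist;    // per-source BFS distances
  std::vector<int> nbr;     // flattened neighbor lists
  std::vector<int> nbr_start;
};

static void build_neighbors(GraphWork& g) {
  g.nbr.clear();
  g.nbr_start.assign(g.n + 1, 0);
  for (int i = 0; i < g.n; ++i) {
    g.nbr_start[i] = (int)g.nbr.size();
    for (int j = 0; j < g.n; ++j) {
      if (g.adj[j * g.n + i]) g.nbr.push_back(j);
    }
  }
  g.nbr_start[g.n] = (int)g.nbr.size();
}

// metrics order: clustering, transitivity, efficiency, char_path_length,
// degree, betweenness, eccentricity, diameter, assortativity, kcore
static void graph_metrics_one(GraphWork& g, const LogicalVector& want,
                              double* out) {
  const int n = g.n;
  for (int m = 0; m < 10; ++m) out[m] = NA_REAL;

  g.deg.assign(n, 0);
  for (int i = 0; i < n; ++i) {
    int d = 0;
    for (int j = 0; j < n; ++j) d += g.adj[j * n + i];
    g.deg[i] = d;
  }

  if (want[0] || want[1]) { // clustering, transitivity
    double sum_ci = 0, sum_t2 = 0, sum_den = 0;
    for (int i = 0; i < n; ++i) {
      int t2 = 0; // 2 * triangles through i
      for (int j = 0; j < n; ++j) {
        if (!g.adj[j * n + i]) continue;
        for (int k = 0; k < n; ++k) {
          if (g.adj[k * n + i] && g.adj[k * n + j]) ++t2;
        }
      }
      double den = (double)g.deg[i] * (g.deg[i] - 1);
      if (den > 0) sum_ci += t2 / den;
      sum_t2 += t2;
      sum_den += den;
    }
    if (want[0]) out[0] = sum_ci / n;
    if (want[1]) out[1] = sum_den > 0 ? sum_t2 / sum_den : 0.0;
  }

  bool need_dist = want[2] || want[3] || want[6] || want[7];
  bool need_btw = want[5];
  if (need_dist || need_btw) build_neighbors(g);

  if (need_dist) {
    double inv_sum = 0, fin_sum = 0;
    long fin_count = 0;
    double ecc_sum = 0, diam = 0;
    std::vector<int> queue(n);
    for (int s = 0; s < n; ++s) {
      g.dist.assign(n, -1);
      g.dist[s] = 0;
      int head = 0, tail = 0;
      queue[tail++] = s;
      int ecc = 0;
      while (head < tail) {
        int v = queue[head++];
        for (int p = g.nbr_start[v]; p < g.nbr_start[v + 1]; ++p) {
          int w = g.nbr[p];
          if (g.dist[w] < 0) {
            g.dist[w] = g.dist[v] + 1;
            if (g.dist[w] > ecc) ecc = g.dist[w];
            queue[tail++] = w;
          }
        }
      }
      for (int t = 0; t < n; ++t) {
        if (t == s) continue;
        if (g.dist[t] > 0) {
          inv_sum += 1.0 / g.dist[t];
          fin_sum += g.dist[t];
          ++fin_count;
        }
      }
      ecc_sum += ecc;
      if (ecc > diam) diam = ecc;
    }
    if (want[2]) out[2] = n > 1 ? inv_sum / ((double)n * (n - 1)) : R_NaN;
    if (want[3]) out[3] = fin_count > 0 ? fin_sum / fin_count : R_NaN;
    if (want[6]) out[6] = ecc_sum / n;
    if (want[7]) out[7] = diam;
  }

  if (want[4]) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += g.deg[i];
    out[4] = s / n;
  }

  if (need_btw) { // Brandes, unnormalized, undirected
    std::vector<double> bc(n, 0.0), sigma(n), delta(n);
    std::vector<int> dist(n), order(n);
    std::vector<std::vector<int>> preds(n);
    for (int s = 0; s < n; ++s) {
      std::fill(sigma.begin(), sigma.end(), 0.0);
      std::fill(dist.begin(), dist.end(), -1);
      for (int i = 0; i < n; ++i) preds[i].clear();
      sigma[s] = 1.0;
      dist[s] = 0;
      int head = 0, tail = 0;
      order[tail++] = s;
      while (head < tail) {
        int v = order[head++];
        for (int p = g.nbr_start[v]; p < g.nbr_start[v + 1]; ++p) {
          int w = g.nbr[p];
          if (dist[w] < 0) {
            dist[w] = dist[v] + 1;
            order[tail++] = w;
          }
          if (dist[w] == dist[v] + 1) {
            sigma[w] += sigma[v];
            preds[w].push_back(v);
          }
        }
      }
      std::fill(delta.begin(), delta.end(), 0.0);
      for (int i = tail - 1; i >= 0; --i) {
        int w = order[i];
        for (int v : preds[w]) {
          delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
        }
        if (w != s) bc[w] += delta[w];
      }
    }
    double s2 = 0;
    for (int i = 0; i < n; ++i) s2 += bc[i] / 2.0;
    out[5] = s2 / n;
  }

  if (want[8]) { // assortativity over directed edge list
    double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
    long m2 = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) {
        if (i != j && g.adj[j * n + i]) {
          double x = g.deg[i], y = g.deg[j];
          sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
          ++m2;
        }
      }
    }
    if (m2 == 0) {
      out[8] = R_NaN;
    } else {
      double vx = sxx - sx * sx / m2;
      double vy = syy - sy * sy / m2;
      double cxy = sxy - sx * sy / m2;
      out[8] = (vx <= 0 || vy <= 0) ? R_NaN : cxy / std::sqrt(vx * vy);
    }
  }

  if (want[9]) { // coreness via iterative peeling
    std::vector<int> cdeg(g.deg);
    std::vector<char> alive(n, 1);
    std::vector<int> core(n, 0);
    int n_alive = n;
    for (int k = 1; k < n && n_alive > 0; ++k) {
      bool removed = true;
      while (removed) {
        removed = false;
        for (int i = 0; i < n; ++i) {
          if (alive[i] && cdeg[i] < k) {
            alive[i] = 0;
            --n_alive;
            removed = true;
            for (int j = 0; j < n; ++j) {
              if (alive[j] && g.adj[j * n + i]) --cdeg[j];
            }
          }
        }
      }
      for (int i = 0; i < n; ++i) {
        if (alive[i]) core[i] = k;
      }
    }
    double s3 = 0;
    for (int i = 0; i < n; ++i) s3 += core[i];
    out[9] = s3 / n;
  }
}

// Binarize-and-measure sweep for one epoch and one network. `fc` is the
// ROI x ROI x window array, `roi_idx` the 1-based indices of the network's
// ROIs, `want` the 10-element metric mask. Values are returned in the order
// (metric fastest, then window, then threshold), matching the long table
// layout built in R.
// [[Rcpp::export]]
NumericVector cpp_window_metric_sweep(NumericVector fc, IntegerVector fcdim,
                                      IntegerVector roi_idx,
                                      NumericVector thresholds,
                                      LogicalVector want) {
  const int n_all = fcdim[0];
  const int n_win = fcdim[2];
  const int n = roi_idx.size();
  const int n_th = thresholds.size();
  int n_want = 0;
  for (int m = 0; m < 10; ++m) {
    if (want[m]) ++n_want;
  }
  NumericVector out((size_t)n_want * n_win * n_th);
  GraphWork g;
  g.n = n;
  g.adj.assign((size_t)n * n, 0);
  double mv[10];
  size_t pos = 0;
  for (int th = 0; th < n_th; ++th) {
    const double tau = thresholds[th];
    for (int w = 0; w < n_win; ++w) {
      const double* slab = &fc[(size_t)w * n_all * n_all];
      for (int i = 0; i < n; ++i) {
        const int ri = roi_idx[i] - 1;
        for (int j = 0; j < n; ++j) {
          const int rj = roi_idx[j] - 1;
          const double v = slab[rj * n_all + ri];
          g.adj[j * n + i] = (i != j && !ISNAN(v) && v > tau) ? 1 : 0;
        }
      }
      graph_metrics_one(g, want, mv);
      for (int m = 0; m < 10; ++m) {
        if (want[m]) out[pos++] = mv[m];
      }
    }
  }
  return out;
}
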