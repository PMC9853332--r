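#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// path-halving union-find
static inline int uf_find(std::vector<int>& up, int i) {
  while (up[i] != i) { up[i] = up[up[i]]; i = up[i]; }
  return i;
}

// One daily step of the colonization/extinction chain, shared by the
// trajectory and ensemble drivers. Consumes exactly one unif_rand() per node,
// in node order, so the R reference engine can reproduce trajectories.
static void spom_day(const IntegerMatrix& X, int t,
                     const IntegerVector& parent, const NumericMatrix& K,
                     const NumericVector& area, double c_rate, double e_rate,
                     double dt, std::vector<int>& w, std::vector<int>& wn,
                     std::vector<int>& up, std::vector<double>& S,
                     std::vector<double>& phiE, std::vector<int>& occ) {
  const int N = X.ncol();
  for (int i = 0; i < N; ++i) {
    up[i] = i;
    if (X(t, i)) {
      S[i] = area[i];
      phiE[i] = 1.0 - std::exp(-e_rate / S[i] * dt);
    } else {
      S[i] = 0.0;
      phiE[i] = 1.0;  // dry-node rule: certain local extinction
    }
  }
  // connected components of the active subgraph (tree edges, both ends wet)
  for (int i = 0; i < N; ++i) {
    int p = parent[i];
    if (p >= 0 && X(t, i) && X(t, p)) {
      int a = uf_find(up, i), b = uf_find(up, p);
      if (a != b) up[a] = b;
    }
  }
  occ.clear();
  for (int j = 0; j < N; ++j)
    if (w[j] && X(t, j)) occ.push_back(j);
  for (int i = 0; i < N; ++i) {
    double u = unif_rand();
    if (w[i]) {
      wn[i] = (u < phiE[i]) ? 0 : 1;
    } else {
      double phiC = 0.0;
      if (X(t, i)) {
        double C = 0.0;
        int ci = uf_find(up, i);
        for (size_t q = 0; q < occ.size(); ++q) {
          int j = occ[q];
          if (j != i && uf_find(up, j) == ci) C += K(i, j) * S[j];
        }
        phiC = 1.0 - std::exp(-c_rate * C * dt);
      }
      wn[i] = (u < phiC) ? 1 : 0;
    }
  }
  std::swap(w, wn);
}

// Full occupancy trajectory of one replicate. X is T x N wet/dry (0/1),
// parent the 0-based downstream neighbour (-1 at the outlet), K the dispersal
// kernel exp(-d_ij/delta) with the distance cutoff already applied, area the
// wetted-bed area dl_i * W_i of node i when active. Returns (T+1) x N with
// row 1 equal to w0.
// [[Rcpp::export]]
IntegerMatrix spom_core(IntegerMatrix X, IntegerVector parent, NumericMatrix K,
                        NumericVector area, double c_rate, double e_rate,
                        IntegerVector w0, double dt) {
  const int T = X.nrow(), N = X.ncol();
  IntegerMatrix W(T + 1, N);
  std::vector<int> w(N), wn(N), up(N), occ;
  std::vector<double> S(N), phiE(N);
  occ.reserve(N);
  for (int i = 0; i < N; ++i) { w[i] = w0[i]; W(0, i) = w0[i]; }
  for (int t = 0; t < T; ++t) {
    spom_day(X, t, parent, K, area, c_rate, e_rate, dt, w, wn, up, S, phiE, occ);
    for (int i = 0; i < N; ++i) W(t + 1, i) = w[i];
  }
  return W;
}

// Ensemble of replicates sharing one wet/dry schedule: returns per-day,
// per-node occupancy counts over n_rep independent trajectories ((T+1) x N).
// [[Rcpp::export]]
NumericMatrix spom_core_ensemble(IntegerMatrix X, IntegerVector parent,
                                 NumericMatrix K, NumericVector area,
                                 double c_rate, double e_rate,
                                 IntegerVector w0, double dt, int n_rep) {
  const int T = X.nrow(), N = X.ncol();
  NumericMatrix counts(T + 1, N);
  std::vector<int> w(N), wn(N), up(N), occ;
  std::vector<double> S(N), phiE(N);
  occ.reserve(N);
  for (int r = 0; r < n_rep; ++r) {
    for (int i = 0; i < N; ++i) { w[i] = w0[i]; counts(0, i) += w0[i]; }
    for (int t = 0; t < T; ++t) {
      spom_day(X, t, parent, K, area, c_rate, e_rate, dt, w, wn, up, S, phiE, occ);
      for (int i = 0; i < N; ++i) counts(t + 1, i) += w[i];
    }
  }
  return counts;
}

// All pairwise along-channel distances on the tree (BFS from every node over
// the undirected adjacency; edge i--parent[i] has length edge_len[i]).
// [[Rcpp::export]]
NumericMatrix tree_distances_cpp(IntegerVector parent, NumericVector edge_len) {
  const int N = parent.size();
  std::vector<std::vector<std::pair<int, double> > > adj(N);
  for (int i = 0; i < N; ++i) {
    int p = parent[i];
    if (p >= 0) {
      adj[i].push_back(std::make_pair(p, edge_len[i]));
      adj[p].push_back(std::make_pair(i, edge_len[i]));
    }
  }
  NumericMatrix D(N, N);
  std::vector<int> queue(N);
  std::vector<bool> seen(N);
  for (int s = 0; s < N; ++s) {
    std::fill(seen.begin(), seen.end(), false);
    int head = 0, tail = 0;
    queue[tail++] = s;
    seen[s] = true;
    while (head < tail) {
      int u = queue[head++];
      for (size_t q = 0; q < adj[u].size(); ++q) {
        int v = adj[u][q].first;
        if (!seen[v]) {
          seen[v] = true;
          D(s, v) = D(s, u) + adj[u][q].second;
          queue[tail++] = v;
        }
      }
    }
  }
  return D;
}

// Per-day length of the largest connected portion (LCP) of the active
// network: union-find over tree edges whose two endpoints are both active,
// component size measured as summed reach length.
// [[Rcpp::export]]
NumericVector lcp_lengths_cpp(IntegerMatrix X, IntegerVector parent,
                              NumericVector reach_len) {
  const int T = X.nrow(), N = X.ncol();
  NumericVector lcp(T);
  std::vector<int> up(N);
  std::vector<double> len(N);
  for (int t = 0; t < T; ++t) {
    for (int i = 0; i < N; ++i) {
      up[i] = i;
      len[i] = X(t, i) ? reach_len[i] : 0.0;
    }
    for (int i = 0; i < N; ++i) {
      int p = parent[i];
      if (p >= 0 && X(t, i) && X(t, p)) {
        int a = uf_find(up, i), b = uf_find(up, p);
        if (a != b) { up[a] = b; len[b] += len[a]; }
      }
    }
    double best = 0.0;
    for (int i = 0; i < N; ++i)
      if (X(t, i) && uf_find(up, i) == i && len[i] > best) best = len[i];
    lcp[t] = best;
  }
  return lcp;
}
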