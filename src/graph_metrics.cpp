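// Core weighted-graph metrics for density-thresholded connectivity matrices.
// Implemented in C++ with CSR adjacency and reusable workspaces because
// null-model normalization evaluates these metrics on thousands of rewired
// graphs per subject. Edge length for path-based metrics is 1/weight (the
// standard convention for correlation-weighted graphs).
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

#define RESTRICT __restrict__

namespace {

// relative tolerance for "equal shortest-path length" when counting paths
const double PATH_TOL = 1e-10;

// undirected graph as an edge list (i < j) plus CSR adjacency
struct Graph {
  int K;
  std::vector<int> ei, ej;
  std::vector<double> ew;
  std::vector<int> off;  // CSR offsets, size K+1
  std::vector<int> nbr;  // size 2E
  std::vector<double> len, wgt;

  void from_matrix(const NumericMatrix &W) {
    K = W.nrow();
    ei.clear();
    ej.clear();
    ew.clear();
    for (int j = 1; j < K; ++j)
      for (int i = 0; i < j; ++i)
        if (W(i, j) > 0) {
          ei.push_back(i);
          ej.push_back(j);
          ew.push_back(W(i, j));
        }
    build_csr();
  }

  void build_csr() {
    int E = (int)ei.size();
    off.assign(K + 1, 0);
    for (int e = 0; e < E; ++e) {
      ++off[ei[e] + 1];
      ++off[ej[e] + 1];
    }
    for (int v = 0; v < K; ++v) off[v + 1] += off[v];
    nbr.resize(2 * E);
    len.resize(2 * E);
    wgt.resize(2 * E);
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int e = 0; e < E; ++e) {
      double l = 1.0 / ew[e];
      nbr[pos[ei[e]]] = ej[e];
      len[pos[ei[e]]] = l;
      wgt[pos[ei[e]]] = ew[e];
      ++pos[ei[e]];
      nbr[pos[ej[e]]] = ei[e];
      len[pos[ej[e]]] = l;
      wgt[pos[ej[e]]] = ew[e];
      ++pos[ej[e]];
    }
  }
};

struct HeapEntry {
  double d;
  int v;
};
inline bool heap_less(const HeapEntry &a, const HeapEntry &b) {
  return a.d > b.d;  // min-heap via std::push_heap
}

// workspace reused across sources, nulls and densities
struct Workspace {
  std::vector<double> d, sigma, delta;
  std::vector<int> order, pred, pred_cnt;
  std::vector<char> done;
  std::vector<HeapEntry> heap;
  std::vector<double> dense_y;  // K x K scaled cube-root weights
  std::vector<double> strength, betweenness;
  std::vector<int> degree;

  void resize(int K, int E2) {
    d.resize(K);
    sigma.resize(K);
    delta.resize(K);
    order.resize(K);
    pred.resize(E2);
    pred_cnt.resize(K);
    done.resize(K);
    heap.reserve(4 * K);
    strength.assign(K, 0.0);
    betweenness.assign(K, 0.0);
    degree.assign(K, 0);
    if (dense_y.size() < (size_t)K * K) dense_y.assign((size_t)K * K, 0.0);
  }
};

struct GlobalMetrics {
  double clustering, path_length;
};

// Brandes' betweenness (Dijkstra variant with a lazy-deletion binary heap)
// accumulating all-pairs finite geodesic lengths. Predecessors live in
// CSR-aligned flat storage (a node's geodesic predecessors are a subset of
// its neighbours).
void brandes(const Graph &g, Workspace &ws, double &dist_sum, long &dist_n) {
  int K = g.K;
  dist_sum = 0.0;
  dist_n = 0;
  std::fill(ws.betweenness.begin(), ws.betweenness.end(), 0.0);
  double *RESTRICT d = ws.d.data();
  double *RESTRICT sigma = ws.sigma.data();
  double *RESTRICT delta = ws.delta.data();
  char *RESTRICT done = ws.done.data();
  for (int s = 0; s < K; ++s) {
    std::fill(ws.d.begin(), ws.d.end(), R_PosInf);
    std::fill(ws.done.begin(), ws.done.end(), 0);
    std::fill(ws.pred_cnt.begin(), ws.pred_cnt.end(), 0);
    std::fill(ws.sigma.begin(), ws.sigma.end(), 0.0);
    int n_order = 0;
    d[s] = 0.0;
    sigma[s] = 1.0;
    ws.heap.clear();
    ws.heap.push_back(HeapEntry{0.0, s});
    while (!ws.heap.empty()) {
      HeapEntry top = ws.heap.front();
      std::pop_heap(ws.heap.begin(), ws.heap.end(), heap_less);
      ws.heap.pop_back();
      int v = top.v;
      if (done[v]) continue;
      done[v] = 1;
      ws.order[n_order++] = v;
      double dv = d[v];
      const int *RESTRICT nbr = g.nbr.data();
      const double *RESTRICT len = g.len.data();
      const int *RESTRICT off = g.off.data();
      int *RESTRICT pred = ws.pred.data();
      int *RESTRICT pred_cnt = ws.pred_cnt.data();
      // settled nodes need no explicit skip: edge lengths are strictly
      // positive and far above the tie tolerance, so neither branch can
      // fire for an already-settled neighbour
      for (int k = off[v]; k < off[v + 1]; ++k) {
        int u = nbr[k];
        double nd = dv + len[k];
        double du = d[u];
        double tol = PATH_TOL * (1.0 + nd);
        if (nd < du - tol) {
          d[u] = nd;
          sigma[u] = sigma[v];
          pred_cnt[u] = 1;
          pred[off[u]] = v;
          ws.heap.push_back(HeapEntry{nd, u});
          std::push_heap(ws.heap.begin(), ws.heap.end(), heap_less);
        } else if (nd - du <= tol && nd - du >= -tol && !done[u]) {
          sigma[u] += sigma[v];
          pred[off[u] + pred_cnt[u]++] = v;
        }
      }
    }
    std::fill(ws.delta.begin(), ws.delta.end(), 0.0);
    for (int k = n_order - 1; k >= 0; --k) {
      int v = ws.order[k];
      double coeff = (1.0 + delta[v]) / sigma[v];
      for (int p = 0; p < ws.pred_cnt[v]; ++p) {
        int u = ws.pred[g.off[v] + p];
        delta[u] += sigma[u] * coeff;
      }
      if (v != s) {
        ws.betweenness[v] += delta[v];
        dist_sum += d[v];
        ++dist_n;
      }
    }
  }
}

// Onnela weighted clustering, BCT convention: weights scaled by the maximum
// weight, nodes with degree < 2 contribute 0, mean over all K nodes. The
// dense cube-root lookup is cleared edge-wise so the buffer can be reused.
double onnela_clustering(const Graph &g, Workspace &ws) {
  int K = g.K;
  double wmax = 0.0;
  for (size_t e = 0; e < g.ew.size(); ++e)
    if (g.ew[e] > wmax) wmax = g.ew[e];
  if (wmax <= 0) return NA_REAL;
  double inv = 1.0 / wmax;
  for (int v = 0; v < K; ++v)
    for (int k = g.off[v]; k < g.off[v + 1]; ++k)
      ws.dense_y[(size_t)v * K + g.nbr[k]] = std::cbrt(g.wgt[k] * inv);
  double total = 0.0;
  for (int v = 0; v < K; ++v) {
    int kv = g.off[v + 1] - g.off[v];
    if (kv < 2) continue;
    double cyc = 0.0;
    const double *vrow = &ws.dense_y[(size_t)v * K];
    for (int p = g.off[v]; p < g.off[v + 1]; ++p) {
      int j = g.nbr[p];
      double yij = vrow[j];
      const double *row = &ws.dense_y[(size_t)j * K];
      for (int q = p + 1; q < g.off[v + 1]; ++q) {
        double yjl = row[g.nbr[q]];
        if (yjl > 0) cyc += 2.0 * yij * vrow[g.nbr[q]] * yjl;
      }
    }
    total += cyc / ((double)kv * (kv - 1));
  }
  // clear only the touched entries
  for (int v = 0; v < K; ++v)
    for (int k = g.off[v]; k < g.off[v + 1]; ++k)
      ws.dense_y[(size_t)v * K + g.nbr[k]] = 0.0;
  return total / K;
}

GlobalMetrics all_metrics(const Graph &g, Workspace &ws) {
  int K = g.K;
  ws.resize(K, (int)g.nbr.size());
  for (int v = 0; v < K; ++v) {
    double s = 0.0;
    for (int k = g.off[v]; k < g.off[v + 1]; ++k) s += g.wgt[k];
    ws.strength[v] = s;
    ws.degree[v] = g.off[v + 1] - g.off[v];
  }
  double dist_sum;
  long dist_n;
  brandes(g, ws, dist_sum, dist_n);
  double norm = (double)(K - 1) * (K - 2) / 2.0;
  for (int v = 0; v < K; ++v) ws.betweenness[v] /= 2.0 * norm;
  GlobalMetrics gm;
  gm.path_length = dist_n > 0 ? dist_sum / dist_n : NA_REAL;
  gm.clustering = onnela_clustering(g, ws);
  return gm;
}

// splitmix64 stream seeded from R's RNG: keeps every draw reproducible
// under set.seed() while avoiding the per-call cost of R's generator in
// the swap loop
struct FastRng {
  uint64_t s;
  explicit FastRng() {
    s = (uint64_t)(unif_rand() * 4294967296.0) ^
        ((uint64_t)(unif_rand() * 4294967296.0) << 32);
  }
  uint64_t next64() {
    s += 0x9E3779B97f4A7C15ULL;
    uint64_t z = s;
    z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
    z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next64() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) {
    int v;
    do {
      v = (int)(unif() * n);
    } while (v >= n);
    return v;
  }
};

// Maslov-Sneppen degree-preserving rewiring of the binary topology followed
// by random reassignment of the original weight multiset to the new edges;
// operates on the edge list in place and rebuilds the CSR.
int rewire_graph(Graph &g, std::vector<char> &adj, int swaps_per_edge,
                 FastRng &rng) {
  int K = g.K;
  int E = (int)g.ei.size();
  if (E < 2) return 0;
  std::fill(adj.begin(), adj.end(), 0);
  for (int e = 0; e < E; ++e)
    adj[(size_t)g.ei[e] * K + g.ej[e]] =
        adj[(size_t)g.ej[e] * K + g.ei[e]] = 1;
  int accepted = 0;
  long attempts = (long)swaps_per_edge * E;
  for (long t = 0; t < attempts; ++t) {
    int e1 = rng.below(E), e2 = rng.below(E);
    if (e1 == e2) continue;
    int a1 = g.ei[e1], b1 = g.ej[e1], a2 = g.ei[e2], b2 = g.ej[e2];
    if (rng.unif() < 0.5) std::swap(a2, b2);
    // proposed replacement edges: (a1, b2) and (a2, b1)
    if (a1 == b2 || a2 == b1 || a1 == a2 || b1 == b2) continue;
    if (adj[(size_t)a1 * K + b2] || adj[(size_t)a2 * K + b1]) continue;
    adj[(size_t)a1 * K + b1] = adj[(size_t)b1 * K + a1] = 0;
    adj[(size_t)a2 * K + b2] = adj[(size_t)b2 * K + a2] = 0;
    adj[(size_t)a1 * K + b2] = adj[(size_t)b2 * K + a1] = 1;
    adj[(size_t)a2 * K + b1] = adj[(size_t)b1 * K + a2] = 1;
    g.ei[e1] = std::min(a1, b2);
    g.ej[e1] = std::max(a1, b2);
    g.ei[e2] = std::min(a2, b1);
    g.ej[e2] = std::max(a2, b1);
    ++accepted;
  }
  // shuffle the weight multiset onto the rewired edges (Fisher-Yates)
  for (int e = E - 1; e > 0; --e) {
    int r = rng.below(e + 1);
    std::swap(g.ew[e], g.ew[r]);
  }
  g.build_csr();
  return accepted;
}

}  // namespace

// [[Rcpp::export(name = ".cpp_graph_metrics")]]
List cpp_graph_metrics(NumericMatrix W) {
  Graph g;
  g.from_matrix(W);
  Workspace ws;
  GlobalMetrics gm = all_metrics(g, ws);
  return List::create(
      Named("strength") = NumericVector(ws.strength.begin(),
                                        ws.strength.end()),
      Named("degree") = IntegerVector(ws.degree.begin(), ws.degree.end()),
      Named("betweenness") =
          NumericVector(ws.betweenness.begin(), ws.betweenness.end()),
      Named("clustering") = gm.clustering,
      Named("path_length") = gm.path_length);
}

// [[Rcpp::export(name = ".cpp_rewire")]]
List cpp_rewire(NumericMatrix W, int swaps_per_edge) {
  Graph g;
  g.from_matrix(W);
  int K = g.K;
  std::vector<char> adj((size_t)K * K, 0);
  FastRng rng;
  int accepted = rewire_graph(g, adj, swaps_per_edge, rng);
  NumericMatrix out(K, K);
  for (size_t e = 0; e < g.ei.size(); ++e) {
    out(g.ei[e], g.ej[e]) = g.ew[e];
    out(g.ej[e], g.ei[e]) = g.ew[e];
  }
  return List::create(Named("weights") = out, Named("accepted") = accepted);
}

// One call per (subject, density): metrics of `n_nulls` rewired surrogates.
// Degree is preserved exactly by construction and therefore not returned.
// [[Rcpp::export(name = ".cpp_null_ensemble")]]
List cpp_null_ensemble(NumericMatrix W, int n_nulls, int swaps_per_edge) {
  int K = W.nrow();
  NumericMatrix strength(n_nulls, K), betweenness(n_nulls, K);
  NumericVector clustering(n_nulls), path_length(n_nulls);
  IntegerVector accepted(n_nulls);
  Graph base;
  base.from_matrix(W);
  Workspace ws;
  std::vector<char> adj((size_t)K * K, 0);
  FastRng rng;
  for (int n = 0; n < n_nulls; ++n) {
    Graph g = base;  // fresh copy: each null rewires the original topology
    accepted[n] = rewire_graph(g, adj, swaps_per_edge, rng);
    GlobalMetrics gm = all_metrics(g, ws);
    for (int v = 0; v < K; ++v) {
      strength(n, v) = ws.strength[v];
      betweenness(n, v) = ws.betweenness[v];
    }
    clustering[n] = gm.clustering;
    path_length[n] = gm.path_length;
  }
  return List::create(Named("strength") = strength,
                      Named("betweenness") = betweenness,
                      Named("clustering") = clustering,
                      Named("path_length") = path_length,
                      Named("accepted") = accepted);
}
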