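// Degree-preserving double-edge-swap rewiring and BFS-based clustering /
// path-length metrics. These sit inside the null-model loop (hundreds of
// rewired networks per subject per sparsity level), hence C++. Adjacency is
// kept as a flat byte matrix: node counts here are small (tens to a few
// hundred), so O(n^2) memory buys O(1) edge tests with no hashing.
#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// xorshift64* PRNG: deterministic across platforms, independent of R's RNG
// stream so null-model draws cannot perturb user-level set.seed() state.
struct XorShift {
  uint64_t s;
  explicit XorShift(uint64_t seed) : s(seed ? seed : 0x9E3779B97F4A7C15ULL) {}
  uint64_t next() {
    s ^= s >> 12; s ^= s << 25; s ^= s >> 27;
    return s * 0x2545F4914F6CDD1DULL;
  }
  int below(int n) { return static_cast<int>(next() % static_cast<uint64_t>(n)); }
};

struct EdgeGraph {
  int n, m;
  std::vector<int> from, to;
  std::vector<uint8_t> adj;  // n x n, row-major
  EdgeGraph(const IntegerMatrix& edges, int n_nodes)
      : n(n_nodes), m(edges.nrow()), from(m), to(m), adj(n_nodes * n_nodes, 0) {
    for (int e = 0; e < m; ++e) {
      int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
      from[e] = a; to[e] = b;
      adj[a * n + b] = adj[b * n + a] = 1;
    }
  }
  void reset(const EdgeGraph& src) {
    from = src.from; to = src.to; adj = src.adj;
  }
  bool has(int a, int b) const { return adj[a * n + b] != 0; }
  void set(int a, int b, uint8_t v) { adj[a * n + b] = adj[b * n + a] = v; }
  // attempt double-edge swaps until `target` succeed or `max_attempts` tried
  int rewire(int target, long long max_attempts, XorShift& rng) {
    if (m < 2) return 0;
    int done = 0;
    for (long long att = 0; att < max_attempts && done < target; ++att) {
      int e1 = rng.below(m), e2 = rng.below(m);
      if (e1 == e2) continue;
      int a = from[e1], b = to[e1], c = from[e2], d = to[e2];
      if (rng.next() & 1) std::swap(c, d);
      // propose (a,d) and (c,b)
      if (a == d || c == b || a == c || b == d) continue;
      if (has(a, d) || has(c, b)) continue;
      set(a, b, 0); set(c, d, 0);
      set(a, d, 1); set(c, b, 1);
      to[e1] = d; from[e2] = c; to[e2] = b;
      ++done;
    }
    return done;
  }
};

// mean local clustering (nodes with degree < 2 contribute 0) and mean
// shortest path over connected ordered pairs, via neighbour lists + BFS
static void cp_lp(const EdgeGraph& g, double& cp, double& lp) {
  int n = g.n;
  std::vector<int> deg(n, 0), start(n + 1, 0);
  for (int e = 0; e < g.m; ++e) { ++deg[g.from[e]]; ++deg[g.to[e]]; }
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> nbr(2 * g.m);
  std::vector<int> pos(start.begin(), start.end() - 1);
  for (int e = 0; e < g.m; ++e) {
    nbr[pos[g.from[e]]++] = g.to[e];
    nbr[pos[g.to[e]]++] = g.from[e];
  }
  double csum = 0.0;
  for (int i = 0; i < n; ++i) {
    int k = deg[i];
    if (k < 2) continue;
    int tri = 0;
    for (int u = start[i]; u < start[i + 1]; ++u)
      for (int v = u + 1; v < start[i + 1]; ++v)
        if (g.has(nbr[u], nbr[v])) ++tri;
    csum += 2.0 * tri / (static_cast<double>(k) * (k - 1));
  }
  cp = csum / n;
  long long dsum = 0, npairs = 0;
  std::vector<int> dist(n), queue(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int w = start[u]; w < start[u + 1]; ++w) {
        int v = nbr[w];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; queue[tail++] = v; }
      }
    }
    for (int t = 0; t < n; ++t) if (t != s && dist[t] > 0) {
      dsum += dist[t]; ++npairs;
    }
  }
  lp = npairs ? static_cast<double>(dsum) / npairs : NA_REAL;
}

// [[Rcpp::export]]
List cpp_rewire(IntegerMatrix edges, int n_nodes, int target_swaps,
                double max_attempts, double seed) {
  EdgeGraph g(edges, n_nodes);
  XorShift rng(static_cast<uint64_t>(seed));
  int done = g.rewire(target_swaps, static_cast<long long>(max_attempts), rng);
  IntegerMatrix out(g.m, 2);
  for (int e = 0; e < g.m; ++e) {
    int a = g.from[e] + 1, b = g.to[e] + 1;
    out(e, 0) = std::min(a, b);
    out(e, 1) = std::max(a, b);
  }
  return List::create(_["edges"] = out, _["n_swaps"] = done);
}

// [[Rcpp::export]]
List cpp_null_cp_lp(IntegerMatrix edges, int n_nodes, int n_null,
                    int swaps_per_edge, double max_attempt_factor,
                    double seed) {
  NumericVector cps(n_null), lps(n_null);
  IntegerVector swaps(n_null);
  EdgeGraph base(edges, n_nodes), g(edges, n_nodes);
  int target = swaps_per_edge * base.m;
  long long cap = static_cast<long long>(max_attempt_factor) * target;
  XorShift rng(static_cast<uint64_t>(seed));
  for (int r = 0; r < n_null; ++r) {
    g.reset(base);
    swaps[r] = g.rewire(target, cap, rng);
    double cp, lp;
    cp_lp(g, cp, lp);
    cps[r] = cp; lps[r] = lp;
  }
  return List::create(_["cp"] = cps, _["lp"] = lps, _["n_swaps"] = swaps);
}

// [[Rcpp::export]]
List cpp_cp_lp(IntegerMatrix edges, int n_nodes) {
  EdgeGraph g(edges, n_nodes);
  double cp, lp;
  cp_lp(g, cp, lp);
  return List::create(_["cp"] = cp, _["lp"] = lp);
}

// global efficiency of an adjacency submatrix given as index list into g
static double sub_eglob(const EdgeGraph& g, const std::vector<int>& nodes) {
  int k = static_cast<int>(nodes.size());
  if (k < 2) return 0.0;
  std::vector<int> dist(k), queue(k);
  double esum = 0.0;
  for (int s = 0; s < k; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int v = 0; v < k; ++v)
        if (dist[v] < 0 && g.has(nodes[u], nodes[v])) {
          dist[v] = dist[u] + 1; queue[tail++] = v;
        }
    }
    for (int t = 0; t < k; ++t)
      if (t != s && dist[t] > 0) esum += 1.0 / dist[t];
  }
  return esum / (static_cast<double>(k) * (k - 1));
}

// [[Rcpp::export]]
List cpp_global_metrics(IntegerMatrix edges, int n_nodes) {
  EdgeGraph g(edges, n_nodes);
  double cp, lp;
  cp_lp(g, cp, lp);
  int n = n_nodes;
  // neighbour lists
  std::vector<std::vector<int>> nb(n);
  for (int e = 0; e < g.m; ++e) {
    nb[g.from[e]].push_back(g.to[e]);
    nb[g.to[e]].push_back(g.from[e]);
  }
  // eglob, nodal efficiency and component count by BFS
  NumericVector nodal_eff(n);
  std::vector<int> dist(n), queue(n), comp(n, -1);
  int n_comp = 0;
  double esum_all = 0.0;
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    dist[s] = 0;
    int head = 0, tail = 0;
    queue[tail++] = s;
    while (head < tail) {
      int u = queue[head++];
      for (int v : nb[u]) if (dist[v] < 0) {
        dist[v] = dist[u] + 1; queue[tail++] = v;
      }
    }
    double esum = 0.0;
    for (int t = 0; t < n; ++t)
      if (t != s && dist[t] > 0) esum += 1.0 / dist[t];
    nodal_eff[s] = (n > 1) ? esum / (n - 1) : 0.0;
    esum_all += esum;
    if (comp[s] < 0) {
      ++n_comp;
      for (int t = 0; t < n; ++t) if (dist[t] >= 0) comp[t] = n_comp;
    }
  }
  double eglob = (n > 1) ? esum_all / (static_cast<double>(n) * (n - 1)) : 0.0;
  // local efficiency: eglob of each node's neighbour-induced subgraph
  double eloc_sum = 0.0;
  for (int i = 0; i < n; ++i) eloc_sum += sub_eglob(g, nb[i]);
  return List::create(_["cp"] = cp, _["lp"] = lp, _["eglob"] = eglob,
                      _["eloc"] = eloc_sum / n,
                      _["nodal_efficiency"] = nodal_eff,
                      _["n_components"] = n_comp);
}
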