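#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Counter-based RNG (SplitMix64): community detection must be reproducible
// per (window, init) independently of call order, so we keep our own stream
// rather than touching R's RNG.
static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97f4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int rand_below(uint64_t &state, int n) {
  return (int)(splitmix64(state) % (uint64_t)n);
}

static void shuffle_vec(std::vector<int> &v, uint64_t &state) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = rand_below(state, i + 1);
    std::swap(v[i], v[j]);
  }
}

// One pass of greedy local moving on a dense (super)graph M (m x m, symmetric,
// self-loops on the diagonal carry collapsed within-community weight).
// Quality convention: Q = sum_{c,d} M[c,d] * [comm c == comm d].
static std::vector<int> local_move(const std::vector<double> &M, int m,
                                   uint64_t &state, bool &moved_any) {
  std::vector<int> comm(m);
  for (int i = 0; i < m; ++i) comm[i] = i;
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  std::vector<double> S(m);
  moved_any = false;
  bool improved = true;
  while (improved) {
    improved = false;
    shuffle_vec(order, state);
    for (int oi = 0; oi < m; ++oi) {
      int i = order[oi];
      std::fill(S.begin(), S.end(), 0.0);
      const double *row = &M[(size_t)i * m];
      for (int j = 0; j < m; ++j)
        if (j != i) S[comm[j]] += row[j];
      int a = comm[i];
      int best = a;
      double best_gain = 0.0;
      for (int c = 0; c < m; ++c) {
        if (c == a) continue;
        double gain = 2.0 * (S[c] - S[a]);
        if (gain > best_gain + 1e-12) {
          best_gain = gain;
          best = c;
        }
      }
      if (best != a) {
        comm[i] = best;
        improved = true;
        moved_any = true;
      }
    }
  }
  // relabel contiguously by first appearance
  std::vector<int> map(m, -1);
  int next = 0;
  for (int i = 0; i < m; ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return comm;
}

// Full multilevel (Louvain-style) run on modularity matrix M0 (diag zero).
static std::vector<int> louvain_run(const std::vector<double> &M0, int n,
                                    uint64_t state) {
  std::vector<double> M = M0;
  int m = n;
  std::vector<int> assign(n);
  for (int i = 0; i < n; ++i) assign[i] = i;
  while (m > 1) {
    bool moved = false;
    std::vector<int> comm = local_move(M, m, state, moved);
    int m2 = 0;
    for (int c = 0; c < m; ++c) m2 = std::max(m2, comm[c] + 1);
    for (int i = 0; i < n; ++i) assign[i] = comm[assign[i]];
    if (!moved || m2 == m) break;
    std::vector<double> M2((size_t)m2 * m2, 0.0);
    for (int c = 0; c < m; ++c)
      for (int d = 0; d < m; ++d)
        M2[(size_t)comm[c] * m2 + comm[d]] += M[(size_t)c * m + d];
    M = M2;
    m = m2;
  }
  return assign;
}

static double partition_quality(const std::vector<double> &B, int n,
                                const std::vector<int> &assign) {
  double q = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && assign[i] == assign[j]) q += B[(size_t)i * n + j];
  return q;
}

// [[Rcpp::export]]
List louvain_best_cpp(NumericMatrix B, int n_init, double seed) {
  int n = B.nrow();
  std::vector<double> M0((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      M0[(size_t)i * n + j] = (i == j) ? 0.0 : B(i, j);

  uint64_t base = (uint64_t)(int64_t)seed;
  NumericVector q_runs(n_init);
  std::vector<int> best_assign(n, 0);
  double best_q = R_NegInf;
  for (int k = 0; k < n_init; ++k) {
    uint64_t state = base;
    // decorrelate init streams via the counter
    for (int warm = 0; warm <= k % 7; ++warm) splitmix64(state);
    state ^= 0xD1B54A32D192ED03ULL * (uint64_t)(k + 1);
    std::vector<int> assign = louvain_run(M0, n, state);
    double q = partition_quality(M0, n, assign);
    q_runs[k] = q;
    if (q > best_q + 1e-15) {
      best_q = q;
      best_assign = assign;
    }
  }
  // contiguous 1-based labels by first appearance
  std::vector<int> map(n, -1);
  int next = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    if (map[best_assign[i]] < 0) map[best_assign[i]] = next++;
    out[i] = map[best_assign[i]] + 1;
  }
  return List::create(_["assignment"] = out, _["quality"] = best_q,
                      _["q_runs"] = q_runs);
}

// Degree-preserving Maslov-Sneppen edge swaps on one sign's edge list,
// refusing candidate edges already occupied by either sign (so positive and
// negative subnetworks never collide on a node pair). `occupied` is the
// union adjacency of both signs and is kept current across calls via the
// returned edge list.
// [[Rcpp::export]]
IntegerMatrix rewire_edgelist_cpp(int n_nodes, IntegerMatrix edges,
                                  IntegerMatrix occupied_pairs, int niter,
                                  double seed) {
  int E = edges.nrow();
  std::vector<char> occ((size_t)n_nodes * n_nodes, 0);
  for (int k = 0; k < occupied_pairs.nrow(); ++k) {
    int u = occupied_pairs(k, 0) - 1, v = occupied_pairs(k, 1) - 1;
    occ[(size_t)u * n_nodes + v] = occ[(size_t)v * n_nodes + u] = 1;
  }
  std::vector<int> eu(E), ev(E);
  for (int k = 0; k < E; ++k) {
    eu[k] = edges(k, 0) - 1;
    ev[k] = edges(k, 1) - 1;
  }
  uint64_t state = (uint64_t)(int64_t)seed;
  splitmix64(state);
  auto occ_at = [&](int a, int b) -> char & {
    return occ[(size_t)a * n_nodes + b];
  };
  if (E >= 2) {
    for (int it = 0; it < niter; ++it) {
      int e1 = rand_below(state, E), e2 = rand_below(state, E);
      if (e1 == e2) continue;
      int a = eu[e1], b = ev[e1], c = eu[e2], d = ev[e2];
      if (rand_below(state, 2)) std::swap(c, d);
      // propose a-d and c-b
      if (a == d || c == b || a == c || b == d) continue;
      if (occ_at(a, d) || occ_at(c, b)) continue;
      occ_at(a, b) = occ_at(b, a) = 0;
      occ_at(c, d) = occ_at(d, c) = 0;
      occ_at(a, d) = occ_at(d, a) = 1;
      occ_at(c, b) = occ_at(b, c) = 1;
      ev[e1] = d;
      ev[e2] = b;
      eu[e2] = c;
    }
  }
  IntegerMatrix out(E, 2);
  for (int k = 0; k < E; ++k) {
    out(k, 0) = eu[k] + 1;
    out(k, 1) = ev[k] + 1;
  }
  return out;
}

// Reassign a weight multiset to a fixed edge topology so node strengths of a
// target network are approximated: repeatedly pick a random unassigned edge,
// rank it by the product of residual endpoint strengths, and give it the
// weight of matching rank among those remaining (weights enter sorted
// descending). Residual strengths are decremented as weights are placed.
// [[Rcpp::export]]
NumericVector assign_null_weights_cpp(IntegerVector ei, IntegerVector ej,
                                      NumericVector strength,
                                      NumericVector w_desc, double seed) {
  int E = ei.size();
  std::vector<double> s(strength.begin(), strength.end());
  std::vector<int> eu(E), ev(E);
  for (int e = 0; e < E; ++e) {
    eu[e] = ei[e] - 1;
    ev[e] = ej[e] - 1;
  }
  std::vector<double> score(E);
  for (int e = 0; e < E; ++e) score[e] = s[eu[e]] * s[ev[e]];
  std::vector<double> wrem(w_desc.begin(), w_desc.end());
  std::vector<int> alive(E);
  for (int e = 0; e < E; ++e) alive[e] = e;
  int n_alive = E;
  NumericVector out(E);
  uint64_t state = (uint64_t)(int64_t)seed;
  splitmix64(state);
  while (n_alive > 0) {
    int p = rand_below(state, n_alive);
    int e = alive[p];
    int r = 0;
    for (int q = 0; q < n_alive; ++q)
      if (score[alive[q]] > score[e]) ++r;
    if (r >= (int)wrem.size()) r = (int)wrem.size() - 1;
    double wv = wrem[r];
    wrem.erase(wrem.begin() + r);
    out[e] = wv;
    alive[p] = alive[n_alive - 1];
    --n_alive;
    int u = eu[e], v = ev[e];
    s[u] -= wv;
    s[v] -= wv;
    for (int q = 0; q < n_alive; ++q) {
      int e2 = alive[q];
      if (eu[e2] == u || ev[e2] == u || eu[e2] == v || ev[e2] == v)
        score[e2] = s[eu[e2]] * s[ev[e2]];
    }
  }
  return out;
}
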