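#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
#include <utility>
using namespace Rcpp;

// Two-level map equation L = q H(Q) + sum_i p_i H(P^i) in its expanded form
//   L = plogp(q) - 2 sum_i plogp(q_i) + sum_i plogp(q_i + S_i)
//       - sum_alpha plogp(p_alpha)
// with q_i the normalized exit weight of module i, S_i its summed visit
// rates and p_alpha the node visit rates (strength / 2W for undirected
// graphs). The greedy optimizer runs Louvain-style passes (node moves,
// module aggregation, repeat) followed by a node-level refinement sweep,
// over n_trials random node orders, keeping the minimum-L partition.

static inline double plogp(double x) {
  return x > 1e-300 ? x * std::log2(x) : 0.0;
}

struct LevelGraph {
  int n = 0;
  std::vector<double> p;  // visit rates per (super)node
  std::vector<std::vector<std::pair<int, double>>> adj;  // normalized w/(2W)
};

static const double EPS = 1e-12;

// one pass of repeated single-node greedy moves; memb holds module ids in
// [0, G.n); returns true when at least one move was accepted
static bool local_moves(const LevelGraph &G, std::vector<int> &memb,
                        std::mt19937 &rng) {
  const int n = G.n;
  std::vector<double> S(n, 0.0), Q(n, 0.0), t(n, 0.0);
  std::vector<int> size(n, 0);
  for (int a = 0; a < n; ++a) {
    S[memb[a]] += G.p[a];
    size[memb[a]] += 1;
    for (auto &e : G.adj[a]) {
      t[a] += e.second;
      if (memb[e.first] != memb[a]) Q[memb[a]] += e.second;
    }
  }
  double sumQ = 0.0;
  for (int m = 0; m < n; ++m) sumQ += Q[m];

  std::vector<int> free_ids;
  {
    std::vector<bool> used(n, false);
    for (int a = 0; a < n; ++a) used[memb[a]] = true;
    for (int m = n - 1; m >= 0; --m)
      if (!used[m]) free_ids.push_back(m);
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::vector<double> dmod(n, 0.0);
  std::vector<int> touched;
  touched.reserve(16);

  bool any_move = false;
  bool moved = true;
  int sweep = 0;
  while (moved && sweep < 200) {
    moved = false;
    ++sweep;
    // Fisher-Yates with the trial RNG: deterministic given the seed
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(rng() % (unsigned)(i + 1));
      std::swap(order[i], order[j]);
    }
    for (int oi = 0; oi < n; ++oi) {
      const int a = order[oi];
      const int A = memb[a];
      const double pa = G.p[a];
      const double ta = t[a];

      touched.clear();
      for (auto &e : G.adj[a]) {
        const int m = memb[e.first];
        if (dmod[m] == 0.0) touched.push_back(m);
        dmod[m] += e.second;
      }
      const double dA = dmod[A];  // links to A \ {a}

      const double qA2 = Q[A] - ta + 2.0 * dA;
      const double remove_gain =
          -2.0 * (plogp(qA2) - plogp(Q[A])) +
          plogp(qA2 + S[A] - pa) - plogp(Q[A] + S[A]);

      double best_delta = 0.0;
      int best_B = -1;
      bool best_new = false;

      auto consider = [&](int B, double dB, double QB, double SB,
                          bool is_new) {
        const double qB2 = QB + ta - 2.0 * dB;
        const double sumQ2 = sumQ - Q[A] - QB + qA2 + qB2;
        const double delta =
            plogp(sumQ2) - plogp(sumQ) + remove_gain -
            2.0 * (plogp(qB2) - plogp(QB)) +
            plogp(qB2 + SB + pa) - plogp(QB + SB);
        if (delta < best_delta - EPS ||
            (delta < best_delta + EPS && best_B >= 0 && !is_new &&
             (best_new || B < best_B))) {
          best_delta = delta;
          best_B = B;
          best_new = is_new;
        }
      };

      for (int m : touched)
        if (m != A) consider(m, dmod[m], Q[m], S[m], false);
      if (size[A] > 1 && !free_ids.empty())
        consider(free_ids.back(), 0.0, 0.0, 0.0, true);

      if (best_B >= 0 && best_delta < -1e-10) {
        const int B = best_B;
        const double dB = best_new ? 0.0 : dmod[B];
        const double qB2 = Q[B] + ta - 2.0 * dB;
        sumQ += (qA2 - Q[A]) + (qB2 - Q[B]);
        Q[A] = qA2;
        Q[B] = qB2;
        S[A] -= pa;
        S[B] += pa;
        size[A] -= 1;
        size[B] += 1;
        memb[a] = B;
        if (best_new) free_ids.pop_back();
        if (size[A] == 0) free_ids.push_back(A);
        moved = true;
        any_move = true;
      }
      for (int m : touched) dmod[m] = 0.0;
    }
  }
  return any_move;
}

// relabel memb to 0..k-1 by first appearance; returns k
static int compact(std::vector<int> &memb) {
  std::vector<int> remap(memb.size(), -1);
  int k = 0;
  for (size_t i = 0; i < memb.size(); ++i) {
    if (remap[memb[i]] < 0) remap[memb[i]] = k++;
    memb[i] = remap[memb[i]];
  }
  return k;
}

static LevelGraph aggregate(const LevelGraph &G, const std::vector<int> &memb,
                            int k) {
  LevelGraph H;
  H.n = k;
  H.p.assign(k, 0.0);
  H.adj.assign(k, {});
  for (int a = 0; a < G.n; ++a) H.p[memb[a]] += G.p[a];
  // accumulate inter-module weights; intra-module weight never crosses a
  // module boundary again, so loops are dropped
  std::vector<std::vector<std::pair<int, double>>> acc(k);
  for (int a = 0; a < G.n; ++a) {
    for (auto &e : G.adj[a]) {
      if (e.first <= a) continue;  // each undirected edge once
      const int ma = memb[a], mb = memb[e.first];
      if (ma == mb) continue;
      acc[std::min(ma, mb)].push_back({std::max(ma, mb), e.second});
    }
  }
  std::vector<double> buf(k, 0.0);
  for (int m = 0; m < k; ++m) {
    std::vector<int> seen;
    for (auto &e : acc[m]) {
      if (buf[e.first] == 0.0) seen.push_back(e.first);
      buf[e.first] += e.second;
    }
    for (int b : seen) {
      H.adj[m].push_back({b, buf[b]});
      H.adj[b].push_back({m, buf[b]});
      buf[b] = 0.0;
    }
  }
  return H;
}

// full two-level codelength of a partition on G, including the constant
// node-visit term
static double codelength(const LevelGraph &G, const std::vector<int> &memb,
                         int k) {
  std::vector<double> S(k, 0.0), Q(k, 0.0);
  for (int a = 0; a < G.n; ++a) {
    S[memb[a]] += G.p[a];
    for (auto &e : G.adj[a])
      if (memb[e.first] != memb[a]) Q[memb[a]] += e.second;
  }
  double sumQ = 0.0, var = 0.0, node_term = 0.0;
  for (int m = 0; m < k; ++m) {
    sumQ += Q[m];
    var += -2.0 * plogp(Q[m]) + plogp(Q[m] + S[m]);
  }
  var += plogp(sumQ);
  for (int a = 0; a < G.n; ++a) node_term -= plogp(G.p[a]);
  return var + node_term;
}

// [[Rcpp::export]]
List optimize_partition_cpp(int n_nodes, IntegerVector from, IntegerVector to,
                            NumericVector weight, int n_trials, int seed) {
  LevelGraph G0;
  G0.n = n_nodes;
  G0.p.assign(n_nodes, 0.0);
  G0.adj.assign(n_nodes, {});
  double W = 0.0;
  for (int e = 0; e < from.size(); ++e) W += weight[e];
  if (W <= 0.0) stop("network must carry positive total edge weight");
  const double inv2W = 1.0 / (2.0 * W);
  for (int e = 0; e < from.size(); ++e) {
    const int a = from[e], b = to[e];
    const double w = weight[e] * inv2W;
    G0.adj[a].push_back({b, w});
    G0.adj[b].push_back({a, w});
    G0.p[a] += w;
    G0.p[b] += w;
  }

  std::vector<int> best;
  double best_L = R_PosInf;

  for (int trial = 0; trial < n_trials; ++trial) {
    std::mt19937 rng((unsigned)seed * 2654435761u + (unsigned)trial);
    std::vector<int> assign(n_nodes);
    for (int i = 0; i < n_nodes; ++i) assign[i] = i;

    LevelGraph G = G0;
    while (true) {
      std::vector<int> memb(G.n);
      for (int i = 0; i < G.n; ++i) memb[i] = i;
      local_moves(G, memb, rng);
      const int k = compact(memb);
      if (k == G.n) break;  // nothing merged at this level
      for (int i = 0; i < n_nodes; ++i) assign[i] = memb[assign[i]];
      if (k == 1) break;
      G = aggregate(G, memb, k);
    }

    compact(assign);
    local_moves(G0, assign, rng);  // node-level refinement
    const int k = compact(assign);
    const double L = codelength(G0, assign, k);
    if (L < best_L - EPS) {
      best_L = L;
      best = assign;
    }
  }

  // the trivial one-module partition is always a member of the search space
  {
    std::vector<int> one(n_nodes, 0);
    const double L1 = codelength(G0, one, 1);
    if (L1 < best_L - EPS) {
      best_L = L1;
      best = one;
    }
  }

  return List::create(_["membership"] = wrap(best),
                      _["codelength"] = best_L);
}
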