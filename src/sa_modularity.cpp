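#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Simulated-annealing maximisation of Newman-Girvan modularity
//   Q = sum_s [ e_s/m - (d_s/(2m))^2 ]
// on an unweighted undirected simple graph. Proposals are single-node
// moves (to a random neighbour's module or to a fresh singleton module)
// with periodic whole-module merges; geometric cooling; a greedy
// local-move polish runs after annealing until no move improves Q.
// Uses R's RNG so results are reproducible under set.seed().

static double move_delta(int i, int a, int b,
                         const std::vector<std::vector<int>> &adj,
                         const std::vector<int> &membership,
                         const std::vector<double> &mod_deg,
                         double m) {
  // delta Q for moving node i from module a to module b (a != b)
  double kia = 0.0, kib = 0.0;
  for (int j : adj[i]) {
    if (membership[j] == a) kia += 1.0;
    else if (membership[j] == b) kib += 1.0;
  }
  double ki = (double)adj[i].size();
  return (kib - kia) / m -
         ki * (mod_deg[b] - mod_deg[a] + ki) / (2.0 * m * m);
}

// [[Rcpp::export(rng = true)]]
IntegerVector sa_partition_cpp(int n, IntegerVector from, IntegerVector to,
                               double t0, double cooling, double n_steps) {
  int m_edges = from.size();
  std::vector<std::vector<int>> adj(n);
  for (int e = 0; e < m_edges; ++e) {
    adj[from[e]].push_back(to[e]);
    adj[to[e]].push_back(from[e]);
  }
  std::vector<int> membership(n);
  std::vector<double> mod_deg(n, 0.0);   // sum of degrees per module
  std::vector<int> mod_size(n, 1);
  for (int i = 0; i < n; ++i) {
    membership[i] = i;
    mod_deg[i] = (double)adj[i].size();
  }
  if (m_edges == 0) {
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) out[i] = i + 1;
    return out;
  }
  double m = (double)m_edges;
  double T = t0;
  long long steps = (long long)n_steps;

  for (long long s = 0; s < steps; ++s) {
    int i = (int)(R::unif_rand() * n);
    if (i >= n) i = n - 1;
    if (adj[i].empty()) continue;
    int a = membership[i];
    int b;
    if (R::unif_rand() < 0.05 && mod_size[a] > 1) {
      // fresh singleton module: reuse any currently empty label
      b = -1;
      for (int c = 0; c < n; ++c) {
        if (mod_size[c] == 0) { b = c; break; }
      }
      if (b < 0) continue;
    } else {
      int j = adj[i][(int)(R::unif_rand() * adj[i].size())];
      b = membership[j];
    }
    if (b == a) continue;
    double dq = move_delta(i, a, b, adj, membership, mod_deg, m);
    if (dq > 0 || R::unif_rand() < std::exp(dq / T)) {
      membership[i] = b;
      double ki = (double)adj[i].size();
      mod_deg[a] -= ki; mod_deg[b] += ki;
      mod_size[a] -= 1; mod_size[b] += 1;
    }
    if ((s + 1) % n == 0) {
      // merge proposal: collapse the two modules joined by a random edge
      int e = (int)(R::unif_rand() * m_edges);
      int ma = membership[from[e]], mb = membership[to[e]];
      if (ma != mb) {
        double eab = 0.0;
        for (int v = 0; v < n; ++v) {
          if (membership[v] != ma) continue;
          for (int w : adj[v]) if (membership[w] == mb) eab += 1.0;
        }
        double dqm = eab / m - mod_deg[ma] * mod_deg[mb] / (2.0 * m * m);
        if (dqm > 0 || R::unif_rand() < std::exp(dqm / T)) {
          for (int v = 0; v < n; ++v)
            if (membership[v] == ma) membership[v] = mb;
          mod_deg[mb] += mod_deg[ma]; mod_deg[ma] = 0.0;
          mod_size[mb] += mod_size[ma]; mod_size[ma] = 0;
        }
      }
      T *= cooling;
      if (T < 1e-8) T = 1e-8;
    }
  }

  // greedy polish: best single-node moves until a local optimum
  bool improved = true;
  int passes = 0;
  while (improved && passes < 100) {
    improved = false;
    ++passes;
    for (int i = 0; i < n; ++i) {
      if (adj[i].empty()) continue;
      int a = membership[i];
      int best_b = a;
      double best_dq = 1e-12;
      for (size_t t = 0; t < adj[i].size(); ++t) {
        int b = membership[adj[i][t]];
        if (b == a) continue;
        double dq = move_delta(i, a, b, adj, membership, mod_deg, m);
        if (dq > best_dq) { best_dq = dq; best_b = b; }
      }
      if (best_b != a) {
        double ki = (double)adj[i].size();
        membership[i] = best_b;
        mod_deg[a] -= ki; mod_deg[best_b] += ki;
        mod_size[a] -= 1; mod_size[best_b] += 1;
        improved = true;
      }
    }
  }

  // compact labels to 1..k in order of first appearance
  std::vector<int> relabel(n, 0);
  int next = 0;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    int lab = membership[i];
    if (relabel[lab] == 0) relabel[lab] = ++next;
    out[i] = relabel[lab];
  }
  return out;
}
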