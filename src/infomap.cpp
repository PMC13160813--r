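// Two-level map-equation community detection (Infomap-style greedy).
//
// Undirected, weighted formulation with edge-weight-proportional flow and
// no teleportation: node visit rates p_a = strength_a / total_strength,
// module exit rates q_i = (boundary-crossing weight of module i) /
// total_strength. The two-level map equation in its plogp expansion is
//
//   L = plogp(sum_i q_i) - 2 sum_i plogp(q_i)
//       + sum_i plogp(q_i + sum_{a in i} p_a) - sum_a plogp(p_a)
//
// The greedy optimizer repeats (a) local moving: visit nodes in random
// order, move each to the neighboring module giving the largest codelength
// decrease; (b) aggregation: collapse modules into supernodes and recurse,
// until no move lowers the codelength. Randomness comes from R's RNG so
// results are reproducible under set.seed()/withr::with_seed().

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double plogp(double x) {
  return x > 0.0 ? x * std::log2(x) : 0.0;
}

struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj; // no self loops
  std::vector<double> selfw;    // self-loop weight (counts twice in strength)
  std::vector<double> strength; // sum_j w_ij + 2*selfw_i
  double total;                 // sum of strengths = 2W
};

struct Partition {
  std::vector<int> module_of;   // node -> module id (0-based, may be sparse)
  std::vector<double> mod_p;    // sum of node visit rates per module
  std::vector<double> mod_q;    // exit rate per module
  double sum_q;
  double codelength;
  double node_term;             // -sum_a plogp(p_a), constant per graph
};

static double full_codelength(const Graph& g, const Partition& pt) {
  double sq = 0.0, t2 = 0.0, t3 = 0.0;
  for (size_t i = 0; i < pt.mod_q.size(); ++i) {
    if (pt.mod_p[i] <= 0.0 && pt.mod_q[i] <= 0.0) continue;
    sq += pt.mod_q[i];
    t2 += plogp(pt.mod_q[i]);
    t3 += plogp(pt.mod_q[i] + pt.mod_p[i]);
  }
  return plogp(sq) - 2.0 * t2 + t3 + pt.node_term;
}

// initialize singleton partition
static Partition init_partition(const Graph& g) {
  Partition pt;
  pt.module_of.resize(g.n);
  pt.mod_p.assign(g.n, 0.0);
  pt.mod_q.assign(g.n, 0.0);
  pt.node_term = 0.0;
  for (int a = 0; a < g.n; ++a) {
    pt.module_of[a] = a;
    double p = g.strength[a] / g.total;
    pt.mod_p[a] = p;
    // exit = all non-self weight
    double kout = (g.strength[a] - 2.0 * g.selfw[a]) / g.total;
    pt.mod_q[a] = kout;
    pt.node_term -= plogp(p);
  }
  pt.sum_q = 0.0;
  for (int a = 0; a < g.n; ++a) pt.sum_q += pt.mod_q[a];
  pt.codelength = full_codelength(g, pt);
  return pt;
}

// Fisher-Yates shuffle driven by R's RNG
static void shuffle_order(std::vector<int>& v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// One round of local moving; returns number of accepted moves. If `trace`
// is non-null, the codelength after each accepted move (plus `adjust`,
// which maps a level's node term back to the original graph's) is
// appended.
static int local_moving(const Graph& g, Partition& pt,
                        std::vector<double>* trace, double adjust) {
  int n_moves = 0;
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;
  std::vector<double> w_to(g.n, 0.0); // weight from node to module
  std::vector<int> touched;

  bool improved = true;
  while (improved) {
    improved = false;
    shuffle_order(order);
    for (int oi = 0; oi < g.n; ++oi) {
      int a = order[oi];
      int ma = pt.module_of[a];
      double p_a = g.strength[a] / g.total;
      double k_noself = (g.strength[a] - 2.0 * g.selfw[a]) / g.total;

      touched.clear();
      for (size_t e = 0; e < g.adj[a].size(); ++e) {
        int b = g.adj[a][e].first;
        int mb = pt.module_of[b];
        if (w_to[mb] == 0.0) touched.push_back(mb);
        w_to[mb] += g.adj[a][e].second / g.total;
      }

      double wA = w_to[ma]; // weight to own module (excluding self)
      // removal deltas for module A
      double qA = pt.mod_q[ma], pA = pt.mod_p[ma];
      double qA2 = qA - (k_noself - 2.0 * wA);
      double pA2 = pA - p_a;
      if (qA2 < 0) qA2 = 0;

      double best_delta = -1e-12;
      int best_m = ma;
      double best_qB2 = 0, best_pB2 = 0, best_sq2 = 0;

      for (size_t t = 0; t < touched.size(); ++t) {
        int mb = touched[t];
        if (mb == ma) continue;
        double wB = w_to[mb];
        double qB = pt.mod_q[mb], pB = pt.mod_p[mb];
        double qB2 = qB + (k_noself - 2.0 * wB);
        double pB2 = pB + p_a;
        if (qB2 < 0) qB2 = 0;
        double sq2 = pt.sum_q + (qA2 - qA) + (qB2 - qB);
        double delta =
          (plogp(sq2) - plogp(pt.sum_q))
          - 2.0 * (plogp(qA2) - plogp(qA) + plogp(qB2) - plogp(qB))
          + (plogp(qA2 + pA2) - plogp(qA + pA))
          + (plogp(qB2 + pB2) - plogp(qB + pB));
        if (delta < best_delta) {
          best_delta = delta;
          best_m = mb;
          best_qB2 = qB2; best_pB2 = pB2; best_sq2 = sq2;
        }
      }

      if (best_m != ma) {
        pt.module_of[a] = best_m;
        pt.mod_q[ma] = qA2; pt.mod_p[ma] = pA2;
        pt.mod_q[best_m] = best_qB2; pt.mod_p[best_m] = best_pB2;
        pt.sum_q = best_sq2;
        pt.codelength += best_delta;
        ++n_moves;
        improved = true;
        if (trace) trace->push_back(pt.codelength + adjust);
      }

      for (size_t t = 0; t < touched.size(); ++t) w_to[touched[t]] = 0.0;
    }
  }
  return n_moves;
}

// collapse modules into supernodes; returns the aggregated graph and
// writes node -> supernode mapping (compact 0-based ids) into `map`
static Graph aggregate(const Graph& g, const std::vector<int>& module_of,
                       std::vector<int>& map) {
  int n = g.n;
  map.assign(n, -1);
  int next_id = 0;
  // compact module ids in order of first appearance
  std::vector<int> compact(n, -1);
  for (int a = 0; a < n; ++a) {
    int m = module_of[a];
    if (compact[m] < 0) compact[m] = next_id++;
    map[a] = compact[m];
  }
  Graph h;
  h.n = next_id;
  h.adj.assign(next_id, std::vector<std::pair<int, double> >());
  h.selfw.assign(next_id, 0.0);
  h.strength.assign(next_id, 0.0);
  h.total = g.total;
  // accumulate supernode-pair weights
  std::vector<std::vector<std::pair<int, double> > > acc(next_id);
  for (int a = 0; a < n; ++a) {
    int ma = map[a];
    h.selfw[ma] += g.selfw[a];
    for (size_t e = 0; e < g.adj[a].size(); ++e) {
      int b = g.adj[a][e].first;
      if (b < a) continue; // each undirected edge once
      int mb = map[b];
      double w = g.adj[a][e].second;
      if (ma == mb) {
        // internal edge of weight w becomes self-loop weight w: self-loops
        // count twice in strength, preserving the members' summed strength
        h.selfw[ma] += w;
      } else {
        int lo = ma < mb ? ma : mb, hi = ma < mb ? mb : ma;
        acc[lo].push_back(std::make_pair(hi, w));
      }
    }
  }
  // merge duplicate supernode pairs
  for (int m = 0; m < next_id; ++m) {
    std::vector<std::pair<int, double> >& v = acc[m];
    if (v.empty()) continue;
    std::sort(v.begin(), v.end());
    int k = 0;
    for (size_t i = 1; i < v.size(); ++i) {
      if (v[i].first == v[k].first) v[k].second += v[i].second;
      else v[++k] = v[i];
    }
    v.resize(k + 1);
    for (size_t i = 0; i < v.size(); ++i) {
      h.adj[m].push_back(v[i]);
      h.adj[v[i].first].push_back(std::make_pair(m, v[i].second));
    }
  }
  for (int m = 0; m < next_id; ++m) {
    double s = 2.0 * h.selfw[m];
    for (size_t e = 0; e < h.adj[m].size(); ++e) s += h.adj[m][e].second;
    h.strength[m] = s;
  }
  return h;
}

// [[Rcpp::export(name = ".infomap_greedy")]]
List infomap_greedy(int n_nodes, IntegerVector ei, IntegerVector ej,
                    NumericVector ew, bool record_trace = false) {
  if (n_nodes < 1) stop("empty graph");
  Graph g;
  g.n = n_nodes;
  g.adj.assign(n_nodes, std::vector<std::pair<int, double> >());
  g.selfw.assign(n_nodes, 0.0);
  g.strength.assign(n_nodes, 0.0);
  for (int e = 0; e < ei.size(); ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    double w = ew[e];
    if (a < 0 || a >= n_nodes || b < 0 || b >= n_nodes)
      stop("edge index out of range");
    if (w <= 0) stop("edge weights must be positive");
    if (a == b) { g.selfw[a] += w; continue; }
    g.adj[a].push_back(std::make_pair(b, w));
    g.adj[b].push_back(std::make_pair(a, w));
  }
  g.total = 0.0;
  for (int a = 0; a < n_nodes; ++a) {
    double s = 2.0 * g.selfw[a];
    for (size_t e = 0; e < g.adj[a].size(); ++e) s += g.adj[a][e].second;
    g.strength[a] = s;
    g.total += s;
  }
  if (g.total <= 0) stop("graph has no edges");

  std::vector<double> trace;
  std::vector<double>* tp = record_trace ? &trace : 0;

  // membership of original nodes through all aggregation levels
  std::vector<int> membership(n_nodes);
  for (int a = 0; a < n_nodes; ++a) membership[a] = a;

  // within-module entropy uses the ORIGINAL node visit rates at every
  // aggregation level; each level's singleton node term is swapped for it
  double node_term_orig = 0.0;
  for (int a = 0; a < n_nodes; ++a)
    node_term_orig -= plogp(g.strength[a] / g.total);

  Graph cur = g;
  double codelength = 0.0;
  while (true) {
    Partition pt = init_partition(cur);
    double adjust = node_term_orig - pt.node_term;
    int moves = local_moving(cur, pt, tp, adjust);
    codelength = pt.codelength + adjust;
    if (moves == 0) break;
    std::vector<int> map;
    Graph nxt = aggregate(cur, pt.module_of, map);
    for (int a = 0; a < n_nodes; ++a)
      membership[a] = map[membership[a]];
    if (nxt.n == cur.n) break;
    cur = nxt;
  }

  // compact final labels to 1..K in order of first appearance
  std::vector<int> compact(n_nodes, -1);
  int next_id = 0;
  IntegerVector out(n_nodes);
  for (int a = 0; a < n_nodes; ++a) {
    int m = membership[a];
    if (compact[m] < 0) compact[m] = ++next_id;
    out[a] = compact[m];
  }

  List res = List::create(
    Named("membership") = out,
    Named("codelength") = codelength,
    Named("n_communities") = next_id);
  if (record_trace)
    res["trace"] = NumericVector(trace.begin(), trace.end());
  return res;
}
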