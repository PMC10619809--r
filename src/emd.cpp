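// Exact earth mover's distance via min-cost flow (successive shortest
// paths with Johnson potentials). Problems here are tiny (<= 64 x 64
// after support trimming), so a dense Dijkstra is ample.
#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

namespace {

const double EPS = 1e-12;

struct Edge { int to; double cap, cost; int rev; };

class MCMF {
public:
  explicit MCMF(int n) : n_(n), g_(n) {}
  void add_edge(int u, int v, double cap, double cost) {
    g_[u].push_back({v, cap, cost, (int)g_[v].size()});
    g_[v].push_back({u, 0.0, -cost, (int)g_[u].size() - 1});
  }
  // min-cost flow from s to t, pushing as much as possible
  double run(int s, int t) {
    double total_cost = 0.0;
    std::vector<double> pot(n_, 0.0); // costs nonneg -> zero init valid
    while (true) {
      std::vector<double> dist(n_, std::numeric_limits<double>::infinity());
      std::vector<int> pv(n_, -1), pe(n_, -1);
      std::vector<bool> done(n_, false);
      dist[s] = 0.0;
      for (int it = 0; it < n_; ++it) { // dense Dijkstra
        int u = -1; double best = std::numeric_limits<double>::infinity();
        for (int v = 0; v < n_; ++v)
          if (!done[v] && dist[v] < best) { best = dist[v]; u = v; }
        if (u < 0) break;
        done[u] = true;
        for (size_t ei = 0; ei < g_[u].size(); ++ei) {
          const Edge &e = g_[u][ei];
          if (e.cap <= EPS) continue;
          double nd = dist[u] + e.cost + pot[u] - pot[e.to];
          if (nd < dist[e.to] - EPS) {
            dist[e.to] = nd; pv[e.to] = u; pe[e.to] = (int)ei;
          }
        }
      }
      if (!done[t]) break; // no augmenting path left
      for (int v = 0; v < n_; ++v)
        if (done[v]) pot[v] += dist[v];
      double push = std::numeric_limits<double>::infinity();
      for (int v = t; v != s; v = pv[v])
        push = std::min(push, g_[pv[v]][pe[v]].cap);
      if (push <= EPS) break;
      for (int v = t; v != s; v = pv[v]) {
        Edge &e = g_[pv[v]][pe[v]];
        e.cap -= push;
        g_[v][e.rev].cap += push;
        total_cost += push * e.cost;
      }
    }
    return total_cost;
  }
private:
  int n_;
  std::vector<std::vector<Edge>> g_;
};

double transport(const std::vector<double> &a, const std::vector<double> &b,
                 const std::vector<std::vector<double>> &cost) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  MCMF net(n + m + 2);
  int S = n + m, T = n + m + 1;
  for (int i = 0; i < n; ++i) net.add_edge(S, i, a[i], 0.0);
  for (int j = 0; j < m; ++j) net.add_edge(n + j, T, b[j], 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      net.add_edge(i, n + j, std::numeric_limits<double>::infinity(),
                   cost[i][j]);
  return net.run(S, T);
}

inline int hamming(unsigned x, unsigned y) {
  unsigned v = x ^ y; int c = 0;
  while (v) { c += v & 1u; v >>= 1; }
  return c;
}

} // namespace

// EMD between two distributions over binary states of n_nodes nodes,
// with Hamming ground distance. Only the signed difference needs to be
// transported, so the problem is trimmed to the states where p > q
// (sources) and p < q (sinks).
// [[Rcpp::export]]
double emd_hamming_cpp(NumericVector p, NumericVector q, int n_nodes) {
  int len = p.size();
  if (q.size() != len) stop("distributions differ in length");
  std::vector<double> a, b;
  std::vector<unsigned> ai, bi;
  for (int s = 0; s < len; ++s) {
    double d = p[s] - q[s];
    if (d > EPS) { a.push_back(d); ai.push_back((unsigned)s); }
    else if (d < -EPS) { b.push_back(-d); bi.push_back((unsigned)s); }
  }
  if (a.empty()) return 0.0;
  std::vector<std::vector<double>> cost(a.size(),
                                        std::vector<double>(b.size()));
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      cost[i][j] = (double)hamming(ai[i], bi[j]);
  return transport(a, b, cost);
}

// General transportation distance between weighted point sets with an
// explicit ground-cost matrix (used for the extended EMD between
// conceptual structures). Supplies and demands must have equal totals.
// [[Rcpp::export]]
double emd_flow_cpp(NumericVector supply, NumericVector demand,
                    NumericMatrix cost) {
  if (cost.nrow() != supply.size() || cost.ncol() != demand.size())
    stop("cost matrix dimensions do not match supply/demand");
  double sa = 0.0, sb = 0.0;
  for (double v : supply) sa += v;
  for (double v : demand) sb += v;
  if (std::abs(sa - sb) > 1e-9) stop("supply and demand totals differ");
  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  std::vector<std::vector<double>> c(a.size(), std::vector<double>(b.size()));
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      c[i][j] = cost(i, j);
  return transport(a, b, c);
}
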