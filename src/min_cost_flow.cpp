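// Successive-shortest-path minimum-cost flow with Dijkstra and node
// potentials (all arc costs are non-negative integers). Each augmentation
// pushes one unit along a cheapest source-sink path, so after the final
// augmentation the flow is simultaneously of maximum value and of minimum
// cost among flows of that value -- exactly the lexicographic
// (pair count, then cost) objective the matcher needs. Fine-balance and
// distance priorities are encoded in the arc costs on the R side.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>

using namespace Rcpp;

struct Arc {
  int to;
  int cap;
  long long cost;
};

// [[Rcpp::export]]
List mcf_solve(int n_nodes, IntegerVector from, IntegerVector to,
               IntegerVector cap, NumericVector cost, int source, int sink) {
  const int m = from.size();
  std::vector<Arc> arcs;
  arcs.reserve(2 * m);
  std::vector<std::vector<int>> adj(n_nodes);
  for (int e = 0; e < m; ++e) {
    adj[from[e]].push_back(arcs.size());
    arcs.push_back({to[e], cap[e], (long long)cost[e]});
    adj[to[e]].push_back(arcs.size());
    arcs.push_back({from[e], 0, -(long long)cost[e]});
  }

  const long long INF = std::numeric_limits<long long>::max() / 4;
  std::vector<long long> pot(n_nodes, 0), dist(n_nodes);
  std::vector<int> prev_arc(n_nodes);
  std::vector<char> done(n_nodes);
  typedef std::pair<long long, int> QN;

  long long total_flow = 0, total_cost = 0;
  for (;;) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    dist[source] = 0;
    std::priority_queue<QN, std::vector<QN>, std::greater<QN>> pq;
    pq.push({0, source});
    while (!pq.empty()) {
      QN top = pq.top(); pq.pop();
      int v = top.second;
      if (done[v]) continue;
      done[v] = 1;
      if (v == sink) break;  // potentials of unsettled nodes handled below
      for (int ei : adj[v]) {
        const Arc &a = arcs[ei];
        if (a.cap <= 0 || done[a.to]) continue;
        long long nd = dist[v] + a.cost + pot[v] - pot[a.to];
        if (nd < dist[a.to]) {
          dist[a.to] = nd;
          prev_arc[a.to] = ei;
          pq.push({nd, a.to});
        }
      }
    }
    if (!done[sink]) break;
    long long ds = dist[sink];
    for (int v = 0; v < n_nodes; ++v)
      pot[v] += std::min(dist[v], ds);  // keeps reduced costs non-negative

    // bottleneck (treated->control arcs have unit capacity, so this is 1,
    // but category->sink arcs are aggregated)
    int push = std::numeric_limits<int>::max();
    for (int v = sink; v != source; ) {
      const Arc &a = arcs[prev_arc[v]];
      push = std::min(push, a.cap);
      v = arcs[prev_arc[v] ^ 1].to;
    }
    for (int v = sink; v != source; ) {
      int ei = prev_arc[v];
      arcs[ei].cap -= push;
      arcs[ei ^ 1].cap += push;
      total_cost += (long long)push * arcs[ei].cost;
      v = arcs[ei ^ 1].to;
    }
    total_flow += push;
  }

  IntegerVector flow(m);
  for (int e = 0; e < m; ++e) flow[e] = arcs[2 * e + 1].cap;
  return List::create(_["flow"] = flow,
                      _["value"] = (double)total_flow,
                      _["cost"] = (double)total_cost);
}
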