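// Min-cut solver for the GrabCut graph: Dinic's max-flow on an undirected
// capacitated graph. Grid graphs with two terminals are small (one node per
// pixel) but igraph-style push-relabel is slow on them; a blocking-flow
// solver runs in well under a second at the image sizes used here.

#include <Rcpp.h>
#include <vector>
#include <queue>

using namespace Rcpp;

namespace {

struct Arc {
  int to;
  double cap;
  int rev;
};

const double EPS = 1e-11;

}  // namespace

// Returns a logical vector over nodes 1..n: TRUE when the node sits on the
// source side of a minimum cut (i.e. remains reachable from the source in
// the residual graph). Edges are undirected: capacity applies both ways.
// [[Rcpp::export(name = ".dinicMinCut")]]
LogicalVector dinicMinCut(IntegerVector from, IntegerVector to,
                          NumericVector cap, int n, int src, int snk) {
  std::vector< std::vector<Arc> > g(n);
  const int m = from.size();
  for (int e = 0; e < m; ++e) {
    int u = from[e] - 1, v = to[e] - 1;
    double c = cap[e];
    if (u < 0 || v < 0 || u >= n || v >= n)
      stop("edge endpoint out of range");
    Arc a = {v, c, (int)g[v].size()};
    Arc b = {u, c, (int)g[u].size()};
    g[u].push_back(a);
    g[v].push_back(b);
  }
  --src; --snk;

  std::vector<int> level(n), it(n);
  std::queue<int> q;

  auto bfs = [&]() -> bool {
    std::fill(level.begin(), level.end(), -1);
    while (!q.empty()) q.pop();
    q.push(src);
    level[src] = 0;
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (size_t k = 0; k < g[u].size(); ++k) {
        const Arc &a = g[u][k];
        if (a.cap > EPS && level[a.to] < 0) {
          level[a.to] = level[u] + 1;
          q.push(a.to);
        }
      }
    }
    return level[snk] >= 0;
  };

  // iterative blocking-flow DFS (explicit stack: path of (node, arc index))
  std::vector<int> pathNode, pathArc;
  while (bfs()) {
    std::fill(it.begin(), it.end(), 0);
    pathNode.clear(); pathArc.clear();
    int cur = src;
    for (;;) {
      if (cur == snk) {
        double bottleneck = R_PosInf;
        for (size_t k = 0; k < pathNode.size(); ++k) {
          const Arc &a = g[pathNode[k]][pathArc[k]];
          if (a.cap < bottleneck) bottleneck = a.cap;
        }
        int retreat = 0;
        for (size_t k = 0; k < pathNode.size(); ++k) {
          Arc &a = g[pathNode[k]][pathArc[k]];
          a.cap -= bottleneck;
          g[a.to][a.rev].cap += bottleneck;
          if (a.cap <= EPS && (int)k < (int)pathNode.size())
            if (retreat == 0) retreat = (int)k + 1;
        }
        if (retreat == 0) retreat = (int)pathNode.size();
        // pop back to the first saturated arc
        while ((int)pathNode.size() >= retreat && !pathNode.empty()) {
          cur = pathNode.back();
          pathNode.pop_back();
          pathArc.pop_back();
        }
        continue;
      }
      bool advanced = false;
      for (; it[cur] < (int)g[cur].size(); ++it[cur]) {
        const Arc &a = g[cur][it[cur]];
        if (a.cap > EPS && level[a.to] == level[cur] + 1) {
          pathNode.push_back(cur);
          pathArc.push_back(it[cur]);
          cur = a.to;
          advanced = true;
          break;
        }
      }
      if (!advanced) {
        level[cur] = -1;  // dead end in this phase
        if (pathNode.empty()) break;
        cur = pathNode.back();
        pathNode.pop_back();
        pathArc.pop_back();
        ++it[cur];
      }
    }
  }

  // residual reachability from the source = source side of the min cut
  LogicalVector side(n);
  std::vector<char> seen(n, 0);
  while (!q.empty()) q.pop();
  q.push(src);
  seen[src] = 1;
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (size_t k = 0; k < g[u].size(); ++k) {
      const Arc &a = g[u][k];
      if (a.cap > EPS && !seen[a.to]) {
        seen[a.to] = 1;
        q.push(a.to);
      }
    }
  }
  for (int v = 0; v < n; ++v) side[v] = seen[v] != 0;
  return side;
}
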