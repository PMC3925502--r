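#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
using namespace Rcpp;

// Dinic's max-flow on an s-t network, used for exact MAP inference of
// submodular pairwise binary energies. Nodes 0..n-1 are voxels, n is the
// source, n+1 the sink. Arcs are stored with explicit reverse arcs.
// Determinism: arcs are inserted in the caller's order and BFS/DFS visit
// them in insertion order, so the min-cut partition is reproducible.

namespace {

struct Arc {
  int to;
  int rev;        // index of reverse arc in adj[to]
  double cap;
};

class Dinic {
public:
  explicit Dinic(int n) : adj(n), level(n), iter(n) {}

  void addArc(int from, int to, double cap, double rcap) {
    Arc a{to, (int)adj[to].size(), cap};
    Arc b{from, (int)adj[from].size(), rcap};
    adj[from].push_back(a);
    adj[to].push_back(b);
  }

  double run(int s, int t) {
    double flow = 0.0;
    while (bfs(s, t)) {
      std::fill(iter.begin(), iter.end(), 0);
      double f;
      while ((f = dfs(s, t, std::numeric_limits<double>::infinity())) > eps)
        flow += f;
    }
    return flow;
  }

  // After run(): nodes reachable from s in the residual graph.
  std::vector<bool> sourceSide(int s) const {
    std::vector<bool> vis(adj.size(), false);
    std::queue<int> q;
    vis[s] = true; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (const Arc &a : adj[u]) {
        if (a.cap > eps && !vis[a.to]) { vis[a.to] = true; q.push(a.to); }
      }
    }
    return vis;
  }

private:
  static constexpr double eps = 1e-11;
  std::vector<std::vector<Arc> > adj;
  std::vector<int> level, iter;

  bool bfs(int s, int t) {
    std::fill(level.begin(), level.end(), -1);
    std::queue<int> q;
    level[s] = 0; q.push(s);
    while (!q.empty()) {
      int u = q.front(); q.pop();
      for (const Arc &a : adj[u]) {
        if (a.cap > eps && level[a.to] < 0) {
          level[a.to] = level[u] + 1;
          q.push(a.to);
        }
      }
    }
    return level[t] >= 0;
  }

  double dfs(int u, int t, double f) {
    if (u == t) return f;
    for (int &i = iter[u]; i < (int)adj[u].size(); ++i) {
      Arc &a = adj[u][i];
      if (a.cap > eps && level[a.to] == level[u] + 1) {
        double d = dfs(a.to, t, std::min(f, a.cap));
        if (d > eps) {
          a.cap -= d;
          adj[a.to][a.rev].cap += d;
          return d;
        }
      }
    }
    return 0.0;
  }
};

} // namespace

// Solve min_x sum_i theta_i(x_i) + sum_e E_e(x_i, x_j) for binary labels
// (columns of `unary`: cost of label -1, cost of label +1; `edgeCosts`
// columns: E(-,-), E(-,+), E(+,-), E(+,+)).  Requires submodularity
// E(-,+) + E(+,-) >= E(-,-) + E(+,+) on every edge.  Returns the label
// vector in {-1, +1} (label +1 <=> node on the source side) and the flow.
// [[Rcpp::export(name = ".maxflowSolve")]]
List maxflowSolve(NumericMatrix unary, IntegerMatrix edges,
                  NumericMatrix edgeCosts) {
  const int n = unary.nrow();
  const int ne = edges.nrow();
  const int S = n, T = n + 1;
  Dinic net(n + 2);

  // Per-node net cost of label +1 after Kolmogorov-Zabih reparameterisation.
  std::vector<double> thetaPos(n), thetaNeg(n);
  for (int i = 0; i < n; ++i) {
    thetaNeg[i] = unary(i, 0);
    thetaPos[i] = unary(i, 1);
  }
  // n-links; fold pairwise tables into unaries + one directed arc per edge.
  std::vector<double> lambda(ne);
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double A = edgeCosts(e, 0), B = edgeCosts(e, 1),
           C = edgeCosts(e, 2), D = edgeCosts(e, 3);
    double lam = B + C - A - D;
    if (lam < -1e-9)
      stop("non-submodular edge table (E(-,+)+E(+,-) < E(-,-)+E(+,+))");
    if (lam < 0) lam = 0;
    // E = A + (D-B)[x_i=+] + (B-A)[x_j=+] + lam [x_i=+][x_j=-]
    thetaPos[i] += D - B;
    thetaPos[j] += B - A;
    lambda[e] = lam;
  }
  // t-links: shift each node's pair so both capacities are non-negative.
  for (int i = 0; i < n; ++i) {
    double m = std::min(thetaNeg[i], thetaPos[i]);
    // label +1 <=> source side <=> arc i->T cut, paying thetaPos
    net.addArc(S, i, thetaNeg[i] - m, 0.0);
    net.addArc(i, T, thetaPos[i] - m, 0.0);
  }
  // term lam * [x_i = +1][x_j = -1]: arc i->j cut when i in S, j in T
  for (int e = 0; e < ne; ++e) {
    int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    net.addArc(i, j, lambda[e], 0.0);
  }

  double flow = net.run(S, T);
  std::vector<bool> src = net.sourceSide(S);
  IntegerVector labels(n);
  for (int i = 0; i < n; ++i) labels[i] = src[i] ? 1 : -1;
  return List::create(_["labels"] = labels, _["flow"] = flow);
}
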