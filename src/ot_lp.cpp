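#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Exact solver for the balanced transportation linear program
//
//   min  sum_ij C[i,j] * G[i,j]
//   s.t. rowSums(G) = a,  colSums(G) = b,  G >= 0
//
// via the transportation simplex (MODI / u-v method).  The basis is a
// spanning tree of the bipartite graph over rows and columns; callers must
// pass strictly positive a and b with equal totals (zero-mass atoms are
// stripped in the R wrapper).  The initial basic solution is a greedy
// minimum-cost allocation completed to a spanning tree by union-find.
// Anti-cycling: after a run of degenerate pivots the entering rule switches
// from Dantzig to Bland.

static const double EPS_RED = 1e-11;   // reduced-cost optimality tolerance
static const double EPS_FLOW = 1e-15;  // flows below this are treated as 0

struct UnionFind {
  std::vector<int> up;
  explicit UnionFind(int n) : up(n) { for (int i = 0; i < n; ++i) up[i] = i; }
  int find(int x) { while (up[x] != x) x = up[x] = up[up[x]]; return x; }
  bool unite(int x, int y) {
    x = find(x); y = find(y);
    if (x == y) return false;
    up[x] = y; return true;
  }
};

// [[Rcpp::export]]
List ot_lp_cpp(NumericVector a, NumericVector b, NumericMatrix C,
               int max_iter = 0) {
  const int m = a.size(), n = b.size();
  if (C.nrow() != m || C.ncol() != n)
    stop("cost matrix dimensions do not match the marginals");
  if (max_iter <= 0) max_iter = 2000 * (m + n) + 10000;
  const int N = m + n;  // tree nodes: 0..m-1 rows, m..m+n-1 columns

  std::vector<double> cost(static_cast<size_t>(m) * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < m; ++i) cost[static_cast<size_t>(i) * n + j] = C(i, j);

  std::vector<double> F(static_cast<size_t>(m) * n, 0.0);
  std::vector<char> basic(static_cast<size_t>(m) * n, 0);
  std::vector<std::vector<int>> adj(N);  // basis tree adjacency

  // ---- greedy minimum-cost initial solution ------------------------------
  {
    std::vector<int> order(static_cast<size_t>(m) * n);
    for (size_t t = 0; t < order.size(); ++t) order[t] = static_cast<int>(t);
    std::sort(order.begin(), order.end(),
              [&](int x, int y) { return cost[x] < cost[y]; });
    std::vector<double> ra(a.begin(), a.end()), rb(b.begin(), b.end());
    UnionFind uf(N);
    int nbasic = 0;
    for (int t : order) {
      int i = t / n, j = t % n;
      if (ra[i] <= 0 || rb[j] <= 0) continue;
      double x = std::min(ra[i], rb[j]);
      if (!uf.unite(i, m + j)) continue;  // keep the basis acyclic
      F[static_cast<size_t>(i) * n + j] = x;
      basic[static_cast<size_t>(i) * n + j] = 1;
      adj[i].push_back(m + j); adj[m + j].push_back(i);
      ra[i] -= x; rb[j] -= x;
      if (++nbasic == m + n - 1) break;
    }
    // residual mass left by cycle-skips: drain it over the current tree by
    // falling back to cheap feasible cells, then complete the tree with
    // zero-flow cells
    for (int t : order) {
      if (nbasic == m + n - 1) break;
      int i = t / n, j = t % n;
      if (basic[static_cast<size_t>(i) * n + j]) continue;
      double x = std::min(ra[i], rb[j]);
      bool joins = uf.unite(i, m + j);
      if (x > 0 || joins) {
        if (!joins) continue;  // positive mass but would close a cycle: skip
        F[static_cast<size_t>(i) * n + j] = x;
        basic[static_cast<size_t>(i) * n + j] = 1;
        adj[i].push_back(m + j); adj[m + j].push_back(i);
        ra[i] -= x; rb[j] -= x;
        ++nbasic;
      }
    }
    // any remaining residual means positive mass could not be placed without
    // closing a cycle: push it along tree paths (rare; handle by NW fallback)
    double resid = 0, tot = 0;
    for (int i = 0; i < m; ++i) { resid += std::abs(ra[i]); tot += a[i]; }
    if (resid > 1e-12 * tot) {
      // rebuild from scratch with the plain northwest-corner rule
      std::fill(F.begin(), F.end(), 0.0);
      std::fill(basic.begin(), basic.end(), 0);
      for (int t = 0; t < N; ++t) adj[t].clear();
      std::vector<double> ra2(a.begin(), a.end()), rb2(b.begin(), b.end());
      int i = 0, j = 0;
      for (int step = 0; step < m + n - 1; ++step) {
        double x = std::min(ra2[i], rb2[j]);
        F[static_cast<size_t>(i) * n + j] = x;
        basic[static_cast<size_t>(i) * n + j] = 1;
        adj[i].push_back(m + j); adj[m + j].push_back(i);
        ra2[i] -= x; rb2[j] -= x;
        if (i == m - 1)      ++j;
        else if (j == n - 1) ++i;
        else if (ra2[i] <= rb2[j]) ++i;
        else ++j;
      }
    }
  }

  std::vector<double> u(m), v(n);
  std::vector<int> parent(N), via(N);
  std::vector<char> seen(N);
  std::vector<int> stack_;

  int iter = 0, degen_run = 0;
  bool optimal = false;

  while (iter < max_iter) {
    ++iter;

    // ---- dual potentials: u[i] + v[j] = C[i,j] on basic cells -------------
    std::fill(seen.begin(), seen.end(), 0);
    stack_.clear(); stack_.push_back(0);
    u[0] = 0.0; seen[0] = 1;
    while (!stack_.empty()) {
      int t = stack_.back(); stack_.pop_back();
      for (int s : adj[t]) {
        if (seen[s]) continue;
        if (t < m) v[s - m] = cost[static_cast<size_t>(t) * n + (s - m)] - u[t];
        else       u[s]     = cost[static_cast<size_t>(s) * n + (t - m)] - v[t - m];
        seen[s] = 1; stack_.push_back(s);
      }
    }

    // ---- entering cell ----------------------------------------------------
    int ei = -1, ej = -1;
    const bool bland = degen_run > 4 * N;
    double best = -EPS_RED;
    for (int i = 0; i < m && !(bland && ei >= 0); ++i) {
      const double ui = u[i];
      const size_t off = static_cast<size_t>(i) * n;
      for (int j = 0; j < n; ++j) {
        if (basic[off + j]) continue;
        double d = cost[off + j] - ui - v[j];
        if (d < best) {
          best = d; ei = i; ej = j;
          if (bland) break;  // first negative cell (Bland's rule)
        }
      }
    }
    if (ei < 0) { optimal = true; break; }

    // ---- unique tree path from row ei to column ej ------------------------
    std::fill(seen.begin(), seen.end(), 0);
    std::queue<int> bq;
    seen[ei] = 1; parent[ei] = -1; bq.push(ei);
    while (!bq.empty()) {
      int t = bq.front(); bq.pop();
      if (t == m + ej) break;
      for (int s : adj[t]) {
        if (seen[s]) continue;
        seen[s] = 1; parent[s] = t;
        bq.push(s);
      }
    }
    if (!seen[m + ej]) stop("internal error: basis tree disconnected");

    // cells along the path, ordered from the ei end to the ej end
    std::vector<std::pair<int, int>> path;
    for (int t = m + ej; parent[t] >= 0; t = parent[t]) {
      int s = parent[t];
      if (s < m) path.push_back(std::make_pair(s, t - m));
      else       path.push_back(std::make_pair(t, s - m));
    }
    std::reverse(path.begin(), path.end());

    // entering cell gets +theta; path cells alternate -, +, -, ...
    double theta = R_PosInf;
    int li = -1, lj = -1;
    for (size_t t = 0; t < path.size(); t += 2) {
      double f = F[static_cast<size_t>(path[t].first) * n + path[t].second];
      if (f < theta - 1e-18 ||
          (std::abs(f - theta) <= 1e-18 &&
           (li < 0 || path[t].first * n + path[t].second < li * n + lj))) {
        theta = f; li = path[t].first; lj = path[t].second;
      }
    }
    if (!R_FINITE(theta)) stop("internal error: unbounded pivot");

    F[static_cast<size_t>(ei) * n + ej] += theta;
    int sign = -1;
    for (size_t t = 0; t < path.size(); ++t) {
      double &f = F[static_cast<size_t>(path[t].first) * n + path[t].second];
      f += sign * theta;
      if (f < EPS_FLOW) f = 0.0;
      sign = -sign;
    }
    basic[static_cast<size_t>(ei) * n + ej] = 1;
    basic[static_cast<size_t>(li) * n + lj] = 0;
    F[static_cast<size_t>(li) * n + lj] = 0.0;
    // incremental basis-tree update
    adj[ei].push_back(m + ej); adj[m + ej].push_back(ei);
    adj[li].erase(std::find(adj[li].begin(), adj[li].end(), m + lj));
    adj[m + lj].erase(std::find(adj[m + lj].begin(), adj[m + lj].end(), li));

    degen_run = (theta <= EPS_FLOW) ? degen_run + 1 : 0;
  }

  double total = 0.0;
  NumericMatrix plan(m, n);
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      plan(i, j) = F[static_cast<size_t>(i) * n + j];
      total += plan(i, j) * cost[static_cast<size_t>(i) * n + j];
    }

  return List::create(_["plan"] = plan, _["cost"] = total,
                      _["iterations"] = iter, _["converged"] = optimal);
}
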