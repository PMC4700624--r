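#include <Rcpp.h>
using namespace Rcpp;

// Depth-limited DFS enumeration of simple start->end chains.
//
// adj: 0-based adjacency lists, each sorted ascending (for a deterministic
//      visit order; final canonical ordering is applied on the R side).
// is_start / is_end: membership flags over the n nodes.
// k: maximum chain length counted in NODES (not edges).
// allow_interior: when false, start and end nodes terminate traversal and
//      may only appear as the first / last node of a chain.
//
// Returns a list of 0-based integer paths.

namespace {

struct DfsState {
  const std::vector<std::vector<int>> *adj;
  const std::vector<bool> *is_start;
  const std::vector<bool> *is_end;
  int k;
  bool allow_interior;
  std::vector<bool> visited;
  std::vector<int> path;
  std::vector<std::vector<int>> out;
};

void dfs(DfsState &st, int v) {
  st.path.push_back(v);
  st.visited[v] = true;
  const int len = static_cast<int>(st.path.size());
  // a chain needs at least two nodes: start and end are distinct roles
  if (len >= 2 && (*st.is_end)[v]) st.out.push_back(st.path);
  const bool terminal =
      !st.allow_interior && len >= 2 && ((*st.is_end)[v] || (*st.is_start)[v]);
  if (len < st.k && !terminal) {
    for (int w : (*st.adj)[v]) {
      if (st.visited[w]) continue;
      // a pure start node can never be re-entered under the default policy;
      // a node that is also an end node may still terminate a chain
      if (!st.allow_interior && (*st.is_start)[w] && !(*st.is_end)[w]) continue;
      dfs(st, w);
    }
  }
  st.visited[v] = false;
  st.path.pop_back();
}

} // namespace

// [[Rcpp::export(name = ".dfs_chains")]]
List dfs_chains(List adj, IntegerVector start_idx, LogicalVector is_start,
                LogicalVector is_end, int k, bool allow_interior) {
  const int n = adj.size();
  std::vector<std::vector<int>> a(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj[i];
    a[i].assign(nb.begin(), nb.end());
  }
  std::vector<bool> bs(n), be(n);
  for (int i = 0; i < n; ++i) {
    bs[i] = is_start[i];
    be[i] = is_end[i];
  }

  DfsState st;
  st.adj = &a;
  st.is_start = &bs;
  st.is_end = &be;
  st.k = k;
  st.allow_interior = allow_interior;
  st.visited.assign(n, false);

  for (int i = 0; i < start_idx.size(); ++i) {
    if (k < 2) break;
    dfs(st, start_idx[i]);
  }

  List res(st.out.size());
  for (R_xlen_t i = 0; i < static_cast<R_xlen_t>(st.out.size()); ++i)
    res[i] = wrap(st.out[i]);
  return res;
}
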