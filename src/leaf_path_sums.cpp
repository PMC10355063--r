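#include <Rcpp.h>
#include <vector>
#include <utility>
using namespace Rcpp;

// All-pairs leaf path-weight sums on an undirected tree, by a single
// post-order sweep. Each visited node carries the vector of accumulated
// weights to the leaves below it; at an internal node the vectors of its
// children are combined pairwise across distinct children, which charges
// every leaf pair exactly once (at the node connecting the pair). Total
// work is O(L^2) for L leaves, matching the number of output entries.
//
// edge:     m x 2 matrix of undirected edges; node ids are positive
//           integers, not necessarily contiguous. No degree-2 nodes.
// w:        weight of each edge (same order as rows of `edge`).
// leaf_map: for node id v, leaf_map[v-1] > 0 gives its (1-based) row in
//           the output matrix; 0 marks an internal node. Length covers
//           the largest node id.
// out_dim:  dimension of the (square) output matrix.
//
// Rows/columns of absent leaves are left at zero. The attribute
// "pair_ops" counts leaf-pair combination operations performed.
// [[Rcpp::export]]
NumericMatrix leaf_path_sums_cpp(IntegerMatrix edge, NumericVector w,
                                 IntegerVector leaf_map, int out_dim) {
  int m = edge.nrow();
  int n_ids = leaf_map.size();
  NumericMatrix out(out_dim, out_dim);
  if (m == 0) {
    out.attr("pair_ops") = 0.0;
    return out;
  }
  if (m == 1) {
    int a = leaf_map[edge(0, 0) - 1], b = leaf_map[edge(0, 1) - 1];
    if (a > 0 && b > 0) {
      out(a - 1, b - 1) = out(b - 1, a - 1) = w[0];
    }
    out.attr("pair_ops") = 1.0;
    return out;
  }

  // adjacency lists: (neighbour, edge index)
  std::vector<std::vector<std::pair<int, int> > > adj(n_ids + 1);
  int n_present = 0;
  for (int i = 0; i < m; ++i) {
    int a = edge(i, 0), b = edge(i, 1);
    if (a < 1 || a > n_ids || b < 1 || b > n_ids)
      stop("edge endpoint out of range of leaf_map");
    if (adj[a].empty()) ++n_present;
    if (adj[b].empty()) ++n_present;
    adj[a].push_back(std::make_pair(b, i));
    adj[b].push_back(std::make_pair(a, i));
  }

  // root the traversal at an internal node (one exists once m > 1)
  int root = 0;
  for (int v = 1; v <= n_ids; ++v)
    if (!adj[v].empty() && leaf_map[v - 1] == 0) { root = v; break; }
  if (root == 0) stop("no internal node found");

  // iterative DFS: parent pointers and a preorder (reverse = postorder)
  std::vector<int> parent(n_ids + 1, 0), pedge(n_ids + 1, -1);
  std::vector<int> order;
  order.reserve(n_present);
  std::vector<int> stack;
  stack.push_back(root);
  parent[root] = root;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t j = 0; j < adj[v].size(); ++j) {
      int u = adj[v][j].first;
      if (parent[u] == 0) {
        parent[u] = v;
        pedge[u] = adj[v][j].second;
        stack.push_back(u);
      }
    }
  }
  if ((int)order.size() != n_present)
    stop("input edges do not form a connected tree");

  // below[v]: list of (output index 0-based, accumulated weight from v)
  std::vector<std::vector<std::pair<int, double> > > below(n_ids + 1);
  double pair_ops = 0.0;

  for (int k = n_present - 1; k >= 0; --k) {
    int v = order[k];
    int lv = leaf_map[v - 1];
    if (lv > 0) {
      below[v].push_back(std::make_pair(lv - 1, 0.0));
      continue;
    }
    std::vector<std::pair<int, double> > acc;
    for (size_t j = 0; j < adj[v].size(); ++j) {
      int c = adj[v][j].first;
      if (parent[c] != v || c == root) continue;
      double wc = w[pedge[c]];
      std::vector<std::pair<int, double> >& bc = below[c];
      // lift child vector across its edge, then cross with leaves already
      // accumulated at v from earlier children
      for (size_t a = 0; a < bc.size(); ++a) {
        double da = bc[a].second + wc;
        int la = bc[a].first;
        for (size_t b = 0; b < acc.size(); ++b) {
          double d = da + acc[b].second;
          out(la, acc[b].first) = d;
          out(acc[b].first, la) = d;
          pair_ops += 1.0;
        }
        bc[a].second = da;
      }
      acc.insert(acc.end(), bc.begin(), bc.end());
      std::vector<std::pair<int, double> >().swap(below[c]);
    }
    below[v].swap(acc);
  }
  out.attr("pair_ops") = pair_ops;
  return out;
}
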