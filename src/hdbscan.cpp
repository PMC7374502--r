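// HDBSCAN (hierarchical density-based clustering) on a point matrix.
//
// Pipeline: core distances -> mutual-reachability minimum spanning tree
// (Prim, O(n^2)) -> single-linkage dendrogram -> condensed tree under the
// minimum-cluster-size parameter -> excess-of-mass flat cluster extraction.
// Follows the algorithm of Campello et al. as popularised by the McInnes
// reference implementation; the O(n^2) MST keeps the code simple and is
// adequate for the desk-scale images this package targets.

#include <Rcpp.h>
#include <algorithm>
#include <functional>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

static const double LAMBDA_CAP = 1e12; // 1/dist for (near-)zero distances

struct Edge {
  int a, b;
  double w;
};

// Euclidean distance between rows i and j of X (n x d, column-major).
static inline double row_dist(const std::vector<double> &X, int n, int d,
                              int i, int j) {
  double s = 0.0;
  for (int k = 0; k < d; ++k) {
    double diff = X[i + k * n] - X[j + k * n];
    s += diff * diff;
  }
  return std::sqrt(s);
}

// [[Rcpp::export(name = ".hdbscan_labels")]]
IntegerVector hdbscan_labels(const NumericMatrix &Xin, int min_cluster_size,
                             int min_samples, bool allow_single_cluster) {
  const int n = Xin.nrow(), d = Xin.ncol();
  IntegerVector labels(n, -1);
  if (n == 0) return labels;
  if (n == 1 || min_cluster_size < 2) return labels;
  std::vector<double> X(Xin.begin(), Xin.end());

  // Core distance: distance to the min_samples-th nearest neighbour,
  // counting the point itself (self-distance 0).
  const int k_core = std::min(min_samples, n);
  std::vector<double> core(n);
  {
    std::vector<double> row(n);
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < n; ++j) row[j] = row_dist(X, n, d, i, j);
      std::nth_element(row.begin(), row.begin() + (k_core - 1), row.end());
      core[i] = row[k_core - 1];
    }
  }

  // Prim MST over the mutual reachability graph:
  // mr(i, j) = max(core_i, core_j, dist(i, j)).
  std::vector<Edge> edges;
  edges.reserve(n - 1);
  {
    const double INF = std::numeric_limits<double>::infinity();
    std::vector<double> best(n, INF);
    std::vector<int> from(n, 0);
    std::vector<char> used(n, 0);
    int cur = 0;
    used[0] = 1;
    for (int it = 1; it < n; ++it) {
      for (int j = 0; j < n; ++j) {
        if (used[j]) continue;
        double mr = std::max(std::max(core[cur], core[j]),
                             row_dist(X, n, d, cur, j));
        if (mr < best[j]) {
          best[j] = mr;
          from[j] = cur;
        }
      }
      int nxt = -1;
      double bw = INF;
      for (int j = 0; j < n; ++j) {
        if (!used[j] && best[j] < bw) {
          bw = best[j];
          nxt = j;
        }
      }
      edges.push_back({from[nxt], nxt, bw});
      used[nxt] = 1;
      cur = nxt;
    }
  }
  std::sort(edges.begin(), edges.end(),
            [](const Edge &x, const Edge &y) { return x.w < y.w; });

  // Single-linkage dendrogram: leaves 0..n-1, internal nodes n..2n-2.
  const int n_nodes = 2 * n - 1;
  std::vector<int> left(n_nodes, -1), right(n_nodes, -1);
  std::vector<double> ndist(n_nodes, 0.0);
  std::vector<int> nsize(n_nodes, 1);
  {
    std::vector<int> parent(n_nodes);
    for (int i = 0; i < n_nodes; ++i) parent[i] = i;
    std::function<int(int)> find = [&](int x) {
      while (parent[x] != x) {
        parent[x] = parent[parent[x]];
        x = parent[x];
      }
      return x;
    };
    std::vector<int> root_node(n_nodes);
    for (int i = 0; i < n_nodes; ++i) root_node[i] = i;
    int next_node = n;
    for (const Edge &e : edges) {
      int ra = find(e.a), rb = find(e.b);
      int na = root_node[ra], nb = root_node[rb];
      left[next_node] = na;
      right[next_node] = nb;
      ndist[next_node] = e.w;
      nsize[next_node] = nsize[na] + nsize[nb];
      parent[ra] = rb;
      root_node[find(rb)] = next_node;
      ++next_node;
    }
  }
  const int root = n_nodes - 1;

  // Condensed tree rows: (parent cluster, child, lambda, child size) where
  // child is a cluster id (>= 0 in cluster numbering) or a point (< 0:
  // encoded as -(point index + 1)).
  struct CRow {
    int parent, child;
    double lambda;
    int size;
    bool is_point;
  };
  std::vector<CRow> rows;
  std::vector<int> cl_parent(1, -1); // cluster tree, cluster 0 = root
  std::vector<double> cl_birth(1, 0.0);
  {
    std::vector<char> ignore(n_nodes, 0);
    std::vector<int> relabel(n_nodes, -1);
    relabel[root] = 0;
    // iterative BFS from the root of the dendrogram
    std::vector<int> bfs;
    bfs.push_back(root);
    for (size_t qi = 0; qi < bfs.size(); ++qi) {
      int node = bfs[qi];
      if (node < n || ignore[node]) continue;
      int L = left[node], R = right[node];
      double dd = ndist[node];
      double lambda = dd > 1.0 / LAMBDA_CAP ? 1.0 / dd : LAMBDA_CAP;
      int sL = nsize[L], sR = nsize[R];
      int cl = relabel[node];
      auto collect_leaves = [&](int start, std::vector<int> &out) {
        std::vector<int> st(1, start);
        while (!st.empty()) {
          int x = st.back();
          st.pop_back();
          if (x < n) {
            out.push_back(x);
          } else {
            ignore[x] = 1;
            st.push_back(left[x]);
            st.push_back(right[x]);
          }
        }
      };
      if (sL >= min_cluster_size && sR >= min_cluster_size) {
        int cL = (int)cl_parent.size();
        cl_parent.push_back(cl);
        cl_birth.push_back(lambda);
        relabel[L] = cL;
        rows.push_back({cl, cL, lambda, sL, false});
        int cR = (int)cl_parent.size();
        cl_parent.push_back(cl);
        cl_birth.push_back(lambda);
        relabel[R] = cR;
        rows.push_back({cl, cR, lambda, sR, false});
        bfs.push_back(L);
        bfs.push_back(R);
      } else if (sL < min_cluster_size && sR < min_cluster_size) {
        std::vector<int> leaves;
        collect_leaves(L, leaves);
        collect_leaves(R, leaves);
        for (int p : leaves) rows.push_back({cl, -(p + 1), lambda, 1, true});
      } else {
        int small = (sL < min_cluster_size) ? L : R;
        int big = (sL < min_cluster_size) ? R : L;
        relabel[big] = cl;
        std::vector<int> leaves;
        collect_leaves(small, leaves);
        for (int p : leaves) rows.push_back({cl, -(p + 1), lambda, 1, true});
        bfs.push_back(big);
      }
    }
  }
  const int n_clusters = (int)cl_parent.size();
  if (n_clusters == 1 && !allow_single_cluster) return labels; // all noise

  // Stability per cluster.
  std::vector<double> stability(n_clusters, 0.0);
  for (const CRow &r : rows) {
    stability[r.parent] += (r.lambda - cl_birth[r.parent]) * r.size;
  }

  // Excess-of-mass selection, deepest clusters first.
  std::vector<std::vector<int> > cl_children(n_clusters);
  for (int c = 1; c < n_clusters; ++c) cl_children[cl_parent[c]].push_back(c);
  std::vector<char> selected(n_clusters, 0);
  int first = allow_single_cluster ? 0 : 1;
  for (int c = n_clusters - 1; c >= first; --c) {
    double sub = 0.0;
    for (int ch : cl_children[c]) sub += stability[ch];
    if (cl_children[c].empty()) {
      selected[c] = 1;
    } else if (sub > stability[c]) {
      selected[c] = 0;
      stability[c] = sub;
    } else {
      selected[c] = 1;
      // deselect all descendants
      std::vector<int> st = cl_children[c];
      while (!st.empty()) {
        int x = st.back();
        st.pop_back();
        selected[x] = 0;
        for (int ch : cl_children[x]) st.push_back(ch);
      }
    }
  }

  // Map each point to the nearest selected ancestor of the cluster it fell
  // out of; otherwise noise. Final labels are compacted to 0..k-1.
  std::vector<int> final_id(n_clusters, -1);
  int k = 0;
  for (int c = 0; c < n_clusters; ++c)
    if (selected[c]) final_id[c] = k++;
  for (const CRow &r : rows) {
    if (!r.is_point) continue;
    int p = -r.child - 1;
    int c = r.parent;
    while (c >= 0 && !selected[c]) c = cl_parent[c];
    labels[p] = (c >= 0) ? final_id[c] : -1;
  }
  return labels;
}
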