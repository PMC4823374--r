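#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
using namespace Rcpp;

// Max-flow / min-cut for the grid-structured binary energy
//
//   E(x) = sum_i (x_i ? u1_i : u0_i) + sum_e w_e [x_i != x_j],  x_i in {0,1}
//
// solved with the Boykov-Kolmogorov augmenting-path algorithm: two search
// trees S (from the source) and T (from the sink) are grown until they
// touch, the connecting path is saturated, and orphaned subtrees are
// re-adopted.  Near-linear in practice on 6-connected image grids.
// Terminal edges are stored as one residual per node (tr_cap > 0: residual
// from source; < 0: residual to sink); the constant sum_i min(u0_i, u1_i)
// is factored out of the flow and is irrelevant for the cut.  Returns the
// cut side per node: TRUE = sink side = label 1.  Free nodes (unreachable
// from either terminal at termination) go to the sink side; any assignment
// of them yields a minimum cut.

namespace {

constexpr int TERMINAL = -1;
constexpr int NO_PARENT = -2;

struct BK {
  int n;
  std::vector<int> first, arc_head, arc_next;
  std::vector<double> rcap, tr_cap;
  std::vector<int> parent;          // arc index to parent, or codes above
  std::vector<signed char> tree;    // 0 free, 1 S, 2 T
  std::deque<int> active, orphans;

  explicit BK(int n_) : n(n_), first(n_, -1), tr_cap(n_, 0.0),
    parent(n_, NO_PARENT), tree(n_, 0) {}

  void add_edge(int i, int j, double w) {
    int a = (int)arc_head.size();
    arc_head.push_back(j); arc_next.push_back(first[i]); first[i] = a;
    arc_head.push_back(i); arc_next.push_back(first[j]); first[j] = a + 1;
    rcap.push_back(w); rcap.push_back(w);
  }

  static int sister(int a) { return a ^ 1; }

  // is `q` connected to its terminal through intact parent pointers?
  bool has_origin(int q) const {
    int i = q;
    while (true) {
      int pa = parent[i];
      if (pa == TERMINAL) return true;
      if (pa == NO_PARENT) return false;
      i = arc_head[pa];
    }
  }

  int root_of(int p) const {
    while (parent[p] != TERMINAL) p = arc_head[parent[p]];
    return p;
  }

  // connect_arc: residual arc from a node p in S to a node q in T
  void augment(int connect_arc) {
    const int p = arc_head[sister(connect_arc)];
    const int q = arc_head[connect_arc];
    const int root_p = root_of(p), root_q = root_of(q);

    double bn = rcap[connect_arc];
    for (int i = p; i != root_p; i = arc_head[parent[i]])
      bn = std::min(bn, rcap[sister(parent[i])]);
    bn = std::min(bn, tr_cap[root_p]);
    for (int i = q; i != root_q; i = arc_head[parent[i]])
      bn = std::min(bn, rcap[parent[i]]);
    bn = std::min(bn, -tr_cap[root_q]);

    rcap[connect_arc] -= bn;
    rcap[sister(connect_arc)] += bn;
    for (int i = p; i != root_p; ) {
      const int pa = parent[i];
      const int nxt = arc_head[pa];
      rcap[sister(pa)] -= bn;
      rcap[pa] += bn;
      if (rcap[sister(pa)] <= 0) { parent[i] = NO_PARENT; orphans.push_back(i); }
      i = nxt;
    }
    tr_cap[root_p] -= bn;
    if (tr_cap[root_p] <= 0 && parent[root_p] == TERMINAL) {
      parent[root_p] = NO_PARENT; orphans.push_back(root_p);
    }
    for (int i = q; i != root_q; ) {
      const int pa = parent[i];
      const int nxt = arc_head[pa];
      rcap[pa] -= bn;
      rcap[sister(pa)] += bn;
      if (rcap[pa] <= 0) { parent[i] = NO_PARENT; orphans.push_back(i); }
      i = nxt;
    }
    tr_cap[root_q] += bn;
    if (tr_cap[root_q] >= 0 && parent[root_q] == TERMINAL) {
      parent[root_q] = NO_PARENT; orphans.push_back(root_q);
    }
  }

  void adopt() {
    while (!orphans.empty()) {
      const int i = orphans.front();
      orphans.pop_front();
      const signed char tr = tree[i];
      int found = NO_PARENT;
      for (int a = first[i]; a != -1; a = arc_next[a]) {
        const int j = arc_head[a];
        if (tree[j] != tr) continue;
        // parent must carry residual toward i (S) / away from i (T)
        const double cap = (tr == 1) ? rcap[sister(a)] : rcap[a];
        if (cap <= 0) continue;
        if (has_origin(j)) { found = a; break; }
      }
      if (found != NO_PARENT) {
        parent[i] = found;
      } else {
        for (int a = first[i]; a != -1; a = arc_next[a]) {
          const int j = arc_head[a];
          if (tree[j] != tr) continue;
          const double cap = (tr == 1) ? rcap[sister(a)] : rcap[a];
          if (cap > 0) active.push_back(j);
          const int pj = parent[j];
          if (pj != TERMINAL && pj != NO_PARENT && arc_head[pj] == i) {
            parent[j] = NO_PARENT;
            orphans.push_back(j);
          }
        }
        tree[i] = 0;
        parent[i] = NO_PARENT;
      }
    }
  }

  void run() {
    for (int i = 0; i < n; ++i) {
      if (tr_cap[i] > 0) { tree[i] = 1; parent[i] = TERMINAL; active.push_back(i); }
      else if (tr_cap[i] < 0) { tree[i] = 2; parent[i] = TERMINAL; active.push_back(i); }
    }
    while (!active.empty()) {
      const int p = active.front();
      active.pop_front();
      if (tree[p] == 0) continue;
      const signed char tr = tree[p];
      int connect_arc = NO_PARENT;
      for (int a = first[p]; a != -1; a = arc_next[a]) {
        const double cap = (tr == 1) ? rcap[a] : rcap[sister(a)];
        if (cap <= 0) continue;
        const int q = arc_head[a];
        if (tree[q] == 0) {
          tree[q] = tr;
          parent[q] = sister(a);
          active.push_back(q);
        } else if (tree[q] != tr) {
          connect_arc = (tr == 1) ? a : sister(a);
          break;
        }
      }
      if (connect_arc != NO_PARENT) {
        active.push_back(p);      // p keeps growing after the augmentation
        augment(connect_arc);
        adopt();
      }
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".bk_mincut")]]
LogicalVector bk_mincut(int n, IntegerMatrix edges, NumericVector w,
                        NumericVector u0, NumericVector u1) {
  BK bk(n);
  for (int i = 0; i < n; ++i) bk.tr_cap[i] = u1[i] - u0[i];
  const int m = edges.nrow();
  for (int e = 0; e < m; ++e) {
    if (w[e] > 0) bk.add_edge(edges(e, 0) - 1, edges(e, 1) - 1, w[e]);
  }
  bk.run();
  LogicalVector x1(n);
  for (int i = 0; i < n; ++i) x1[i] = (bk.tree[i] != 1);
  return x1;
}
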