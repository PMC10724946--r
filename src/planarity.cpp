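// Planarity testing (left-right criterion) and greedy PMFG construction.
//
// Directed half-edges are encoded as 2*k (u->v) and 2*k+1 (v->u) for the
// k-th undirected edge; -1 stands for "no edge".

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Interval {
  int high, low;
  Interval() : high(-1), low(-1) {}
  Interval(int h, int l) : high(h), low(l) {}
  bool empty() const { return high == -1 && low == -1; }
};

struct ConflictPair {
  Interval L, R;
};

class LRPlanarity {
public:
  LRPlanarity(int n_, const std::vector<int>& eu_, const std::vector<int>& ev_)
    : n(n_), m((int)eu_.size()), eu(eu_), ev(ev_) {}

  bool run() {
    if (n > 2 && m > 3 * n - 6) return false;
    if (m == 0) return true;

    adj.assign(n, {});
    for (int k = 0; k < m; ++k) {
      adj[eu[k]].push_back(2 * k);
      adj[ev[k]].push_back(2 * k + 1);
    }
    height.assign(n, -1);
    parent_edge.assign(n, -1);
    lowpt.assign(2 * m, 0);
    lowpt2.assign(2 * m, 0);
    nesting_depth.assign(2 * m, 0);
    oriented.assign(m, 0);
    chosen.assign(m, -1);
    skip_init.assign(2 * m, 0);
    ind.assign(n, 0);

    roots.clear();
    for (int v = 0; v < n; ++v) {
      if (height[v] == -1) {
        height[v] = 0;
        roots.push_back(v);
        dfs_orientation(v);
      }
    }

    // order the oriented out-adjacency by nesting depth (stable sort keeps
    // insertion order on ties); only the DFS orientation of each edge is kept
    ordered_adj.assign(n, {});
    for (int v = 0; v < n; ++v) {
      for (size_t j = 0; j < adj[v].size(); ++j) {
        int de = adj[v][j];
        if (chosen[de >> 1] == de) ordered_adj[v].push_back(de);
      }
      std::stable_sort(ordered_adj[v].begin(), ordered_adj[v].end(),
                       [&](int a, int b) {
                         return nesting_depth[a] < nesting_depth[b];
                       });
    }

    ref_.assign(2 * m, -1);
    side.assign(2 * m, 1);
    lowpt_edge.assign(2 * m, -1);
    stack_bottom.assign(2 * m, 0);
    std::fill(skip_init.begin(), skip_init.end(), 0);
    std::fill(ind.begin(), ind.end(), 0);
    S.clear();

    for (size_t i = 0; i < roots.size(); ++i) {
      if (!dfs_testing(roots[i])) return false;
    }
    return true;
  }

private:
  int n, m;
  const std::vector<int>& eu;
  const std::vector<int>& ev;
  std::vector<std::vector<int>> adj, ordered_adj;
  std::vector<int> height, parent_edge, roots;
  std::vector<int> lowpt, lowpt2, nesting_depth, ref_, side, lowpt_edge,
      stack_bottom, ind;
  std::vector<char> oriented, skip_init;
  std::vector<int> chosen;
  std::vector<ConflictPair> S;
  std::vector<int> dfs_stack;

  inline int head(int de) const { return (de & 1) ? eu[de >> 1] : ev[de >> 1]; }
  inline int tail(int de) const { return (de & 1) ? ev[de >> 1] : eu[de >> 1]; }

  void dfs_orientation(int root) {
    dfs_stack.clear();
    dfs_stack.push_back(root);
    while (!dfs_stack.empty()) {
      int v = dfs_stack.back();
      dfs_stack.pop_back();
      int e = parent_edge[v];
      while (ind[v] < (int)adj[v].size()) {
        int vw = adj[v][ind[v]];
        int k = vw >> 1;
        bool descend = false;
        if (!skip_init[vw]) {
          if (oriented[k]) { ++ind[v]; continue; }
          oriented[k] = 1;
          chosen[k] = vw;
          lowpt[vw] = height[v];
          lowpt2[vw] = height[v];
          int w = head(vw);
          if (height[w] == -1) {  // tree edge
            parent_edge[w] = vw;
            height[w] = height[v] + 1;
            dfs_stack.push_back(v);
            dfs_stack.push_back(w);
            skip_init[vw] = 1;
            descend = true;
          } else {  // back edge
            lowpt[vw] = height[w];
          }
        }
        if (descend) break;
        // nesting depth of vw
        nesting_depth[vw] = 2 * lowpt[vw];
        if (lowpt2[vw] < height[v]) nesting_depth[vw] += 1;  // chordal
        // update lowpoints of parent edge
        if (e != -1) {
          if (lowpt[vw] < lowpt[e]) {
            lowpt2[e] = std::min(lowpt[e], lowpt2[vw]);
            lowpt[e] = lowpt[vw];
          } else if (lowpt[vw] > lowpt[e]) {
            lowpt2[e] = std::min(lowpt2[e], lowpt[vw]);
          } else {
            lowpt2[e] = std::min(lowpt2[e], lowpt2[vw]);
          }
        }
        ++ind[v];
      }
    }
  }

  inline bool conflicting(const Interval& I, int b) const {
    return !I.empty() && lowpt[I.high] > lowpt[b];
  }

  inline int lowest(const ConflictPair& P) const {
    if (P.L.empty()) return lowpt[P.R.low];
    if (P.R.empty()) return lowpt[P.L.low];
    return std::min(lowpt[P.L.low], lowpt[P.R.low]);
  }

  bool add_constraints(int ei, int e) {
    ConflictPair P;
    // merge return edges of e_i into P.R
    while (true) {
      ConflictPair Q = S.back();
      S.pop_back();
      if (!Q.L.empty()) std::swap(Q.L, Q.R);
      if (!Q.L.empty()) return false;  // not planar
      if (lowpt[Q.R.low] > lowpt[e]) {  // merge intervals
        if (P.R.empty()) {
          P.R = Q.R;
        } else {
          ref_[P.R.low] = Q.R.high;
        }
        P.R.low = Q.R.low;
      } else {  // align
        ref_[Q.R.low] = lowpt_edge[e];
      }
      if ((int)S.size() == stack_bottom[ei]) break;
    }
    // merge conflicting return edges of earlier children into P.L
    while (!S.empty() &&
           (conflicting(S.back().L, ei) || conflicting(S.back().R, ei))) {
      ConflictPair Q = S.back();
      S.pop_back();
      if (conflicting(Q.R, ei)) std::swap(Q.L, Q.R);
      if (conflicting(Q.R, ei)) return false;  // not planar
      if (P.R.low != -1) ref_[P.R.low] = Q.R.high;
      if (Q.R.low != -1) P.R.low = Q.R.low;
      if (P.L.empty()) {
        P.L = Q.L;
      } else {
        ref_[P.L.low] = Q.L.high;
      }
      P.L.low = Q.L.low;
    }
    if (!(P.L.empty() && P.R.empty())) S.push_back(P);
    return true;
  }

  void remove_back_edges(int e) {
    int u = tail(e);
    // drop entire conflict pairs whose lowest return point is u
    while (!S.empty() && lowest(S.back()) == height[u]) {
      ConflictPair P = S.back();
      S.pop_back();
      if (P.L.low != -1) side[P.L.low] = -1;
    }
    if (!S.empty()) {  // one more conflict pair to trim
      ConflictPair P = S.back();
      S.pop_back();
      while (P.L.high != -1 && head(P.L.high) == u) P.L.high = ref_[P.L.high];
      if (P.L.high == -1 && P.L.low != -1) {  // interval emptied
        ref_[P.L.low] = P.R.low;
        side[P.L.low] = -1;
        P.L.low = -1;
      }
      while (P.R.high != -1 && head(P.R.high) == u) P.R.high = ref_[P.R.high];
      if (P.R.high == -1 && P.R.low != -1) {
        ref_[P.R.low] = P.L.low;
        side[P.R.low] = -1;
        P.R.low = -1;
      }
      S.push_back(P);
    }
    // side of e is the side of a highest return edge
    if (lowpt[e] < height[u] && !S.empty()) {
      int hl = S.back().L.high;
      int hr = S.back().R.high;
      if (hl != -1 && (hr == -1 || lowpt[hl] > lowpt[hr])) {
        ref_[e] = hl;
      } else {
        ref_[e] = hr;
      }
    }
  }

  bool dfs_testing(int root) {
    dfs_stack.clear();
    dfs_stack.push_back(root);
    while (!dfs_stack.empty()) {
      int v = dfs_stack.back();
      dfs_stack.pop_back();
      int e = parent_edge[v];
      bool skip_final = false;
      while (ind[v] < (int)ordered_adj[v].size()) {
        int ei = ordered_adj[v][ind[v]];
        bool descend = false;
        if (!skip_init[ei]) {
          stack_bottom[ei] = (int)S.size();
          int w = head(ei);
          if (ei == parent_edge[w]) {  // tree edge
            dfs_stack.push_back(v);
            dfs_stack.push_back(w);
            skip_init[ei] = 1;
            skip_final = true;
            descend = true;
          } else {  // back edge
            lowpt_edge[ei] = ei;
            ConflictPair P;
            P.R = Interval(ei, ei);
            S.push_back(P);
          }
        }
        if (descend) break;
        // integrate new return edges
        if (lowpt[ei] < height[v]) {
          if (ei == ordered_adj[v][0]) {
            if (e != -1) lowpt_edge[e] = lowpt_edge[ei];
          } else if (!add_constraints(ei, e)) {
            return false;
          }
        }
        ++ind[v];
      }
      if (!skip_final && e != -1) remove_back_edges(e);
    }
    return true;
  }
};

bool lr_planar_vec(int n, const std::vector<int>& eu,
                   const std::vector<int>& ev) {
  LRPlanarity lr(n, eu, ev);
  return lr.run();
}

}  // namespace

//' @noRd
// [[Rcpp::export(name = ".lr_is_planar")]]
bool lr_is_planar(int n, IntegerVector u, IntegerVector v) {
  int m = u.size();
  std::vector<int> eu(m), ev(m);
  for (int i = 0; i < m; ++i) {
    if (u[i] < 0 || u[i] >= n || v[i] < 0 || v[i] >= n || u[i] == v[i])
      stop("invalid edge endpoints");
    eu[i] = u[i];
    ev[i] = v[i];
  }
  return lr_planar_vec(n, eu, ev);
}

//' @noRd
// [[Rcpp::export(name = ".pmfg_select")]]
LogicalVector pmfg_select(int n, IntegerVector u, IntegerVector v) {
  int m = u.size();
  LogicalVector keep(m, false);
  long target = (n >= 3) ? 3L * (n - 2) : (long)n * (n - 1) / 2;
  std::vector<int> au, av;
  au.reserve(target > 0 ? target : 0);
  av.reserve(target > 0 ? target : 0);
  long accepted = 0;
  for (int i = 0; i < m; ++i) {
    if (accepted >= target) break;
    au.push_back(u[i]);
    av.push_back(v[i]);
    if (lr_planar_vec(n, au, av)) {
      keep[i] = true;
      ++accepted;
    } else {
      au.pop_back();
      av.pop_back();
    }
  }
  return keep;
}

//' @noRd
// [[Rcpp::export(name = ".rmultiset_overlap")]]
IntegerVector rmultiset_overlap(int universe, IntegerVector sizes, int ndraw) {
  // Monte-Carlo draws of |A_1 cap ... cap A_m| for independent uniform
  // random subsets of the given sizes; uses R's RNG (set.seed applies).
  int m = sizes.size();
  IntegerVector out(ndraw);
  std::vector<int> perm(universe);
  std::vector<int> count(universe);
  for (int d = 0; d < ndraw; ++d) {
    std::fill(count.begin(), count.end(), 0);
    for (int j = 0; j < m; ++j) {
      for (int i = 0; i < universe; ++i) perm[i] = i;
      int sz = sizes[j];
      for (int i = 0; i < sz; ++i) {
        int pick = i + (int)(unif_rand() * (universe - i));
        if (pick >= universe) pick = universe - 1;
        std::swap(perm[i], perm[pick]);
        ++count[perm[i]];
      }
    }
    int inter = 0;
    for (int i = 0; i < universe; ++i)
      if (count[i] == m) ++inter;
    out[d] = inter;
  }
  return out;
}
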