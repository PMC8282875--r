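#include <Rcpp.h>
#include <queue>
#include <set>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Reflected (edge-inclusive) index fold onto 0..n-1.
static inline int refl(int i, int n) {
  if (n == 1) return 0;
  int m = 2 * n;
  int j = i % m;
  if (j < 0) j += m;
  return (j < n) ? j : (m - 1 - j);
}

// Flat-SE grayscale erosion (min) / dilation (max) over arbitrary offsets,
// reflected borders.
// [[Rcpp::export]]
NumericMatrix morph_extreme_cpp(NumericMatrix img, IntegerVector di,
                                IntegerVector dj, bool take_max) {
  int nr = img.nrow(), nc = img.ncol(), k = di.size();
  NumericMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double v = take_max ? R_NegInf : R_PosInf;
      for (int o = 0; o < k; ++o) {
        double x = img(refl(i + di[o], nr), refl(j + dj[o], nc));
        if (take_max) { if (x > v) v = x; } else { if (x < v) v = x; }
      }
      out(i, j) = v;
    }
  }
  return out;
}

static const int DX8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DY8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DX4[4] = {0, -1, 1, 0};
static const int DY4[4] = {-1, 0, 0, 1};

// Connected-component labelling of a logical mask; 0 outside, 1..m inside.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int *dx = (connectivity == 8) ? DX8 : DX4;
  const int *dy = (connectivity == 8) ? DY8 : DY4;
  int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      stack.clear();
      stack.push_back(i + j * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < nd; ++d) {
          int qi = pi + dy[d], qj = pj + dx[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && lab(qi, qj) == 0) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct QNode {
  double v;
  long long ord;
  int idx;
};
struct QNodeCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.v != b.v) return a.v > b.v;  // min-heap on value
    return a.ord > b.ord;              // FIFO among equal values
  }
};

// Watershed by immersion/flooding (Meyer) without watershed lines: regional
// minima (8-connected plateaus with no strictly lower 8-neighbour) seed the
// basins; remaining pixels are flooded in ascending gray order, ties broken
// by insertion order (seeds inserted in scanline order). Every pixel ends up
// in exactly one basin.
// [[Rcpp::export]]
IntegerMatrix watershed_cpp(NumericMatrix grad) {
  int nr = grad.nrow(), nc = grad.ncol(), n = nr * nc;
  IntegerMatrix lab(nr, nc);
  std::vector<signed char> state(n, 0);  // 0 unvisited, 1 plateau seen, 2 done

  // --- regional minima via plateau BFS (8-connectivity) ---
  int next = 0;
  std::vector<int> plateau, stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int p0 = i + j * nr;
      if (state[p0] != 0) continue;
      double v = grad(i, j);
      bool is_min = true;
      plateau.clear();
      stack.clear();
      stack.push_back(p0);
      state[p0] = 1;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        plateau.push_back(p);
        int pi = p % nr, pj = p / nr;
        for (int d = 0; d < 8; ++d) {
          int qi = pi + DY8[d], qj = pj + DX8[d];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          double qv = grad(qi, qj);
          if (qv < v) { is_min = false; continue; }
          if (qv == v) {
            int q = qi + qj * nr;
            if (state[q] == 0) { state[q] = 1; stack.push_back(q); }
          }
        }
      }
      if (is_min) {
        ++next;
        for (size_t t = 0; t < plateau.size(); ++t) {
          lab(plateau[t] % nr, plateau[t] / nr) = next;
          state[plateau[t]] = 2;
        }
      } else {
        for (size_t t = 0; t < plateau.size(); ++t) state[plateau[t]] = 0;
      }
    }
  }

  // --- priority flood from the minima ---
  std::priority_queue<QNode, std::vector<QNode>, QNodeCmp> pq;
  long long ord = 0;
  std::vector<char> queued(n, 0);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (lab(i, j) == 0) continue;
      for (int d = 0; d < 8; ++d) {
        int qi = i + DY8[d], qj = j + DX8[d];
        if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
        int q = qi + qj * nr;
        if (lab(qi, qj) == 0 && !queued[q]) {
          queued[q] = 1;
          pq.push(QNode{grad(qi, qj), ord++, q});
        }
      }
    }
  }
  while (!pq.empty()) {
    QNode nd = pq.top(); pq.pop();
    int pi = nd.idx % nr, pj = nd.idx / nr;
    if (lab(pi, pj) != 0) continue;
    // adopt the label of the first labelled neighbour in fixed scan order
    int l = 0;
    for (int d = 0; d < 8 && l == 0; ++d) {
      int qi = pi + DY8[d], qj = pj + DX8[d];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      l = lab(qi, qj);
    }
    lab(pi, pj) = l;  // l > 0: queue only holds neighbours of labelled pixels
    for (int d = 0; d < 8; ++d) {
      int qi = pi + DY8[d], qj = pj + DX8[d];
      if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
      int q = qi + qj * nr;
      if (lab(qi, qj) == 0 && !queued[q]) {
        queued[q] = 1;
        pq.push(QNode{grad(qi, qj), ord++, q});
      }
    }
  }
  return lab;
}

struct DSU {
  std::vector<int> parent;
  DSU(int k) : parent(k + 1) {
    for (int i = 0; i <= k; ++i) parent[i] = i;
  }
  int find(int x) {
    while (parent[x] != x) {
      parent[x] = parent[parent[x]];
      x = parent[x];
    }
    return x;
  }
};

// Flooding-based superpixel merge at a single threshold Tm. Regions are
// visited in ascending order of current mean intensity; the visited region
// absorbs, one at a time, the adjacent region with the smallest absolute
// mean difference <= Tm (ties to the lowest label), recomputing its
// pixel-area-weighted mean after every absorption. Whole passes repeat until
// no adjacent pair satisfies the criterion. Returns the root label (1..k)
// for every input label; the merged region keeps the lowest member label.
// [[Rcpp::export]]
IntegerVector flood_merge_cpp(int k, NumericVector mean0, NumericVector area0,
                              IntegerMatrix adj_pairs, double Tm) {
  std::vector<double> sum(k + 1), area(k + 1), mean(k + 1);
  for (int i = 1; i <= k; ++i) {
    area[i] = area0[i - 1];
    mean[i] = mean0[i - 1];
    sum[i] = mean[i] * area[i];
  }
  std::vector<std::set<int>> adj(k + 1);
  for (int r = 0; r < adj_pairs.nrow(); ++r) {
    int a = adj_pairs(r, 0), b = adj_pairs(r, 1);
    if (a == b) continue;
    adj[a].insert(b);
    adj[b].insert(a);
  }
  DSU dsu(k);
  const double eps = 1e-9;
  bool changed = true;
  while (changed) {
    changed = false;
    std::vector<int> roots;
    for (int i = 1; i <= k; ++i)
      if (dsu.find(i) == i) roots.push_back(i);
    std::sort(roots.begin(), roots.end(), [&](int a, int b) {
      if (mean[a] != mean[b]) return mean[a] < mean[b];
      return a < b;
    });
    for (size_t t = 0; t < roots.size(); ++t) {
      int r = roots[t];
      if (dsu.find(r) != r) continue;  // absorbed earlier in this pass
      while (true) {
        int best = -1;
        double bestd = 0;
        for (std::set<int>::iterator it = adj[r].begin();
             it != adj[r].end(); ++it) {
          int rn = dsu.find(*it);
          if (rn == r) continue;
          double d = std::fabs(mean[r] - mean[rn]);
          if (d > Tm) continue;
          if (best < 0 || d < bestd - eps ||
              (std::fabs(d - bestd) <= eps && rn < best)) {
            best = rn;
            bestd = d;
          }
        }
        if (best < 0) break;
        int keep = std::min(r, best), lose = std::max(r, best);
        dsu.parent[lose] = keep;
        sum[keep] += sum[lose];
        area[keep] += area[lose];
        mean[keep] = sum[keep] / area[keep];
        if (adj[keep].size() < adj[lose].size()) adj[keep].swap(adj[lose]);
        adj[keep].insert(adj[lose].begin(), adj[lose].end());
        adj[lose].clear();
        r = keep;
        changed = true;
      }
    }
  }
  IntegerVector out(k);
  for (int i = 1; i <= k; ++i) out[i - 1] = dsu.find(i);
  return out;
}
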