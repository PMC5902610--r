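#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Meyer-style seeded watershed: flood the height surface upward from the
// seed labels, restricted to mask. Ties in height are resolved by insertion
// order (scan order for the initial seeds), so the result is deterministic.
struct QNode {
  double h;
  unsigned long order;
  int idx;
  int label;
};
struct QCmp {
  bool operator()(const QNode &a, const QNode &b) const {
    if (a.h != b.h) return a.h > b.h;     // min-heap on height
    return a.order > b.order;             // FIFO among equal heights
  }
};

// [[Rcpp::export]]
IntegerMatrix watershed_seeded_cpp(NumericMatrix height, IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  const int nr = height.nrow(), nc = height.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("height, seeds and mask must share dimensions");

  IntegerMatrix out(nr, nc);
  std::priority_queue<QNode, std::vector<QNode>, QCmp> pq;
  unsigned long counter = 0;

  // seeds claim their pixels outright, even outside the mask
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      int s = seeds(i, j);
      if (s > 0) {
        out(i, j) = s;
        pq.push(QNode{height(i, j), counter++, i + j * nr, s});
      }
    }
  }

  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};

  while (!pq.empty()) {
    QNode nd = pq.top();
    pq.pop();
    int i = nd.idx % nr, j = nd.idx / nr;
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (out(ii, jj) != 0) continue;
      if (!mask(ii, jj)) continue;
      out(ii, jj) = nd.label;
      // Meyer: flood level never recedes
      double h = height(ii, jj);
      if (h < nd.h) h = nd.h;
      pq.push(QNode{h, counter++, ii + jj * nr, nd.label});
    }
  }
  return out;
}

// 8-connected component labeling of a binary mask; labels assigned in
// column-major scan order starting at 1.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, bool eight = true) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix out(nr, nc);
  int next = 0;
  std::vector<int> stack;

  const int di8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nnb = eight ? 8 : 4;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || out(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(i + j * nr);
      out(i, j) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int ci = idx % nr, cj = idx / nr;
        for (int k = 0; k < nnb; ++k) {
          int ii = ci + di8[k], jj = cj + dj8[k];
          if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
          if (!mask(ii, jj) || out(ii, jj) != 0) continue;
          out(ii, jj) = next;
          stack.push_back(ii + jj * nr);
        }
      }
    }
  }
  return out;
}
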