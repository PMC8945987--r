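#include <Rcpp.h>
#include <queue>
#include <vector>

using namespace Rcpp;

// Marker-controlled watershed (Meyer's flooding algorithm) on an elevation
// surface, restricted to a foreground mask.  Basins grow from the seed
// labels in order of increasing elevation; ties are broken by insertion
// order into the priority queue, which makes the result deterministic for
// a fixed input.  Unreached foreground pixels (not mask-connected to any
// seed) keep label 0.

struct QElem {
  double value;
  long long order;
  int idx;
};

struct QCmp {
  bool operator()(const QElem &a, const QElem &b) const {
    if (a.value != b.value) return a.value > b.value;  // min-heap on value
    return a.order > b.order;                          // FIFO on ties
  }
};

// [[Rcpp::export]]
IntegerMatrix seeded_watershed_cpp(NumericMatrix elevation,
                                   IntegerMatrix seeds,
                                   LogicalMatrix mask) {
  const int nr = elevation.nrow(), nc = elevation.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation, seeds and mask must have identical dimensions");

  IntegerMatrix labels(nr, nc);
  std::priority_queue<QElem, std::vector<QElem>, QCmp> pq;
  long long order = 0;

  const int dr[4] = {-1, 1, 0, 0};
  const int dc[4] = {0, 0, -1, 1};

  // seed pixels start labelled; their neighbours enter the queue
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0 && mask(r, c)) {
        labels(r, c) = seeds(r, c);
      }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (labels(r, c) > 0)
        for (int k = 0; k < 4; ++k) {
          int rr = r + dr[k], cc = c + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (!mask(rr, cc) || labels(rr, cc) > 0) continue;
          pq.push({elevation(rr, cc), order++, rr + cc * nr});
        }

  while (!pq.empty()) {
    QElem e = pq.top();
    pq.pop();
    int r = e.idx % nr, c = e.idx / nr;
    if (labels(r, c) > 0) continue;  // already flooded via another path
    // take the label of any already-labelled neighbour (first by scan order)
    int lab = 0;
    for (int k = 0; k < 4 && lab == 0; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (labels(rr, cc) > 0) lab = labels(rr, cc);
    }
    if (lab == 0) continue;  // orphaned queue entry
    labels(r, c) = lab;
    for (int k = 0; k < 4; ++k) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      if (!mask(rr, cc) || labels(rr, cc) > 0) continue;
      pq.push({elevation(rr, cc), order++, rr + cc * nr});
    }
  }
  return labels;
}
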