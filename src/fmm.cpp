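// Multi-label fast marching on a 2D grid with a 4-neighbor first-order
// Godunov upwind stencil and a lazy-deletion binary heap. Each seed starts
// its own front; a pixel is frozen with the arrival time and label of the
// first front to reach it, producing the "stained glass" region partition.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Node {
  double t;
  int r, c, lab;
};

// min-heap ordering; exact ties broken by raster order then label so the
// pop sequence (and hence the partition) is deterministic
struct NodeCmp {
  bool operator()(const Node& a, const Node& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.r != b.r) return a.r > b.r;
    if (a.c != b.c) return a.c > b.c;
    return a.lab > b.lab;
  }
};

enum Status { FAR = 0, BAND = 1, KNOWN = 2 };

// Largest root of the upwind quadratic (T-a)^2 + (T-b)^2 = (h/F)^2 with
// a, b the smaller KNOWN neighbor time on each axis; falls back to the 1D
// update min(a,b) + h/F when the other axis cannot be causal.
inline double upwind_time(double a, double b, double hf) {
  double lo = std::min(a, b), hi = std::max(a, b);
  if (!std::isfinite(lo)) return INF;
  if (!std::isfinite(hi) || hi - lo >= hf) return lo + hf;
  double diff = a - b;
  double disc = 2.0 * hf * hf - diff * diff;
  return 0.5 * ((a + b) + std::sqrt(disc));
}

}  // namespace

// [[Rcpp::export]]
List fmm_march_cpp(NumericMatrix speed, IntegerMatrix seeds,
                   LogicalMatrix domain, bool init_only = false) {
  const int nr = speed.nrow(), nc = speed.ncol();
  const int ns = seeds.nrow();
  NumericMatrix T(nr, nc);
  IntegerMatrix R(nr, nc);            // 0 = unassigned sentinel
  std::vector<unsigned char> status((size_t)nr * nc, FAR);
  std::fill(T.begin(), T.end(), INF);

  auto at = [nr](int r, int c) { return (size_t)c * nr + r; };
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};

  std::priority_queue<Node, std::vector<Node>, NodeCmp> heap;

  // seeds: KNOWN, T = 0, own label (1-based input coordinates and labels)
  for (int s = 0; s < ns; ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("seed outside the image domain");
    if (!domain(r, c)) stop("seed outside the lung mask domain");
    T(r, c) = 0.0;
    R(r, c) = s + 1;
    status[at(r, c)] = KNOWN;
  }
  // narrow band: 4-neighbors of seeds get T = 1/F and the seed's label;
  // iterating seeds in index order makes the lower label win exact ties
  for (int s = 0; s < ns; ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    for (int k = 0; k < 4; ++k) {
      int qr = r + dr4[k], qc = c + dc4[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (!domain(qr, qc) || status[at(qr, qc)] == KNOWN) continue;
      double f = speed(qr, qc);
      if (!(f > 0)) stop("speed must be strictly positive");
      double t = 1.0 / f;
      if (t < T(qr, qc)) {
        T(qr, qc) = t;
        R(qr, qc) = s + 1;
        status[at(qr, qc)] = BAND;
        heap.push({t, qr, qc, s + 1});
      }
    }
  }

  std::vector<double> pops;
  if (!init_only) {
    pops.reserve((size_t)nr * nc);
    while (!heap.empty()) {
      Node nd = heap.top();
      heap.pop();
      if (status[at(nd.r, nd.c)] == KNOWN) continue;  // stale duplicate
      status[at(nd.r, nd.c)] = KNOWN;
      pops.push_back(nd.t);
      for (int k = 0; k < 4; ++k) {
        int qr = nd.r + dr4[k], qc = nd.c + dc4[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (!domain(qr, qc) || status[at(qr, qc)] == KNOWN) continue;
        double f = speed(qr, qc);
        if (!(f > 0)) stop("speed must be strictly positive");
        double hf = 1.0 / f;
        // smaller KNOWN neighbor time per axis, and the label of the
        // overall-minimum KNOWN axis neighbor (ties: lower row, then col)
        double a = INF, b = INF, bestT = INF;
        int bestLab = 0;
        const int raster[4] = {0, 2, 3, 1};  // up, left, right, down
        for (int mi = 0; mi < 4; ++mi) {
          int m = raster[mi];
          int pr = qr + dr4[m], pc = qc + dc4[m];
          if (pr < 0 || pr >= nr || pc < 0 || pc >= nc) continue;
          if (!domain(pr, pc) || status[at(pr, pc)] != KNOWN) continue;
          double tp = T(pr, pc);
          if (m < 2) { if (tp < b) b = tp; }
          else       { if (tp < a) a = tp; }
          if (tp < bestT) { bestT = tp; bestLab = R(pr, pc); }
        }
        double tn = upwind_time(a, b, hf);
        if (tn < T(qr, qc)) {
          T(qr, qc) = tn;
          R(qr, qc) = bestLab;
          status[at(qr, qc)] = BAND;
          heap.push({tn, qr, qc, bestLab});
        }
      }
    }
  }

  IntegerMatrix st(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) st(r, c) = status[at(r, c)];
  int unreached = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (domain(r, c) && !std::isfinite(T(r, c))) ++unreached;

  return List::create(_["T"] = T, _["R"] = R, _["status"] = st,
                      _["pops"] = NumericVector(pops.begin(), pops.end()),
                      _["unreached"] = unreached);
}
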