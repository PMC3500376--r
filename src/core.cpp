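#include <Rcpp.h>
#include <queue>
#include <vector>
#include <limits>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 2004),
// squared distances in cell units. `feature` marks cells distance 0.
// ---------------------------------------------------------------------------

// "absent" cells carry a huge finite penalty instead of Inf so the
// lower-envelope arithmetic stays well defined; grids here are far below
// the scale where 1e20 could be confused with a real squared distance.
static const double DT_LARGE = 1e20;

static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    if (k == 0 && s <= z[0]) s = z[0];
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_squared(LogicalMatrix feature) {
  int nr = feature.nrow(), nc = feature.ncol();
  NumericMatrix g(nr, nc);
  // pass 1: columns
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; c++) {
    for (int r = 0; r < nr; r++) f[r] = feature(r, c) ? 0.0 : DT_LARGE;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; r++) g(r, c) = d[r];
  }
  // pass 2: rows
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) f[c] = g(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; c++) out(r, c) = d[c];
  }
  return out;
}

// ---------------------------------------------------------------------------
// Multi-source Dijkstra on an 8-connected grid.
// Edge weight between neighbouring cells a,b: mean(cost_a, cost_b) * dist,
// dist = cellsize (orthogonal) or cellsize*sqrt(2) (diagonal).
// cost: NA = nodata (cell excluded). sources: 1-based linear indices
// (column-major, R convention). Returns accumulated cost and 1-based
// predecessor index (0 for sources/unreached). Equal-cost ties resolved
// toward the smallest predecessor linear index (deterministic backtracking).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List grid_dijkstra(NumericMatrix cost, IntegerVector sources, double cellsize) {
  int nr = cost.nrow(), nc = cost.ncol();
  int n = nr * nc;
  double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(n, INF);
  std::vector<int> pred(n, 0);
  std::vector<bool> done(n, false);
  const double SQ2 = std::sqrt(2.0);

  typedef std::pair<double, int> PD;
  std::priority_queue<PD, std::vector<PD>, std::greater<PD> > pq;

  for (int i = 0; i < sources.size(); i++) {
    int s = sources[i] - 1;
    if (s < 0 || s >= n) stop("source index out of range");
    if (NumericVector::is_na(cost[s])) stop("source cell is nodata");
    dist[s] = 0.0;
    pq.push(PD(0.0, s));
  }

  int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  while (!pq.empty()) {
    PD top = pq.top();
    pq.pop();
    int u = top.second;
    if (done[u]) continue;
    done[u] = true;
    int r = u % nr, c = u / nr;  // column-major
    double cu = cost[u];
    for (int k = 0; k < 8; k++) {
      int rr = r + dr[k], cc = c + dc[k];
      if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
      int v = rr + cc * nr;
      double cv = cost[v];
      if (NumericVector::is_na(cv)) continue;
      double d = (dr[k] != 0 && dc[k] != 0) ? cellsize * SQ2 : cellsize;
      double w = 0.5 * (cu + cv) * d;
      double nd = dist[u] + w;
      if (nd < dist[v]) {
        dist[v] = nd;
        pred[v] = u + 1;
        pq.push(PD(nd, v));
      } else if (nd == dist[v] && pred[v] > 0 && u + 1 < pred[v]) {
        pred[v] = u + 1;  // tie-break: smallest predecessor index
      }
    }
  }

  NumericVector dout(n);
  IntegerVector pout(n);
  for (int i = 0; i < n; i++) {
    dout[i] = NumericVector::is_na(cost[i]) ? NA_REAL : dist[i];
    pout[i] = pred[i];
  }
  dout.attr("dim") = Dimension(nr, nc);
  return List::create(_["dist"] = dout, _["pred"] = pout);
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a logical mask (8- or 4-neighbourhood).
// Returns integer matrix of labels (0 outside mask), labelled in row-major
// discovery order for determinism.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask, int neighbourhood) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);
  int nnb = (neighbourhood == 4) ? 4 : 8;
  int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  int dr4[4] = {-1, 0, 0, 1};
  int dc4[4] = {0, -1, 1, 0};
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; r++) {
    for (int c = 0; c < nc; c++) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      next++;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        int u = stack.back();
        stack.pop_back();
        int ur = u % nr, uc = u / nr;
        for (int k = 0; k < nnb; k++) {
          int rr = ur + (nnb == 4 ? dr4[k] : dr8[k]);
          int cc = uc + (nnb == 4 ? dc4[k] : dc8[k]);
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * nr);
          }
        }
      }
    }
  }
  return lab;
}
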