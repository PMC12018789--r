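#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Geodesic diameter of a connected binary mask on a 16-neighbourhood pixel
// graph: axial steps cost 1, diagonal sqrt(2), knight moves sqrt(5) (both
// intermediate cells must be foreground, so paths cannot jump gaps).
// Endpoint pairs whose straight segment stays inside the mask are upgraded
// to their exact Euclidean distance, so convex masks yield the exact
// pixel-centre max Feret diameter while folded masks fall back to the
// chamfer geodesic (metric error below 2.8%).

static const int NOFF = 16;
static const int offr[NOFF] = {-1,-1,-1, 0, 0, 1, 1, 1, -1,-1, 1, 1,-2,-2, 2, 2};
static const int offc[NOFF] = {-1, 0, 1,-1, 1,-1, 0, 1, -2, 2,-2, 2,-1, 1,-1, 1};
// knight-move intermediates (two cells nearest the ideal line), -9 = none
static const int midr[NOFF][2] = {{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},
                                  {0,-1},{0,-1},{0,1},{0,1},{-1,-1},{-1,-1},{1,1},{1,1}};
static const int midc[NOFF][2] = {{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},{-9,-9},
                                  {-1,-1},{1,1},{-1,-1},{1,1},{0,-1},{0,1},{0,-1},{0,1}};

static inline double stepcost(int k) {
  if (k < 8) return (offr[k] != 0 && offc[k] != 0) ? std::sqrt(2.0) : 1.0;
  return std::sqrt(5.0);
}

struct QNode {
  double d; int idx;
  bool operator<(const QNode& o) const { return d > o.d; }
};

static void dijkstra(const LogicalMatrix& m, int sr, int sc,
                     std::vector<double>& dist) {
  int nr = m.nrow(), nc = m.ncol();
  std::fill(dist.begin(), dist.end(), R_PosInf);
  std::priority_queue<QNode> pq;
  dist[sr + sc * nr] = 0.0;
  pq.push({0.0, sr + sc * nr});
  while (!pq.empty()) {
    QNode t = pq.top(); pq.pop();
    int r = t.idx % nr, c = t.idx / nr;
    if (t.d > dist[t.idx]) continue;
    for (int k = 0; k < NOFF; ++k) {
      int r2 = r + offr[k], c2 = c + offc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc || !m(r2, c2)) continue;
      if (k >= 8) {
        int ar = r + midr[k][0], ac = c + midc[k][0];
        int br = r + midr[k][1], bc = c + midc[k][1];
        if (!m(ar, ac) || !m(br, bc)) continue;
      }
      double nd = t.d + stepcost(k);
      int idx2 = r2 + c2 * nr;
      if (nd < dist[idx2] - 1e-12) {
        dist[idx2] = nd;
        pq.push({nd, idx2});
      }
    }
  }
}

// straight segment between pixel centres stays inside the mask?
static bool visible(const LogicalMatrix& m, int r1, int c1, int r2, int c2) {
  double dr = r2 - r1, dc = c2 - c1;
  double len = std::sqrt(dr * dr + dc * dc);
  int nstep = (int)std::ceil(len / 0.25);
  for (int s = 1; s < nstep; ++s) {
    double f = (double)s / nstep;
    int rr = (int)std::lround(r1 + f * dr);
    int cc = (int)std::lround(c1 + f * dc);
    if (!m(rr, cc)) return false;
  }
  return true;
}

static std::vector<int> boundary_pixels(const LogicalMatrix& m) {
  int nr = m.nrow(), nc = m.ncol();
  std::vector<int> b;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (!m(r, c)) continue;
      bool edge = (r == 0 || r == nr - 1 || c == 0 || c == nc - 1);
      if (!edge)
        edge = !m(r - 1, c) || !m(r + 1, c) || !m(r, c - 1) || !m(r, c + 1);
      if (edge) b.push_back(r + c * nr);
    }
  return b;
}

// [[Rcpp::export(name = ".geodesic_diameter_cpp")]]
List geodesic_diameter_cpp(LogicalMatrix mask, int exact_limit = 20000) {
  int nr = mask.nrow(), nc = mask.ncol();
  long npix = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) if (mask(r, c)) ++npix;
  if (npix == 0) stop("empty mask");
  if (npix == 1)
    return List::create(_["diameter"] = 0.0, _["exact"] = true);

  std::vector<int> bnd = boundary_pixels(mask);
  int B = (int)bnd.size();
  std::vector<double> dist((size_t)nr * nc);
  double best = 0.0;
  int br1 = -1, bc1 = -1, br2 = -1, bc2 = -1;

  if (npix <= exact_limit) {
    for (int i = 0; i < B; ++i) {
      int r1 = bnd[i] % nr, c1 = bnd[i] / nr;
      dijkstra(mask, r1, c1, dist);
      for (int j = i + 1; j < B; ++j) {
        double d = dist[bnd[j]];
        if (!std::isfinite(d)) stop("mask is not connected");
        int r2 = bnd[j] % nr, c2 = bnd[j] / nr;
        if (visible(mask, r1, c1, r2, c2)) {
          double dr = r2 - r1, dc = c2 - c1;
          d = std::sqrt(dr * dr + dc * dc);
        }
        if (d > best) { best = d; br1 = r1; bc1 = c1; br2 = r2; bc2 = c2; }
      }
    }
    return List::create(_["diameter"] = best, _["exact"] = true,
                        _["from"] = IntegerVector::create(br1 + 1, bc1 + 1),
                        _["to"] = IntegerVector::create(br2 + 1, bc2 + 1));
  }

  // farthest-point sweeps from the first boundary pixel; a few restarts
  int cur = bnd[0];
  for (int sweep = 0; sweep < 4; ++sweep) {
    int r1 = cur % nr, c1 = cur / nr;
    dijkstra(mask, r1, c1, dist);
    double far = -1.0; int faridx = cur;
    for (int j = 0; j < B; ++j) {
      double d = dist[bnd[j]];
      if (!std::isfinite(d)) stop("mask is not connected");
      int r2 = bnd[j] % nr, c2 = bnd[j] / nr;
      if (visible(mask, r1, c1, r2, c2)) {
        double dr = r2 - r1, dc = c2 - c1;
        d = std::sqrt(dr * dr + dc * dc);
      }
      if (d > far) { far = d; faridx = bnd[j]; }
    }
    if (far > best) {
      best = far;
      br1 = r1; bc1 = c1; br2 = faridx % nr; bc2 = faridx / nr;
    }
    if (faridx == cur) break;
    cur = faridx;
  }
  return List::create(_["diameter"] = best, _["exact"] = false,
                      _["from"] = IntegerVector::create(br1 + 1, bc1 + 1),
                      _["to"] = IntegerVector::create(br2 + 1, bc2 + 1));
}
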