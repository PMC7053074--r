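#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <set>
#include <utility>
#include <vector>
using namespace Rcpp;

// Voronoi tessellation of cell centres on a periodic strip (x-periodic with
// the given width, solid base at y = 0, slough boundary at y = ymax).  Each
// cell's region is the bounding box around its centre, pre-clipped to
// 0 <= y <= ymax, cut by the perpendicular-bisector half-planes of nearby
// centres (including periodic images).  Two cells are Delaunay neighbours
// exactly when their regions share an edge, so one sweep yields both
// connectivity and areas.  Candidates come from a uniform grid; a cell
// whose region could reach beyond the grid search radius falls back to an
// all-pairs sweep (sparse regions only).
//
// Returns: edges - two-column 1-based index matrix (i < j) of pairs whose
//                  regions share an edge and whose minimum-image centre
//                  distance does not exceed `cutoff`;
//          areas - region areas, clipped to [0, width] x [0, ymax].

#define MAXV 256

struct Poly {
  double px[MAXV], py[MAXV];
  int lab[MAXV];
  int n;
};

// clip poly by half-plane a . q <= b; edges created on the cut get `label`
static bool clip_halfplane(Poly& in, Poly& out, double ax, double ay,
                           double b, int label) {
  double d[MAXV];
  const int n = in.n;
  for (int k = 0; k < n; ++k) d[k] = ax * in.px[k] + ay * in.py[k] - b;
  int m = 0;
  for (int k = 0; k < n; ++k) {
    int k1 = (k + 1 == n) ? 0 : k + 1;
    bool sin = d[k] <= 0.0, ein = d[k1] <= 0.0;
    if (sin && ein) {
      out.px[m] = in.px[k1];
      out.py[m] = in.py[k1];
      out.lab[m++] = in.lab[k1];
    } else if (sin != ein) {
      double t = d[k] / (d[k] - d[k1]);
      if (m >= MAXV - 2) stop("tessellation polygon overflow");
      out.px[m] = in.px[k] + t * (in.px[k1] - in.px[k]);
      out.py[m] = in.py[k] + t * (in.py[k1] - in.py[k]);
      out.lab[m++] = sin ? label : in.lab[k];
      if (!sin) {
        out.px[m] = in.px[k1];
        out.py[m] = in.py[k1];
        out.lab[m++] = in.lab[k1];
      }
    }
  }
  out.n = m;
  return m > 0;
}

static double poly_area(const Poly& p) {
  double a = 0.0;
  for (int k = 0; k < p.n; ++k) {
    int k1 = (k + 1 == p.n) ? 0 : k + 1;
    a += p.px[k] * p.py[k1] - p.px[k1] * p.py[k];
  }
  return 0.5 * std::fabs(a);
}

struct Cand {
  double d2, cx, cy;
  int j;
};

// clip the region of cell i against the sorted candidate list; returns the
// final polygon (in `a` or `b`) and the max squared vertex distance
static Poly* carve_region(Poly* a, Poly* b, double xi, double yi,
                          std::vector<Cand>& cands, double& maxv2) {
  std::sort(cands.begin(), cands.end(),
            [](const Cand& u, const Cand& v) { return u.d2 < v.d2; });
  maxv2 = 0.0;
  for (int k = 0; k < a->n; ++k) {
    double dx = a->px[k] - xi, dy = a->py[k] - yi;
    double v2 = dx * dx + dy * dy;
    if (v2 > maxv2) maxv2 = v2;
  }
  for (size_t c = 0; c < cands.size(); ++c) {
    if (cands[c].d2 > 4.0 * maxv2) break; // bisector cannot reach polygon
    const double ux = cands[c].cx - xi, uy = cands[c].cy - yi;
    const double bb =
        ux * (xi + cands[c].cx) / 2.0 + uy * (yi + cands[c].cy) / 2.0;
    if (!clip_halfplane(*a, *b, ux, uy, bb, (int)c))
      stop("degenerate geometry: empty Voronoi region");
    std::swap(a, b);
    maxv2 = 0.0;
    for (int k = 0; k < a->n; ++k) {
      double dx = a->px[k] - xi, dy = a->py[k] - yi;
      double v2 = dx * dx + dy * dy;
      if (v2 > maxv2) maxv2 = v2;
    }
  }
  return a;
}

// [[Rcpp::export]]
List tessellation_cpp(NumericVector x, NumericVector y, double width,
                      double ymax, double cutoff) {
  const int n = x.size();
  if (n < 3) stop("tessellation requires at least 3 cells");
  // box half-width: strictly below width/2 so a cell never sees its own image
  const double R = std::min(width / 2.0 * 0.999, 5.0);
  const double cut2 = cutoff * cutoff;

  const double* px_ = REAL(x);
  const double* py_ = REAL(y);

  // uniform grid over the strip for candidate search (flat CSR layout)
  const double bw = 1.0;
  const int nbx = std::max(1, (int)std::ceil(width / bw));
  double ytop = ymax;
  for (int i = 0; i < n; ++i) ytop = std::max(ytop, py_[i]);
  const int nby = std::max(1, (int)std::ceil((ytop + 1e-9) / bw));
  const int nbins = nbx * nby;
  std::vector<int> bin_of(n), bin_start(nbins + 1, 0), bin_items(n);
  for (int i = 0; i < n; ++i) {
    int bx = (int)std::floor(px_[i] / bw);
    bx = ((bx % nbx) + nbx) % nbx;
    int by = std::min(std::max((int)std::floor(py_[i] / bw), 0), nby - 1);
    bin_of[i] = by * nbx + bx;
    ++bin_start[bin_of[i] + 1];
  }
  for (int b = 0; b < nbins; ++b) bin_start[b + 1] += bin_start[b];
  {
    std::vector<int> cursor(bin_start.begin(), bin_start.end() - 1);
    for (int i = 0; i < n; ++i) bin_items[cursor[bin_of[i]]++] = i;
  }
  const int K = 3;                    // grid search ring
  const double rcov = (K - 1) * bw;   // guaranteed coverage radius

  NumericVector areas(n);
  std::set<std::pair<int, int> > edge_set;
  std::vector<Cand> cands;
  cands.reserve(128);
  Poly bufa, bufb;

  for (int i = 0; i < n; ++i) {
    const double xi = px_[i], yi = py_[i];
    const int bx0 = ((int)std::floor(xi / bw) % nbx + nbx) % nbx;
    const int by0 = std::min(std::max((int)std::floor(yi / bw), 0), nby - 1);

    bool fallback = false;
    for (int pass = 0; pass < 2; ++pass) {
      cands.clear();
      if (!fallback) {
        for (int dby = -K; dby <= K; ++dby) {
          int by = by0 + dby;
          if (by < 0 || by >= nby) continue;
          for (int dbx = -K; dbx <= K; ++dbx) {
            int bx = bx0 + dbx;
            bx = (bx % nbx + nbx) % nbx;
            const int b = by * nbx + bx;
            for (int q = bin_start[b]; q < bin_start[b + 1]; ++q) {
              int j = bin_items[q];
              if (j == i) continue;
              double dx = px_[j] - xi;
              dx -= width * std::round(dx / width); // minimum image
              double dy = py_[j] - yi;
              Cand c;
              c.d2 = dx * dx + dy * dy;
              c.cx = xi + dx;
              c.cy = py_[j];
              c.j = j;
              cands.push_back(c);
            }
          }
        }
      } else {
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          for (int s = -1; s <= 1; ++s) {
            const double cx = px_[j] + s * width;
            const double dx = cx - xi, dy = py_[j] - yi;
            if (std::fabs(dx) > 2.0 * R || std::fabs(dy) > 2.0 * R) continue;
            Cand c;
            c.d2 = dx * dx + dy * dy;
            c.cx = cx;
            c.cy = py_[j];
            c.j = j;
            cands.push_back(c);
          }
        }
      }

      // bounding box pre-clipped to the strip 0 <= y <= ymax' (ymax, or the
      // top-most centre for transiently overshooting cells)
      bufa.n = 4;
      double ylo = std::max(yi - R, 0.0);
      double yhi = std::min(yi + R, std::max(ytop, ymax));
      bufa.px[0] = xi - R; bufa.py[0] = ylo; bufa.lab[0] = -1;
      bufa.px[1] = xi + R; bufa.py[1] = ylo; bufa.lab[1] = -2;
      bufa.px[2] = xi + R; bufa.py[2] = yhi; bufa.lab[2] = -3;
      bufa.px[3] = xi - R; bufa.py[3] = yhi; bufa.lab[3] = -4;

      double maxv2;
      Poly* poly = carve_region(&bufa, &bufb, xi, yi, cands, maxv2);

      // grid pass is only valid if no centre beyond the coverage radius
      // could have clipped the region
      if (!fallback && 4.0 * maxv2 > rcov * rcov) {
        fallback = true;
        continue;
      }

      // neighbours: candidates owning a polygon edge of nonzero length
      for (int k = 0; k < poly->n; ++k) {
        int lb = poly->lab[k];
        if (lb < 0) continue;
        int k1 = (k + 1 == poly->n) ? 0 : k + 1;
        double ex = poly->px[k1] - poly->px[k];
        double ey = poly->py[k1] - poly->py[k];
        if (ex * ex + ey * ey < 1e-18) continue;
        if (cands[lb].d2 > cut2) continue;
        int j = cands[lb].j;
        edge_set.insert(
            std::make_pair(std::min(i, j) + 1, std::max(i, j) + 1));
      }
      // area within the crypt domain
      if (ytop > ymax) {
        clip_halfplane(*poly, bufb, 0.0, 1.0, ymax, -6);
        areas[i] = poly_area(bufb);
      } else {
        areas[i] = poly_area(*poly);
      }
      break;
    }
  }

  IntegerMatrix edges(edge_set.size(), 2);
  int r = 0;
  for (std::set<std::pair<int, int> >::const_iterator it = edge_set.begin();
       it != edge_set.end(); ++it, ++r) {
    edges(r, 0) = it->first;
    edges(r, 1) = it->second;
  }
  return List::create(_["edges"] = edges, _["areas"] = areas);
}

// Net spring forces over an edge list with per-edge rest lengths.
// Positions are x-periodic; displacement uses the minimum image.
// [[Rcpp::export]]
NumericMatrix net_forces_cpp(NumericVector x, NumericVector y,
                             IntegerMatrix edges, NumericVector rest,
                             double mu, double width) {
  const int n = x.size(), m = edges.nrow();
  const double* px = REAL(x);
  const double* py = REAL(y);
  NumericMatrix F(n, 2);
  double* fx = REAL(F);
  double* fy = fx + n;
  for (int e = 0; e < m; ++e) {
    const int i = edges(e, 0) - 1, j = edges(e, 1) - 1;
    double dx = px[j] - px[i];
    dx -= width * std::round(dx / width);
    const double dy = py[j] - py[i];
    const double len = std::sqrt(dx * dx + dy * dy);
    if (len < 1e-12) stop("coincident cell centres in edge set");
    const double f = mu * (len - rest[e]) / len;
    fx[i] += f * dx;
    fy[i] += f * dy;
    fx[j] -= f * dx;
    fy[j] -= f * dy;
  }
  return F;
}
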