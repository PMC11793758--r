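#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

// Closest point on triangle (a,b,c) to p, after Ericson, "Real-Time
// Collision Detection", ch. 5.1.5.  Writes the closest point into `out`
// and barycentric coordinates (w.r.t. a,b,c) into `bary`.
static inline void closest_pt_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out, double *bary) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) {
    ab[k] = b[k] - a[k];
    ac[k] = c[k] - a[k];
    ap[k] = p[k] - a[k];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    for (int k = 0; k < 3; ++k) out[k] = a[k];
    bary[0] = 1.0; bary[1] = 0.0; bary[2] = 0.0;
    return;
  }
  double bp[3];
  for (int k = 0; k < 3; ++k) bp[k] = p[k] - b[k];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) {
    for (int k = 0; k < 3; ++k) out[k] = b[k];
    bary[0] = 0.0; bary[1] = 1.0; bary[2] = 0.0;
    return;
  }
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + v * ab[k];
    bary[0] = 1.0 - v; bary[1] = v; bary[2] = 0.0;
    return;
  }
  double cp[3];
  for (int k = 0; k < 3; ++k) cp[k] = p[k] - c[k];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) {
    for (int k = 0; k < 3; ++k) out[k] = c[k];
    bary[0] = 0.0; bary[1] = 0.0; bary[2] = 1.0;
    return;
  }
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int k = 0; k < 3; ++k) out[k] = a[k] + w * ac[k];
    bary[0] = 1.0 - w; bary[1] = 0.0; bary[2] = w;
    return;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int k = 0; k < 3; ++k) out[k] = b[k] + w * (c[k] - b[k]);
    bary[0] = 0.0; bary[1] = 1.0 - w; bary[2] = w;
    return;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int k = 0; k < 3; ++k) out[k] = a[k] + ab[k] * v + ac[k] * w;
  bary[0] = 1.0 - v - w; bary[1] = v; bary[2] = w;
}

struct UniformGrid {
  double origin[3];
  double cell;
  int dims[3];
  // CSR layout: cells[start[c] .. start[c+1]) holds triangle ids of cell c
  std::vector<int> start;
  std::vector<int> tris;
  int ncells() const { return dims[0] * dims[1] * dims[2]; }
  inline int flat(int ix, int iy, int iz) const {
    return ix + dims[0] * (iy + dims[1] * iz);
  }
  inline void cell_of(const double *p, int *c) const {
    for (int k = 0; k < 3; ++k) {
      int i = (int)std::floor((p[k] - origin[k]) / cell);
      if (i < 0) i = 0;
      if (i >= dims[k]) i = dims[k] - 1;
      c[k] = i;
    }
  }
};

static void build_grid(const std::vector<double> &V, const std::vector<int> &F,
                       UniformGrid &g) {
  const int nv = (int)V.size() / 3, nf = (int)F.size() / 3;
  double lo[3], hi[3];
  for (int k = 0; k < 3; ++k) { lo[k] = R_PosInf; hi[k] = R_NegInf; }
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) {
      double x = V[3 * i + k];
      if (x < lo[k]) lo[k] = x;
      if (x > hi[k]) hi[k] = x;
    }
  // cell size: twice the mean triangle AABB max-extent (never zero)
  double mean_ext = 0.0;
  for (int f = 0; f < nf; ++f) {
    double ext = 0.0;
    for (int k = 0; k < 3; ++k) {
      double a = V[3 * F[3 * f] + k], b = V[3 * F[3 * f + 1] + k],
             c = V[3 * F[3 * f + 2] + k];
      double mx = std::max(a, std::max(b, c));
      double mn = std::min(a, std::min(b, c));
      ext = std::max(ext, mx - mn);
    }
    mean_ext += ext;
  }
  mean_ext /= std::max(nf, 1);
  double diag = 0.0;
  for (int k = 0; k < 3; ++k) diag = std::max(diag, hi[k] - lo[k]);
  double cell = 2.0 * mean_ext;
  if (cell <= 0.0) cell = (diag > 0.0 ? diag : 1.0);
  // cap grid at 192^3 cells
  for (int k = 0; k < 3; ++k) {
    double need = (hi[k] - lo[k]) / cell;
    if (need > 192.0) cell = (hi[k] - lo[k]) / 192.0;
  }
  g.cell = cell;
  for (int k = 0; k < 3; ++k) {
    g.origin[k] = lo[k];
    g.dims[k] = std::max(1, (int)std::ceil((hi[k] - lo[k]) / cell + 1e-9));
  }
  const int nc = g.ncells();
  std::vector<int> count(nc, 0);
  std::vector<int> c0(3), c1(3);
  for (int pass = 0; pass < 2; ++pass) {
    if (pass == 1) {
      g.start.assign(nc + 1, 0);
      for (int c = 0; c < nc; ++c) g.start[c + 1] = g.start[c] + count[c];
      g.tris.assign(g.start[nc], 0);
      std::fill(count.begin(), count.end(), 0);
    }
    for (int f = 0; f < nf; ++f) {
      double lo3[3], hi3[3];
      for (int k = 0; k < 3; ++k) {
        double a = V[3 * F[3 * f] + k], b = V[3 * F[3 * f + 1] + k],
               c = V[3 * F[3 * f + 2] + k];
        lo3[k] = std::min(a, std::min(b, c));
        hi3[k] = std::max(a, std::max(b, c));
      }
      int cl[3], ch[3];
      g.cell_of(lo3, cl);
      g.cell_of(hi3, ch);
      for (int iz = cl[2]; iz <= ch[2]; ++iz)
        for (int iy = cl[1]; iy <= ch[1]; ++iy)
          for (int ix = cl[0]; ix <= ch[0]; ++ix) {
            int c = g.flat(ix, iy, iz);
            if (pass == 0) count[c]++;
            else g.tris[g.start[c] + count[c]++] = f;
          }
    }
  }
}

// [[Rcpp::export]]
List cpp_nearest_points(NumericMatrix V, IntegerMatrix F, NumericMatrix Q) {
  const int nv = V.nrow(), nf = F.nrow(), nq = Q.nrow();
  if (nf == 0) stop("reference mesh has no faces");
  // contiguous row-major copies: the query loop must not pay the Rcpp
  // element-accessor cost
  std::vector<double> Vr(3 * (size_t)nv);
  for (int i = 0; i < nv; ++i)
    for (int k = 0; k < 3; ++k) Vr[3 * i + k] = V(i, k);
  std::vector<int> Fr(3 * (size_t)nf);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) Fr[3 * f + k] = F(f, k);
  UniformGrid g;
  build_grid(Vr, Fr, g);

  NumericMatrix closest(nq, 3), bary(nq, 3);
  IntegerVector face(nq);
  NumericVector dist(nq);
  std::vector<int> stamp(nf, -1);

  int maxring = std::max(g.dims[0], std::max(g.dims[1], g.dims[2]));
  double p[3], out[3], bc[3], bout[3], bbc[3];

  for (int q = 0; q < nq; ++q) {
    p[0] = Q(q, 0); p[1] = Q(q, 1); p[2] = Q(q, 2);
    int cc[3];
    g.cell_of(p, cc);
    double best = R_PosInf;
    int bestf = -1;
    // expand rings; once a candidate exists keep going while a nearer
    // triangle could still hide in an unvisited ring
    for (int r = 0; r <= maxring; ++r) {
      if (bestf >= 0 && (double)(r - 1) * g.cell > best) break;
      int xl = std::max(cc[0] - r, 0), xh = std::min(cc[0] + r, g.dims[0] - 1);
      int yl = std::max(cc[1] - r, 0), yh = std::min(cc[1] + r, g.dims[1] - 1);
      int zl = std::max(cc[2] - r, 0), zh = std::min(cc[2] + r, g.dims[2] - 1);
      for (int iz = zl; iz <= zh; ++iz)
        for (int iy = yl; iy <= yh; ++iy)
          for (int ix = xl; ix <= xh; ++ix) {
            // only the shell of the ring (interior already visited)
            int ring = std::max(std::abs(ix - cc[0]),
                       std::max(std::abs(iy - cc[1]), std::abs(iz - cc[2])));
            if (ring != r) continue;
            int cell = g.flat(ix, iy, iz);
            for (int t = g.start[cell]; t < g.start[cell + 1]; ++t) {
              int f = g.tris[t];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              const double *a = &Vr[3 * (size_t)Fr[3 * f]];
              const double *b = &Vr[3 * (size_t)Fr[3 * f + 1]];
              const double *c = &Vr[3 * (size_t)Fr[3 * f + 2]];
              closest_pt_triangle(p, a, b, c, out, bc);
              double d2 = 0.0;
              for (int k = 0; k < 3; ++k) {
                double dk = p[k] - out[k];
                d2 += dk * dk;
              }
              double d = std::sqrt(d2);
              if (d < best) {
                best = d;
                bestf = f;
                for (int k = 0; k < 3; ++k) { bout[k] = out[k]; bbc[k] = bc[k]; }
              }
            }
          }
    }
    face[q] = bestf + 1;  // 1-based for R
    dist[q] = best;
    for (int k = 0; k < 3; ++k) {
      closest(q, k) = bout[k];
      bary(q, k) = bbc[k];
    }
  }
  return List::create(_["point"] = closest, _["face"] = face,
                      _["distance"] = dist, _["bary"] = bary);
}
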