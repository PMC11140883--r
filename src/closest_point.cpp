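#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to point p. Ericson, Real-Time
// Collision Detection, 5.1.5. Writes the foot point into out[3].
static inline double closest_on_tri(const double *p,
                                    const double *a, const double *b,
                                    const double *c, double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) {
    out[0] = a[0]; out[1] = a[1]; out[2] = a[2];
  } else {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) {
      out[0] = b[0]; out[1] = b[1]; out[2] = b[2];
    } else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        for (int i = 0; i < 3; ++i) out[i] = a[i] + v*ab[i];
      } else {
        double cp[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
        double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
        double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
        if (d6 >= 0.0 && d5 <= d6) {
          out[0] = c[0]; out[1] = c[1]; out[2] = c[2];
        } else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            for (int i = 0; i < 3; ++i) out[i] = a[i] + w*ac[i];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              for (int i = 0; i < 3; ++i) out[i] = b[i] + w*(c[i]-b[i]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i]*v + ac[i]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-out[0], dy = p[1]-out[1], dz = p[2]-out[2];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

struct Grid {
  double lo[3], cell;
  int dim[3];
  std::vector< std::vector<int> > bins;
  int idx(int i, int j, int k) const { return (k*dim[1] + j)*dim[0] + i; }
};

// Build a uniform grid over triangle AABBs.
static void build_grid(const NumericMatrix &V, const IntegerMatrix &F,
                       const std::vector<int> &tris, Grid &g) {
  const int n = V.nrow();
  double hi[3];
  for (int c = 0; c < 3; ++c) { g.lo[c] = R_PosInf; hi[c] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int c = 0; c < 3; ++c) {
      double v = V(i, c);
      if (v < g.lo[c]) g.lo[c] = v;
      if (v > hi[c]) hi[c] = v;
    }
  double ext = 0.0;
  for (int c = 0; c < 3; ++c) ext = std::max(ext, hi[c] - g.lo[c]);
  if (ext <= 0.0) ext = 1.0;
  int m = (int) tris.size();
  int res = (int) std::ceil(std::cbrt((double) std::max(m, 1)));
  res = std::min(std::max(res, 1), 64);
  g.cell = ext / res * 1.000001;
  for (int c = 0; c < 3; ++c) {
    g.dim[c] = std::max(1, (int) std::ceil((hi[c] - g.lo[c]) / g.cell));
    g.lo[c] -= 1e-9 * ext;
  }
  g.bins.assign((size_t) g.dim[0] * g.dim[1] * g.dim[2], std::vector<int>());
  for (size_t t = 0; t < tris.size(); ++t) {
    int f = tris[t];
    double tlo[3] = {R_PosInf, R_PosInf, R_PosInf};
    double thi[3] = {R_NegInf, R_NegInf, R_NegInf};
    for (int k = 0; k < 3; ++k) {
      int vi = F(f, k);
      for (int c = 0; c < 3; ++c) {
        double v = V(vi, c);
        if (v < tlo[c]) tlo[c] = v;
        if (v > thi[c]) thi[c] = v;
      }
    }
    int i0[3], i1[3];
    for (int c = 0; c < 3; ++c) {
      i0[c] = std::min(std::max((int)((tlo[c]-g.lo[c])/g.cell), 0), g.dim[c]-1);
      i1[c] = std::min(std::max((int)((thi[c]-g.lo[c])/g.cell), 0), g.dim[c]-1);
    }
    for (int k = i0[2]; k <= i1[2]; ++k)
      for (int j = i0[1]; j <= i1[1]; ++j)
        for (int i = i0[0]; i <= i1[0]; ++i)
          g.bins[g.idx(i, j, k)].push_back(f);
  }
}

// Closest points on a triangle mesh for a block of query points.
// V: n x 3 vertices, F: m x 3 zero-based faces, valid: length-m flag
// (degenerate faces are skipped), Q: q x 3 queries.
// Ties broken toward the lowest face index.
// [[Rcpp::export]]
List cp_mesh_query(NumericMatrix V, IntegerMatrix F, LogicalVector valid,
                   NumericMatrix Q) {
  int m = F.nrow(), q = Q.nrow();
  std::vector<int> tris;
  tris.reserve(m);
  for (int f = 0; f < m; ++f) if (valid[f]) tris.push_back(f);
  if (tris.empty()) stop("mesh has no non-degenerate faces");

  Grid g;
  build_grid(V, F, tris, g);

  NumericVector dist(q);
  IntegerVector face(q);
  NumericMatrix foot(q, 3);
  std::vector<uint8_t> seen((size_t) m, 0);
  std::vector<int> touched;
  touched.reserve(256);

  int maxshell = g.dim[0] + g.dim[1] + g.dim[2] + 2;
  for (int iq = 0; iq < q; ++iq) {
    double p[3] = {Q(iq,0), Q(iq,1), Q(iq,2)};
    int ci[3];
    for (int c = 0; c < 3; ++c)
      ci[c] = std::min(std::max((int)((p[c]-g.lo[c])/g.cell), 0), g.dim[c]-1);
    double best = R_PosInf;
    int bestf = -1;
    double bestp[3] = {0,0,0};
    touched.clear();
    std::vector<int> cand;
    for (int shell = 0; shell < maxshell; ++shell) {
      // once every cell within Chebyshev radius (shell-1) is processed,
      // unseen triangles are at least (shell-1)*cell away
      if (bestf >= 0 && (double)(shell - 1) * g.cell > best) break;
      cand.clear();
      int i0 = std::max(ci[0]-shell, 0), i1 = std::min(ci[0]+shell, g.dim[0]-1);
      int j0 = std::max(ci[1]-shell, 0), j1 = std::min(ci[1]+shell, g.dim[1]-1);
      int k0 = std::max(ci[2]-shell, 0), k1 = std::min(ci[2]+shell, g.dim[2]-1);
      for (int k = k0; k <= k1; ++k)
        for (int j = j0; j <= j1; ++j)
          for (int i = i0; i <= i1; ++i) {
            // only the new shell surface
            if (shell > 0 &&
                std::abs(i-ci[0]) != shell && std::abs(j-ci[1]) != shell &&
                std::abs(k-ci[2]) != shell) continue;
            const std::vector<int> &bin = g.bins[g.idx(i,j,k)];
            for (size_t b = 0; b < bin.size(); ++b) {
              int f = bin[b];
              if (!seen[f]) { seen[f] = 1; touched.push_back(f); cand.push_back(f); }
            }
          }
      std::sort(cand.begin(), cand.end());
      double out[3];
      for (size_t b = 0; b < cand.size(); ++b) {
        int f = cand[b];
        int v0 = F(f,0), v1 = F(f,1), v2 = F(f,2);
        double a[3] = {V(v0,0), V(v0,1), V(v0,2)};
        double bb[3] = {V(v1,0), V(v1,1), V(v1,2)};
        double cc[3] = {V(v2,0), V(v2,1), V(v2,2)};
        double d = closest_on_tri(p, a, bb, cc, out);
        if (d < best) {
          best = d; bestf = f;
          bestp[0] = out[0]; bestp[1] = out[1]; bestp[2] = out[2];
        }
      }
      // all cells already covered
      if (i0 == 0 && j0 == 0 && k0 == 0 &&
          i1 == g.dim[0]-1 && j1 == g.dim[1]-1 && k1 == g.dim[2]-1 &&
          bestf >= 0) break;
    }
    for (size_t t = 0; t < touched.size(); ++t) seen[touched[t]] = 0;
    dist[iq] = best;
    face[iq] = bestf + 1;  // 1-based for R
    foot(iq,0) = bestp[0]; foot(iq,1) = bestp[1]; foot(iq,2) = bestp[2];
  }
  return List::create(_["distance"] = dist, _["face"] = face,
                      _["foot"] = foot);
}

// Maximum pairwise distance (caliper diameter) over a point set.
// Returns the distance and the achieving 1-based index pair.
// [[Rcpp::export]]
List cp_diameter(NumericMatrix P) {
  int n = P.nrow();
  if (n < 2) stop("need at least two points");
  double best = -1.0;
  int bi = 0, bj = 1;
  for (int i = 0; i < n - 1; ++i) {
    double xi = P(i,0), yi = P(i,1), zi = P(i,2);
    for (int j = i + 1; j < n; ++j) {
      double dx = P(j,0)-xi, dy = P(j,1)-yi, dz = P(j,2)-zi;
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > best) { best = d2; bi = i; bj = j; }
    }
  }
  return List::create(_["diameter"] = std::sqrt(best),
                      _["i"] = bi + 1, _["j"] = bj + 1);
}
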