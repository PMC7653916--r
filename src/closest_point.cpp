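#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, 5.1.5. Writes result into out[3].
static inline void closestOnTri(const double *p, const double *a,
                                const double *b, const double *c,
                                double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
  double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1*d4 - d3*d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = (d1 - d3 != 0.0) ? d1 / (d1 - d3) : 0.0;
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0]*cp[0] + ab[1]*cp[1] + ab[2]*cp[2];
  double d6 = ac[0]*cp[0] + ac[1]*cp[1] + ac[2]*cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5*d2 - d1*d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = (d2 - d6 != 0.0) ? d2 / (d2 - d6) : 0.0;
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3*d6 - d5*d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double denom = (d4 - d3) + (d5 - d6);
    double w = (denom != 0.0) ? (d4 - d3) / denom : 0.0;
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = va + vb + vc;
  double v = vb / denom, w = vc / denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// For each query point, the closest point on the triangle mesh (V, F).
// F is 1-based. Per-face bounding spheres give a quick reject, so the scan
// over faces is cheap once a good candidate is known.
// [[Rcpp::export]]
List cpp_closest_point(NumericMatrix query, NumericMatrix V, IntegerMatrix F) {
  const int nq = query.nrow(), nf = F.nrow(), nv = V.nrow();
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) { vx[i] = V(i,0); vy[i] = V(i,1); vz[i] = V(i,2); }

  std::vector<double> cx(nf), cy(nf), cz(nf), rad(nf);
  std::vector<int> ia(nf), ib(nf), ic(nf);
  for (int f = 0; f < nf; ++f) {
    int a = F(f,0) - 1, b = F(f,1) - 1, c = F(f,2) - 1;
    ia[f] = a; ib[f] = b; ic[f] = c;
    cx[f] = (vx[a] + vx[b] + vx[c]) / 3.0;
    cy[f] = (vy[a] + vy[b] + vy[c]) / 3.0;
    cz[f] = (vz[a] + vz[b] + vz[c]) / 3.0;
    double r2 = 0.0;
    const int idx[3] = {a, b, c};
    for (int k = 0; k < 3; ++k) {
      double dx = vx[idx[k]] - cx[f], dy = vy[idx[k]] - cy[f],
             dz = vz[idx[k]] - cz[f];
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 > r2) r2 = d2;
    }
    rad[f] = std::sqrt(r2);
  }

  NumericMatrix foot(nq, 3);
  NumericVector dist(nq);
  IntegerVector face(nq);
  double tri_a[3], tri_b[3], tri_c[3], p[3], out[3];

  for (int q = 0; q < nq; ++q) {
    p[0] = query(q,0); p[1] = query(q,1); p[2] = query(q,2);
    double best = R_PosInf; int bestf = -1;
    double bx = 0, by = 0, bz = 0;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0] - cx[f], dy = p[1] - cy[f], dz = p[2] - cz[f];
      double dcen = std::sqrt(dx*dx + dy*dy + dz*dz);
      double lower = dcen - rad[f];
      if (lower > 0.0 && lower * lower >= best) continue;
      tri_a[0] = vx[ia[f]]; tri_a[1] = vy[ia[f]]; tri_a[2] = vz[ia[f]];
      tri_b[0] = vx[ib[f]]; tri_b[1] = vy[ib[f]]; tri_b[2] = vz[ib[f]];
      tri_c[0] = vx[ic[f]]; tri_c[1] = vy[ic[f]]; tri_c[2] = vz[ic[f]];
      closestOnTri(p, tri_a, tri_b, tri_c, out);
      double ex = out[0]-p[0], ey = out[1]-p[1], ez = out[2]-p[2];
      double d2 = ex*ex + ey*ey + ez*ez;
      if (d2 < best) {
        best = d2; bestf = f; bx = out[0]; by = out[1]; bz = out[2];
      }
    }
    foot(q,0) = bx; foot(q,1) = by; foot(q,2) = bz;
    dist[q] = std::sqrt(best);
    face[q] = bestf + 1;
  }
  return List::create(_["point"] = foot, _["distance"] = dist,
                      _["face"] = face);
}
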