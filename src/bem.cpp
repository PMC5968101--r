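// Double-layer BEM assembly for the EEG forward problem.
//
// Collocation at mesh vertices with linear (hat) interpolation of the surface
// potential. Triangle integrals of the solid-angle kernel are computed by an
// adaptive midpoint quadrature whose constant part is corrected to the exact
// van Oosterom-Strackee triangle solid angle; the self (vertex-adjacent) lump
// is fixed by the interior 4*pi identity, which makes the discrete operator
// exact on constants.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double dot3(const double* a, const double* b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

static inline void cross3(const double* a, const double* b, double* out) {
  out[0] = a[1] * b[2] - a[2] * b[1];
  out[1] = a[2] * b[0] - a[0] * b[2];
  out[2] = a[0] * b[1] - a[1] * b[0];
}

// Signed solid angle of triangle (y1, y2, y3) as seen from the origin
// (van Oosterom & Strackee 1983). Positive when the outward normal implied by
// the vertex order points away from the origin.
static double solid_angle(const double* y1, const double* y2,
                          const double* y3) {
  double n1 = std::sqrt(dot3(y1, y1));
  double n2 = std::sqrt(dot3(y2, y2));
  double n3 = std::sqrt(dot3(y3, y3));
  double cr[3];
  cross3(y2, y3, cr);
  double num = dot3(y1, cr);
  double den = n1 * n2 * n3 + dot3(y1, y2) * n3 + dot3(y1, y3) * n2 +
               dot3(y2, y3) * n1;
  return 2.0 * std::atan2(num, den);
}

// Accumulate \int_T h_k dOmega for the three linear hat functions of the
// parent triangle, by recursive subdivision + 3-point midpoint rule.
// Corners carry their parent-barycentric coordinates.
static void hat_quadrature(const double y[3][3], const double bary[3][3],
                           int depth, double w[3]) {
  double e1 = 0, e2 = 0, e3 = 0;
  for (int d = 0; d < 3; ++d) {
    double a = y[1][d] - y[0][d];
    double b = y[2][d] - y[1][d];
    double c = y[0][d] - y[2][d];
    e1 += a * a; e2 += b * b; e3 += c * c;
  }
  double maxedge = std::sqrt(std::max(e1, std::max(e2, e3)));
  double cen[3] = {(y[0][0] + y[1][0] + y[2][0]) / 3.0,
                   (y[0][1] + y[1][1] + y[2][1]) / 3.0,
                   (y[0][2] + y[1][2] + y[2][2]) / 3.0};
  double dist = std::sqrt(dot3(cen, cen));
  if (depth < 4 && dist < 1.5 * maxedge) {
    double m12[3], m23[3], m31[3], b12[3], b23[3], b31[3];
    for (int d = 0; d < 3; ++d) {
      m12[d] = 0.5 * (y[0][d] + y[1][d]);
      m23[d] = 0.5 * (y[1][d] + y[2][d]);
      m31[d] = 0.5 * (y[2][d] + y[0][d]);
      b12[d] = 0.5 * (bary[0][d] + bary[1][d]);
      b23[d] = 0.5 * (bary[1][d] + bary[2][d]);
      b31[d] = 0.5 * (bary[2][d] + bary[0][d]);
    }
    double ys[3][3], bs[3][3];
#define SUB(p1, q1, p2, q2, p3, q3)                                     \
    for (int d = 0; d < 3; ++d) {                                       \
      ys[0][d] = p1[d]; bs[0][d] = q1[d];                               \
      ys[1][d] = p2[d]; bs[1][d] = q2[d];                               \
      ys[2][d] = p3[d]; bs[2][d] = q3[d];                               \
    }                                                                   \
    hat_quadrature(ys, bs, depth + 1, w);
    SUB(y[0], bary[0], m12, b12, m31, b31)
    SUB(y[1], bary[1], m23, b23, m12, b12)
    SUB(y[2], bary[2], m31, b31, m23, b23)
    SUB(m12, b12, m23, b23, m31, b31)
#undef SUB
    return;
  }
  // leaf: 3 edge-midpoint quadrature points, area vector N = 0.5 (e1 x e2)
  double u[3], v[3], N[3];
  for (int d = 0; d < 3; ++d) {
    u[d] = y[1][d] - y[0][d];
    v[d] = y[2][d] - y[0][d];
  }
  cross3(u, v, N);
  N[0] *= 0.5; N[1] *= 0.5; N[2] *= 0.5;
  const double* pts[3][2] = {{y[0], y[1]}, {y[1], y[2]}, {y[2], y[0]}};
  const double* bpt[3][2] = {{bary[0], bary[1]}, {bary[1], bary[2]},
                             {bary[2], bary[0]}};
  for (int q = 0; q < 3; ++q) {
    double m[3], hb[3];
    for (int d = 0; d < 3; ++d) {
      m[d] = 0.5 * (pts[q][0][d] + pts[q][1][d]);
      hb[d] = 0.5 * (bpt[q][0][d] + bpt[q][1][d]);
    }
    double r3 = std::pow(dot3(m, m), 1.5);
    if (r3 <= 0) continue;
    double k = dot3(m, N) / r3 / 3.0;  // kernel * (1/3 weight)
    w[0] += k * hb[0];
    w[1] += k * hb[1];
    w[2] += k * hb[2];
  }
}

// [[Rcpp::export]]
NumericMatrix bem_assemble_dl(NumericMatrix verts, IntegerMatrix faces,
                              IntegerVector vert_surface,
                              IntegerVector face_surface) {
  const int nv = verts.nrow();
  const int nf = faces.nrow();
  NumericMatrix D(nv, nv);
  const double fourpi = 4.0 * M_PI;
  std::vector<double> vx(nv), vy(nv), vz(nv);
  for (int i = 0; i < nv; ++i) {
    vx[i] = verts(i, 0); vy[i] = verts(i, 1); vz[i] = verts(i, 2);
  }
  for (int i = 0; i < nv; ++i) {
    double r[3] = {vx[i], vy[i], vz[i]};
    double lump = fourpi;
    int si = vert_surface[i];
    for (int t = 0; t < nf; ++t) {
      int a = faces(t, 0), b = faces(t, 1), c = faces(t, 2);
      if (a == i || b == i || c == i) continue;  // flat limit; handled by lump
      double y[3][3] = {{vx[a] - r[0], vy[a] - r[1], vz[a] - r[2]},
                        {vx[b] - r[0], vy[b] - r[1], vz[b] - r[2]},
                        {vx[c] - r[0], vy[c] - r[1], vz[c] - r[2]}};
      double omega = solid_angle(y[0], y[1], y[2]);
      double bary[3][3] = {{1, 0, 0}, {0, 1, 0}, {0, 0, 1}};
      double w[3] = {0, 0, 0};
      hat_quadrature(y, bary, 0, w);
      double corr = (omega - (w[0] + w[1] + w[2])) / 3.0;
      D(i, a) += w[0] + corr;
      D(i, b) += w[1] + corr;
      D(i, c) += w[2] + corr;
      if (face_surface[t] == si) lump -= omega;
    }
    D(i, i) += lump;
  }
  return D;
}

// Total solid angle of a closed mesh seen from query points (4*pi inside,
// 0 outside).
// [[Rcpp::export]]
NumericVector bem_solid_angle_total(NumericMatrix verts, IntegerMatrix faces,
                                    NumericMatrix points) {
  const int nf = faces.nrow();
  const int np = points.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double r[3] = {points(p, 0), points(p, 1), points(p, 2)};
    double acc = 0;
    for (int t = 0; t < nf; ++t) {
      int a = faces(t, 0), b = faces(t, 1), c = faces(t, 2);
      double y1[3] = {verts(a, 0) - r[0], verts(a, 1) - r[1],
                      verts(a, 2) - r[2]};
      double y2[3] = {verts(b, 0) - r[0], verts(b, 1) - r[1],
                      verts(b, 2) - r[2]};
      double y3[3] = {verts(c, 0) - r[0], verts(c, 1) - r[1],
                      verts(c, 2) - r[2]};
      acc += solid_angle(y1, y2, y3);
    }
    out[p] = acc;
  }
  return out;
}
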