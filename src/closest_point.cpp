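#include <Rcpp.h>
using namespace Rcpp;

// Closest point on a triangle (a,b,c) to point p.
// Region-based method: project onto the plane and clamp to edges/vertices.
static inline void closest_on_triangle(const double *p, const double *a,
                                       const double *b, const double *c,
                                       double *out) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ac[i] = c[i] - a[i];
    ap[i] = p[i] - a[i];
  }
  double d1 = ab[0] * ap[0] + ab[1] * ap[1] + ab[2] * ap[2];
  double d2 = ac[0] * ap[0] + ac[1] * ap[1] + ac[2] * ap[2];
  if (d1 <= 0.0 && d2 <= 0.0) { for (int i = 0; i < 3; ++i) out[i] = a[i]; return; }

  double bp[3];
  for (int i = 0; i < 3; ++i) bp[i] = p[i] - b[i];
  double d3 = ab[0] * bp[0] + ab[1] * bp[1] + ab[2] * bp[2];
  double d4 = ac[0] * bp[0] + ac[1] * bp[1] + ac[2] * bp[2];
  if (d3 >= 0.0 && d4 <= d3) { for (int i = 0; i < 3; ++i) out[i] = b[i]; return; }

  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + v * ab[i];
    return;
  }

  double cp[3];
  for (int i = 0; i < 3; ++i) cp[i] = p[i] - c[i];
  double d5 = ab[0] * cp[0] + ab[1] * cp[1] + ab[2] * cp[2];
  double d6 = ac[0] * cp[0] + ac[1] * cp[1] + ac[2] * cp[2];
  if (d6 >= 0.0 && d5 <= d6) { for (int i = 0; i < 3; ++i) out[i] = c[i]; return; }

  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    for (int i = 0; i < 3; ++i) out[i] = a[i] + w * ac[i];
    return;
  }

  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    for (int i = 0; i < 3; ++i) out[i] = b[i] + w * (c[i] - b[i]);
    return;
  }

  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  for (int i = 0; i < 3; ++i) out[i] = a[i] + ab[i] * v + ac[i] * w;
}

// [[Rcpp::export(name = ".closest_point_on_mesh")]]
List closest_point_on_mesh(NumericMatrix query, NumericMatrix vertices,
                           IntegerMatrix faces) {
  const int nq = query.nrow(), nf = faces.nrow();
  NumericMatrix points(nq, 3);
  NumericVector dist(nq);
  IntegerVector tri(nq);

  // triangle vertex pointers flattened for speed
  std::vector<double> V(vertices.nrow() * 3);
  for (int i = 0; i < vertices.nrow(); ++i)
    for (int j = 0; j < 3; ++j) V[3 * i + j] = vertices(i, j);

  for (int q = 0; q < nq; ++q) {
    double p[3] = {query(q, 0), query(q, 1), query(q, 2)};
    double best = R_PosInf, bestpt[3] = {0, 0, 0};
    int besttri = -1;
    for (int f = 0; f < nf; ++f) {
      const double *a = &V[3 * (faces(f, 0) - 1)];
      const double *b = &V[3 * (faces(f, 1) - 1)];
      const double *c = &V[3 * (faces(f, 2) - 1)];
      double out[3];
      closest_on_triangle(p, a, b, c, out);
      double d2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double e = out[i] - p[i];
        d2 += e * e;
      }
      if (d2 < best) {
        best = d2;
        besttri = f;
        for (int i = 0; i < 3; ++i) bestpt[i] = out[i];
      }
    }
    for (int i = 0; i < 3; ++i) points(q, i) = bestpt[i];
    dist[q] = std::sqrt(best);
    tri[q] = besttri + 1;  // 1-based triangle index
  }
  return List::create(_["points"] = points, _["distance"] = dist,
                      _["triangle"] = tri);
}
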