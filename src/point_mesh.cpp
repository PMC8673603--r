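#include <Rcpp.h>
#include <cfloat>
#include <map>
#include <utility>
using namespace Rcpp;

// Closest point on triangle (a,b,c) to p. Ericson, Real-Time Collision
// Detection, ch. 5.1.5.
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

static inline double point_segment_dist2(const double *p, const double *a,
                                         const double *b) {
  double ab[3], ap[3];
  double num = 0.0, den = 0.0;
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i];
    ap[i] = p[i] - a[i];
    num += ab[i] * ap[i];
    den += ab[i] * ab[i];
  }
  double t = den > 0 ? num / den : 0.0;
  if (t < 0.0) t = 0.0;
  if (t > 1.0) t = 1.0;
  double d2 = 0.0;
  for (int i = 0; i < 3; ++i) {
    double d = ap[i] - t * ab[i];
    d2 += d * d;
  }
  return d2;
}

// Signed distance from each query point to a triangle mesh.
// V: n x 3 vertices, F: m x 3 1-based face indices, P: k x 3 points.
// Sign: positive on the side the face normal of the closest triangle points
// to, negative behind it. A closest point lying on an open-boundary edge of
// the mesh means the query point is beyond the surface's silhouette, where
// the one-sided sign is meaningless; such points are reported positive
// (outside). Brute force over faces with an AABB early-out.
// [[Rcpp::export(name = ".point_mesh_signed_distance")]]
List point_mesh_signed_distance(NumericMatrix P, NumericMatrix V,
                                IntegerMatrix F) {
  const int k = P.nrow(), m = F.nrow();
  if (m == 0) stop("empty mesh");

  // undirected edge -> incident faces (for edge pseudonormals and open
  // boundary detection), vertex -> incident faces (for vertex pseudonormals)
  std::map<std::pair<int, int>, std::vector<int> > edge_faces;
  std::vector<std::vector<int> > vert_faces(V.nrow());
  for (int t = 0; t < m; ++t) {
    for (int e = 0; e < 3; ++e) {
      int u = F(t, e), v = F(t, (e + 1) % 3);
      if (u > v) std::swap(u, v);
      edge_faces[std::make_pair(u, v)].push_back(t);
      vert_faces[F(t, e) - 1].push_back(t);
    }
  }
  std::vector<char> vert_on_boundary(V.nrow(), 0);
  for (std::map<std::pair<int, int>, std::vector<int> >::const_iterator it =
         edge_faces.begin(); it != edge_faces.end(); ++it) {
    if (it->second.size() == 1) {
      vert_on_boundary[it->first.first - 1] = 1;
      vert_on_boundary[it->first.second - 1] = 1;
    }
  }

  // flatten triangles and precompute AABBs + normals
  std::vector<double> tv(9 * m), lo(3 * m), hi(3 * m), nrm(3 * m);
  for (int t = 0; t < m; ++t) {
    for (int c = 0; c < 3; ++c) {
      int vi = F(t, c) - 1;
      for (int i = 0; i < 3; ++i) tv[9 * t + 3 * c + i] = V(vi, i);
    }
    for (int i = 0; i < 3; ++i) {
      double a = tv[9 * t + i], b = tv[9 * t + 3 + i], c = tv[9 * t + 6 + i];
      lo[3 * t + i] = std::min(a, std::min(b, c));
      hi[3 * t + i] = std::max(a, std::max(b, c));
    }
    double e1[3], e2[3];
    for (int i = 0; i < 3; ++i) {
      e1[i] = tv[9 * t + 3 + i] - tv[9 * t + i];
      e2[i] = tv[9 * t + 6 + i] - tv[9 * t + i];
    }
    nrm[3 * t + 0] = e1[1] * e2[2] - e1[2] * e2[1];
    nrm[3 * t + 1] = e1[2] * e2[0] - e1[0] * e2[2];
    nrm[3 * t + 2] = e1[0] * e2[1] - e1[1] * e2[0];
    double nn = std::sqrt(nrm[3 * t] * nrm[3 * t] +
                          nrm[3 * t + 1] * nrm[3 * t + 1] +
                          nrm[3 * t + 2] * nrm[3 * t + 2]);
    if (nn > 0) for (int i = 0; i < 3; ++i) nrm[3 * t + i] /= nn;
  }

  NumericVector dist(k);
  IntegerVector face(k);
  const double tie = 1e-9;
  for (int q = 0; q < k; ++q) {
    double p[3] = {P(q, 0), P(q, 1), P(q, 2)};
    double best2 = DBL_MAX, best_dot = 0.0, bestcp[3] = {0, 0, 0};
    int bestt = -1;
    for (int t = 0; t < m; ++t) {
      double bb2 = 0.0;
      for (int i = 0; i < 3; ++i) {
        double d = 0.0;
        if (p[i] < lo[3 * t + i]) d = lo[3 * t + i] - p[i];
        else if (p[i] > hi[3 * t + i]) d = p[i] - hi[3 * t + i];
        bb2 += d * d;
      }
      if (bb2 > best2 + tie) continue;
      double cp[3];
      closest_on_triangle(p, &tv[9 * t], &tv[9 * t + 3], &tv[9 * t + 6], cp);
      double d2 = 0.0, dot = 0.0;
      for (int i = 0; i < 3; ++i) {
        d2 += (p[i] - cp[i]) * (p[i] - cp[i]);
        dot += (p[i] - cp[i]) * nrm[3 * t + i];
      }
      if (d2 < best2 - tie ||
          (d2 <= best2 + tie && std::fabs(dot) > std::fabs(best_dot))) {
        if (d2 < best2) best2 = d2;
        bestt = t;
        best_dot = dot;
        for (int i = 0; i < 3; ++i) bestcp[i] = cp[i];
      }
    }

    // classify the closest feature (face interior / edge / vertex) via
    // barycentric coordinates and take the angle-weighted pseudonormal
    // there (Baerentzen & Aanaes); the one-sided face normal is unreliable
    // at concave creases
    const double *A = &tv[9 * bestt], *B = &tv[9 * bestt + 3],
                 *C = &tv[9 * bestt + 6];
    double v0[3], v1[3], v2[3];
    for (int i = 0; i < 3; ++i) {
      v0[i] = B[i] - A[i];
      v1[i] = C[i] - A[i];
      v2[i] = bestcp[i] - A[i];
    }
    double d00 = 0, d01 = 0, d11 = 0, d20 = 0, d21 = 0;
    for (int i = 0; i < 3; ++i) {
      d00 += v0[i] * v0[i]; d01 += v0[i] * v1[i]; d11 += v1[i] * v1[i];
      d20 += v2[i] * v0[i]; d21 += v2[i] * v1[i];
    }
    double den = d00 * d11 - d01 * d01;
    double bv = den > 0 ? (d11 * d20 - d01 * d21) / den : 0.0;
    double bw = den > 0 ? (d00 * d21 - d01 * d20) / den : 0.0;
    double bu = 1.0 - bv - bw;
    double bary[3] = {bu, bv, bw};
    const double beps = 1e-7;
    int n_zero = 0, zero_idx[3];
    for (int i = 0; i < 3; ++i) if (bary[i] < beps) zero_idx[n_zero++] = i;

    double pn[3] = {nrm[3 * bestt], nrm[3 * bestt + 1], nrm[3 * bestt + 2]};
    bool on_open_boundary = false;
    if (n_zero == 1) {
      // on the edge opposite vertex zero_idx[0]
      int e0 = (zero_idx[0] + 1) % 3, e1 = (zero_idx[0] + 2) % 3;
      int u = F(bestt, e0), v = F(bestt, e1);
      if (u > v) std::swap(u, v);
      const std::vector<int> &fs = edge_faces[std::make_pair(u, v)];
      if (fs.size() == 1) {
        on_open_boundary = true;
      } else {
        pn[0] = pn[1] = pn[2] = 0.0;
        for (size_t j = 0; j < fs.size(); ++j)
          for (int i = 0; i < 3; ++i) pn[i] += nrm[3 * fs[j] + i];
      }
    } else if (n_zero == 2) {
      // at the vertex not indexed by either zero
      int vi = 3 - zero_idx[0] - zero_idx[1];
      int vid = F(bestt, vi) - 1;
      const std::vector<int> &fs = vert_faces[vid];
      pn[0] = pn[1] = pn[2] = 0.0;
      for (size_t j = 0; j < fs.size(); ++j) {
        int t = fs[j];
        // incidence angle of the triangle at this vertex
        int corner = -1;
        for (int cc = 0; cc < 3; ++cc) if (F(t, cc) - 1 == vid) corner = cc;
        const double *pa = &tv[9 * t + 3 * corner];
        const double *pb = &tv[9 * t + 3 * ((corner + 1) % 3)];
        const double *pc = &tv[9 * t + 3 * ((corner + 2) % 3)];
        double e1v[3], e2v[3], n1 = 0, n2 = 0, dd = 0;
        for (int i = 0; i < 3; ++i) {
          e1v[i] = pb[i] - pa[i]; e2v[i] = pc[i] - pa[i];
          n1 += e1v[i] * e1v[i]; n2 += e2v[i] * e2v[i];
          dd += e1v[i] * e2v[i];
        }
        double ca = dd / std::sqrt(n1 * n2);
        if (ca > 1.0) ca = 1.0;
        if (ca < -1.0) ca = -1.0;
        double ang = std::acos(ca);
        for (int i = 0; i < 3; ++i) pn[i] += ang * nrm[3 * t + i];
      }
      if (vert_on_boundary[vid]) on_open_boundary = true;
    }
    double s = 0.0;
    for (int i = 0; i < 3; ++i) s += (p[i] - bestcp[i]) * pn[i];
    double d = std::sqrt(best2);
    dist[q] = (s >= 0.0 || on_open_boundary) ? d : -d;
    face[q] = bestt + 1;
  }
  return List::create(_["distance"] = dist, _["face"] = face);
}
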