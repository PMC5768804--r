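#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Iso-surface extraction on a regular grid by marching tetrahedra: every
// grid cell is split into 6 tetrahedra around the (0,0,0)-(1,1,1) diagonal
// and each tetrahedron contributes 0, 1 or 2 triangles with vertices
// linearly interpolated along the crossed edges. Produces a triangle soup
// (vertices are not merged); orientation is not normalized, which is
// irrelevant for distance queries and volume-free STL export.

static const int CUBE_OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
static const int TETS[6][4] = {
  {0,5,1,6},{0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6}
};

struct V3 { double x, y, z; };

static inline V3 edge_point(const V3 &p, const V3 &q, double fp, double fq,
                            double iso) {
  double denom = fq - fp;
  double t = (denom == 0.0) ? 0.5 : (iso - fp) / denom;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  V3 r;
  r.x = p.x + t * (q.x - p.x);
  r.y = p.y + t * (q.y - p.y);
  r.z = p.z + t * (q.z - p.z);
  return r;
}

// [[Rcpp::export]]
List cpp_marching_tetrahedra(NumericVector field, IntegerVector shape,
                             NumericVector spacing, NumericVector origin,
                             double iso) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  std::vector<double> vx, vy, vz;

  V3 cp[8]; double cf[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ii = i + CUBE_OFF[c][0], jj = j + CUBE_OFF[c][1],
              kk = k + CUBE_OFF[c][2];
          cf[c] = field[ii + (size_t)nx * (jj + (size_t)ny * kk)];
          cp[c].x = origin[0] + ii * spacing[0];
          cp[c].y = origin[1] + jj * spacing[1];
          cp[c].z = origin[2] + kk * spacing[2];
          if (cf[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {TETS[t][0], TETS[t][1], TETS[t][2], TETS[t][3]};
          int in[4], nin = 0, out[4], nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (cf[vi[c]] >= iso) in[nin++] = vi[c];
            else out[nout++] = vi[c];
          }
          if (nin == 0 || nin == 4) continue;
          V3 tri[6]; int ntri_pts = 0;
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in[0] : out[0];
            int *others = (nin == 1) ? out : in;
            for (int c = 0; c < 3; ++c)
              tri[ntri_pts++] =
                edge_point(cp[a], cp[others[c]], cf[a], cf[others[c]], iso);
          } else { // 2 in, 2 out: quad split into two triangles
            V3 e00 = edge_point(cp[in[0]], cp[out[0]], cf[in[0]], cf[out[0]], iso);
            V3 e01 = edge_point(cp[in[0]], cp[out[1]], cf[in[0]], cf[out[1]], iso);
            V3 e10 = edge_point(cp[in[1]], cp[out[0]], cf[in[1]], cf[out[0]], iso);
            V3 e11 = edge_point(cp[in[1]], cp[out[1]], cf[in[1]], cf[out[1]], iso);
            tri[ntri_pts++] = e00; tri[ntri_pts++] = e01; tri[ntri_pts++] = e11;
            tri[ntri_pts++] = e00; tri[ntri_pts++] = e11; tri[ntri_pts++] = e10;
          }
          for (int c = 0; c < ntri_pts; ++c) {
            vx.push_back(tri[c].x); vy.push_back(tri[c].y); vz.push_back(tri[c].z);
          }
        }
      }

  const int nv = (int)vx.size();
  NumericMatrix verts(nv, 3);
  for (int c = 0; c < nv; ++c) {
    verts(c, 0) = vx[c]; verts(c, 1) = vy[c]; verts(c, 2) = vz[c];
  }
  IntegerMatrix faces(nv / 3, 3);
  for (int f = 0; f < nv / 3; ++f) {
    faces(f, 0) = 3 * f; faces(f, 1) = 3 * f + 1; faces(f, 2) = 3 * f + 2;
  }
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Squared distance from point p to triangle (a, b, c); Ericson's
// region-based closest-point algorithm.
static double pt_tri_d2(const double *p, const double *a, const double *b,
                        const double *c) {
  double ab[3], ac[3], ap[3];
  for (int i = 0; i < 3; ++i) {
    ab[i] = b[i] - a[i]; ac[i] = c[i] - a[i]; ap[i] = p[i] - a[i];
  }
  double d1 = ab[0]*ap[0] + ab[1]*ap[1] + ab[2]*ap[2];
  double d2 = ac[0]*ap[0] + ac[1]*ap[1] + ac[2]*ap[2];
  double qx, qy, qz;
  if (d1 <= 0.0 && d2 <= 0.0) { qx = a[0]; qy = a[1]; qz = a[2]; }
  else {
    double bp[3] = {p[0]-b[0], p[1]-b[1], p[2]-b[2]};
    double d3 = ab[0]*bp[0] + ab[1]*bp[1] + ab[2]*bp[2];
    double d4 = ac[0]*bp[0] + ac[1]*bp[1] + ac[2]*bp[2];
    if (d3 >= 0.0 && d4 <= d3) { qx = b[0]; qy = b[1]; qz = b[2]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
        double v = d1 / (d1 - d3);
        qx = a[0] + v*ab[0]; qy = a[1] + v*ab[1]; qz = a[2] + v*ab[2];
      } else {
        double cpv[3] = {p[0]-c[0], p[1]-c[1], p[2]-c[2]};
        double d5 = ab[0]*cpv[0] + ab[1]*cpv[1] + ab[2]*cpv[2];
        double d6 = ac[0]*cpv[0] + ac[1]*cpv[1] + ac[2]*cpv[2];
        if (d6 >= 0.0 && d5 <= d6) { qx = c[0]; qy = c[1]; qz = c[2]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
            double w = d2 / (d2 - d6);
            qx = a[0] + w*ac[0]; qy = a[1] + w*ac[1]; qz = a[2] + w*ac[2];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
              double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
              qx = b[0] + w*(c[0]-b[0]); qy = b[1] + w*(c[1]-b[1]);
              qz = b[2] + w*(c[2]-b[2]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, w = vc * denom;
              qx = a[0] + ab[0]*v + ac[0]*w;
              qy = a[1] + ab[1]*v + ac[1]*w;
              qz = a[2] + ab[2]*v + ac[2]*w;
            }
          }
        }
      }
    }
  }
  double dx = p[0]-qx, dy = p[1]-qy, dz = p[2]-qz;
  return dx*dx + dy*dy + dz*dz;
}

// Minimum distance from each query point to a triangle mesh (0-based faces).
// [[Rcpp::export]]
NumericVector cpp_points_to_mesh(NumericMatrix points, NumericMatrix verts,
                                 IntegerMatrix faces) {
  const int np = points.nrow(), nf = faces.nrow();
  NumericVector out(np);
  std::vector<double> P(3 * np), V(3 * verts.nrow());
  for (int i = 0; i < np; ++i)
    for (int c = 0; c < 3; ++c) P[3*i + c] = points(i, c);
  for (int i = 0; i < verts.nrow(); ++i)
    for (int c = 0; c < 3; ++c) V[3*i + c] = verts(i, c);
  // triangle centroids + bounding radii for a cheap lower-bound reject
  std::vector<double> C(3 * nf), R(nf);
  for (int f = 0; f < nf; ++f) {
    const double *a = &V[3*faces(f,0)], *b = &V[3*faces(f,1)],
                 *c = &V[3*faces(f,2)];
    double r2 = 0.0;
    for (int d = 0; d < 3; ++d) C[3*f + d] = (a[d] + b[d] + c[d]) / 3.0;
    const double *vv[3] = {a, b, c};
    for (int v = 0; v < 3; ++v) {
      double s = 0.0;
      for (int d = 0; d < 3; ++d) {
        double e = vv[v][d] - C[3*f + d]; s += e * e;
      }
      if (s > r2) r2 = s;
    }
    R[f] = std::sqrt(r2);
  }
  for (int i = 0; i < np; ++i) {
    const double *p = &P[3*i];
    double best = R_PosInf, best_d = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double dx = p[0]-C[3*f], dy = p[1]-C[3*f+1], dz = p[2]-C[3*f+2];
      double lb = std::sqrt(dx*dx + dy*dy + dz*dz) - R[f];
      if (lb > best_d) continue;
      double d2 = pt_tri_d2(p, &V[3*faces(f,0)], &V[3*faces(f,1)],
                            &V[3*faces(f,2)]);
      if (d2 < best) { best = d2; best_d = std::sqrt(best); }
    }
    out[i] = best_d;
  }
  return out;
}
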