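#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Generalized winding number of each query point w.r.t. a closed triangle
// mesh (van Oosterom & Strackee solid-angle formula, summed over faces and
// divided by 4*pi).  ~0 outside, ~1 inside for watertight meshes.
// [[Rcpp::export]]
NumericVector cpp_winding_number(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector w(np);
  for (int p = 0; p < np; ++p) {
    const double px = P(p,0), py = P(p,1), pz = P(p,2);
    double acc = 0.0;
    for (int f = 0; f < nf; ++f) {
      const int i0 = F(f,0), i1 = F(f,1), i2 = F(f,2);
      const double ax = V(i0,0)-px, ay = V(i0,1)-py, az = V(i0,2)-pz;
      const double bx = V(i1,0)-px, by = V(i1,1)-py, bz = V(i1,2)-pz;
      const double cx = V(i2,0)-px, cy = V(i2,1)-py, cz = V(i2,2)-pz;
      const double la = std::sqrt(ax*ax+ay*ay+az*az);
      const double lb = std::sqrt(bx*bx+by*by+bz*bz);
      const double lc = std::sqrt(cx*cx+cy*cy+cz*cz);
      const double det = ax*(by*cz-bz*cy) - ay*(bx*cz-bz*cx) + az*(bx*cy-by*cx);
      const double den = la*lb*lc + (ax*bx+ay*by+az*bz)*lc +
        (bx*cx+by*cy+bz*cz)*la + (ax*cx+ay*cy+az*cz)*lb;
      acc += 2.0 * std::atan2(det, den);
    }
    w[p] = acc / (4.0 * M_PI);
  }
  return w;
}

static inline double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// squared distance from point p to triangle (a,b,c); Ericson, Real-Time
// Collision Detection, closest-point-on-triangle.
static double pt_tri_d2(const double *p, const double *a, const double *b, const double *c) {
  double ab[3], ac[3], ap[3];
  for (int k = 0; k < 3; ++k) { ab[k]=b[k]-a[k]; ac[k]=c[k]-a[k]; ap[k]=p[k]-a[k]; }
  double d1 = ab[0]*ap[0]+ab[1]*ap[1]+ab[2]*ap[2];
  double d2 = ac[0]*ap[0]+ac[1]*ap[1]+ac[2]*ap[2];
  double q[3];
  if (d1 <= 0 && d2 <= 0) { q[0]=a[0]; q[1]=a[1]; q[2]=a[2]; }
  else {
    double bp[3]; for (int k=0;k<3;++k) bp[k]=p[k]-b[k];
    double d3 = ab[0]*bp[0]+ab[1]*bp[1]+ab[2]*bp[2];
    double d4 = ac[0]*bp[0]+ac[1]*bp[1]+ac[2]*bp[2];
    if (d3 >= 0 && d4 <= d3) { q[0]=b[0]; q[1]=b[1]; q[2]=b[2]; }
    else {
      double vc = d1*d4 - d3*d2;
      if (vc <= 0 && d1 >= 0 && d3 <= 0) {
        double v = clamp01(d1 / (d1 - d3));
        for (int k=0;k<3;++k) q[k] = a[k] + v*ab[k];
      } else {
        double cp[3]; for (int k=0;k<3;++k) cp[k]=p[k]-c[k];
        double d5 = ab[0]*cp[0]+ab[1]*cp[1]+ab[2]*cp[2];
        double d6 = ac[0]*cp[0]+ac[1]*cp[1]+ac[2]*cp[2];
        if (d6 >= 0 && d5 <= d6) { q[0]=c[0]; q[1]=c[1]; q[2]=c[2]; }
        else {
          double vb = d5*d2 - d1*d6;
          if (vb <= 0 && d2 >= 0 && d6 <= 0) {
            double wv = clamp01(d2 / (d2 - d6));
            for (int k=0;k<3;++k) q[k] = a[k] + wv*ac[k];
          } else {
            double va = d3*d6 - d5*d4;
            if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
              double wv = clamp01((d4 - d3) / ((d4 - d3) + (d5 - d6)));
              for (int k=0;k<3;++k) q[k] = b[k] + wv*(c[k]-b[k]);
            } else {
              double denom = 1.0 / (va + vb + vc);
              double v = vb * denom, wv = vc * denom;
              for (int k=0;k<3;++k) q[k] = a[k] + ab[k]*v + ac[k]*wv;
            }
          }
        }
      }
    }
  }
  double dx=p[0]-q[0], dy=p[1]-q[1], dz=p[2]-q[2];
  return dx*dx + dy*dy + dz*dz;
}

// Unsigned distance from each query point to the mesh surface (brute force
// over triangles; intended for <= a few thousand faces).
// [[Rcpp::export]]
NumericVector cpp_dist_to_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int np = P.nrow(), nf = F.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    double pp[3] = { P(p,0), P(p,1), P(p,2) };
    double best = R_PosInf;
    for (int f = 0; f < nf; ++f) {
      double a[3] = { V(F(f,0),0), V(F(f,0),1), V(F(f,0),2) };
      double b[3] = { V(F(f,1),0), V(F(f,1),1), V(F(f,1),2) };
      double c[3] = { V(F(f,2),0), V(F(f,2),1), V(F(f,2),2) };
      double d2 = pt_tri_d2(pp, a, b, c);
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}

// ---- triangle / axis-aligned-box overlap (separating axis theorem) ----
static bool axis_test(const double *v0, const double *v1, const double *v2,
                      double ax, double ay, double az, const double *h) {
  double p0 = ax*v0[0] + ay*v0[1] + az*v0[2];
  double p1 = ax*v1[0] + ay*v1[1] + az*v1[2];
  double p2 = ax*v2[0] + ay*v2[1] + az*v2[2];
  double mn = std::min(p0, std::min(p1,p2)), mx = std::max(p0, std::max(p1,p2));
  double r = h[0]*std::fabs(ax) + h[1]*std::fabs(ay) + h[2]*std::fabs(az);
  return !(mn > r || mx < -r);
}

static bool tri_box_overlap(const double *center, const double *h,
                            const double *ta, const double *tb, const double *tc) {
  double v0[3], v1[3], v2[3];
  for (int k=0;k<3;++k) { v0[k]=ta[k]-center[k]; v1[k]=tb[k]-center[k]; v2[k]=tc[k]-center[k]; }
  // box face normals
  for (int k=0;k<3;++k) {
    double mn = std::min(v0[k], std::min(v1[k], v2[k]));
    double mx = std::max(v0[k], std::max(v1[k], v2[k]));
    if (mn > h[k] || mx < -h[k]) return false;
  }
  double e0[3], e1[3], e2[3];
  for (int k=0;k<3;++k) { e0[k]=v1[k]-v0[k]; e1[k]=v2[k]-v1[k]; e2[k]=v0[k]-v2[k]; }
  // triangle normal
  double n[3] = { e0[1]*e1[2]-e0[2]*e1[1], e0[2]*e1[0]-e0[0]*e1[2], e0[0]*e1[1]-e0[1]*e1[0] };
  double d = n[0]*v0[0] + n[1]*v0[1] + n[2]*v0[2];
  double r = h[0]*std::fabs(n[0]) + h[1]*std::fabs(n[1]) + h[2]*std::fabs(n[2]);
  if (std::fabs(d) > r) return false;
  // 9 cross-product axes
  const double *edges[3] = { e0, e1, e2 };
  for (int e = 0; e < 3; ++e) {
    const double *ed = edges[e];
    if (!axis_test(v0,v1,v2, 0, -ed[2], ed[1], h)) return false;
    if (!axis_test(v0,v1,v2, ed[2], 0, -ed[0], h)) return false;
    if (!axis_test(v0,v1,v2, -ed[1], ed[0], 0, h)) return false;
  }
  return true;
}

// Flags, for every cell of a regular grid, whether any mesh triangle
// intersects the cell box.  Returns an integer array of length prod(dims),
// x-fastest ordering.
// [[Rcpp::export]]
IntegerVector cpp_cells_intersecting(NumericMatrix V, IntegerMatrix F,
                                     NumericVector origin, double spacing,
                                     IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector out(nx * ny * nz);
  const double h[3] = { spacing/2, spacing/2, spacing/2 };
  for (int f = 0; f < F.nrow(); ++f) {
    double a[3] = { V(F(f,0),0), V(F(f,0),1), V(F(f,0),2) };
    double b[3] = { V(F(f,1),0), V(F(f,1),1), V(F(f,1),2) };
    double c[3] = { V(F(f,2),0), V(F(f,2),1), V(F(f,2),2) };
    int lo[3], hi[3];
    for (int k = 0; k < 3; ++k) {
      double mn = std::min(a[k], std::min(b[k], c[k]));
      double mx = std::max(a[k], std::max(b[k], c[k]));
      lo[k] = std::max(0, (int)std::floor((mn - origin[k]) / spacing));
      int top = (k==0?nx:(k==1?ny:nz)) - 1;
      hi[k] = std::min(top, (int)std::floor((mx - origin[k]) / spacing));
    }
    for (int kz = lo[2]; kz <= hi[2]; ++kz)
      for (int ky = lo[1]; ky <= hi[1]; ++ky)
        for (int kx = lo[0]; kx <= hi[0]; ++kx) {
          int idx = kx + nx*(ky + ny*kz);
          if (out[idx]) continue;
          double center[3] = { origin[0] + (kx + 0.5)*spacing,
                               origin[1] + (ky + 0.5)*spacing,
                               origin[2] + (kz + 0.5)*spacing };
          if (tri_box_overlap(center, h, a, b, c)) out[idx] = 1;
        }
  }
  return out;
}

// Nearest-visible-point distance from each voxel center (used by the
// distance-field encoder; points are a deformed visible surface cloud).
// [[Rcpp::export]]
NumericVector cpp_min_point_dist(NumericMatrix centers, NumericMatrix pts) {
  const int nc = centers.nrow(), np = pts.nrow();
  NumericVector out(nc);
  for (int i = 0; i < nc; ++i) {
    double cx = centers(i,0), cy = centers(i,1), cz = centers(i,2);
    double best = R_PosInf;
    for (int j = 0; j < np; ++j) {
      double dx = pts(j,0)-cx, dy = pts(j,1)-cy, dz = pts(j,2)-cz;
      double d2 = dx*dx+dy*dy+dz*dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Ray / mesh occlusion: for each origin, does the ray origin + t*dir
// (t > tmin) hit any triangle interior?  Barycentric tolerance btol > 0
// shrinks triangles slightly so rays grazing an edge or vertex do not
// count as hits (rim nodes of a blocky surface stay visible).
// [[Rcpp::export]]
IntegerVector cpp_ray_hits_mesh(NumericMatrix origins, NumericVector dir,
                                NumericMatrix V, IntegerMatrix F,
                                double tmin, double btol) {
  const int np = origins.nrow(), nf = F.nrow();
  IntegerVector out(np);
  const double dx = dir[0], dy = dir[1], dz = dir[2];
  for (int f = 0; f < nf; ++f) {
    const double ax = V(F(f,0),0), ay = V(F(f,0),1), az = V(F(f,0),2);
    const double e1x = V(F(f,1),0)-ax, e1y = V(F(f,1),1)-ay, e1z = V(F(f,1),2)-az;
    const double e2x = V(F(f,2),0)-ax, e2y = V(F(f,2),1)-ay, e2z = V(F(f,2),2)-az;
    // pvec = dir x e2 (constant per triangle)
    const double px = dy*e2z - dz*e2y;
    const double py = dz*e2x - dx*e2z;
    const double pz = dx*e2y - dy*e2x;
    const double det = e1x*px + e1y*py + e1z*pz;
    if (std::fabs(det) < 1e-14) continue;
    const double inv_det = 1.0/det;
    for (int p = 0; p < np; ++p) {
      if (out[p]) continue;
      const double tx = origins(p,0)-ax, ty = origins(p,1)-ay, tz = origins(p,2)-az;
      const double u = (tx*px + ty*py + tz*pz) * inv_det;
      if (u < btol || u > 1.0-btol) continue;
      const double qx = ty*e1z - tz*e1y;
      const double qy = tz*e1x - tx*e1z;
      const double qz = tx*e1y - ty*e1x;
      const double v = (dx*qx + dy*qy + dz*qz) * inv_det;
      if (v < btol || u + v > 1.0-btol) continue;
      const double t = (e2x*qx + e2y*qy + e2z*qz) * inv_det;
      if (t > tmin) out[p] = 1;
    }
  }
  return out;
}
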