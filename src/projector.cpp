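// Cone-beam geometry: right-handed world frame, z = superior (rotation axis),
// isocenter at the origin. At gantry angle beta the source sits at
// SAD * (cos b, sin b, 0); the flat detector is centered on the opposite side
// at distance SDD from the source, with u along (-sin b, cos b, 0) and v
// along +z. Projections are line integrals (attenuation mm^-1 times mm).
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double trilinear(const double *vol, const int *dim,
                               double fx, double fy, double fz) {
  // fx,fy,fz: continuous 0-based voxel coordinates; outside -> 0
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > dim[0] - 1 || fy > dim[1] - 1 || fz > dim[2] - 1)
    return 0.0;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 == dim[0] - 1) x0--;
  if (y0 == dim[1] - 1) y0--;
  if (z0 == dim[2] - 1) z0--;
  double tx = fx - x0, ty = fy - y0, tz = fz - z0;
  const int nx = dim[0], nxy = dim[0] * dim[1];
  const double *p = vol + x0 + y0 * nx + z0 * nxy;
  double c00 = p[0] * (1 - tx) + p[1] * tx;
  double c10 = p[nx] * (1 - tx) + p[nx + 1] * tx;
  double c01 = p[nxy] * (1 - tx) + p[nxy + 1] * tx;
  double c11 = p[nxy + nx] * (1 - tx) + p[nxy + nx + 1] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

static inline void splat(double *vol, const int *dim,
                         double fx, double fy, double fz, double val) {
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > dim[0] - 1 || fy > dim[1] - 1 || fz > dim[2] - 1)
    return;
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 == dim[0] - 1) x0--;
  if (y0 == dim[1] - 1) y0--;
  if (z0 == dim[2] - 1) z0--;
  double tx = fx - x0, ty = fy - y0, tz = fz - z0;
  const int nx = dim[0], nxy = dim[0] * dim[1];
  double *p = vol + x0 + y0 * nx + z0 * nxy;
  p[0] += val * (1 - tx) * (1 - ty) * (1 - tz);
  p[1] += val * tx * (1 - ty) * (1 - tz);
  p[nx] += val * (1 - tx) * ty * (1 - tz);
  p[nx + 1] += val * tx * ty * (1 - tz);
  p[nxy] += val * (1 - tx) * (1 - ty) * tz;
  p[nxy + 1] += val * tx * (1 - ty) * tz;
  p[nxy + nx] += val * (1 - tx) * ty * tz;
  p[nxy + nx + 1] += val * tx * ty * tz;
}

// slab-clip a parametric ray p = src + t*dir against the volume bounding box
static inline bool clip_ray(const double src[3], const double dir[3],
                            const double lo[3], const double hi[3],
                            double &t0, double &t1) {
  t0 = 0.0; t1 = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(dir[a]) < 1e-12) {
      if (src[a] < lo[a] || src[a] > hi[a]) return false;
    } else {
      double ta = (lo[a] - src[a]) / dir[a];
      double tb = (hi[a] - src[a]) / dir[a];
      if (ta > tb) std::swap(ta, tb);
      if (ta > t0) t0 = ta;
      if (tb < t1) t1 = tb;
      if (t0 >= t1) return false;
    }
  }
  return true;
}

// [[Rcpp::export]]
NumericVector forward_project_cpp(NumericVector vol, IntegerVector shape,
                                  NumericVector spacing, NumericVector origin,
                                  double sad, double sdd,
                                  int det_cols, int det_rows,
                                  double pitch_u, double pitch_v,
                                  NumericVector angles_rad, double step_mm) {
  const int dim[3] = {shape[0], shape[1], shape[2]};
  const double *v = vol.begin();
  const int na = angles_rad.size();
  NumericVector out(Dimension(det_cols, det_rows, na));
  double *o = out.begin();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a];
    hi[a] = origin[a] + (dim[a] - 1) * spacing[a];
  }
  const double u0 = -(det_cols - 1) / 2.0 * pitch_u;
  const double v0 = -(det_rows - 1) / 2.0 * pitch_v;
  for (int k = 0; k < na; ++k) {
    const double cb = std::cos(angles_rad[k]), sb = std::sin(angles_rad[k]);
    const double src[3] = {sad * cb, sad * sb, 0.0};
    // detector center and in-plane axes
    const double dc[3] = {-(sdd - sad) * cb, -(sdd - sad) * sb, 0.0};
    const double ux = -sb, uy = cb;
    double *slice = o + (size_t)k * det_cols * det_rows;
    for (int iv = 0; iv < det_rows; ++iv) {
      const double vv = v0 + iv * pitch_v;
      for (int iu = 0; iu < det_cols; ++iu) {
        const double uu = u0 + iu * pitch_u;
        const double px = dc[0] + uu * ux;
        const double py = dc[1] + uu * uy;
        const double pz = vv;
        double dir[3] = {px - src[0], py - src[1], pz - src[2]};
        double t0, t1;
        double acc = 0.0;
        if (clip_ray(src, dir, lo, hi, t0, t1)) {
          const double L = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                                     dir[2] * dir[2]);
          const double dt = step_mm / L;
          // midpoint sampling over [t0, t1]
          const int n = (int)std::ceil((t1 - t0) / dt);
          const double dtt = (t1 - t0) / n;
          for (int s = 0; s < n; ++s) {
            const double t = t0 + (s + 0.5) * dtt;
            const double wx = (src[0] + t * dir[0] - origin[0]) / spacing[0];
            const double wy = (src[1] + t * dir[1] - origin[1]) / spacing[1];
            const double wz = (src[2] + t * dir[2] - origin[2]) / spacing[2];
            acc += trilinear(v, dim, wx, wy, wz);
          }
          acc *= dtt * L;  // path length per sample in mm
        }
        slice[iu + (size_t)iv * det_cols] = acc;
      }
    }
  }
  return out;
}

// exact adjoint of forward_project_cpp (ray-driven splatting); used for
// adjoint-consistency checks, not for FDK reconstruction
// [[Rcpp::export]]
NumericVector forward_adjoint_cpp(NumericVector proj, IntegerVector shape,
                                  NumericVector spacing, NumericVector origin,
                                  double sad, double sdd,
                                  int det_cols, int det_rows,
                                  double pitch_u, double pitch_v,
                                  NumericVector angles_rad, double step_mm) {
  const int dim[3] = {shape[0], shape[1], shape[2]};
  NumericVector out(Dimension(dim[0], dim[1], dim[2]));
  double *v = out.begin();
  const double *p = proj.begin();
  const int na = angles_rad.size();
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a];
    hi[a] = origin[a] + (dim[a] - 1) * spacing[a];
  }
  const double u0 = -(det_cols - 1) / 2.0 * pitch_u;
  const double v0 = -(det_rows - 1) / 2.0 * pitch_v;
  for (int k = 0; k < na; ++k) {
    const double cb = std::cos(angles_rad[k]), sb = std::sin(angles_rad[k]);
    const double src[3] = {sad * cb, sad * sb, 0.0};
    const double dc[3] = {-(sdd - sad) * cb, -(sdd - sad) * sb, 0.0};
    const double ux = -sb, uy = cb;
    const double *slice = p + (size_t)k * det_cols * det_rows;
    for (int iv = 0; iv < det_rows; ++iv) {
      const double vv = v0 + iv * pitch_v;
      for (int iu = 0; iu < det_cols; ++iu) {
        const double val = slice[iu + (size_t)iv * det_cols];
        if (val == 0.0) continue;
        const double uu = u0 + iu * pitch_u;
        const double px = dc[0] + uu * ux;
        const double py = dc[1] + uu * uy;
        double dir[3] = {px - src[0], py - src[1], vv - src[2]};
        double t0, t1;
        if (!clip_ray(src, dir, lo, hi, t0, t1)) continue;
        const double L = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                                   dir[2] * dir[2]);
        const double dt = step_mm / L;
        const int n = (int)std::ceil((t1 - t0) / dt);
        const double dtt = (t1 - t0) / n;
        const double w = val * dtt * L;
        for (int s = 0; s < n; ++s) {
          const double t = t0 + (s + 0.5) * dtt;
          const double wx = (src[0] + t * dir[0] - origin[0]) / spacing[0];
          const double wy = (src[1] + t * dir[1] - origin[1]) / spacing[1];
          const double wz = (src[2] + t * dir[2] - origin[2]) / spacing[2];
          splat(v, dim, wx, wy, wz, w);
        }
      }
    }
  }
  return out;
}

// voxel-driven FDK backprojection of filtered projections; accumulates
// dbeta * (SAD^2 / U^2) * q(u(x), v(x)) with bilinear detector interpolation
// [[Rcpp::export]]
NumericVector back_project_cpp(NumericVector proj, IntegerVector shape,
                               NumericVector spacing, NumericVector origin,
                               double sad, double sdd,
                               int det_cols, int det_rows,
                               double pitch_u, double pitch_v,
                               NumericVector angles_rad, double dbeta,
                               bool fdk_weight) {
  const int nx = shape[0], ny = shape[1], nz = shape[2];
  NumericVector out(Dimension(nx, ny, nz));
  double *vol = out.begin();
  const double *p = proj.begin();
  const int na = angles_rad.size();
  const double uc = (det_cols - 1) / 2.0;  // pixel index of detector center
  const double vc = (det_rows - 1) / 2.0;
  for (int k = 0; k < na; ++k) {
    const double cb = std::cos(angles_rad[k]), sb = std::sin(angles_rad[k]);
    const double *slice = p + (size_t)k * det_cols * det_rows;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = origin[2] + iz * spacing[2];
      for (int iy = 0; iy < ny; ++iy) {
        const double y = origin[1] + iy * spacing[1];
        double *col = vol + (size_t)iy * nx + (size_t)iz * nx * ny;
        for (int ix = 0; ix < nx; ++ix) {
          const double x = origin[0] + ix * spacing[0];
          // distance from source plane along central axis
          const double U = sad - (x * cb + y * sb);
          if (U < 1e-6) continue;
          const double mag = sdd / U;
          const double ud = (-x * sb + y * cb) * mag;  // detector mm
          const double vd = z * mag;
          const double fu = ud / pitch_u + uc;
          const double fv = vd / pitch_v + vc;
          if (fu < 0 || fv < 0 || fu > det_cols - 1 || fv > det_rows - 1)
            continue;
          int iu = (int)std::floor(fu), ivv = (int)std::floor(fv);
          if (iu == det_cols - 1) iu--;
          if (ivv == det_rows - 1) ivv--;
          const double tu = fu - iu, tv = fv - ivv;
          const double *q = slice + iu + (size_t)ivv * det_cols;
          const double val =
            q[0] * (1 - tu) * (1 - tv) + q[1] * tu * (1 - tv) +
            q[det_cols] * (1 - tu) * tv + q[det_cols + 1] * tu * tv;
          const double w = fdk_weight ? dbeta * sad * sad / (U * U) : dbeta;
          col[ix] += w * val;
        }
      }
    }
  }
  return out;
}
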