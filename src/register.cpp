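// Multiresolution free-form deformation registration.
//
// Transform: additive cubic B-spline displacement fields, one incremental
// field per resolution level (control-point spacing halves per level, ending
// at the requested spacing on the finest level). Metric: Mattes mutual
// information (32-bin joint histogram, order-0 Parzen window for the fixed
// image, cubic B-spline window for the moving image) or mean squared
// difference. Optimizer: gradient ascent with an inverse-decay step schedule
// and infinity-norm gradient normalization; a fixed, seeded voxel sample set
// per level keeps the result deterministic.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

static inline double trilinear_clamp(const double *vol, const int *dim,
                                     double fx, double fy, double fz) {
  fx = clampd(fx, 0, dim[0] - 1);
  fy = clampd(fy, 0, dim[1] - 1);
  fz = clampd(fz, 0, dim[2] - 1);
  int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
  if (x0 == dim[0] - 1) x0--;
  if (y0 == dim[1] - 1) y0--;
  if (z0 == dim[2] - 1) z0--;
  if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
  double tx = fx - x0, ty = fy - y0, tz = fz - z0;
  const int nx = dim[0], nxy = dim[0] * dim[1];
  const double *p = vol + x0 + y0 * nx + (size_t)z0 * nxy;
  double c00 = p[0] * (1 - tx) + p[1] * tx;
  double c10 = p[nx] * (1 - tx) + p[nx + 1] * tx;
  double c01 = p[nxy] * (1 - tx) + p[nxy + 1] * tx;
  double c11 = p[nxy + nx] * (1 - tx) + p[nxy + nx + 1] * tx;
  double c0 = c00 * (1 - ty) + c10 * ty;
  double c1 = c01 * (1 - ty) + c11 * ty;
  return c0 * (1 - tz) + c1 * tz;
}

// uniform cubic B-spline basis values for local coordinate t in [0,1)
static inline void bspline_w(double t, double w[4]) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3 * t + 3 * t2 - t3) / 6.0;
  w[1] = (4 - 6 * t2 + 3 * t3) / 6.0;
  w[2] = (1 + 3 * t + 3 * t2 - 3 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

// cubic B-spline Parzen kernel and derivative
static inline double beta3(double u) {
  u = std::fabs(u);
  if (u < 1) return (4 - 6 * u * u + 3 * u * u * u) / 6.0;
  if (u < 2) { const double w = 2 - u; return w * w * w / 6.0; }
  return 0.0;
}
static inline double beta3d(double u) {
  const double s = u < 0 ? -1.0 : 1.0;
  u = std::fabs(u);
  if (u < 1) return s * (-12 * u + 9 * u * u) / 6.0;
  if (u < 2) { const double w = 2 - u; return s * (-3 * w * w) / 6.0; }
  return 0.0;
}

struct Level {
  std::vector<double> fx, mv, gx, gy, gz;  // fixed, moving, moving gradient
  int dim[3];
  double sp[3];
};

static Level downsample(const std::vector<double> &fx,
                        const std::vector<double> &mv,
                        const int dim[3], const double sp[3], int factor) {
  Level L;
  for (int a = 0; a < 3; ++a) {
    L.dim[a] = std::max(1, dim[a] / factor);
    L.sp[a] = sp[a] * factor;
  }
  const size_t nv = (size_t)L.dim[0] * L.dim[1] * L.dim[2];
  L.fx.assign(nv, 0.0); L.mv.assign(nv, 0.0);
  for (int iz = 0; iz < L.dim[2]; ++iz)
    for (int iy = 0; iy < L.dim[1]; ++iy)
      for (int ix = 0; ix < L.dim[0]; ++ix) {
        double sf = 0, sm = 0; int n = 0;
        for (int dz = 0; dz < factor; ++dz)
          for (int dy = 0; dy < factor; ++dy)
            for (int dx = 0; dx < factor; ++dx) {
              int jx = ix * factor + dx, jy = iy * factor + dy,
                jz = iz * factor + dz;
              if (jx >= dim[0] || jy >= dim[1] || jz >= dim[2]) continue;
              size_t j = jx + (size_t)jy * dim[0] + (size_t)jz * dim[0] * dim[1];
              sf += fx[j]; sm += mv[j]; ++n;
            }
        size_t i = ix + (size_t)iy * L.dim[0] + (size_t)iz * L.dim[0] * L.dim[1];
        L.fx[i] = sf / n; L.mv[i] = sm / n;
      }
  // central-difference gradient of the moving image, per mm
  L.gx.assign(nv, 0.0); L.gy.assign(nv, 0.0); L.gz.assign(nv, 0.0);
  for (int iz = 0; iz < L.dim[2]; ++iz)
    for (int iy = 0; iy < L.dim[1]; ++iy)
      for (int ix = 0; ix < L.dim[0]; ++ix) {
        size_t i = ix + (size_t)iy * L.dim[0] + (size_t)iz * L.dim[0] * L.dim[1];
        int xp = std::min(ix + 1, L.dim[0] - 1), xm = std::max(ix - 1, 0);
        int yp = std::min(iy + 1, L.dim[1] - 1), ym = std::max(iy - 1, 0);
        int zp = std::min(iz + 1, L.dim[2] - 1), zm = std::max(iz - 1, 0);
        const size_t sxy = (size_t)L.dim[0] * L.dim[1];
        L.gx[i] = (L.mv[xp + (size_t)iy * L.dim[0] + iz * sxy] -
                   L.mv[xm + (size_t)iy * L.dim[0] + iz * sxy]) /
          ((xp - xm) * L.sp[0]);
        L.gy[i] = (L.mv[ix + (size_t)yp * L.dim[0] + iz * sxy] -
                   L.mv[ix + (size_t)ym * L.dim[0] + iz * sxy]) /
          ((yp - ym) * L.sp[1]);
        L.gz[i] = (L.mv[ix + (size_t)iy * L.dim[0] + zp * sxy] -
                   L.mv[ix + (size_t)iy * L.dim[0] + zm * sxy]) /
          ((zp - zm) * L.sp[2]);
      }
  return L;
}

// [[Rcpp::export]]
List bspline_register_cpp(NumericVector fixed, NumericVector moving,
                          IntegerVector shape, NumericVector spacing,
                          NumericVector origin, double grid_spacing_mm,
                          int levels, int iterations, int n_samples,
                          int n_bins, std::string metric, int seed,
                          double step0_mm, double smooth_alpha) {
  const int dim[3] = {shape[0], shape[1], shape[2]};
  const double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double org[3] = {origin[0], origin[1], origin[2]};
  const size_t nvox = (size_t)dim[0] * dim[1] * dim[2];
  std::vector<double> fx(fixed.begin(), fixed.end());
  std::vector<double> mv(moving.begin(), moving.end());

  // intensity binning shared across levels (2-bin pad each side for the
  // Parzen window support)
  double vmin = R_PosInf, vmax = R_NegInf;
  for (size_t i = 0; i < nvox; ++i) {
    vmin = std::min(vmin, std::min(fx[i], mv[i]));
    vmax = std::max(vmax, std::max(fx[i], mv[i]));
  }
  if (!(vmax > vmin)) vmax = vmin + 1.0;
  const double binw = (vmax - vmin) / (n_bins - 5);
  const bool use_mi = metric == "mi";

  // accumulated dense displacement field at full resolution (mm)
  std::vector<double> Vt(3 * nvox, 0.0);
  const double extent[3] = {(dim[0] - 1) * sp[0], (dim[1] - 1) * sp[1],
                            (dim[2] - 1) * sp[2]};
  unsigned long long rng = (unsigned long long)seed * 6364136223846793005ULL + 1442695040888963407ULL;
  auto next_rng = [&rng]() {
    rng = rng * 6364136223846793005ULL + 1442695040888963407ULL;
    return (double)((rng >> 11) & 0x1FFFFFFFFFFFFFULL) / 9007199254740992.0;
  };
  std::vector<double> metric_trace;

  for (int lev = levels - 1; lev >= 0; --lev) {
    const int factor = 1 << lev;
    Level L = downsample(fx, mv, dim, sp, factor);
    const size_t nvl = (size_t)L.dim[0] * L.dim[1] * L.dim[2];
    const double gsp = grid_spacing_mm * factor;
    int nc[3];
    double corg[3];
    for (int a = 0; a < 3; ++a) {
      nc[a] = (int)std::floor(extent[a] / gsp) + 5;
      corg[a] = org[a] - gsp;
    }
    const size_t ncp = (size_t)nc[0] * nc[1] * nc[2];
    std::vector<double> coef(3 * ncp, 0.0), grad(3 * ncp, 0.0);

    // sample set: voxel centers of the level grid (all, or a seeded subset)
    int ns = (n_samples >= (int)nvl) ? (int)nvl : n_samples;
    std::vector<size_t> sidx(ns);
    if (ns == (int)nvl) {
      for (int s = 0; s < ns; ++s) sidx[s] = s;
    } else {
      for (int s = 0; s < ns; ++s) sidx[s] = (size_t)(next_rng() * nvl);
    }
    // per-sample precomputation: world position + previous-level field +
    // B-spline support weights and base control index
    std::vector<double> sx(ns), sy(ns), sz(ns), sF(ns);
    std::vector<double> wts((size_t)ns * 12);  // 4 weights per axis
    std::vector<int> base((size_t)ns * 3);
    for (int s = 0; s < ns; ++s) {
      size_t i = sidx[s];
      int ix = i % L.dim[0], iy = (i / L.dim[0]) % L.dim[1],
        iz = i / ((size_t)L.dim[0] * L.dim[1]);
      double x = org[0] + ix * L.sp[0];
      double y = org[1] + iy * L.sp[1];
      double z = org[2] + iz * L.sp[2];
      // accumulated field sampled at the (undeformed) sample position
      double fxi = (x - org[0]) / sp[0], fyi = (y - org[1]) / sp[1],
        fzi = (z - org[2]) / sp[2];
      sx[s] = x + trilinear_clamp(Vt.data(), dim, fxi, fyi, fzi);
      sy[s] = y + trilinear_clamp(Vt.data() + nvox, dim, fxi, fyi, fzi);
      sz[s] = z + trilinear_clamp(Vt.data() + 2 * nvox, dim, fxi, fyi, fzi);
      sF[s] = L.fx[i];
      const double pos[3] = {x, y, z};
      for (int a = 0; a < 3; ++a) {
        double u = (pos[a] - corg[a]) / gsp;
        int ib = (int)std::floor(u);
        if (ib < 1) ib = 1;
        if (ib > nc[a] - 3) ib = nc[a] - 3;
        base[(size_t)s * 3 + a] = ib - 1;
        bspline_w(u - ib, &wts[(size_t)s * 12 + a * 4]);
      }
    }

    std::vector<double> sM(ns), sGx(ns), sGy(ns), sGz(ns), sB(ns);
    std::vector<int> sFbin(ns);
    for (int s = 0; s < ns; ++s)
      sFbin[s] = std::min(std::max((int)((sF[s] - vmin) / binw + 2.0), 0),
                          n_bins - 1);
    std::vector<double> hist((size_t)n_bins * n_bins);
    std::vector<double> pf(n_bins), pm(n_bins);

    double final_metric = 0.0, g0max = 1.0;
    double best_val = R_NegInf;
    int stall = 0;
    std::vector<double> tmp(ncp);
    for (int it = 0; it < iterations; ++it) {
      // forward pass: warped moving value + gradient per sample
      for (int s = 0; s < ns; ++s) {
        const double *w = &wts[(size_t)s * 12];
        const int *b = &base[(size_t)s * 3];
        double bx = 0, by = 0, bz = 0;
        for (int kz = 0; kz < 4; ++kz) {
          const double wz_ = w[8 + kz];
          for (int ky = 0; ky < 4; ++ky) {
            const double wyz = wz_ * w[4 + ky];
            size_t cbase = (size_t)(b[0]) +
              (size_t)(b[1] + ky) * nc[0] +
              (size_t)(b[2] + kz) * nc[0] * nc[1];
            for (int kx = 0; kx < 4; ++kx) {
              const double ww = wyz * w[kx];
              size_t c = cbase + kx;
              bx += ww * coef[c];
              by += ww * coef[c + ncp];
              bz += ww * coef[c + 2 * ncp];
            }
          }
        }
        const double px = (sx[s] + bx - org[0]) / L.sp[0];
        const double py = (sy[s] + by - org[1]) / L.sp[1];
        const double pz = (sz[s] + bz - org[2]) / L.sp[2];
        sM[s] = trilinear_clamp(L.mv.data(), L.dim, px, py, pz);
        sGx[s] = trilinear_clamp(L.gx.data(), L.dim, px, py, pz);
        sGy[s] = trilinear_clamp(L.gy.data(), L.dim, px, py, pz);
        sGz[s] = trilinear_clamp(L.gz.data(), L.dim, px, py, pz);
        sB[s] = clampd((sM[s] - vmin) / binw + 2.0, 1.0, n_bins - 2.0);
      }

      std::fill(grad.begin(), grad.end(), 0.0);
      double value = 0.0;
      if (use_mi) {
        std::fill(hist.begin(), hist.end(), 0.0);
        for (int s = 0; s < ns; ++s) {
          const int m0 = (int)std::floor(sB[s]) - 1;
          for (int m = 0; m < 4; ++m) {
            int mb = std::min(std::max(m0 + m, 0), n_bins - 1);
            hist[sFbin[s] + (size_t)mb * n_bins] += beta3(sB[s] - (m0 + m));
          }
        }
        std::fill(pf.begin(), pf.end(), 0.0);
        std::fill(pm.begin(), pm.end(), 0.0);
        for (int m = 0; m < n_bins; ++m)
          for (int f = 0; f < n_bins; ++f) {
            double p = hist[f + (size_t)m * n_bins] / ns;
            hist[f + (size_t)m * n_bins] = p;
            pf[f] += p; pm[m] += p;
          }
        for (int m = 0; m < n_bins; ++m)
          for (int f = 0; f < n_bins; ++f) {
            double p = hist[f + (size_t)m * n_bins];
            if (p > 0) value += p * std::log(p / (pf[f] * pm[m]));
          }
        for (int s = 0; s < ns; ++s) {
          const int m0 = (int)std::floor(sB[s]) - 1;
          double dv = 0.0;
          for (int m = 0; m < 4; ++m) {
            int mb = std::min(std::max(m0 + m, 0), n_bins - 1);
            double p = hist[sFbin[s] + (size_t)mb * n_bins];
            if (p <= 0 || pm[mb] <= 0) continue;
            dv += beta3d(sB[s] - (m0 + m)) / binw * std::log(p / pm[mb]);
          }
          dv /= ns;
          const double gx = dv * sGx[s], gy = dv * sGy[s], gz = dv * sGz[s];
          const double *w = &wts[(size_t)s * 12];
          const int *b = &base[(size_t)s * 3];
          for (int kz = 0; kz < 4; ++kz)
            for (int ky = 0; ky < 4; ++ky) {
              const double wyz = w[8 + kz] * w[4 + ky];
              size_t cbase = (size_t)(b[0]) + (size_t)(b[1] + ky) * nc[0] +
                (size_t)(b[2] + kz) * nc[0] * nc[1];
              for (int kx = 0; kx < 4; ++kx) {
                const double ww = wyz * w[kx];
                size_t c = cbase + kx;
                grad[c] += gx * ww;
                grad[c + ncp] += gy * ww;
                grad[c + 2 * ncp] += gz * ww;
              }
            }
        }
      } else {  // mean squared difference (maximize its negative)
        for (int s = 0; s < ns; ++s) {
          const double diff = sM[s] - sF[s];
          value -= diff * diff / ns;
          const double dv = -2.0 * diff / ns;
          const double gx = dv * sGx[s], gy = dv * sGy[s], gz = dv * sGz[s];
          const double *w = &wts[(size_t)s * 12];
          const int *b = &base[(size_t)s * 3];
          for (int kz = 0; kz < 4; ++kz)
            for (int ky = 0; ky < 4; ++ky) {
              const double wyz = w[8 + kz] * w[4 + ky];
              size_t cbase = (size_t)(b[0]) + (size_t)(b[1] + ky) * nc[0] +
                (size_t)(b[2] + kz) * nc[0] * nc[1];
              for (int kx = 0; kx < 4; ++kx) {
                const double ww = wyz * w[kx];
                size_t c = cbase + kx;
                grad[c] += gx * ww;
                grad[c + ncp] += gy * ww;
                grad[c + 2 * ncp] += gz * ww;
              }
            }
        }
      }
      final_metric = value;
      double gmax = 0.0;
      for (size_t c = 0; c < 3 * ncp; ++c)
        gmax = std::max(gmax, std::fabs(grad[c]));
      if (gmax <= 0) break;
      // calibrate the step on the first iteration so that the largest
      // control-point move is step0_mm; thereafter steps shrink with the
      // gradient (and with the 1/(1+k) decay), so the optimizer settles
      // instead of random-walking at the optimum
      if (gmax > g0max || it == 0) g0max = gmax;  // running normalizer:
      // the largest single-iteration control-point move never exceeds step0
      const double step = step0_mm / (1.0 + it / 30.0) / g0max;
      for (size_t c = 0; c < 3 * ncp; ++c)
        coef[c] += step * grad[c];
      // membrane regularization: diffuse each coefficient channel toward
      // the mean of its 6-neighborhood; uniform (translation-like) fields
      // are unaffected, high-frequency overfit of the sampled metric decays
      if (smooth_alpha > 0) {
        for (int ax = 0; ax < 3; ++ax) {
          double *ch = coef.data() + (size_t)ax * ncp;
          std::copy(ch, ch + ncp, tmp.begin());
          for (int cz = 0; cz < nc[2]; ++cz)
            for (int cy = 0; cy < nc[1]; ++cy)
              for (int cx = 0; cx < nc[0]; ++cx) {
                size_t i = cx + (size_t)cy * nc[0] + (size_t)cz * nc[0] * nc[1];
                double s = 0; int n = 0;
                if (cx > 0) { s += tmp[i - 1]; ++n; }
                if (cx < nc[0] - 1) { s += tmp[i + 1]; ++n; }
                if (cy > 0) { s += tmp[i - nc[0]]; ++n; }
                if (cy < nc[1] - 1) { s += tmp[i + nc[0]]; ++n; }
                if (cz > 0) { s += tmp[i - (size_t)nc[0] * nc[1]]; ++n; }
                if (cz < nc[2] - 1) { s += tmp[i + (size_t)nc[0] * nc[1]]; ++n; }
                ch[i] = (1 - smooth_alpha) * tmp[i] + smooth_alpha * s / n;
              }
        }
      }
      // improvement-based early stop
      if (value > best_val + 1e-6 * std::max(1.0, std::fabs(best_val))) {
        best_val = value; stall = 0;
      } else if (++stall >= 80) break;
    }
    metric_trace.push_back(final_metric);

    // bake this level's spline into the dense accumulated field
    for (int iz = 0; iz < dim[2]; ++iz)
      for (int iy = 0; iy < dim[1]; ++iy) {
        double wy4[4], wz4[4];
        double uz = (org[2] + iz * sp[2] - corg[2]) / gsp;
        int ibz = std::min(std::max((int)std::floor(uz), 1), nc[2] - 3);
        bspline_w(uz - ibz, wz4);
        double uy = (org[1] + iy * sp[1] - corg[1]) / gsp;
        int iby = std::min(std::max((int)std::floor(uy), 1), nc[1] - 3);
        bspline_w(uy - iby, wy4);
        for (int ix = 0; ix < dim[0]; ++ix) {
          double ux = (org[0] + ix * sp[0] - corg[0]) / gsp;
          int ibx = std::min(std::max((int)std::floor(ux), 1), nc[0] - 3);
          double wx4[4];
          bspline_w(ux - ibx, wx4);
          double bx = 0, by = 0, bz = 0;
          for (int kz = 0; kz < 4; ++kz)
            for (int ky = 0; ky < 4; ++ky) {
              const double wyz = wz4[kz] * wy4[ky];
              size_t cbase = (size_t)(ibx - 1) +
                (size_t)(iby - 1 + ky) * nc[0] +
                (size_t)(ibz - 1 + kz) * nc[0] * nc[1];
              for (int kx = 0; kx < 4; ++kx) {
                const double ww = wyz * wx4[kx];
                size_t c = cbase + kx;
                bx += ww * coef[c];
                by += ww * coef[c + ncp];
                bz += ww * coef[c + 2 * ncp];
              }
            }
          size_t i = ix + (size_t)iy * dim[0] + (size_t)iz * dim[0] * dim[1];
          Vt[i] += bx; Vt[i + nvox] += by; Vt[i + 2 * nvox] += bz;
        }
      }
  }

  NumericVector disp((R_xlen_t)(3 * nvox));
  disp.attr("dim") = IntegerVector::create(dim[0], dim[1], dim[2], 3);
  std::copy(Vt.begin(), Vt.end(), disp.begin());
  return List::create(_["disp"] = disp,
                      _["metric"] = metric_trace.back(),
                      _["metric_trace"] = NumericVector(metric_trace.begin(),
                                                        metric_trace.end()));
}
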