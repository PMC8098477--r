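#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static const double TWOPI = 6.283185307179586476925286766559;

// wrap angle (radians) to (-pi, pi]
static inline double wrap_rad(double a) {
  double w = a - TWOPI * std::nearbyint(a / TWOPI);
  if (w <= -M_PI) w += TWOPI;
  return w;
}

// minimal-image squared norm of fractional vector
static inline double frac_norm2(double ux, double uy, double uz) {
  double a = ux - std::nearbyint(ux);
  double b = uy - std::nearbyint(uy);
  double c = uz - std::nearbyint(uz);
  return a * a + b * b + c * c;
}

// Exhaustive origin-alignment search: residual(u) = sum_s w_s
// |wrap(dphi_s + 2 pi h_s . u)| / sum w over the fractional grid
// u = (ia/na, ib/nb, ic/nc). Returns argmin (0-based indices), the minimal
// residual (radians) and optionally the full residual grid.
// [[Rcpp::export]]
List cpp_align_residual_grid(IntegerMatrix hkl, NumericVector dphi,
                             NumericVector w, int na, int nb, int nc,
                             bool return_grid = false) {
  int n = hkl.nrow();
  double sw = 0.0;
  for (int s = 0; s < n; ++s) sw += w[s];
  // per-axis angle increments (radians per grid step)
  std::vector<double> stx(n), sty(n), stz(n);
  for (int s = 0; s < n; ++s) {
    stx[s] = TWOPI * hkl(s, 0) / na;
    sty[s] = TWOPI * hkl(s, 1) / nb;
    stz[s] = TWOPI * hkl(s, 2) / nc;
  }
  NumericVector grid;
  if (return_grid) grid = NumericVector((R_xlen_t)na * nb * nc);
  double best = R_PosInf, best_norm2 = R_PosInf;
  int bia = 0, bib = 0, bic = 0;
  std::vector<double> angx(n), angxy(n);
  const double eps = 1e-12;
  for (int ia = 0; ia < na; ++ia) {
    for (int s = 0; s < n; ++s) angx[s] = dphi[s] + stx[s] * ia;
    for (int ib = 0; ib < nb; ++ib) {
      for (int s = 0; s < n; ++s) angxy[s] = angx[s] + sty[s] * ib;
      for (int ic = 0; ic < nc; ++ic) {
        double acc = 0.0;
        for (int s = 0; s < n; ++s) {
          double a = angxy[s] + stz[s] * ic;
          a -= TWOPI * std::nearbyint(a / TWOPI);
          acc += w[s] * std::fabs(a);
        }
        double res = acc / sw;
        if (return_grid)
          grid[(R_xlen_t)ia + (R_xlen_t)na * (ib + (R_xlen_t)nb * ic)] = res;
        if (res < best - eps) {
          best = res;
          best_norm2 = frac_norm2((double)ia / na, (double)ib / nb,
                                  (double)ic / nc);
          bia = ia; bib = ib; bic = ic;
        } else if (res < best + eps) {
          double n2 = frac_norm2((double)ia / na, (double)ib / nb,
                                 (double)ic / nc);
          if (n2 < best_norm2 - 1e-15) {
            best = std::min(best, res);
            best_norm2 = n2;
            bia = ia; bib = ib; bic = ic;
          }
        }
      }
    }
  }
  List out = List::create(Named("idx") = IntegerVector::create(bia, bib, bic),
                          Named("residual") = best);
  if (return_grid) out["grid"] = grid;
  return out;
}

// Exact alignment residual at a list of fractional candidates (K x 3).
// [[Rcpp::export]]
NumericVector cpp_align_residual_at(IntegerMatrix hkl, NumericVector dphi,
                                    NumericVector w, NumericMatrix U) {
  int n = hkl.nrow(), K = U.nrow();
  double sw = 0.0;
  for (int s = 0; s < n; ++s) sw += w[s];
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    double acc = 0.0;
    for (int s = 0; s < n; ++s) {
      double a = dphi[s] + TWOPI * (hkl(s, 0) * U(k, 0) + hkl(s, 1) * U(k, 1) +
                                    hkl(s, 2) * U(k, 2));
      a -= TWOPI * std::nearbyint(a / TWOPI);
      acc += w[s] * std::fabs(a);
    }
    out[k] = acc / sw;
  }
  return out;
}

// Symmetry phase residual at candidate origins. Each observation contributes
// an estimate psi_s - 2 pi f_s . u of its orbit representative's phase; the
// metric is the intensity-weighted mean absolute wrapped deviation from the
// orbit's weighted circular mean, over orbits with >= 2 observations.
// group: 1-based orbit id per observation, must be sorted ascending.
// [[Rcpp::export]]
NumericVector cpp_sym_residual_at(IntegerMatrix f, NumericVector psi,
                                  NumericVector w, IntegerVector group,
                                  NumericMatrix U) {
  int n = f.nrow(), K = U.nrow();
  // orbit boundaries
  std::vector<int> start;
  start.push_back(0);
  for (int s = 1; s < n; ++s) if (group[s] != group[s - 1]) start.push_back(s);
  start.push_back(n);
  int ng = (int)start.size() - 1;
  NumericVector out(K);
  std::vector<double> est(n);
  for (int k = 0; k < K; ++k) {
    for (int s = 0; s < n; ++s)
      est[s] = psi[s] - TWOPI * (f(s, 0) * U(k, 0) + f(s, 1) * U(k, 1) +
                                 f(s, 2) * U(k, 2));
    double acc = 0.0, accw = 0.0;
    for (int g = 0; g < ng; ++g) {
      int s0 = start[g], s1 = start[g + 1];
      if (s1 - s0 < 2) continue;
      double cr = 0.0, ci = 0.0;
      for (int s = s0; s < s1; ++s) {
        cr += w[s] * std::cos(est[s]);
        ci += w[s] * std::sin(est[s]);
      }
      double mean = std::atan2(ci, cr);
      for (int s = s0; s < s1; ++s) {
        acc += w[s] * std::fabs(wrap_rad(est[s] - mean));
        accw += w[s];
      }
    }
    out[k] = accw > 0 ? acc / accw : NA_REAL;
  }
  return out;
}

// Centric residual at candidate origins: weighted mean wrapped distance
// (modulo pi) of the shifted phase to its allowed value. delta = phi - theta
// at u = 0 (radians).
// [[Rcpp::export]]
NumericVector cpp_centric_residual_at(IntegerMatrix hkl, NumericVector delta,
                                      NumericVector w, NumericMatrix U) {
  int n = hkl.nrow(), K = U.nrow();
  double sw = 0.0;
  for (int s = 0; s < n; ++s) sw += w[s];
  NumericVector out(K);
  for (int k = 0; k < K; ++k) {
    double acc = 0.0;
    for (int s = 0; s < n; ++s) {
      double a = delta[s] - TWOPI * (hkl(s, 0) * U(k, 0) + hkl(s, 1) * U(k, 1) +
                                     hkl(s, 2) * U(k, 2));
      a -= M_PI * std::nearbyint(a / M_PI);  // wrap modulo pi to (-pi/2, pi/2]
      acc += w[s] * std::fabs(a);
    }
    out[k] = acc / sw;
  }
  return out;
}

// ---------------------------------------------------------------------------
// volume kernels

static inline double bilin_yz(const double *vol, int nx, int ny, int nz,
                              int ix, double y, double z) {
  if (y < 0 || z < 0 || y > ny - 1 || z > nz - 1) return 0.0;
  int iy = (int)std::floor(y), iz = (int)std::floor(z);
  if (iy >= ny - 1) iy = ny - 2;
  if (iz >= nz - 1) iz = nz - 2;
  if (iy < 0) iy = 0;
  if (iz < 0) iz = 0;
  double fy = y - iy, fz = z - iz;
  R_xlen_t b = ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
  R_xlen_t dy = nx, dz = (R_xlen_t)nx * ny;
  double v00 = vol[b], v10 = vol[b + dy], v01 = vol[b + dz],
         v11 = vol[b + dy + dz];
  return v00 * (1 - fy) * (1 - fz) + v10 * fy * (1 - fz) +
         v01 * (1 - fy) * fz + v11 * fy * fz;
}

// Project a volume rotated by theta (degrees, about the x axis) along z.
// [[Rcpp::export]]
NumericMatrix cpp_project_x(NumericVector vol, int nx, int ny, int nz,
                            double theta_deg) {
  double th = theta_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  NumericMatrix out(nx, ny);
  const double *v = REAL(vol);
  for (int iz = 0; iz < nz; ++iz) {
    double dz0 = iz - cz;
    for (int iy = 0; iy < ny; ++iy) {
      double dy0 = iy - cy;
      // sample the object rotated by +theta: source point = R(-theta) (y,z)
      double ys = cy + ct * dy0 + st * dz0;
      double zs = cz - st * dy0 + ct * dz0;
      if (ys < 0 || zs < 0 || ys > ny - 1 || zs > nz - 1) continue;
      for (int ix = 0; ix < nx; ++ix)
        out(ix, iy) += bilin_yz(v, nx, ny, nz, ix, ys, zs);
    }
  }
  return out;
}

// Rotate a volume about its center by rotation matrix R (object rotation:
// output(x) = input(R^T (x - c) + c)), trilinear interpolation.
// [[Rcpp::export]]
NumericVector cpp_rotate_vol(NumericVector vol, int nx, int ny, int nz,
                             NumericMatrix R) {
  NumericVector out((R_xlen_t)nx * ny * nz);
  const double *v = REAL(vol);
  double *o = REAL(out);
  double cx = 0.5 * (nx - 1), cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  double r00 = R(0, 0), r01 = R(0, 1), r02 = R(0, 2);
  double r10 = R(1, 0), r11 = R(1, 1), r12 = R(1, 2);
  double r20 = R(2, 0), r21 = R(2, 1), r22 = R(2, 2);
  for (int iz = 0; iz < nz; ++iz) {
    double dz = iz - cz;
    for (int iy = 0; iy < ny; ++iy) {
      double dy = iy - cy;
      for (int ix = 0; ix < nx; ++ix) {
        double dx = ix - cx;
        // R^T (x - c)
        double xs = cx + r00 * dx + r10 * dy + r20 * dz;
        double ys = cy + r01 * dx + r11 * dy + r21 * dz;
        double zs = cz + r02 * dx + r12 * dy + r22 * dz;
        double val = 0.0;
        if (xs >= 0 && ys >= 0 && zs >= 0 && xs <= nx - 1 && ys <= ny - 1 &&
            zs <= nz - 1) {
          int jx = (int)std::floor(xs), jy = (int)std::floor(ys),
              jz = (int)std::floor(zs);
          if (jx >= nx - 1) jx = nx - 2;
          if (jy >= ny - 1) jy = ny - 2;
          if (jz >= nz - 1) jz = nz - 2;
          double fx = xs - jx, fy = ys - jy, fz = zs - jz;
          R_xlen_t b = jx + (R_xlen_t)nx * (jy + (R_xlen_t)ny * jz);
          R_xlen_t dxs = 1, dys = nx, dzs = (R_xlen_t)nx * ny;
          val = v[b] * (1 - fx) * (1 - fy) * (1 - fz) +
                v[b + dxs] * fx * (1 - fy) * (1 - fz) +
                v[b + dys] * (1 - fx) * fy * (1 - fz) +
                v[b + dzs] * (1 - fx) * (1 - fy) * fz +
                v[b + dxs + dys] * fx * fy * (1 - fz) +
                v[b + dxs + dzs] * fx * (1 - fy) * fz +
                v[b + dys + dzs] * (1 - fx) * fy * fz +
                v[b + dxs + dys + dzs] * fx * fy * fz;
        }
        o[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)] = val;
      }
    }
  }
  return out;
}

// Back-project filtered projections (nx x ny x ntilt) into an nx x ny x nz
// volume; tilt angles in degrees about the x axis.
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector projs, int nx, int ny, int ntilt,
                              NumericVector theta_deg, int nz) {
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  const double *p = REAL(projs);
  double cy = 0.5 * (ny - 1), cz = 0.5 * (nz - 1);
  for (int t = 0; t < ntilt; ++t) {
    double th = theta_deg[t] * M_PI / 180.0;
    double ct = std::cos(th), st = std::sin(th);
    const double *pt = p + (R_xlen_t)t * nx * ny;
    for (int iz = 0; iz < nz; ++iz) {
      double dz = iz - cz;
      for (int iy = 0; iy < ny; ++iy) {
        double yp = cy + (iy - cy) * ct - dz * st;
        if (yp < 0 || yp > ny - 1) continue;
        int jy = (int)std::floor(yp);
        if (jy >= ny - 1) jy = ny - 2;
        double fy = yp - jy;
        const double *c0 = pt + (R_xlen_t)jy * nx;
        const double *c1 = pt + (R_xlen_t)(jy + 1) * nx;
        double *orow = o + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz);
        for (int ix = 0; ix < nx; ++ix)
          orow[ix] += c0[ix] * (1 - fy) + c1[ix] * fy;
      }
    }
  }
  return out;
}

// 26-connectivity labeling of a 3D logical mask.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int nx, int ny, int nz) {
  IntegerVector lab((R_xlen_t)nx * ny * nz);
  int cur = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < (R_xlen_t)nx * ny * nz; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++cur;
    stack.push_back(i);
    lab[i] = cur;
    while (!stack.empty()) {
      R_xlen_t j = stack.back();
      stack.pop_back();
      int ix = j % nx, iy = (j / nx) % ny, iz = j / ((R_xlen_t)nx * ny);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int qx = ix + dx, qy = iy + dy, qz = iz + dz;
            if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
              continue;
            R_xlen_t q = qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz);
            if (mask[q] && !lab[q]) {
              lab[q] = cur;
              stack.push_back(q);
            }
          }
    }
  }
  return lab;
}

// Apply blur "hits" in place: around each site, the cubic subvolume of
// half-width hw voxels is replaced by its Gaussian-filtered copy
// (sigma_vox per axis); the filter reads from an extended neighbourhood so
// density exchanges with the surroundings (boundary leakage only).
// [[Rcpp::export]]
NumericVector cpp_damage_hits(NumericVector vol, int nx, int ny, int nz,
                              IntegerMatrix sites, int hw, double sigma_vox) {
  NumericVector out = clone(vol);
  double *v = REAL(out);
  int kr = (int)std::ceil(3.0 * sigma_vox);
  int klen = 2 * kr + 1;
  std::vector<double> kern(klen);
  double ks = 0.0;
  for (int i = -kr; i <= kr; ++i) {
    kern[i + kr] = std::exp(-0.5 * (i / sigma_vox) * (i / sigma_vox));
    ks += kern[i + kr];
  }
  for (int i = 0; i < klen; ++i) kern[i] /= ks;
  int ext = hw + kr;
  int elen = 2 * ext + 1;
  std::vector<double> buf(elen * elen * elen), tmp(elen * elen * elen);
  for (int h = 0; h < sites.nrow(); ++h) {
    int sx = sites(h, 0), sy = sites(h, 1), sz = sites(h, 2);
    // copy extended region (clamped reads at the volume edge)
    for (int dz = -ext; dz <= ext; ++dz)
      for (int dy = -ext; dy <= ext; ++dy)
        for (int dx = -ext; dx <= ext; ++dx) {
          int qx = std::min(std::max(sx + dx, 0), nx - 1);
          int qy = std::min(std::max(sy + dy, 0), ny - 1);
          int qz = std::min(std::max(sz + dz, 0), nz - 1);
          buf[(dx + ext) + elen * ((dy + ext) + elen * (dz + ext))] =
              v[qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz)];
        }
    // separable convolution (x then y then z)
    for (int iz = 0; iz < elen; ++iz)
      for (int iy = 0; iy < elen; ++iy)
        for (int ix = kr; ix < elen - kr; ++ix) {
          double a = 0.0;
          for (int kk = -kr; kk <= kr; ++kk)
            a += kern[kk + kr] * buf[(ix + kk) + elen * (iy + elen * iz)];
          tmp[ix + elen * (iy + elen * iz)] = a;
        }
    for (int iz = 0; iz < elen; ++iz)
      for (int iy = kr; iy < elen - kr; ++iy)
        for (int ix = kr; ix < elen - kr; ++ix) {
          double a = 0.0;
          for (int kk = -kr; kk <= kr; ++kk)
            a += kern[kk + kr] * tmp[ix + elen * ((iy + kk) + elen * iz)];
          buf[ix + elen * (iy + elen * iz)] = a;
        }
    for (int iz = kr; iz < elen - kr; ++iz)
      for (int iy = kr; iy < elen - kr; ++iy)
        for (int ix = kr; ix < elen - kr; ++ix) {
          double a = 0.0;
          for (int kk = -kr; kk <= kr; ++kk)
            a += kern[kk + kr] * buf[ix + elen * (iy + elen * (iz + kk))];
          tmp[ix + elen * (iy + elen * iz)] = a;
        }
    // write back only the hit box, clipped to the volume
    for (int dz = -hw; dz <= hw; ++dz)
      for (int dy = -hw; dy <= hw; ++dy)
        for (int dx = -hw; dx <= hw; ++dx) {
          int qx = sx + dx, qy = sy + dy, qz = sz + dz;
          if (qx < 0 || qy < 0 || qz < 0 || qx >= nx || qy >= ny || qz >= nz)
            continue;
          v[qx + (R_xlen_t)nx * (qy + (R_xlen_t)ny * qz)] =
              tmp[(dx + ext) + elen * ((dy + ext) + elen * (dz + ext))];
        }
  }
  return out;
}

// 1D-FFT direction scoring for lattice-basis search: for each unit direction
// d, project the reciprocal-space points S (Angstrom^-1) onto d and score the
// periodogram |sum_s exp(2 pi i f t_s)| over candidate periods f (Angstrom)
// in [fmin, fmin + (nf-1) df]. Returns per-direction best score and the
// parabolically refined best period.
// [[Rcpp::export]]
List cpp_dps_score(NumericMatrix S, NumericMatrix D, double fmin, double df,
                   int nf) {
  int n = S.nrow(), m = D.nrow();
  NumericVector score(m), fbest(m);
  std::vector<double> zr(n), zi(n), sr(n), si(n);
  std::vector<double> mag(nf);
  for (int j = 0; j < m; ++j) {
    for (int s = 0; s < n; ++s) {
      double t = S(s, 0) * D(j, 0) + S(s, 1) * D(j, 1) + S(s, 2) * D(j, 2);
      double a0 = TWOPI * fmin * t, as = TWOPI * df * t;
      zr[s] = std::cos(a0); zi[s] = std::sin(a0);
      sr[s] = std::cos(as); si[s] = std::sin(as);
    }
    int besti = 0;
    double bestv = -1.0;
    for (int i = 0; i < nf; ++i) {
      double ar = 0.0, ai = 0.0;
      for (int s = 0; s < n; ++s) {
        ar += zr[s];
        ai += zi[s];
        double nr = zr[s] * sr[s] - zi[s] * si[s];
        zi[s] = zr[s] * si[s] + zi[s] * sr[s];
        zr[s] = nr;
      }
      mag[i] = std::sqrt(ar * ar + ai * ai);
      if (mag[i] > bestv) { bestv = mag[i]; besti = i; }
    }
    double f = fmin + besti * df;
    if (besti > 0 && besti < nf - 1) {
      double y0 = mag[besti - 1], y1 = mag[besti], y2 = mag[besti + 1];
      double den = y0 - 2 * y1 + y2;
      if (std::fabs(den) > 1e-12) f += df * 0.5 * (y0 - y2) / den;
    }
    score[j] = bestv;
    fbest[j] = f;
  }
  return List::create(Named("score") = score, Named("f") = fbest);
}
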