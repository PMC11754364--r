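// Single-frequency steady-state FDTD on a staggered (Yee) grid with CPML
// absorbing boundaries.
//
// Layout: material voxel (i,j,k) is centered on the integer lattice point
// (i,j,k) in units of the spacing.  Field components are staggered as
//   Ex[i,j,k] -> (i+1/2, j,     k    )   Hx[i,j,k] -> (i,     j+1/2, k+1/2)
//   Ey[i,j,k] -> (i,     j+1/2, k    )   Hy[i,j,k] -> (i+1/2, j,     k+1/2)
//   Ez[i,j,k] -> (i,     j,     k+1/2)   Hz[i,j,k] -> (i+1/2, j+1/2, k    )
// so each E component sits on the face between two material voxels; its
// update coefficients use the arithmetic average of sigma and eps over those
// two voxels.  Any E component touching a perfect-conductor voxel is frozen
// at zero.  The outermost cell layer acts as a PEC shell behind the CPML.
//
// The drive is a lumped resistive voltage source (Taflove-style semi-implicit
// update): undriven feed edges keep the resistor term and act as matched
// terminations.  Steady state is detected from per-period phasors at monitor
// cells; the converged complex field is extracted by a discrete Fourier
// projection over one final full period and returned collocated at voxel
// centers.
//
// Numerics: single-precision fields with FTZ/DAZ enabled (subnormal traps
// otherwise dominate runtime as the wavefront decays into the PML); the
// E-update b-coefficients carry the 1/dx of the curl so the inner loops are
// pure fused multiply-adds; CPML c-coefficients are dimensionless and act on
// raw field differences.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
#if defined(__SSE2__) || defined(__x86_64__)
#include <xmmintrin.h>
#include <pmmintrin.h>
#define PH_SET_FTZ() do { _MM_SET_FLUSH_ZERO_MODE(_MM_FLUSH_ZERO_ON); \
  _MM_SET_DENORMALS_ZERO_MODE(_MM_DENORMALS_ZERO_ON); } while (0)
#else
#define PH_SET_FTZ() do {} while (0)
#endif
using namespace Rcpp;

static const double EPS0 = 8.8541878128e-12;
static const double MU0  = 1.25663706212e-6;
static const double ETA0 = 376.730313668;

struct PmlProfile {
  // b, c (dimensionless), 1/kappa at integer and half positions along one axis
  std::vector<float> b_i, c_i, ik_i, b_h, c_h, ik_h;
};

// depth: fraction into the PML (0 at interface, 1 at outer boundary), <0 interior
static void pml_coeffs(double depth, double smax, double kmax, double amax,
                       double m, double dt, double &b, double &c, double &ik) {
  if (depth <= 0.0) { b = 0.0; c = 0.0; ik = 1.0; return; }
  double u = depth > 1.0 ? 1.0 : depth;
  double s = smax * std::pow(u, m);
  double k = 1.0 + (kmax - 1.0) * std::pow(u, m);
  double a = amax * (1.0 - u);
  b = std::exp(-(s / k + a) * dt / EPS0);
  double denom = k * (s + k * a);
  c = (denom > 0.0) ? s * (b - 1.0) / denom : 0.0;
  ik = 1.0 / k;
}

// CPML profile for one axis of length n with npml layers at each end.
static PmlProfile build_pml(int n, int npml, double dx, double dt,
                            double kmax, double amax, double m,
                            double sigma_scale) {
  PmlProfile p;
  p.b_i.assign(n, 0.f); p.c_i.assign(n, 0.f); p.ik_i.assign(n, 1.f);
  p.b_h.assign(n, 0.f); p.c_h.assign(n, 0.f); p.ik_h.assign(n, 1.f);
  double smax = sigma_scale * 0.8 * (m + 1.0) / (ETA0 * dx);
  // PML occupies cells [1, npml] and [n-2-npml, n-2]; cells 0 / n-1 are the
  // PEC shell.  Inner PML interfaces at indices npml + 1 and n-2-npml.
  double lo = npml + 1.0, hi = (double)(n - 2 - npml);
  for (int i = 0; i < n; ++i) {
    double pos_i = (double)i, pos_h = (double)i + 0.5;
    double d_i = std::max((lo - pos_i) / npml, (pos_i - hi) / npml);
    double d_h = std::max((lo - pos_h) / npml, (pos_h - hi) / npml);
    double b, c, ik;
    pml_coeffs(d_i, smax, kmax, amax, m, dt, b, c, ik);
    p.b_i[i] = (float)b; p.c_i[i] = (float)c; p.ik_i[i] = (float)ik;
    pml_coeffs(d_h, smax, kmax, amax, m, dt, b, c, ik);
    p.b_h[i] = (float)b; p.c_h[i] = (float)c; p.ik_h[i] = (float)ik;
  }
  return p;
}

// [[Rcpp::export(name = ".fdtd_run_3d")]]
List fdtd_run_3d(IntegerVector labels, IntegerVector dims,
                 NumericVector mat_sigma, NumericVector mat_eps,
                 LogicalVector mat_pec,
                 double dx, double dt, int steps_per_period,
                 NumericVector waveform,
                 IntegerMatrix src_ijk, IntegerVector src_comp,
                 NumericVector src_res, NumericVector src_amp,
                 int n_pml, double kappa_max, double alpha_max, double grade_m,
                 double pml_sigma_scale, IntegerMatrix monitors,
                 double tol, int max_periods, int min_periods) {
  PH_SET_FTZ();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const size_t N = (size_t)nx * ny * nz;
  const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
  const double idx_ = 1.0 / dx;

  std::vector<float> Ex(N, 0.f), Ey(N, 0.f), Ez(N, 0.f);
  std::vector<float> Hx(N, 0.f), Hy(N, 0.f), Hz(N, 0.f);
  // per-edge update coefficients; bE* carry the 1/dx of the curl
  std::vector<float> aEx(N, 0.f), bEx(N, 0.f);
  std::vector<float> aEy(N, 0.f), bEy(N, 0.f);
  std::vector<float> aEz(N, 0.f), bEz(N, 0.f);

  {
    const int nmat = mat_sigma.size();
    const int *lab = INTEGER(labels);
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          size_t id = i + sy * j + sz * k;
          int l0 = lab[id];
          if (l0 < 0 || l0 >= nmat) stop("label out of range");
          int nb[3];
          nb[0] = (i + 1 < nx) ? lab[id + sx] : l0;
          nb[1] = (j + 1 < ny) ? lab[id + sy] : l0;
          nb[2] = (k + 1 < nz) ? lab[id + sz] : l0;
          float *pa[3] = {&aEx[id], &aEy[id], &aEz[id]};
          float *pb[3] = {&bEx[id], &bEy[id], &bEz[id]};
          for (int c = 0; c < 3; ++c) {
            if (mat_pec[l0] || mat_pec[nb[c]]) { *pa[c] = 0.f; *pb[c] = 0.f; }
            else {
              double s = 0.5 * (mat_sigma[l0] + mat_sigma[nb[c]]);
              double e = 0.5 * (mat_eps[l0] + mat_eps[nb[c]]) * EPS0;
              double a = s * dt / (2.0 * e);
              *pa[c] = (float)((1.0 - a) / (1.0 + a));
              *pb[c] = (float)((dt / e) / (1.0 + a) * idx_);
            }
          }
        }
  }

  // lumped resistive sources: override coefficients, remember drive constants
  const int nsrc = src_ijk.nrow();
  std::vector<size_t> s_idx(nsrc);
  std::vector<int> s_comp(nsrc);
  std::vector<double> s_cs(nsrc), s_amp(nsrc);
  for (int s = 0; s < nsrc; ++s) {
    int i = src_ijk(s, 0), j = src_ijk(s, 1), k = src_ijk(s, 2);
    if (i < 1 || i >= nx - 1 || j < 1 || j >= ny - 1 || k < 1 || k >= nz - 1)
      stop("source site outside grid interior");
    size_t id = i + sy * j + sz * k;
    int comp = src_comp[s];
    size_t step = (comp == 0) ? sx : (comp == 1) ? sy : sz;
    int l0 = labels[id], l1 = labels[id + step];
    double sg = 0.5 * (mat_sigma[l0] + mat_sigma[l1]);
    double e  = 0.5 * (mat_eps[l0] + mat_eps[l1]) * EPS0;
    double R = src_res[s];
    double a = sg * dt / (2.0 * e);
    double bl = dt / (2.0 * e * R * dx);      // lumped resistor term
    double den = 1.0 + a + bl;
    float ca = (float)((1.0 - a - bl) / den);
    float cb = (float)((dt / e) / den * idx_);
    if (comp == 0) { aEx[id] = ca; bEx[id] = cb; }
    else if (comp == 1) { aEy[id] = ca; bEy[id] = cb; }
    else { aEz[id] = ca; bEz[id] = cb; }
    s_idx[s] = id; s_comp[s] = comp;
    s_cs[s] = (dt / (e * R * dx * dx)) / den; // per volt of source waveform
    s_amp[s] = src_amp[s];
  }

  PmlProfile px = build_pml(nx, n_pml, dx, dt, kappa_max, alpha_max, grade_m, pml_sigma_scale);
  PmlProfile py = build_pml(ny, n_pml, dx, dt, kappa_max, alpha_max, grade_m, pml_sigma_scale);
  PmlProfile pz = build_pml(nz, n_pml, dx, dt, kappa_max, alpha_max, grade_m, pml_sigma_scale);

  // psi convolution memories (full-size arrays, touched only in PML slabs)
  std::vector<float> pExy(N, 0.f), pExz(N, 0.f), pEyx(N, 0.f), pEyz(N, 0.f),
      pEzx(N, 0.f), pEzy(N, 0.f), pHxy(N, 0.f), pHxz(N, 0.f), pHyx(N, 0.f),
      pHyz(N, 0.f), pHzx(N, 0.f), pHzy(N, 0.f);

  const float hb = (float)(dt / (MU0 * dx));

  auto in_pml = [&](int pos, int n) {
    return (pos <= n_pml) || (pos >= n - 2 - n_pml);
  };

  const int nmon = monitors.nrow();
  std::vector<size_t> mon_idx(nmon);
  for (int m = 0; m < nmon; ++m)
    mon_idx[m] = (size_t)monitors(m, 0) + sy * monitors(m, 1) + sz * monitors(m, 2);
  std::vector<double> mon_re(3 * nmon), mon_im(3 * nmon);
  std::vector<double> mon_mag_prev(nmon, -1.0);

  const int Np = steps_per_period;
  std::vector<double> ctab(Np), stab(Np);
  for (int n = 0; n < Np; ++n) {
    double ph = 2.0 * M_PI * n / Np;
    ctab[n] = std::cos(ph); stab[n] = std::sin(ph);
  }

  std::vector<float> axr, axi, ayr, ayi, azr, azi;

  double residual = NA_REAL;
  bool converged = false, measuring = false;
  int period = 0, periods_run = 0;
  if ((long)waveform.size() < (long)max_periods * Np)
    stop("waveform shorter than max_periods");

  long n_glob = 0;
  for (period = 0; period < max_periods; ++period) {
    std::fill(mon_re.begin(), mon_re.end(), 0.0);
    std::fill(mon_im.begin(), mon_im.end(), 0.0);
    for (int n = 0; n < Np; ++n, ++n_glob) {
      // ---- H update (E at step n available) ----
      for (int k = 1; k < nz - 1; ++k) {
        const bool kp = in_pml(k, nz);
        const float bkh = pz.b_h[k], ckh = pz.c_h[k], ikzh = pz.ik_h[k];
        for (int j = 1; j < ny - 1; ++j) {
          const bool jp = in_pml(j, ny);
          const float bjh = py.b_h[j], cjh = py.c_h[j], ikyh = py.ik_h[j];
          const size_t row = sy * j + sz * k;
          for (int i = 1; i < nx - 1; ++i) {
            const size_t id = i + row;
            const float dEz_y = Ez[id + sy] - Ez[id];
            const float dEy_z = Ey[id + sz] - Ey[id];
            const float dEx_z = Ex[id + sz] - Ex[id];
            const float dEz_x = Ez[id + sx] - Ez[id];
            const float dEy_x = Ey[id + sx] - Ey[id];
            const float dEx_y = Ex[id + sy] - Ex[id];
            const float ikxh = px.ik_h[i];
            float ty_x = dEz_y * ikyh, tz_x = dEy_z * ikzh;
            float tz_y = dEx_z * ikzh, tx_y = dEz_x * ikxh;
            float tx_z = dEy_x * ikxh, ty_z = dEx_y * ikyh;
            if (jp) {
              pHxy[id] = bjh * pHxy[id] + cjh * dEz_y;
              pHzy[id] = bjh * pHzy[id] + cjh * dEx_y;
              ty_x += pHxy[id]; ty_z += pHzy[id];
            }
            if (kp) {
              pHxz[id] = bkh * pHxz[id] + ckh * dEy_z;
              pHyz[id] = bkh * pHyz[id] + ckh * dEx_z;
              tz_x += pHxz[id]; tz_y += pHyz[id];
            }
            if (in_pml(i, nx)) {
              pHyx[id] = px.b_h[i] * pHyx[id] + px.c_h[i] * dEz_x;
              pHzx[id] = px.b_h[i] * pHzx[id] + px.c_h[i] * dEy_x;
              tx_y += pHyx[id]; tx_z += pHzx[id];
            }
            Hx[id] -= hb * (ty_x - tz_x);
            Hy[id] -= hb * (tz_y - tx_y);
            Hz[id] -= hb * (tx_z - ty_z);
          }
        }
      }
      // ---- E update (uses H at step n+1/2) ----
      for (int k = 1; k < nz - 1; ++k) {
        const bool kp = in_pml(k, nz);
        const float bki = pz.b_i[k], cki = pz.c_i[k], ikz = pz.ik_i[k];
        for (int j = 1; j < ny - 1; ++j) {
          const bool jp = in_pml(j, ny);
          const float bji = py.b_i[j], cji = py.c_i[j], iky = py.ik_i[j];
          const size_t row = sy * j + sz * k;
          for (int i = 1; i < nx - 1; ++i) {
            const size_t id = i + row;
            const float dHz_y = Hz[id] - Hz[id - sy];
            const float dHy_z = Hy[id] - Hy[id - sz];
            const float dHx_z = Hx[id] - Hx[id - sz];
            const float dHz_x = Hz[id] - Hz[id - sx];
            const float dHy_x = Hy[id] - Hy[id - sx];
            const float dHx_y = Hx[id] - Hx[id - sy];
            const float ikx = px.ik_i[i];
            float ty_x = dHz_y * iky, tz_x = dHy_z * ikz;
            float tz_y = dHx_z * ikz, tx_y = dHz_x * ikx;
            float tx_z = dHy_x * ikx, ty_z = dHx_y * iky;
            if (jp) {
              pExy[id] = bji * pExy[id] + cji * dHz_y;
              pEzy[id] = bji * pEzy[id] + cji * dHx_y;
              ty_x += pExy[id]; ty_z += pEzy[id];
            }
            if (kp) {
              pExz[id] = bki * pExz[id] + cki * dHy_z;
              pEyz[id] = bki * pEyz[id] + cki * dHx_z;
              tz_x += pExz[id]; tz_y += pEyz[id];
            }
            if (in_pml(i, nx)) {
              pEyx[id] = px.b_i[i] * pEyx[id] + px.c_i[i] * dHz_x;
              pEzx[id] = px.b_i[i] * pEzx[id] + px.c_i[i] * dHy_x;
              tx_y += pEyx[id]; tx_z += pEzx[id];
            }
            Ex[id] = aEx[id] * Ex[id] + bEx[id] * (ty_x - tz_x);
            Ey[id] = aEy[id] * Ey[id] + bEy[id] * (tz_y - tx_y);
            Ez[id] = aEz[id] * Ez[id] + bEz[id] * (tx_z - ty_z);
          }
        }
      }
      // ---- sources (voltage value at t = (n+1/2) dt) ----
      double v = waveform[n_glob];
      for (int s = 0; s < nsrc; ++s) {
        if (s_amp[s] == 0.0) continue;
        float add = (float)(-s_cs[s] * s_amp[s] * v);
        if (s_comp[s] == 0) Ex[s_idx[s]] += add;
        else if (s_comp[s] == 1) Ey[s_idx[s]] += add;
        else Ez[s_idx[s]] += add;
      }
      // ---- monitor DFT accumulation (collocated E at monitor cells) ----
      double cn = ctab[n], sn = stab[n];
      for (int m = 0; m < nmon; ++m) {
        size_t id = mon_idx[m];
        double ex = 0.5 * (Ex[id] + Ex[id - sx]);
        double ey = 0.5 * (Ey[id] + Ey[id - sy]);
        double ez = 0.5 * (Ez[id] + Ez[id - sz]);
        mon_re[3 * m]     += ex * cn; mon_im[3 * m]     -= ex * sn;
        mon_re[3 * m + 1] += ey * cn; mon_im[3 * m + 1] -= ey * sn;
        mon_re[3 * m + 2] += ez * cn; mon_im[3 * m + 2] -= ez * sn;
      }
      // ---- full-grid DFT during the measurement period ----
      if (measuring) {
        float cf = (float)cn, sf = (float)sn;
        for (size_t id = 0; id < N; ++id) {
          axr[id] += Ex[id] * cf; axi[id] -= Ex[id] * sf;
          ayr[id] += Ey[id] * cf; ayi[id] -= Ey[id] * sf;
          azr[id] += Ez[id] * cf; azi[id] -= Ez[id] * sf;
        }
      }
    } // steps within period
    periods_run = period + 1;

    // per-period monitor magnitudes and residual
    double mmax = 0.0;
    std::vector<double> mag(nmon);
    for (int m = 0; m < nmon; ++m) {
      double s2 = 0.0;
      for (int c = 0; c < 3; ++c) {
        double re = 2.0 * mon_re[3 * m + c] / Np;
        double im = 2.0 * mon_im[3 * m + c] / Np;
        s2 += re * re + im * im;
      }
      mag[m] = std::sqrt(s2);
      if (mag[m] > mmax) mmax = mag[m];
    }
    if (!std::isfinite(mmax) || mmax > 1e30)
      stop("FDTD instability (field blow-up): check the Courant factor");
    if (measuring) break; // measurement period complete
    double res = NA_REAL;
    if (mon_mag_prev[0] >= 0.0 && mmax > 0.0) {
      double d = 0.0;
      for (int m = 0; m < nmon; ++m)
        d = std::max(d, std::fabs(mag[m] - mon_mag_prev[m]));
      res = d / mmax;
    }
    for (int m = 0; m < nmon; ++m) mon_mag_prev[m] = mag[m];
    if (R_finite(res)) residual = res;
    bool last_chance = (period == max_periods - 2);
    if ((R_finite(res) && res < tol && periods_run >= min_periods) || last_chance) {
      converged = R_finite(res) && res < tol;
      measuring = true;
      axr.assign(N, 0.f); axi.assign(N, 0.f);
      ayr.assign(N, 0.f); ayi.assign(N, 0.f);
      azr.assign(N, 0.f); azi.assign(N, 0.f);
    }
    Rcpp::checkUserInterrupt();
  } // periods

  // collocate phasors at voxel centers; amplitude normalization 2/Np
  ComplexVector Excc(N), Eycc(N), Ezcc(N);
  double nrm = 2.0 / Np;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        size_t id = i + sy * j + sz * k;
        size_t ixm = (i > 0) ? id - sx : id;
        size_t iym = (j > 0) ? id - sy : id;
        size_t izm = (k > 0) ? id - sz : id;
        Rcomplex cx, cy, cz;
        cx.r = nrm * 0.5 * (axr[id] + axr[ixm]);
        cx.i = nrm * 0.5 * (axi[id] + axi[ixm]);
        cy.r = nrm * 0.5 * (ayr[id] + ayr[iym]);
        cy.i = nrm * 0.5 * (ayi[id] + ayi[iym]);
        cz.r = nrm * 0.5 * (azr[id] + azr[izm]);
        cz.i = nrm * 0.5 * (azi[id] + azi[izm]);
        Excc[id] = cx; Eycc[id] = cy; Ezcc[id] = cz;
      }
  return List::create(_["Ex"] = Excc, _["Ey"] = Eycc, _["Ez"] = Ezcc,
                      _["residual"] = residual, _["converged"] = converged,
                      _["periods_run"] = periods_run);
}

// 1-D reduction of the same discretization (TEM line along z: Ex(z), Hy(z)),
// used for quantitative validation against the closed-form attenuation
// constant and for the normal-incidence CPML reflection check.
// Soft additive source on Ex at cell k_src.  Returns the steady-period DFT
// phasor of Ex(z) plus the full time series at a monitor cell.
// [[Rcpp::export(name = ".fdtd_run_1d")]]
List fdtd_run_1d(NumericVector sigma, NumericVector eps_r,
                 double dz, double dt, int steps_per_period,
                 NumericVector waveform, int k_src, int k_mon,
                 int n_pml, double kappa_max, double alpha_max, double grade_m,
                 double pml_sigma_scale, int n_periods) {
  PH_SET_FTZ();
  const int nz = sigma.size();
  std::vector<double> Ex(nz, 0.0), Hy(nz, 0.0), pE(nz, 0.0), pH(nz, 0.0);
  std::vector<double> aE(nz, 0.0), bE(nz, 0.0);
  for (int k = 0; k < nz; ++k) {
    double e = eps_r[k] * EPS0;
    double a = sigma[k] * dt / (2.0 * e);
    aE[k] = (1.0 - a) / (1.0 + a);
    bE[k] = (dt / e) / (1.0 + a);
  }
  PmlProfile pz = build_pml(nz, n_pml, dz, dt, kappa_max, alpha_max, grade_m,
                            pml_sigma_scale);
  const double idz = 1.0 / dz, hb = dt / (MU0 * dz);
  const int Np = steps_per_period;
  long nsteps = (long)n_periods * Np;
  if ((long)waveform.size() < nsteps) stop("waveform too short");
  std::vector<double> ctab(Np), stab(Np);
  for (int n = 0; n < Np; ++n) {
    ctab[n] = std::cos(2.0 * M_PI * n / Np);
    stab[n] = std::sin(2.0 * M_PI * n / Np);
  }
  std::vector<double> ar(nz, 0.0), ai(nz, 0.0);
  NumericVector mon(nsteps);
  auto in_pml = [&](int pos) { return pos <= n_pml || pos >= nz - 2 - n_pml; };
  long n_glob = 0;
  for (int p = 0; p < n_periods; ++p) {
    bool measure = (p == n_periods - 1);
    for (int n = 0; n < Np; ++n, ++n_glob) {
      for (int k = 1; k < nz - 1; ++k) {
        double dE = Ex[k + 1] - Ex[k];
        double t = dE * pz.ik_h[k];
        if (in_pml(k)) {
          pH[k] = pz.b_h[k] * pH[k] + pz.c_h[k] * dE;
          t += pH[k];
        }
        Hy[k] += hb * t;
      }
      for (int k = 1; k < nz - 1; ++k) {
        double dH = Hy[k] - Hy[k - 1];
        double t = dH * pz.ik_i[k];
        if (in_pml(k)) {
          pE[k] = pz.b_i[k] * pE[k] + pz.c_i[k] * dH;
          t += pE[k];
        }
        Ex[k] = aE[k] * Ex[k] + bE[k] * idz * t;
      }
      Ex[k_src] += waveform[n_glob];
      mon[n_glob] = Ex[k_mon];
      if (measure) {
        for (int k = 0; k < nz; ++k) {
          ar[k] += Ex[k] * ctab[n];
          ai[k] -= Ex[k] * stab[n];
        }
      }
    }
  }
  ComplexVector ph(nz);
  for (int k = 0; k < nz; ++k) {
    Rcomplex c; c.r = 2.0 * ar[k] / Np; c.i = 2.0 * ai[k] / Np;
    ph[k] = c;
  }
  return List::create(_["phasor"] = ph, _["monitor"] = mon);
}
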