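// Fixed-step Euler-Maruyama integrator for the full functional architecture.
// The R level owns all parameter objects; everything arrives here flattened.
// The formulas mirror the pure-R reference implementations (planar_flow,
// wta_rhs, feedback_rhs, switching_rhs, kick_rhs) exactly; tests assert the
// agreement.

#include <Rcpp.h>
using namespace Rcpp;

static inline double plogis_(double x) { return 1.0 / (1.0 + std::exp(-x)); }

struct Mode {
  int type;              // 0 linear, 1 monostable, 2 bistable, 3 limit cycle
  double mu_e, a_z, b_z, u0, k_lin, tgt_y, tgt_z;
  double g_ul, g_uh, g_dl, g_dh, y_c, y_steep, v_sharp;
  double r, c, ecc, mu;
  bool needs_kick;
  double kick_amp, prox_w, inh_eps0, inh_a, inh_b, inh_c;
  int natt;
  double attY[2], attZ[2];
};

// planar field in glyph coordinates (Y, Z); tau_f = 1
static inline void planar_field(const Mode& m, double Y, double Z,
                                double& dY, double& dZ) {
  double u = Y - 1.0;
  dY = (Z - (u * u * u - u)) / m.mu_e;
  dZ = -m.mu_e * (m.a_z * Z + m.b_z * (u - m.u0));
}

static inline double shape_vel(const Mode& m, double Y, double dY) {
  double up = plogis_(dY / m.v_sharp);
  double hi = plogis_((Y - m.y_c) * m.y_steep);
  double g = up * (m.g_ul * (1 - hi) + m.g_uh * hi) +
             (1 - up) * (m.g_dl * (1 - hi) + m.g_dh * hi);
  return std::fabs(dY) * g;
}

// full 3-D field of one mode at (x, y, z)
static inline void mode_field3(const Mode& m, double y, double z,
                               double& fx, double& fy, double& fz) {
  if (m.type == 0) {
    fx = 0.0;
    fy = -m.k_lin * (y - m.tgt_y);
    fz = -m.k_lin * (z - m.tgt_z);
    return;
  }
  double Y = (y - m.c) / m.r + 1.0;
  double Z = z / m.r;
  double dY, dZ;
  planar_field(m, Y, Z, dY, dZ);
  // manifold contraction: the radial distance to the cylinder surface
  // decays with rate 1/(mu * tau_f)
  double gy = (y - m.c) / m.r, gz = z / (m.ecc * m.r);
  double rho = std::sqrt(gy * gy + gz * gz);
  double cy = 0.0, cz = 0.0;
  if (rho > 1e-4) {
    double grad_y = (y - m.c) / (m.r * m.r * rho);
    double grad_z = z / (m.ecc * m.r * m.ecc * m.r * rho);
    double ng2 = grad_y * grad_y + grad_z * grad_z;
    if (ng2 > 1e-8) {
      double fac = -(rho - 1.0) / (m.mu * ng2);
      cy = fac * grad_y;
      cz = fac * grad_z;
    }
  }
  // normal projection: remove the contraction component along the planar flow
  double fvy = m.r * dY, fvz = m.r * dZ;
  double nf2 = fvy * fvy + fvz * fvz;
  if (nf2 > 1e-6) {
    double dp = (cy * fvy + cz * fvz) / nf2;
    cy -= dp * fvy;
    cz -= dp * fvz;
  }
  fx = m.r * shape_vel(m, Y, dY);
  fy = fvy + cy;
  fz = fvz + cz;
}

static inline double proximity(const Mode& m, double y, double z) {
  if (m.natt == 0) return 0.0;
  double Y = (y - m.c) / m.r + 1.0;
  double Z = z / m.r;
  double best = R_PosInf;
  for (int a = 0; a < m.natt; ++a) {
    double dy = Y - m.attY[a], dz = (Z - m.attZ[a]) / m.ecc;
    double d2 = dy * dy + dz * dz;
    if (d2 < best) best = d2;
  }
  return std::exp(-best / (m.prox_w * m.prox_w));
}

// [[Rcpp::export]]
List sim_core(NumericMatrix modepar, IntegerVector seq_ids,
              NumericVector k_inh, NumericVector k_exc,
              NumericVector primacy, double C0, double C_ns,
              List scales, List kickpar,
              double dt, int n_steps, double noise_s, double xi_min,
              NumericVector noise_on,   // u, xi, nu, lam, kick
              NumericVector u0, NumericVector xi0, NumericVector nu0,
              NumericVector lam0, NumericVector kick0,
              int record_stride, int record_mode,
              Nullable<NumericMatrix> xi_frozen_) {
  const int K = modepar.nrow();
  const int Kp = seq_ids.size();
  std::vector<Mode> M(K);
  for (int j = 0; j < K; ++j) {
    Mode& m = M[j];
    int c = 0;
    m.type = (int)modepar(j, c++);   m.mu_e = modepar(j, c++);
    m.a_z = modepar(j, c++);         m.b_z = modepar(j, c++);
    m.u0 = modepar(j, c++);          m.k_lin = modepar(j, c++);
    m.tgt_y = modepar(j, c++);       m.tgt_z = modepar(j, c++);
    m.g_ul = modepar(j, c++);        m.g_uh = modepar(j, c++);
    m.g_dl = modepar(j, c++);        m.g_dh = modepar(j, c++);
    m.y_c = modepar(j, c++);         m.y_steep = modepar(j, c++);
    m.v_sharp = modepar(j, c++);     m.r = modepar(j, c++);
    m.c = modepar(j, c++);           m.ecc = modepar(j, c++);
    m.mu = modepar(j, c++);          m.needs_kick = modepar(j, c++) > 0.5;
    m.kick_amp = modepar(j, c++);    m.prox_w = modepar(j, c++);
    m.inh_eps0 = modepar(j, c++);    m.inh_a = modepar(j, c++);
    m.inh_b = modepar(j, c++);       m.inh_c = modepar(j, c++);
    m.natt = (int)modepar(j, c++);
    m.attY[0] = modepar(j, c++);     m.attZ[0] = modepar(j, c++);
    m.attY[1] = modepar(j, c++);     m.attZ[1] = modepar(j, c++);
  }
  const double tau_c = as<double>(scales["tau_c"]);
  const double tau_v = as<double>(scales["tau_v"]);
  const double tau_lam = as<double>(scales["tau_lambda"]);
  const double kp_tau_delta = as<double>(kickpar["tau_delta"]);
  const double kp_tau_cr = as<double>(kickpar["tau_cr"]);
  const double kp_theta_cr = as<double>(kickpar["theta_cr"]);
  const double kp_theta1 = as<double>(kickpar["theta_1"]);
  const double kp_gam1 = as<double>(kickpar["gamma_1"]);
  const double kp_ingain = as<double>(kickpar["in_gain"]);
  const double kp_eps2 = as<double>(kickpar["eps_2"]);
  const double kp_d2g = as<double>(kickpar["d2_gain"]);
  const double kp_sup = as<double>(kickpar["cr_suppress"]);
  const double kp_fldw = as<double>(kickpar["fld_w"]);
  const double kp_wg = as<double>(kickpar["w_gain"]);
  const double kp_tw = as<double>(kickpar["tau_w"]);

  const bool frozen = xi_frozen_.isNotNull();
  NumericMatrix xi_frozen;
  if (frozen) {
    xi_frozen = NumericMatrix(xi_frozen_);
    if (xi_frozen.nrow() < n_steps + 1 || xi_frozen.ncol() != K)
      stop("xi_frozen must be (n_steps + 1) x K");
  }

  // state
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> xi(xi0.begin(), xi0.end());
  std::vector<double> nu(nu0.begin(), nu0.end());
  std::vector<double> lam(lam0.begin(), lam0.end());
  double d1 = kick0[0], d2 = kick0[1], dcr = kick0[2];
  double wmem = (kick0.size() > 3) ? kick0[3] : 0.0;
  if (frozen) for (int j = 0; j < K; ++j) xi[j] = xi_frozen(0, j);

  const int n_rec = n_steps / record_stride + 1;
  // columns: full: t,x,y,z,dy,dz, xi[K], dy_kick,dz_kick, d1,d2,dcr,
  //          nu[Kp], lam[Kp]
  // analysis: t,x,y,z,dy,dz, delta_y,delta_z, d1, xi[seq (Kp)]
  const int ncol = (record_mode == 0) ? (6 + K + 5 + 2 * Kp) : (9 + Kp);
  NumericMatrix out(n_rec, ncol);
  int rec = 0;

  std::vector<double> fx(K), fy(K), fz(K), L(K), C(K);
  const double sq_dt = std::sqrt(dt);
  const double n_u = noise_on[0], n_xi = noise_on[1], n_nu = noise_on[2],
               n_lam = noise_on[3], n_k = noise_on[4];
  RNGScope scope;

  for (int step = 0; step <= n_steps; ++step) {
    // ------ deterministic RHS ------
    double Fy = 0, Fz = 0, Fx = 0;
    for (int j = 0; j < K; ++j) {
      mode_field3(M[j], u[1], u[2], fx[j], fy[j], fz[j]);
      Fx += xi[j] * fx[j];
      Fy += xi[j] * fy[j];
      Fz += xi[j] * fz[j];
    }
    // kick output + trigger input
    double prox = 0.0, ky = 0.0, kz = 0.0;
    for (int j = 0; j < K; ++j) {
      if (!M[j].needs_kick || xi[j] <= 1e-12) continue;
      prox += xi[j] * proximity(M[j], u[1], u[2]);
      double e = M[j].ecc;
      double cY = (u[1] - M[j].c) / M[j].r;
      double cZ = u[2] / (M[j].r * e);
      double nn = std::sqrt(cY * cY + cZ * cZ);
      double ty, tz;
      if (nn < 1e-6) { ty = 0.0; tz = 1.0; }
      else {
        ty = cZ / nn; tz = -cY / nn * e;
        double tn = std::sqrt(ty * ty + tz * tz);
        ty /= tn; tz /= tn;
      }
      ky += xi[j] * M[j].kick_amp * M[j].r * ty;
      kz += xi[j] * M[j].kick_amp * M[j].r * tz;
    }
    // only the supra-threshold part of the pulse reaches the output (and
    // the feedback quantum): sub-ignition leakage would otherwise offset
    // the rest position and stall the trigger
    double d1p = (d1 > 0.15) ? (d1 - 0.15) / 0.85 : 0.0;
    double delta_y = d1p * ky, delta_z = d1p * kz;
    double fgate = 1.0 / (1.0 + (Fy * Fy + Fz * Fz) / (kp_fldw * kp_fldw));
    double G = fgate * prox;
    double trig = plogis_((dcr - kp_theta_cr) / 0.01);
    double dd1 = (kp_gam1 * d1 * (d1 - kp_theta1) * (1 - d1) - d2 +
                  kp_ingain * trig) / kp_tau_delta;
    double dd2 = kp_eps2 * (kp_d2g * d1 - d2) / kp_tau_delta;
    double ddcr = (G * (1 - kp_sup * d2) - dcr) / kp_tau_cr;
    double dwmem = kp_wg * d1p * (1 - wmem) - wmem / kp_tw;

    double du_x = Fx, du_y = Fy + delta_y, du_z = Fz + delta_z;

    // gates and primacy from lambda
    std::vector<double> dxi(K, 0.0), dnu(Kp, 0.0), dlam(Kp, 0.0);
    if (!frozen) {
      for (int j = 0; j < K; ++j) { L[j] = 1.0; C[j] = C_ns; }
      double tailprod = 1.0;
      for (int p = Kp - 1; p >= 0; --p) {
        tailprod *= lam[p] * lam[p];
        int id = seq_ids[p] - 1;
        L[id] = tailprod;
        C[id] = C0 + (primacy[p] - C0) * lam[p] * lam[p];
      }
      double S = 0.0;
      for (int j = 0; j < K; ++j) S += xi[j] * xi[j] / C[j];
      const double kappa = 3.0;   // competition rate scale (see wta_rhs)
      for (int j = 0; j < K; ++j)
        dxi[j] = (kappa / C[j]) * xi[j] * (L[j] - C[j] * S) / tau_c;
      // feedback integration and switching
      double F_exc = 1.0 - lam[Kp - 1] * lam[Kp - 1];
      for (int p = 0; p < Kp; ++p) {
        int id = seq_ids[p] - 1;
        const Mode& m = M[id];
        double drive = m.inh_eps0 + m.inh_c +
          m.inh_a * std::max(wmem, 0.0) +
          m.inh_b * std::max(dcr, 0.0);
        double F_inh = xi[id] * drive;
        dnu[p] = (k_inh[p] * F_inh - k_exc[p] * F_exc * nu[p]) / tau_v;
        double S_val = plogis_(20.0 * (nu[p] - 0.5));
        double a = 2.2 * S_val - 0.8;
        double mlam = std::fabs(lam[p]);
        double sgn = (lam[p] > 0) - (lam[p] < 0);
        double push = (a < 0) ? 0.25 * sgn * (-a) * (1.0 - mlam) : 0.0;
        if (a > 1) push -= 0.25 * sgn * (a - 1.0) * mlam;
        dlam[p] = (-lam[p] * (mlam - 1.0) * (mlam - a) + push) / tau_lam;
      }
    }

    // ------ record (state plus RHS at this state) ------
    if (step % record_stride == 0) {
      double t = step * dt;
      if (record_mode == 0) {
        int c = 0;
        out(rec, c++) = t;
        out(rec, c++) = u[0]; out(rec, c++) = u[1]; out(rec, c++) = u[2];
        out(rec, c++) = du_y; out(rec, c++) = du_z;   // deterministic part
        for (int j = 0; j < K; ++j) out(rec, c++) = xi[j];
        out(rec, c++) = delta_y; out(rec, c++) = delta_z;
        out(rec, c++) = d1; out(rec, c++) = d2; out(rec, c++) = dcr;
        for (int p = 0; p < Kp; ++p) out(rec, c++) = nu[p];
        for (int p = 0; p < Kp; ++p) out(rec, c++) = lam[p];
      } else {
        int c = 0;
        out(rec, c++) = t;
        out(rec, c++) = u[0]; out(rec, c++) = u[1]; out(rec, c++) = u[2];
        out(rec, c++) = du_y; out(rec, c++) = du_z;
        out(rec, c++) = delta_y; out(rec, c++) = delta_z;
        out(rec, c++) = d1;
        for (int p = 0; p < Kp; ++p) out(rec, c++) = xi[seq_ids[p] - 1];
      }
      ++rec;
    }
    if (step == n_steps) break;

    // ------ Euler-Maruyama update ------
    double wy = 0, wz = 0;
    if (noise_s > 0) {
      double wx = n_u * noise_s * sq_dt * R::norm_rand();
      wy = n_u * noise_s * sq_dt * R::norm_rand();
      wz = n_u * noise_s * sq_dt * R::norm_rand();
      u[0] += dt * du_x + wx;
      u[1] += dt * du_y + wy;
      u[2] += dt * du_z + wz;
    } else {
      u[0] += dt * du_x; u[1] += dt * du_y; u[2] += dt * du_z;
    }
    // store realized derivative (deterministic + noise/dt) in the NEXT
    // record?  The analysed derivative series is the one recorded above
    // plus the realized noise increment; patch the row just written.
    if ((step % record_stride) == 0 && noise_s > 0 && n_u > 0) {
      out(rec - 1, 4) += wy / dt;
      out(rec - 1, 5) += wz / dt;
    }
    if (!frozen) {
      for (int j = 0; j < K; ++j) {
        double w = (noise_s > 0 && n_xi > 0)
          ? noise_s * sq_dt * R::norm_rand() : 0.0;
        xi[j] += dt * dxi[j] + w;
        if (xi[j] < xi_min) xi[j] = xi_min;
      }
      for (int p = 0; p < Kp; ++p) {
        double wn = (noise_s > 0 && n_nu > 0)
          ? noise_s * sq_dt * R::norm_rand() : 0.0;
        nu[p] += dt * dnu[p] + wn;
        double wl = (noise_s > 0 && n_lam > 0)
          ? noise_s * sq_dt * R::norm_rand() : 0.0;
        lam[p] += dt * dlam[p] + wl;
        if (lam[p] > 1.0) lam[p] = 1.0;
        if (lam[p] < -1.0) lam[p] = -1.0;
      }
    } else {
      for (int j = 0; j < K; ++j) xi[j] = xi_frozen(step + 1, j);
    }
    {
      double w1 = (noise_s > 0 && n_k > 0)
        ? noise_s * sq_dt * R::norm_rand() : 0.0;
      double w2 = (noise_s > 0 && n_k > 0)
        ? noise_s * sq_dt * R::norm_rand() : 0.0;
      double w3 = (noise_s > 0 && n_k > 0)
        ? noise_s * sq_dt * R::norm_rand() : 0.0;
      d1 += dt * dd1 + w1;
      if (d1 < 0) d1 = 0;      // pulse variable: no recovery undershoot
      d2 += dt * dd2 + w2;
      dcr += dt * ddcr + w3;
      double w4 = (noise_s > 0 && n_k > 0)
        ? noise_s * sq_dt * R::norm_rand() : 0.0;
      wmem += dt * dwmem + w4;
    }
    if (!std::isfinite(u[0]) || !std::isfinite(u[1]) ||
        !std::isfinite(u[2]) ||
        std::fabs(u[0]) > 1e6 || std::fabs(u[1]) > 1e6 ||
        std::fabs(u[2]) > 1e6)
      stop("sim_core: state blow-up at t = %f", step * dt);
  }

  NumericVector last_u = NumericVector::create(u[0], u[1], u[2]);
  return List::create(_["traj"] = out,
                      _["last_u"] = last_u,
                      _["last_xi"] = NumericVector(xi.begin(), xi.end()),
                      _["last_nu"] = NumericVector(nu.begin(), nu.end()),
                      _["last_lam"] = NumericVector(lam.begin(), lam.end()),
                      _["last_kick"] = NumericVector::create(d1, d2, dcr, wmem));
}
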