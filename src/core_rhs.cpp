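#include <Rcpp.h>
using namespace Rcpp;

// Right-hand side of the core PCP reaction network. Mirrors the reference
// implementation in R/core.R (core_rhs); kept in C++ because the fixed-step
// integrator evaluates it tens of thousands of times per simulation.
//
// State layout (length 3n + 7*6n): DshC, PkC, VangC cell blocks, then the
// n x 6 edge blocks Fz, Vm, Dm, DF, PV, B0, BD in column-major order.
// `part` holds 1-based linear indices of the apposed edge in an n x 6
// matrix (boundary edges point to themselves: mirror boundary).

// pars: numeric vector in the fixed order assembled by core_par_vec() in
// R/core.R.
// [[Rcpp::export]]
NumericVector core_rhs_cpp(NumericVector y, int n, IntegerVector part,
                           NumericVector m, NumericVector pars) {
  const double k_T = pars[0], k_ret = pars[1];
  const double k1 = pars[2], k1_off = pars[3], beta = pars[4];
  const double k2 = pars[5], k2_off = pars[6], s_D = pars[7];
  const double k3 = pars[8], k3_off = pars[9], delta = pars[10];
  const double k4 = pars[11], k4_off = pars[12], gamma = pars[13];
  const double D_m = pars[14], D_c = pars[15], phi = pars[16];
  const double h = pars[17], e_max = pars[18], e_pv = pars[19];
  const double delta_s = pars[20], eps_s = pars[21], delta_g = pars[22];

  const int ne = 6 * n;
  const double *DshC = y.begin(), *PkC = y.begin() + n, *VangC = y.begin() + 2 * n;
  const double *Fz = y.begin() + 3 * n, *Vm = Fz + ne, *Dm = Vm + ne,
               *DF = Dm + ne, *PV = DF + ne, *B0 = PV + ne, *BD = B0 + ne;

  NumericVector dy(y.size());
  double *dDshC = dy.begin(), *dPkC = dy.begin() + n, *dVangC = dy.begin() + 2 * n;
  double *dFz = dy.begin() + 3 * n, *dVm = dFz + ne, *dDm = dVm + ne,
         *dDF = dDm + ne, *dPV = dDF + ne, *dB0 = dPV + ne, *dBD = dB0 + ne;

  std::vector<double> capV(ne), relV(ne);  // bridge Vang capture/release

  auto pw = [&](double x) { return h == 2.0 ? x * x : std::pow(x, h); };

  for (int e = 0; e < 6; ++e) {
    const int eL = (e + 5) % 6, eR = (e + 1) % 6;
    for (int i = 0; i < n; ++i) {
      const int k = e * n + i;
      const int q = part[k] - 1;               // apposed edge, linear index
      const double Vm_ac = Vm[q];
      const double DFBD = DF[k] + BD[k];
      const double DFBD_ac = DF[q] + BD[q];
      const double inh = 1.0 / (1.0 + pw(beta * PV[k]));

      const double r_T = k_T * m[k] * DshC[i];
      const double r_ret = k_ret * Dm[k];
      const double r_DF_on = k1 * Dm[k] * Fz[k] * inh;
      const double u_ff = pw(delta * DFBD_ac);
      const double r_DF_off = k1_off * DF[k] *
        (1.0 + phi * u_ff / (1.0 + u_ff));
      const double r_B0_on = k2 * Fz[k] * Vm_ac;
      const double r_B0_off = k2_off * B0[k];
      const double r_BD_on1 = k2 * DF[k] * Vm_ac / (1.0 + u_ff);
      const double r_BD_off1 = s_D * k2_off * BD[k] *
        (1.0 + phi * u_ff / (1.0 + u_ff));
      const double r_BD_on2 = k1 * Dm[k] * B0[k] * inh;
      const double r_BD_off2 = k1_off * BD[k];

      const double u = pw(delta * DFBD_ac);
      const double sat = u / (1.0 + u);
      const double S_tot = Fz[q] + DF[q] + B0[q] + BD[q];
      const double u_g = pw(delta_g * S_tot);
      const double gate = u_g / (1.0 + u_g);
      const double r_V_on = k3 * VangC[i] * (1.0 + e_max * sat) * gate;
      const double r_V_off = k3_off * Vm[k];

      const double inh_pv = 1.0 / (1.0 + pw(gamma * DFBD));
      const double r_PV_on = k4 * PkC[i] * Vm[k] * inh_pv *
        (1.0 + e_pv * sat);
      const double u_s = pw(delta_s * S_tot);
      const double r_PV_off = k4_off * PV[k] *
        (eps_s + (1.0 - eps_s) / (1.0 + u_s));

      capV[k] = r_B0_on + r_BD_on1;
      relV[k] = r_B0_off + r_BD_off1;

      dDshC[i] += -r_T + r_ret;
      dPkC[i] += -r_PV_on + r_PV_off;
      dVangC[i] += -r_V_on + r_V_off;

      const double lapFz = Fz[eL * n + i] + Fz[eR * n + i] - 2.0 * Fz[k];
      const double lapVm = Vm[eL * n + i] + Vm[eR * n + i] - 2.0 * Vm[k];
      const double lapDm = Dm[eL * n + i] + Dm[eR * n + i] - 2.0 * Dm[k];

      dFz[k] = -r_DF_on + r_DF_off - r_B0_on + r_B0_off + D_m * lapFz;
      dVm[k] = r_V_on - r_V_off - r_PV_on + r_PV_off + D_m * lapVm;
      dDm[k] = r_T - r_ret - r_DF_on + r_DF_off - r_BD_on2 + r_BD_off2 +
        D_m * lapDm;
      const double lapDF = DF[eL * n + i] + DF[eR * n + i] - 2.0 * DF[k];
      const double lapPV = PV[eL * n + i] + PV[eR * n + i] - 2.0 * PV[k];
      dDF[k] = r_DF_on - r_DF_off - r_BD_on1 + r_BD_off1 + D_c * lapDF;
      dPV[k] = r_PV_on - r_PV_off + D_c * lapPV;
      dB0[k] = r_B0_on - r_B0_off - r_BD_on2 + r_BD_off2;
      dBD[k] = r_BD_on1 - r_BD_off1 + r_BD_on2 - r_BD_off2;
    }
  }
  // partner's bridge reactions consume/release Vang on THIS membrane
  for (int k = 0; k < ne; ++k) {
    const int q = part[k] - 1;
    dVm[k] += -capV[q] + relV[q];
  }
  return dy;
}
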