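// Two-state diabatic model evaluation and decoherence-corrected
// fewest-switches surface hopping, in Hartree atomic units throughout.
// R-facing wrappers convert fs/eV/Angstrom at the interface.
#include <Rcpp.h>
#include <complex>
#include <cmath>
using namespace Rcpp;

typedef std::complex<double> cplx;

// ---------------------------------------------------------------------------
// Diabatic models. kind 1: Tully single avoided crossing (1 dof),
// params = (A, B, C, D). kind 2: carbonyl-lock (2 dof),
// params = (r0, q0, gap0, slope_r, couple_q, v12, k_lock, k_r, k_q,
//           coupling_decay). All parameters in atomic units.
// V is symmetric 2x2: (V11, V22, V12); dV is 3 x ndof.
// ---------------------------------------------------------------------------
static void eval_model(int kind, const double* p, const double* R,
                       double* V, double* dV, int ndof) {
  if (kind == 1) {
    const double A = p[0], B = p[1], C = p[2], D = p[3];
    const double x = R[0];
    double v11, d11;
    if (x >= 0.0) { v11 =  A * (1.0 - std::exp(-B * x)); }
    else          { v11 = -A * (1.0 - std::exp( B * x)); }
    d11 = A * B * std::exp(-B * std::fabs(x));
    const double v12 = C * std::exp(-D * x * x);
    V[0] = v11; V[1] = -v11; V[2] = v12;
    dV[0] = d11; dV[1] = -d11; dV[2] = -2.0 * D * x * v12;
  } else if (kind == 2) {
    const double r0 = p[0], q0 = p[1], gap0 = p[2], slope_r = p[3],
      couple_q = p[4], v12 = p[5], k_lock = p[6], k_r = p[7], k_q = p[8],
      cdecay = p[9];
    const double dr = R[0] - r0, dq = R[1] - q0;
    const double keff = k_r + k_lock;
    const double v11 = 0.5 * keff * dr * dr + 0.5 * k_q * dq * dq;
    const double gap = gap0 - slope_r * dr - couple_q * (q0 - R[1]);
    const double c12 = v12 * std::exp(-cdecay * dr * dr);
    V[0] = v11; V[1] = v11 + gap; V[2] = c12;
    // columns: dof r then dof q; rows V11,V22,V12
    dV[0] = keff * dr;             dV[3] = k_q * dq;
    dV[1] = keff * dr - slope_r;   dV[4] = k_q * dq + couple_q;
    dV[2] = -2.0 * cdecay * dr * c12; dV[5] = 0.0;
  } else {
    stop("unknown model kind code");
  }
}

static int model_ndof(int kind) { return kind == 1 ? 1 : 2; }

// [[Rcpp::export]]
List cpp_model_eval(int kind, NumericVector params, NumericVector R) {
  int ndof = model_ndof(kind);
  if ((int)R.size() != ndof) stop("coordinate vector has wrong length");
  double V[3];
  std::vector<double> dV(3 * ndof);
  eval_model(kind, params.begin(), R.begin(), V, dV.data(), ndof);
  NumericMatrix Vm(2, 2), G11(1, ndof), G22(1, ndof), G12(1, ndof);
  Vm(0,0) = V[0]; Vm(1,1) = V[1]; Vm(0,1) = Vm(1,0) = V[2];
  NumericMatrix dVm(3, ndof);
  for (int k = 0; k < 3 * ndof; ++k) dVm[k] = dV[k];
  return List::create(_["V"] = Vm, _["dV"] = dVm);
}

// ---------------------------------------------------------------------------
// Adiabatization of a symmetric 2x2: energies, eigenvectors (columns),
// adiabatic gradients and the nonadiabatic coupling vector d01.
// ---------------------------------------------------------------------------
struct Adiab {
  double E0, E1;
  double U[4];                 // column-major 2x2, columns = eigvecs
  std::vector<double> g0, g1;  // adiabatic gradients
  std::vector<double> d01;     // NACV, 1/bohr
  bool capped;
};

static void adiabatize_core(int kind, const double* p, const double* R,
                            const double* prevU, Adiab& out, int ndof) {
  double V[3];
  std::vector<double> dV(3 * ndof);
  eval_model(kind, p, R, V, dV.data(), ndof);
  const double m = 0.5 * (V[0] + V[1]);
  const double del = 0.5 * (V[1] - V[0]);
  const double W = std::sqrt(del * del + V[2] * V[2]);
  out.E0 = m - W; out.E1 = m + W;
  // ground eigenvector via the numerically dominant closed form:
  // (W+del, -V12) for del >= 0, (V12, del-W) otherwise; both satisfy the
  // eigen equation and the chosen one has norm >= W, so normalization is
  // safe whenever the states are split at all.
  double u0x, u0y;
  if (del >= 0) { u0x = W + del; u0y = -V[2]; }
  else          { u0x = V[2];    u0y = del - W; }
  double n0 = std::sqrt(u0x * u0x + u0y * u0y);
  if (n0 < 1e-300) {        // exact degeneracy: fall back to diabatic order
    u0x = 1.0; u0y = 0.0; n0 = 1.0;
  }
  u0x /= n0; u0y /= n0;
  double u1x = -u0y, u1y = u0x;   // orthogonal complement
  if (prevU != nullptr) {         // phase continuity vs previous frame
    if (u0x * prevU[0] + u0y * prevU[1] < 0) { u0x = -u0x; u0y = -u0y; }
    if (u1x * prevU[2] + u1y * prevU[3] < 0) { u1x = -u1x; u1y = -u1y; }
  }
  out.U[0] = u0x; out.U[1] = u0y; out.U[2] = u1x; out.U[3] = u1y;
  out.g0.assign(ndof, 0.0); out.g1.assign(ndof, 0.0); out.d01.assign(ndof, 0.0);
  double gap = out.E1 - out.E0;
  out.capped = false;
  double denom = gap;
  if (denom < 1e-8) { denom = 1e-8; out.capped = true; }
  for (int k = 0; k < ndof; ++k) {
    const double a = dV[0 + 3 * k], b = dV[1 + 3 * k], c = dV[2 + 3 * k];
    // u_i^T dV u_j with dV = [[a, c], [c, b]]
    out.g0[k] = a * u0x * u0x + b * u0y * u0y + 2.0 * c * u0x * u0y;
    out.g1[k] = a * u1x * u1x + b * u1y * u1y + 2.0 * c * u1x * u1y;
    const double off = a * u0x * u1x + b * u0y * u1y +
      c * (u0x * u1y + u0y * u1x);
    out.d01[k] = off / denom;
  }
}

// [[Rcpp::export]]
List cpp_adiabatize(int kind, NumericVector params, NumericVector R,
                    Nullable<NumericMatrix> prevU) {
  int ndof = model_ndof(kind);
  if ((int)R.size() != ndof) stop("coordinate vector has wrong length");
  Adiab a;
  const double* pu = nullptr;
  double pubuf[4];
  if (prevU.isNotNull()) {
    NumericMatrix pm(prevU);
    pubuf[0] = pm(0,0); pubuf[1] = pm(1,0); pubuf[2] = pm(0,1); pubuf[3] = pm(1,1);
    pu = pubuf;
  } else {
    // detect machine-precision degeneracy with no history to lean on
    double V[3]; std::vector<double> dV(3 * ndof);
    eval_model(kind, params.begin(), R.begin(), V, dV.data(), ndof);
    double del = 0.5 * (V[1] - V[0]);
    if (std::sqrt(del * del + V[2] * V[2]) < 1e-12)
      stop("adiabatic states degenerate at machine precision and no previous frame supplied; use a smaller step so the seam is bracketed");
  }
  adiabatize_core(kind, params.begin(), R.begin(), pu, a, ndof);
  NumericMatrix U(2, 2);
  U(0,0) = a.U[0]; U(1,0) = a.U[1]; U(0,1) = a.U[2]; U(1,1) = a.U[3];
  return List::create(
    _["energies"] = NumericVector::create(a.E0, a.E1),
    _["grad0"] = NumericVector(a.g0.begin(), a.g0.end()),
    _["grad1"] = NumericVector(a.g1.begin(), a.g1.end()),
    _["nacv"] = NumericVector(a.d01.begin(), a.d01.end()),
    _["eigvec"] = U, _["capped"] = a.capped);
}

// ---------------------------------------------------------------------------
// Electronic propagation: RK4 on the adiabatic TDSE
//   dc0/dt = -i E0 c0 + sigma c1
//   dc1/dt = -i E1 c1 - sigma c0,     sigma = Rdot . d01
// with linear interpolation of E and sigma across the nuclear step and the
// mean energy removed (a global phase). Returns the propagated amplitudes,
// the accumulated fewest-switches integrand for active -> other, and the
// norm deviation before renormalization.
// ---------------------------------------------------------------------------
struct CoefStep { cplx c0, c1; double phop; double norm_dev; };

static void propagate_coeff_core(cplx c0, cplx c1,
                                 double E0a, double E1a, double E0b, double E1b,
                                 double siga, double sigb,
                                 double dt, int nsub, int active,
                                 CoefStep& out) {
  const double h = dt / nsub;
  double phop = 0.0;
  for (int s = 0; s < nsub; ++s) {
    const double t0 = (double)s / nsub, t1 = (double)(s + 1) / nsub,
      tm = 0.5 * (t0 + t1);
    // values at substep start / mid / end (linear interpolation)
    double e0[3], e1[3], sg[3], tt[3] = { t0, tm, t1 };
    for (int k = 0; k < 3; ++k) {
      e0[k] = E0a + (E0b - E0a) * tt[k];
      e1[k] = E1a + (E1b - E1a) * tt[k];
      sg[k] = siga + (sigb - siga) * tt[k];
      const double em = 0.5 * (e0[k] + e1[k]);   // remove global phase
      e0[k] -= em; e1[k] -= em;
    }
    const cplx I(0.0, 1.0);
    auto deriv = [&](cplx a0, cplx a1, int k, cplx& d0, cplx& d1) {
      d0 = -I * e0[k] * a0 + sg[k] * a1;
      d1 = -I * e1[k] * a1 - sg[k] * a0;
    };
    cplx k10, k11, k20, k21, k30, k31, k40, k41;
    deriv(c0, c1, 0, k10, k11);
    deriv(c0 + 0.5 * h * k10, c1 + 0.5 * h * k11, 1, k20, k21);
    deriv(c0 + 0.5 * h * k20, c1 + 0.5 * h * k21, 1, k30, k31);
    deriv(c0 + h * k30, c1 + h * k31, 2, k40, k41);
    c0 += (h / 6.0) * (k10 + 2.0 * k20 + 2.0 * k30 + k40);
    c1 += (h / 6.0) * (k11 + 2.0 * k21 + 2.0 * k31 + k41);
    // fewest-switches integrand, Re part, rectangle rule at substep end:
    // P_{i->j} += -2 Re(c_i^* c_j sigma_ij) h / |c_i|^2, sigma_01 = +sg
    const double sig_now = sg[2];
    const cplx ca = (active == 0) ? c0 : c1;
    const cplx cb = (active == 0) ? c1 : c0;
    const double sigma_ab = (active == 0) ? sig_now : -sig_now;
    const double pa = std::norm(ca);
    if (pa > 1e-12)
      phop += -2.0 * (std::conj(ca) * cb).real() * sigma_ab * h / pa;
  }
  const double nrm = std::sqrt(std::norm(c0) + std::norm(c1));
  out.norm_dev = std::fabs(nrm - 1.0);
  out.c0 = c0 / nrm; out.c1 = c1 / nrm;
  out.phop = phop;
}

// [[Rcpp::export]]
List cpp_propagate_coeff(ComplexVector c, NumericVector Eprev,
                         NumericVector Ecur, double sigma_prev,
                         double sigma_cur, double dt, int nsub, int active) {
  if (c.size() != 2) stop("two amplitudes expected");
  CoefStep st;
  cplx c0(c[0].r, c[0].i), c1(c[1].r, c[1].i);
  propagate_coeff_core(c0, c1, Eprev[0], Eprev[1], Ecur[0], Ecur[1],
                       sigma_prev, sigma_cur, dt, nsub, active, st);
  ComplexVector out(2);
  out[0].r = st.c0.real(); out[0].i = st.c0.imag();
  out[1].r = st.c1.real(); out[1].i = st.c1.imag();
  double p = st.phop;
  if (p < 0.0) p = 0.0;
  if (p > 1.0) p = 1.0;
  return List::create(_["c"] = out, _["p_hop"] = p,
                      _["norm_dev"] = st.norm_dev);
}

// ---------------------------------------------------------------------------
// Energy-based decoherence: damp inactive amplitudes with
// tau = (1/|Ej-Ei|) (1 + C/Ekin), then restore the total norm through the
// active amplitude.
// ---------------------------------------------------------------------------
static void decoherence_core(cplx& c0, cplx& c1, int active, double gap,
                             double ekin, double Cpar, double dt) {
  if (ekin <= 0.0 || gap <= 0.0) return;   // tau -> infinity: no damping
  const double tau = (1.0 / gap) * (1.0 + Cpar / ekin);
  const double f = std::exp(-dt / tau);
  cplx& inact = (active == 0) ? c1 : c0;
  cplx& act = (active == 0) ? c0 : c1;
  inact *= f;
  const double pin = std::norm(inact);
  const double pact = std::norm(act);
  if (pact > 1e-300) act *= std::sqrt((1.0 - pin) / pact);
}

// [[Rcpp::export]]
ComplexVector cpp_apply_decoherence(ComplexVector c, int active, double gap,
                                    double ekin, double Cpar, double dt) {
  cplx c0(c[0].r, c[0].i), c1(c[1].r, c[1].i);
  decoherence_core(c0, c1, active, gap, ekin, Cpar, dt);
  ComplexVector out(2);
  out[0].r = c0.real(); out[0].i = c0.imag();
  out[1].r = c1.real(); out[1].i = c1.imag();
  return out;
}

// ---------------------------------------------------------------------------
// Velocity rescaling along the NACV direction so that total energy is
// conserved across a hop. Returns ok = FALSE for a frustrated hop.
// ---------------------------------------------------------------------------
static bool rescale_core(std::vector<double>& v, const double* mass,
                         const double* d, int ndof, double dEpot) {
  // v' = v + gamma d / m ; solve A g^2 + B g - dEpot = 0
  double A = 0.0, B = 0.0, dn = 0.0;
  for (int k = 0; k < ndof; ++k) {
    A += 0.5 * d[k] * d[k] / mass[k];
    B += v[k] * d[k];
    dn += d[k] * d[k];
  }
  if (dn < 1e-24) {
    // coupling direction undefined: rescale speed isotropically
    double ke = 0.0;
    for (int k = 0; k < ndof; ++k) ke += 0.5 * mass[k] * v[k] * v[k];
    if (ke + dEpot < 0.0) return false;
    const double s = std::sqrt((ke + dEpot) / ke);
    for (int k = 0; k < ndof; ++k) v[k] *= s;
    return true;
  }
  const double disc = B * B + 4.0 * A * dEpot;
  if (disc < 0.0) return false;
  const double sq = std::sqrt(disc);
  const double g1 = (-B + sq) / (2.0 * A), g2 = (-B - sq) / (2.0 * A);
  const double g = (std::fabs(g1) < std::fabs(g2)) ? g1 : g2;
  for (int k = 0; k < ndof; ++k) v[k] += g * d[k] / mass[k];
  return true;
}

// [[Rcpp::export]]
List cpp_rescale_velocities(NumericVector v, NumericVector mass,
                            NumericVector d, double dEpot) {
  std::vector<double> vv(v.begin(), v.end());
  bool ok = rescale_core(vv, mass.begin(), d.begin(), v.size(), dEpot);
  return List::create(_["ok"] = ok,
                      _["v"] = NumericVector(vv.begin(), vv.end()));
}

// ---------------------------------------------------------------------------
// Full DC-TSH trajectory. Per nuclear step: nuclei (velocity Verlet, with
// optional Langevin O-step) -> adiabatize -> electronic coefficients ->
// decoherence -> hop attempt. Constraints are harmonic biases on model
// degrees of freedom. All quantities in atomic units.
// constraints: matrix with columns (dof 1-based, k, target); target = NaN
// means "value at excitation".
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_run_trajectory(int kind, NumericVector params, NumericVector mass,
                        NumericVector R0, NumericVector V0,
                        ComplexVector c_init, int active0,
                        double dt, int nsteps, int nsub,
                        double gap_stop, bool stop_at_gap,
                        bool forbid_recrossing,
                        double deco_C, bool deco_enabled,
                        NumericMatrix constraints,
                        double langevin_gamma, double langevin_kT,
                        double x_stop) {
  const int ndof = model_ndof(kind);
  if ((int)R0.size() != ndof) stop("initial coordinates have wrong length");
  std::vector<double> R(R0.begin(), R0.end()), V(V0.begin(), V0.end());
  cplx c0(c_init[0].r, c_init[0].i), c1(c_init[1].r, c_init[1].i);
  int active = active0;

  const int ncon = constraints.nrow();
  std::vector<int> con_dof(ncon);
  std::vector<double> con_k(ncon), con_t(ncon);
  for (int i = 0; i < ncon; ++i) {
    con_dof[i] = (int)constraints(i, 0) - 1;
    if (con_dof[i] < 0 || con_dof[i] >= ndof) stop("constraint dof out of range");
    con_k[i] = constraints(i, 1);
    con_t[i] = R_IsNA(constraints(i, 2)) || std::isnan(constraints(i, 2))
      ? R[con_dof[i]] : constraints(i, 2);
  }
  auto constraint_force = [&](const std::vector<double>& x,
                              std::vector<double>& f) {
    double e = 0.0;
    for (int i = 0; i < ncon; ++i) {
      const double dx = x[con_dof[i]] - con_t[i];
      f[con_dof[i]] -= con_k[i] * dx;
      e += 0.5 * con_k[i] * dx * dx;
    }
    return e;
  };

  const int nmax = nsteps + 1;
  NumericMatrix pos(nmax, ndof), vel(nmax, ndof), ener(nmax, 2),
    nacv(nmax, ndof);
  IntegerVector state(nmax);
  ComplexMatrix coef(nmax, 2);
  NumericVector tvec(nmax), ekin_v(nmax), etot(nmax), sigma_v(nmax);
  std::vector<int> hop_frame, hop_from, hop_to;
  int frustrated = 0, norm_warn = 0, capped_n = 0, first_crossing = 0;
  double max_norm_dev = 0.0;
  int term = 0;   // 0 = t_max, 1 = gap-stop, 2 = left region (x_stop)

  Adiab ad;
  adiabatize_core(kind, params.begin(), R.data(), nullptr, ad, ndof);
  std::vector<double> force(ndof);
  auto fill_force = [&](const Adiab& a, std::vector<double>& f) {
    const std::vector<double>& g = (active == 0) ? a.g0 : a.g1;
    for (int k = 0; k < ndof; ++k) f[k] = -g[k];
    return constraint_force(R, f);
  };
  double e_con = fill_force(ad, force);

  const bool use_langevin = langevin_gamma > 0.0;
  const double oc1 = use_langevin ? std::exp(-langevin_gamma * dt) : 1.0;
  const double oc2 = use_langevin ? std::sqrt(1.0 - oc1 * oc1) : 0.0;

  int nrec = 0;
  auto record = [&](int istep) {
    for (int k = 0; k < ndof; ++k) {
      pos(nrec, k) = R[k]; vel(nrec, k) = V[k]; nacv(nrec, k) = ad.d01[k];
    }
    ener(nrec, 0) = ad.E0; ener(nrec, 1) = ad.E1;
    state[nrec] = active;
    coef(nrec, 0).r = c0.real(); coef(nrec, 0).i = c0.imag();
    coef(nrec, 1).r = c1.real(); coef(nrec, 1).i = c1.imag();
    double ke = 0.0, sg = 0.0;
    for (int k = 0; k < ndof; ++k) {
      ke += 0.5 * mass[k] * V[k] * V[k];
      sg += V[k] * ad.d01[k];
    }
    ekin_v[nrec] = ke; sigma_v[nrec] = sg;
    etot[nrec] = ke + ((active == 0) ? ad.E0 : ad.E1) + e_con;
    tvec[nrec] = istep * dt;
    ++nrec;
  };
  record(0);

  for (int istep = 1; istep <= nsteps; ++istep) {
    const Adiab prev = ad;
    double sig_prev = 0.0;
    for (int k = 0; k < ndof; ++k) sig_prev += V[k] * prev.d01[k];

    // --- nuclear step (BAOAB; reduces to velocity Verlet when gamma = 0)
    for (int k = 0; k < ndof; ++k) V[k] += 0.5 * dt * force[k] / mass[k];
    for (int k = 0; k < ndof; ++k) R[k] += 0.5 * dt * V[k];
    if (use_langevin)
      for (int k = 0; k < ndof; ++k)
        V[k] = oc1 * V[k] + oc2 * std::sqrt(langevin_kT / mass[k]) * norm_rand();
    for (int k = 0; k < ndof; ++k) R[k] += 0.5 * dt * V[k];

    adiabatize_core(kind, params.begin(), R.data(), prev.U, ad, ndof);
    if (ad.capped) ++capped_n;
    e_con = fill_force(ad, force);
    for (int k = 0; k < ndof; ++k) V[k] += 0.5 * dt * force[k] / mass[k];

    double sig_cur = 0.0;
    for (int k = 0; k < ndof; ++k) sig_cur += V[k] * ad.d01[k];

    // --- electronic coefficients
    CoefStep st;
    propagate_coeff_core(c0, c1, prev.E0, prev.E1, ad.E0, ad.E1,
                         sig_prev, sig_cur, dt, nsub, active, st);
    c0 = st.c0; c1 = st.c1;
    if (st.norm_dev > max_norm_dev) max_norm_dev = st.norm_dev;
    if (st.norm_dev > 1e-4) ++norm_warn;

    // --- decoherence
    double ekin = 0.0;
    for (int k = 0; k < ndof; ++k) ekin += 0.5 * mass[k] * V[k] * V[k];
    if (deco_enabled)
      decoherence_core(c0, c1, active, ad.E1 - ad.E0, ekin, deco_C, dt);

    // --- hop attempt (substep-accumulated probability, one draw per step)
    double p = st.phop;
    if (p < 0.0) p = 0.0;
    if (p > 1.0) p = 1.0;
    const int target = 1 - active;
    if (forbid_recrossing && active == 0 && target == 1) p = 0.0;
    if (p > 0.0 && unif_rand() < p) {
      const double e_from = (active == 0) ? ad.E0 : ad.E1;
      const double e_to = (target == 0) ? ad.E0 : ad.E1;
      const double dEpot = e_from - e_to;   // >0 downward
      if (rescale_core(V, mass.begin(), ad.d01.data(), ndof, dEpot)) {
        hop_frame.push_back(istep); hop_from.push_back(active);
        hop_to.push_back(target);
        active = target;
        e_con = fill_force(ad, force);   // forces on the new surface
      } else {
        ++frustrated;
      }
    }

    record(istep);
    if (active == 0 && first_crossing == 0) first_crossing = nrec;  // 1-based
    const double gap = ad.E1 - ad.E0;
    if (stop_at_gap && active == 0 && gap < gap_stop) { term = 1; break; }
    if (!std::isnan(x_stop) && std::fabs(R[0]) > x_stop) { term = 2; break; }
  }

  // trim records to nrec rows
  NumericMatrix posT(nrec, ndof), velT(nrec, ndof), enerT(nrec, 2),
    nacvT(nrec, ndof);
  ComplexMatrix coefT(nrec, 2);
  IntegerVector stateT(nrec);
  NumericVector tT(nrec), ekT(nrec), etT(nrec), sgT(nrec);
  for (int i = 0; i < nrec; ++i) {
    for (int k = 0; k < ndof; ++k) {
      posT(i,k) = pos(i,k); velT(i,k) = vel(i,k); nacvT(i,k) = nacv(i,k);
    }
    enerT(i,0) = ener(i,0); enerT(i,1) = ener(i,1);
    coefT(i,0) = coef(i,0); coefT(i,1) = coef(i,1);
    stateT[i] = state[i]; tT[i] = tvec[i]; ekT[i] = ekin_v[i];
    etT[i] = etot[i]; sgT[i] = sigma_v[i];
  }
  IntegerMatrix hops(hop_frame.size(), 3);
  for (size_t i = 0; i < hop_frame.size(); ++i) {
    hops(i, 0) = hop_frame[i] + 1;  // 1-based frame index
    hops(i, 1) = hop_from[i]; hops(i, 2) = hop_to[i];
  }
  return List::create(
    _["positions"] = posT, _["velocities"] = velT, _["energies"] = enerT,
    _["nacv"] = nacvT, _["state"] = stateT, _["coeffs"] = coefT,
    _["time"] = tT, _["ekin"] = ekT, _["etot"] = etT, _["sigma"] = sgT,
    _["hops"] = hops, _["frustrated"] = frustrated,
    _["first_crossing"] = first_crossing,
    _["max_norm_dev"] = max_norm_dev, _["norm_warnings"] = norm_warn,
    _["nacv_capped"] = capped_n, _["terminated"] = term);
}

// ---------------------------------------------------------------------------
// Ground-state Langevin (BAOAB) sampling on the adiabatic ground surface.
// Returns the final position/velocity of a single chain.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_langevin_chain(int kind, NumericVector params, NumericVector mass,
                        NumericVector R0, NumericVector V0,
                        double dt, int nsteps, double gamma, double kT) {
  const int ndof = model_ndof(kind);
  std::vector<double> R(R0.begin(), R0.end()), V(V0.begin(), V0.end());
  Adiab ad;
  adiabatize_core(kind, params.begin(), R.data(), nullptr, ad, ndof);
  std::vector<double> force(ndof);
  for (int k = 0; k < ndof; ++k) force[k] = -ad.g0[k];
  const double c1 = std::exp(-gamma * dt), c2 = std::sqrt(1.0 - c1 * c1);
  for (int istep = 0; istep < nsteps; ++istep) {
    const Adiab prev = ad;
    for (int k = 0; k < ndof; ++k) V[k] += 0.5 * dt * force[k] / mass[k];
    for (int k = 0; k < ndof; ++k) R[k] += 0.5 * dt * V[k];
    for (int k = 0; k < ndof; ++k)
      V[k] = c1 * V[k] + c2 * std::sqrt(kT / mass[k]) * norm_rand();
    for (int k = 0; k < ndof; ++k) R[k] += 0.5 * dt * V[k];
    adiabatize_core(kind, params.begin(), R.data(), prev.U, ad, ndof);
    for (int k = 0; k < ndof; ++k) force[k] = -ad.g0[k];
    for (int k = 0; k < ndof; ++k) V[k] += 0.5 * dt * force[k] / mass[k];
  }
  return List::create(_["R"] = NumericVector(R.begin(), R.end()),
                      _["V"] = NumericVector(V.begin(), V.end()));
}
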