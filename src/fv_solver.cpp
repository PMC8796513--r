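// Finite-volume kernel for 1D tracer transport along the neuraxis.
//
// Conservative operator-split update per time step:
//   1. explicit upwind advection (van Leer MUSCL limiter) of the combined
//      fluid throughflow + steady-streaming drift flux, plus injection and
//      ventricular-compartment sources,
//   2. implicit (backward Euler) axial dispersion, solved with a
//      pre-factorized Thomas algorithm (coefficients are time-invariant).
//
// Amounts are tracked as concentration (uM) x cell volume (mL) = nmol, so
// total mass, cumulative cranial outflow and cumulative injection form a
// closed ledger.
#include <Rcpp.h>
using namespace Rcpp;

static inline double van_leer(double r) {
  double ar = std::fabs(r);
  return (r + ar) / (1.0 + ar);
}

// limited face value for donor cell `up` with downwind cell `dn` and
// upstream-of-donor cell `uu` (-1 when absent -> first order)
static inline double face_value(const std::vector<double>& c,
                                int up, int dn, int uu, bool limiter) {
  double cu = c[up], cd = c[dn];
  if (!limiter || uu < 0) return cu;
  double den = cd - cu;
  if (std::fabs(den) < 1e-300) return cu;
  double r = (cu - c[uu]) / den;
  return cu + 0.5 * van_leer(r) * den;
}

// [[Rcpp::export(name = ".fv_transport_core")]]
List fv_transport_core(int n, double dz,
                       NumericVector V,        // cell volumes (mL)
                       NumericVector Aface,    // face areas (cm^2), n+1
                       NumericVector Dface,    // dispersion at faces (cm^2/s)
                       NumericVector ussface,  // drift at faces (cm/s)
                       bool absorbing,
                       int junction_cell,      // 1-based
                       double prod_rate,       // mL/s into the ventricles
                       NumericVector vent_vol, // 5 compartment volumes (mL)
                       bool icv,
                       int inj_cell,           // 1-based SAS cell (ignored if icv)
                       double bolus_rate, double bolus_conc, double bolus_end,
                       double flush_rate, double flush_start, double flush_end,
                       double dt, int n_steps, int out_every,
                       bool limiter, NumericVector c0) {
  if (n < 2 || n_steps < 1 || out_every < 1)
    stop("invalid solver dimensions");
  const int jc = junction_cell - 1;
  const int kin = icv ? -1 : inj_cell - 1;
  const int nv = vent_vol.size();

  // steady drift component of the face fluxes (mL/s, +z = caudad)
  std::vector<double> Fdrift(n + 1), F(n + 1);
  for (int f = 0; f <= n; ++f) Fdrift[f] = Aface[f] * ussface[f];
  Fdrift[n] = 0.0;                  // closed caudal wall
  if (!absorbing) Fdrift[0] = 0.0;  // reflecting cranial wall

  // injection rate schedule (piecewise constant)
  auto inj_rate = [&](double t) -> double {
    if (t < bolus_end) return bolus_rate;
    if (t >= flush_start && t < flush_end) return flush_rate;
    return 0.0;
  };
  auto inj_conc = [&](double t) -> double {
    return (t < bolus_end) ? bolus_conc : 0.0;
  };

  // fluid throughflow: every source caudal of a face drains through it
  // toward the cranial outlet
  auto set_fluxes = [&](double q_inj) {
    double q_vent = prod_rate + (icv ? q_inj : 0.0);
    double q_sas = icv ? 0.0 : q_inj;
    for (int f = 0; f <= n; ++f) {
      double q = 0.0;
      if (absorbing) {
        if (jc > f) q += q_vent;
        if (kin >= 0 && kin + 1 > f) q += q_sas;
      }
      F[f] = Fdrift[f] - q;
    }
    if (!absorbing && (prod_rate > 0 || q_inj > 0))
      stop("reflecting boundaries require zero production and injection flow");
    F[n] = 0.0;
  };

  // CFL check against the worst-case fluxes
  {
    double q_worst = std::max(bolus_rate, flush_rate);
    set_fluxes(q_worst);
    for (int f = 0; f <= n; ++f) {
      double cfl = std::fabs(F[f]) * dt /
        std::min(V[std::max(f - 1, 0)], V[std::min(f, n - 1)]);
      if (cfl > 0.9)
        stop("advective CFL violated (%.3f) at face %d for dt = %g s; "
             "reduce dt", cfl, f, dt);
    }
    double q_out_worst = prod_rate / 2.0 + (icv ? q_worst : 0.0);
    for (int v = 0; v < nv; ++v) {
      double q = (v <= 1) ? q_out_worst : prod_rate + (icv ? q_worst : 0.0);
      if (q * dt / vent_vol[v] > 0.5)
        stop("ventricular compartment %d too small for dt = %g s; reduce dt",
             v + 1, dt);
    }
  }

  // pre-factorized Thomas coefficients for implicit dispersion
  std::vector<double> G(n + 1), sub(n), diag(n), sup(n), cp(n);
  for (int f = 0; f <= n; ++f)
    G[f] = (f == 0 || f == n) ? 0.0 : Aface[f] * Dface[f] / dz;
  for (int i = 0; i < n; ++i) {
    sub[i] = (i > 0) ? -G[i] * dt / V[i] : 0.0;
    sup[i] = (i < n - 1) ? -G[i + 1] * dt / V[i] : 0.0;
    diag[i] = 1.0 + (G[i] + G[i + 1]) * dt / V[i];
  }
  cp[0] = sup[0] / diag[0];
  for (int i = 1; i < n; ++i)
    cp[i] = sup[i] / (diag[i] - sub[i] * cp[i - 1]);

  const int n_out = n_steps / out_every + 1;
  NumericMatrix conc_out(n, n_out);
  NumericMatrix vent_out(nv, n_out);
  NumericVector t_out(n_out), outflow_out(n_out), injected_out(n_out);

  std::vector<double> c(n, 0.0), m(n, 0.0), flux(n + 1), dp(n);
  std::vector<double> mv(nv, 0.0);
  if (c0.size() == n) {
    for (int i = 0; i < n; ++i) { c[i] = c0[i]; m[i] = c0[i] * V[i]; }
    for (int i = 0; i < n; ++i) conc_out(i, 0) = c[i];
  } else if (c0.size() != 0) {
    stop("initial concentration must have one value per cell");
  }
  double outflow = 0.0, injected = 0.0;
  double cur_q = -1.0;
  int col = 1;
  t_out[0] = 0.0;

  for (int s = 0; s < n_steps; ++s) {
    double t = s * dt;
    double q_inj = inj_rate(t);
    if (q_inj != cur_q) { set_fluxes(q_inj); cur_q = q_inj; }

    // --- advection fluxes ---
    for (int f = 1; f < n; ++f) {
      double Ff = F[f];
      if (Ff == 0.0) { flux[f] = 0.0; continue; }
      double cf = (Ff > 0.0)
        ? face_value(c, f - 1, f, f - 2, limiter)
        : face_value(c, f, f - 1, (f + 1 <= n - 1) ? f + 1 : -1, limiter);
      flux[f] = Ff * cf;
    }
    flux[n] = 0.0;
    flux[0] = (absorbing && F[0] < 0.0) ? F[0] * c[0] : 0.0;

    for (int i = 0; i < n; ++i) m[i] += dt * (flux[i] - flux[i + 1]);
    outflow += -flux[0] * dt;

    // --- sources ---
    double cinj = inj_conc(t);
    if (q_inj > 0.0) injected += q_inj * cinj * dt;
    if (!icv && kin >= 0 && q_inj > 0.0) m[kin] += q_inj * cinj * dt;

    // --- ventricular compartment chain (explicit) ---
    if (prod_rate > 0.0 || icv) {
      double q_icv = icv ? q_inj : 0.0;
      double qL = prod_rate / 2.0 + q_icv, qR = prod_rate / 2.0;
      double qT = prod_rate + q_icv;
      double cL = mv[0] / vent_vol[0], cR = mv[1] / vent_vol[1];
      double c3 = mv[2] / vent_vol[2], cA = mv[3] / vent_vol[3];
      double c4 = mv[4] / vent_vol[4];
      mv[0] += dt * (q_icv * cinj - qL * cL);
      mv[1] += dt * (-qR * cR);
      mv[2] += dt * (qL * cL + qR * cR - qT * c3);
      mv[3] += dt * (qT * c3 - qT * cA);
      mv[4] += dt * (qT * cA - qT * c4);
      m[jc] += dt * qT * c4;
    }

    // --- implicit dispersion (Thomas solve on concentrations) ---
    for (int i = 0; i < n; ++i) c[i] = m[i] / V[i];
    dp[0] = c[0] / diag[0];
    for (int i = 1; i < n; ++i)
      dp[i] = (c[i] - sub[i] * dp[i - 1]) / (diag[i] - sub[i] * cp[i - 1]);
    c[n - 1] = dp[n - 1];
    for (int i = n - 2; i >= 0; --i) c[i] = dp[i] - cp[i] * c[i + 1];
    for (int i = 0; i < n; ++i) m[i] = c[i] * V[i];

    if ((s + 1) % out_every == 0 && col < n_out) {
      double cmin = 0.0;
      for (int i = 0; i < n; ++i) {
        if (c[i] < cmin) cmin = c[i];
        conc_out(i, col) = c[i] < 0.0 ? 0.0 : c[i];
      }
      if (cmin < -1e-12)
        stop("negative concentration %.3g at t = %.1f s; flux limiter "
             "required", cmin, t);
      for (int v = 0; v < nv; ++v) vent_out(v, col) = mv[v] / vent_vol[v];
      t_out[col] = (s + 1) * dt;
      outflow_out[col] = outflow;
      injected_out[col] = injected;
      ++col;
    }
  }

  double mass_in_model = 0.0;
  for (int i = 0; i < n; ++i) mass_in_model += m[i];
  for (int v = 0; v < nv; ++v) mass_in_model += mv[v];

  return List::create(
    _["conc"] = conc_out, _["vent_conc"] = vent_out, _["t_s"] = t_out,
    _["outflow_nmol"] = outflow_out, _["injected_nmol"] = injected_out,
    _["mass_in_model_nmol"] = mass_in_model,
    _["outflow_total_nmol"] = outflow,
    _["injected_total_nmol"] = injected);
}
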