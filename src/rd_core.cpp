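#include <Rcpp.h>
using namespace Rcpp;

// Finite-volume reaction-diffusion core on a 1D material grid.
//
// State per material cell i (amounts, not concentrations):
//   u   free invader, mf free barcode, Ma bound-arrested, Ms bound-swollen
//   w   lab-frame cell width (cartesian) -- radial geometry keeps widths and
//       derives shell volumes from the cumulative radii.
// Units: micrometres, seconds, mM (k_bind passed as 1/(mM s)).

namespace {

// ---- geometry helpers -------------------------------------------------

// Shell volumes (per unit solid angle) and interface areas for radial_1d;
// for cartesian these degenerate to widths and unit areas.
void geom_volumes(const std::vector<double>& w, int geometry,
                  std::vector<double>& vol, std::vector<double>& area_out) {
  const int n = (int)w.size();
  vol.resize(n);
  area_out.resize(n); // area of the OUTER interface of cell i
  if (geometry == 0) {
    for (int i = 0; i < n; ++i) { vol[i] = w[i]; area_out[i] = 1.0; }
  } else {
    double r = 0.0;
    for (int i = 0; i < n; ++i) {
      double r2 = r + w[i];
      vol[i] = (r2 * r2 * r2 - r * r * r) / 3.0;
      area_out[i] = r2 * r2;
      r = r2;
    }
  }
}

// ---- reaction ---------------------------------------------------------

// Analytic update of the local kinetics over dt:
//   binding  du/dt = dmf/dt = -k' u mf   (k' = k_bind / cell volume,
//            second-order in amounts), then
//   swelling Ma -> Ms with first-order rate k_swell.
// Closed forms keep every species non-negative for any dt.
void reaction_update(std::vector<double>& u, std::vector<double>& mf,
                     std::vector<double>& Ma, std::vector<double>& Ms,
                     const std::vector<double>& vol,
                     double k_bind, double k_swell, double dt) {
  const int n = (int)u.size();
  const double es = std::exp(-k_swell * dt);
  for (int i = 0; i < n; ++i) {
    double bound = 0.0;
    if (k_bind > 0.0 && u[i] > 0.0 && mf[i] > 0.0) {
      const double kp = k_bind / vol[i];
      double a0 = u[i], b0 = mf[i];
      const bool swapped = b0 > a0;
      if (swapped) std::swap(a0, b0);
      const double diff = a0 - b0;
      double a_t;
      if (diff < 1e-12 * a0) {
        // equal-concentration second-order kinetics
        a_t = a0 / (1.0 + kp * a0 * dt);
      } else {
        const double z = kp * diff * dt;
        // a(t) = diff / (diff/a0 + (b0/a0) * (1 - exp(-z))), cancellation-safe
        const double denom = diff / a0 + (b0 / a0) * (-std::expm1(-z));
        a_t = diff / denom;
      }
      const double b_t = a_t - diff;
      bound = a0 - a_t; // == b0 - b_t
      if (bound < 0.0) bound = 0.0;
      if (swapped) { u[i] = b_t; mf[i] = a_t; } else { u[i] = a_t; mf[i] = b_t; }
    }
    double Ma1 = Ma[i] + bound;
    double Ma2 = (k_swell > 0.0) ? Ma1 * es : Ma1;
    Ms[i] += Ma1 - Ma2;
    Ma[i] = Ma2;
  }
}

// ---- swelling geometry ------------------------------------------------

// phi_i = swollen fraction of the conserved barcode pool
void swollen_fraction(const std::vector<double>& mf, const std::vector<double>& Ma,
                      const std::vector<double>& Ms, std::vector<double>& phi) {
  const int n = (int)mf.size();
  phi.resize(n);
  for (int i = 0; i < n; ++i) {
    const double tot = mf[i] + Ma[i] + Ms[i];
    phi[i] = (tot > 0.0) ? Ms[i] / tot : 0.0;
  }
}

void width_update(std::vector<double>& w, const std::vector<double>& phi,
                  double w0, double gf) {
  const int n = (int)w.size();
  for (int i = 0; i < n; ++i) {
    double wi = w0 * (1.0 + (gf - 1.0) * phi[i]);
    if (wi > w[i]) w[i] = wi; // monotone by construction (phi only grows)
  }
}

// ---- diffusivity ------------------------------------------------------

void diffusivity_cells(const std::vector<double>& phi, double D0, double D1,
                       double theta, double smooth, std::vector<double>& D) {
  const int n = (int)phi.size();
  D.resize(n);
  if (smooth > 0.0) {
    for (int i = 0; i < n; ++i)
      D[i] = D0 + (D1 - D0) / (1.0 + std::exp(-(phi[i] - theta) / smooth));
  } else {
    for (int i = 0; i < n; ++i) D[i] = (phi[i] >= theta) ? D1 : D0;
  }
}

inline double harmonic(double a, double b) {
  return (a > 0.0 && b > 0.0) ? 2.0 * a * b / (a + b) : 0.0;
}

// ---- diffusion --------------------------------------------------------

// reusable scratch space for the diffusion solvers
struct Workspace {
  std::vector<double> vol, aout, g, sub, dia, sup, rhs, c, du;
  void resize(int n) {
    vol.resize(n); aout.resize(n); g.assign(n, 0.0); sub.assign(n, 0.0);
    dia.resize(n); sup.assign(n, 0.0); rhs.resize(n); c.resize(n); du.resize(n);
  }
};

// Backward-Euler conservative finite volume for the free invader, with an
// optional linearized binding sink (rate coefficient sigma_i, amount/s per
// unit concentration) on the diagonal.
// Zero flux at the centre (i = 0), Dirichlet reservoir u_res beyond the
// outer face of cell n-1. Returns boundary influx over dt.
double diffusion_be_sink(std::vector<double>& u, const std::vector<double>& w,
                         const std::vector<double>& D, int geometry,
                         double u_res, double dt, Workspace& ws,
                         const double* sigma) {
  const int n = (int)u.size();
  ws.resize(n);
  std::vector<double>& vol = ws.vol;
  std::vector<double>& aout = ws.aout;
  geom_volumes(w, geometry, vol, aout);

  // interface conductances g_i = A * D_int / h between cell i and i+1
  std::vector<double>& g = ws.g;
  for (int i = 0; i + 1 < n; ++i) {
    const double h = 0.5 * (w[i] + w[i + 1]);
    g[i] = aout[i] * harmonic(D[i], D[i + 1]) / h;
  }
  const double gb = aout[n - 1] * D[n - 1] / (0.5 * w[n - 1]); // reservoir face

  // tridiagonal system in new concentrations c:
  //   -dt*g[i-1] c[i-1] + (vol_i + dt*(g[i-1]+g[i])) c_i - dt*g[i] c[i+1] = u_i
  std::vector<double>& sub = ws.sub;
  std::vector<double>& dia = ws.dia;
  std::vector<double>& sup = ws.sup;
  std::vector<double>& rhs = ws.rhs;
  for (int i = 0; i < n; ++i) {
    double gl = (i > 0) ? g[i - 1] : 0.0;
    double gr = (i + 1 < n) ? g[i] : gb;
    dia[i] = vol[i] + dt * (gl + gr);
    if (sigma) dia[i] += dt * sigma[i];
    if (i > 0) sub[i] = -dt * gl;
    if (i + 1 < n) sup[i] = -dt * g[i];
    rhs[i] = u[i];
  }
  rhs[n - 1] += dt * gb * u_res;

  // Thomas algorithm
  for (int i = 1; i < n; ++i) {
    const double m = sub[i] / dia[i - 1];
    dia[i] -= m * sup[i - 1];
    rhs[i] -= m * rhs[i - 1];
  }
  std::vector<double>& c = ws.c;
  c[n - 1] = rhs[n - 1] / dia[n - 1];
  for (int i = n - 2; i >= 0; --i) c[i] = (rhs[i] - sup[i] * c[i + 1]) / dia[i];

  for (int i = 0; i < n; ++i) u[i] = c[i] * vol[i];
  return dt * gb * (u_res - c[n - 1]);
}

double diffusion_be(std::vector<double>& u, const std::vector<double>& w,
                    const std::vector<double>& D, int geometry,
                    double u_res, double dt, Workspace& ws) {
  return diffusion_be_sink(u, w, D, geometry, u_res, dt, ws, nullptr);
}

// Implicitly coupled binding-diffusion step for the free invader: the
// bimolecular sink -k u mf is linearized per cell with the analytic
// effective rate sigma = mf * (1 - exp(-k c dt)) / (c dt) and Picard
// iterated, so the reaction front stays sharp at any dt (a split step
// would let u penetrate sqrt(D0 dt) of virgin material unconsumed).
// Consumed invader is moved to Ma with exact 1:1 stoichiometry.
double binding_diffusion_be(std::vector<double>& u, std::vector<double>& mf,
                            std::vector<double>& Ma,
                            const std::vector<double>& w,
                            const std::vector<double>& D, int geometry,
                            double k_bind, double u_res, double dt,
                            Workspace& ws, std::vector<double>& sigma,
                            std::vector<double>& u_work, int n_picard = 3) {
  const int n = (int)u.size();
  std::vector<double> vol, aout;
  geom_volumes(w, geometry, vol, aout);
  sigma.assign(n, 0.0);
  double influx = 0.0;
  for (int it = 0; it < n_picard; ++it) {
    // effective sink coefficient from the current concentration iterate
    for (int i = 0; i < n; ++i) {
      if (k_bind <= 0.0 || mf[i] <= 0.0) { sigma[i] = 0.0; continue; }
      const double c = u_work.empty() ? u[i] / vol[i]
                                      : u_work[i] / vol[i]; // previous iterate
      const double z = k_bind * c * dt;
      sigma[i] = (z > 1e-8) ? mf[i] * (-std::expm1(-z)) / (c * dt)
                            : mf[i] * k_bind * (1.0 - 0.5 * z);
    }
    u_work = u; // restart from the pre-step amounts each iterate
    influx = diffusion_be_sink(u_work, w, D, geometry, u_res, dt, ws,
                               sigma.data());
  }
  // commit: u_work holds the final solve; consumed = dt * sigma_i * c_i
  for (int i = 0; i < n; ++i) {
    double consumed = dt * sigma[i] * ws.c[i];
    if (consumed > mf[i]) { // clamp, return the excess to the free pool
      u_work[i] += consumed - mf[i];
      consumed = mf[i];
    }
    mf[i] -= consumed;
    Ma[i] += consumed;
  }
  u = u_work;
  return influx;
}

// Explicit FTCS with automatic CFL sub-stepping (cross-check scheme).
double diffusion_explicit(std::vector<double>& u, const std::vector<double>& w,
                          const std::vector<double>& D, int geometry,
                          double u_res, double dt, Workspace& ws) {
  const int n = (int)u.size();
  ws.resize(n);
  std::vector<double>& vol = ws.vol;
  std::vector<double>& aout = ws.aout;
  geom_volumes(w, geometry, vol, aout);

  double wmin = w[0], Dmax = D[0];
  for (int i = 1; i < n; ++i) { wmin = std::min(wmin, w[i]); Dmax = std::max(Dmax, D[i]); }
  const double dt_stab = 0.4 * wmin * wmin / Dmax;
  const int nsub = std::max(1, (int)std::ceil(dt / dt_stab));
  const double h = dt / nsub;

  std::vector<double>& g = ws.g;
  for (int i = 0; i + 1 < n; ++i)
    g[i] = aout[i] * harmonic(D[i], D[i + 1]) / (0.5 * (w[i] + w[i + 1]));
  const double gb = aout[n - 1] * D[n - 1] / (0.5 * w[n - 1]);

  double influx = 0.0;
  std::vector<double>& c = ws.c;
  std::vector<double>& du = ws.du;
  for (int s = 0; s < nsub; ++s) {
    for (int i = 0; i < n; ++i) c[i] = u[i] / vol[i];
    for (int i = 0; i < n; ++i) {
      double f = 0.0;
      if (i + 1 < n) f += g[i] * (c[i + 1] - c[i]);
      else f += gb * (u_res - c[i]);
      if (i > 0) f -= g[i - 1] * (c[i] - c[i - 1]);
      du[i] = h * f;
    }
    for (int i = 0; i < n; ++i) u[i] += du[i];
    influx += h * gb * (u_res - c[n - 1]);
  }
  return influx;
}

// linear interpolation with constant extrapolation; xs ascending
double interp1(const std::vector<double>& xs, const std::vector<double>& ys, double x) {
  const int n = (int)xs.size();
  if (x <= xs[0]) return ys[0];
  if (x >= xs[n - 1]) return ys[n - 1];
  int lo = 0, hi = n - 1;
  while (hi - lo > 1) { int mid = (lo + hi) / 2; if (xs[mid] <= x) lo = mid; else hi = mid; }
  const double t = (x - xs[lo]) / (xs[hi] - xs[lo]);
  return ys[lo] + t * (ys[hi] - ys[lo]);
}

std::vector<double> num2vec(NumericVector x) {
  return std::vector<double>(x.begin(), x.end());
}

} // namespace

// [[Rcpp::export]]
List cpp_reaction_step(NumericVector u, NumericVector m_free, NumericVector M_arr,
                       NumericVector M_sw, NumericVector w, int geometry,
                       double k_bind, double k_swell, double dt) {
  std::vector<double> uu = num2vec(u), mf = num2vec(m_free),
      Ma = num2vec(M_arr), Ms = num2vec(M_sw), ww = num2vec(w);
  std::vector<double> vol, aout;
  geom_volumes(ww, geometry, vol, aout);
  reaction_update(uu, mf, Ma, Ms, vol, k_bind, k_swell, dt);
  return List::create(_["u"] = wrap(uu), _["m_free"] = wrap(mf),
                      _["M_arr"] = wrap(Ma), _["M_sw"] = wrap(Ms));
}

// [[Rcpp::export]]
List cpp_diffusivity(NumericVector m_free, NumericVector M_arr, NumericVector M_sw,
                     double D0, double D1, double theta, double smooth) {
  std::vector<double> phi, D;
  std::vector<double> mf = num2vec(m_free), Ma = num2vec(M_arr), Ms = num2vec(M_sw);
  swollen_fraction(mf, Ma, Ms, phi);
  diffusivity_cells(phi, D0, D1, theta, smooth, D);
  const int n = (int)D.size();
  NumericVector Dint(n > 1 ? n - 1 : 0);
  for (int i = 0; i + 1 < n; ++i) Dint[i] = harmonic(D[i], D[i + 1]);
  return List::create(_["phi"] = wrap(phi), _["D_cell"] = wrap(D),
                      _["D_interface"] = Dint);
}

// [[Rcpp::export]]
List cpp_diffusion_step(NumericVector u, NumericVector w, NumericVector D_cell,
                        int geometry, double u_res, double dt, int scheme) {
  std::vector<double> uu = num2vec(u), ww = num2vec(w), DD = num2vec(D_cell);
  Workspace ws;
  double influx = (scheme == 1)
      ? diffusion_explicit(uu, ww, DD, geometry, u_res, dt, ws)
      : diffusion_be(uu, ww, DD, geometry, u_res, dt, ws);
  return List::create(_["u"] = wrap(uu), _["influx"] = influx);
}

// Full operator-split time loop (reaction -> swelling -> diffusion),
// sampling total invader signal (lab-frame concentration) on a fixed
// depth-from-outer-boundary raster every dt_out.
// [[Rcpp::export]]
List cpp_simulate(NumericVector u0, NumericVector mf0, NumericVector Ma0,
                  NumericVector Ms0, double w0, int geometry,
                  double D0, double D1, double k_bind, double k_swell,
                  double gf, double theta, double smooth, double u_res,
                  double t_end, double dt_out, double dt, int scheme,
                  NumericVector raster) {
  std::vector<double> u = num2vec(u0), mf = num2vec(mf0),
      Ma = num2vec(Ma0), Ms = num2vec(Ms0);
  const int n = (int)u.size();
  std::vector<double> w(n, w0), phi, D, vol, aout, sigma, u_work;
  Workspace ws;

  const int n_out = (int)std::floor(t_end / dt_out + 1e-9) + 1;
  const int n_ras = raster.size();
  NumericMatrix kymo(n_out, n_ras);
  NumericVector times(n_out);

  const int nsub = std::max(1, (int)std::ceil(dt_out / dt - 1e-9));
  const double h = dt_out / nsub;
  double influx = 0.0, t = 0.0;

  std::vector<double> depth(n), conc(n);
  auto emit = [&](int row) {
    times[row] = t;
    geom_volumes(w, geometry, vol, aout);
    double total = 0.0;
    for (int i = 0; i < n; ++i) total += w[i];
    // depth of cell centres measured from the outer boundary; ascending order
    double cum = 0.0;
    for (int i = 0; i < n; ++i) {
      const double centre = cum + 0.5 * w[i];
      depth[n - 1 - i] = total - centre;
      conc[n - 1 - i] = (u[i] + Ma[i] + Ms[i]) / vol[i];
      cum += w[i];
    }
    for (int j = 0; j < n_ras; ++j) kymo(row, j) = interp1(depth, conc, raster[j]);
  };

  emit(0);
  for (int row = 1; row < n_out; ++row) {
    for (int s = 0; s < nsub; ++s) {
      geom_volumes(w, geometry, vol, aout);
      if (scheme == 1) {
        // fully split path (cross-check scheme)
        reaction_update(u, mf, Ma, Ms, vol, k_bind, k_swell, h);
        swollen_fraction(mf, Ma, Ms, phi);
        width_update(w, phi, w0, gf);
        diffusivity_cells(phi, D0, D1, theta, smooth, D);
        influx += diffusion_explicit(u, w, D, geometry, u_res, h, ws);
      } else {
        // swelling split off; binding coupled implicitly to diffusion so
        // the reaction front stays sharp at any dt
        reaction_update(u, mf, Ma, Ms, vol, 0.0, k_swell, h);
        swollen_fraction(mf, Ma, Ms, phi);
        width_update(w, phi, w0, gf);
        diffusivity_cells(phi, D0, D1, theta, smooth, D);
        influx += binding_diffusion_be(u, mf, Ma, w, D, geometry, k_bind,
                                       u_res, h, ws, sigma, u_work);
      }
      t += h;
    }
    for (int i = 0; i < n; ++i)
      if (!std::isfinite(u[i]) || !std::isfinite(Ma[i]) || !std::isfinite(Ms[i]))
        stop("non-finite field value at t = %f (cell %d); reduce dt", t, i + 1);
    emit(row);
  }

  return List::create(
      _["times"] = times, _["kymograph"] = kymo, _["t"] = t,
      _["u"] = wrap(u), _["m_free"] = wrap(mf), _["M_arr"] = wrap(Ma),
      _["M_sw"] = wrap(Ms), _["w"] = wrap(w), _["influx"] = influx);
}
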