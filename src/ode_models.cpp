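#include <Rcpp.h>
#include <cmath>
#include <cstring>
using namespace Rcpp;

// Subcellular ODE right-hand sides and an adaptive Cash-Karp RK45 integrator.
//
// State and parameter vectors arrive in a fixed order established by the R
// wrappers (see R/vl_model.R, R/tan_model.R); no name lookups happen here.
//
// VL state  (11): D, X, C_u, C_o, C_c, A, C_A, T, C_oT, C_cT, Y
// VL params (27): s_A, s_CA, s_C, s_CT, s_D, s_T, s_X, s_Y,
//                 d_A, d_CA, d_C, d_CT, d_D, d_Dx, d_T, d_u, d_X, d_Y,
//                 K_C, K_D, K_T, p_c, p_u, xi_D, xi_Dx, xi_X, xi_c
// Tan state  (6): B_C, B_N, L_C, N_C, L_N, N_N
// Tan params(11): B_synth, k_deg, k_R_C, k_F_C, k_R_N, k_F_N, k_diff,
//                 k_active_C, k_active_N, V_C, V_N

#define VL_NSTATE 11
#define TAN_NSTATE 6
#define MAX_NSTATE 11

static void vl_rhs_raw(const double* y, double* dy, const double* p,
                       double W, double gamma) {
  const double s_A = p[0], s_CA = p[1], s_C = p[2], s_CT = p[3], s_D = p[4],
               s_T = p[5], s_X = p[6], s_Y = p[7];
  const double d_A = p[8], d_CA = p[9], d_C = p[10], d_CT = p[11], d_D = p[12],
               d_Dx = p[13], d_T = p[14], d_u = p[15], d_X = p[16],
               d_Y = p[17];
  const double K_C = p[18], K_D = p[19], K_T = p[20];
  const double p_c = p[21], p_u = p[22];
  const double xi_D = p[23], xi_Dx = p[24], xi_X = p[25], xi_c = p[26];

  // Wnt-modified rates; with the default xi_c = 0 the phosphorylation rate
  // is Wnt-independent (hypothesis 1).
  const double dD_hat = d_D + xi_D * W;
  const double dDx_hat = d_Dx + xi_Dx * W;
  const double dX_hat = d_X + xi_X * W;
  const double pc_hat = p_c + xi_c * W;

  const double D = y[0], X = y[1], C_u = y[2], C_o = y[3], C_c = y[4],
               A = y[5], C_A = y[6], T = y[7], C_oT = y[8], C_cT = y[9],
               Y = y[10];
  const double C_F = C_o + C_c;
  const double C_T = C_oT + C_cT;

  const double destr = p_u * D / (C_F + K_D); // destruction-complex turnover
  const double phos = pc_hat * C_o / (C_o + K_C);

  dy[0] = gamma * s_D * X - (dD_hat + dDx_hat) * D;
  dy[1] = s_X - gamma * s_D * X - dX_hat * X + dDx_hat * D;
  dy[2] = destr * C_F - d_u * C_u;
  // the open-form substrate of the destruction complex is C_o, so that the
  // C_o + C_c balance matches the C_F substrate in the C_u equation
  dy[3] = s_C + d_CA * C_A + d_CT * C_oT -
          (s_CA * A + s_CT * T + d_C) * C_o - phos - destr * C_o;
  dy[4] = phos + d_CT * C_cT - (s_CT * T + d_C) * C_c - destr * C_c;
  dy[5] = s_A + d_CA * C_A - (s_CA * C_o + d_A) * A;
  dy[6] = s_CA * C_o * A - d_CA * C_A;
  dy[7] = s_T + d_CT * C_T - (s_CT * C_F + d_T) * T;
  dy[8] = s_CT * C_o * T - d_CT * C_oT;
  dy[9] = s_CT * C_c * T - d_CT * C_cT;
  dy[10] = s_Y * C_T / (C_T + K_T) - d_Y * Y;
}

static void tan_rhs_raw(const double* y, double* dy, const double* p,
                        double W, double gamma) {
  const double B_synth = p[0], k_deg = p[1];
  const double k_R_C = p[2], k_F_C = p[3], k_R_N = p[4], k_F_N = p[5];
  const double k_diff = p[6], k_active_C = p[7], k_active_N = p[8];
  const double V_C = p[9], V_N = p[10];

  const double B_C = y[0], B_N = y[1], L_C = y[2], N_C = y[3], L_N = y[4],
               N_N = y[5];

  const double shuttle = k_diff * (B_C - B_N);
  const double active = k_active_C * B_C - k_active_N * B_N;
  const double bind_C = k_F_C * B_C * L_C - k_R_C * N_C;
  const double bind_N = k_F_N * B_N * L_N - k_R_N * N_N;

  dy[0] = B_synth - k_deg * gamma * (1.0 - W / 2.0) * B_C - bind_C -
          (shuttle + active) / V_C;
  dy[1] = -bind_N + (shuttle + active) / V_N;
  dy[2] = -bind_C;
  dy[3] = bind_C;
  dy[4] = -bind_N;
  dy[5] = bind_N;
}

typedef void (*rhs_fn)(const double*, double*, const double*, double, double);

static rhs_fn pick_rhs(int model, int* nstate) {
  if (model == 1) {
    *nstate = VL_NSTATE;
    return vl_rhs_raw;
  }
  *nstate = TAN_NSTATE;
  return tan_rhs_raw;
}

// [[Rcpp::export]]
NumericVector vl_rhs_cpp(NumericVector y, NumericVector p, double W,
                         double gamma) {
  NumericVector dy(VL_NSTATE);
  vl_rhs_raw(REAL(y), REAL(dy), REAL(p), W, gamma);
  return dy;
}

// [[Rcpp::export]]
NumericVector tan_rhs_cpp(NumericVector y, NumericVector p, double W,
                          double gamma) {
  NumericVector dy(TAN_NSTATE);
  tan_rhs_raw(REAL(y), REAL(dy), REAL(p), W, gamma);
  return dy;
}

// Cash-Karp embedded Runge-Kutta 4(5) with standard step-size control.
// Advances y in place from t = 0 to t = dt.  Returns false on failure
// (step count exhausted or step size underflow).
static bool rkck_advance(rhs_fn f, double* y, int n, const double* p, double W,
                         double gamma, double dt, double atol, double rtol) {
  static const double b21 = 1.0 / 5.0;
  static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
  static const double b41 = 3.0 / 10.0, b42 = -9.0 / 10.0, b43 = 6.0 / 5.0;
  static const double b51 = -11.0 / 54.0, b52 = 5.0 / 2.0, b53 = -70.0 / 27.0,
                      b54 = 35.0 / 27.0;
  static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                      b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                      b65 = 253.0 / 4096.0;
  static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                      c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
  static const double dc1 = c1 - 2825.0 / 27648.0, dc3 = c3 - 18575.0 / 48384.0,
                      dc4 = c4 - 13525.0 / 55296.0, dc5 = -277.0 / 14336.0,
                      dc6 = c6 - 1.0 / 4.0;

  double k1[MAX_NSTATE], k2[MAX_NSTATE], k3[MAX_NSTATE], k4[MAX_NSTATE],
      k5[MAX_NSTATE], k6[MAX_NSTATE], ytmp[MAX_NSTATE], yerr[MAX_NSTATE],
      ynew[MAX_NSTATE];

  double t = 0.0;
  double h = dt; // try the whole interval first; control shrinks as needed
  const int max_steps = 1000000;

  for (int step = 0; step < max_steps; ++step) {
    if (t >= dt) return true;
    if (h > dt - t) h = dt - t;

    f(y, k1, p, W, gamma);
    for (int i = 0; i < n; ++i) ytmp[i] = y[i] + h * b21 * k1[i];
    f(ytmp, k2, p, W, gamma);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    f(ytmp, k3, p, W, gamma);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    f(ytmp, k4, p, W, gamma);
    for (int i = 0; i < n; ++i)
      ytmp[i] =
          y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] + b54 * k4[i]);
    f(ytmp, k5, p, W, gamma);
    for (int i = 0; i < n; ++i)
      ytmp[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                            b64 * k4[i] + b65 * k5[i]);
    f(ytmp, k6, p, W, gamma);

    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] + c6 * k6[i]);
      yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] + dc5 * k5[i] +
                     dc6 * k6[i]);
      double sk = atol + rtol * std::max(std::fabs(y[i]), std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sk;
      if (e > errmax) errmax = e;
    }

    if (errmax <= 1.0) {
      t += h;
      std::memcpy(y, ynew, n * sizeof(double));
      double fac = (errmax > 1e-10) ? 0.9 * std::pow(errmax, -0.2) : 5.0;
      if (fac > 5.0) fac = 5.0;
      h *= fac;
    } else {
      double fac = 0.9 * std::pow(errmax, -0.25);
      if (fac < 0.1) fac = 0.1;
      h *= fac;
      if (h < 1e-14 * dt) return false;
    }
  }
  return false;
}

static void clip_state(double* y, int n) {
  // guarantee non-negativity: integration noise below tolerance is zeroed
  for (int i = 0; i < n; ++i) {
    if (std::fabs(y[i]) < 1e-12) y[i] = 0.0;
    if (y[i] < 0.0) {
      if (y[i] > -1e-6) y[i] = 0.0;
      else stop("integration produced a negative concentration (%g)", y[i]);
    }
  }
}

// [[Rcpp::export]]
NumericVector ode_advance_cpp(int model, NumericVector y, NumericVector p,
                              double W, double gamma, double dt,
                              double atol = 1e-8, double rtol = 1e-6) {
  int n;
  rhs_fn f = pick_rhs(model, &n);
  NumericVector out = clone(y);
  if (!rkck_advance(f, REAL(out), n, REAL(p), W, gamma, dt, atol, rtol))
    stop("ODE integration failed to converge over dt = %g", dt);
  clip_state(REAL(out), n);
  return out;
}

// Advance one subcellular system per row of Y, each with its own Wnt level
// and mutation parameter; used once per mechanics step for the whole crypt.
// [[Rcpp::export]]
NumericMatrix ode_advance_batch_cpp(int model, NumericMatrix Y,
                                    NumericVector p, NumericVector W,
                                    NumericVector gamma, double dt,
                                    double atol = 1e-8, double rtol = 1e-6) {
  int n;
  rhs_fn f = pick_rhs(model, &n);
  const int ncell = Y.nrow();
  if (Y.ncol() != n) stop("state matrix has %d columns, expected %d",
                          Y.ncol(), n);
  NumericMatrix out = clone(Y);
  double* od = REAL(out);
  const double* pw = REAL(W);
  const double* pg = REAL(gamma);
  const double* pp = REAL(p);
  double buf[MAX_NSTATE];
  for (int c = 0; c < ncell; ++c) {
    for (int i = 0; i < n; ++i) buf[i] = od[(size_t)i * ncell + c];
    if (!rkck_advance(f, buf, n, pp, pw[c], pg[c], dt, atol, rtol))
      stop("ODE integration failed for cell %d over dt = %g", c + 1, dt);
    clip_state(buf, n);
    for (int i = 0; i < n; ++i) od[(size_t)i * ncell + c] = buf[i];
  }
  return out;
}
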