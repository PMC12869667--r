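#include <Rcpp.h>
using namespace Rcpp;

// Parameter vector layout (kept in sync with par_vec() on the R side):
// 0 w_ma, 1 w_mv, 2 w_av, 3 w_va, 4 w_Ia, 5 w_Iv,
// 6 l_av, 7 l_va, 8 l_a, 9 l_v,
// 10 tau_fast, 11 tau_slow, 12 act_slope, 13 act_center, 14 z_max,
// 15 i0_a, 16 i0_v

static inline double act(double u, double slope, double center, double zmax) {
  return zmax / (1.0 + std::exp(-slope * (u - center)));
}

// Explicit-Euler integration of the five-unit network plus the two slow
// feedback-inhibition traces.  ext_a/ext_v give the external input amplitude
// (0 outside stimulus pulses) for each step; step i covers [i*dt, (i+1)*dt).
// jitter_step / jitter_a / jitter_v inject the winner-takes-all symmetry
// breaking: at the start of step jitter_step[k] (0-based) the interneuron
// membrane inputs receive one-off additive offsets jitter_a[k], jitter_v[k].
// Returns the trace on the (n_steps + 1)-point grid (row 0 = initial state)
// and the final state for chunk chaining.
// [[Rcpp::export]]
List cpp_simulate(NumericVector u0, NumericVector q0,
                  NumericVector ext_a, NumericVector ext_v,
                  NumericVector par, double dt,
                  IntegerVector jitter_step,
                  NumericVector jitter_a, NumericVector jitter_v,
                  bool record) {
  const int n = ext_a.size();
  if (ext_v.size() != n) stop("ext_a and ext_v must have equal length");
  if (u0.size() != 5 || q0.size() != 2) stop("state must be (5 u, 2 q)");
  if (par.size() != 17) stop("parameter vector must have 17 elements");
  if (!(dt > 0)) stop("dt must be > 0");

  const double w_ma = par[0], w_mv = par[1], w_av = par[2], w_va = par[3];
  const double w_Ia = par[4], w_Iv = par[5];
  const double l_av = par[6], l_va = par[7], l_a = par[8], l_v = par[9];
  const double tau_f = par[10], tau_s = par[11];
  const double slope = par[12], center = par[13], zmax = par[14];
  const double i0a = par[15], i0v = par[16];
  for (int i = 0; i < 17; ++i)
    if (!std::isfinite(par[i])) stop("non-finite network parameter");

  double ua = u0[0], uv = u0[1], um = u0[2], uIa = u0[3], uIv = u0[4];
  double qa = q0[0], qv = q0[1];
  for (int i = 0; i < 5; ++i)
    if (!std::isfinite(u0[i])) stop("non-finite initial state");

  const double kf = dt / tau_f, ks = dt / tau_s;

  NumericMatrix tr(record ? n + 1 : 0, record ? 7 : 0);
  auto rec = [&](int row) {
    tr(row, 0) = act(ua, slope, center, zmax);
    tr(row, 1) = act(uv, slope, center, zmax);
    tr(row, 2) = act(um, slope, center, zmax);
    tr(row, 3) = act(uIa, slope, center, zmax);
    tr(row, 4) = act(uIv, slope, center, zmax);
    tr(row, 5) = qa;
    tr(row, 6) = qv;
  };
  if (record) rec(0);

  int jk = 0;
  const int nj = jitter_step.size();

  for (int i = 0; i < n; ++i) {
    while (jk < nj && jitter_step[jk] == i) {
      uIa += jitter_a[jk];
      uIv += jitter_v[jk];
      ++jk;
    }
    const double za  = act(ua,  slope, center, zmax);
    const double zv  = act(uv,  slope, center, zmax);
    const double zIa = act(uIa, slope, center, zmax);
    const double zIv = act(uIv, slope, center, zmax);

    const double net_a  = i0a * ext_a[i] + w_av * zv - l_v * qv;
    const double net_v  = i0v * ext_v[i] + w_va * za - l_a * qa;
    const double net_m  = w_ma * za + w_mv * zv;
    const double net_Ia = w_Ia * za - l_va * zIv;
    const double net_Iv = w_Iv * zv - l_av * zIa;

    ua  += kf * (net_a - ua);
    uv  += kf * (net_v - uv);
    um  += kf * (net_m - um);
    uIa += kf * (net_Ia - uIa);
    uIv += kf * (net_Iv - uIv);
    qa  += ks * (zIa - qa);
    qv  += ks * (zIv - qv);

    if (record) rec(i + 1);
  }

  if (!(std::isfinite(ua) && std::isfinite(uv) && std::isfinite(um) &&
        std::isfinite(uIa) && std::isfinite(uIv) &&
        std::isfinite(qa) && std::isfinite(qv)))
    stop("simulation diverged to a non-finite state");

  return List::create(
    _["trace"] = tr,
    _["u"] = NumericVector::create(ua, uv, um, uIa, uIv),
    _["q"] = NumericVector::create(qa, qv));
}
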