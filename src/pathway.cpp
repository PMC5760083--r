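// Streaming core of the adaptive motion pathway.
//
// Runs the full chain -- adaptive photoreceptor, high-pass LMC with ON/OFF
// split and Lipetz saturation, delay-and-correlate EMD, divisive motion
// adaptation with activity-dependent exponent, linear LPTC pooling -- over a
// luminance frame stack, one model time step at a time.  All first-order
// filters use the exact exponential update for piecewise-constant input, so
// traces are stable under halving of dt.  Filter memories can be passed in
// and out, which lets the R wrapper stream long protocols chunk by chunk
// without materialising the whole stimulus.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List pathway_core(NumericVector frames, double dt_frame, double dt, List par,
                  bool wrap, bool adapt_on, Nullable<List> state_in,
                  IntegerVector snap_steps) {
  IntegerVector dim = frames.attr("dim");
  const int T = dim[0], nr = dim[1], nc = dim[2];
  if (nc < 2) stop("retinotopic grid needs at least 2 columns");
  const int N = nr * nc;
  const int ndet = wrap ? nc : nc - 1;
  const int M = nr * ndet;

  const double tau_prf = par["pr_tau_fast"], tau_prs = par["pr_tau_slow"],
               c_pr = par["c_pr"], tau_hp = par["lmc_tau_hp"],
               c_lmc = par["c_lmc"], tau_del = par["emd_tau_delay"],
               tau_f = par["emd_tau_fast"], tau_s = par["emd_tau_slow"],
               c_emd = par["c_emd"], a_min = par["a_min"],
               a_max = par["a_max"], p1 = par["p1"], p2 = par["p2"];

  const double al_prf = 1.0 - std::exp(-dt / tau_prf);
  const double al_prs = 1.0 - std::exp(-dt / tau_prs);
  const double al_hp = 1.0 - std::exp(-dt / tau_hp);
  const double al_del = 1.0 - std::exp(-dt / tau_del);
  const double al_f = 1.0 - std::exp(-dt / tau_f);
  const double al_s = 1.0 - std::exp(-dt / tau_s);

  const bool interp = std::fabs(dt_frame - dt) > 1e-12;
  const int nsteps = interp
      ? (int)std::lround((T - 1) * dt_frame / dt) + 1
      : T;

  // filter memories: per pixel
  NumericVector prf(N), prs(N), lmclp(N), don(N), doff(N);
  // per detector (shared slow branch and exponent; four fast branches)
  NumericVector f_onpd(M), f_onnd(M), f_offpd(M), f_offnd(M), slow(M), a(M);

  std::vector<double> I(N), ons(N), offs(N);

  if (state_in.isNotNull()) {
    List st(state_in);
    prf = clone(as<NumericVector>(st["pr_fast"]));
    prs = clone(as<NumericVector>(st["pr_slow"]));
    lmclp = clone(as<NumericVector>(st["lmc_lp"]));
    don = clone(as<NumericVector>(st["delay_on"]));
    doff = clone(as<NumericVector>(st["delay_off"]));
    f_onpd = clone(as<NumericVector>(st["fast_on_pd"]));
    f_onnd = clone(as<NumericVector>(st["fast_on_nd"]));
    f_offpd = clone(as<NumericVector>(st["fast_off_pd"]));
    f_offnd = clone(as<NumericVector>(st["fast_off_nd"]));
    slow = clone(as<NumericVector>(st["slow"]));
    a = clone(as<NumericVector>(st["a"]));
  } else {
    // cold start: every memory at the steady state of the first frame
    for (int c = 0; c < nc; ++c)
      for (int r = 0; r < nr; ++r) {
        int p = r + nr * c;
        double I0 = frames[(std::size_t)T * (r + (std::size_t)nr * c)];
        prf[p] = I0;
        prs[p] = I0;
        lmclp[p] = I0 / (I0 + c_pr);  // high-pass output 0, ON/OFF sat 0
      }
    for (int m = 0; m < M; ++m) a[m] = a_min;
  }

  NumericVector lptc(nsteps), a_mean(nsteps);
  NumericMatrix energy_cm(nsteps, ndet);
  List snaps(snap_steps.size());
  int sp = 0;

  for (int k = 0; k < nsteps; ++k) {
    // stimulus for this step (linear interpolation between frames if the
    // stimulus is sampled more coarsely than the model)
    if (!interp) {
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r)
          I[r + nr * c] =
              frames[k + (std::size_t)T * (r + (std::size_t)nr * c)];
    } else {
      double tt = k * dt / dt_frame;
      int i0 = (int)tt;
      if (i0 > T - 2) i0 = T - 2;
      double w = tt - i0;
      if (w < 0) w = 0;
      if (w > 1) w = 1;
      for (int c = 0; c < nc; ++c)
        for (int r = 0; r < nr; ++r) {
          std::size_t base = (std::size_t)T * (r + (std::size_t)nr * c);
          I[r + nr * c] = (1.0 - w) * frames[i0 + base] + w * frames[i0 + 1 + base];
        }
    }

    // peripheral stages, per pixel
    for (int p = 0; p < N; ++p) {
      double x = I[p];
      prf[p] += (x - prf[p]) * al_prf;
      prs[p] += (x - prs[p]) * al_prs;
      double prv = prf[p] / (prs[p] + c_pr);
      lmclp[p] += (prv - lmclp[p]) * al_hp;
      double h = prv - lmclp[p];
      double on = h > 0 ? h : 0.0;
      double off = h < 0 ? -h : 0.0;
      ons[p] = on / (on + c_lmc);
      offs[p] = off / (off + c_lmc);
      don[p] += (ons[p] - don[p]) * al_del;
      doff[p] += (offs[p] - doff[p]) * al_del;
    }

    bool take_snap =
        (sp < snap_steps.size() && snap_steps[sp] == k + 1);
    NumericMatrix s_u1, s_u2, s_u3, s_u4, s_a1, s_a2, s_a3, s_a4, s_sg, s_en,
        s_ax;
    if (take_snap) {
      s_u1 = NumericMatrix(nr, ndet); s_u2 = NumericMatrix(nr, ndet);
      s_u3 = NumericMatrix(nr, ndet); s_u4 = NumericMatrix(nr, ndet);
      s_a1 = NumericMatrix(nr, ndet); s_a2 = NumericMatrix(nr, ndet);
      s_a3 = NumericMatrix(nr, ndet); s_a4 = NumericMatrix(nr, ndet);
      s_sg = NumericMatrix(nr, ndet); s_en = NumericMatrix(nr, ndet);
      s_ax = NumericMatrix(nr, ndet);
    }

    double pool = 0.0, asum = 0.0;
    for (int j = 0; j < ndet; ++j) {
      int j2 = wrap ? (j + 1) % nc : j + 1;
      double ecol = 0.0;
      for (int r = 0; r < nr; ++r) {
        int pa = r + nr * j, pb = r + nr * j2, m = r + nr * j;
        // delay-and-correlate half-detectors (rectified at 0)
        double onpd = don[pa] * ons[pb];
        double onnd = ons[pa] * don[pb];
        double offpd = doff[pa] * offs[pb];
        double offnd = offs[pa] * doff[pb];
        if (onpd < 0) onpd = 0;
        if (onnd < 0) onnd = 0;
        if (offpd < 0) offpd = 0;
        if (offnd < 0) offnd = 0;

        double ave = 0.25 * (onpd + onnd + offpd + offnd);
        slow[m] += (ave - slow[m]) * al_s;
        f_onpd[m] += (onpd - f_onpd[m]) * al_f;
        f_onnd[m] += (onnd - f_onnd[m]) * al_f;
        f_offpd[m] += (offpd - f_offpd[m]) * al_f;
        f_offnd[m] += (offnd - f_offnd[m]) * al_f;

        double o1, o2, o3, o4;
        if (adapt_on) {
          double av = a[m];
          av += dt * (-(av - a_min) * p1 + (a_max - av) * p2 * slow[m]);
          if (av < a_min) av = a_min;
          if (av > a_max) av = a_max;
          a[m] = av;
          // x^a short-circuited for numerically dead branches (pow is the
          // dominant cost on large retinas; 1e-30^0.5 is far below any
          // response scale)
          double sl = slow[m] > 1e-30 ? std::pow(slow[m], av) : 0.0;
          double denom = sl + std::pow(c_emd, av);
          o1 = f_onpd[m] > 1e-30 ? std::pow(f_onpd[m], av) / denom : 0.0;
          o2 = f_onnd[m] > 1e-30 ? std::pow(f_onnd[m], av) / denom : 0.0;
          o3 = f_offpd[m] > 1e-30 ? std::pow(f_offpd[m], av) / denom : 0.0;
          o4 = f_offnd[m] > 1e-30 ? std::pow(f_offnd[m], av) / denom : 0.0;
        } else {
          // adaptation frozen: divisive stage bypassed, raw branches pass
          o1 = onpd; o2 = onnd; o3 = offpd; o4 = offnd;
        }
        double sgn = (o1 + o3) - (o2 + o4);
        pool += sgn;
        ecol += std::fabs(sgn);
        asum += a[m];
        if (take_snap) {
          s_u1(r, j) = onpd; s_u2(r, j) = onnd;
          s_u3(r, j) = offpd; s_u4(r, j) = offnd;
          s_a1(r, j) = o1; s_a2(r, j) = o2; s_a3(r, j) = o3; s_a4(r, j) = o4;
          s_sg(r, j) = sgn; s_en(r, j) = std::fabs(sgn); s_ax(r, j) = a[m];
        }
      }
      energy_cm(k, j) = ecol / nr;
    }
    lptc[k] = pool;
    a_mean[k] = asum / M;
    if (take_snap) {
      snaps[sp] = List::create(
          _["unadapted"] = List::create(_["on_pd"] = s_u1, _["on_nd"] = s_u2,
                                        _["off_pd"] = s_u3, _["off_nd"] = s_u4),
          _["adapted"] = List::create(_["on_pd"] = s_a1, _["on_nd"] = s_a2,
                                      _["off_pd"] = s_a3, _["off_nd"] = s_a4),
          _["signed"] = s_sg, _["energy"] = s_en, _["a"] = s_ax,
          _["lptc"] = pool, _["step"] = k + 1);
      ++sp;
    }
  }

  List state_out = List::create(
      _["pr_fast"] = prf, _["pr_slow"] = prs, _["lmc_lp"] = lmclp,
      _["delay_on"] = don, _["delay_off"] = doff, _["fast_on_pd"] = f_onpd,
      _["fast_on_nd"] = f_onnd, _["fast_off_pd"] = f_offpd,
      _["fast_off_nd"] = f_offnd, _["slow"] = slow, _["a"] = a);

  return List::create(_["lptc"] = lptc, _["a_mean"] = a_mean,
                      _["energy_az"] = energy_cm, _["snapshots"] = snaps,
                      _["state"] = state_out, _["nsteps"] = nsteps);
}
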