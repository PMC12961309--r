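// Delay-coupled Jansen-Rit network integrator (stochastic Heun).
//
// The delayed long-range input x_k(t) = sum_l W(k,l) * psp_l(t - d_kl)
// is evaluated by grouping connectome entries by their integer delay and
// gathering from a circular PSP history buffer, so each step costs one
// fused multiply-add per nonzero connection and stage. Noise is drawn
// from R's RNG (seeded on the R side) so runs are reproducible.

#include <RcppArmadillo.h>

#include <algorithm>
#include <array>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct JR {
  double A, B, a, b, C1, C2, C3, C4, vmax, v0, r, qcon;
};

inline double sigm(double v, const JR& p) {
  return 2.0 * p.vmax / (1.0 + std::exp(p.r * (p.v0 - v)));
}

inline double coup(double x, double gmin, double gmax, double gmid,
                   double gsigma, double ga) {
  return gmin + (gmax - gmin) /
         (1.0 + std::exp(-ga * (x - gmid)) * gsigma);
}

}  // namespace

// [[Rcpp::export]]
List jr_integrate_cpp(const arma::mat& weights, const arma::imat& delays,
                      NumericVector jr, NumericVector cp,
                      NumericVector stim_amp, int onset_step,
                      int dur_steps, int waveform, double noise_std,
                      double dt, int n_steps, int transient_steps,
                      int decim, double diverge_bound) {
  const int n = weights.n_rows;
  JR p{jr[0], jr[1], jr[2], jr[3], jr[4], jr[5],
       jr[6], jr[7], jr[8], jr[9], jr[10], jr[11]};
  const double gmin = cp[0], gmax = cp[1], gmid = cp[2],
               gsigma = cp[3], ga = cp[4];

  // flatten nonzero connections into contiguous arrays sorted by
  // (delay, source region) for streaming access in the gather loop
  int max_delay = 0;
  std::vector<std::array<int, 3>> tmp;  // delay, l, k
  tmp.reserve(n * n / 4);
  for (int l = 0; l < n; ++l) {
    for (int k = 0; k < n; ++k) {
      if (weights(k, l) != 0.0) {
        int d = delays(k, l);
        tmp.push_back({d, l, k});
        if (d > max_delay) max_delay = d;
      }
    }
  }
  std::sort(tmp.begin(), tmp.end());
  const size_t ne = tmp.size();
  std::vector<int> e_k(ne), e_l(ne);
  std::vector<double> e_w(ne);
  std::vector<size_t> grp_start;   // group boundaries
  std::vector<int> grp_delay;
  for (size_t i = 0; i < ne; ++i) {
    if (i == 0 || tmp[i][0] != tmp[i - 1][0]) {
      grp_start.push_back(i);
      grp_delay.push_back(tmp[i][0]);
    }
    e_k[i] = tmp[i][2];
    e_l[i] = tmp[i][1];
    e_w[i] = weights(tmp[i][2], tmp[i][1]);
  }
  grp_start.push_back(ne);

  const int L = max_delay + 2;  // history length incl. predictor slot
  arma::mat hist(n, L, arma::fill::zeros);

  arma::vec y0(n, arma::fill::zeros), y1(n, arma::fill::zeros),
      y2(n, arma::fill::zeros), y3(n, arma::fill::zeros),
      y4(n, arma::fill::zeros), y5(n, arma::fill::zeros);
  arma::vec x(n), qn(n), k1_0(n), k1_1(n), k1_2(n), k1_3(n), k1_4(n),
      k1_5(n), p0(n), p1(n), p2(n), p3(n), p4(n), p5(n);

  const int n_out = (n_steps - transient_steps) / decim + 1;
  arma::mat out(n, n_out);
  int out_col = 0;

  const double a2 = p.a * p.a, b2 = p.b * p.b;
  const double Aa = p.A * p.a, BbC4 = p.B * p.b * p.C4;
  bool ok = true;
  int fail_step = -1;

  RNGScope scope;

  auto gather = [&](int t, arma::vec& xv) {
    xv.zeros();
    double* xp = xv.memptr();
    for (size_t g = 0; g + 1 < grp_start.size(); ++g) {
      int c = (t - grp_delay[g]) % L;
      if (c < 0) c += L;
      const double* col = hist.colptr(c);
      const size_t lo = grp_start[g], hi = grp_start[g + 1];
      for (size_t i = lo; i < hi; ++i)
        xp[e_k[i]] += e_w[i] * col[e_l[i]];
    }
  };

  auto stim_at = [&](int t) -> double {
    int rel = t - onset_step;
    if (rel < 0) return 0.0;
    if (waveform == 1) {  // rect
      return rel < dur_steps ? 1.0 : 0.0;
    }
    // biexponential: fast rise (tau_r = dur/10), decay tau_d = dur,
    // normalised so the time integral matches the rectangular pulse
    double tau_d = dur_steps * dt, tau_r = tau_d / 10.0, ts = rel * dt;
    double shape = std::exp(-ts / tau_d) - std::exp(-ts / tau_r);
    return shape / (tau_d - tau_r) * tau_d;
  };

  for (int t = 0; t < n_steps; ++t) {
    // inputs at step t
    gather(t, x);
    const double st_now = stim_at(t), st_next = stim_at(t + 1);
    if (noise_std > 0.0)
      for (int k = 0; k < n; ++k) qn[k] = noise_std * R::norm_rand();
    else
      qn.zeros();

    // predictor (Euler)
    for (int k = 0; k < n; ++k) {
      double qc = coup(x[k], gmin, gmax, gmid, gsigma, ga);
      double d3 = Aa * sigm(y1[k] - y2[k], p) - 2.0 * p.a * y3[k] -
                  a2 * y0[k];
      double d4 = Aa * (p.C2 * sigm(p.C1 * y0[k], p) + qc + p.qcon +
                        stim_amp[k] * st_now + qn[k]) -
                  2.0 * p.a * y4[k] - a2 * y1[k];
      double d5 = BbC4 * sigm(p.C3 * y0[k], p) - 2.0 * p.b * y5[k] -
                  b2 * y2[k];
      k1_0[k] = y3[k]; k1_1[k] = y4[k]; k1_2[k] = y5[k];
      k1_3[k] = d3; k1_4[k] = d4; k1_5[k] = d5;
      p0[k] = y0[k] + dt * y3[k];
      p1[k] = y1[k] + dt * y4[k];
      p2[k] = y2[k] + dt * y5[k];
      p3[k] = y3[k] + dt * d3;
      p4[k] = y4[k] + dt * d4;
      p5[k] = y5[k] + dt * d5;
    }

    // predictor PSP into the t+1 slot so zero-delay edges see it
    {
      int c = (t + 1) % L;
      double* col = hist.colptr(c);
      for (int k = 0; k < n; ++k) col[k] = p1[k] - p2[k];
    }
    gather(t + 1, x);

    // corrector (same noise increment: additive noise, Heun)
    for (int k = 0; k < n; ++k) {
      double qc = coup(x[k], gmin, gmax, gmid, gsigma, ga);
      double d3 = Aa * sigm(p1[k] - p2[k], p) - 2.0 * p.a * p3[k] -
                  a2 * p0[k];
      double d4 = Aa * (p.C2 * sigm(p.C1 * p0[k], p) + qc + p.qcon +
                        stim_amp[k] * st_next + qn[k]) -
                  2.0 * p.a * p4[k] - a2 * p1[k];
      double d5 = BbC4 * sigm(p.C3 * p0[k], p) - 2.0 * p.b * p5[k] -
                  b2 * p2[k];
      const double h = dt * 0.5;
      y0[k] += h * (k1_0[k] + p3[k]);
      y1[k] += h * (k1_1[k] + p4[k]);
      y2[k] += h * (k1_2[k] + p5[k]);
      y3[k] += h * (k1_3[k] + d3);
      y4[k] += h * (k1_4[k] + d4);
      y5[k] += h * (k1_5[k] + d5);
    }

    // final PSP overwrites the predictor slot
    {
      int c = (t + 1) % L;
      double* col = hist.colptr(c);
      for (int k = 0; k < n; ++k) col[k] = y1[k] - y2[k];
    }

    if ((t & 127) == 0) {
      for (int k = 0; k < n; ++k) {
        if (!std::isfinite(y1[k]) || std::abs(y1[k]) > diverge_bound ||
            std::abs(y2[k]) > diverge_bound) {
          ok = false;
          fail_step = t;
          break;
        }
      }
      if (!ok) break;
    }

    // record: step index t+1 corresponds to state after the update
    int rec = t + 1 - transient_steps;
    if (rec >= 0 && rec % decim == 0 && out_col < n_out) {
      for (int k = 0; k < n; ++k) out(k, out_col) = y1[k] - y2[k];
      ++out_col;
    }
  }

  arma::mat fin(6, n);
  fin.row(0) = y0.t(); fin.row(1) = y1.t(); fin.row(2) = y2.t();
  fin.row(3) = y3.t(); fin.row(4) = y4.t(); fin.row(5) = y5.t();

  return List::create(_["psp"] = out.cols(0, std::max(out_col - 1, 0)),
                      _["final_state"] = fin, _["ok"] = ok,
                      _["fail_step"] = fail_step);
}
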