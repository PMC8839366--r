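#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Fixed-step Heun (explicit trapezoid) method-of-steps integrator for
// mass-action models with instantaneous, discrete-delay and
// distributed-delay channels.
//
// Delayed channels read a stored "signal" series: the product of the
// channel's factor species at past grid nodes. For times before 0 the
// signal equals the constant pre-history product `presig`; distributed
// channels therefore carry a cumulative tail weight so kernels longer than
// the stored horizon contribute exactly presig * (remaining mass).
//
// Channel encoding (0-based indices):
//   ch_type: 0 instantaneous, 1 discrete delay, 2 distributed (kernel)
//   ch_f1/ch_f2: factor species (ch_f2 = -1 for unary channels)
//   ch_lag: discrete lag in steps
//   ch_sig: signal index for delayed channels (-1 for instantaneous)
//   ch_weights[c][L]: quadrature weight at lag L*dt (kernel channels)
//   ch_tailw[c][L]: sum of weights at lags >= L plus the tail mass
// [[Rcpp::export]]
List dde_heun_cpp(NumericVector state0, int K, double dt,
                  NumericVector ch_rate, IntegerVector ch_f1,
                  IntegerVector ch_f2, IntegerVector ch_type,
                  IntegerVector ch_lag, IntegerVector ch_sig,
                  List ch_weights, List ch_tailw,
                  List ch_targets, List ch_coefs,
                  IntegerVector sig_f1, IntegerVector sig_f2,
                  NumericVector presig) {
  const int n = state0.size();
  const int nc = ch_rate.size();
  const int ns = sig_f1.size();

  NumericMatrix X(K + 1, n);
  NumericMatrix SIG(K + 1, std::max(ns, 1));

  std::vector<NumericVector> W(nc), TW(nc);
  std::vector<IntegerVector> TG(nc);
  std::vector<NumericVector> CF(nc);
  for (int c = 0; c < nc; ++c) {
    if (ch_type[c] == 2) {
      W[c] = as<NumericVector>(ch_weights[c]);
      TW[c] = as<NumericVector>(ch_tailw[c]);
    }
    TG[c] = as<IntegerVector>(ch_targets[c]);
    CF[c] = as<NumericVector>(ch_coefs[c]);
  }

  std::vector<double> x(n), xp(n), d1(n), d2(n);
  for (int i = 0; i < n; ++i) x[i] = state0[i];

  // Delayed reads at the t = 0 node use the average of the pre-history
  // product and the post-jump product: the initial condition jumps there,
  // and the averaged node value makes the trapezoid errors of the two
  // steps adjacent to the jump cancel (second order is preserved).
  std::vector<double> read0(std::max(ns, 1));

  auto set_sig = [&](int idx, const std::vector<double>& st) {
    for (int s = 0; s < ns; ++s) {
      double v = st[sig_f1[s]];
      if (sig_f2[s] >= 0) v *= st[sig_f2[s]];
      SIG(idx, s) = v;
    }
  };

  auto rhs = [&](const std::vector<double>& st, int idx,
                 std::vector<double>& d) {
    std::fill(d.begin(), d.end(), 0.0);
    for (int c = 0; c < nc; ++c) {
      double v;
      const int tp = ch_type[c];
      if (tp == 0) {
        v = st[ch_f1[c]];
        if (ch_f2[c] >= 0) v *= st[ch_f2[c]];
        v *= ch_rate[c];
      } else if (tp == 1) {
        const int li = idx - ch_lag[c];
        const int s = ch_sig[c];
        double y;
        if (li < 0) y = presig[s];
        else if (li == 0 && ch_lag[c] > 0) y = read0[s];
        else y = SIG(li, s);
        v = ch_rate[c] * y;
      } else {
        const NumericVector& w = W[c];
        const NumericVector& tw = TW[c];
        const int H = w.size() - 1;
        const int Lmax = (idx < H) ? idx : H;
        const int s = ch_sig[c];
        const double* sc = &SIG(0, s);
        double acc = 0.0;
        for (int L = 0; L <= Lmax; ++L) acc += w[L] * sc[idx - L];
        if (idx <= H) acc += w[idx] * (read0[s] - sc[0]);
        acc += presig[s] * tw[Lmax + 1];
        v = ch_rate[c] * acc;
      }
      const IntegerVector& tg = TG[c];
      const NumericVector& cf = CF[c];
      for (int q = 0; q < tg.size(); ++q) d[tg[q]] += cf[q] * v;
    }
  };

  for (int i = 0; i < n; ++i) X(0, i) = x[i];
  set_sig(0, x);
  for (int s = 0; s < ns; ++s) read0[s] = 0.5 * (presig[s] + SIG(0, s));

  for (int k = 0; k < K; ++k) {
    rhs(x, k, d1);
    for (int i = 0; i < n; ++i) xp[i] = x[i] + dt * d1[i];
    set_sig(k + 1, xp);               // provisional value for lag-0 lookups
    rhs(xp, k + 1, d2);
    bool bad = false;
    for (int i = 0; i < n; ++i) {
      x[i] += 0.5 * dt * (d1[i] + d2[i]);
      if (!std::isfinite(x[i])) bad = true;
    }
    if (bad)
      return List::create(_["ok"] = false, _["bad_step"] = k + 1, _["X"] = X);
    set_sig(k + 1, x);
    for (int i = 0; i < n; ++i) X(k + 1, i) = x[i];
  }

  return List::create(_["ok"] = true, _["bad_step"] = -1, _["X"] = X);
}
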