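#include <Rcpp.h>
using namespace Rcpp;

// Ships are coded 1..4, planets 1..2, keys 1 (left) / 2 (right).
// 0 means none/missed. `dest` maps ship -> planet, length 4.

// One SARSA(lambda) learning step after observing `reward` at `planet`
// following a first-stage choice of `chosen`.
static inline void mf_step(double *qmf, double *v2, int chosen, int planet,
                           double reward, double alpha, double lam) {
  // stage-1 backup towards the current second-stage value
  qmf[chosen] += alpha * (v2[planet] - qmf[chosen]);
  // outcome prediction error at the second stage
  double d2 = reward - v2[planet];
  v2[planet] += alpha * d2;
  // eligibility-traced stage-1 update
  qmf[chosen] += alpha * lam * d2;
}

// [[Rcpp::export]]
double cpp_session_loglik(NumericVector par, IntegerVector block,
                          IntegerVector left, IntegerVector right,
                          IntegerVector chosen, IntegerVector key,
                          NumericVector reward, IntegerVector dest) {
  const double alpha = par[0], lam = par[1], beta = par[2], pi = par[3],
               rho = par[4], w = par[5];
  const int n = block.size();
  double qmf[5] = {0.0, 0.5, 0.5, 0.5, 0.5};
  double v2[3] = {0.0, 0.5, 0.5};
  int prev_ship = 0, prev_key = 0;
  int prev_block = NA_INTEGER;
  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    if (block[t] != prev_block) {
      // stickiness referents reset at block start
      prev_ship = 0;
      prev_key = 0;
      prev_block = block[t];
    }
    const int c = chosen[t];
    if (c == 0) continue;  // missed: no likelihood term, no update
    const int L = left[t], R = right[t];
    const double xl =
        beta * (w * v2[dest[L - 1]] + (1.0 - w) * qmf[L] +
                pi * (L == prev_ship ? 1.0 : 0.0) +
                rho * (prev_key == 1 ? 1.0 : 0.0));
    const double xr =
        beta * (w * v2[dest[R - 1]] + (1.0 - w) * qmf[R] +
                pi * (R == prev_ship ? 1.0 : 0.0) +
                rho * (prev_key == 2 ? 1.0 : 0.0));
    const double m = xl > xr ? xl : xr;
    const double lse = m + std::log(std::exp(xl - m) + std::exp(xr - m));
    ll += (c == L ? xl : xr) - lse;
    mf_step(qmf, v2, c, dest[c - 1], reward[t], alpha, lam);
    prev_ship = c;
    prev_key = key[t];
  }
  return ll;
}

// Sequential choice generation for one session. Side assignment, pair
// schedule, miss events and reward walks are drawn in R beforehand; this
// routine consumes one uniform deviate per non-missed trial (choice draw).
// [[Rcpp::export]]
List cpp_simulate_choices(NumericVector par, IntegerVector block,
                          IntegerVector left, IntegerVector right,
                          IntegerVector missed, NumericVector walk1,
                          NumericVector walk2, IntegerVector dest) {
  const double alpha = par[0], lam = par[1], beta = par[2], pi = par[3],
               rho = par[4], w = par[5];
  const int n = block.size();
  IntegerVector chosen(n), key(n), payoff(n);
  double qmf[5] = {0.0, 0.5, 0.5, 0.5, 0.5};
  double v2[3] = {0.0, 0.5, 0.5};
  int prev_ship = 0, prev_key = 0;
  int prev_block = NA_INTEGER;
  for (int t = 0; t < n; ++t) {
    if (block[t] != prev_block) {
      prev_ship = 0;
      prev_key = 0;
      prev_block = block[t];
    }
    if (missed[t] == 1) {
      chosen[t] = 0;
      key[t] = 0;
      payoff[t] = NA_INTEGER;
      continue;
    }
    const int L = left[t], R = right[t];
    const double xl =
        beta * (w * v2[dest[L - 1]] + (1.0 - w) * qmf[L] +
                pi * (L == prev_ship ? 1.0 : 0.0) +
                rho * (prev_key == 1 ? 1.0 : 0.0));
    const double xr =
        beta * (w * v2[dest[R - 1]] + (1.0 - w) * qmf[R] +
                pi * (R == prev_ship ? 1.0 : 0.0) +
                rho * (prev_key == 2 ? 1.0 : 0.0));
    const double m = xl > xr ? xl : xr;
    const double pl = std::exp(xl - m) / (std::exp(xl - m) + std::exp(xr - m));
    const double u = R::unif_rand();
    int c, k;
    if (u < pl) {
      c = L;
      k = 1;
    } else {
      c = R;
      k = 2;
    }
    const int p = dest[c - 1];
    const double v = (p == 1) ? walk1[t] : walk2[t];
    // display mapping: half-up rounding of 9v, shifted onto -4..+5
    const int pay = (int)std::floor(9.0 * v + 0.5) - 4;
    const double r = (pay + 4) / 9.0;
    mf_step(qmf, v2, c, p, r, alpha, lam);
    chosen[t] = c;
    key[t] = k;
    payoff[t] = pay;
    prev_ship = c;
    prev_key = k;
  }
  return List::create(_["chosen"] = chosen, _["key"] = key,
                      _["payoff"] = payoff);
}
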