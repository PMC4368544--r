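// Backward-induction kernels for the relief-consumption task.
//
// State space: capital s = 0..S units, trials t = 1..T, actions c = 0..min(s, A).
// Transitions are deterministic (s' = s - c); all expectations are over the
// softmax policy itself.  These kernels sit inside the per-subject likelihood
// and are called thousands of times per fit, so inner loops avoid allocation
// and redundant exp() calls (the spread softmax is factorised around the
// integer part of rho, and Gaussian biases are evaluated inline).

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const double INV_SQRT_2PI = 0.3989422804014326779;

static inline void softmax_into(const double* q, int n, double beta, double* p) {
  double m = q[0];
  for (int i = 1; i < n; ++i) if (q[i] > m) m = q[i];
  double z = 0.0;
  for (int i = 0; i < n; ++i) { p[i] = std::exp(beta * (q[i] - m)); z += p[i]; }
  for (int i = 0; i < n; ++i) p[i] /= z;
}

// p[c] proportional to exp(-beta * |rho - c|) for c = 0..n-1, using two exp()
// calls: factors exp(-beta) descend stepwise away from floor(rho).  All
// intermediate values lie in (0, 1], so this is overflow-safe for any rho.
static inline void spread_softmax_into(double rho, int n, double beta,
                                       const double* ebpow, double* p) {
  int c0 = (int)std::floor(rho);
  if (c0 >= n) c0 = n - 1;
  if (c0 < 0) c0 = 0;
  const double frac = rho - c0; // may exceed 1 when rho is beyond the grid
  // shift by the smallest distance so the leading term never underflows
  double dmin = frac;
  if (c0 + 1 < n && 1.0 - frac < dmin) dmin = 1.0 - frac;
  double z = 0.0;
  const double e_dn = std::exp(-beta * (frac - dmin));
  for (int c = c0; c >= 0; --c) { // |rho - c| = frac + (c0 - c)
    p[c] = e_dn * ebpow[c0 - c];
    z += p[c];
  }
  const double e_up = std::exp(-beta * (1.0 - frac - dmin));
  for (int c = c0 + 1; c < n; ++c) { // |rho - c| = (1 - frac) + (c - c0 - 1)
    p[c] = e_up * ebpow[c - c0 - 1];
    z += p[c];
  }
  for (int c = 0; c < n; ++c) p[c] /= z;
}

// Policy-implied variance of the consumption amount c = 0..n-1.
static inline double policy_variance(const double* p, int n) {
  double m = 0.0, m2 = 0.0;
  for (int c = 0; c < n; ++c) { m += p[c] * c; m2 += p[c] * c * c; }
  return m2 - m * m;
}

// Sophisticated planner under the anticipation-discounting function
//   Delta(d) = gc^d + alpha * B(d),  B(d) = sum_{tau=0}^{d-1} gc^(d-tau) ga^tau,
// with utility U(c) = c^k.  Q(s,c,t) = U(c) + gc*VG_{t+1}(s-c) + alpha*W_{t+1}(s-c)
// where VG, VK are policy-expected values discounted at rates gc and ga, and W
// carries the anticipation (dread/savoring) stream:
//   W_t(s) = gc*EU_t(s) + E_pi[ gc*W_{t+1}(s-c) + gc*ga*VK_{t+1}(s-c) ].
// The split is exact algebra (B(d) = gc*B(d-1) + gc*ga^(d-1)), verified against
// brute-force path enumeration in the test-suite.
//
// Optional Gaussian spending biases (sd 2 units, centred at 0 / rho_t / min(A, s))
// are added to Q before the softmax; with all omegas zero this is the pure
// anticipation-discounting policy.
// [[Rcpp::export]]
List cpp_anticipation_policy(int T, int S, int A,
                             double alpha, double gc, double ga,
                             double k, double beta,
                             double wmin, double wmean, double wmax,
                             bool want_q) {
  const int A1 = A + 1, S1 = S + 1;
  NumericVector prob(static_cast<R_xlen_t>(A1) * S1 * T, 0.0);
  NumericVector qout(want_q ? static_cast<R_xlen_t>(A1) * S1 * T : 0, NA_REAL);
  const bool bias = (wmin > 0.0 || wmean > 0.0 || wmax > 0.0);

  std::vector<double> U(A1);
  for (int c = 0; c < A1; ++c) U[c] = (c == 0) ? 0.0 : std::pow((double)c, k);

  // Gaussian pdf ordinates, sd = 2: centre 0 (min bias) and every integer
  // centre 0..A (max bias, centred at min(A, s)).
  std::vector<double> pdf0(A1), pdfmax(static_cast<size_t>(A1) * A1);
  for (int c = 0; c < A1; ++c)
    pdf0[c] = 0.5 * INV_SQRT_2PI * std::exp(-0.125 * c * c);
  for (int mu = 0; mu < A1; ++mu)
    for (int c = 0; c < A1; ++c)
      pdfmax[mu * A1 + c] =
          0.5 * INV_SQRT_2PI * std::exp(-0.125 * (c - mu) * (c - mu));

  std::vector<double> VG0(S1), VG1(S1, 0.0), VK0(S1), VK1(S1, 0.0),
      W0(S1), W1(S1, 0.0);
  std::vector<double> q(A1), qb(A1), p(A1);

  for (int t = T; t >= 1; --t) {
    const double rem = (double)(T - t + 1);
    for (int s = 0; s <= S; ++s) {
      const int amax = (s < A) ? s : A;
      const int n = amax + 1;
      if (t < T) {
        for (int c = 0; c < n; ++c)
          q[c] = U[c] + gc * VG1[s - c] + alpha * W1[s - c];
      } else {
        for (int c = 0; c < n; ++c) q[c] = U[c];
      }
      if (bias) {
        const double rho = (double)s / rem;
        const double* pm = &pdfmax[amax * A1];
        for (int c = 0; c < n; ++c) {
          const double zm = 0.5 * (c - rho);
          qb[c] = q[c] + wmin * pdf0[c] +
                  wmean * 0.5 * INV_SQRT_2PI * std::exp(-0.5 * zm * zm) +
                  wmax * pm[c];
        }
        softmax_into(qb.data(), n, beta, p.data());
      } else {
        softmax_into(q.data(), n, beta, p.data());
      }
      double eu = 0.0, vg = 0.0, vk = 0.0, w = 0.0;
      if (t < T) {
        for (int c = 0; c < n; ++c) {
          eu += p[c] * U[c];
          vg += p[c] * (U[c] + gc * VG1[s - c]);
          vk += p[c] * (U[c] + ga * VK1[s - c]);
          w  += p[c] * (gc * W1[s - c] + gc * ga * VK1[s - c]);
        }
      } else {
        for (int c = 0; c < n; ++c) eu += p[c] * U[c];
        vg = eu; vk = eu;
      }
      VG0[s] = vg; VK0[s] = vk; W0[s] = gc * eu + w;
      const R_xlen_t off = (static_cast<R_xlen_t>(t - 1) * S1 + s) * A1;
      for (int c = 0; c < n; ++c) prob[off + c] = p[c];
      if (want_q) for (int c = 0; c < n; ++c) qout[off + c] = q[c];
    }
    std::swap(VG0, VG1); std::swap(VK0, VK1); std::swap(W0, W1);
  }

  List out = List::create(_["prob"] = prob);
  if (want_q) out["q"] = qout;
  return out;
}

// Income Maximization heuristic model: mixture of spend / spread softmax
// policies with an income-maximizing component whose action value is
//   Qmax(s,c,t) = rho_t(s) + gamma * W_{t+1}(s-c),
//   W(s,t) = rho_t(s) + gamma * E_mix[ W_{t+1}(s-c) ],
// i.e. the gamma-discounted expected stream of mean-relief-remaining under the
// mixture policy itself (strict backward induction resolves the circularity).
// Component policies are combined by inverse-variance weighting of their
// implied consumption distributions (variance floored at 1e-10).
// [[Rcpp::export]]
List cpp_income_max_policy(int T, int S, int A,
                           double b_spend, double b_spread, double b_max,
                           double gam) {
  const int A1 = A + 1, S1 = S + 1;
  NumericVector prob(static_cast<R_xlen_t>(A1) * S1 * T, 0.0);
  NumericVector wts(static_cast<R_xlen_t>(3) * S1 * T, 0.0);
  NumericVector wtab(static_cast<R_xlen_t>(S1) * T, 0.0);

  // The spend propensity M_spend = c depends on state only through the number
  // of feasible actions, so its softmax and variance are precomputed per amax.
  std::vector<double> p_spend_all(static_cast<size_t>(A1) * A1, 0.0);
  std::vector<double> v_spend(A1);
  {
    std::vector<double> m(A1), p(A1);
    for (int amax = 0; amax <= A; ++amax) {
      for (int c = 0; c <= amax; ++c) m[c] = (double)c;
      softmax_into(m.data(), amax + 1, b_spend, p.data());
      for (int c = 0; c <= amax; ++c) p_spend_all[amax * A1 + c] = p[c];
      v_spend[amax] = policy_variance(p.data(), amax + 1);
    }
  }
  // Step factors exp(-b_spread)^j for the factorised spread softmax.
  std::vector<double> ebpow(A1);
  {
    const double eb = std::exp(-b_spread);
    ebpow[0] = 1.0;
    for (int j = 1; j < A1; ++j) ebpow[j] = ebpow[j - 1] * eb;
  }

  std::vector<double> W0(S1), W1(S1, 0.0);
  std::vector<double> m3(A1), p2(A1), p3(A1), pm(A1);

  for (int t = T; t >= 1; --t) {
    const double rem = (double)(T - t + 1);
    for (int s = 0; s <= S; ++s) {
      const int amax = (s < A) ? s : A;
      const int n = amax + 1;
      const double rho = (double)s / rem;

      spread_softmax_into(rho, n, b_spread, ebpow.data(), p2.data());

      if (t < T) {
        for (int c = 0; c < n; ++c) m3[c] = rho + gam * W1[s - c];
      } else {
        for (int c = 0; c < n; ++c) m3[c] = rho;
      }
      softmax_into(m3.data(), n, b_max, p3.data());

      const double* p1 = &p_spend_all[amax * A1];
      double v1 = v_spend[amax];
      double v2 = policy_variance(p2.data(), n);
      double v3 = policy_variance(p3.data(), n);
      if (v1 < 1e-10) v1 = 1e-10;
      if (v2 < 1e-10) v2 = 1e-10;
      if (v3 < 1e-10) v3 = 1e-10;
      const double iv1 = 1.0 / v1, iv2 = 1.0 / v2, iv3 = 1.0 / v3;
      const double z = iv1 + iv2 + iv3;
      const double w1 = iv1 / z, w2 = iv2 / z, w3 = iv3 / z;

      double wfut = 0.0;
      for (int c = 0; c < n; ++c) {
        pm[c] = w1 * p1[c] + w2 * p2[c] + w3 * p3[c];
        if (t < T) wfut += pm[c] * W1[s - c];
      }
      W0[s] = rho + gam * wfut;

      const R_xlen_t off = (static_cast<R_xlen_t>(t - 1) * S1 + s) * A1;
      for (int c = 0; c < n; ++c) prob[off + c] = pm[c];
      const R_xlen_t woff = (static_cast<R_xlen_t>(t - 1) * S1 + s) * 3;
      wts[woff] = w1; wts[woff + 1] = w2; wts[woff + 2] = w3;
      wtab[static_cast<R_xlen_t>(t - 1) * S1 + s] = W0[s];
    }
    std::swap(W0, W1);
  }

  return List::create(_["prob"] = prob, _["weights"] = wts, _["w"] = wtab);
}
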