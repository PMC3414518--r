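#include <Rcpp.h>
using namespace Rcpp;

// Exact log-likelihood of bout initiations as a competing-risks
// inhomogeneous point process, assembled from piecewise-constant-state
// segments prepared in R (see prepare_likelihood_data).
//
// Segment matrix columns:
//  0 ind (1-based index into the per-individual parameter vectors)
//  1 t0, 2 t1            segment end points (session-local seconds)
//  3 R1, 4 R2            rewarded-manipulation counts per option-type
//  5 Om1, 6 Om2          observations seen (manipulation class), per type
//  7 Oe1, 8 Oe2          ... entry class
//  9 Of1, 10 Of2         ... feeding class
// 11 tau11, 12 tau21, 13 tau12, 14 tau22
//                        last qualifying observation time per
//                        (option-type k, box l), NaN if none this session
// 15 event               0 = none, else 1..4 encoding the option
//                        (k = (e-1) % 2 + 1, l = (e-1) / 2 + 1) of a bout
//                        initiated at t1
//
// The transient addend for option (k, l) uses the most recent qualifying
// observation anywhere (general), on box l (box), of type k (sametype)
// and at (k, l) exactly (specific); each kernel decays as exp(-rho dt)
// and integrates in closed form.  The exponentials of the at most four
// distinct tau values are computed once per segment and shared across
// the four options (the general/box/sametype clocks are maxima of the
// per-option clocks).

// [[Rcpp::export]]
List smfm_loglik_cpp(NumericMatrix seg,
                     double r1, double r2,
                     NumericVector lp, NumericVector lambda,
                     double gamma, double sm, double se, double sf,
                     NumericVector gg, NumericVector gb,
                     NumericVector gst, NumericVector gs,
                     double rho, bool multiplicative) {
  const int n = seg.nrow();
  double ll = 0.0;
  int n_events = 0;
  const double r[2] = {r1, r2};
  const double l_sm = std::log1p(-sm), l_se = std::log1p(-se),
    l_sf = std::log1p(-sf);
  const int ni = lp.size();
  std::vector<double> l_lam(ni);
  for (int i = 0; i < ni; ++i) l_lam[i] = std::log1p(-lambda[i]);

  for (int i = 0; i < n; ++i) {
    const int ind = (int) seg(i, 0) - 1;
    const double t0 = seg(i, 1), t1 = seg(i, 2);
    const double base = std::exp(lp[ind]);
    double learn[2];
    for (int k = 0; k < 2; ++k) {
      const double A = 1.0 - std::exp(seg(i, 3 + k) * l_lam[ind] +
                                      seg(i, 5 + k) * l_sm +
                                      seg(i, 7 + k) * l_se +
                                      seg(i, 9 + k) * l_sf);
      learn[k] = 1.0 + gamma * A;
    }
    // tau[k][l], with cached integral and endpoint exponentials
    double tau[2][2], I[2][2], V[2][2];
    int amax_k = -1, amax_l = -1;  // argmax over all four clocks
    double tmax = -1e300;
    for (int k = 0; k < 2; ++k)
      for (int l = 0; l < 2; ++l) {
        const double tt = seg(i, 11 + l * 2 + k);
        tau[k][l] = tt;
        if (ISNAN(tt)) { I[k][l] = 0.0; V[k][l] = 0.0; continue; }
        const double e0 = std::exp(-rho * (t0 - tt));
        const double e1 = std::exp(-rho * (t1 - tt));
        I[k][l] = (e0 - e1) / rho;  // kernel integral per unit strength
        V[k][l] = e1;               // kernel value at t1
        if (tt > tmax) { tmax = tt; amax_k = k; amax_l = l; }
      }
    const double L = t1 - t0;
    const int ev = (int) seg(i, 15);
    const double g_g = gg[ind], g_b = gb[ind], g_t = gst[ind],
      g_s = gs[ind];

    for (int k = 0; k < 2; ++k) {
      const double rb = r[k] * base;
      for (int l = 0; l < 2; ++l) {
        double Tint = 0.0, T1 = 0.0;
        if (amax_k >= 0) {
          // general: most recent clock anywhere
          Tint += g_g * I[amax_k][amax_l];
          T1 += g_g * V[amax_k][amax_l];
          // box level: most recent on box l
          const int kb = (ISNAN(tau[0][l]) ||
                          (!ISNAN(tau[1][l]) && tau[1][l] > tau[0][l]))
            ? 1 : 0;
          if (!ISNAN(tau[kb][l])) {
            Tint += g_b * I[kb][l]; T1 += g_b * V[kb][l];
          }
          // sametype: most recent of option-type k on either box
          const int lt = (ISNAN(tau[k][0]) ||
                          (!ISNAN(tau[k][1]) && tau[k][1] > tau[k][0]))
            ? 1 : 0;
          if (g_t > 0.0 && !ISNAN(tau[k][lt])) {
            Tint += g_t * I[k][lt]; T1 += g_t * V[k][lt];
          }
          // specific: the (k, l) clock itself
          if (!ISNAN(tau[k][l])) {
            Tint += g_s * I[k][l]; T1 += g_s * V[k][l];
          }
        }
        if (multiplicative)
          ll -= rb * learn[k] * (L + Tint);
        else
          ll -= rb * (learn[k] * L + Tint);
        if (ev == l * 2 + k + 1) {
          const double rate = multiplicative
            ? rb * learn[k] * (1.0 + T1)
            : rb * (learn[k] + T1);
          ll += std::log(rate);
          ++n_events;
        }
      }
    }
  }
  return List::create(_["loglik"] = ll, _["n_events"] = n_events,
                      _["n_segments"] = n);
}
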