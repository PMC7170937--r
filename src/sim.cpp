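#include <Rcpp.h>
using namespace Rcpp;

// Monthly recursion of the six carbon pools + plant-available water.
//
// Parameter vector `par` follows the canonical order kept in R (PAR_NAMES):
//  0 lue, 1 f_auto, 2 alloc_foliar, 3 alloc_labile, 4 alloc_root,
//  5 labile_release, 6 lcma, 7 turn_foliar, 8 turn_root, 9 turn_wood,
// 10 decomp_litter, 11 decomp_som, 12 lit2som, 13 theta, 14 w_half,
// 15 cc_foliar, 16 cc_wood, 17 cc_litter, 18 cc_som, 19 resilience
//
// `init` order (POOL_NAMES): labile, foliar, fine_root, wood, litter, som,
// water.  `forc` columns: t_mean, precip, sw_rad, days, ba_frac.
//
// Step order per month: (1) GPP and Ra, (2) NPP allocation + labile release,
// (3) turnover, (4) decomposition (temperature x moisture scalars), (5) fire
// combustion + fire-induced mortality, (6) water bucket.  Each pool's
// demanded outfluxes are scaled proportionally if they exceed the start-of-
// month stock, so pools never go negative.

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(NumericVector par, NumericVector init, NumericMatrix forc,
              double k_ext, double t_ref, double gt_cap, double w_max,
              double evap_coef) {
  const int n = forc.nrow();
  const double lue = par[0], f_auto = par[1];
  const double a_fol = par[2], a_lab = par[3], a_root = par[4];
  const double a_wood = 1.0 - a_fol - a_lab - a_root;
  const double rel_rate = par[5], lcma = par[6];
  const double t_fol = par[7], t_root = par[8], t_wood = par[9];
  const double d_lit = par[10], d_som = par[11], l2s = par[12];
  const double theta = par[13], w_half = par[14];
  const double cc_f = par[15], cc_w = par[16], cc_l = par[17], cc_s = par[18];
  const double resil = par[19];

  double L = init[0], F = init[1], Rt = init[2], W = init[3];
  double Li = init[4], S = init[5], Wa = init[6];

  NumericMatrix states(n, 7);
  NumericMatrix fluxes(n, 13);

  for (int t = 0; t < n; ++t) {
    const double tm = forc(t, 0), prec = forc(t, 1), sw = forc(t, 2);
    const double days = forc(t, 3), ba = forc(t, 4);

    // (1) photosynthesis and autotrophic respiration
    double gT = std::exp(theta * (tm - t_ref));
    if (gT > gt_cap) gT = gt_cap;
    const double lai = F / lcma;
    const double apar = 0.5 * sw * (1.0 - std::exp(-k_ext * lai));
    const double gpp = lue * apar * gT * days;
    const double ra = f_auto * gpp;
    const double npp = gpp - ra;
    const double gW = Wa / (Wa + w_half);

    // demanded outfluxes at start-of-month stocks, limited proportionally
    double rel = rel_rate * L;
    if (rel > L) rel = L;
    double tof = t_fol * F;
    if (tof > F) tof = F;
    double tor = t_root * Rt;
    if (tor > Rt) tor = Rt;
    double tow = t_wood * W;
    if (tow > W) tow = W;
    double rate_rh_l = d_lit * gT * gW;
    double rate_l2s = l2s * gT * gW;
    double out_li = (rate_rh_l + rate_l2s) * Li;
    if (out_li > Li && out_li > 0.0) {
      const double sc = Li / out_li;
      rate_rh_l *= sc;
      rate_l2s *= sc;
    }
    const double rh_lit = rate_rh_l * Li;
    const double tosom = rate_l2s * Li;
    double rh_som = d_som * gT * gW * S;
    if (rh_som > S) rh_som = S;

    // (2)-(4) pool updates
    L += a_lab * npp - rel;
    F += a_fol * npp + rel - tof;
    Rt += a_root * npp - tor;
    W += a_wood * npp - tow;
    Li += tof + tor - rh_lit - tosom;
    S += tow + tosom - rh_som;

    // (5) fire: combustion + mortality of live pools to litter
    const double mfac = (1.0 - resil) * ba;
    const double cb_L = L * ba * cc_f, mt_L = L * mfac * (1.0 - cc_f);
    const double cb_F = F * ba * cc_f, mt_F = F * mfac * (1.0 - cc_f);
    const double cb_R = Rt * ba * cc_f, mt_R = Rt * mfac * (1.0 - cc_f);
    const double cb_W = W * ba * cc_w, mt_W = W * mfac * (1.0 - cc_w);
    const double cb_Li = Li * ba * cc_l;
    const double cb_S = S * ba * cc_s;
    const double fire = cb_L + cb_F + cb_R + cb_W + cb_Li + cb_S;
    L -= cb_L + mt_L;
    F -= cb_F + mt_F;
    Rt -= cb_R + mt_R;
    W -= cb_W + mt_W;
    Li += mt_L + mt_F + mt_R + mt_W - cb_Li;
    S -= cb_S;

    // (6) water bucket: precip in, GPP-proportional evapotranspiration out
    Wa += prec - evap_coef * gpp;
    if (Wa < 0.0) Wa = 0.0;
    if (Wa > w_max) Wa = w_max;

    states(t, 0) = L;
    states(t, 1) = F;
    states(t, 2) = Rt;
    states(t, 3) = W;
    states(t, 4) = Li;
    states(t, 5) = S;
    states(t, 6) = Wa;

    const double ter = ra + rh_lit + rh_som;
    fluxes(t, 0) = gpp;
    fluxes(t, 1) = ra;
    fluxes(t, 2) = rh_lit;
    fluxes(t, 3) = rh_som;
    fluxes(t, 4) = fire;
    fluxes(t, 5) = mt_L;
    fluxes(t, 6) = mt_F;
    fluxes(t, 7) = mt_R;
    fluxes(t, 8) = mt_W;
    fluxes(t, 9) = npp;
    fluxes(t, 10) = ter;
    fluxes(t, 11) = ter - gpp;         // NEE
    fluxes(t, 12) = ter - gpp + fire;  // NBE
  }

  return List::create(_["states"] = states, _["fluxes"] = fluxes);
}
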