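// Layered tipping-bucket water balance for one stand-alone soil column.
//
// Explicit sub-daily stepping: precipitation -> litter -> ponded storage ->
// infiltration -> moisture-limited evapotranspiration -> gravity drainage of
// water above field capacity (rate-limited by Mualem-van Genuchten unsaturated
// conductivity) -> lateral Darcy exchange with a fixed boundary water table
// (WTDx) -> saturation-excess runoff.  All transfers are explicit amounts
// moved between stores, so the daily flux ledger closes to machine precision.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Column {
  int L;
  std::vector<double> dz, th_r, th_s, alpha, nvg, ksat, th_fc, th_wilt;
  std::vector<double> ztop; // depth of layer top below surface
  double total_depth;
  double litter_dz, lit_th_r, lit_th_s, lit_th_fc;
  double wtdx, lat_len, pond_max, root_depth, sat_frac;
};

// Mualem-van Genuchten relative conductivity at effective saturation se
inline double k_rel(double se, double m) {
  if (se <= 0.0) return 0.0;
  if (se >= 1.0) return 1.0;
  double t = 1.0 - std::pow(1.0 - std::pow(se, 1.0 / m), m);
  return std::sqrt(se) * t * t;
}

inline double clamp01(double x) { return x < 0.0 ? 0.0 : (x > 1.0 ? 1.0 : x); }

// Water table depth: top of the contiguous saturated stack reaching the
// column bottom, linearly interpolated into the first unsaturated layer
// above it; capped at total_depth when no bottom saturation exists.
double diagnose_wtd(const Column& c, const std::vector<double>& th, double ponded) {
  if (ponded > 1e-12) return 0.0;
  int j = c.L - 1;
  while (j >= 0 && th[j] >= c.sat_frac * c.th_s[j] - 1e-12) --j;
  if (j < 0) return 0.0;                 // fully saturated
  if (j == c.L - 1) return c.total_depth; // bottom layer unsaturated
  double wtd = c.ztop[j + 1];             // top of saturated stack
  double sat_level = c.sat_frac * c.th_s[j];
  if (sat_level > c.th_fc[j]) {
    double frac = (th[j] - c.th_fc[j]) / (sat_level - c.th_fc[j]);
    if (frac > 0.0) wtd -= clamp01(frac) * c.dz[j];
  }
  if (wtd < 0.0) wtd = 0.0;
  return wtd;
}

} // namespace

// [[Rcpp::export(name = ".simulate_column_cpp")]]
List simulate_column_cpp(NumericVector dz, NumericVector theta_r, NumericVector theta_s,
                         NumericVector vg_alpha, NumericVector vg_n, NumericVector ksat,
                         NumericVector theta_fc, NumericVector theta_wilt,
                         double litter_dz, double litter_theta_r, double litter_theta_s,
                         double litter_theta_fc,
                         double wtdx, double lateral_length, double pond_max,
                         double root_depth, double sat_frac,
                         NumericVector theta0, double litter_theta0, double ponded0,
                         NumericVector precip, NumericVector pet, int substeps) {
  Column c;
  c.L = dz.size();
  c.dz.assign(dz.begin(), dz.end());
  c.th_r.assign(theta_r.begin(), theta_r.end());
  c.th_s.assign(theta_s.begin(), theta_s.end());
  c.alpha.assign(vg_alpha.begin(), vg_alpha.end());
  c.nvg.assign(vg_n.begin(), vg_n.end());
  c.ksat.assign(ksat.begin(), ksat.end());
  c.th_fc.assign(theta_fc.begin(), theta_fc.end());
  c.th_wilt.assign(theta_wilt.begin(), theta_wilt.end());
  c.ztop.resize(c.L);
  double z = 0.0;
  for (int i = 0; i < c.L; ++i) { c.ztop[i] = z; z += c.dz[i]; }
  c.total_depth = z;
  c.litter_dz = litter_dz; c.lit_th_r = litter_theta_r;
  c.lit_th_s = litter_theta_s; c.lit_th_fc = litter_theta_fc;
  c.wtdx = wtdx; c.lat_len = lateral_length; c.pond_max = pond_max;
  c.root_depth = root_depth; c.sat_frac = sat_frac;

  const int ndays = precip.size();
  std::vector<double> th(theta0.begin(), theta0.end());
  double lit = litter_theta0, pond = ponded0;

  // root zone = litter + layers whose top lies above root_depth
  int nroot = 0;
  for (int i = 0; i < c.L; ++i) if (c.ztop[i] < root_depth - 1e-12) nroot = i + 1;
  double rz_dz = litter_dz, rz_fc = litter_dz * litter_theta_fc, rz_w = litter_dz * litter_theta_r;
  for (int i = 0; i < nroot; ++i) {
    rz_dz += c.dz[i];
    rz_fc += c.dz[i] * c.th_fc[i];
    rz_w  += c.dz[i] * c.th_wilt[i];
  }

  NumericVector out_wtd(ndays), out_thns(ndays), out_et(ndays), out_lat(ndays),
      out_run(ndays), out_dstor(ndays);
  const double dt = 1.0 / substeps;

  for (int d = 0; d < ndays; ++d) {
    double P = precip[d], PET = pet[d];
    if (P < 0.0) stop("negative precipitation on day %d", d + 1);
    double et_day = 0.0, lat_day = 0.0, run_day = 0.0;
    double stor0 = pond + lit * litter_dz;
    for (int i = 0; i < c.L; ++i) stor0 += th[i] * c.dz[i];

    for (int s = 0; s < substeps; ++s) {
      // 1. precipitation wets the litter, overflow ponds
      double rain = P * dt;
      double lit_space = (c.lit_th_s - lit) * litter_dz;
      double to_lit = rain < lit_space ? rain : lit_space;
      lit += to_lit / litter_dz;
      pond += rain - to_lit;
      // 2. litter drains to the pond above its field capacity
      if (lit > c.lit_th_fc) {
        pond += (lit - c.lit_th_fc) * litter_dz;
        lit = c.lit_th_fc;
      }
      // 3. infiltration into the top layer
      if (pond > 0.0) {
        double space = (c.th_s[0] - th[0]) * c.dz[0];
        double inf = c.ksat[0] * dt;
        if (inf > pond) inf = pond;
        if (inf > space) inf = space;
        if (inf > 0.0) { pond -= inf; th[0] += inf / c.dz[0]; }
      }
      // 4. evapotranspiration, limited by a linear root-zone stress ramp
      if (PET > 0.0) {
        double rz = lit * litter_dz;
        for (int i = 0; i < nroot; ++i) rz += th[i] * c.dz[i];
        double f = (rz - rz_w) / (rz_fc - rz_w);
        f = clamp01(f);
        double demand = PET * dt * f;
        // surface litter evaporates first
        double avail = (lit - c.lit_th_r) * litter_dz;
        if (avail < 0.0) avail = 0.0;
        double take = demand < avail ? demand : avail;
        lit -= take / litter_dz;
        et_day += take;
        demand -= take;
        // root uptake proportional to available water in each root-zone layer
        if (demand > 1e-15) {
          double tot = 0.0;
          for (int i = 0; i < nroot; ++i) {
            double a = (th[i] - c.th_wilt[i]) * c.dz[i];
            if (a > 0.0) tot += a;
          }
          if (tot > 0.0) {
            double frac = demand < tot ? demand / tot : 1.0;
            for (int i = 0; i < nroot; ++i) {
              double a = (th[i] - c.th_wilt[i]) * c.dz[i];
              if (a <= 0.0) continue;
              take = a * frac;
              th[i] -= take / c.dz[i];
              et_day += take;
            }
          }
        }
      }
      // 5. gravity drainage of water above field capacity, top-down,
      //    rate-limited by unsaturated conductivity, blocked by full layers
      for (int i = 0; i < c.L - 1; ++i) {
        double excess = (th[i] - c.th_fc[i]) * c.dz[i];
        if (excess <= 0.0) continue;
        double k;
        if (th[i] >= c.th_s[i] - 1e-12) k = c.ksat[i];
        else {
          double m = 1.0 - 1.0 / c.nvg[i];
          double se = (th[i] - c.th_r[i]) / (c.th_s[i] - c.th_r[i]);
          k = c.ksat[i] * k_rel(se, m);
        }
        double flux = k * dt;
        if (flux > excess) flux = excess;
        double space = (c.th_s[i + 1] - th[i + 1]) * c.dz[i + 1];
        if (flux > space) flux = space;
        if (flux > 0.0) {
          th[i] -= flux / c.dz[i];
          th[i + 1] += flux / c.dz[i + 1];
        }
      }
      // 6. lateral Darcy exchange with the boundary water table
      {
        double wtd = diagnose_wtd(c, th, pond);
        double head = c.wtdx < c.total_depth ? c.wtdx : c.total_depth;
        double zsat = wtd < head ? wtd : head;   // top of transmitting zone
        double b = c.total_depth - zsat;
        if (b > 1e-12 && c.lat_len > 0.0 && std::isfinite(c.lat_len)) {
          double ksum = 0.0;
          for (int i = 0; i < c.L; ++i) {
            double top = c.ztop[i], bot = c.ztop[i] + c.dz[i];
            double ov = (bot < c.total_depth ? bot : c.total_depth) - (top > zsat ? top : zsat);
            if (ov > 0.0) ksum += c.ksat[i] * ov;
          }
          double keff = ksum / b;
          double q = keff * (c.wtdx - wtd) / c.lat_len * (b / c.total_depth) * dt;
          if (q > 0.0) { // discharge: water table falls from the top
            double removed = 0.0;
            if (pond > 0.0) {
              double take = q < pond ? q : pond;
              pond -= take; removed += take;
            }
            for (int i = 0; i < c.L && removed < q - 1e-15; ++i) {
              if (c.ztop[i] + c.dz[i] <= wtd) continue; // above the water table
              double avail = (th[i] - c.th_fc[i]) * c.dz[i];
              if (avail <= 0.0) continue;
              double take = (q - removed) < avail ? (q - removed) : avail;
              th[i] -= take / c.dz[i];
              removed += take;
            }
            lat_day += removed;
          } else if (q < 0.0) { // recharge: water table rises from the bottom
            double want = -q, added = 0.0;
            for (int i = c.L - 1; i >= 0 && added < want - 1e-15; --i) {
              double space = (c.th_s[i] - th[i]) * c.dz[i];
              if (space <= 0.0) continue;
              double put = (want - added) < space ? (want - added) : space;
              th[i] += put / c.dz[i];
              added += put;
            }
            lat_day -= added;
          }
        }
      }
      // 7. saturation-excess runoff
      if (pond > c.pond_max) {
        run_day += pond - c.pond_max;
        pond = c.pond_max;
      }
    }

    double stor1 = pond + lit * litter_dz;
    for (int i = 0; i < c.L; ++i) stor1 += th[i] * c.dz[i];
    out_et[d] = et_day;
    out_lat[d] = lat_day;
    out_run[d] = run_day;
    out_dstor[d] = stor1 - stor0;
    out_wtd[d] = diagnose_wtd(c, th, pond);
    out_thns[d] = (lit * litter_dz + th[0] * c.dz[0] + th[1] * c.dz[1]) /
                  (litter_dz + c.dz[0] + c.dz[1]);
  }

  return List::create(_["theta"] = NumericVector(th.begin(), th.end()),
                      _["litter_theta"] = lit, _["ponded"] = pond,
                      _["wtd"] = out_wtd, _["theta_ns"] = out_thns,
                      _["et_actual"] = out_et, _["lateral"] = out_lat,
                      _["runoff"] = out_run, _["delta_storage"] = out_dstor);
}

// [[Rcpp::export(name = ".diagnose_wtd_cpp")]]
double diagnose_wtd_cpp(NumericVector dz, NumericVector theta_s, NumericVector theta_fc,
                        NumericVector theta, double ponded, double sat_frac) {
  Column c;
  c.L = dz.size();
  c.dz.assign(dz.begin(), dz.end());
  c.th_s.assign(theta_s.begin(), theta_s.end());
  c.th_fc.assign(theta_fc.begin(), theta_fc.end());
  c.ztop.resize(c.L);
  double z = 0.0;
  for (int i = 0; i < c.L; ++i) { c.ztop[i] = z; z += c.dz[i]; }
  c.total_depth = z;
  c.sat_frac = sat_frac;
  std::vector<double> th(theta.begin(), theta.end());
  return diagnose_wtd(c, th, ponded);
}
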