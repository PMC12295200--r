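// Independent-reaction-times engine for one track history.
//
// Given the 1-ps particle configuration and the (viscosity-scaled,
// ionic-strength-corrected) reaction tables, samples first-passage reaction
// times for every reactive particle pair and exponential pseudo-first-order
// scavenging times, then commits events in time order up to the hand-off
// time. Trajectories are never propagated; positions are advanced by free
// Gaussian displacements only when a new channel needs a separation
// (standard IRT position-update approximation).
//
// Pair kernels:
//   fully diffusion controlled (absorbing contact):
//     W(t) = (R/r0) erfc( (r0-R)/sqrt(4 D t) ),  Winf = R/r0
//   partially controlled (radiation boundary, velocity v = k_act/(4 pi R^2 N_A)):
//     W(t) = (R/r0) a [ erfc(y) - exp(b g + g^2 D t) erfc(y + g sqrt(D t)) ]
//     with y = b/sqrt(4 D t), b = r0 - R, g = 1/R + v/D, a = vR/(D + vR);
//     Winf = (R/r0) a.
// The exp*erfc product is evaluated as exp(-y^2) * erfcx(y + g sqrt(Dt)).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

const double SQRT1_2 = 0.70710678118654752440;

double erfc_(double x) {
  // erfc(x) = 2 * pnorm(-x * sqrt(2))
  return 2.0 * R::pnorm(-x * M_SQRT2, 0.0, 1.0, 1, 0);
}

double erfcx_(double x) {
  // scaled complementary error function, x >= 0
  if (x > 6.0) {
    double ix2 = 1.0 / (x * x);
    return (1.0 / (x * 1.77245385090551603)) *
           (1.0 - 0.5 * ix2 + 0.75 * ix2 * ix2 - 1.875 * ix2 * ix2 * ix2);
  }
  return std::exp(x * x) * erfc_(x);
}

struct Event {
  double t;
  int a, b;      // particle indices; b = -1 for scavenging
  int rid;       // 1-based reaction index
  bool pair;
};
struct EvCmp {
  bool operator()(const Event& l, const Event& r) const { return l.t > r.t; }
};

struct Engine {
  // particle state
  std::vector<double> x, y, z, tpos;
  std::vector<int> spi;          // 0-based species index
  std::vector<char> alive;
  // species data
  const NumericVector& D;
  const IntegerMatrix& pair_rid;
  // reaction data (0-based rows)
  const IntegerVector& ctrl;
  const NumericVector& Reff, alph, gam, Drel;
  const IntegerVector& prod;
  // scavenging channels grouped by species
  std::vector<std::vector<std::pair<double, int> > > scav; // (rate, rid)
  double t_handoff, boxL, wmin;
  std::priority_queue<Event, std::vector<Event>, EvCmp> pq;

  Engine(const NumericVector& D_, const IntegerMatrix& pr,
         const IntegerVector& ctrl_, const NumericVector& Reff_,
         const NumericVector& alph_, const NumericVector& gam_,
         const NumericVector& Drel_, const IntegerVector& prod_)
      : D(D_), pair_rid(pr), ctrl(ctrl_), Reff(Reff_), alph(alph_),
        gam(gam_), Drel(Drel_), prod(prod_) {}

  double dist(int i, int j) const {
    double dx = x[i] - x[j];
    if (boxL > 0.0) dx -= boxL * std::round(dx / boxL);
    double dy = y[i] - y[j], dz = z[i] - z[j];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  void update_pos(int i, double t) {
    double dt = t - tpos[i];
    if (dt <= 0.0) return;
    double s = std::sqrt(2.0 * D[spi[i]] * dt);
    x[i] += norm_rand() * s;
    y[i] += norm_rand() * s;
    z[i] += norm_rand() * s;
    tpos[i] = t;
  }

  // conditional first-passage CDF for the radiation-boundary kernel
  double radbc_cdf(double b, double g, double Dr, double t) const {
    double sDt = std::sqrt(Dr * t);
    double yv = b / (2.0 * sDt);
    return erfc_(yv) - std::exp(-yv * yv) * erfcx_(yv + g * sDt);
  }

  // sampled waiting time (from now) for pair channel, or +Inf
  double sample_pair_time(int r, double r0, double horizon) {
    if (horizon <= 0.0) return R_PosInf;
    double R_ = Reff[r];
    if (ctrl[r] == 0) {                 // fully diffusion controlled
      if (r0 <= R_) return 0.0;
      double winf = R_ / r0;
      if (winf < wmin) return R_PosInf;
      double u = unif_rand();
      if (u >= winf) return R_PosInf;
      double u2 = u / winf;
      double xq = R::qnorm(1.0 - 0.5 * u2, 0.0, 1.0, 1, 0) * SQRT1_2;
      double b = r0 - R_;
      double t = (b * b) / (4.0 * Drel[r] * xq * xq);
      return (t <= horizon) ? t : R_PosInf;
    }
    // radiation boundary
    double a = alph[r];
    double winf = (r0 <= R_) ? a : (R_ / r0) * a;
    if (winf < wmin) return R_PosInf;
    double u = unif_rand();
    if (u >= winf) return R_PosInf;
    double u2 = u / winf;
    double b = (r0 > R_) ? (r0 - R_) : 0.0;
    double g = gam[r], Dr = Drel[r];
    if (radbc_cdf(b, g, Dr, horizon) < u2) return R_PosInf;
    double lo = -18.0, hi = std::log10(horizon);
    // bracket: CDF(10^lo) ~ 0
    for (int it = 0; it < 80; ++it) {
      double mid = 0.5 * (lo + hi);
      if (radbc_cdf(b, g, Dr, std::pow(10.0, mid)) < u2) lo = mid; else hi = mid;
    }
    return std::pow(10.0, 0.5 * (lo + hi));
  }

  void add_pair_channel(int i, int j, double tnow) {
    int rid = pair_rid(spi[i], spi[j]);
    if (rid == 0) return;
    double dt = sample_pair_time(rid - 1, dist(i, j), t_handoff - tnow);
    if (R_finite(dt)) {
      Event e; e.t = tnow + dt; e.a = i; e.b = j; e.rid = rid; e.pair = true;
      pq.push(e);
    }
  }

  void add_scav_channels(int i, double tnow) {
    const std::vector<std::pair<double, int> >& ch = scav[spi[i]];
    for (size_t c = 0; c < ch.size(); ++c) {
      double t = tnow + exp_rand() / ch[c].first;
      if (t <= t_handoff) {
        Event e; e.t = t; e.a = i; e.b = -1; e.rid = ch[c].second; e.pair = false;
        pq.push(e);
      }
    }
  }

  int add_particle(int sp0, double px, double py, double pz, double t) {
    x.push_back(px); y.push_back(py); z.push_back(pz);
    tpos.push_back(t); spi.push_back(sp0); alive.push_back(1);
    return (int)x.size() - 1;
  }
};

}  // namespace

// [[Rcpp::export]]
List irt_history_cpp(IntegerVector sp, NumericMatrix pos, NumericVector D,
                     IntegerMatrix pair_rid, IntegerVector ctrl,
                     NumericVector Reff, NumericVector alpha,
                     NumericVector gamma_, NumericVector Drel,
                     IntegerVector prod_sp, IntegerVector scav_sp,
                     NumericVector scav_rate, IntegerVector scav_rid,
                     double t_handoff, double box_L, double w_min) {
  int n = sp.size();
  Engine eng(D, pair_rid, ctrl, Reff, alpha, gamma_, Drel, prod_sp);
  eng.t_handoff = t_handoff;
  eng.boxL = box_L;
  eng.wmin = w_min;
  eng.x.resize(n); eng.y.resize(n); eng.z.resize(n);
  eng.tpos.assign(n, 0.0); eng.alive.assign(n, 1); eng.spi.resize(n);
  for (int i = 0; i < n; ++i) {
    eng.spi[i] = sp[i] - 1;
    eng.x[i] = pos(i, 0); eng.y[i] = pos(i, 1); eng.z[i] = pos(i, 2);
  }
  eng.scav.resize(D.size());
  for (int c = 0; c < scav_sp.size(); ++c) {
    eng.scav[scav_sp[c] - 1].push_back(
        std::make_pair(scav_rate[c], (int)scav_rid[c]));
  }

  // initial channels
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) eng.add_pair_channel(i, j, 0.0);
    eng.add_scav_channels(i, 0.0);
  }

  std::vector<double> ev_t;
  std::vector<int> ev_rid, ev_kind;

  while (!eng.pq.empty()) {
    Event ev = eng.pq.top();
    eng.pq.pop();
    if (!eng.alive[ev.a]) continue;
    if (ev.pair && !eng.alive[ev.b]) continue;
    if (ev.t < 0 || !R_finite(ev.t)) stop("event-queue inconsistency: bad time");
    eng.alive[ev.a] = 0;
    if (ev.pair) eng.alive[ev.b] = 0;
    ev_t.push_back(ev.t);
    ev_rid.push_back(ev.rid);
    ev_kind.push_back(ev.pair ? 0 : 1);

    int pr = prod_sp[ev.rid - 1];
    if (pr > 0) {
      eng.update_pos(ev.a, ev.t);
      double px = eng.x[ev.a], py = eng.y[ev.a], pz = eng.z[ev.a];
      if (ev.pair) {
        eng.update_pos(ev.b, ev.t);
        double dx = eng.x[ev.b] - px;
        if (box_L > 0.0) dx -= box_L * std::round(dx / box_L);
        px += 0.5 * dx;
        py += 0.5 * (eng.y[ev.b] - py);
        pz += 0.5 * (eng.z[ev.b] - pz);
      }
      int m = eng.add_particle(pr - 1, px, py, pz, ev.t);
      for (int j = 0; j < m; ++j) {
        if (!eng.alive[j]) continue;
        eng.update_pos(j, ev.t);
        eng.add_pair_channel(m, j, ev.t);
      }
      eng.add_scav_channels(m, ev.t);
    }
  }

  // surviving species (1-based indices)
  std::vector<int> surv;
  for (size_t i = 0; i < eng.alive.size(); ++i) {
    if (eng.alive[i]) surv.push_back(eng.spi[i] + 1);
  }

  return List::create(_["t"] = wrap(ev_t), _["rid"] = wrap(ev_rid),
                      _["kind"] = wrap(ev_kind), _["survivors"] = wrap(surv));
}
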