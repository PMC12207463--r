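// Hot inner loops of the simulator. Semantics mirror the R-level contracts:
// movement/timer resolution in randomized order, resource pickup on landing,
// freeze -> removal -> respawn transitions, beam tracing blocked by walls,
// symmetric dot-product rewards with max-of-pair freeze durations.
//
// The R functions env_step()/resolve_interaction() delegate their inner
// phases here, and cpp_rollout() runs whole episodes for feedforward feature
// policies (training and probes) through the exact same static helpers, so
// there is one implementation of the game rules.
//
// All randomness uses R's RNG (RNGScope), so runs reproduce under set.seed().

#include <Rcpp.h>
using namespace Rcpp;

static inline int unif_index(int n) {
  int k = (int)std::floor(unif_rand() * n) + 1;
  if (k > n) k = n;
  return k;
}

static const int FWD_DR[5] = {0, -1, 0, 1, 0};
static const int FWD_DC[5] = {0, 0, 1, 0, -1};
static const int RGT_DR[5] = {0, 0, 1, 0, -1};
static const int RGT_DC[5] = {0, 1, 0, -1, 0};

// ---------------------------------------------------------------------------
// phase A: timers, movement, pickup (mutates its arguments in place)
static void phase_a_inner(const IntegerVector &order, const IntegerVector &actions,
                          const LogicalMatrix &wall, IntegerMatrix &occ,
                          IntegerMatrix &resources,
                          IntegerVector &row, IntegerVector &col,
                          IntegerVector &orient, NumericMatrix &inv,
                          LogicalVector &ready, IntegerVector &freeze,
                          IntegerVector &removal, LogicalVector &pending,
                          const LogicalVector &scripted, const IntegerVector &slot,
                          const IntegerMatrix &spawn_points,
                          const IntegerVector &spawn_slot, int removal_steps) {
  const int nr = wall.nrow(), nc = wall.ncol();
  const int n_spawn = spawn_points.nrow();
  bool restricted = false;
  for (int s = 0; s < n_spawn; ++s) {
    if (!IntegerVector::is_na(spawn_slot[s])) { restricted = true; break; }
  }
  for (int oi = 0; oi < order.size(); ++oi) {
    int i = order[oi] - 1;
    if (removal[i] > 0) {
      removal[i] -= 1;
      if (removal[i] == 0) {
        std::vector<int> free_pts;
        for (int s = 0; s < n_spawn; ++s) {
          if (restricted && !IntegerVector::is_na(spawn_slot[s]) &&
              spawn_slot[s] != slot[i]) continue;
          int rr = spawn_points(s, 0), cc = spawn_points(s, 1);
          if (occ(rr - 1, cc - 1) == 0) free_pts.push_back(s);
        }
        if (free_pts.empty()) continue;   // retried next step
        int pick = free_pts[unif_index((int)free_pts.size()) - 1];
        int rr = spawn_points(pick, 0), cc = spawn_points(pick, 1);
        row[i] = rr; col[i] = cc;
        orient[i] = unif_index(4);
        for (int c3 = 0; c3 < 3; ++c3) inv(c3, i) = 0.0;
        ready[i] = false;
        occ(rr - 1, cc - 1) = i + 1;
      }
      continue;
    }
    if (freeze[i] > 0) {
      freeze[i] -= 1;
      if (freeze[i] == 0 && pending[i]) {
        pending[i] = false;
        removal[i] = removal_steps;
        occ(row[i] - 1, col[i] - 1) = 0;
        row[i] = NA_INTEGER; col[i] = NA_INTEGER;
      }
      continue;
    }
    if (IntegerVector::is_na(row[i]) || scripted[i]) continue;
    int act = actions[i];
    if (act == 6) {
      orient[i] = ((orient[i] - 2) % 4 + 4) % 4 + 1;      // TURN_LEFT
    } else if (act == 7) {
      orient[i] = (orient[i] % 4) + 1;                    // TURN_RIGHT
    } else if (act >= 2 && act <= 5) {
      int o = orient[i], dr = 0, dc = 0;
      if (act == 2) { dr = FWD_DR[o]; dc = FWD_DC[o]; }
      else if (act == 3) { dr = -FWD_DR[o]; dc = -FWD_DC[o]; }
      else if (act == 4) { dr = -RGT_DR[o]; dc = -RGT_DC[o]; }
      else { dr = RGT_DR[o]; dc = RGT_DC[o]; }
      int nrw = row[i] + dr, ncl = col[i] + dc;
      if (nrw >= 1 && nrw <= nr && ncl >= 1 && ncl <= nc &&
          !wall(nrw - 1, ncl - 1) && occ(nrw - 1, ncl - 1) == 0) {
        occ(row[i] - 1, col[i] - 1) = 0;
        row[i] = nrw; col[i] = ncl;
        occ(nrw - 1, ncl - 1) = i + 1;
        int res = resources(nrw - 1, ncl - 1);
        if (res > 0) {
          inv(res - 1, i) += 1.0;
          ready[i] = true;
          resources(nrw - 1, ncl - 1) = 0;
        }
      }
    }
  }
}

// beam trace: first agent within beam_range along heading, blocked by walls;
// returns 0-based index or -1
static int beam_hit(const LogicalMatrix &wall, const IntegerMatrix &occ,
                    const IntegerVector &row, const IntegerVector &col,
                    const IntegerVector &orient, int beam_range, int i) {
  int o = orient[i];
  int r = row[i], c = col[i];
  for (int k = 0; k < beam_range; ++k) {
    r += FWD_DR[o]; c += FWD_DC[o];
    if (r < 1 || r > wall.nrow() || c < 1 || c > wall.ncol()) return -1;
    if (wall(r - 1, c - 1)) return -1;
    int j = occ(r - 1, c - 1);
    if (j > 0) return j - 1;
  }
  return -1;
}

// interaction resolution: returns target (0-based) and reward, applying the
// freeze/removal-pending effects; -1 if the beam is a no-op
static int resolve_inner(const LogicalMatrix &wall, const IntegerMatrix &occ,
                         const IntegerVector &row, const IntegerVector &col,
                         const IntegerVector &orient, const NumericMatrix &inv,
                         const LogicalVector &ready, IntegerVector &freeze,
                         LogicalVector &pending, const IntegerVector &pfreeze,
                         int beam_range, double reward_scale,
                         bool require_initiator_ready, int i, double *out_reward) {
  if (IntegerVector::is_na(row[i]) || freeze[i] > 0) return -1;
  if (require_initiator_ready && !ready[i]) return -1;
  int j = beam_hit(wall, occ, row, col, orient, beam_range, i);
  if (j < 0) return -1;
  if (!ready[j] || freeze[j] > 0) return -1;
  double rew = 0.0;
  for (int c3 = 0; c3 < 3; ++c3) rew += inv(c3, i) * inv(c3, j);
  rew *= reward_scale;
  int dur = std::max(pfreeze[i], pfreeze[j]);
  freeze[i] = dur; freeze[j] = dur;
  pending[i] = true; pending[j] = true;
  *out_reward = rew;
  return j;
}

static void features_inner(int i, const IntegerMatrix &res_points,
                           const IntegerMatrix &resources,
                           const IntegerVector &row, const IntegerVector &col,
                           const IntegerVector &orient, const NumericMatrix &inv,
                           const LogicalVector &ready, const IntegerVector &slot,
                           int beam_range, double *out) {
  int o = orient[i];
  double fr_dr = FWD_DR[o], fr_dc = FWD_DC[o], rr_dr = RGT_DR[o], rr_dc = RGT_DC[o];
  out[0] = ready[i] ? 1.0 : 0.0;
  for (int c3 = 0; c3 < 3; ++c3)
    out[1 + c3] = std::min(inv(c3, i), 5.0) / 5.0;
  double best_f = 0, best_r = 0, bestd;
  // nearest stocked resource point
  bestd = 1e18; bool found = false;
  for (int p = 0; p < res_points.nrow(); ++p) {
    int pr = res_points(p, 0), pc = res_points(p, 1);
    if (resources(pr - 1, pc - 1) <= 0) continue;
    double dr = pr - row[i], dc = pc - col[i];
    double f = dr * fr_dr + dc * fr_dc, r = dr * rr_dr + dc * rr_dc;
    if (f < -1 || f > 9 || std::fabs(r) > 5) continue;
    double d = std::fabs(f) + std::fabs(r);
    if (d < bestd) { bestd = d; best_f = f; best_r = r; found = true; }
  }
  out[4] = found ? 1.0 : 0.0; out[5] = found ? best_f / 9.0 : 0.0;
  out[6] = found ? best_r / 5.0 : 0.0;
  for (int ch = 0; ch < 3; ++ch) {
    bestd = 1e18; found = false;
    for (int j = 0; j < row.size(); ++j) {
      if (j == i || IntegerVector::is_na(row[j])) continue;
      bool want = (ch == 0) ? (ready[j] && slot[j] == 1)
                : (ch == 1) ? (ready[j] && slot[j] == 2)
                            : (!ready[j]);
      if (!want) continue;
      double dr = row[j] - row[i], dc = col[j] - col[i];
      double f = dr * fr_dr + dc * fr_dc, r = dr * rr_dr + dc * rr_dc;
      if (f < -1 || f > 9 || std::fabs(r) > 5) continue;
      double d = std::fabs(f) + std::fabs(r);
      if (d < bestd) { bestd = d; best_f = f; best_r = r; found = true; }
    }
    out[7 + 3 * ch] = found ? 1.0 : 0.0;
    out[8 + 3 * ch] = found ? best_f / 9.0 : 0.0;
    out[9 + 3 * ch] = found ? best_r / 5.0 : 0.0;
  }
  // beam-alignment indicators: a ready agent of the given slot is straight
  // ahead within beam range (what the beam would reach, walls aside)
  for (int ch = 0; ch < 2; ++ch) {
    double flag = 0.0;
    for (int j = 0; j < row.size(); ++j) {
      if (j == i || IntegerVector::is_na(row[j])) continue;
      if (!(ready[j] && slot[j] == ch + 1)) continue;
      double dr = row[j] - row[i], dc = col[j] - col[i];
      double f = dr * fr_dr + dc * fr_dc, r = dr * rr_dr + dc * rr_dc;
      if (r == 0 && f >= 1 && f <= beam_range) { flag = 1.0; break; }
    }
    out[16 + ch] = flag;
  }
}

// feedforward feature policy: two ReLU trunk layers, ReLU heads, linear
// outputs; x = c(features, inventory)
struct FFParams {
  NumericMatrix t1W, t2W, p1W, p2W, v1W, v2W;
  NumericVector t1b, t2b, p1b, p2b, v1b, v2b;
  bool valid = false;
};

// flat copies for tight inner loops (column-major, as R stores them)
struct FFFlat {
  int d = 0, h1 = 0, h2 = 0, hp = 0, hv = 0, na = 0;
  std::vector<double> t1W, t1b, t2W, t2b, p1W, p1b, p2W, p2b, v1W, v1b, v2W;
  double v2b = 0.0;
  void load(const List &params) {
    NumericMatrix m;
    NumericVector v;
    m = as<NumericMatrix>(params["trunk1_W"]); d = m.nrow(); h1 = m.ncol();
    t1W.assign(m.begin(), m.end());
    v = as<NumericVector>(params["trunk1_b"]); t1b.assign(v.begin(), v.end());
    m = as<NumericMatrix>(params["trunk2_W"]); h2 = m.ncol();
    t2W.assign(m.begin(), m.end());
    v = as<NumericVector>(params["trunk2_b"]); t2b.assign(v.begin(), v.end());
    m = as<NumericMatrix>(params["pol1_W"]); hp = m.ncol();
    p1W.assign(m.begin(), m.end());
    v = as<NumericVector>(params["pol1_b"]); p1b.assign(v.begin(), v.end());
    m = as<NumericMatrix>(params["pol2_W"]); na = m.ncol();
    p2W.assign(m.begin(), m.end());
    v = as<NumericVector>(params["pol2_b"]); p2b.assign(v.begin(), v.end());
    m = as<NumericMatrix>(params["val1_W"]); hv = m.ncol();
    v1W.assign(m.begin(), m.end());
    v = as<NumericVector>(params["val1_b"]); v1b.assign(v.begin(), v.end());
    m = as<NumericMatrix>(params["val2_W"]); v2W.assign(m.begin(), m.end());
    v2b = as<NumericVector>(params["val2_b"])[0];
  }
  void forward(const double *x, double *logits, double *value,
               std::vector<double> &a1, std::vector<double> &a2,
               std::vector<double> &ah) const {
    a1.resize(h1); a2.resize(h2); ah.resize(std::max(hp, hv));
    for (int j = 0; j < h1; ++j) {
      const double *w = &t1W[(size_t)j * d];
      double sum = t1b[j];
      for (int k = 0; k < d; ++k) sum += x[k] * w[k];
      a1[j] = sum > 0 ? sum : 0;
    }
    for (int j = 0; j < h2; ++j) {
      const double *w = &t2W[(size_t)j * h1];
      double sum = t2b[j];
      for (int k = 0; k < h1; ++k) sum += a1[k] * w[k];
      a2[j] = sum > 0 ? sum : 0;
    }
    for (int j = 0; j < hp; ++j) {
      const double *w = &p1W[(size_t)j * h2];
      double sum = p1b[j];
      for (int k = 0; k < h2; ++k) sum += a2[k] * w[k];
      ah[j] = sum > 0 ? sum : 0;
    }
    for (int j = 0; j < na; ++j) {
      const double *w = &p2W[(size_t)j * hp];
      double sum = p2b[j];
      for (int k = 0; k < hp; ++k) sum += ah[k] * w[k];
      logits[j] = sum;
    }
    for (int j = 0; j < hv; ++j) {
      const double *w = &v1W[(size_t)j * h2];
      double sum = v1b[j];
      for (int k = 0; k < h2; ++k) sum += a2[k] * w[k];
      ah[j] = sum > 0 ? sum : 0;
    }
    double vv = v2b;
    for (int k = 0; k < hv; ++k) vv += ah[k] * v2W[k];
    *value = vv;
  }
};

static void ff_forward_inner(const FFParams &p, const double *x, int d,
                             double *logits, double *value) {
  int h1 = p.t1W.ncol(), h2 = p.t2W.ncol(), hp = p.p1W.ncol(), hv = p.v1W.ncol();
  int na = p.p2W.ncol();
  std::vector<double> a1(h1), a2(h2), ah(std::max(hp, hv));
  for (int j = 0; j < h1; ++j) {
    double s = p.t1b[j];
    for (int k = 0; k < d; ++k) s += x[k] * p.t1W(k, j);
    a1[j] = s > 0 ? s : 0;
  }
  for (int j = 0; j < h2; ++j) {
    double s = p.t2b[j];
    for (int k = 0; k < h1; ++k) s += a1[k] * p.t2W(k, j);
    a2[j] = s > 0 ? s : 0;
  }
  for (int j = 0; j < hp; ++j) {
    double s = p.p1b[j];
    for (int k = 0; k < h2; ++k) s += a2[k] * p.p1W(k, j);
    ah[j] = s > 0 ? s : 0;
  }
  for (int j = 0; j < na; ++j) {
    double s = p.p2b[j];
    for (int k = 0; k < hp; ++k) s += ah[k] * p.p2W(k, j);
    logits[j] = s;
  }
  for (int j = 0; j < hv; ++j) {
    double s = p.v1b[j];
    for (int k = 0; k < h2; ++k) s += a2[k] * p.v1W(k, j);
    ah[j] = s > 0 ? s : 0;
  }
  double v = p.v2b[0];
  for (int k = 0; k < hv; ++k) v += ah[k] * p.v2W(k, 0);
  *value = v;
}

// ---------------------------------------------------------------------------
// exported wrappers

// [[Rcpp::export]]
List cpp_step_phase_a(IntegerVector order, IntegerVector actions,
                      LogicalMatrix wall, IntegerMatrix occ_in,
                      IntegerMatrix resources_in,
                      IntegerVector row_in, IntegerVector col_in,
                      IntegerVector orient_in, NumericMatrix inv_in,
                      LogicalVector ready_in, IntegerVector freeze_in,
                      IntegerVector removal_in, LogicalVector pending_in,
                      LogicalVector scripted, IntegerVector slot,
                      IntegerMatrix spawn_points, IntegerVector spawn_slot,
                      int removal_steps) {
  RNGScope rngScope;
  IntegerMatrix occ = clone(occ_in), resources = clone(resources_in);
  IntegerVector row = clone(row_in), col = clone(col_in), orient = clone(orient_in);
  NumericMatrix inv = clone(inv_in);
  LogicalVector ready = clone(ready_in);
  IntegerVector freeze = clone(freeze_in), removal = clone(removal_in);
  LogicalVector pending = clone(pending_in);
  phase_a_inner(order, actions, wall, occ, resources, row, col, orient, inv,
                ready, freeze, removal, pending, scripted, slot,
                spawn_points, spawn_slot, removal_steps);
  return List::create(_["occ"] = occ, _["resources"] = resources,
                      _["row"] = row, _["col"] = col, _["orient"] = orient,
                      _["inv"] = inv, _["ready"] = ready,
                      _["freeze"] = freeze, _["removal"] = removal,
                      _["removal_pending"] = pending);
}

// [[Rcpp::export]]
List cpp_resolve_interaction(LogicalMatrix wall, IntegerMatrix occ,
                             IntegerVector row, IntegerVector col,
                             IntegerVector orient, NumericMatrix inv,
                             LogicalVector ready, IntegerVector freeze_in,
                             LogicalVector pending_in, IntegerVector pfreeze,
                             int beam_range, double reward_scale,
                             bool require_initiator_ready, int i) {
  IntegerVector freeze = clone(freeze_in);
  LogicalVector pending = clone(pending_in);
  double rew = 0.0;
  int j = resolve_inner(wall, occ, row, col, orient, inv, ready, freeze,
                        pending, pfreeze, beam_range, reward_scale,
                        require_initiator_ready, i - 1, &rew);
  return List::create(_["target"] = j + 1, _["reward"] = rew,
                      _["freeze"] = freeze, _["removal_pending"] = pending);
}

// [[Rcpp::export]]
NumericMatrix cpp_features_all(IntegerVector who,
                               IntegerMatrix res_points, IntegerMatrix resources,
                               IntegerVector row, IntegerVector col,
                               IntegerVector orient, NumericMatrix inv,
                               LogicalVector ready, IntegerVector slot,
                               int beam_range) {
  int n = who.size();
  NumericMatrix out(n, 18);
  std::vector<double> buf(18);
  for (int w = 0; w < n; ++w) {
    int i = who[w] - 1;
    if (IntegerVector::is_na(row[i])) {
      for (int j = 0; j < 18; ++j) out(w, j) = NA_REAL;
      continue;
    }
    features_inner(i, res_points, resources, row, col, orient, inv, ready,
                   slot, beam_range, buf.data());
    for (int j = 0; j < 18; ++j) out(w, j) = buf[j];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_ff_forward(NumericMatrix t1W, NumericVector t1b,
                    NumericMatrix t2W, NumericVector t2b,
                    NumericMatrix p1W, NumericVector p1b,
                    NumericMatrix p2W, NumericVector p2b,
                    NumericMatrix v1W, NumericVector v1b,
                    NumericMatrix v2W, NumericVector v2b,
                    NumericVector x) {
  FFParams p;
  p.t1W = t1W; p.t1b = t1b; p.t2W = t2W; p.t2b = t2b;
  p.p1W = p1W; p.p1b = p1b; p.p2W = p2W; p.p2b = p2b;
  p.v1W = v1W; p.v1b = v1b; p.v2W = v2W; p.v2b = v2b;
  int na = p2W.ncol();
  NumericVector logits(na);
  double value = 0.0;
  ff_forward_inner(p, x.begin(), x.size(), logits.begin(), &value);
  return List::create(_["logits"] = logits, _["value"] = value);
}

// Full episode rollout for feedforward feature policies. Agents whose entry
// in `params` is NULL (or flagged scripted) submit NOOP. Trajectories are
// recorded for learning agents when `record`; the rollout stops early when
// `stop_agent` (1-based, 0 = never) initiates an interaction event.
// [[Rcpp::export]]
List cpp_rollout(int n_steps, List params, LogicalMatrix wall,
                 IntegerMatrix occ_in, IntegerMatrix resources_in,
                 IntegerMatrix res_points, IntegerMatrix spawn_points,
                 IntegerVector spawn_slot,
                 IntegerVector row_in, IntegerVector col_in,
                 IntegerVector orient_in, NumericMatrix inv_in,
                 LogicalVector ready_in, IntegerVector freeze_in,
                 IntegerVector removal_in, LogicalVector pending_in,
                 LogicalVector scripted, IntegerVector slot,
                 IntegerVector pfreeze, IntegerVector resource_colors,
                 int removal_steps, int beam_range, double restock_prob,
                 double reward_scale, bool require_initiator_ready,
                 bool record, int stop_agent) {
  RNGScope rngScope;
  IntegerMatrix occ = clone(occ_in), resources = clone(resources_in);
  IntegerVector row = clone(row_in), col = clone(col_in), orient = clone(orient_in);
  NumericMatrix inv = clone(inv_in);
  LogicalVector ready = clone(ready_in);
  IntegerVector freeze = clone(freeze_in), removal = clone(removal_in);
  LogicalVector pending = clone(pending_in);

  const int n = row.size();
  std::vector<FFFlat> pol(n);
  std::vector<bool> learner(n, false);
  for (int i = 0; i < n; ++i) {
    if (params[i] != R_NilValue && !scripted[i]) {
      pol[i].load(as<List>(params[i]));
      learner[i] = true;
    }
  }
  std::vector<double> wa1, wa2, wah;
  const int n_act = 8;

  // trajectory buffers
  std::vector<NumericMatrix> tobs, tinv;
  std::vector<IntegerVector> tact;
  std::vector<NumericVector> trew, tval;
  std::vector<int> tlen(n, 0);
  if (record) {
    for (int i = 0; i < n; ++i) {
      tobs.push_back(NumericMatrix(learner[i] ? n_steps : 0, 18));
      tinv.push_back(NumericMatrix(learner[i] ? n_steps : 0, 3));
      tact.push_back(IntegerVector(learner[i] ? n_steps : 0));
      trew.push_back(NumericVector(learner[i] ? n_steps : 0));
      tval.push_back(NumericVector(learner[i] ? n_steps : 0));
    }
  }

  // event buffers
  std::vector<int> ev_step, ev_init, ev_tgt;
  std::vector<double> ev_rew, ev_inv;
  NumericVector total_reward(n);

  IntegerVector order(n), actions(n);
  std::vector<int> rec_now(n);
  std::vector<double> x(21), logits(n_act), probs(n_act);
  int steps_done = 0, chosen = 0;

  for (int t = 0; t < n_steps && chosen == 0; ++t) {
    // randomized processing order (Fisher-Yates on R's RNG)
    for (int i = 0; i < n; ++i) order[i] = i + 1;
    for (int i = n - 1; i > 0; --i) {
      int k = unif_index(i + 1) - 1;
      int tmp = order[i]; order[i] = order[k]; order[k] = tmp;
    }
    // act
    for (int i = 0; i < n; ++i) {
      actions[i] = 1; rec_now[i] = -1;
      if (!learner[i] || IntegerVector::is_na(row[i]) || freeze[i] > 0) continue;
      features_inner(i, res_points, resources, row, col, orient, inv, ready,
                     slot, beam_range, x.data());
      for (int c3 = 0; c3 < 3; ++c3) x[18 + c3] = inv(c3, i);
      double value = 0.0;
      pol[i].forward(x.data(), logits.data(), &value, wa1, wa2, wah);
      double mx = logits[0];
      for (int a = 1; a < n_act; ++a) mx = std::max(mx, logits[a]);
      double tot = 0.0;
      for (int a = 0; a < n_act; ++a) { probs[a] = std::exp(logits[a] - mx); tot += probs[a]; }
      double u = unif_rand() * tot, acc = 0.0;
      int act = n_act;
      for (int a = 0; a < n_act; ++a) { acc += probs[a]; if (u <= acc) { act = a + 1; break; } }
      actions[i] = act;
      if (record) {
        int k = tlen[i];
        for (int j = 0; j < 18; ++j) tobs[i](k, j) = x[j];
        for (int c3 = 0; c3 < 3; ++c3) tinv[i](k, c3) = inv(c3, i);
        tact[i][k] = act;
        tval[i][k] = value;
        trew[i][k] = 0.0;
        rec_now[i] = k;
        tlen[i] = k + 1;
      }
    }
    // phase A
    phase_a_inner(order, actions, wall, occ, resources, row, col, orient, inv,
                  ready, freeze, removal, pending, scripted, slot,
                  spawn_points, spawn_slot, removal_steps);
    // phase B: beams in the same randomized order
    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi] - 1;
      if (actions[i] != 8 || scripted[i]) continue;
      double rew = 0.0;
      int j = resolve_inner(wall, occ, row, col, orient, inv, ready, freeze,
                            pending, pfreeze, beam_range, reward_scale,
                            require_initiator_ready, i, &rew);
      if (j < 0) continue;
      ev_step.push_back(t + 1);
      ev_init.push_back(i + 1);
      ev_tgt.push_back(j + 1);
      ev_rew.push_back(rew);
      for (int c3 = 0; c3 < 3; ++c3) ev_inv.push_back(inv(c3, i));
      for (int c3 = 0; c3 < 3; ++c3) ev_inv.push_back(inv(c3, j));
      total_reward[i] += rew; total_reward[j] += rew;
      if (record) {
        if (rec_now[i] >= 0) trew[i][rec_now[i]] += rew;
        if (rec_now[j] >= 0) trew[j][rec_now[j]] += rew;
      }
      if (stop_agent > 0 && i == stop_agent - 1) chosen = j + 1;
    }
    // restock
    for (int p = 0; p < res_points.nrow(); ++p) {
      int pr = res_points(p, 0), pc = res_points(p, 1);
      if (resources(pr - 1, pc - 1) == 0 && unif_rand() < restock_prob) {
        resources(pr - 1, pc - 1) = resource_colors[unif_index(resource_colors.size()) - 1];
      }
    }
    steps_done = t + 1;
  }

  List traj(n);
  if (record) {
    for (int i = 0; i < n; ++i) {
      if (!learner[i] || tlen[i] == 0) { traj[i] = R_NilValue; continue; }
      int k = tlen[i];
      traj[i] = List::create(
        _["obs"] = tobs[i](Range(0, k - 1), _),
        _["inv"] = tinv[i](Range(0, k - 1), _),
        _["actions"] = tact[i][Range(0, k - 1)],
        _["rewards"] = trew[i][Range(0, k - 1)],
        _["values"] = tval[i][Range(0, k - 1)]);
    }
  }
  int ne = (int)ev_step.size();
  NumericMatrix ev_inv_i(ne, 3), ev_inv_t(ne, 3);
  for (int e = 0; e < ne; ++e) {
    for (int c3 = 0; c3 < 3; ++c3) {
      ev_inv_i(e, c3) = ev_inv[6 * e + c3];
      ev_inv_t(e, c3) = ev_inv[6 * e + 3 + c3];
    }
  }
  return List::create(
    _["steps"] = steps_done,
    _["chosen"] = chosen,
    _["trajectories"] = traj,
    _["total_reward"] = total_reward,
    _["events"] = List::create(
      _["step_index"] = wrap(ev_step), _["initiator"] = wrap(ev_init),
      _["target"] = wrap(ev_tgt), _["reward"] = wrap(ev_rew),
      _["inv_initiator"] = ev_inv_i, _["inv_target"] = ev_inv_t),
    _["final"] = List::create(
      _["occ"] = occ, _["resources"] = resources, _["row"] = row,
      _["col"] = col, _["orient"] = orient, _["inv"] = inv,
      _["ready"] = ready, _["freeze"] = freeze, _["removal"] = removal,
      _["removal_pending"] = pending));
}

// Loss and gradients for one feedforward feature-policy segment (plain
// advantage actor-critic, mean over steps) — the compiled twin of the R
// matrix-algebra path, used for on-policy updates.
// [[Rcpp::export]]
List cpp_ff_segment_grads(List params, NumericMatrix X, IntegerVector actions,
                          NumericVector rewards, double bootstrap,
                          double gamma, double ent_w, double vw) {
  FFFlat p; p.load(params);
  const int n = X.nrow(), d = X.ncol();
  const int h1 = p.h1, h2 = p.h2, hp = p.hp, hv = p.hv, na = p.na;
  std::vector<double> A1((size_t)n * h1), A2((size_t)n * h2),
      AP((size_t)n * hp), AV((size_t)n * hv), LOG((size_t)n * na),
      values(n), xrow(d);
  std::vector<double> wa1, wa2, wah;
  std::vector<double> lg(na);
  for (int t = 0; t < n; ++t) {
    for (int k = 0; k < d; ++k) xrow[k] = X(t, k);
    // forward with stored activations
    for (int j = 0; j < h1; ++j) {
      const double *w = &p.t1W[(size_t)j * d];
      double sum = p.t1b[j];
      for (int k = 0; k < d; ++k) sum += xrow[k] * w[k];
      A1[(size_t)j * n + t] = sum > 0 ? sum : 0;
    }
    for (int j = 0; j < h2; ++j) {
      const double *w = &p.t2W[(size_t)j * h1];
      double sum = p.t2b[j];
      for (int k = 0; k < h1; ++k) sum += A1[(size_t)k * n + t] * w[k];
      A2[(size_t)j * n + t] = sum > 0 ? sum : 0;
    }
    for (int j = 0; j < hp; ++j) {
      const double *w = &p.p1W[(size_t)j * h2];
      double sum = p.p1b[j];
      for (int k = 0; k < h2; ++k) sum += A2[(size_t)k * n + t] * w[k];
      AP[(size_t)j * n + t] = sum > 0 ? sum : 0;
    }
    for (int j = 0; j < na; ++j) {
      const double *w = &p.p2W[(size_t)j * hp];
      double sum = p.p2b[j];
      for (int k = 0; k < hp; ++k) sum += AP[(size_t)k * n + t] * w[k];
      LOG[(size_t)j * n + t] = sum;
    }
    for (int j = 0; j < hv; ++j) {
      const double *w = &p.v1W[(size_t)j * h2];
      double sum = p.v1b[j];
      for (int k = 0; k < h2; ++k) sum += A2[(size_t)k * n + t] * w[k];
      AV[(size_t)j * n + t] = sum > 0 ? sum : 0;
    }
    double vv = p.v2b;
    for (int k = 0; k < hv; ++k) vv += AV[(size_t)k * n + t] * p.v2W[k];
    values[t] = vv;
  }
  // returns and advantages
  std::vector<double> targets(n), adv(n);
  double acc = bootstrap;
  for (int t = n - 1; t >= 0; --t) { acc = rewards[t] + gamma * acc; targets[t] = acc; }
  for (int t = 0; t < n; ++t) adv[t] = targets[t] - values[t];
  // softmax, entropy, loss
  double pg_loss = 0, vf_loss = 0, ent_mean = 0, ret_mean = 0;
  std::vector<double> dlog((size_t)n * na), dval(n);
  std::vector<double> pr(na);
  for (int t = 0; t < n; ++t) {
    double mx = LOG[t];
    for (int j = 1; j < na; ++j) mx = std::max(mx, LOG[(size_t)j * n + t]);
    double tot = 0;
    for (int j = 0; j < na; ++j) { pr[j] = std::exp(LOG[(size_t)j * n + t] - mx); tot += pr[j]; }
    double ent = 0;
    for (int j = 0; j < na; ++j) {
      pr[j] /= tot;
      double lpj = std::log(std::max(pr[j], 1e-12));
      ent -= pr[j] * lpj;
    }
    int a = actions[t] - 1;
    double lpa = std::log(std::max(pr[a], 1e-12));
    pg_loss += -lpa * adv[t];
    vf_loss += 0.5 * (values[t] - targets[t]) * (values[t] - targets[t]);
    ent_mean += ent;
    ret_mean += targets[t];
    for (int j = 0; j < na; ++j) {
      double lpj = std::log(std::max(pr[j], 1e-12));
      double oh = (j == a) ? 1.0 : 0.0;
      dlog[(size_t)j * n + t] = (adv[t] * (pr[j] - oh) +
                                 ent_w * pr[j] * (lpj + ent)) / n;
    }
    dval[t] = vw * (values[t] - targets[t]) / n;
  }
  pg_loss /= n; vf_loss /= n; ent_mean /= n; ret_mean /= n;
  double total = pg_loss + vw * vf_loss - ent_w * ent_mean;

  // backward (accumulate over steps)
  NumericMatrix g_p2W(hp, na), g_p1W(h2, hp), g_v1W(h2, hv), g_v2W(hv, 1),
      g_t2W(h1, h2), g_t1W(d, h1);
  NumericVector g_p2b(na), g_p1b(hp), g_v1b(hv), g_t2b(h2), g_t1b(h1);
  double g_v2b = 0.0;
  std::vector<double> dAP(hp), dA2(h2), dA1(h1), dAV(hv);
  for (int t = 0; t < n; ++t) {
    // policy head
    for (int j = 0; j < na; ++j) g_p2b[j] += dlog[(size_t)j * n + t];
    for (int k = 0; k < hp; ++k) {
      double apk = AP[(size_t)k * n + t];
      double s = 0;
      for (int j = 0; j < na; ++j) {
        double dl = dlog[(size_t)j * n + t];
        g_p2W(k, j) += apk * dl;
        s += dl * p.p2W[(size_t)j * hp + k];
      }
      dAP[k] = (apk > 0) ? s : 0;   // relu mask via activation
    }
    for (int j = 0; j < hp; ++j) g_p1b[j] += dAP[j];
    for (int k = 0; k < h2; ++k) {
      double a2k = A2[(size_t)k * n + t];
      double s = 0;
      for (int j = 0; j < hp; ++j) {
        g_p1W(k, j) += a2k * dAP[j];
        s += dAP[j] * p.p1W[(size_t)j * h2 + k];
      }
      dA2[k] = s;
    }
    // value head
    double dv = dval[t];
    g_v2b += dv;
    for (int k = 0; k < hv; ++k) {
      double avk = AV[(size_t)k * n + t];
      g_v2W(k, 0) += avk * dv;
      dAV[k] = (avk > 0) ? dv * p.v2W[k] : 0;
    }
    for (int j = 0; j < hv; ++j) g_v1b[j] += dAV[j];
    for (int k = 0; k < h2; ++k) {
      double a2k = A2[(size_t)k * n + t];
      double s = 0;
      for (int j = 0; j < hv; ++j) {
        g_v1W(k, j) += a2k * dAV[j];
        s += dAV[j] * p.v1W[(size_t)j * h2 + k];
      }
      dA2[k] += s;
      if (A2[(size_t)k * n + t] <= 0) dA2[k] = 0;
    }
    // trunk
    for (int j = 0; j < h2; ++j) g_t2b[j] += dA2[j];
    for (int k = 0; k < h1; ++k) {
      double a1k = A1[(size_t)k * n + t];
      double s = 0;
      for (int j = 0; j < h2; ++j) {
        g_t2W(k, j) += a1k * dA2[j];
        s += dA2[j] * p.t2W[(size_t)j * h1 + k];
      }
      dA1[k] = (a1k > 0) ? s : 0;
    }
    for (int j = 0; j < h1; ++j) g_t1b[j] += dA1[j];
    for (int k = 0; k < d; ++k) {
      double xk = X(t, k);
      for (int j = 0; j < h1; ++j) g_t1W(k, j) += xk * dA1[j];
    }
  }
  List grads = List::create(
      _["trunk1_W"] = g_t1W, _["trunk1_b"] = g_t1b,
      _["trunk2_W"] = g_t2W, _["trunk2_b"] = g_t2b,
      _["pol1_W"] = g_p1W, _["pol1_b"] = g_p1b,
      _["pol2_W"] = g_p2W, _["pol2_b"] = g_p2b,
      _["val1_W"] = g_v1W, _["val1_b"] = g_v1b,
      _["val2_W"] = g_v2W, _["val2_b"] = g_v2b);
  return List::create(_["loss"] = total, _["pg_loss"] = pg_loss,
                      _["vf_loss"] = vf_loss, _["entropy"] = ent_mean,
                      _["mean_return"] = ret_mean, _["grads"] = grads);
}
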