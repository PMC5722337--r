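#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// One asymmetric encounter per tick, focal-agent-only updates, starvation
// replacement via within-caste binary tournament.  Uses R's global RNG
// (unif_rand) with a fixed draw order -- pair draw, engagement, battle
// tie-break, tournament -- so the pure-R reference engine consumes an
// identical stream and produces bit-identical trajectories.
//
// Agents must be ordered by caste in contiguous blocks (as produced by
// init_population()); caste membership never changes, so tournament
// candidate pools are fixed index ranges.

// [[Rcpp::export]]
List run_core(IntegerVector caste, IntegerVector signal,
              NumericVector resources, NumericVector endowment,
              NumericVector birth_tick, NumericMatrix params,
              int ticks, int snapshot_interval, double threshold_fraction,
              int flee_prob_form, int flee_cost_base, int defeat_loss_basis,
              bool record_events) {
  const int n = caste.size();
  if (n < 2) stop("population must contain at least 2 agents");

  // params: 3 rows (caste) x 4 cols (endow, met, honest, dishonest), scaled
  std::vector<double> met(3), hon(3), dis(3);
  for (int c = 0; c < 3; ++c) {
    met[c] = params(c, 1);
    hon[c] = params(c, 2);
    dis[c] = params(c, 3);
  }

  // contiguous caste blocks
  int caste_off[3], caste_n[3] = {0, 0, 0};
  for (int i = 0; i < n; ++i) caste_n[caste[i]]++;
  caste_off[0] = 0;
  caste_off[1] = caste_n[0];
  caste_off[2] = caste_n[0] + caste_n[1];
  for (int i = 1; i < n; ++i) {
    if (caste[i] < caste[i - 1]) stop("agents must be ordered by caste");
  }

  std::vector<int> sig(signal.begin(), signal.end());
  std::vector<double> res(resources.begin(), resources.end());
  std::vector<double> born(birth_tick.begin(), birth_tick.end());

  // snapshot bookkeeping: 9 (caste, signal) cells per snapshot
  int n_snap = 2 + (ticks > 0 ? (ticks - 1) / snapshot_interval : 0);
  if (ticks == 0) n_snap = 1;
  IntegerVector snap_tick(n_snap);
  IntegerMatrix snap_count(n_snap, 9);
  NumericMatrix snap_sum(n_snap, 9);
  int snap_i = 0;
  auto take_snapshot = [&](int tick) {
    snap_tick[snap_i] = tick;
    for (int i = 0; i < n; ++i) {
      int cell = caste[i] * 3 + sig[i];
      snap_count(snap_i, cell)++;
      snap_sum(snap_i, cell) += res[i];
    }
    snap_i++;
  };

  std::vector<int> d_tick, d_caste, d_signal;
  std::vector<double> d_age;

  std::vector<int> e_tick, e_party, e_counter, e_action, e_won;
  std::vector<double> e_delta;

  RNGScope scope;
  take_snapshot(0);

  for (int tick = 1; tick <= ticks; ++tick) {
    // 1. pair draw: focal agent, then counterparty from the remaining n-1
    int i = (int)std::floor(unif_rand() * n);
    int j = (int)std::floor(unif_rand() * (n - 1));
    if (j >= i) j++;

    // 2. engagement: peaceable signal -> fight; otherwise either
    //    P(fight) = res/endow (linear form, 0) or, in the signal-gated
    //    form (1), deterministic flight from a strictly higher signal with
    //    the resource-ratio rule reserved for equal signals
    bool peaceable = sig[j] < caste[i];
    bool fight;
    if (peaceable) {
      fight = true;
    } else if (flee_prob_form == 1 && sig[j] > caste[i]) {
      fight = false;
    } else {
      double r = res[i] / endowment[i];
      if (r > 1.0) r = 1.0;
      if (r < 0.0) r = 0.0;
      if (flee_prob_form == 2) {
        // logistic in the resource ratio, midpoint 0.5, steepness 10
        double p = 1.0 / (1.0 + std::exp(-10.0 * (r - 0.5)));
        fight = unif_rand() < p;
      } else if (flee_prob_form == 3) {
        // hard threshold at half the endowment
        fight = r >= 0.5;
      } else {
        fight = unif_rand() < r;
      }
    }

    bool won = false;
    double delta;
    if (fight) {
      // 3. battle: higher true caste wins; within caste the richer wins;
      //    exact tie -> fair coin
      if (caste[i] != caste[j]) won = caste[i] > caste[j];
      else if (res[i] != res[j]) won = res[i] > res[j];
      else won = unif_rand() < 0.5;

      if (won) {
        bool loser_honest = sig[j] == caste[j];
        double f = loser_honest ? hon[caste[i]] : dis[caste[i]];
        delta = f * res[j];
      } else {
        // a defeated focal agent loses a fraction of its own resources;
        // the governing appropriation row is either the winner's caste
        // (0) or the loser's own caste (1)
        bool loser_honest = sig[i] == caste[i];
        int row = (defeat_loss_basis == 1) ? caste[i] : caste[j];
        double f = loser_honest ? hon[row] : dis[row];
        delta = -f * res[i];
      }
      res[i] += delta;
    } else {
      // cost base: 0 = fraction of endowment, 1 = fraction of current
      // resources, 2 = met_cost_factor taken as an absolute amount
      double cost = (flee_cost_base == 2) ? met[caste[i]]
                    : met[caste[i]] * ((flee_cost_base == 1) ? res[i]
                                                             : endowment[i]);
      double nr = res[i] - cost;
      if (nr < 0.0) nr = 0.0;
      delta = nr - res[i];
      res[i] = nr;
    }

    if (record_events) {
      e_tick.push_back(tick);
      e_party.push_back(i + 1);
      e_counter.push_back(j + 1);
      e_action.push_back(fight ? 1 : 0);
      e_won.push_back(fight ? (won ? 1 : 0) : NA_INTEGER);
      e_delta.push_back(delta);
    }

    // 4. starvation check on the focal agent only
    if (res[i] < threshold_fraction * endowment[i]) {
      int c = caste[i];
      int off = caste_off[c], m = caste_n[c];
      if (m < 3) stop("tournament needs at least 2 living candidates");
      d_tick.push_back(tick);
      d_caste.push_back(c);
      d_signal.push_back(sig[i]);
      d_age.push_back(tick - born[i]);

      // binary tournament over the caste pool excluding the dying agent:
      // draw two distinct pool positions, richer candidate's signal copied
      int pos_i = i - off;
      int a = (int)std::floor(unif_rand() * (m - 1));
      int b = (int)std::floor(unif_rand() * (m - 2));
      if (b >= a) b++;
      int abs_a = off + a + (a >= pos_i ? 1 : 0);
      int abs_b = off + b + (b >= pos_i ? 1 : 0);
      int winner;
      if (res[abs_a] > res[abs_b]) winner = abs_a;
      else if (res[abs_b] > res[abs_a]) winner = abs_b;
      else winner = (unif_rand() < 0.5) ? abs_a : abs_b;

      sig[i] = sig[winner];
      res[i] = endowment[i];
      born[i] = tick;
    }

    if (tick % snapshot_interval == 0 || tick == ticks) {
      if (tick % snapshot_interval == 0 && tick != ticks) take_snapshot(tick);
      else if (tick == ticks) take_snapshot(tick);
    }
  }

  List events = R_NilValue;
  if (record_events) {
    events = List::create(
      _["tick"] = IntegerVector(e_tick.begin(), e_tick.end()),
      _["party"] = IntegerVector(e_party.begin(), e_party.end()),
      _["counterparty"] = IntegerVector(e_counter.begin(), e_counter.end()),
      _["action"] = IntegerVector(e_action.begin(), e_action.end()),
      _["party_won"] = IntegerVector(e_won.begin(), e_won.end()),
      _["delta"] = NumericVector(e_delta.begin(), e_delta.end()));
  }

  return List::create(
    _["snap_tick"] = snap_tick[Range(0, snap_i - 1)],
    _["snap_count"] = snap_count(Range(0, snap_i - 1), _),
    _["snap_sum"] = snap_sum(Range(0, snap_i - 1), _),
    _["death_tick"] = IntegerVector(d_tick.begin(), d_tick.end()),
    _["death_caste"] = IntegerVector(d_caste.begin(), d_caste.end()),
    _["death_signal"] = IntegerVector(d_signal.begin(), d_signal.end()),
    _["death_age"] = NumericVector(d_age.begin(), d_age.end()),
    _["final_signal"] = IntegerVector(sig.begin(), sig.end()),
    _["final_resources"] = NumericVector(res.begin(), res.end()),
    _["final_birth_tick"] = NumericVector(born.begin(), born.end()),
    _["events"] = events);
}
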