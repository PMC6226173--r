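#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Lattice engine. Colonies live in a structure-of-arrays store; metabolites are
// a continuous per-element field consumed in whole units. Every stochastic draw
// comes from R's RNG, so R-level set.seed() fixes entire trajectories.

static const double EPS = 1e-9;

struct Params {
  int nE, nG, nM;
  double displacement;
  bool advect_mets;
  std::vector<double> met_inflow;      // per metabolite
  std::vector<double> bact_inflow;     // per genus, colonies/step (may be
                                       // fractional; emitted via accumulator)
  double gamma_max, n_mid, p_unstick, p_embed;
  double energy_max, hungry, decay, gain, repro_min;
  std::vector<int> doubling;           // per genus, timesteps
  int max_per_element;
  std::vector<int> priority;           // metabolite indices, 0-based, consumption order
  std::vector<unsigned char> consumes; // nG x nM row-major
  std::vector<double> produces;        // nG x nM row-major, units per unit consumed
  bool dose_replace;
};

struct World {
  std::vector<int>    genus;   // 0-based
  std::vector<double> energy;
  std::vector<double> x;       // [0, nE)
  std::vector<int>    adh;     // 0 FREE, 1 MUCUS, 2 SEED
  std::vector<double> met;     // nE x nM column-major: met[e + m*nE]
  std::vector<double> binflow_acc;   // per-genus fractional inflow accumulator
  long long t;
  size_t size() const { return genus.size(); }
};

struct StepRep {
  int births = 0, deaths = 0, washouts = 0, inflow = 0;
  int stuck = 0, unstuck = 0, embed = 0, consumed = 0;
  double produced = 0.0, met_in = 0.0, met_washed = 0.0;
};

struct Workspace {
  std::vector<int> cnt, start, pos, order, ate, cand;
};

static Params as_params(const List& q) {
  Params p;
  p.nE = as<int>(q["n_elements"]);
  p.nG = as<int>(q["n_genera"]);
  p.nM = as<int>(q["n_mets"]);
  p.displacement = as<double>(q["displacement"]);
  p.advect_mets = as<bool>(q["advect_mets"]);
  p.met_inflow = as< std::vector<double> >(q["met_inflow"]);
  p.bact_inflow = as< std::vector<double> >(q["bact_inflow"]);
  p.gamma_max = as<double>(q["gamma_max"]);
  p.n_mid = as<double>(q["n_mid"]);
  p.p_unstick = as<double>(q["p_unstick"]);
  p.p_embed = as<double>(q["p_embed"]);
  p.energy_max = as<double>(q["energy_max"]);
  p.hungry = as<double>(q["hungry"]);
  p.decay = as<double>(q["decay"]);
  p.gain = as<double>(q["gain"]);
  p.repro_min = as<double>(q["repro_min"]);
  p.doubling = as< std::vector<int> >(q["doubling"]);
  p.max_per_element = as<int>(q["max_per_element"]);
  p.priority = as< std::vector<int> >(q["priority"]);
  IntegerMatrix cons = q["consumes"];
  NumericMatrix prod = q["produces"];
  p.consumes.assign((size_t)p.nG * p.nM, 0);
  p.produces.assign((size_t)p.nG * p.nM, 0.0);
  for (int g = 0; g < p.nG; ++g)
    for (int m = 0; m < p.nM; ++m) {
      p.consumes[(size_t)g * p.nM + m] = cons(g, m) != 0;
      p.produces[(size_t)g * p.nM + m] = prod(g, m);
    }
  p.dose_replace = as<bool>(q["dose_replace"]);
  return p;
}

static World as_world(const List& s, const Params& p) {
  World w;
  IntegerVector genus = s["genus"];
  NumericVector energy = s["energy"];
  NumericVector x = s["x"];
  IntegerVector adh = s["adhesion"];
  NumericMatrix met = s["met"];
  size_t n = genus.size();
  w.genus.resize(n); w.energy.resize(n); w.x.resize(n); w.adh.resize(n);
  for (size_t i = 0; i < n; ++i) {
    w.genus[i] = genus[i] - 1;  // R is 1-based
    w.energy[i] = energy[i];
    w.x[i] = x[i];
    w.adh[i] = adh[i];
  }
  w.met.assign(met.begin(), met.end());
  w.binflow_acc = as< std::vector<double> >(s["binflow_acc"]);
  if ((int) w.binflow_acc.size() != p.nG)
    w.binflow_acc.assign(p.nG, 0.0);
  w.t = (long long) as<double>(s["t"]);
  return w;
}

static List world_to_list(const World& w, const Params& p) {
  size_t n = w.size();
  IntegerVector genus(n), adh(n);
  NumericVector energy(n), x(n);
  for (size_t i = 0; i < n; ++i) {
    genus[i] = w.genus[i] + 1;
    energy[i] = w.energy[i];
    x[i] = w.x[i];
    adh[i] = w.adh[i];
  }
  NumericMatrix met(p.nE, p.nM);
  std::copy(w.met.begin(), w.met.end(), met.begin());
  return List::create(_["genus"] = genus, _["energy"] = energy, _["x"] = x,
                      _["adhesion"] = adh, _["met"] = met,
                      _["binflow_acc"] = wrap(w.binflow_acc),
                      _["t"] = (double) w.t);
}

static NumericVector rep_to_vector(const StepRep& r, const World& w) {
  double met_total = 0.0;
  for (double v : w.met) met_total += v;
  NumericVector out = NumericVector::create(
    _["t"] = (double) w.t,
    _["births"] = r.births, _["deaths_starvation"] = r.deaths,
    _["washouts"] = r.washouts, _["inflow"] = r.inflow,
    _["stuck_events"] = r.stuck, _["unstuck_events"] = r.unstuck,
    _["embed_events"] = r.embed, _["consumed"] = r.consumed,
    _["produced"] = r.produced, _["met_in"] = r.met_in,
    _["met_washed"] = r.met_washed,
    _["population"] = (double) w.size(), _["met_total"] = met_total);
  return out;
}

static void count_elements(const World& w, const Params& p, std::vector<int>& cnt) {
  cnt.assign(p.nE, 0);
  for (size_t i = 0; i < w.size(); ++i) cnt[(int) w.x[i]]++;
}

// ---- core operations --------------------------------------------------------

static void op_inject(World& w, const Params& p, const std::vector<int>& extra,
                      bool replace, StepRep& r) {
  for (int m = 0; m < p.nM; ++m) {
    double a = p.met_inflow[m];
    if (a > 0) { w.met[(size_t) m * p.nE] += a; r.met_in += a; }
  }
  for (int g = 0; g < p.nG; ++g) {
    int n;
    if (g < (int) extra.size() && extra[g] >= 0 && replace) {
      n = extra[g];            // dose overrides the inlet for this step
    } else {
      w.binflow_acc[g] += p.bact_inflow[g];
      n = (int) std::floor(w.binflow_acc[g] + EPS);
      w.binflow_acc[g] -= n;
      if (g < (int) extra.size() && extra[g] >= 0) n += extra[g];
    }
    for (int k = 0; k < n; ++k) {
      w.genus.push_back(g);
      w.energy.push_back(p.energy_max);
      w.x.push_back(unif_rand());   // element 0
      w.adh.push_back(0);
    }
    r.inflow += n;
  }
}

static void op_adhesion(World& w, const Params& p, Workspace& ws, StepRep& r) {
  count_elements(w, p, ws.cnt);
  size_t n = w.size();
  for (size_t i = 0; i < n; ++i) {
    int a = w.adh[i];
    if (a == 0) {
      int N = ws.cnt[(int) w.x[i]];
      double gam = p.gamma_max * p.n_mid / (p.n_mid + (double) N);
      if (unif_rand() < gam) { w.adh[i] = 1; r.stuck++; }
    } else if (a == 1) {
      if (unif_rand() < p.p_embed) { w.adh[i] = 2; r.embed++; }
      else if (unif_rand() < p.p_unstick) { w.adh[i] = 0; r.unstuck++; }
    }
  }
}

static void op_advect(World& w, const Params& p, StepRep& r) {
  double d = p.displacement;
  size_t n = w.size(), keep = 0;
  for (size_t i = 0; i < n; ++i) {
    double xi = w.x[i];
    if (w.adh[i] == 0) {
      xi += d;
      if (xi >= p.nE) { r.washouts++; continue; }
    }
    if (keep != i) {
      w.genus[keep] = w.genus[i];
      w.energy[keep] = w.energy[i];
      w.adh[keep] = w.adh[i];
    }
    w.x[keep] = xi;
    ++keep;
  }
  w.genus.resize(keep); w.energy.resize(keep); w.x.resize(keep); w.adh.resize(keep);
  if (p.advect_mets && d > 0) {
    double f = std::min(1.0, d);
    for (int m = 0; m < p.nM; ++m) {
      double* col = &w.met[(size_t) m * p.nE];
      double carry = 0.0;
      for (int e = 0; e < p.nE; ++e) {
        double out = f * col[e];
        col[e] += carry - out;
        if (col[e] < 0) col[e] = 0;
        carry = out;
      }
      r.met_washed += carry;
    }
  }
}

// Allocate meals on one element: metabolites visited in priority order, each
// hungry eligible colony gets at most one unit total; when demand exceeds the
// floor(units) available, winners are a uniform random subset.
static void allocate_on_element(World& w, const Params& p, int e,
                                const std::vector<int>& order, int b0, int b1,
                                std::vector<int>& ate, std::vector<int>& cand,
                                StepRep& r) {
  for (int pi = 0; pi < p.nM; ++pi) {
    int m = p.priority[pi];
    double& units = w.met[(size_t) m * p.nE + e];
    int U = (int) std::floor(units + EPS);
    if (U <= 0) continue;
    cand.clear();
    for (int k = b0; k < b1; ++k) {
      int i = order[k];
      if (ate[i] >= 0) continue;
      if (w.energy[i] >= p.hungry) continue;
      if (!p.consumes[(size_t) w.genus[i] * p.nM + m]) continue;
      cand.push_back(i);
    }
    int H = (int) cand.size();
    if (H == 0) continue;
    int take = std::min(H, U);
    if (take < H) {   // partial Fisher-Yates: uniform subset without replacement
      for (int k = 0; k < take; ++k) {
        int j = k + (int) (unif_rand() * (H - k));
        if (j >= H) j = H - 1;
        std::swap(cand[k], cand[j]);
      }
    }
    for (int k = 0; k < take; ++k) ate[cand[k]] = m;
    units -= take;
    if (units < 0) units = 0;
    r.consumed += take;
  }
}

static void build_buckets(const World& w, const Params& p, Workspace& ws) {
  count_elements(w, p, ws.cnt);
  ws.start.assign(p.nE + 1, 0);
  for (int e = 0; e < p.nE; ++e) ws.start[e + 1] = ws.start[e] + ws.cnt[e];
  ws.pos.assign(ws.start.begin(), ws.start.end() - 1);
  ws.order.resize(w.size());
  for (size_t i = 0; i < w.size(); ++i) {
    int e = (int) w.x[i];
    ws.order[ws.pos[e]++] = (int) i;
  }
}

static void op_consume_metabolize(World& w, const Params& p, Workspace& ws, StepRep& r) {
  build_buckets(w, p, ws);
  size_t n = w.size();
  ws.ate.assign(n, -1);
  for (int e = 0; e < p.nE; ++e) {
    if (ws.start[e] == ws.start[e + 1]) continue;
    allocate_on_element(w, p, e, ws.order, ws.start[e], ws.start[e + 1],
                        ws.ate, ws.cand, r);
  }
  for (size_t i = 0; i < n; ++i) {
    if (ws.ate[i] >= 0) {
      w.energy[i] = std::min(p.energy_max, w.energy[i] + p.gain);
      int g = w.genus[i], e = (int) w.x[i];
      const double* py = &p.produces[(size_t) g * p.nM];
      for (int m = 0; m < p.nM; ++m) {
        if (py[m] > 0) { w.met[(size_t) m * p.nE + e] += py[m]; r.produced += py[m]; }
      }
    }
    w.energy[i] -= p.decay;
  }
  size_t keep = 0;
  for (size_t i = 0; i < w.size(); ++i) {
    if (w.energy[i] <= EPS) { r.deaths++; continue; }
    if (keep != i) {
      w.genus[keep] = w.genus[i]; w.energy[keep] = w.energy[i];
      w.x[keep] = w.x[i]; w.adh[keep] = w.adh[i];
    }
    ++keep;
  }
  w.genus.resize(keep); w.energy.resize(keep); w.x.resize(keep); w.adh.resize(keep);
}

static void op_reproduce(World& w, const Params& p, Workspace& ws, StepRep& r) {
  long long ts = w.t + 1;   // index of the step being completed
  bool any = false;
  for (int g = 0; g < p.nG; ++g)
    if (p.doubling[g] >= 1 && ts % p.doubling[g] == 0) any = true;
  if (!any) return;
  count_elements(w, p, ws.cnt);
  size_t n0 = w.size();
  for (size_t i = 0; i < n0; ++i) {
    int g = w.genus[i];
    if (p.doubling[g] < 1 || ts % p.doubling[g] != 0) continue;
    if (!(w.energy[i] > p.repro_min)) continue;    // strict
    int e = (int) w.x[i];
    if (ws.cnt[e] >= p.max_per_element) continue;  // space constrained
    double half = w.energy[i] / 2.0;
    w.energy[i] = half;
    w.genus.push_back(g);
    w.energy.push_back(half);
    w.x.push_back(w.x[i]);
    w.adh.push_back(0);   // daughter released from the mucosal layer
    ws.cnt[e]++;
    r.births++;
  }
}

static StepRep do_step(World& w, const Params& p, Workspace& ws,
                       const std::vector<int>& extra) {
  StepRep r;
  op_inject(w, p, extra, p.dose_replace, r);
  op_adhesion(w, p, ws, r);
  op_advect(w, p, r);
  op_consume_metabolize(w, p, ws, r);
  op_reproduce(w, p, ws, r);
  w.t += 1;
  return r;
}

// ---- exported wrappers ------------------------------------------------------

// [[Rcpp::export]]
List cpp_step(List world, List params, IntegerVector extra) {
  Params p = as_params(params);
  World w = as_world(world, p);
  Workspace ws;
  std::vector<int> ex = as< std::vector<int> >(extra);
  StepRep r = do_step(w, p, ws, ex);
  return List::create(_["world"] = world_to_list(w, p),
                      _["report"] = rep_to_vector(r, w));
}

// [[Rcpp::export]]
List cpp_inject(List world, List params, IntegerVector extra, bool replace) {
  Params p = as_params(params);
  World w = as_world(world, p);
  StepRep r;
  std::vector<int> ex = as< std::vector<int> >(extra);
  op_inject(w, p, ex, replace, r);
  return List::create(_["world"] = world_to_list(w, p),
                      _["report"] = rep_to_vector(r, w));
}

// [[Rcpp::export]]
List cpp_update_adhesion(List world, List params) {
  Params p = as_params(params);
  World w = as_world(world, p);
  Workspace ws;
  StepRep r;
  op_adhesion(w, p, ws, r);
  return List::create(_["world"] = world_to_list(w, p),
                      _["report"] = rep_to_vector(r, w));
}

// [[Rcpp::export]]
List cpp_advect(List world, List params) {
  Params p = as_params(params);
  World w = as_world(world, p);
  StepRep r;
  op_advect(w, p, r);
  return List::create(_["world"] = world_to_list(w, p),
                      _["report"] = rep_to_vector(r, w));
}

// [[Rcpp::export]]
List cpp_metabolize(List world, List params) {
  Params p = as_params(params);
  World w = as_world(world, p);
  Workspace ws;
  StepRep r;
  op_consume_metabolize(w, p, ws, r);
  return List::create(_["world"] = world_to_list(w, p),
                      _["report"] = rep_to_vector(r, w));
}

// [[Rcpp::export]]
List cpp_reproduce(List world, List params) {
  Params p = as_params(params);
  World w = as_world(world, p);
  Workspace ws;
  StepRep r;
  op_reproduce(w, p, ws, r);
  return List::create(_["world"] = world_to_list(w, p),
                      _["report"] = rep_to_vector(r, w));
}

// Dry-run allocation for a single element (1-based index): reports which
// colonies would eat which metabolite, without mutating the caller's state.
// [[Rcpp::export]]
List cpp_allocate_element(List world, List params, int element) {
  Params p = as_params(params);
  World w = as_world(world, p);
  int e = element;
  std::vector<int> order;
  for (size_t i = 0; i < w.size(); ++i)
    if ((int) w.x[i] == e) order.push_back((int) i);
  std::vector<int> ate(w.size(), -1), cand;
  StepRep r;
  allocate_on_element(w, p, e, order, 0, (int) order.size(), ate, cand, r);
  std::vector<int> who, what;
  for (size_t i = 0; i < ate.size(); ++i)
    if (ate[i] >= 0) { who.push_back((int) i + 1); what.push_back(ate[i] + 1); }
  return List::create(_["colony"] = wrap(who), _["metabolite"] = wrap(what),
                      _["units_consumed"] = r.consumed);
}

// Advance n_steps, recording genus counts and per-element totals whenever the
// absolute timestep is a multiple of record_every. dose_t holds absolute
// pre-step timesteps at which dose_amount colonies of dose_genus (1-based,
// 0 = none) override the boundary inflow for that genus.
// [[Rcpp::export]]
List cpp_run(List world, List params, int n_steps, int record_every,
             IntegerVector dose_t, int dose_genus, int dose_amount) {
  Params p = as_params(params);
  World w = as_world(world, p);
  Workspace ws;

  int nrec = 0;
  if (record_every > 0)
    for (int k = 1; k <= n_steps; ++k)
      if ((w.t + k) % record_every == 0) nrec++;
  IntegerMatrix series(nrec, p.nG);
  IntegerMatrix spatial(nrec, p.nE);
  NumericVector rec_t(nrec);
  NumericMatrix reports(n_steps, 14);

  std::vector<int> extra(p.nG, -1), none(p.nG, -1);
  std::vector<long long> doses(dose_t.begin(), dose_t.end());
  std::sort(doses.begin(), doses.end());
  size_t di = 0;
  int ri = 0;

  for (int k = 0; k < n_steps; ++k) {
    const std::vector<int>* ex = &none;
    if (dose_genus >= 1 && di < doses.size() && doses[di] == w.t) {
      extra.assign(p.nG, -1);
      extra[dose_genus - 1] = dose_amount;
      ex = &extra;
      ++di;
    }
    StepRep r = do_step(w, p, ws, *ex);
    double met_total = 0.0;
    for (double v : w.met) met_total += v;
    reports(k, 0) = (double) w.t;
    reports(k, 1) = r.births; reports(k, 2) = r.deaths;
    reports(k, 3) = r.washouts; reports(k, 4) = r.inflow;
    reports(k, 5) = r.stuck; reports(k, 6) = r.unstuck;
    reports(k, 7) = r.embed; reports(k, 8) = r.consumed;
    reports(k, 9) = r.produced; reports(k, 10) = r.met_in;
    reports(k, 11) = r.met_washed;
    reports(k, 12) = (double) w.size(); reports(k, 13) = met_total;
    if (record_every > 0 && w.t % record_every == 0) {
      std::vector<int> gc(p.nG, 0);
      count_elements(w, p, ws.cnt);
      for (size_t i = 0; i < w.size(); ++i) gc[w.genus[i]]++;
      for (int g = 0; g < p.nG; ++g) series(ri, g) = gc[g];
      for (int e = 0; e < p.nE; ++e) spatial(ri, e) = ws.cnt[e];
      rec_t[ri] = (double) w.t;
      ++ri;
    }
    if (k % 2048 == 0) Rcpp::checkUserInterrupt();
  }
  colnames(reports) = CharacterVector::create(
    "t", "births", "deaths_starvation", "washouts", "inflow",
    "stuck_events", "unstuck_events", "embed_events", "consumed",
    "produced", "met_in", "met_washed", "population", "met_total");
  return List::create(_["world"] = world_to_list(w, p),
                      _["reports"] = reports,
                      _["rec_t"] = rec_t,
                      _["series"] = series,
                      _["spatial"] = spatial);
}
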