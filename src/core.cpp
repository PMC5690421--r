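#include <Rcpp.h>
#include <unordered_set>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Steep sigmoid phi(x) = 2/(1+exp(-slope*x)) - 1 == tanh(slope*x/2).
// tanh saturates to exactly +/-1.0 in double precision beyond |t| = 19,
// so the branch below is bit-identical to std::tanh while skipping the
// expensive evaluation in the (common) saturated regime.
static inline double phi(double x, double slope) {
  const double t = 0.5 * slope * x;
  if (t > 19.0) return 1.0;
  if (t < -19.0) return -1.0;
  return std::tanh(t);
}

// ---------------------------------------------------------------------------
// Internal network representation shared by the simulation entry points.
// Nodes must be in canonical order: sorted by layer, input layer first.
// ---------------------------------------------------------------------------
struct NetRef {
  int n, m, n_in;
  const int *layer;       // 1-based layer per node
  const double *bias;
  const int *is_mod;      // modulatory flag per node (0/1)
  std::vector<int> src, tgt;          // 0-based endpoints
  std::vector<double> w;              // mutable weights
  std::vector<std::vector<int>> incoming;  // per node: connection indices
  double slope;

  NetRef(const IntegerVector &layer_, const NumericVector &bias_,
         const LogicalVector &mod_, const IntegerVector &src_,
         const IntegerVector &tgt_, const NumericVector &w_, double slope_)
      : n(layer_.size()), m(src_.size()), layer(&layer_[0]), bias(&bias_[0]),
        is_mod(&mod_[0]), slope(slope_) {
    n_in = 0;
    for (int i = 0; i < n; ++i) if (layer[i] == 1) ++n_in;
    src.resize(m); tgt.resize(m); w.resize(m);
    incoming.assign(n, {});
    for (int k = 0; k < m; ++k) {
      src[k] = src_[k] - 1;
      tgt[k] = tgt_[k] - 1;
      w[k] = w_[k];
      incoming[tgt[k]].push_back(k);
    }
    build_forward_index();
  }

  // CSR view of the non-modulatory inputs per node (weight indices), so
  // the forward pass runs branch-free; weights are read through w[] so
  // learning updates are picked up immediately.
  std::vector<int> fwd_off, fwd_k, fwd_j;
  void build_forward_index() {
    fwd_off.assign(n + 1, 0);
    fwd_k.clear(); fwd_j.clear();
    for (int i = 0; i < n; ++i) {
      fwd_off[i] = (int)fwd_k.size();
      for (int k : incoming[i])
        if (!is_mod[src[k]]) { fwd_k.push_back(k); fwd_j.push_back(src[k]); }
    }
    fwd_off[n] = (int)fwd_k.size();
  }

  // one forward pass; a must have length n, inputs already placed in a[0..n_in)
  void forward(std::vector<double> &a) const {
    for (int i = n_in; i < n; ++i) {
      double s = bias[i];
      for (int q = fwd_off[i]; q < fwd_off[i + 1]; ++q)
        s += w[fwd_k[q]] * a[fwd_j[q]];
      a[i] = phi(s, slope);
    }
  }

  // connections whose target is a regular (non-modulatory, non-input) node
  // that can actually receive a modulatory signal; everything else is
  // guaranteed m_i = 0 and therefore exactly unchanged by learning
  std::vector<int> plastic_connections(bool diffusion,
                                       const std::vector<double> &gs,
                                       const std::vector<double> &gw) const {
    std::vector<char> reachable(n, 0);
    if (diffusion) {
      for (int i = 0; i < n; ++i)
        reachable[i] = (gs[i] > 0.0 || gw[i] > 0.0);
    } else {
      for (int k = 0; k < m; ++k)
        if (is_mod[src[k]]) reachable[tgt[k]] = 1;
    }
    std::vector<int> out;
    out.reserve(m);
    for (int k = 0; k < m; ++k)
      if (!is_mod[tgt[k]] && reachable[tgt[k]]) out.push_back(k);
    return out;
  }
};

// [[Rcpp::export]]
NumericVector cpp_forward(IntegerVector layer, NumericVector bias,
                          LogicalVector is_mod, IntegerVector src,
                          IntegerVector tgt, NumericVector w,
                          NumericVector input, double slope) {
  NetRef net(layer, bias, is_mod, src, tgt, w, slope);
  std::vector<double> a(net.n, 0.0);
  for (int i = 0; i < net.n_in; ++i) a[i] = input[i];
  net.forward(a);
  return NumericVector(a.begin(), a.end());
}

// ---------------------------------------------------------------------------
// Full lifetime simulation: foraging steps with one-step-delayed seasonal
// feedback, optional neuromodulated Hebbian learning, optional activation
// record and per-season |dw| trace.
// ---------------------------------------------------------------------------
struct LifetimeOut {
  int nut = 0, poi = 0;
  std::vector<int> behavior;
  std::vector<int> blk_nut, blk_poi, blk_len;
};

static void run_lifetime(NetRef &net,
                         const IntegerMatrix &foods,
                         const IntegerVector &season,
                         const LogicalVector &new_season,
                         const IntegerVector &block,
                         const LogicalVector &nutritious,
                         int n_blocks,
                         bool learning_on, bool diffusion, bool eligibility,
                         double eta, double clamp, bool has_clamp,
                         const std::vector<double> &gs,
                         const std::vector<double> &gw,
                         int summer_out, int winter_out,
                         LifetimeOut &out,
                         double *rec,      // n x T column-major or nullptr
                         double *tr) {     // m x n_blocks or nullptr
  const int T = foods.nrow();
  const int n = net.n, m = net.m;
  std::vector<double> a(n, 0.0), mi(n, 0.0), msum(n, 0.0);
  std::vector<char> has_mod_in(n, 0);
  if (!diffusion) {
    for (int k = 0; k < m; ++k)
      if (net.is_mod[net.src[k]]) has_mod_in[net.tgt[k]] = 1;
  }
  const std::vector<int> plastic =
      learning_on ? net.plastic_connections(diffusion, gs, gw)
                  : std::vector<int>();
  std::vector<int> mod_conns;   // connections carrying modulatory signals
  if (learning_on && !diffusion)
    for (int k = 0; k < m; ++k)
      if (net.is_mod[net.src[k]]) mod_conns.push_back(k);
  out.behavior.assign(T, 0);
  out.blk_nut.assign(n_blocks, 0);
  out.blk_poi.assign(n_blocks, 0);
  out.blk_len.assign(n_blocks, 0);

  // Under the default eligibility pairing, the Hebbian product uses the
  // activations of the step whose feedback is arriving (the previous
  // presentation), so credit lands on the synapses that produced the
  // outcome; season boundaries clear the eligibility.  The concurrent
  // pairing uses the current step's activations instead.
  std::vector<double> prev_a(n, 0.0);
  bool prev_valid = false;
  double fb = 0.0;
  for (int t = 0; t < T; ++t) {
    if (new_season[t]) { fb = 0.0; prev_valid = false; }
    const double sfb = (season[t] == 0) ? fb : 0.0;
    const double wfb = (season[t] == 1) ? fb : 0.0;
    a[0] = foods(t, 0); a[1] = foods(t, 1); a[2] = foods(t, 2);
    a[net.n_in - 2] = sfb;
    a[net.n_in - 1] = wfb;
    net.forward(a);
    if (rec)
      for (int i = 0; i < n; ++i) rec[(size_t)t * n + i] = a[i];

    const bool eat = (season[t] == 0 ? a[summer_out] : a[winter_out]) > 0.0;
    out.behavior[t] = eat ? 1 : 0;
    const int b = block[t];
    out.blk_len[b]++;
    if (eat) {
      if (nutritious[t]) { out.nut++; out.blk_nut[b]++; }
      else               { out.poi++; out.blk_poi[b]++; }
    }

    if (learning_on && (!eligibility || prev_valid)) {
      bool any = true;
      if (diffusion) {
        if (sfb == 0.0 && wfb == 0.0) {
          any = false;  // phi(0) = 0 exactly: no weight changes this step
        } else {
          for (int i = net.n_in; i < n; ++i)
            if (gs[i] > 0.0 || gw[i] > 0.0)
              mi[i] = phi(sfb * gs[i] + wfb * gw[i], net.slope);
        }
      } else {
        std::fill(msum.begin(), msum.end(), 0.0);
        for (int k : mod_conns) msum[net.tgt[k]] += net.w[k] * a[net.src[k]];
        for (int i = net.n_in; i < n; ++i)
          if (has_mod_in[i]) mi[i] = phi(msum[i], net.slope);
      }
      if (any) {
        const std::vector<double> &ha = eligibility ? prev_a : a;
        for (int k : plastic) {
          const int i = net.tgt[k];
          double dw = eta * mi[i] * ha[i] * ha[net.src[k]];
          net.w[k] += dw;
          if (has_clamp) {
            if (net.w[k] > clamp) net.w[k] = clamp;
            if (net.w[k] < -clamp) net.w[k] = -clamp;
          }
          if (tr) tr[(size_t)b * m + k] += std::fabs(dw);
        }
      }
    }
    fb = eat ? (nutritious[t] ? 1.0 : -1.0) : 0.0;
    prev_a = a;
    prev_valid = true;
  }
}

static std::vector<double> source_falloff(int n, const double *x,
                                          const double *y, double sx,
                                          double sy, double pre,
                                          double sigma, double cutoff) {
  std::vector<double> g(n);
  for (int i = 0; i < n; ++i) {
    double d = std::hypot(x[i] - sx, y[i] - sy);
    g[i] = (d <= cutoff) ? pre * std::exp(-d * d / (2.0 * sigma * sigma)) : 0.0;
  }
  return g;
}

// [[Rcpp::export]]
List cpp_lifetime(IntegerVector layer, NumericVector xpos, NumericVector ypos,
                  NumericVector bias, LogicalVector is_mod,
                  IntegerVector src, IntegerVector tgt, NumericVector w,
                  IntegerMatrix foods, IntegerVector season,
                  LogicalVector new_season, IntegerVector block,
                  LogicalVector nutritious, int n_blocks,
                  bool learning_on, bool diffusion, bool eligibility,
                  double eta, double sigma, double cutoff, double prefactor,
                  double clamp, bool has_clamp,
                  NumericVector source_x, NumericVector source_y,
                  int summer_out, int winter_out,
                  bool record, bool trace, double slope) {
  NetRef net(layer, bias, is_mod, src, tgt, w, slope);
  std::vector<double> gs, gw;
  if (diffusion) {
    gs = source_falloff(net.n, &xpos[0], &ypos[0], source_x[0], source_y[0],
                        prefactor, sigma, cutoff);
    gw = source_falloff(net.n, &xpos[0], &ypos[0], source_x[1], source_y[1],
                        prefactor, sigma, cutoff);
  } else {
    gs.assign(net.n, 0.0);
    gw.assign(net.n, 0.0);
  }
  const int T = foods.nrow();
  NumericMatrix rec(record ? net.n : 0, record ? T : 0);
  NumericMatrix tr(trace ? net.m : 0, trace ? n_blocks : 0);
  LifetimeOut out;
  run_lifetime(net, foods, season, new_season, block, nutritious, n_blocks,
               learning_on, diffusion, eligibility, eta, clamp, has_clamp,
               gs, gw, summer_out - 1, winter_out - 1, out,
               record ? &rec[0] : nullptr, trace ? &tr[0] : nullptr);
  double fitness = 0.5 + (double)(out.nut - out.poi) / T;
  return List::create(
      _["fitness"] = fitness,
      _["nutritious_eaten"] = out.nut,
      _["poisonous_eaten"] = out.poi,
      _["total_food"] = T,
      _["behavior"] = IntegerVector(out.behavior.begin(), out.behavior.end()),
      _["weights"] = NumericVector(net.w.begin(), net.w.end()),
      _["block_nutritious"] = IntegerVector(out.blk_nut.begin(), out.blk_nut.end()),
      _["block_poisonous"] = IntegerVector(out.blk_poi.begin(), out.blk_poi.end()),
      _["block_length"] = IntegerVector(out.blk_len.begin(), out.blk_len.end()),
      _["record"] = rec,
      _["trace"] = tr);
}

// ---------------------------------------------------------------------------
// Batched evaluation used by the evolutionary loop: each genome is run with
// learning on through each of the supplied environments; returns the mean
// lifetime fitness per genome and the concatenated eat/not-eat behavior.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_evaluate_population(List genomes, List envs,
                             IntegerVector layer, NumericVector xpos,
                             NumericVector ypos, bool diffusion,
                             bool eligibility, double modul_threshold,
                             double eta, double sigma, double cutoff,
                             double prefactor,
                             NumericVector source_x, NumericVector source_y,
                             int summer_out, int winter_out, double slope) {
  const int P = genomes.size(), E = envs.size();
  const int n = layer.size();
  int last_layer = layer[n - 1];

  // per-env step tables
  std::vector<IntegerMatrix> foods(E);
  std::vector<IntegerVector> season(E), block(E);
  std::vector<LogicalVector> new_season(E), nutritious(E);
  int T = 0;
  for (int e = 0; e < E; ++e) {
    List env = envs[e];
    foods[e] = as<IntegerMatrix>(env["foods"]);
    season[e] = as<IntegerVector>(env["season"]);
    new_season[e] = as<LogicalVector>(env["new_season"]);
    block[e] = as<IntegerVector>(env["block"]);
    nutritious[e] = as<LogicalVector>(env["nutritious"]);
    T = foods[e].nrow();
  }
  int n_blocks = 0;
  for (int t = 0; t < T; ++t)
    if (block[0][t] + 1 > n_blocks) n_blocks = block[0][t] + 1;

  NumericVector fitness(P);
  IntegerMatrix behavior(P, T * E);
  std::vector<double> gs = source_falloff(n, &xpos[0], &ypos[0], source_x[0],
                                          source_y[0], prefactor, sigma, cutoff);
  std::vector<double> gw = source_falloff(n, &xpos[0], &ypos[0], source_x[1],
                                          source_y[1], prefactor, sigma, cutoff);
  if (!diffusion) { gs.assign(n, 0.0); gw.assign(n, 0.0); }

  for (int p = 0; p < P; ++p) {
    List g = genomes[p];
    IntegerVector src = g["source"], tgt = g["target"];
    NumericVector w0 = g["weight"], bias = g["bias"], modul = g["modul"];
    LogicalVector is_mod(n);
    for (int i = 0; i < n; ++i)
      is_mod[i] = (!diffusion) && layer[i] > 1 && layer[i] < last_layer &&
                  modul[i] < modul_threshold;
    double fsum = 0.0;
    for (int e = 0; e < E; ++e) {
      NetRef net(layer, bias, is_mod, src, tgt, w0, slope);
      LifetimeOut out;
      run_lifetime(net, foods[e], season[e], new_season[e], block[e],
                   nutritious[e], n_blocks, true, diffusion, eligibility,
                   eta, 0.0, false, gs, gw, summer_out - 1, winter_out - 1,
                   out, nullptr, nullptr);
      fsum += 0.5 + (double)(out.nut - out.poi) / T;
      for (int t = 0; t < T; ++t) behavior(p, e * T + t) = out.behavior[t];
    }
    fitness[p] = fsum / E;
  }
  return List::create(_["fitness"] = fitness, _["behavior"] = behavior);
}

// ---------------------------------------------------------------------------
// ARK knockout scan for one node: Gray-code enumeration of all kept-subsets
// of the p incoming contribution rows, scored as mean squared deviation from
// the recorded activation (the square root is applied R-side).
// contrib: p x T matrix, row k = w_k * recorded activation of source k
//          (all-zero row when the source is modulatory).
// y: recorded activation of the node (length T).
// Returns MSE indexed by kept-mask (bit k set = connection k kept).
// [[Rcpp::export]]
NumericVector cpp_knockout_mse(NumericMatrix contrib, NumericVector y,
                               double bias, double slope) {
  const int p = contrib.nrow(), T = contrib.ncol();
  if (p > 30) stop("in-degree too large for exhaustive knockout");
  const size_t M = (size_t)1 << p;
  NumericVector mse(M);
  std::vector<double> s(T, 0.0);  // running kept sum, starts at empty mask
  size_t gray_prev = 0;
  for (size_t idx = 0; idx < M; ++idx) {
    size_t gray = idx ^ (idx >> 1);
    size_t diff = gray ^ gray_prev;
    if (diff) {
      int b = 0;
      while (!((diff >> b) & 1)) ++b;
      const double sign = ((gray >> b) & 1) ? 1.0 : -1.0;
      for (int t = 0; t < T; ++t) s[t] += sign * contrib(b, t);
    }
    double acc = 0.0;
    for (int t = 0; t < T; ++t) {
      double d = phi(s[t] + bias, slope) - y[t];
      acc += d * d;
    }
    mse[gray] = acc / T;
    gray_prev = gray;
  }
  return mse;
}

// ---------------------------------------------------------------------------
// Mutation operator (uses the R RNG; seed R-side for reproducibility).
// Draw order: add attempt, remove attempt, per-connection endpoint
// reassignment, per-connection weight mutation, per-node bias, per-node
// modul.  Polynomial mutation with distribution index eta_m throughout.
// ---------------------------------------------------------------------------
static double poly_mut(double x, double lb, double ub, double eta) {
  const double u = unif_rand();
  const double d1 = (x - lb) / (ub - lb), d2 = (ub - x) / (ub - lb);
  const double mp = 1.0 / (eta + 1.0);
  double dq;
  if (u <= 0.5) {
    double xy = 1.0 - d1;
    double val = 2.0 * u + (1.0 - 2.0 * u) * std::pow(xy, eta + 1.0);
    dq = std::pow(val, mp) - 1.0;
  } else {
    double xy = 1.0 - d2;
    double val = 2.0 * (1.0 - u) + 2.0 * (u - 0.5) * std::pow(xy, eta + 1.0);
    dq = 1.0 - std::pow(val, mp);
  }
  double r = x + dq * (ub - lb);
  if (r < lb) r = lb;
  if (r > ub) r = ub;
  return r;
}

// [[Rcpp::export]]
List cpp_mutate(IntegerVector src0, IntegerVector tgt0, NumericVector w0,
                NumericVector bias0, NumericVector modul0,
                IntegerVector layer, IntegerVector legal_src,
                IntegerVector legal_tgt, double p_add, double p_remove,
                double p_reassign, double p_weight, double p_bias,
                double p_modul, double eta_m) {
  const int n = layer.size();
  const int n_legal = legal_src.size();
  std::vector<int> src(src0.begin(), src0.end());
  std::vector<int> tgt(tgt0.begin(), tgt0.end());
  std::vector<double> w(w0.begin(), w0.end());
  std::vector<double> bias(bias0.begin(), bias0.end());
  std::vector<double> modul(modul0.begin(), modul0.end());

  auto code = [](int s, int t) { return s * 1024 + t; };
  std::unordered_set<int> present;
  for (size_t k = 0; k < src.size(); ++k) present.insert(code(src[k], tgt[k]));

  // add-connection attempt: uniform over absent legal forward pairs
  if (unif_rand() < p_add && (int)src.size() < n_legal) {
    for (int tries = 0; tries < 1000; ++tries) {
      int j = (int)std::floor(unif_rand() * n_legal);
      if (j >= n_legal) j = n_legal - 1;
      int c = code(legal_src[j], legal_tgt[j]);
      if (!present.count(c)) {
        src.push_back(legal_src[j]);
        tgt.push_back(legal_tgt[j]);
        w.push_back(unif_rand() * 2.0 - 1.0);
        present.insert(c);
        break;
      }
    }
  }
  // remove-connection attempt
  if (unif_rand() < p_remove && !src.empty()) {
    int j = (int)std::floor(unif_rand() * src.size());
    if (j >= (int)src.size()) j = src.size() - 1;
    present.erase(code(src[j], tgt[j]));
    src.erase(src.begin() + j);
    tgt.erase(tgt.begin() + j);
    w.erase(w.begin() + j);
  }
  // per-connection endpoint reassignment (one resample on an illegal
  // proposal, then no-op)
  for (size_t k = 0; k < src.size(); ++k) {
    if (unif_rand() >= p_reassign) continue;
    bool move_source = unif_rand() < 0.5;
    std::vector<int> cand;
    cand.reserve(n);
    for (int i = 1; i <= n; ++i) {
      if (move_source) {
        if (layer[i - 1] < layer[tgt[k] - 1]) cand.push_back(i);
      } else {
        if (layer[i - 1] > layer[src[k] - 1]) cand.push_back(i);
      }
    }
    if (cand.empty()) continue;
    for (int attempt = 0; attempt < 2; ++attempt) {
      int j = (int)std::floor(unif_rand() * cand.size());
      if (j >= (int)cand.size()) j = cand.size() - 1;
      int ns = move_source ? cand[j] : src[k];
      int nt = move_source ? tgt[k] : cand[j];
      int c = code(ns, nt);
      if (c == code(src[k], tgt[k]) || present.count(c)) continue;
      present.erase(code(src[k], tgt[k]));
      src[k] = ns;
      tgt[k] = nt;
      present.insert(c);
      break;
    }
  }
  // per-connection weight mutation
  for (size_t k = 0; k < src.size(); ++k)
    if (unif_rand() < p_weight) w[k] = poly_mut(w[k], -1.0, 1.0, eta_m);
  // per-node bias and modul mutation
  for (int i = 0; i < n; ++i)
    if (unif_rand() < p_bias) bias[i] = poly_mut(bias[i], -1.0, 1.0, eta_m);
  for (int i = 0; i < n; ++i)
    if (unif_rand() < p_modul) modul[i] = poly_mut(modul[i], 0.0, 1.0, eta_m);

  return List::create(
      _["source"] = IntegerVector(src.begin(), src.end()),
      _["target"] = IntegerVector(tgt.begin(), tgt.end()),
      _["weight"] = NumericVector(w.begin(), w.end()),
      _["bias"] = NumericVector(bias.begin(), bias.end()),
      _["modul"] = NumericVector(modul.begin(), modul.end()));
}
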