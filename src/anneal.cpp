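// Simulated-annealing maximizer for the Bernoulli niche-model likelihood.
//
// The packed state holds the free coordinates of one model variant (see
// free_param_layout() on the R side). Proposals are single-coordinate, so
// the log-likelihood is updated incrementally: a diet-position or range
// move touches one consumer row, a niche-position move touches one
// resource column (plus the species' own row under a coupled variant),
// and a global-coefficient move recomputes all consumer rows. Producer
// rows are constant (all probabilities sit on the floor) and never
// revisited. Uses R's RNG throughout so runs are reproducible from
// set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

enum Variant { V_PNM = 0, V_ANM = 1, V_R_OF_C = 2, V_R_OF_N = 3,
               V_C_OF_N = 4, V_CR_OF_N = 5 };
enum SlotType { SL_N = 0, SL_C = 1, SL_R = 2,
                SL_C0 = 3, SL_C1 = 4, SL_R0 = 5, SL_R1 = 6 };

struct Model {
  int S;
  std::vector<int> A;          // column-major S x S
  std::vector<char> producer, specialist;
  int variant;
  double a, p_floor, r_floor, r_max;
  std::vector<double> n, c, r; // raw per-species parameters
  double g[4];                 // c0, c1, r0, r1
  std::vector<double> rowll;
  double lnl;
  double producer_rowll;

  bool couple_c() const { return variant == V_C_OF_N || variant == V_CR_OF_N; }
  bool couple_r() const {
    return variant == V_R_OF_C || variant == V_R_OF_N || variant == V_CR_OF_N;
  }
  static double clampd(double x, double lo, double hi) {
    return x < lo ? lo : (x > hi ? hi : x);
  }
  double ceff(int i) const {
    if (producer[i]) return 0.0;
    if (couple_c()) return clampd(g[0] + g[1] * n[i], 0.0, 1.0);
    return c[i];
  }
  double reff(int i) const {
    if (producer[i] || specialist[i]) return r_floor;
    if (variant == V_R_OF_C)
      return clampd(g[2] * std::exp(g[3] * ceff(i)), r_floor, r_max);
    if (variant == V_R_OF_N || variant == V_CR_OF_N)
      return clampd(g[2] + g[3] * n[i], r_floor, r_max);
    return clampd(r[i], r_floor, r_max);
  }
  // Bernoulli term of entry (i, j) with an explicit resource position.
  double term_at(int i, int j, double nj, double ce, double re) const {
    double d = (nj - ce) / (0.5 * re);
    double p = a * std::exp(-d * d);
    if (p < p_floor) p = p_floor;
    return A[i + S * j] ? std::log(p) : std::log1p(-p);
  }
  double row_loglik(int i) const {
    if (producer[i]) return producer_rowll;
    double ce = ceff(i), re = reff(i), s = 0.0;
    for (int j = 0; j < S; ++j) s += term_at(i, j, n[j], ce, re);
    return s;
  }
  void full_eval() {
    lnl = 0.0;
    for (int i = 0; i < S; ++i) { rowll[i] = row_loglik(i); lnl += rowll[i]; }
  }
};

struct Change {
  std::vector<int> rows;
  std::vector<double> newll;
  double dll;
  void reset() { rows.clear(); newll.clear(); dll = 0.0; }
};

// Log-likelihood delta of setting one slot to value v, without committing.
static void eval_change(Model &M, int type, int idx, double v, Change &ch) {
  ch.reset();
  if (type == SL_N) {
    double old = M.n[idx];
    bool rowtoo = (M.couple_c() || M.couple_r()) && !M.producer[idx];
    for (int i = 0; i < M.S; ++i) {
      if (M.producer[i]) continue;
      if (rowtoo && i == idx) continue;
      double ce = M.ceff(i), re = M.reff(i);
      double tnew = M.term_at(i, idx, v, ce, re);
      double told = M.term_at(i, idx, old, ce, re);
      ch.rows.push_back(i);
      ch.newll.push_back(M.rowll[i] - told + tnew);
      ch.dll += tnew - told;
    }
    if (rowtoo) {
      M.n[idx] = v;
      double nr = M.row_loglik(idx);
      M.n[idx] = old;
      ch.rows.push_back(idx);
      ch.newll.push_back(nr);
      ch.dll += nr - M.rowll[idx];
    }
  } else if (type == SL_C || type == SL_R) {
    double *slot = (type == SL_C) ? &M.c[idx] : &M.r[idx];
    double old = *slot;
    *slot = v;
    double nr = M.row_loglik(idx);
    *slot = old;
    ch.rows.push_back(idx);
    ch.newll.push_back(nr);
    ch.dll = nr - M.rowll[idx];
  } else {
    int k = type - SL_C0;
    double old = M.g[k];
    M.g[k] = v;
    for (int i = 0; i < M.S; ++i) {
      if (M.producer[i]) continue;
      double nr = M.row_loglik(i);
      ch.rows.push_back(i);
      ch.newll.push_back(nr);
      ch.dll += nr - M.rowll[i];
    }
    M.g[k] = old;
  }
}

static void commit(Model &M, int type, int idx, double v, const Change &ch) {
  switch (type) {
  case SL_N: M.n[idx] = v; break;
  case SL_C: M.c[idx] = v; break;
  case SL_R: M.r[idx] = v; break;
  default: M.g[type - SL_C0] = v;
  }
  for (size_t k = 0; k < ch.rows.size(); ++k) M.rowll[ch.rows[k]] = ch.newll[k];
  M.lnl += ch.dll;
}

static double reflect(double x, double lo, double hi) {
  if (hi <= lo) return lo;
  double w = hi - lo, w2 = 2.0 * w;
  double y = (x - lo) - std::floor((x - lo) / w2) * w2;
  return lo + (y <= w ? y : w2 - y);
}

static void load_state(Model &M, const IntegerVector &slot_type,
                       const IntegerVector &slot_index,
                       const std::vector<double> &x) {
  for (int s = 0; s < (int)x.size(); ++s) {
    int t = slot_type[s], i = slot_index[s];
    switch (t) {
    case SL_N: M.n[i] = x[s]; break;
    case SL_C: M.c[i] = x[s]; break;
    case SL_R: M.r[i] = x[s]; break;
    default: M.g[t - SL_C0] = x[s];
    }
  }
}

// Coordinate-wise deterministic polish: coarse scan of each free slot
// plus snap candidates from the observed links, with two local
// refinements around the best value.
static void polish(Model &M, const IntegerVector &slot_type,
                   const IntegerVector &slot_index,
                   const NumericVector &lo, const NumericVector &hi,
                   std::vector<double> &x, const IntegerMatrix &links,
                   int cycles) {
  int nslot = x.size(), m = links.nrow();
  Change ch;
  for (int cyc = 0; cyc < cycles; ++cyc) {
    for (int s = 0; s < nslot; ++s) {
      int type = slot_type[s], idx = slot_index[s];
      std::vector<double> cand;
      double w = hi[s] - lo[s];
      for (int k = 0; k <= 32; ++k) cand.push_back(lo[s] + w * k / 32.0);
      if (type == SL_C) {
        for (int e = 0; e < m; ++e)
          if (links(e, 0) == idx) cand.push_back(M.n[links(e, 1)]);
      } else if (type == SL_N) {
        for (int e = 0; e < m; ++e)
          if (links(e, 1) == idx) cand.push_back(M.ceff(links(e, 0)));
      }
      for (int level = 0; level < 3; ++level) {
        double best_v = x[s], best_d = 0.0;
        for (double v : cand) {
          if (v < lo[s] || v > hi[s] || v == x[s]) continue;
          eval_change(M, type, idx, v, ch);
          if (ch.dll > best_d + 1e-12) { best_d = ch.dll; best_v = v; }
        }
        if (best_d > 0) {
          eval_change(M, type, idx, best_v, ch);
          commit(M, type, idx, best_v, ch);
          x[s] = best_v;
        }
        // refine around the current value with a shrinking window
        double win = w / std::pow(16.0, level + 1);
        cand.clear();
        for (int k = -4; k <= 4; ++k) cand.push_back(x[s] + win * k / 4.0);
      }
    }
  }
}

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(IntegerMatrix A, LogicalVector producer,
                LogicalVector specialist, int variant,
                NumericVector n0, NumericVector c0, NumericVector r0,
                NumericVector g0,
                IntegerVector slot_type, IntegerVector slot_index,
                NumericVector slot_lo, NumericVector slot_hi,
                NumericVector init, IntegerMatrix links,
                double T0, double cooling, int stages, int steps_per_stage,
                double step_sigma, double snap_prob, int polish_cycles,
                double a, double p_floor, double r_floor, double r_max) {
  int S = A.nrow();
  Model M;
  M.S = S;
  M.A.assign(A.begin(), A.end());
  M.producer.assign(producer.begin(), producer.end());
  M.specialist.assign(specialist.begin(), specialist.end());
  M.variant = variant;
  M.a = a; M.p_floor = p_floor; M.r_floor = r_floor; M.r_max = r_max;
  M.n.assign(n0.begin(), n0.end());
  M.c.assign(c0.begin(), c0.end());
  M.r.assign(r0.begin(), r0.end());
  for (int k = 0; k < 4; ++k) M.g[k] = g0[k];
  M.rowll.assign(S, 0.0);
  M.producer_rowll = S * std::log1p(-p_floor);

  int nslot = init.size();
  std::vector<double> x(init.begin(), init.end());
  load_state(M, slot_type, slot_index, x);
  M.full_eval();

  // reverse lookup for snap moves
  std::vector<int> slot_of_n(S, -1), slot_of_c(S, -1);
  for (int s = 0; s < nslot; ++s) {
    if (slot_type[s] == SL_N) slot_of_n[slot_index[s]] = s;
    if (slot_type[s] == SL_C) slot_of_c[slot_index[s]] = s;
  }

  std::vector<double> best_x = x;
  double best_lnl = M.lnl;
  NumericVector trace(stages);
  int m = links.nrow();
  Change ch;
  double T = T0;

  RNGScope rng;
  for (int stage = 0; stage < stages; ++stage) {
    for (int step = 0; step < steps_per_stage; ++step) {
      int s = -1;
      double v = 0.0;
      if (m > 0 && unif_rand() < snap_prob) {
        int e = (int)(unif_rand() * m); if (e >= m) e = m - 1;
        int i = links(e, 0), j = links(e, 1);
        if (unif_rand() < 0.5) { s = slot_of_c[i]; if (s >= 0) v = M.n[j]; }
        else                   { s = slot_of_n[j]; if (s >= 0) v = M.ceff(i); }
        if (s < 0) continue;  // the targeted coordinate is not free
        v = Model::clampd(v, slot_lo[s], slot_hi[s]);
      } else {
        s = (int)(unif_rand() * nslot); if (s >= nslot) s = nslot - 1;
        v = reflect(x[s] + norm_rand() * step_sigma, slot_lo[s], slot_hi[s]);
      }
      eval_change(M, slot_type[s], slot_index[s], v, ch);
      if (ch.dll >= 0 || unif_rand() < std::exp(ch.dll / T)) {
        commit(M, slot_type[s], slot_index[s], v, ch);
        x[s] = v;
        if (M.lnl > best_lnl) { best_lnl = M.lnl; best_x = x; }
      }
    }
    M.full_eval();  // guard against incremental drift
    if (M.lnl > best_lnl) { best_lnl = M.lnl; best_x = x; }
    trace[stage] = best_lnl;
    T *= cooling;
  }

  load_state(M, slot_type, slot_index, best_x);
  M.full_eval();
  if (polish_cycles > 0)
    polish(M, slot_type, slot_index, slot_lo, slot_hi, best_x, links,
           polish_cycles);
  M.full_eval();

  return List::create(_["state"] = NumericVector(best_x.begin(), best_x.end()),
                      _["lnl"] = M.lnl,
                      _["trace"] = trace);
}
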