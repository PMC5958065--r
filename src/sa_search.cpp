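#include <Rcpp.h>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// A logic tree with at most three leaves over window-local SNP columns.
// Shapes (up to commutativity every <=3-leaf AND/OR tree fits one of these):
//   nl == 1 : leaf0
//   nl == 2 : leaf0 <op_out> leaf1
//   nl == 3 : (leaf0 <op_in> leaf1) <op_out> leaf2
// op encoding: 0 = AND, 1 = OR. Leaf SNPs are kept pairwise distinct.
struct Tree {
  int nl;
  int snp[3];
  int al[3];
  int op_in;
  int op_out;
};

// xorshift64* PRNG: deterministic and independent of R's RNG state, so a
// restart seed fully determines one annealing trajectory.
static inline uint64_t rng_next(uint64_t &s) {
  s ^= s >> 12;
  s ^= s << 25;
  s ^= s >> 27;
  return s * 2685821657736338717ULL;
}
static inline double rng_unif(uint64_t &s) {
  return (double)(rng_next(s) >> 11) * (1.0 / 9007199254740992.0);
}
static inline int rng_int(uint64_t &s, int n) {
  int k = (int)(rng_unif(s) * n);
  return (k >= n) ? (n - 1) : k;
}
static uint64_t rng_seed(int seed) {
  uint64_t s = (uint64_t)(uint32_t)seed * 0x9E3779B97F4A7C15ULL + 0xBF58476D1CE4E5B9ULL;
  if (s == 0) s = 1;
  for (int i = 0; i < 8; ++i) rng_next(s);
  return s;
}

static inline double bin_dev_term(int k, int n) {
  // -2 * log-likelihood of a saturated-at-group binomial cell, 0*log(0) = 0
  double d = 0.0;
  if (n == 0) return 0.0;
  double p = (double)k / (double)n;
  if (k > 0) d += (double)k * std::log(p);
  if (n - k > 0) d += (double)(n - k) * std::log(1.0 - p);
  return -2.0 * d;
}

// Residual deviance of the chromosome-level logistic fit of phenotype on the
// tree indicator; closed form because the predictor is binary (group
// proportions are the MLE). Chromosomes missing at any leaf SNP are dropped.
// A constant indicator scores the null deviance on the used chromosomes.
static double tree_deviance(const Tree &t, const IntegerMatrix &haps,
                            const IntegerVector &y) {
  int n = haps.nrow();
  int n1 = 0, k1 = 0, n0 = 0, k0 = 0;
  for (int c = 0; c < n; ++c) {
    bool miss = false;
    bool lit[3];
    for (int j = 0; j < t.nl; ++j) {
      int a = haps(c, t.snp[j]);
      if (a == NA_INTEGER) { miss = true; break; }
      lit[j] = (a == t.al[j]);
    }
    if (miss) continue;
    bool v;
    if (t.nl == 1) {
      v = lit[0];
    } else if (t.nl == 2) {
      v = t.op_out ? (lit[0] || lit[1]) : (lit[0] && lit[1]);
    } else {
      bool inner = t.op_in ? (lit[0] || lit[1]) : (lit[0] && lit[1]);
      v = t.op_out ? (inner || lit[2]) : (inner && lit[2]);
    }
    if (v) { ++n1; k1 += y[c]; } else { ++n0; k0 += y[c]; }
  }
  if (n1 == 0 || n0 == 0) {
    return bin_dev_term(k1 + k0, n1 + n0);  // null deviance, constant predictor
  }
  return bin_dev_term(k1, n1) + bin_dev_term(k0, n0);
}

static Tree random_leaf_tree(uint64_t &s, int k) {
  Tree t;
  t.nl = 1;
  t.snp[0] = rng_int(s, k);
  t.al[0] = rng_int(s, 2);
  t.snp[1] = t.snp[2] = -1;
  t.al[1] = t.al[2] = 0;
  t.op_in = 0;
  t.op_out = 0;
  return t;
}

static inline bool snp_used_elsewhere(const Tree &t, int snp, int except) {
  for (int j = 0; j < t.nl; ++j)
    if (j != except && t.snp[j] == snp) return true;
  return false;
}

// Propose one move in place; returns false when the drawn move is not
// applicable to the current state (caller skips the iteration).
static bool propose(Tree &t, uint64_t &s, int k, const double *cumw) {
  double u = rng_unif(s);
  int move = 5;
  for (int m = 0; m < 6; ++m) {
    if (u < cumw[m]) { move = m; break; }
  }
  switch (move) {
  case 0: {  // replace-leaf-SNP (allele kept)
    int j = rng_int(s, t.nl);
    int avail = k - (t.nl - 1);
    if (avail <= 0) return false;
    int pick = rng_int(s, avail);
    for (int snp = 0; snp < k; ++snp) {
      if (snp_used_elsewhere(t, snp, j)) continue;
      if (pick-- == 0) { t.snp[j] = snp; return true; }
    }
    return false;
  }
  case 1: {  // flip-leaf-allele
    int j = rng_int(s, t.nl);
    t.al[j] ^= 1;
    return true;
  }
  case 2: {  // toggle-operator
    if (t.nl == 1) return false;
    if (t.nl == 2) { t.op_out ^= 1; return true; }
    if (rng_int(s, 2)) t.op_out ^= 1; else t.op_in ^= 1;
    return true;
  }
  case 3: {  // grow-leaf
    if (t.nl >= 3 || t.nl >= k) return false;
    int avail = k - t.nl;
    int pick = rng_int(s, avail);
    int chosen = -1;
    for (int snp = 0; snp < k; ++snp) {
      if (snp_used_elsewhere(t, snp, -1)) continue;
      if (pick-- == 0) { chosen = snp; break; }
    }
    if (chosen < 0) return false;
    if (t.nl == 1) {
      t.snp[1] = chosen;
      t.al[1] = rng_int(s, 2);
      t.op_out = rng_int(s, 2);
      t.nl = 2;
    } else {
      t.snp[2] = chosen;
      t.al[2] = rng_int(s, 2);
      t.op_in = t.op_out;
      t.op_out = rng_int(s, 2);
      t.nl = 3;
    }
    return true;
  }
  case 4: {  // prune-leaf
    if (t.nl == 1) return false;
    int j = rng_int(s, t.nl);
    if (t.nl == 2) {
      if (j == 0) { t.snp[0] = t.snp[1]; t.al[0] = t.al[1]; }
      t.nl = 1;
    } else {
      if (j == 2) {
        t.op_out = t.op_in;
      } else if (j == 0) {
        t.snp[0] = t.snp[1]; t.al[0] = t.al[1];
        t.snp[1] = t.snp[2]; t.al[1] = t.al[2];
      } else {
        t.snp[1] = t.snp[2]; t.al[1] = t.al[2];
      }
      t.nl = 2;
    }
    return true;
  }
  default: {  // reshape: re-draw the outer leaf and both operators (3-leaf)
    if (t.nl != 3) return false;
    int outer = rng_int(s, 3);
    int a = (outer == 0) ? 1 : 0;
    int b = (outer == 2) ? 1 : 2;
    Tree nt = t;
    nt.snp[0] = t.snp[a]; nt.al[0] = t.al[a];
    nt.snp[1] = t.snp[b]; nt.al[1] = t.al[b];
    nt.snp[2] = t.snp[outer]; nt.al[2] = t.al[outer];
    nt.op_in = rng_int(s, 2);
    nt.op_out = rng_int(s, 2);
    t = nt;
    return true;
  }
  }
}

static void store_tree(IntegerMatrix &mat, int r, const Tree &t) {
  mat(r, 0) = t.nl;
  mat(r, 1) = t.snp[0]; mat(r, 2) = t.snp[1]; mat(r, 3) = t.snp[2];
  mat(r, 4) = t.al[0];  mat(r, 5) = t.al[1];  mat(r, 6) = t.al[2];
  mat(r, 7) = t.op_in;  mat(r, 8) = t.op_out;
}

//' @title Multi-restart simulated-annealing search (internal C++ core)
//' @noRd
// [[Rcpp::export(name = ".sa_search_cpp")]]
List sa_search_cpp(IntegerMatrix haps, IntegerVector y,
                   IntegerVector restart_seeds, int n_iter,
                   double t_start, double t_end,
                   NumericVector move_weights) {
  int k = haps.ncol();
  int nr = restart_seeds.size();
  if (k < 1) stop("window has no SNP columns");
  if (move_weights.size() != 6) stop("move_weights must have 6 entries");
  double cumw[6];
  double tot = 0.0;
  for (int m = 0; m < 6; ++m) tot += move_weights[m];
  double acc = 0.0;
  for (int m = 0; m < 6; ++m) { acc += move_weights[m] / tot; cumw[m] = acc; }
  cumw[5] = 1.0 + 1e-12;

  IntegerMatrix best_any(nr, 9), best3(nr, 9);
  NumericVector dev_any(nr, NA_REAL), dev3(nr, NA_REAL);
  double log_ratio = (n_iter > 1) ? std::log(t_end / t_start) : 0.0;

  for (int r = 0; r < nr; ++r) {
    Rcpp::checkUserInterrupt();
    uint64_t s = rng_seed(restart_seeds[r]);
    Tree cur = random_leaf_tree(s, k);
    double d = tree_deviance(cur, haps, y);
    double ba = d; Tree ta = cur;
    double b3 = NA_REAL; Tree t3 = cur;
    if (cur.nl == 3) { b3 = d; t3 = cur; }
    for (int i = 0; i < n_iter; ++i) {
      double T = (n_iter > 1)
        ? t_start * std::exp(log_ratio * (double)i / (double)(n_iter - 1))
        : t_end;
      Tree prop = cur;
      if (!propose(prop, s, k, cumw)) continue;
      double d2 = tree_deviance(prop, haps, y);
      double delta = d2 - d;
      if (delta <= 0.0 || rng_unif(s) < std::exp(-delta / T)) {
        cur = prop;
        d = d2;
        if (d < ba - 1e-12) { ba = d; ta = cur; }
        if (cur.nl == 3 && (ISNA(b3) || d < b3 - 1e-12)) { b3 = d; t3 = cur; }
      }
    }
    dev_any[r] = ba;
    store_tree(best_any, r, ta);
    if (!ISNA(b3)) { dev3[r] = b3; store_tree(best3, r, t3); }
  }

  return List::create(
    _["dev_any"] = dev_any, _["tree_any"] = best_any,
    _["dev3"] = dev3, _["tree3"] = best3);
}

//' @title Closed-form chromosome-level deviance for a flat tree (internal)
//' @noRd
// [[Rcpp::export(name = ".tree_deviance_cpp")]]
double tree_deviance_flat(IntegerMatrix haps, IntegerVector y,
                          int nl, IntegerVector snps, IntegerVector als,
                          int op_in, int op_out) {
  Tree t;
  t.nl = nl;
  for (int j = 0; j < 3; ++j) {
    t.snp[j] = (j < snps.size()) ? snps[j] : -1;
    t.al[j] = (j < als.size()) ? als[j] : 0;
  }
  t.op_in = op_in;
  t.op_out = op_out;
  return tree_deviance(t, haps, y);
}
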