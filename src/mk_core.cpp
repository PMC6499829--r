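// Mk-model likelihood core: transition probabilities, Felsenstein pruning,
// exact node marginals, and the Metropolis sampler used for both posterior
// sampling (beta = 1) and power-posterior segments (stepping stones).
//
// Trees arrive from R as lists prepared by prep_tree(): a postorder edge
// matrix in ape's node numbering (tips 1..ntip, root ntip+1), branch lengths,
// 0-based tip states (one column per character), target node ids for
// marginal recording, and an optional node constraint (state fixing).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

struct PrepTree {
  arma::umat edge;      // postorder, col 0 = parent, col 1 = child (1-based)
  arma::vec elen;
  int ntip;
  int nnode;            // total nodes = ntip + n internal
  int root;
  arma::imat tipstates; // ntip x nchar, 0-based
  arma::ivec targets;   // node ids for marginal recording (may be empty)
  int cnode;            // constrained node id, 0 = none
  int cstate;           // 0-based fixed state
};

static PrepTree unpack_tree(const List& tr) {
  PrepTree t;
  IntegerMatrix e = tr["edge"];
  t.edge.set_size(e.nrow(), 2);
  for (int i = 0; i < e.nrow(); ++i) {
    t.edge(i, 0) = (unsigned) e(i, 0);
    t.edge(i, 1) = (unsigned) e(i, 1);
  }
  t.elen = as<arma::vec>(tr["elen"]);
  t.ntip = as<int>(tr["ntip"]);
  IntegerMatrix ts = tr["tipstates"];
  t.tipstates.set_size(ts.nrow(), ts.ncol());
  for (int i = 0; i < ts.nrow(); ++i)
    for (int j = 0; j < ts.ncol(); ++j) t.tipstates(i, j) = ts(i, j);
  t.targets = as<arma::ivec>(tr["targets"]);
  t.cnode = as<int>(tr["cnode"]);
  t.cstate = as<int>(tr["cstate"]);
  t.nnode = t.edge.max();
  t.root = t.ntip + 1;
  return t;
}

// P(t) = exp(Qt).  Closed forms for the binary case and for the
// equal-rates (Jukes-Cantor-like) case; scaling-and-squaring otherwise.
static arma::mat pmat(const arma::mat& Q, double t, bool equal_rates) {
  int k = Q.n_rows;
  if (t <= 0.0) return arma::eye(k, k);
  if (k == 2) {
    double a = Q(0, 1), b = Q(1, 0), s = a + b;
    arma::mat P(2, 2);
    if (s <= 0.0) { P.eye(); return P; }
    double e = std::exp(-s * t);
    P(0, 0) = (b + a * e) / s;
    P(0, 1) = (a - a * e) / s;
    P(1, 0) = (b - b * e) / s;
    P(1, 1) = (a + b * e) / s;
    return P;
  }
  if (equal_rates) {
    double q = Q(0, 1);
    double e = std::exp(-k * q * t);
    double stay = 1.0 / k + (k - 1.0) / k * e;
    double move = 1.0 / k * (1.0 - e);
    arma::mat P(k, k);
    P.fill(move);
    P.diag().fill(stay);
    return P;
  }
  return arma::expmat(Q * t);
}

// [[Rcpp::export]]
arma::mat expm_qt(const arma::mat& Q, double t) {
  return pmat(Q, t, false);
}

// Pruning log-likelihood for every character column, with per-node
// rescaling.  Node constraint (if any) masks all but the fixed state just
// before the node's partials are consumed.
static void prune_loglik(const PrepTree& t, const std::vector<arma::mat>& P,
                         const arma::vec& rootf, arma::vec& out) {
  int k = rootf.n_elem;
  int nchar = t.tipstates.n_cols;
  int nedge = t.edge.n_rows;
  arma::mat L(t.nnode + 1, k);
  for (int ch = 0; ch < nchar; ++ch) {
    L.ones();
    for (int i = 1; i <= t.ntip; ++i) {
      L.row(i).zeros();
      L(i, t.tipstates(i - 1, ch)) = 1.0;
    }
    if (t.cnode >= 1 && t.cnode <= t.ntip) {
      // constraining a tip is legal in principle; mask directly
      for (int s = 0; s < k; ++s) if (s != t.cstate) L(t.cnode, s) = 0.0;
    }
    double logscale = 0.0;
    std::vector<bool> masked(t.nnode + 1, false);
    for (int e = 0; e < nedge; ++e) {
      int p = t.edge(e, 0), c = t.edge(e, 1);
      if (c == t.cnode && c > t.ntip && !masked[c]) {
        for (int s = 0; s < k; ++s) if (s != t.cstate) L(c, s) = 0.0;
        masked[c] = true;
      }
      arma::rowvec msg = L.row(c) * P[e].t(); // msg(sp) = sum_sc P(sp,sc) L(c,sc)
      L.row(p) %= msg;
      double m = L.row(p).max();
      if (m <= 0.0) { out(ch) = R_NegInf; goto next_char; }
      if (m < 1e-6) { L.row(p) /= m; logscale += std::log(m); }
    }
    if (t.cnode == t.root) {
      for (int s = 0; s < k; ++s) if (s != t.cstate) L(t.root, s) = 0.0;
    }
    {
      double lik = arma::dot(rootf, L.row(t.root).t());
      out(ch) = (lik > 0.0) ? std::log(lik) + logscale : R_NegInf;
    }
    next_char: ;
  }
}

// Exact marginal state distributions at the target nodes for one character,
// via a down (pruning) pass and an up pass.  Rows are renormalised as we go,
// which is safe because the marginals are normalised at the end.
static arma::mat node_marg(const PrepTree& t, const std::vector<arma::mat>& P,
                           const arma::vec& rootf, int ch) {
  int k = rootf.n_elem;
  int nedge = t.edge.n_rows;
  arma::mat L(t.nnode + 1, k, arma::fill::ones);
  arma::mat M(nedge, k); // per-edge message to the parent
  for (int i = 1; i <= t.ntip; ++i) {
    L.row(i).zeros();
    L(i, t.tipstates(i - 1, ch)) = 1.0;
  }
  for (int e = 0; e < nedge; ++e) {
    int p = t.edge(e, 0), c = t.edge(e, 1);
    arma::rowvec msg = L.row(c) * P[e].t();
    M.row(e) = msg;
    L.row(p) %= msg;
    double m = L.row(p).max();
    if (m > 0.0) L.row(p) /= m;
  }
  // A(v): distribution contribution from everything above v (incl. v's stem)
  arma::mat A(t.nnode + 1, k, arma::fill::zeros);
  A.row(t.root) = rootf.t();
  // group sibling edges by parent for exclusion products
  std::vector<std::vector<int>> child_edges(t.nnode + 1);
  for (int e = 0; e < nedge; ++e) child_edges[t.edge(e, 0)].push_back(e);
  for (int e = nedge - 1; e >= 0; --e) { // reverse postorder = preorder
    int p = t.edge(e, 0), c = t.edge(e, 1);
    arma::rowvec B = A.row(p);
    for (int e2 : child_edges[p]) if (e2 != e) B %= M.row(e2);
    A.row(c) = B * P[e];
    double m = A.row(c).max();
    if (m > 0.0) A.row(c) /= m;
  }
  arma::mat out(t.targets.n_elem, k);
  for (arma::uword i = 0; i < t.targets.n_elem; ++i) {
    int v = t.targets(i);
    arma::rowvec m = A.row(v) % L.row(v);
    out.row(i) = m / arma::accu(m);
  }
  return out;
}

// [[Rcpp::export]]
arma::vec tree_loglik_cpp(const List& tree, const arma::mat& Q,
                          const arma::vec& root_freqs, bool equal_rates) {
  PrepTree t = unpack_tree(tree);
  int nedge = t.edge.n_rows;
  std::vector<arma::mat> P(nedge);
  for (int e = 0; e < nedge; ++e) P[e] = pmat(Q, t.elen(e), equal_rates);
  arma::vec out(t.tipstates.n_cols);
  prune_loglik(t, P, root_freqs, out);
  return out;
}

// [[Rcpp::export]]
arma::mat node_marginals_cpp(const List& tree, const arma::mat& Q,
                             const arma::vec& root_freqs, bool equal_rates,
                             int char_index) {
  PrepTree t = unpack_tree(tree);
  int nedge = t.edge.n_rows;
  std::vector<arma::mat> P(nedge);
  for (int e = 0; e < nedge; ++e) P[e] = pmat(Q, t.elen(e), equal_rates);
  return node_marg(t, P, root_freqs, char_index - 1);
}

static arma::mat build_Q(const arma::imat& pat, const arma::vec& rates) {
  int k = pat.n_rows;
  arma::mat Q(k, k, arma::fill::zeros);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j) Q(i, j) = rates(pat(i, j));
  Q.diag() = -arma::sum(Q, 1);
  return Q;
}

static arma::vec stationary(const arma::mat& Q) {
  int k = Q.n_rows;
  if (k == 2) {
    double a = Q(0, 1), b = Q(1, 0), s = a + b;
    arma::vec pi(2);
    if (s <= 0) { pi.fill(0.5); return pi; }
    pi(0) = b / s; pi(1) = a / s;
    return pi;
  }
  arma::mat ns = arma::null(Q.t());
  arma::vec pi = arma::abs(ns.col(0));
  return pi / arma::accu(pi);
}

static double reflect(double x, double lo, double hi) {
  double w = hi - lo;
  while (x < lo || x > hi) {
    if (x < lo) x = 2.0 * lo - x;
    if (x > hi) x = 2.0 * hi - x;
  }
  (void) w;
  return x;
}

static double total_loglik(const PrepTree& t, const arma::mat& Q,
                           const arma::vec& rootf, bool equal_rates,
                           const arma::vec& wts, arma::vec& scratch) {
  int nedge = t.edge.n_rows;
  std::vector<arma::mat> P(nedge);
  for (int e = 0; e < nedge; ++e) P[e] = pmat(Q, t.elen(e), equal_rates);
  prune_loglik(t, P, rootf, scratch);
  return arma::dot(wts, scratch);
}

// Random-scan Metropolis over free rates with uniform prior U(lower, upper),
// sliding-window proposals reflected at the bounds, and a fresh tree drawn
// uniformly from the sample as part of each proposal.  `beta` tempers the
// likelihood (power posterior); raw lnL is always recorded.  Window widths
// adapt toward acceptance 0.2-0.4 during burn-in, then freeze.
// [[Rcpp::export]]
List mk_mcmc_cpp(const List& trees, const arma::imat& rate_pat, int n_free,
                 double lower, double upper, const arma::vec& root_freqs,
                 bool root_equilibrium, double beta, int generations,
                 int thin, int burnin, const arma::vec& init_rates,
                 const arma::vec& init_window, bool adapt,
                 bool record_marginals, const arma::vec& char_weights) {
  RNGScope scope;
  int ntrees = trees.size();
  std::vector<PrepTree> tv(ntrees);
  for (int i = 0; i < ntrees; ++i) tv[i] = unpack_tree(trees[i]);
  int k = rate_pat.n_rows;
  int nchar = tv[0].tipstates.n_cols;
  int n_targets = tv[0].targets.n_elem;
  bool equal_rates = (n_free == 1);
  arma::vec wts = char_weights;
  arma::vec scratch(nchar);

  arma::vec rates = init_rates;
  arma::vec window = init_window;
  arma::mat Q = build_Q(rate_pat, rates);
  arma::vec rootf = root_equilibrium ? stationary(Q) : root_freqs;
  int tree_idx = (int) std::floor(unif_rand() * ntrees);
  if (tree_idx >= ntrees) tree_idx = ntrees - 1;
  double lnL = total_loglik(tv[tree_idx], Q, rootf, equal_rates, wts, scratch);

  int nsamp = 0;
  for (int g = burnin + 1; g <= generations; ++g) if (g % thin == 0) ++nsamp;
  arma::mat out_rates(nsamp, n_free);
  arma::vec out_lnL(nsamp);
  arma::ivec out_tree(nsamp);
  arma::cube out_marg;
  if (record_marginals && n_targets > 0)
    out_marg.set_size(nsamp, n_targets, k);

  arma::ivec acc(n_free, arma::fill::zeros), tries(n_free, arma::fill::zeros);
  long acc_total = 0;
  int isamp = 0;
  const int adapt_interval = 50;

  for (int g = 1; g <= generations; ++g) {
    int j = (int) std::floor(unif_rand() * n_free);
    if (j >= n_free) j = n_free - 1;
    arma::vec prop = rates;
    prop(j) = reflect(prop(j) + (unif_rand() - 0.5) * window(j), lower, upper);
    int tprop = (int) std::floor(unif_rand() * ntrees);
    if (tprop >= ntrees) tprop = ntrees - 1;
    arma::mat Qp = build_Q(rate_pat, prop);
    arma::vec rfp = root_equilibrium ? stationary(Qp) : root_freqs;
    double lnLp = total_loglik(tv[tprop], Qp, rfp, equal_rates, wts, scratch);
    ++tries(j);
    double lr = beta * (lnLp - lnL);
    if (lr >= 0.0 || unif_rand() < std::exp(lr)) {
      rates = prop; Q = Qp; rootf = rfp; lnL = lnLp; tree_idx = tprop;
      ++acc(j); ++acc_total;
    }
    if (adapt && g <= burnin && g % adapt_interval == 0) {
      for (int r = 0; r < n_free; ++r) {
        if (tries(r) == 0) continue;
        double ar = (double) acc(r) / tries(r);
        if (ar > 0.4) window(r) = std::min(window(r) * 1.2, upper - lower);
        else if (ar < 0.2) window(r) *= 0.7;
        acc(r) = 0; tries(r) = 0;
      }
    }
    if (g > burnin && g % thin == 0) {
      out_rates.row(isamp) = rates.t();
      out_lnL(isamp) = lnL;
      out_tree(isamp) = tree_idx + 1;
      if (record_marginals && n_targets > 0) {
        const PrepTree& t = tv[tree_idx];
        int nedge = t.edge.n_rows;
        std::vector<arma::mat> P(nedge);
        for (int e = 0; e < nedge; ++e)
          P[e] = pmat(Q, t.elen(e), equal_rates);
        arma::mat m = node_marg(t, P, rootf, 0);
        for (int a = 0; a < n_targets; ++a)
          for (int s = 0; s < k; ++s) out_marg(isamp, a, s) = m(a, s);
      }
      ++isamp;
    }
  }
  double accept_rate = (double) acc_total / generations;
  List res = List::create(
    _["rates"] = out_rates, _["lnL"] = out_lnL, _["tree_index"] = out_tree,
    _["window"] = window, _["final_rates"] = rates,
    _["accept_rate"] = accept_rate);
  if (record_marginals && n_targets > 0) res["marginals"] = out_marg;
  return res;
}
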