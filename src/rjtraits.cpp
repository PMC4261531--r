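// Core numerics: CTMC transition probabilities, Felsenstein pruning with
// per-node rescaling, and the reversible-jump MCMC over rate-class
// partitions (including a structural-zero bin).
//
// State space of the sampler: a set partition of the named rates into
// positive-value classes plus a distinguished (possibly empty) zero bin,
// with one positive value per class.  The model prior is uniform over
// these (partition, zero-set) configurations; class values carry the
// rate prior (uniform or gamma under a hyperprior).  All Metropolis-
// Hastings ratios below are derived for proposal densities on that
// quotient space, so the chain's marginal over configurations is exact.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Transition probabilities
// ---------------------------------------------------------------------------

// Holds a spectral factorisation of Q so that P(t) over many branch
// lengths costs one small complex product each.  Falls back to
// scaling-and-squaring (arma::expmat) when Q is defective.
struct QExp {
  int ns;
  bool closed2;      // 2-state closed form
  double a, b;       // 2-state rates: a = q01, b = q10
  bool spectral;     // eigendecomposition valid
  arma::cx_mat V, Vinv;
  arma::cx_vec lam;
  arma::mat Q;

  void init(const arma::mat& Qin) {
    Q = Qin;
    ns = Q.n_rows;
    closed2 = (ns == 2);
    spectral = false;
    if (closed2) {
      a = Q(0, 1);
      b = Q(1, 0);
      return;
    }
    arma::cx_vec ev;
    arma::cx_mat evec;
    bool ok = arma::eig_gen(ev, evec, Q);
    if (ok) {
      arma::cx_mat vinv;
      ok = arma::inv(vinv, evec);
      if (ok) {
        // reject the factorisation when reconstruction is poor (defective Q)
        arma::mat rec = arma::real(evec * arma::diagmat(ev) * vinv);
        double scale = std::max(1.0, arma::norm(Q, "inf"));
        if (arma::norm(rec - Q, "inf") < 1e-9 * scale) {
          V = evec; Vinv = vinv; lam = ev;
          spectral = true;
        }
      }
    }
  }

  arma::mat P(double t) const {
    if (closed2) {
      arma::mat out(2, 2);
      double s = a + b;
      if (s <= 0.0) { out.eye(); return out; }
      double e = std::exp(-s * t);
      out(0, 0) = (b + a * e) / s; out(0, 1) = 1.0 - out(0, 0);
      out(1, 0) = (b - b * e) / s; out(1, 1) = 1.0 - out(1, 0);
      return out;
    }
    arma::mat out;
    if (spectral) {
      arma::cx_vec elt = arma::exp(lam * t);
      out = arma::real(V * arma::diagmat(elt) * Vinv);
    } else {
      out = arma::expmat(Q * t);
    }
    // clip tiny negative round-off
    out.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    return out;
  }
};

// [[Rcpp::export]]
arma::mat trans_mat_cpp(const arma::mat& Q, double t) {
  if (t < 0) stop("branch length t must be >= 0");
  QExp qe;
  qe.init(Q);
  return qe.P(t);
}

// ---------------------------------------------------------------------------
// Pruning likelihood
// ---------------------------------------------------------------------------

// Plain-struct view of one preprocessed tree (edges in postorder).
struct TreeC {
  arma::imat edge;   // E x 2, 0-based (parent, child), postorder
  arma::vec len;
  int ntip, nnode, root;
  arma::mat tip;     // ntip x ns partial-likelihood rows
};

static TreeC tree_from_list(const List& tr) {
  TreeC t;
  IntegerMatrix e = tr["edge"];
  t.edge.set_size(e.nrow(), 2);
  for (int i = 0; i < e.nrow(); ++i) {
    t.edge(i, 0) = e(i, 0) - 1;
    t.edge(i, 1) = e(i, 1) - 1;
  }
  t.len = as<arma::vec>(tr["len"]);
  t.ntip = as<int>(tr["ntip"]);
  t.nnode = as<int>(tr["nnode"]);
  t.root = as<int>(tr["root"]) - 1;
  t.tip = as<arma::mat>(tr["tip"]);
  return t;
}

// log-likelihood by pruning; clamp_node (0-based, -1 = none) restricts the
// marginal state at one node to clamp_state.
static double prune_ll(const TreeC& tr, const QExp& qe,
                       const arma::vec& rootp,
                       int clamp_node = -1, int clamp_state = -1) {
  int ns = rootp.n_elem;
  arma::mat part(tr.nnode, ns);
  part.rows(0, tr.ntip - 1) = tr.tip;
  if (tr.nnode > tr.ntip)
    part.rows(tr.ntip, tr.nnode - 1).ones();
  double logscale = 0.0;
  for (arma::uword i = 0; i < tr.edge.n_rows; ++i) {
    int par = tr.edge(i, 0), chi = tr.edge(i, 1);
    arma::vec v = part.row(chi).t();
    if (chi == clamp_node) {
      arma::vec mask(ns, arma::fill::zeros);
      mask(clamp_state) = 1.0;
      v %= mask;
    }
    double mx = v.max();
    if (mx <= 0.0) return -arma::datum::inf;
    v /= mx;
    logscale += std::log(mx);
    arma::vec msg = qe.P(tr.len(i)) * v;
    part.row(par) %= msg.t();
  }
  arma::vec v = part.row(tr.root).t();
  if (tr.root == clamp_node) {
    arma::vec mask(ns, arma::fill::zeros);
    mask(clamp_state) = 1.0;
    v %= mask;
  }
  double L = arma::dot(rootp, v);
  if (L <= 0.0) return -arma::datum::inf;
  return std::log(L) + logscale;
}

// [[Rcpp::export]]
double prune_ll_cpp(const List& tree, const arma::mat& Q,
                    const arma::vec& rootp,
                    int clamp_node = -1, int clamp_state = -1) {
  TreeC tr = tree_from_list(tree);
  QExp qe;
  qe.init(Q);
  int cn = clamp_node >= 1 ? clamp_node - 1 : -1;
  int cs = clamp_state >= 1 ? clamp_state - 1 : -1;
  return prune_ll(tr, qe, rootp, cn, cs);
}

// Marginal state probabilities at one node by clamped pruning.
// [[Rcpp::export]]
arma::vec node_probs_cpp(const List& tree, const arma::mat& Q,
                         const arma::vec& rootp, int node) {
  TreeC tr = tree_from_list(tree);
  QExp qe;
  qe.init(Q);
  int ns = rootp.n_elem;
  arma::vec ll(ns);
  for (int s = 0; s < ns; ++s)
    ll(s) = prune_ll(tr, qe, rootp, node - 1, s);
  double mx = ll.max();
  if (!std::isfinite(mx)) stop("all clamped likelihoods are zero");
  arma::vec w = arma::exp(ll - mx);
  return w / arma::accu(w);
}

// ---------------------------------------------------------------------------
// Reversible-jump sampler
// ---------------------------------------------------------------------------

struct RjState {
  arma::ivec assign;            // per rate: 0 = zero bin, else class id 1..k
  std::vector<double> vals;     // class values, vals[j-1] for class j
  int k() const { return (int)vals.size(); }
  int tree_idx;                 // 0-based
  double ll;
  double hmean, hshape;         // gamma hyperprior parameters
};

struct PriorC {
  int kind;                     // 0 uniform, 1 gamma hyperprior
  double lo, hi;                // uniform bounds
  double hyper_max;             // upper bound for gamma mean and shape
};

static double prior_draw(const PriorC& pr, const RjState& st) {
  if (pr.kind == 0) return R::runif(pr.lo, pr.hi);
  return R::rgamma(st.hshape, st.hmean / st.hshape);
}

static double prior_dens(const PriorC& pr, const RjState& st, double v) {
  if (pr.kind == 0)
    return (v > pr.lo && v <= pr.hi) ? 1.0 / (pr.hi - pr.lo) : 0.0;
  return R::dgamma(v, st.hshape, st.hmean / st.hshape, 0);
}

static arma::mat build_Q(const RjState& st, const arma::imat& rate_map) {
  int ns = rate_map.n_rows;
  arma::mat Q(ns, ns, arma::fill::zeros);
  for (int i = 0; i < ns; ++i) {
    double rs = 0.0;
    for (int j = 0; j < ns; ++j) {
      if (i == j) continue;
      int r = rate_map(i, j);
      if (r >= 0) {
        int a = st.assign(r);
        double v = (a == 0) ? 0.0 : st.vals[a - 1];
        Q(i, j) = v;
        rs += v;
      }
    }
    Q(i, i) = -rs;
  }
  return Q;
}

// [[Rcpp::export]]
List rjmcmc_cpp(const List& trees, const arma::imat& rate_map, int n_rates,
                const List& prior, const arma::vec& rootp,
                int iters, int burnin, int thin,
                double ratedev0, double target_acc, int tune_interval,
                bool likelihood_on) {
  int ntrees = trees.size();
  std::vector<TreeC> trs(ntrees);
  for (int i = 0; i < ntrees; ++i)
    trs[i] = tree_from_list(trees[i]);

  PriorC pr;
  std::string pk = as<std::string>(prior["kind"]);
  pr.kind = (pk == "gamma") ? 1 : 0;
  pr.lo = as<double>(prior["lo"]);
  pr.hi = as<double>(prior["hi"]);
  pr.hyper_max = as<double>(prior["hyper_max"]);

  RjState st;
  st.assign = arma::ivec(n_rates, arma::fill::ones);  // one class holds all
  st.vals.assign(1, 1.0);
  st.tree_idx = 0;
  st.hmean = 1.0;
  st.hshape = 1.0;

  auto loglik = [&](const RjState& s, int ti) -> double {
    if (!likelihood_on) return 0.0;
    arma::mat Q = build_Q(s, rate_map);
    QExp qe;
    qe.init(Q);
    return prune_ll(trs[ti], qe, rootp, -1, -1);
  };

  st.ll = loglik(st, st.tree_idx);
  if (likelihood_on && !std::isfinite(st.ll)) {
    st.vals[0] = 0.1;
    st.ll = loglik(st, st.tree_idx);
    if (!std::isfinite(st.ll))
      stop("non-finite log-likelihood at initialization");
  }

  // move-type probabilities (constant across states)
  double w_val = 0.45, w_sm = 0.20, w_zero = 0.20,
         w_tree = (ntrees > 1) ? 0.10 : 0.0,
         w_hyp = (pr.kind == 1) ? 0.05 : 0.0;
  double w_tot = w_val + w_sm + w_zero + w_tree + w_hyp;

  double ratedev = ratedev0;
  double hyperdev = 0.75;
  int n_out = (iters > burnin) ? (iters - burnin) / thin : 0;
  arma::mat out_rates(n_out, n_rates);
  arma::imat out_zero(n_out, n_rates);
  arma::vec out_ll(n_out);
  arma::ivec out_tree(n_out), out_k(n_out);
  arma::vec out_hmean(n_out), out_hshape(n_out);
  arma::vec out_ratedev(n_out);

  long acc_win = 0, att_win = 0;   // value-move window for tuning
  long acc_all = 0, att_all = 0;

  RNGScope scope;
  int row = 0;
  for (int it = 1; it <= iters; ++it) {
    double u = R::runif(0.0, w_tot);
    if (u < w_val) {
      // ---- perturb one class value (sliding window) ----
      int k = st.k();
      if (k >= 1) {
        att_win++; att_all++;
        int j = (int)std::floor(R::runif(0.0, 1.0) * k);
        if (j >= k) j = k - 1;
        double v = st.vals[j];
        double v2 = v + ratedev * (R::runif(0.0, 1.0) - 0.5);
        bool ok = (pr.kind == 0) ? (v2 > pr.lo && v2 <= pr.hi) : (v2 > 0.0);
        if (ok) {
          RjState cand = st;
          cand.vals[j] = v2;
          double cll = loglik(cand, cand.tree_idx);
          double lr = likelihood_on ? std::exp(cll - st.ll) : 1.0;
          double prr = (pr.kind == 0)
              ? 1.0 : prior_dens(pr, st, v2) / prior_dens(pr, st, v);
          if (R::runif(0.0, 1.0) < lr * prr) {
            st = cand; st.ll = cll;
            acc_win++; acc_all++;
          }
        }
      }
    } else if (u < w_val + w_sm) {
      // ---- split / merge ----
      if (R::runif(0.0, 1.0) < 0.5) {
        // split one class into two; new class value drawn from the prior
        int k = st.k();
        if (k >= 1) {
          int j = (int)std::floor(R::runif(0.0, 1.0) * k);
          if (j >= k) j = k - 1;
          std::vector<int> mem;
          for (int r = 0; r < n_rates; ++r)
            if (st.assign(r) == j + 1) mem.push_back(r);
          int m = (int)mem.size();
          if (m >= 2) {
            long ncode = (1L << m) - 2;
            long code = 1 + (long)std::floor(R::runif(0.0, 1.0) * ncode);
            if (code > ncode) code = ncode;
            RjState cand = st;
            double vnew = prior_draw(pr, st);
            cand.vals.push_back(vnew);
            for (int b = 0; b < m; ++b)
              if ((code >> b) & 1L) cand.assign(mem[b]) = k + 1;
            double cll = loglik(cand, cand.tree_idx);
            double lr = likelihood_on ? std::exp(cll - st.ll) : 1.0;
            double A = lr * (double)ncode / (double)(k + 1);
            if (R::runif(0.0, 1.0) < A) { st = cand; st.ll = cll; }
          }
        }
      } else {
        // merge: absorb class j2 into j1 (keeps j1's value)
        int k = st.k();
        if (k >= 2) {
          int j1 = (int)std::floor(R::runif(0.0, 1.0) * k);
          if (j1 >= k) j1 = k - 1;
          int j2 = (int)std::floor(R::runif(0.0, 1.0) * (k - 1));
          if (j2 >= k - 1) j2 = k - 2;
          if (j2 >= j1) j2++;
          int m1 = 0, m2 = 0;
          for (int r = 0; r < n_rates; ++r) {
            if (st.assign(r) == j1 + 1) m1++;
            if (st.assign(r) == j2 + 1) m2++;
          }
          int ms = m1 + m2;
          long ncode = (1L << ms) - 2;
          RjState cand = st;
          for (int r = 0; r < n_rates; ++r)
            if (cand.assign(r) == j2 + 1) cand.assign(r) = j1 + 1;
          // compact: relabel last class into slot j2
          if (j2 + 1 != k) {
            for (int r = 0; r < n_rates; ++r)
              if (cand.assign(r) == k) cand.assign(r) = j2 + 1;
            cand.vals[j2] = cand.vals[k - 1];
          }
          cand.vals.pop_back();
          double cll = loglik(cand, cand.tree_idx);
          double lr = likelihood_on ? std::exp(cll - st.ll) : 1.0;
          double A = lr * (double)k / (double)ncode;
          if (R::runif(0.0, 1.0) < A) { st = cand; st.ll = cll; }
        }
      }
    } else if (u < w_val + w_sm + w_zero) {
      // ---- move one rate into / out of the zero bin ----
      int r = (int)std::floor(R::runif(0.0, 1.0) * n_rates);
      if (r >= n_rates) r = n_rates - 1;
      int k = st.k();
      if (st.assign(r) > 0) {
        int j = st.assign(r) - 1;
        int m = 0;
        for (int q = 0; q < n_rates; ++q)
          if (st.assign(q) == j + 1) m++;
        RjState cand = st;
        cand.assign(r) = 0;
        double A_mult;
        if (m == 1) {
          // class vanishes with its value
          if (j + 1 != k) {
            for (int q = 0; q < n_rates; ++q)
              if (cand.assign(q) == k) cand.assign(q) = j + 1;
            cand.vals[j] = cand.vals[k - 1];
          }
          cand.vals.pop_back();
          A_mult = 1.0 / (double)k;
        } else {
          A_mult = 1.0 / (double)(k + 1);
        }
        double cll = loglik(cand, cand.tree_idx);
        double lr = likelihood_on ? std::exp(cll - st.ll) : 1.0;
        if (R::runif(0.0, 1.0) < lr * A_mult) { st = cand; st.ll = cll; }
      } else {
        // zero -> one of k existing classes or a fresh class
        int dest = (int)std::floor(R::runif(0.0, 1.0) * (k + 1));
        if (dest > k) dest = k;
        RjState cand = st;
        if (dest == k) {
          cand.vals.push_back(prior_draw(pr, st));
          cand.assign(r) = k + 1;
        } else {
          cand.assign(r) = dest + 1;
        }
        double cll = loglik(cand, cand.tree_idx);
        double lr = likelihood_on ? std::exp(cll - st.ll) : 1.0;
        if (R::runif(0.0, 1.0) < lr * (double)(k + 1)) { st = cand; st.ll = cll; }
      }
    } else if (u < w_val + w_sm + w_zero + w_tree) {
      // ---- resample the tree index ----
      int ti = (int)std::floor(R::runif(0.0, 1.0) * ntrees);
      if (ti >= ntrees) ti = ntrees - 1;
      if (ti != st.tree_idx) {
        double cll = loglik(st, ti);
        double lr = likelihood_on ? std::exp(cll - st.ll) : 1.0;
        if (R::runif(0.0, 1.0) < lr) { st.tree_idx = ti; st.ll = cll; }
      }
    } else {
      // ---- gamma hyperprior update (mean, shape) ----
      double m2 = st.hmean + hyperdev * (R::runif(0.0, 1.0) - 0.5);
      double s2 = st.hshape + hyperdev * (R::runif(0.0, 1.0) - 0.5);
      if (m2 > 0.0 && m2 <= pr.hyper_max && s2 > 0.0 && s2 <= pr.hyper_max) {
        double lr = 0.0;
        for (int j = 0; j < st.k(); ++j) {
          lr += R::dgamma(st.vals[j], s2, m2 / s2, 1)
              - R::dgamma(st.vals[j], st.hshape, st.hmean / st.hshape, 1);
        }
        if (std::log(R::runif(0.0, 1.0)) < lr) {
          st.hmean = m2; st.hshape = s2;
        }
      }
    }

    // ratedev autotuning: burn-in only, multiplicative update
    if (it <= burnin && it % tune_interval == 0 && att_win > 0) {
      double obs = (double)acc_win / (double)att_win;
      ratedev *= std::exp(obs - target_acc);
      if (ratedev < 1e-6) ratedev = 1e-6;
      if (ratedev > 1e6) ratedev = 1e6;
      acc_win = 0; att_win = 0;
    }

    if (it > burnin && (it - burnin) % thin == 0 && row < n_out) {
      for (int r = 0; r < n_rates; ++r) {
        int a = st.assign(r);
        out_rates(row, r) = (a == 0) ? 0.0 : st.vals[a - 1];
        out_zero(row, r) = (a == 0) ? 1 : 0;
      }
      out_ll(row) = st.ll;
      out_tree(row) = st.tree_idx + 1;
      out_k(row) = st.k();
      out_hmean(row) = st.hmean;
      out_hshape(row) = st.hshape;
      out_ratedev(row) = ratedev;
      row++;
    }
  }

  double acc_rate = (att_all > 0) ? (double)acc_all / (double)att_all
                                  : NA_REAL;
  return List::create(
      _["rates"] = out_rates, _["zero"] = out_zero, _["logL"] = out_ll,
      _["tree_index"] = out_tree, _["n_classes"] = out_k,
      _["hyper_mean"] = out_hmean, _["hyper_shape"] = out_hshape,
      _["ratedev"] = out_ratedev, _["final_ratedev"] = ratedev,
      _["acceptance"] = acc_rate);
}
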