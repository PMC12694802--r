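// Sum-of-trees (BART) backfitting MCMC.
//
// Model: z_i = sum_j g(x_i; T_j, M_j) + e_i, e_i ~ N(0, sigma^2), with the
// regularization prior of the BART literature: P(split at depth d) =
// alpha (1+d)^-beta, split rules uniform over (variable, cutpoint-grid),
// leaf values mu ~ N(0, sigma_mu^2), sigma^2 ~ nu*lambda / chi^2_nu.
// Each sweep updates every tree by one Metropolis-Hastings move
// (grow/prune/change/swap) on the leaf-marginalized likelihood of its
// partial residuals, then redraws leaf values from their normal full
// conditionals, then redraws sigma^2 from its scaled-inverse-chi^2 full
// conditional. Proposals that would create an empty leaf are rejected, so
// the chain targets the posterior restricted to trees whose leaves all
// contain data; the uniform rule prior then cancels from the change and
// swap ratios and from the grow/prune rule factor.
//
// All randomness comes from R's RNG, so runs are reproducible under
// set.seed() and retained draws are a prefix-stable stream.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Node {
  int var;      // -1 for leaf
  double cut;
  int l, r, parent;
  double mu;
  bool active;
};

struct Tree {
  std::vector<Node> nodes;
  std::vector<int> free_list;

  Tree() { nodes.push_back(Node{-1, 0.0, -1, -1, -1, 0.0, true}); }

  int alloc() {
    if (!free_list.empty()) {
      int id = free_list.back();
      free_list.pop_back();
      nodes[id].active = true;
      return id;
    }
    nodes.push_back(Node{-1, 0.0, -1, -1, -1, 0.0, true});
    return (int)nodes.size() - 1;
  }
  void release(int id) {
    nodes[id].active = false;
    free_list.push_back(id);
  }
  int depth(int id) const {
    int d = 0;
    while (nodes[id].parent >= 0) { id = nodes[id].parent; ++d; }
    return d;
  }
  bool is_leaf(int id) const { return nodes[id].var < 0; }
  bool is_nog(int id) const {  // internal node with two leaf children
    return nodes[id].active && !is_leaf(id) &&
           is_leaf(nodes[id].l) && is_leaf(nodes[id].r);
  }
  void collect_leaves(std::vector<int> &out) const {
    out.clear();
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (nodes[i].active && is_leaf(i)) out.push_back(i);
  }
  void collect_nogs(std::vector<int> &out) const {
    out.clear();
    for (int i = 0; i < (int)nodes.size(); ++i)
      if (is_nog(i)) out.push_back(i);
  }
};

double leaf_log_marg(double n, double sr, double sr2, double s2, double t2) {
  if (n <= 0) return 0.0;
  return -0.5 * n * std::log(2.0 * M_PI * s2)
       + 0.5 * std::log(s2 / (s2 + n * t2))
       - sr2 / (2.0 * s2)
       + t2 * sr * sr / (2.0 * s2 * (s2 + n * t2));
}

struct LeafStat { double n = 0, sr = 0, sr2 = 0; };

int runif_int(int k) {  // uniform on 0..k-1
  int v = (int)std::floor(unif_rand() * k);
  return v >= k ? k - 1 : v;
}

struct Sampler {
  const NumericMatrix &X;
  const std::vector<double> &z;
  int n, p, m;
  double alpha, beta, sigma_mu2, nu, lambda;
  double p_grow, p_prune, p_change, p_swap;
  const std::vector<std::vector<double>> &cuts;
  double sigma2;

  std::vector<Tree> trees;
  std::vector<std::vector<int>> leaf_of;   // per tree: obs -> node id
  std::vector<std::vector<double>> fit;    // per tree: obs -> leaf mu
  std::vector<double> total_fit;
  std::vector<double> resid;               // workspace: partial residuals
  std::vector<double> split_counts;        // tallies over retained draws
  std::vector<double> db_grow, db_prune;   // detailed-balance trace pairs

  Sampler(const NumericMatrix &X_, const std::vector<double> &z_, int m_,
          double alpha_, double beta_, double sigma_mu_, double nu_,
          double lambda_, double sigma_init, NumericVector move_probs,
          const std::vector<std::vector<double>> &cuts_)
      : X(X_), z(z_), n((int)z_.size()), p(X_.ncol()), m(m_), alpha(alpha_),
        beta(beta_), sigma_mu2(sigma_mu_ * sigma_mu_), nu(nu_),
        lambda(lambda_), p_grow(move_probs[0]), p_prune(move_probs[1]),
        p_change(move_probs[2]), p_swap(move_probs[3]), cuts(cuts_),
        sigma2(sigma_init * sigma_init) {
    trees.resize(m);
    leaf_of.assign(m, std::vector<int>(n, 0));
    fit.assign(m, std::vector<double>(n, 0.0));
    total_fit.assign(n, 0.0);
    resid.resize(n);
    split_counts.assign(p, 0.0);
  }

  double psplit(int d) const { return alpha * std::pow(1.0 + d, -beta); }

  // stats of partial residuals per node of tree j (indexed by node id)
  void node_stats(int j, std::vector<LeafStat> &st) const {
    st.assign(trees[j].nodes.size(), LeafStat());
    for (int i = 0; i < n; ++i) {
      LeafStat &s = st[leaf_of[j][i]];
      s.n += 1; s.sr += resid[i]; s.sr2 += resid[i] * resid[i];
    }
  }

  void propose_grow(int j, bool trace) {
    Tree &t = trees[j];
    std::vector<int> leaves;
    t.collect_leaves(leaves);
    int L = (int)leaves.size();
    int leaf = leaves[runif_int(L)];
    int var = runif_int(p);
    const std::vector<double> &cv = cuts[var];
    double cut = cv[runif_int((int)cv.size())];
    double u = unif_rand();  // acceptance draw taken unconditionally

    LeafStat sl, srt, sa;
    for (int i = 0; i < n; ++i) {
      if (leaf_of[j][i] != leaf) continue;
      double r = resid[i];
      sa.n += 1; sa.sr += r; sa.sr2 += r * r;
      if (X(i, var) <= cut) { sl.n += 1; sl.sr += r; sl.sr2 += r * r; }
      else { srt.n += 1; srt.sr += r; srt.sr2 += r * r; }
    }
    if (sl.n == 0 || srt.n == 0) return;  // empty child: auto-reject

    int d = t.depth(leaf);
    double ll = leaf_log_marg(sl.n, sl.sr, sl.sr2, sigma2, sigma_mu2)
              + leaf_log_marg(srt.n, srt.sr, srt.sr2, sigma2, sigma_mu2)
              - leaf_log_marg(sa.n, sa.sr, sa.sr2, sigma2, sigma_mu2);
    double lprior = std::log(psplit(d)) + 2.0 * std::log1p(-psplit(d + 1))
                  - std::log1p(-psplit(d));
    std::vector<int> nogs;
    t.collect_nogs(nogs);
    int parent = t.nodes[leaf].parent;
    int nog_after = (int)nogs.size() + 1 -
                    ((parent >= 0 && t.is_nog(parent)) ? 1 : 0);
    double logr = ll + lprior + std::log(p_prune) + std::log((double)L)
                - std::log(p_grow) - std::log((double)nog_after);
    if (trace) {
      // reversing prune on the would-be tree, via the prune formula
      double rev = prune_log_ratio_terms(sl, srt, sa, d, nog_after, L);
      db_grow.push_back(logr);
      db_prune.push_back(rev);
    }
    if (std::log(u) < logr) {
      int l = t.alloc(), r = t.alloc();
      t.nodes[l].parent = leaf; t.nodes[r].parent = leaf;
      t.nodes[l].var = -1; t.nodes[r].var = -1;
      t.nodes[l].mu = t.nodes[leaf].mu; t.nodes[r].mu = t.nodes[leaf].mu;
      t.nodes[leaf].var = var; t.nodes[leaf].cut = cut;
      t.nodes[leaf].l = l; t.nodes[leaf].r = r;
      for (int i = 0; i < n; ++i) {
        if (leaf_of[j][i] == leaf)
          leaf_of[j][i] = (X(i, var) <= cut) ? l : r;
      }
    }
  }

  // MH log-ratio of pruning a nog node at depth d whose children have stats
  // sl/sr (merged sa), where the current tree has n_nog nog nodes and the
  // pruned tree would have n_leaves_after leaves.
  double prune_log_ratio_terms(const LeafStat &sl, const LeafStat &sr,
                               const LeafStat &sa, int d, int n_nog,
                               int n_leaves_after) const {
    double ll = leaf_log_marg(sa.n, sa.sr, sa.sr2, sigma2, sigma_mu2)
              - leaf_log_marg(sl.n, sl.sr, sl.sr2, sigma2, sigma_mu2)
              - leaf_log_marg(sr.n, sr.sr, sr.sr2, sigma2, sigma_mu2);
    double lprior = -(std::log(psplit(d)) + 2.0 * std::log1p(-psplit(d + 1))
                      - std::log1p(-psplit(d)));
    return ll + lprior + std::log(p_grow) + std::log((double)n_nog)
         - std::log(p_prune) - std::log((double)n_leaves_after);
  }

  void propose_prune(int j) {
    Tree &t = trees[j];
    std::vector<int> nogs;
    t.collect_nogs(nogs);
    if (nogs.empty()) return;
    int node = nogs[runif_int((int)nogs.size())];
    double u = unif_rand();
    int l = t.nodes[node].l, r = t.nodes[node].r;
    LeafStat sl, sr, sa;
    for (int i = 0; i < n; ++i) {
      int lf = leaf_of[j][i];
      if (lf != l && lf != r) continue;
      double rr = resid[i];
      sa.n += 1; sa.sr += rr; sa.sr2 += rr * rr;
      if (lf == l) { sl.n += 1; sl.sr += rr; sl.sr2 += rr * rr; }
      else { sr.n += 1; sr.sr += rr; sr.sr2 += rr * rr; }
    }
    std::vector<int> leaves;
    t.collect_leaves(leaves);
    int n_leaves_after = (int)leaves.size() - 1;
    double logr = prune_log_ratio_terms(sl, sr, sa, t.depth(node),
                                        (int)nogs.size(), n_leaves_after);
    if (std::log(u) < logr) {
      for (int i = 0; i < n; ++i) {
        int lf = leaf_of[j][i];
        if (lf == l || lf == r) leaf_of[j][i] = node;
      }
      t.nodes[node].mu = t.nodes[l].mu;
      t.nodes[node].var = -1; t.nodes[node].l = -1; t.nodes[node].r = -1;
      t.release(l); t.release(r);
    }
  }

  void propose_change(int j) {
    Tree &t = trees[j];
    std::vector<int> nogs;
    t.collect_nogs(nogs);
    if (nogs.empty()) return;
    int node = nogs[runif_int((int)nogs.size())];
    int var = runif_int(p);
    const std::vector<double> &cv = cuts[var];
    double cut = cv[runif_int((int)cv.size())];
    double u = unif_rand();
    int l = t.nodes[node].l, r = t.nodes[node].r;
    LeafStat ol, orr, nl, nr;
    for (int i = 0; i < n; ++i) {
      int lf = leaf_of[j][i];
      if (lf != l && lf != r) continue;
      double rr = resid[i];
      if (lf == l) { ol.n += 1; ol.sr += rr; ol.sr2 += rr * rr; }
      else { orr.n += 1; orr.sr += rr; orr.sr2 += rr * rr; }
      if (X(i, var) <= cut) { nl.n += 1; nl.sr += rr; nl.sr2 += rr * rr; }
      else { nr.n += 1; nr.sr += rr; nr.sr2 += rr * rr; }
    }
    if (nl.n == 0 || nr.n == 0) return;  // empty child: auto-reject
    double logr =
        leaf_log_marg(nl.n, nl.sr, nl.sr2, sigma2, sigma_mu2)
      + leaf_log_marg(nr.n, nr.sr, nr.sr2, sigma2, sigma_mu2)
      - leaf_log_marg(ol.n, ol.sr, ol.sr2, sigma2, sigma_mu2)
      - leaf_log_marg(orr.n, orr.sr, orr.sr2, sigma2, sigma_mu2);
    if (std::log(u) < logr) {
      t.nodes[node].var = var; t.nodes[node].cut = cut;
      for (int i = 0; i < n; ++i) {
        int lf = leaf_of[j][i];
        if (lf == l || lf == r)
          leaf_of[j][i] = (X(i, var) <= cut) ? l : r;
      }
    }
  }

  // descend from `root` of tree t with current rules; return leaf id
  int descend(const Tree &t, int root, int i) const {
    int id = root;
    while (t.nodes[id].var >= 0)
      id = (X(i, t.nodes[id].var) <= t.nodes[id].cut) ? t.nodes[id].l
                                                      : t.nodes[id].r;
    return id;
  }

  void propose_swap(int j) {
    Tree &t = trees[j];
    std::vector<std::pair<int, int>> pairs;  // (parent, internal child)
    for (int i = 0; i < (int)t.nodes.size(); ++i) {
      if (!t.nodes[i].active || t.is_leaf(i)) continue;
      if (!t.is_leaf(t.nodes[i].l)) pairs.push_back({i, t.nodes[i].l});
      if (!t.is_leaf(t.nodes[i].r)) pairs.push_back({i, t.nodes[i].r});
    }
    if (pairs.empty()) return;
    std::pair<int, int> pc = pairs[runif_int((int)pairs.size())];
    double u = unif_rand();
    int a = pc.first, b = pc.second;

    // subtree membership under `a`
    std::vector<char> in_sub(t.nodes.size(), 0);
    std::vector<int> stack{a};
    while (!stack.empty()) {
      int id = stack.back(); stack.pop_back();
      in_sub[id] = 1;
      if (!t.is_leaf(id)) { stack.push_back(t.nodes[id].l);
                            stack.push_back(t.nodes[id].r); }
    }
    // old per-leaf stats within the subtree
    std::vector<LeafStat> old_st(t.nodes.size());
    std::vector<int> sub_obs;
    for (int i = 0; i < n; ++i) {
      int lf = leaf_of[j][i];
      if (!in_sub[lf]) continue;
      sub_obs.push_back(i);
      LeafStat &s = old_st[lf];
      s.n += 1; s.sr += resid[i]; s.sr2 += resid[i] * resid[i];
    }
    // swap rules, reassign
    std::swap(t.nodes[a].var, t.nodes[b].var);
    std::swap(t.nodes[a].cut, t.nodes[b].cut);
    std::vector<LeafStat> new_st(t.nodes.size());
    std::vector<int> new_leaf(sub_obs.size());
    for (size_t k = 0; k < sub_obs.size(); ++k) {
      int i = sub_obs[k];
      int lf = descend(t, a, i);
      new_leaf[k] = lf;
      LeafStat &s = new_st[lf];
      s.n += 1; s.sr += resid[i]; s.sr2 += resid[i] * resid[i];
    }
    bool empty = false;
    double ll = 0.0;
    for (int id = 0; id < (int)t.nodes.size(); ++id) {
      if (!in_sub[id] || !t.nodes[id].active || !t.is_leaf(id)) continue;
      if (new_st[id].n == 0) { empty = true; break; }
      ll += leaf_log_marg(new_st[id].n, new_st[id].sr, new_st[id].sr2,
                          sigma2, sigma_mu2)
          - leaf_log_marg(old_st[id].n, old_st[id].sr, old_st[id].sr2,
                          sigma2, sigma_mu2);
    }
    if (!empty && std::log(u) < ll) {
      for (size_t k = 0; k < sub_obs.size(); ++k)
        leaf_of[j][sub_obs[k]] = new_leaf[k];
    } else {  // reject: swap back
      std::swap(t.nodes[a].var, t.nodes[b].var);
      std::swap(t.nodes[a].cut, t.nodes[b].cut);
    }
  }

  void update_tree(int j, bool trace) {
    for (int i = 0; i < n; ++i)
      resid[i] = z[i] - total_fit[i] + fit[j][i];
    double u = unif_rand();
    if (u < p_grow) propose_grow(j, trace);
    else if (u < p_grow + p_prune) propose_prune(j);
    else if (u < p_grow + p_prune + p_change) propose_change(j);
    else propose_swap(j);

    // leaf values from their normal full conditionals, node-index order
    std::vector<LeafStat> st;
    node_stats(j, st);
    Tree &t = trees[j];
    for (int id = 0; id < (int)t.nodes.size(); ++id) {
      if (!t.nodes[id].active || !t.is_leaf(id)) continue;
      double post_var = 1.0 / (st[id].n / sigma2 + 1.0 / sigma_mu2);
      double post_mean = post_var * st[id].sr / sigma2;
      t.nodes[id].mu = post_mean + std::sqrt(post_var) * norm_rand();
    }
    for (int i = 0; i < n; ++i) {
      double newfit = t.nodes[leaf_of[j][i]].mu;
      total_fit[i] += newfit - fit[j][i];
      fit[j][i] = newfit;
    }
  }

  void draw_sigma2() {
    double ss = 0.0;
    for (int i = 0; i < n; ++i) {
      double e = z[i] - total_fit[i];
      ss += e * e;
    }
    sigma2 = (nu * lambda + ss) / R::rchisq(nu + n);
  }

  // serialize tree j into rows of (var+1, cut, l, r, mu) with 1-based
  // within-tree child indices (0 = none); returns rows appended
  int serialize_tree(int j, std::vector<double> &out) {
    Tree &t = trees[j];
    std::vector<int> order, remap(t.nodes.size(), -1);
    std::vector<int> stack{0};
    while (!stack.empty()) {  // preorder
      int id = stack.back(); stack.pop_back();
      remap[id] = (int)order.size();
      order.push_back(id);
      if (!t.is_leaf(id)) { stack.push_back(t.nodes[id].r);
                            stack.push_back(t.nodes[id].l); }
    }
    for (int id : order) {
      const Node &nd = t.nodes[id];
      bool leaf = nd.var < 0;
      out.push_back(leaf ? 0 : nd.var + 1);
      out.push_back(leaf ? 0 : nd.cut);
      out.push_back(leaf ? 0 : remap[nd.l] + 1);
      out.push_back(leaf ? 0 : remap[nd.r] + 1);
      out.push_back(nd.mu);
      if (!leaf) split_counts[nd.var] += 1;
    }
    return (int)order.size();
  }
};

}  // namespace

// [[Rcpp::export]]
double cpp_leaf_log_marginal(double n, double sum_r, double sum_r2,
                             double sigma, double sigma_mu) {
  if (n < 0) stop("n must be >= 0");
  if (sigma <= 0 || sigma_mu <= 0) stop("sigma and sigma_mu must be > 0");
  if (!std::isfinite(sum_r) || !std::isfinite(sum_r2))
    stop("non-finite sums");
  return leaf_log_marg(n, sum_r, sum_r2, sigma * sigma, sigma_mu * sigma_mu);
}

// [[Rcpp::export]]
NumericVector cpp_draw_sigma(NumericVector residuals, double nu, double lambda,
                             int n_draws) {
  if (nu <= 0 || lambda <= 0) stop("nu and lambda must be > 0");
  double ss = 0.0;
  int n = residuals.size();
  for (int i = 0; i < n; ++i) ss += residuals[i] * residuals[i];
  NumericVector out(n_draws);
  for (int d = 0; d < n_draws; ++d)
    out[d] = std::sqrt((nu * lambda + ss) / R::rchisq(nu + n));
  return out;
}

// [[Rcpp::export]]
List cpp_bart(NumericMatrix X, NumericVector z, int m, double alpha,
              double beta, double sigma_mu, double nu, double lambda,
              double sigma_init, NumericVector move_probs, List cutpoints,
              int n_burn, int n_draw, int thin, bool update_sigma,
              bool db_trace) {
  int n = z.size(), p = X.ncol();
  if (n < 2) stop("need at least 2 observations");
  if (X.nrow() != n) stop("rows of X must match z");
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(z[i])) stop("non-finite response");
  std::vector<std::vector<double>> cuts(p);
  bool any_cut = false;
  for (int v = 0; v < p; ++v) {
    NumericVector cv = cutpoints[v];
    cuts[v] = std::vector<double>(cv.begin(), cv.end());
    if (!cuts[v].empty()) any_cut = true;
  }
  if (!any_cut) stop("degenerate design: no admissible cutpoints");
  for (int v = 0; v < p; ++v) {
    if (cuts[v].empty()) cuts[v].push_back(R_NegInf);  // never splits usefully
  }
  std::vector<double> zz(z.begin(), z.end());
  Sampler s(X, zz, m, alpha, beta, sigma_mu, nu, lambda, sigma_init,
            move_probs, cuts);

  std::vector<double> nodes_out;
  std::vector<int> tree_sizes;
  tree_sizes.reserve((size_t)n_draw * m);
  NumericVector sigma_draws(n_draw);

  int total = n_burn + n_draw * thin;
  int kept = 0;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < m; ++j) s.update_tree(j, db_trace);
    if (update_sigma) s.draw_sigma2();
    if (it >= n_burn && (it - n_burn) % thin == thin - 1) {
      for (int j = 0; j < m; ++j)
        tree_sizes.push_back(s.serialize_tree(j, nodes_out));
      sigma_draws[kept++] = std::sqrt(s.sigma2);
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  int n_nodes = (int)nodes_out.size() / 5;
  NumericMatrix nodes(n_nodes, 5);
  for (int r = 0; r < n_nodes; ++r)
    for (int c = 0; c < 5; ++c) nodes(r, c) = nodes_out[(size_t)r * 5 + c];
  colnames(nodes) = CharacterVector::create("var", "cut", "left", "right",
                                            "value");
  return List::create(
      _["nodes"] = nodes, _["tree_sizes"] = wrap(tree_sizes),
      _["sigma"] = sigma_draws, _["split_counts"] = wrap(s.split_counts),
      _["db_grow"] = wrap(s.db_grow), _["db_prune_rev"] = wrap(s.db_prune));
}

// [[Rcpp::export]]
NumericMatrix cpp_bart_predict(NumericMatrix nodes, IntegerVector tree_sizes,
                               NumericMatrix X_new, int n_draw, int m) {
  int n = X_new.nrow();
  NumericMatrix out(n, n_draw);
  std::vector<int> offsets(tree_sizes.size() + 1, 0);
  for (int t = 0; t < tree_sizes.size(); ++t)
    offsets[t + 1] = offsets[t] + tree_sizes[t];
  if ((int)tree_sizes.size() != n_draw * m)
    stop("tree_sizes length does not match n_draw * m");
  for (int d = 0; d < n_draw; ++d) {
    for (int j = 0; j < m; ++j) {
      int base = offsets[d * m + j];
      for (int i = 0; i < n; ++i) {
        int id = 0;
        while (nodes(base + id, 0) > 0) {
          int var = (int)nodes(base + id, 0) - 1;
          id = (X_new(i, var) <= nodes(base + id, 1))
                   ? (int)nodes(base + id, 2) - 1
                   : (int)nodes(base + id, 3) - 1;
        }
        out(i, d) += nodes(base + id, 4);
      }
    }
    if (d % 50 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
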