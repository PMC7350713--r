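#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for Brownian motion on a binary tree with arbitrary
// per-edge effective lengths (branch length + alpha * jump count for the
// augmented Levy likelihood). Edges must be supplied in postorder (every
// child edge before its parent's edge). Nodes are 1-based as in ape.
//
// Returns the REML (contrast) log-likelihood, and enough root state to form
// the ML-root version: logL_ML = logL_REML - 0.5 * log(2 pi sigma2 * v_root).

struct PruneResult {
  double loglik;   // REML
  double root_mean;
  double root_v;   // in branch-length units (variance / sigma2)
  bool ok;
};

static PruneResult prune_core(const IntegerMatrix& edge,
                              const NumericVector& elen,
                              int ntip, int nnode,
                              const NumericVector& x, double sigma2) {
  const int ntot = ntip + nnode;
  std::vector<double> m(ntot), v(ntot);
  std::vector<int> nseen(ntot, 0);
  PruneResult res{0.0, 0.0, 0.0, true};
  for (int i = 0; i < ntip; ++i) { m[i] = x[i]; v[i] = 0.0; }
  // stash first-child info per parent while scanning postorder edges
  std::vector<double> cm(ntot), cv(ntot);
  double ll = 0.0;
  const double LOG2PI = 1.83787706640934548;
  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    double mv = m[ch], vv = v[ch] + elen[e];
    if (nseen[par] == 0) {
      cm[par] = mv; cv[par] = vv; nseen[par] = 1;
    } else {
      double vsum = cv[par] + vv;
      if (vsum <= 0) vsum = 1e-12;  // zero-length cherry guard
      double d = cm[par] - mv;
      ll += -0.5 * (LOG2PI + std::log(sigma2 * vsum) + d * d / (sigma2 * vsum));
      m[par] = (cm[par] * vv + mv * cv[par]) / vsum;
      v[par] = cv[par] * vv / vsum;
      nseen[par] = 2;
    }
  }
  int root = ntip;  // ape convention: root id = ntip + 1 (0-based: ntip)
  res.loglik = ll;
  res.root_mean = m[root];
  res.root_v = v[root];
  return res;
}

// [[Rcpp::export]]
List c_bm_loglik(IntegerMatrix edge, NumericVector elen, int ntip, int nnode,
                 NumericVector x, double sigma2, bool reml) {
  PruneResult r = prune_core(edge, elen, ntip, nnode, x, sigma2);
  double ll = r.loglik;
  if (!reml) {
    double vr = r.root_v > 0 ? r.root_v : 1e-12;
    ll += -0.5 * std::log(2.0 * M_PI * sigma2 * vr);
  }
  return List::create(_["loglik"] = ll, _["root_mean"] = r.root_mean,
                      _["root_v"] = r.root_v);
}

// MCMC over per-branch jump counts, sigma2, and jump rate, with alpha fixed.
// Augmented likelihood: Gaussian pruning with effective length
// len + n * alpha; Poisson(jump_rate * len) prior on counts; Jeffreys prior
// on sigma2 (multiplicative moves accept on the likelihood ratio alone);
// conjugate Gamma(a0, b0) prior on jump_rate updated by Gibbs.
// Iterations: per generation one sweep of +/-1 count proposals over all
// edges, one sigma2 move, one Gibbs draw of jump_rate. Uses R's RNG, so
// runs are reproducible under set.seed().
// [[Rcpp::export]]
List c_jump_mcmc(IntegerMatrix edge, NumericVector elen, int ntip, int nnode,
                 NumericVector x, double alpha,
                 int n_samples, int burnin, int thin,
                 double sigma2_init, double rate_init,
                 double rate_a0, double rate_b0, bool reml) {
  const int nedge = edge.nrow();
  std::vector<int> counts(nedge, 0);
  NumericVector eff(clone(elen));
  double sigma2 = sigma2_init, rate = rate_init;
  double total_len = 0.0;
  for (int e = 0; e < nedge; ++e) total_len += elen[e];

  auto loglik = [&](double s2) {
    PruneResult r = prune_core(edge, eff, ntip, nnode, x, s2);
    double ll = r.loglik;
    if (!reml) {
      double vr = r.root_v > 0 ? r.root_v : 1e-12;
      ll += -0.5 * std::log(2.0 * M_PI * s2 * vr);
    }
    return ll;
  };
  double ll = loglik(sigma2);

  const int n_gen = (burnin + n_samples) * thin;
  NumericVector pp(nedge, 0.0), mean_counts(nedge, 0.0);
  NumericVector s2_trace(n_samples), rate_trace(n_samples);
  int rec = 0, kept = 0;
  for (int g = 1; g <= n_gen; ++g) {
    // sweep counts
    for (int e = 0; e < nedge; ++e) {
      int n0 = counts[e];
      int n1 = (unif_rand() < 0.5) ? n0 + 1 : n0 - 1;
      if (n1 < 0) continue;
      double old_eff = eff[e];
      eff[e] = elen[e] + n1 * alpha;
      double ll_new = loglik(sigma2);
      double mean_j = rate * elen[e];
      double lpr;  // Poisson prior ratio
      if (n1 > n0) lpr = std::log(mean_j) - std::log((double)n1);
      else lpr = std::log((double)n0) - std::log(mean_j);
      if (std::log(unif_rand()) < ll_new - ll + lpr) {
        counts[e] = n1; ll = ll_new;
      } else {
        eff[e] = old_eff;
      }
    }
    // sigma2 multiplicative move (Jeffreys prior cancels the Hastings term)
    {
      double f = std::exp(0.6 * (unif_rand() - 0.5));
      double s2_new = sigma2 * f;
      double ll_new = loglik(s2_new);
      if (std::log(unif_rand()) < ll_new - ll) {
        sigma2 = s2_new; ll = ll_new;
      }
    }
    // Gibbs for jump rate
    {
      double tot = 0.0;
      for (int e = 0; e < nedge; ++e) tot += counts[e];
      rate = R::rgamma(rate_a0 + tot, 1.0 / (rate_b0 + total_len));
    }
    if (g % thin == 0) {
      ++rec;
      if (rec > burnin) {
        for (int e = 0; e < nedge; ++e) {
          if (counts[e] > 0) pp[e] += 1.0;
          mean_counts[e] += counts[e];
        }
        s2_trace[kept] = sigma2;
        rate_trace[kept] = rate;
        ++kept;
      }
    }
  }
  for (int e = 0; e < nedge; ++e) { pp[e] /= kept; mean_counts[e] /= kept; }
  return List::create(_["pp"] = pp, _["mean_counts"] = mean_counts,
                      _["sigma2_trace"] = s2_trace,
                      _["jump_rate_trace"] = rate_trace,
                      _["n_sampled_vectors"] = kept);
}

// Marginal Levy log-likelihood by Gaussian-mixture pruning: per-branch jump
// counts are summed over a capped, renormalized Poisson, so each node's
// partial likelihood is a mixture of Gaussians in the node state, reduced
// to at most max_comp components by weight-preserving moment matching of
// the lowest-weight components (merged into the kept component with the
// nearest mean). Mirrors the reference R implementation; REML root.
struct Mix {
  std::vector<double> m, v, lw;
};

static double logsumexp_vec(const std::vector<double>& lw) {
  double mx = -INFINITY;
  for (double w : lw) if (w > mx) mx = w;
  if (!std::isfinite(mx)) return mx;
  double s = 0.0;
  for (double w : lw) s += std::exp(w - mx);
  return mx + std::log(s);
}

static void reduce_mix(Mix& mx, int max_comp) {
  // drop non-finite weights first (zero-probability components)
  {
    Mix keep;
    for (size_t i = 0; i < mx.lw.size(); ++i)
      if (std::isfinite(mx.lw[i])) {
        keep.m.push_back(mx.m[i]); keep.v.push_back(mx.v[i]);
        keep.lw.push_back(mx.lw[i]);
      }
    if (!keep.lw.empty()) mx = keep;
  }
  const int n = mx.lw.size();
  if (n <= max_comp) return;
  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::sort(idx.begin(), idx.end(),
            [&](int a, int b) { return mx.lw[a] > mx.lw[b]; });
  std::vector<int> kept(idx.begin(), idx.begin() + max_comp);
  for (int t = max_comp; t < n; ++t) {
    int d = idx[t];
    // nearest kept component by mean
    int k = kept[0];
    double best = std::fabs(mx.m[k] - mx.m[d]);
    for (int j = 1; j < max_comp; ++j) {
      double dd = std::fabs(mx.m[kept[j]] - mx.m[d]);
      if (dd < best) { best = dd; k = kept[j]; }
    }
    double lw_new = (mx.lw[k] > mx.lw[d])
      ? mx.lw[k] + std::log1p(std::exp(mx.lw[d] - mx.lw[k]))
      : mx.lw[d] + std::log1p(std::exp(mx.lw[k] - mx.lw[d]));
    double wk = std::exp(mx.lw[k] - lw_new);
    double mu = wk * mx.m[k] + (1 - wk) * mx.m[d];
    mx.v[k] = wk * (mx.v[k] + mx.m[k] * mx.m[k]) +
      (1 - wk) * (mx.v[d] + mx.m[d] * mx.m[d]) - mu * mu;
    mx.m[k] = mu;
    mx.lw[k] = lw_new;
  }
  Mix out;
  // preserve the kept components in weight order (matches the R reference)
  for (int j = 0; j < max_comp; ++j) {
    out.m.push_back(mx.m[kept[j]]);
    out.v.push_back(mx.v[kept[j]]);
    out.lw.push_back(mx.lw[kept[j]]);
  }
  mx = out;
}

// [[Rcpp::export]]
double c_levy_marginal_loglik(IntegerMatrix edge, NumericVector elen,
                              int ntip, int nnode, NumericVector x,
                              double sigma2, double jump_rate, double alpha,
                              int cap, int max_comp) {
  const int ntot = ntip + nnode;
  const double LOG2PI = 1.83787706640934548;
  std::vector<Mix> mix(ntot), stash(ntot);
  std::vector<int> nseen(ntot, 0);
  for (int i = 0; i < ntip; ++i) {
    mix[i].m = {x[i]}; mix[i].v = {0.0}; mix[i].lw = {0.0};
  }
  std::vector<double> lwn(cap + 1);
  for (int e = 0; e < edge.nrow(); ++e) {
    int par = edge(e, 0) - 1, ch = edge(e, 1) - 1;
    double len = elen[e];
    // normalized truncated-Poisson count weights for this branch
    double lam = jump_rate * len;
    for (int n = 0; n <= cap; ++n)
      lwn[n] = R::dpois(n, lam, 1);
    double norm = logsumexp_vec(lwn);
    Mix br;
    const Mix& cc = mix[ch];
    for (int n = 0; n <= cap; ++n) {
      double add = sigma2 * len + sigma2 * alpha * n;
      for (size_t i = 0; i < cc.m.size(); ++i) {
        br.m.push_back(cc.m[i]);
        br.v.push_back(cc.v[i] + add);
        br.lw.push_back(cc.lw[i] + lwn[n] - norm);
      }
    }
    reduce_mix(br, max_comp);
    if (nseen[par] == 0) {
      stash[par] = br; nseen[par] = 1;
    } else {
      const Mix& s = stash[par];
      Mix node;
      for (size_t i = 0; i < s.m.size(); ++i) {
        for (size_t j = 0; j < br.m.size(); ++j) {
          double vs = s.v[i] + br.v[j];
          if (vs <= 0) vs = 1e-12;
          double d = s.m[i] - br.m[j];
          node.lw.push_back(s.lw[i] + br.lw[j] -
                            0.5 * (LOG2PI + std::log(vs) + d * d / vs));
          node.m.push_back((s.m[i] * br.v[j] + br.m[j] * s.v[i]) / vs);
          node.v.push_back(s.v[i] * br.v[j] / vs);
        }
      }
      reduce_mix(node, max_comp);
      mix[par] = node;
      stash[par] = Mix();
      nseen[par] = 2;
    }
  }
  return logsumexp_vec(mix[ntip].lw);
}
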