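// Permutation engine for network-based statistics.
//
// Two hot paths live here: (1) union-find connected components over
// suprathreshold edge sets, evaluated once per permutation; (2) edge-wise
// linear mixed models (random intercept per subject) refitted under
// within-subject session-label permutations. The LMM uses the profiled
// restricted likelihood in the variance ratio lambda = tau^2/sigma^2:
// for fixed lambda the GLS normal-equation matrix A(lambda) is shared by
// every edge, so a lambda grid amortises the expensive pieces across edges,
// and a golden-section refinement sharpens each edge's optimum.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------- union-find

static int uf_find(std::vector<int> &par, int x) {
  while (par[x] != x) { par[x] = par[par[x]]; x = par[x]; }
  return x;
}

static void uf_union(std::vector<int> &par, int a, int b) {
  a = uf_find(par, a); b = uf_find(par, b);
  if (a != b) par[b] = a;
}

// Component label (1-based, in order of first appearance) for each edge of an
// undirected graph given as 1-based endpoint vectors.
// [[Rcpp::export]]
IntegerVector cpp_edge_components(IntegerVector ei, IntegerVector ej, int n_nodes) {
  int m = ei.size();
  std::vector<int> par(n_nodes);
  for (int v = 0; v < n_nodes; ++v) par[v] = v;
  for (int e = 0; e < m; ++e) uf_union(par, ei[e] - 1, ej[e] - 1);
  IntegerVector lab(m);
  std::map<int, int> seen;
  int next = 0;
  for (int e = 0; e < m; ++e) {
    int root = uf_find(par, ei[e] - 1);
    auto it = seen.find(root);
    if (it == seen.end()) { seen[root] = ++next; lab[e] = next; }
    else lab[e] = it->second;
  }
  return lab;
}

// Maximum over connected components of sum(|stat|) across kept edges.
// Returns 0 when no edge is kept.
// [[Rcpp::export]]
double cpp_max_component_strength(NumericVector stat, IntegerVector ei,
                                  IntegerVector ej, int n_nodes,
                                  LogicalVector keep) {
  int m = ei.size();
  std::vector<int> par(n_nodes);
  for (int v = 0; v < n_nodes; ++v) par[v] = v;
  for (int e = 0; e < m; ++e)
    if (keep[e]) uf_union(par, ei[e] - 1, ej[e] - 1);
  std::map<int, double> strength;
  double best = 0.0;
  for (int e = 0; e < m; ++e) {
    if (!keep[e]) continue;
    int root = uf_find(par, ei[e] - 1);
    double s = (strength[root] += std::fabs(stat[e]));
    if (s > best) best = s;
  }
  return best;
}

// ------------------------------------------------------------- LMM machinery

namespace {

struct Design {
  arma::mat X;        // n x p fixed-effect design (sum-to-zero coding)
  arma::mat XtX;      // p x p
  arma::mat U;        // p x q, column i = sum of X rows for subject i
  arma::vec ni;       // q, observations per subject
};

// Sum-to-zero coding: session 1 -> (-1,-1), 2 -> (1,0), 3 -> (0,1);
// sex in {0,1} -> {-1,+1}. Column order: intercept, [sex], s2, s3,
// [sex:s2, sex:s3].
arma::mat build_X(const arma::ivec &sess, const arma::ivec &sex,
                  bool include_sex, bool include_inter) {
  int n = sess.n_elem;
  int p = 3 + (include_sex ? 1 : 0) + (include_inter ? 2 : 0);
  arma::mat X(n, p);
  for (int i = 0; i < n; ++i) {
    int c = 0;
    X(i, c++) = 1.0;
    double sx = sex[i] ? 1.0 : -1.0;
    if (include_sex) X(i, c++) = sx;
    double s2 = (sess[i] == 2) ? 1.0 : (sess[i] == 1 ? -1.0 : 0.0);
    double s3 = (sess[i] == 3) ? 1.0 : (sess[i] == 1 ? -1.0 : 0.0);
    X(i, c++) = s2;
    X(i, c++) = s3;
    if (include_inter) { X(i, c++) = sx * s2; X(i, c++) = sx * s3; }
  }
  return X;
}

Design make_design(const arma::mat &X, const arma::ivec &subj, int nsubj) {
  Design d;
  d.X = X;
  d.XtX = X.t() * X;
  d.U.zeros(X.n_cols, nsubj);
  d.ni.zeros(nsubj);
  for (arma::uword i = 0; i < X.n_rows; ++i) {
    d.U.col(subj[i]) += X.row(i).t();
    d.ni[subj[i]] += 1.0;
  }
  return d;
}

// Restricted-likelihood criterion pieces for one lambda:
// A = X'V*^-1 X and log|V*| with V* = I + lambda Z Z'.
struct LambdaCtx {
  double lambda;
  arma::vec c;        // q, lambda/(1 + lambda*ni)
  arma::mat Ainv;     // p x p
  double logdetA;
  double logdetV;
  bool ok;
};

LambdaCtx make_ctx(double loglam, const Design &d) {
  LambdaCtx ctx;
  ctx.lambda = std::exp(loglam);
  int q = d.ni.n_elem;
  ctx.c.set_size(q);
  ctx.logdetV = 0.0;
  for (int i = 0; i < q; ++i) {
    ctx.c[i] = ctx.lambda / (1.0 + ctx.lambda * d.ni[i]);
    ctx.logdetV += std::log1p(ctx.lambda * d.ni[i]);
  }
  arma::mat A = d.XtX - (d.U.each_row() % ctx.c.t()) * d.U.t();
  arma::mat R;
  ctx.ok = arma::chol(R, A);
  if (!ctx.ok) return ctx;
  ctx.logdetA = 2.0 * arma::accu(arma::log(R.diag()));
  ctx.Ainv = arma::inv_sympd(A);
  return ctx;
}

// Per-edge sufficient statistics.
struct EdgeStats {
  arma::vec Xty;      // p
  arma::vec s;        // q, per-subject sums of y
  double yty;
};

// Profiled REML criterion (up to a constant) at a prepared lambda.
double reml_crit(const LambdaCtx &ctx, const Design &d, const EdgeStats &es,
                 int n, int p, double *rss_out = nullptr,
                 arma::vec *beta_out = nullptr) {
  if (!ctx.ok) return arma::datum::inf;
  arma::vec b = es.Xty - d.U * (ctx.c % es.s);
  arma::vec beta = ctx.Ainv * b;
  double yy = es.yty - arma::dot(ctx.c, arma::square(es.s));
  double rss = yy - arma::dot(b, beta);
  if (!(rss > 0.0)) return arma::datum::inf;
  if (rss_out) *rss_out = rss;
  if (beta_out) *beta_out = beta;
  return (n - p) * std::log(rss) + ctx.logdetV + ctx.logdetA;
}

struct FitResult {
  arma::vec beta;
  arma::mat covb;     // sigma2 * Ainv
  double sigma2;
  double lambda;
  bool ok;
};

// Grid search plus golden-section refinement on log(lambda).
FitResult fit_edge(const Design &d, const EdgeStats &es,
                   const std::vector<LambdaCtx> &grid,
                   const std::vector<double> &loglams,
                   int n, int p, int n_refine) {
  FitResult out; out.ok = false;
  int gbest = -1; double fbest = arma::datum::inf;
  for (size_t g = 0; g < grid.size(); ++g) {
    double f = reml_crit(grid[g], d, es, n, p);
    if (f < fbest) { fbest = f; gbest = (int)g; }
  }
  if (gbest < 0) return out;
  double lo = loglams[std::max(gbest - 1, 0)];
  double hi = loglams[std::min(gbest + 1, (int)loglams.size() - 1)];
  if (lo == hi) { lo -= 0.5; hi += 0.5; }
  const double gr = 0.61803398874989484820;
  double x1 = hi - gr * (hi - lo), x2 = lo + gr * (hi - lo);
  LambdaCtx c1 = make_ctx(x1, d), c2 = make_ctx(x2, d);
  double f1 = reml_crit(c1, d, es, n, p), f2 = reml_crit(c2, d, es, n, p);
  for (int it = 0; it < n_refine; ++it) {
    if (f1 < f2) {
      hi = x2; x2 = x1; f2 = f1; c2 = c1;
      x1 = hi - gr * (hi - lo);
      c1 = make_ctx(x1, d); f1 = reml_crit(c1, d, es, n, p);
    } else {
      lo = x1; x1 = x2; f1 = f2; c1 = c2;
      x2 = lo + gr * (hi - lo);
      c2 = make_ctx(x2, d); f2 = reml_crit(c2, d, es, n, p);
    }
  }
  const LambdaCtx &cb = (f1 < f2) ? c1 : c2;
  double fb = std::min(f1, f2);
  if (!std::isfinite(fb)) return out;
  double rss; arma::vec beta;
  if (!std::isfinite(reml_crit(cb, d, es, n, p, &rss, &beta))) return out;
  out.sigma2 = rss / (n - p);
  out.beta = beta;
  out.covb = out.sigma2 * cb.Ainv;
  out.lambda = cb.lambda;
  out.ok = true;
  return out;
}

// Wald F for a coefficient block; z = sign(dominant contrast) * sqrt(F).
void term_test(const FitResult &fit, const arma::uvec &idx, double df,
               double &F, double &pval, double &z) {
  arma::vec bt = fit.beta(idx);
  arma::mat Vt = fit.covb(idx, idx);
  arma::mat Vinv;
  if (!arma::inv_sympd(Vinv, Vt)) { F = pval = z = NA_REAL; return; }
  int q = idx.n_elem;
  F = arma::as_scalar(bt.t() * Vinv * bt) / q;
  if (!std::isfinite(F) || F < 0) { F = pval = z = NA_REAL; return; }
  pval = R::pf(F, (double)q, df, 0, 0);
  int jmax = 0; double tmax = 0.0;
  for (int j = 0; j < q; ++j) {
    double tj = bt[j] / std::sqrt(Vt(j, j));
    if (std::fabs(tj) > std::fabs(tmax)) { tmax = tj; jmax = j; }
  }
  (void)jmax;
  z = ((tmax < 0) ? -1.0 : 1.0) * std::sqrt(F);
}

std::vector<LambdaCtx> make_grid(const Design &d, std::vector<double> &loglams) {
  loglams.clear();
  for (double ll = -10.0; ll <= 6.0 + 1e-9; ll += 0.5) loglams.push_back(ll);
  std::vector<LambdaCtx> grid;
  grid.reserve(loglams.size());
  for (double ll : loglams) grid.push_back(make_ctx(ll, d));
  return grid;
}

EdgeStats edge_stats(const arma::mat &Y, arma::uword e, const Design &d,
                     const arma::ivec &subj) {
  EdgeStats es;
  es.Xty = d.X.t() * Y.col(e);
  es.s.zeros(d.ni.n_elem);
  for (arma::uword i = 0; i < Y.n_rows; ++i) es.s[subj[i]] += Y(i, e);
  es.yty = arma::dot(Y.col(e), Y.col(e));
  return es;
}

// Fisher-Yates using R's RNG (so set.seed() in R governs reproducibility).
void shuffle_r(std::vector<int> &v) {
  for (int i = (int)v.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

} // namespace

// Fit the random-intercept LMM for every edge and test the requested
// coefficient blocks. sess in {1,2,3}; sex in {0,1}; subj 0-based.
// Terms: 0 = sex, 1 = session, 2 = interaction. df supplied per term.
// [[Rcpp::export]]
List cpp_lmm_fit(const arma::mat &Y, const arma::ivec &sess,
                 const arma::ivec &sex, const arma::ivec &subj, int nsubj,
                 bool include_sex, bool include_inter,
                 const arma::ivec &terms, const arma::vec &df_terms,
                 int n_refine = 20, bool want_cov = false) {
  int n = Y.n_rows, E = Y.n_cols;
  arma::mat X = build_X(sess, sex, include_sex, include_inter);
  int p = X.n_cols;
  Design d = make_design(X, subj, nsubj);
  std::vector<double> loglams;
  std::vector<LambdaCtx> grid = make_grid(d, loglams);

  int T = terms.n_elem;
  arma::mat Fm(E, T), Pm(E, T), Zm(E, T);
  Fm.fill(NA_REAL); Pm.fill(NA_REAL); Zm.fill(NA_REAL);
  arma::mat Beta(p, E); Beta.fill(NA_REAL);
  arma::vec sigma2(E), lambda(E);
  sigma2.fill(NA_REAL); lambda.fill(NA_REAL);
  arma::cube covb;
  if (want_cov) covb.set_size(p, p, E);

  int c_sex = include_sex ? 1 : -1;
  int c_sess = include_sex ? 2 : 1;
  int c_int = include_inter ? (c_sess + 2) : -1;

  for (int e = 0; e < E; ++e) {
    EdgeStats es = edge_stats(Y, e, d, subj);
    FitResult fit = fit_edge(d, es, grid, loglams, n, p, n_refine);
    if (!fit.ok) continue;
    Beta.col(e) = fit.beta;
    sigma2[e] = fit.sigma2;
    lambda[e] = fit.lambda;
    if (want_cov) covb.slice(e) = fit.covb;
    for (int t = 0; t < T; ++t) {
      arma::uvec idx;
      if (terms[t] == 0 && c_sex >= 0) idx = {(arma::uword)c_sex};
      else if (terms[t] == 1) idx = {(arma::uword)c_sess, (arma::uword)(c_sess + 1)};
      else if (terms[t] == 2 && c_int >= 0) idx = {(arma::uword)c_int, (arma::uword)(c_int + 1)};
      else continue;
      double F, pv, z;
      term_test(fit, idx, df_terms[t], F, pv, z);
      Fm(e, t) = F; Pm(e, t) = pv; Zm(e, t) = z;
    }
  }
  List out = List::create(_["F"] = Fm, _["p"] = Pm, _["z"] = Zm,
                          _["beta"] = Beta, _["sigma2"] = sigma2,
                          _["lambda"] = lambda);
  if (want_cov) out["covb"] = covb;
  return out;
}

// Permutation null of the maximum component strength, per term.
// Within-subject terms (session, interaction) permute session labels within
// each subject; the between-subject term (sex) permutes subjects' sex labels.
// Returns the observed per-edge statistics and the null matrix.
// [[Rcpp::export]]
List cpp_nbr_perm(const arma::mat &Y, const arma::ivec &sess,
                  const arma::ivec &sex, const arma::ivec &subj, int nsubj,
                  bool include_sex, bool include_inter,
                  const arma::ivec &terms, const arma::vec &df_terms,
                  double alpha, const arma::ivec &ei, const arma::ivec &ej,
                  int n_nodes, int n_perm, int n_refine = 8) {
  int E = Y.n_cols, T = terms.n_elem;
  IntegerVector ei_r(ei.begin(), ei.end()), ej_r(ej.begin(), ej.end());

  List obs = cpp_lmm_fit(Y, sess, sex, subj, nsubj, include_sex, include_inter,
                         terms, df_terms, std::max(n_refine, 30), false);
  arma::mat obsP = obs["p"], obsZ = obs["z"];

  bool any_within = false, any_between = false;
  for (int t = 0; t < T; ++t) {
    if (terms[t] == 0) any_between = true; else any_within = true;
  }

  // rows of each subject, for within-subject shuffles
  std::vector<std::vector<int>> rows(nsubj);
  for (arma::uword i = 0; i < Y.n_rows; ++i) rows[subj[i]].push_back((int)i);

  arma::mat nullmax(n_perm, T, arma::fill::zeros);

  for (int b = 0; b < n_perm; ++b) {
    if (any_within) {
      arma::ivec sess_p = sess;
      for (int s = 0; s < nsubj; ++s) {
        std::vector<int> lab;
        for (int r : rows[s]) lab.push_back(sess[r]);
        shuffle_r(lab);
        for (size_t k = 0; k < rows[s].size(); ++k) sess_p[rows[s][k]] = lab[k];
      }
      List fit = cpp_lmm_fit(Y, sess_p, sex, subj, nsubj, include_sex,
                             include_inter, terms, df_terms, n_refine, false);
      arma::mat P = fit["p"], Z = fit["z"];
      for (int t = 0; t < T; ++t) {
        if (terms[t] == 0) continue;
        LogicalVector keep(E);
        NumericVector st(E);
        for (int e = 0; e < E; ++e) {
          bool k = std::isfinite(P(e, t)) && P(e, t) < alpha;
          keep[e] = k; st[e] = k ? Z(e, t) : 0.0;
        }
        nullmax(b, t) = cpp_max_component_strength(st, ei_r, ej_r, n_nodes, keep);
      }
    }
    if (any_between) {
      std::vector<int> subj_sex(nsubj, 0);
      for (arma::uword i = 0; i < Y.n_rows; ++i) subj_sex[subj[i]] = sex[i];
      shuffle_r(subj_sex);
      arma::ivec sex_p = sex;
      for (arma::uword i = 0; i < Y.n_rows; ++i) sex_p[i] = subj_sex[subj[i]];
      List fit = cpp_lmm_fit(Y, sess, sex_p, subj, nsubj, include_sex,
                             include_inter, terms, df_terms, n_refine, false);
      arma::mat P = fit["p"], Z = fit["z"];
      for (int t = 0; t < T; ++t) {
        if (terms[t] != 0) continue;
        LogicalVector keep(E);
        NumericVector st(E);
        for (int e = 0; e < E; ++e) {
          bool k = std::isfinite(P(e, t)) && P(e, t) < alpha;
          keep[e] = k; st[e] = k ? Z(e, t) : 0.0;
        }
        nullmax(b, t) = cpp_max_component_strength(st, ei_r, ej_r, n_nodes, keep);
      }
    }
  }

  return List::create(_["observed"] = obs, _["null_max"] = nullmax);
}
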