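// Continuous-time micro-step simulator for stochastic actor-oriented models.
// Effect codes match saom_effect_names() on the R side:
//  1 outdegree, 2 reciprocity, 3 transitive_triplets,
//  4 transitive_recip_triplets, 5 three_cycles, 6 indegree_popularity,
//  7 outdegree_popularity_sqrt, 8 outdegree_activity_sqrt,
//  9 out_out_assortativity, 10 cov_ego, 11 cov_alter, 12 cov_same,
// 13 cov_similarity, 14 same_cov_x_reciprocity.
// Covariate effects 10-11 read a (centred) column of `attr`; 12-14 read a
// precomputed dyadic matrix (equality or centred similarity).
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

struct Effect {
  int code;
  double beta;
  const double *attr; // node attribute column (centred), or null
  const double *dyad; // n x n dyadic matrix, column-major, or null
};

// x is the adjacency in column-major int form: x[a + n*b] = tie a -> b
static inline double actor_stat(const Effect &e, int i, const int *x,
                                const int *outdeg, const int *indeg,
                                int n) {
  double s = 0.0;
  switch (e.code) {
  case 1:
    return outdeg[i];
  case 2:
    for (int j = 0; j < n; ++j) s += x[i + n * j] * x[j + n * i];
    return s;
  case 3: // sum_j x_ij * #(h: x_ih x_hj)
    for (int j = 0; j < n; ++j) {
      if (!x[i + n * j]) continue;
      for (int h = 0; h < n; ++h) s += x[i + n * h] * x[h + n * j];
    }
    return s;
  case 4:
    for (int j = 0; j < n; ++j) {
      if (!(x[i + n * j] && x[j + n * i])) continue;
      for (int h = 0; h < n; ++h) s += x[i + n * h] * x[h + n * j];
    }
    return s;
  case 5:
    for (int j = 0; j < n; ++j) {
      if (!x[i + n * j]) continue;
      for (int h = 0; h < n; ++h) s += x[j + n * h] * x[h + n * i];
    }
    return s;
  case 6:
    for (int j = 0; j < n; ++j) if (x[i + n * j]) s += indeg[j];
    return s;
  case 7:
    for (int j = 0; j < n; ++j)
      if (x[i + n * j]) s += std::sqrt((double)outdeg[j]);
    return s;
  case 8:
    return std::pow((double)outdeg[i], 1.5);
  case 9:
    for (int j = 0; j < n; ++j)
      if (x[i + n * j]) s += std::sqrt((double)outdeg[j]);
    return std::sqrt((double)outdeg[i]) * s;
  case 10:
    return e.attr[i] * outdeg[i];
  case 11:
    for (int j = 0; j < n; ++j) if (x[i + n * j]) s += e.attr[j];
    return s;
  case 12:
  case 13:
    for (int j = 0; j < n; ++j) if (x[i + n * j]) s += e.dyad[i + n * j];
    return s;
  case 14:
    for (int j = 0; j < n; ++j)
      if (x[i + n * j] && x[j + n * i]) s += e.dyad[i + n * j];
    return s;
  default:
    stop("unknown effect code");
  }
  return s;
}

static inline double actor_eval(const std::vector<Effect> &effs, int i,
                                const int *x, const int *outdeg,
                                const int *indeg, int n) {
  double f = 0.0;
  for (size_t k = 0; k < effs.size(); ++k)
    f += effs[k].beta * actor_stat(effs[k], i, x, outdeg, indeg, n);
  return f;
}

static std::vector<Effect> build_effects(const IntegerVector &codes,
                                         const NumericVector &betas,
                                         const NumericMatrix &attr,
                                         const List &dyads) {
  std::vector<Effect> effs(codes.size());
  for (int k = 0; k < codes.size(); ++k) {
    effs[k].code = codes[k];
    effs[k].beta = betas[k];
    effs[k].attr = &attr(0, k);
    SEXP dk = dyads[k];
    effs[k].dyad = Rf_isNull(dk) ? nullptr : REAL(dk);
  }
  return effs;
}

// Choice probabilities of actor i over (toggle tie to j) for all j != i and
// "no change" (returned at position i). Multinomial logit on the evaluation
// function of the candidate networks.
// [[Rcpp::export]]
NumericVector cpp_choice_probs(int i1, IntegerMatrix x, IntegerVector codes,
                               NumericVector betas, NumericMatrix attr,
                               List dyads) {
  int n = x.nrow(), i = i1 - 1;
  IntegerMatrix xc = clone(x);
  int *xp = INTEGER(xc);
  std::vector<int> outdeg(n, 0), indeg(n, 0);
  for (int b = 0; b < n; ++b)
    for (int a = 0; a < n; ++a) {
      outdeg[a] += xp[a + n * b];
      indeg[b] += xp[a + n * b];
    }
  std::vector<Effect> effs = build_effects(codes, betas, attr, dyads);
  NumericVector f(n);
  f[i] = actor_eval(effs, i, xp, outdeg.data(), indeg.data(), n);
  for (int j = 0; j < n; ++j) {
    if (j == i) continue;
    int old = xp[i + n * j], nw = 1 - old;
    xp[i + n * j] = nw;
    outdeg[i] += nw - old;
    indeg[j] += nw - old;
    f[j] = actor_eval(effs, i, xp, outdeg.data(), indeg.data(), n);
    xp[i + n * j] = old;
    outdeg[i] -= nw - old;
    indeg[j] -= nw - old;
  }
  double mx = max(f);
  NumericVector p = exp(f - mx);
  return p / sum(p);
}

// Simulate one period of unit model time. presence[i] in (0,1] scales actor
// i's rate; presence 0 deactivates the actor entirely.
// [[Rcpp::export]]
List cpp_sim_period(IntegerMatrix x0, IntegerVector codes,
                    NumericVector betas, NumericMatrix attr, List dyads,
                    double rho, double alpha, NumericVector presence,
                    bool record = false, int max_steps = 1000000) {
  int n = x0.nrow();
  IntegerMatrix x = clone(x0);
  int *xp = INTEGER(x);
  std::vector<int> outdeg(n, 0), indeg(n, 0);
  for (int b = 0; b < n; ++b)
    for (int a = 0; a < n; ++a) {
      outdeg[a] += xp[a + n * b];
      indeg[b] += xp[a + n * b];
    }
  std::vector<Effect> effs = build_effects(codes, betas, attr, dyads);
  std::vector<int> step_i, step_j;
  std::vector<double> lambda(n), f(n), prob(n);
  double t = 0.0;
  int nsteps = 0;
  while (nsteps < max_steps) {
    double total = 0.0;
    for (int a = 0; a < n; ++a) {
      lambda[a] = presence[a] > 0.0
        ? rho * std::exp(alpha * outdeg[a]) * presence[a] : 0.0;
      total += lambda[a];
    }
    if (total <= 0.0) break;
    t += R::rexp(1.0 / total);
    if (t > 1.0) break;
    // draw acting actor proportional to its rate
    double u = R::runif(0.0, total);
    int i = 0;
    double acc = lambda[0];
    while (u > acc && i < n - 1) acc += lambda[++i];
    // candidate evaluations; no-change option sits at position i
    f[i] = actor_eval(effs, i, xp, outdeg.data(), indeg.data(), n);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (presence[j] <= 0.0) { // absent alters are out of the choice set
        f[j] = R_NegInf;
        continue;
      }
      int old = xp[i + n * j], nw = 1 - old;
      xp[i + n * j] = nw; outdeg[i] += nw - old; indeg[j] += nw - old;
      f[j] = actor_eval(effs, i, xp, outdeg.data(), indeg.data(), n);
      xp[i + n * j] = old; outdeg[i] -= nw - old; indeg[j] -= nw - old;
    }
    double mx = R_NegInf;
    for (int j = 0; j < n; ++j) if (f[j] > mx) mx = f[j];
    double z = 0.0;
    for (int j = 0; j < n; ++j) {
      prob[j] = std::isfinite(f[j]) ? std::exp(f[j] - mx) : 0.0;
      z += prob[j];
    }
    double v = R::runif(0.0, z);
    int choice = 0;
    double acc2 = prob[0];
    while (v > acc2 && choice < n - 1) acc2 += prob[++choice];
    if (choice != i) {
      int old = xp[i + n * choice], nw = 1 - old;
      xp[i + n * choice] = nw;
      outdeg[i] += nw - old;
      indeg[choice] += nw - old;
      if (record) { step_i.push_back(i + 1); step_j.push_back(choice + 1); }
    } else if (record) {
      step_i.push_back(i + 1); step_j.push_back(0);
    }
    ++nsteps;
  }
  List out = List::create(_["x"] = x, _["n_steps"] = nsteps);
  if (record)
    out["steps"] = DataFrame::create(_["actor"] = wrap(step_i),
                                     _["target"] = wrap(step_j));
  return out;
}
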