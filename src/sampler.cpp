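#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// mean kinetic factor over variants at kinetic parameter C, given
// b_i = 1 + exp(dg_i / kT)
static double mean_kappa_at(double C, const std::vector<double>& b) {
  double s = 0.0;
  for (double bi : b) s += std::exp(-C * bi);
  return s / (double)b.size();
}

static double solve_c_impl(double kappa_bar, const std::vector<double>& b) {
  double lo = 0.0, hi = 1.0;
  int guard = 0;
  while (mean_kappa_at(hi, b) > kappa_bar && guard++ < 4000) hi *= 2.0;
  // bisection to relative tolerance 1e-10 (mean kappa is strictly
  // decreasing in C, so the bracket is valid)
  for (int it = 0; it < 1000 && (hi - lo) > 1e-10 * hi; ++it) {
    double mid = 0.5 * (lo + hi);
    if (mean_kappa_at(mid, b) > kappa_bar) lo = mid; else hi = mid;
  }
  return 0.5 * (lo + hi);
}

// [[Rcpp::export]]
double solve_c_cpp(double kappa_bar, NumericVector dg, double kT) {
  std::vector<double> b(dg.size());
  for (int i = 0; i < dg.size(); ++i) b[i] = 1.0 + std::exp(dg[i] / kT);
  return solve_c_impl(kappa_bar, b);
}

// Gaussian log-likelihood term of one variant
static inline double ll_term(double fs_exp, double fs_model, double sigma) {
  double r = fs_exp - fs_model;
  return -0.5 * std::log(2.0 * M_PI * sigma * sigma) -
         r * r / (2.0 * sigma * sigma);
}

static inline double fs_of(double dgtot, double kT) {
  return 1.0 / (1.0 + std::exp(dgtot / kT)); // logistic, overflow-safe
}

// full log-likelihood with the kinetic factor; kappa_bar on the closed
// interval [0, 1]: 0 means full equilibration (all kappa_i = 0), 1 means
// no frameshifting at all
static double loglik_kinetic(const std::vector<double>& dgtot,
                             const NumericVector& fs_exp,
                             const NumericVector& sigma,
                             double kappa_bar, double kT) {
  int N = dgtot.size();
  std::vector<double> kap(N, 0.0);
  if (kappa_bar >= 1.0) {
    std::fill(kap.begin(), kap.end(), 1.0);
  } else if (kappa_bar > 0.0) {
    std::vector<double> b(N);
    for (int i = 0; i < N; ++i) b[i] = 1.0 + std::exp(dgtot[i] / kT);
    double C = solve_c_impl(kappa_bar, b);
    for (int i = 0; i < N; ++i) kap[i] = std::exp(-C * b[i]);
  }
  double ll = 0.0;
  for (int i = 0; i < N; ++i)
    ll += ll_term(fs_exp[i], fs_of(dgtot[i], kT) * (1.0 - kap[i]), sigma[i]);
  return ll;
}

// Metropolis-within-Gibbs sampler for the base-pair free-energy posterior.
//
// One Metropolis step = one sequential sub-step per free (unpinned)
// variable, plus, when kinetic, one sub-step for the mean kinetic factor.
// Each sub-step consumes exactly two draws from R's RNG stream, in this
// order: the Gaussian proposal (R::rnorm), then the acceptance uniform
// (R::unif_rand).  Proposals outside the closed prior box are rejected
// (the uniform is still drawn, keeping the stream layout fixed).  Pinned
// variables are held at 0 and consume no draws.  The state after each
// full step is recorded.
// [[Rcpp::export]]
List metropolis_cpp(IntegerMatrix M, NumericVector fs_exp,
                    NumericVector sigma_exp, int n_steps,
                    double proposal_sigma, double prior_low,
                    double prior_high, LogicalVector pinned, double kT,
                    bool kinetic, double kappa_proposal_sigma,
                    double kappa_init) {
  const int N = M.nrow(), n = M.ncol();
  if (fs_exp.size() != N || sigma_exp.size() != N)
    stop("design matrix and data dimensions disagree");
  if (pinned.size() != n)
    stop("pinned mask length must equal the number of variables");

  // column sparsity for incremental updates
  std::vector<std::vector<std::pair<int, int>>> cols(n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < N; ++i)
      if (M(i, j) != 0) cols[j].push_back(std::make_pair(i, M(i, j)));

  std::vector<double> dg(n, 0.0), dgtot(N, 0.0), lterm(N);
  double ll = 0.0;
  if (kinetic) {
    ll = loglik_kinetic(dgtot, fs_exp, sigma_exp, kappa_init, kT);
  } else {
    for (int i = 0; i < N; ++i) {
      lterm[i] = ll_term(fs_exp[i], fs_of(dgtot[i], kT), sigma_exp[i]);
      ll += lterm[i];
    }
  }
  double kb = kappa_init;

  NumericMatrix out(n_steps, n);
  NumericVector kout(kinetic ? n_steps : 0);
  IntegerVector accept(n), kaccept(1);

  RNGScope scope;
  for (int s = 0; s < n_steps; ++s) {
    for (int j = 0; j < n; ++j) {
      if (pinned[j]) continue;
      double prop = R::rnorm(dg[j], proposal_sigma);
      double u = R::unif_rand();
      if (prop < prior_low || prop > prior_high) continue;
      double delta = prop - dg[j];
      if (!kinetic) {
        double dll = 0.0;
        for (size_t k = 0; k < cols[j].size(); ++k) {
          int i = cols[j][k].first, m = cols[j][k].second;
          double nt = ll_term(fs_exp[i], fs_of(dgtot[i] + m * delta, kT),
                              sigma_exp[i]);
          dll += nt - lterm[i];
        }
        if (std::log(u) <= dll) {
          dg[j] = prop;
          for (size_t k = 0; k < cols[j].size(); ++k) {
            int i = cols[j][k].first, m = cols[j][k].second;
            dgtot[i] += m * delta;
            lterm[i] = ll_term(fs_exp[i], fs_of(dgtot[i], kT), sigma_exp[i]);
          }
          ll += dll;
          accept[j]++;
        }
      } else {
        std::vector<double> nt(dgtot);
        for (size_t k = 0; k < cols[j].size(); ++k)
          nt[cols[j][k].first] += cols[j][k].second * delta;
        double lln = loglik_kinetic(nt, fs_exp, sigma_exp, kb, kT);
        if (std::log(u) <= lln - ll) {
          dg[j] = prop;
          dgtot.swap(nt);
          ll = lln;
          accept[j]++;
        }
      }
    }
    if (kinetic) {
      double prop = R::rnorm(kb, kappa_proposal_sigma);
      double u = R::unif_rand();
      if (prop >= 0.0 && prop <= 1.0) { // uniform prior on [0, 1]
        double lln = loglik_kinetic(dgtot, fs_exp, sigma_exp, prop, kT);
        if (std::log(u) <= lln - ll) {
          kb = prop;
          ll = lln;
          kaccept[0]++;
        }
      }
      kout[s] = kb;
    }
    for (int j = 0; j < n; ++j) out(s, j) = dg[j];
  }

  return List::create(_["dg_samples"] = out, _["kappa_samples"] = kout,
                      _["accept"] = accept, _["kappa_accept"] = kaccept,
                      _["final_loglik"] = ll);
}

// posterior-predictive mean and sd of the frameshifting efficiency per
// design row, streaming over posterior samples
// [[Rcpp::export]]
List predict_fs_cpp(NumericMatrix S, NumericVector kappa_samples,
                    IntegerMatrix M, double kT) {
  const int ns = S.nrow(), n = S.ncol(), N = M.nrow();
  if (n != M.ncol()) stop("sample and design dimensions disagree");
  bool kinetic = kappa_samples.size() > 0;
  if (kinetic && kappa_samples.size() != ns)
    stop("kappa_samples length must equal the number of samples");

  std::vector<std::vector<std::pair<int, int>>> rows(N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < n; ++j)
      if (M(i, j) != 0) rows[i].push_back(std::make_pair(j, M(i, j)));

  std::vector<double> sum(N, 0.0), sumsq(N, 0.0), dgtot(N), b(N);
  for (int s = 0; s < ns; ++s) {
    for (int i = 0; i < N; ++i) {
      double t = 0.0;
      for (size_t k = 0; k < rows[i].size(); ++k)
        t += rows[i][k].second * S(s, rows[i][k].first);
      dgtot[i] = t;
    }
    std::vector<double> kap(N, 0.0);
    if (kinetic) {
      double kb = kappa_samples[s];
      if (kb >= 1.0) std::fill(kap.begin(), kap.end(), 1.0);
      else if (kb > 0.0) {
        for (int i = 0; i < N; ++i) b[i] = 1.0 + std::exp(dgtot[i] / kT);
        double C = solve_c_impl(kb, b);
        for (int i = 0; i < N; ++i) kap[i] = std::exp(-C * b[i]);
      }
    }
    for (int i = 0; i < N; ++i) {
      double f = fs_of(dgtot[i], kT) * (1.0 - kap[i]);
      sum[i] += f;
      sumsq[i] += f * f;
    }
  }
  NumericVector mean(N), sd(N);
  for (int i = 0; i < N; ++i) {
    mean[i] = sum[i] / ns;
    double var = ns > 1 ? (sumsq[i] - ns * mean[i] * mean[i]) / (ns - 1) : 0.0;
    sd[i] = var > 0 ? std::sqrt(var) : 0.0;
  }
  return List::create(_["mean"] = mean, _["sd"] = sd);
}
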