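// Metropolis-within-Gibbs sampler for the Bayesian APC model.
//
// Observation model: y(i,j) ~ Poisson( off(i,j) * exp(mu + a_i + p_j + c_k) )
// with off = person-years / 1e5 and k = M(I-i)+j. Effects carry RW2 priors
// kappa^((d-2)/2) exp(-kappa/2 x'Qx); precisions carry conjugate
// Gamma(alpha, lambda) hyperpriors and are drawn exactly from their full
// conditional Gamma(alpha + (d-2)/2, lambda + x'Qx/2). Effect components
// are updated one at a time by Gaussian random-walk MH; proposal scales are
// adapted during burn-in only, so detailed balance holds for retained
// draws. Uses R's RNG, so results are reproducible under set.seed().

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline double qform(const NumericMatrix& Q, const std::vector<double>& x) {
  const int d = x.size();
  double s = 0.0;
  for (int r = 0; r < d; ++r) {
    double qx = 0.0;
    for (int cidx = 0; cidx < d; ++cidx) qx += Q(r, cidx) * x[cidx];
    s += x[r] * qx;
  }
  return s;
}

// change in x'Qx when x[i] += delta
static inline double qform_delta(const NumericMatrix& Q,
                                 const std::vector<double>& x,
                                 int i, double delta) {
  const int d = x.size();
  double qx = 0.0;
  for (int r = 0; r < d; ++r) qx += Q(i, r) * x[r];
  return 2.0 * delta * qx + delta * delta * Q(i, i);
}

// [[Rcpp::export]]
List apc_gibbs_cpp(const NumericMatrix y, const NumericMatrix off,
                   const IntegerMatrix kmap, const int K,
                   const NumericVector alphas, const NumericVector lambdas,
                   const NumericMatrix Qa, const NumericMatrix Qp,
                   const NumericMatrix Qc, const int iterations,
                   const int burnin, const int thin,
                   const NumericVector scales0, const bool adapt) {
  const int I = y.nrow(), J = y.ncol();

  // sufficient sums and cohort cell lists
  std::vector<double> rowY(I, 0.0), colY(J, 0.0), kY(K, 0.0);
  double totY = 0.0, totOff = 0.0;
  std::vector< std::vector<int> > kcells(K);
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) {
      rowY[i] += y(i, j); colY[j] += y(i, j); totY += y(i, j);
      totOff += off(i, j);
      kY[kmap(i, j) - 1] += y(i, j);
      kcells[kmap(i, j) - 1].push_back(i + I * j);
    }

  // state
  double mu = std::log((totY + 0.5) / totOff);
  std::vector<double> a(I, 0.0), p(J, 0.0), cvec(K, 0.0);
  double kap[3];
  for (int b = 0; b < 3; ++b) kap[b] = alphas[b] / lambdas[b];

  NumericMatrix M(I, J);  // fitted means, maintained incrementally
  for (int j = 0; j < J; ++j)
    for (int i = 0; i < I; ++i) M(i, j) = off(i, j) * std::exp(mu);

  const int nkeep = (iterations - burnin) / thin;
  NumericVector keep_mu(nkeep), keep_lp(nkeep);
  NumericMatrix keep_a(nkeep, I), keep_p(nkeep, J), keep_c(nkeep, K),
      keep_kap(nkeep, 3);

  double scales[4];
  for (int b = 0; b < 4; ++b) scales[b] = scales0[b % scales0.size()];
  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};
  long post_att[4] = {0, 0, 0, 0}, post_acc[4] = {0, 0, 0, 0};

  int kept = 0;
  for (int iter = 1; iter <= iterations; ++iter) {
    const bool post = iter > burnin;

    // --- intercept (flat prior) ---
    {
      double totM = 0.0;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < I; ++i) totM += M(i, j);
      double delta = norm_rand() * scales[0];
      double dll = delta * totY - std::expm1(delta) * totM;
      ++att[0]; if (post) ++post_att[0];
      if (std::log(unif_rand()) < dll) {
        ++acc[0]; if (post) ++post_acc[0];
        mu += delta;
        double ed = std::exp(delta);
        for (int j = 0; j < J; ++j)
          for (int i = 0; i < I; ++i) M(i, j) *= ed;
      }
    }

    // --- age effects ---
    for (int i = 0; i < I; ++i) {
      double sM = 0.0;
      for (int j = 0; j < J; ++j) sM += M(i, j);
      double delta = norm_rand() * scales[1];
      double dpost = delta * rowY[i] - std::expm1(delta) * sM -
                     0.5 * kap[0] * qform_delta(Qa, a, i, delta);
      ++att[1]; if (post) ++post_att[1];
      if (std::log(unif_rand()) < dpost) {
        ++acc[1]; if (post) ++post_acc[1];
        a[i] += delta;
        double ed = std::exp(delta);
        for (int j = 0; j < J; ++j) M(i, j) *= ed;
      }
    }

    // --- period effects ---
    for (int j = 0; j < J; ++j) {
      double sM = 0.0;
      for (int i = 0; i < I; ++i) sM += M(i, j);
      double delta = norm_rand() * scales[2];
      double dpost = delta * colY[j] - std::expm1(delta) * sM -
                     0.5 * kap[1] * qform_delta(Qp, p, j, delta);
      ++att[2]; if (post) ++post_att[2];
      if (std::log(unif_rand()) < dpost) {
        ++acc[2]; if (post) ++post_acc[2];
        p[j] += delta;
        double ed = std::exp(delta);
        for (int i = 0; i < I; ++i) M(i, j) *= ed;
      }
    }

    // --- cohort effects ---
    for (int k = 0; k < K; ++k) {
      double sM = 0.0;
      const std::vector<int>& cells = kcells[k];
      for (size_t u = 0; u < cells.size(); ++u)
        sM += M[cells[u]];
      double delta = norm_rand() * scales[3];
      double dpost = delta * kY[k] - std::expm1(delta) * sM -
                     0.5 * kap[2] * qform_delta(Qc, cvec, k, delta);
      ++att[3]; if (post) ++post_att[3];
      if (std::log(unif_rand()) < dpost) {
        ++acc[3]; if (post) ++post_acc[3];
        cvec[k] += delta;
        double ed = std::exp(delta);
        for (size_t u = 0; u < cells.size(); ++u)
          M[cells[u]] *= ed;
      }
    }

    // --- conjugate precision updates ---
    double qf[3] = {qform(Qa, a), qform(Qp, p), qform(Qc, cvec)};
    int dims[3] = {I, J, K};
    for (int b = 0; b < 3; ++b) {
      if (!std::isfinite(qf[b])) stop("non-finite RW2 quadratic form");
      kap[b] = R::rgamma(alphas[b] + 0.5 * (dims[b] - 2),
                         1.0 / (lambdas[b] + 0.5 * qf[b]));
    }

    // --- proposal adaptation (burn-in only) ---
    if (adapt && iter <= burnin && iter % 50 == 0) {
      for (int b = 0; b < 4; ++b) {
        double rate = att[b] > 0 ? (double)acc[b] / att[b] : 0.0;
        scales[b] *= std::exp(0.8 * (rate - 0.4));
        if (scales[b] < 1e-6) scales[b] = 1e-6;
        if (scales[b] > 10.0) scales[b] = 10.0;
        att[b] = acc[b] = 0;
      }
    }

    // --- retention ---
    if (post && (iter - burnin) % thin == 0 && kept < nkeep) {
      double lp = 0.0;
      for (int j = 0; j < J; ++j)
        for (int i = 0; i < I; ++i) {
          lp -= M(i, j);
          if (y(i, j) > 0) lp += y(i, j) * std::log(M(i, j));
        }
      for (int b = 0; b < 3; ++b)
        lp += 0.5 * (dims[b] - 2) * std::log(kap[b]) - 0.5 * kap[b] * qf[b] +
              (alphas[b] - 1.0) * std::log(kap[b]) - lambdas[b] * kap[b];
      if (!std::isfinite(lp))
        stop("divergence: non-finite log posterior at iteration %d", iter);
      keep_mu[kept] = mu; keep_lp[kept] = lp;
      for (int i = 0; i < I; ++i) keep_a(kept, i) = a[i];
      for (int j = 0; j < J; ++j) keep_p(kept, j) = p[j];
      for (int k = 0; k < K; ++k) keep_c(kept, k) = cvec[k];
      for (int b = 0; b < 3; ++b) keep_kap(kept, b) = kap[b];
      ++kept;
    }
  }

  NumericVector arate(4);
  for (int b = 0; b < 4; ++b)
    arate[b] = post_att[b] > 0 ? (double)post_acc[b] / post_att[b] : NA_REAL;
  arate.names() = CharacterVector::create("intercept", "age", "period",
                                          "cohort");
  return List::create(_["mu"] = keep_mu, _["age"] = keep_a,
                      _["period"] = keep_p, _["cohort"] = keep_c,
                      _["kappa"] = keep_kap, _["logPosterior"] = keep_lp,
                      _["acceptance"] = arate);
}
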