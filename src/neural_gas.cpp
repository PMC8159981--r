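#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Squared Euclidean distances from x to every codebook row.
static void sq_dists(const NumericMatrix& W, const double* x, int d,
                     std::vector<double>& out) {
  const int K = W.nrow();
  for (int i = 0; i < K; ++i) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) {
      const double diff = W(i, j) - x[j];
      s += diff * diff;
    }
    out[i] = s;
  }
}

// Distance ranks: rank_i = #{j : d_j < d_i, or d_j == d_i and j < i}.
// Ties are broken by unit index so the update is fully deterministic.
static void dist_ranks(const std::vector<double>& dist, std::vector<int>& rank) {
  const int K = (int)dist.size();
  for (int i = 0; i < K; ++i) {
    int r = 0;
    for (int j = 0; j < K; ++j) {
      if (j == i) continue;
      if (dist[j] < dist[i] || (dist[j] == dist[i] && j < i)) ++r;
    }
    rank[i] = r;
  }
}

// One neural-gas adaptation: w_i += eps * exp(-rank_i / lambda) * (x - w_i).
static void adapt_one(NumericMatrix& W, const double* x, int d,
                      double eps, double lambda,
                      std::vector<double>& dist, std::vector<int>& rank) {
  const int K = W.nrow();
  sq_dists(W, x, d, dist);
  dist_ranks(dist, rank);
  for (int i = 0; i < K; ++i) {
    const double h = eps * std::exp(-(double)rank[i] / lambda);
    if (h == 0.0) continue;
    for (int j = 0; j < d; ++j) W(i, j) += h * (x[j] - W(i, j));
  }
}

// [[Rcpp::export(name = ".ng_adapt_cpp")]]
NumericMatrix ng_adapt_cpp(NumericMatrix W, NumericVector x,
                           double eps, double lambda) {
  NumericMatrix Wout = clone(W);
  std::vector<double> dist(W.nrow());
  std::vector<int> rank(W.nrow());
  adapt_one(Wout, x.begin(), W.ncol(), eps, lambda, dist, rank);
  return Wout;
}

// [[Rcpp::export(name = ".ng_ss_intra_cpp")]]
double ng_ss_intra_cpp(NumericMatrix X, NumericMatrix W) {
  const int n = X.nrow(), d = X.ncol(), K = W.nrow();
  double total = 0.0;
  for (int s = 0; s < n; ++s) {
    double best = R_PosInf;
    for (int i = 0; i < K; ++i) {
      double acc = 0.0;
      for (int j = 0; j < d; ++j) {
        const double diff = X(s, j) - W(i, j);
        acc += diff * diff;
      }
      if (acc < best) best = acc;
    }
    total += best;
  }
  return total;
}

// Online training: `orders` holds one shuffled presentation order per epoch
// (1-based sample indices, epochs x n).  The global step t drives both
// exponential schedules with t_max = epochs * n.
// [[Rcpp::export(name = ".ng_train_cpp")]]
List ng_train_cpp(NumericMatrix X, NumericMatrix W0, IntegerMatrix orders,
                  double eps_init, double eps_final,
                  double lambda_init, double lambda_final) {
  const int n = X.nrow(), d = X.ncol();
  const int epochs = orders.nrow();
  const double t_max = (double)epochs * (double)n;
  NumericMatrix W = clone(W0);
  NumericVector ss_hist(epochs);
  std::vector<double> dist(W.nrow());
  std::vector<int> rank(W.nrow());
  std::vector<double> x(d);
  const double leps = std::log(eps_final / eps_init);
  const double llam = std::log(lambda_final / lambda_init);
  double t = 0.0;
  for (int e = 0; e < epochs; ++e) {
    for (int s = 0; s < n; ++s) {
      const int idx = orders(e, s) - 1;
      for (int j = 0; j < d; ++j) x[j] = X(idx, j);
      const double frac = t / t_max;
      const double eps = eps_init * std::exp(leps * frac);
      const double lambda = lambda_init * std::exp(llam * frac);
      adapt_one(W, x.data(), d, eps, lambda, dist, rank);
      t += 1.0;
    }
    ss_hist[e] = ng_ss_intra_cpp(X, W);
  }
  return List::create(_["codebook"] = W, _["ss_intra_history"] = ss_hist);
}
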