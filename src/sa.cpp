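#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// per-draw whole-area equilibrium density K_n(E) = sum_i c(i,n) exp(b_n E_i)
// cmat: units x draws, b: draws, effort: units
// [[Rcpp::export]]
NumericVector cppObjectivePerDraw(const NumericMatrix& cmat,
                                  const NumericVector& b,
                                  const NumericVector& effort) {
  const int I = cmat.nrow(), N = cmat.ncol();
  if (b.size() != N) stop("b length must equal the number of draws");
  if (effort.size() != I) stop("effort length must equal the unit count");
  NumericVector K(N);
  for (int n = 0; n < N; ++n) {
    const double bn = b[n];
    double acc = 0.0;
    const double* col = &cmat(0, n);
    for (int i = 0; i < I; ++i) acc += col[i] * std::exp(bn * effort[i]);
    K[n] = acc;
  }
  return K;
}

static double objU(const NumericMatrix& cmat, const NumericVector& b,
                   const std::vector<double>& effort) {
  const int I = cmat.nrow(), N = cmat.ncol();
  double tot = 0.0;
  for (int n = 0; n < N; ++n) {
    const double bn = b[n];
    double acc = 0.0;
    const double* col = &cmat(0, n);
    for (int i = 0; i < I; ++i) acc += col[i] * std::exp(bn * effort[i]);
    tot += acc;
  }
  return tot / N;
}

// softmax map from I-1 auxiliary variables to the effort simplex,
// max-shifted against overflow; the last unit takes the exact remainder
static void softmaxEffort(const std::vector<double>& a, double Etotal,
                          std::vector<double>& effort) {
  const int I = (int)a.size() + 1;
  double mx = 0.0;  // implicit a_I = 0
  for (double ai : a) if (ai > mx) mx = ai;
  double denom = std::exp(-mx);
  for (double ai : a) denom += std::exp(ai - mx);
  double sum = 0.0;
  for (int i = 0; i < I - 1; ++i) {
    effort[i] = Etotal * std::exp(a[i] - mx) / denom;
    sum += effort[i];
  }
  effort[I - 1] = Etotal - sum;
  if (effort[I - 1] < 0.0) effort[I - 1] = 0.0;
}

// simulated annealing on the softmax reparameterization: Gaussian
// single-coordinate proposals, exponential cooling per sweep of I
// proposals, best-found solution tracked. Uses R's RNG for
// reproducibility under set.seed().
// [[Rcpp::export]]
List cppAnnealAllocation(NumericVector a0, double Etotal,
                         const NumericMatrix& cmat, const NumericVector& b,
                         int steps, double t0, double cooling,
                         double propSD) {
  const int I = cmat.nrow();
  if ((int)a0.size() != I - 1) stop("a0 must have length I - 1");
  std::vector<double> a(a0.begin(), a0.end()), aBest(a), effort(I);
  softmaxEffort(a, Etotal, effort);
  double u = objU(cmat, b, effort);
  double uBest = u;
  double temp = t0;
  const int sweep = std::max(I - 1, 1);
  RNGScope scope;
  for (int s = 0; s < steps; ++s) {
    int j = (int)std::floor(unif_rand() * (I - 1));
    if (j >= I - 1) j = I - 2;
    const double old = a[j];
    a[j] += propSD * norm_rand();
    softmaxEffort(a, Etotal, effort);
    const double uNew = objU(cmat, b, effort);
    const double dU = uNew - u;
    if (R_finite(uNew) && (dU <= 0.0 || unif_rand() < std::exp(-dU / temp))) {
      u = uNew;
      if (u < uBest) { uBest = u; aBest = a; }
    } else {
      a[j] = old;
    }
    if ((s + 1) % sweep == 0) temp *= cooling;
  }
  softmaxEffort(aBest, Etotal, effort);
  return List::create(_["a"] = NumericVector(aBest.begin(), aBest.end()),
                      _["effort"] = NumericVector(effort.begin(),
                                                  effort.end()),
                      _["U"] = uBest);
}
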