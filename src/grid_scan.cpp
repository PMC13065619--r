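#include <Rcpp.h>
using namespace Rcpp;

// Exhaustive scan of the diet-proportion simplex grid.
//
// M: m x k matrix of source mean signatures (calibration coefficients
//    already folded into the rows), obs: length-m observed signature,
// nsteps: grid resolution (proportions are multiples of 1/nsteps),
// rescale: if true the mixture prediction is rescaled to `total` before
//    the absolute deviation is computed.
//
// Enumerates compositions (c_1,...,c_k) of nsteps in ascending
// lexicographic order; keeping only strict improvements therefore returns
// the lexicographically smallest argmin. Ties within `tie_tol` of the
// final minimum are counted. Also accumulates, for every source j and
// grid value v, the minimum deviation over all diets with p_j = v
// (the uniqueness profile).
// [[Rcpp::export]]
List grid_scan(const NumericMatrix& M, const NumericVector& obs,
               const int nsteps, const bool rescale, const double total,
               const bool profile = true, const double tie_tol = 1e-9) {
  const int m = M.nrow(), k = M.ncol();
  if (obs.size() != m) stop("observed signature length mismatch");
  if (nsteps < 1) stop("nsteps must be >= 1");
  if (k < 2) stop("need at least 2 sources");

  std::vector<int> c(k, 0);
  c[k - 1] = nsteps;
  std::vector<int> best(k, 0);
  double best_dev = R_PosInf;
  long n_ties = 0;

  NumericMatrix prof(profile ? k : 0, profile ? (nsteps + 1) : 0);
  if (profile) std::fill(prof.begin(), prof.end(), R_PosInf);

  std::vector<double> q(m);
  const double inv_n = 1.0 / nsteps;
  unsigned long iter = 0;

  for (;;) {
    // mixture prediction q = M * p
    double qsum = 0.0;
    for (int i = 0; i < m; ++i) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += c[j] * M(i, j);
      q[i] = acc * inv_n;
      qsum += q[i];
    }
    double dev;
    if (rescale) {
      if (qsum <= 0.0) {
        dev = R_PosInf;
      } else {
        const double scale = total / qsum;
        dev = 0.0;
        for (int i = 0; i < m; ++i) dev += std::fabs(q[i] * scale - obs[i]);
      }
    } else {
      dev = 0.0;
      for (int i = 0; i < m; ++i) dev += std::fabs(q[i] - obs[i]);
    }

    if (dev < best_dev - tie_tol) {
      best_dev = dev;
      for (int j = 0; j < k; ++j) best[j] = c[j];
      n_ties = 1;
    } else if (dev <= best_dev + tie_tol) {
      ++n_ties;
      if (dev < best_dev) best_dev = dev;  // keep earlier (lex-smaller) argmin
    }
    if (profile) {
      for (int j = 0; j < k; ++j) {
        if (dev < prof(j, c[j])) prof(j, c[j]) = dev;
      }
    }

    // lexicographic successor
    if (c[0] == nsteps) break;
    if (c[k - 1] > 0) {
      const int s = c[k - 1];
      c[k - 1] = 0;
      c[k - 2] += 1;
      c[k - 1] = s - 1;
    } else {
      int j = k - 2;
      while (c[j] == 0) --j;
      const int s = c[j];
      c[j] = 0;
      c[j - 1] += 1;
      c[k - 1] = s - 1;
    }
    if ((++iter & 0xFFFFUL) == 0UL) R_CheckUserInterrupt();
  }

  IntegerVector best_out(best.begin(), best.end());
  return List::create(_["best"] = best_out,
                      _["bmd"] = best_dev,
                      _["n_ties"] = (double) n_ties,
                      _["profile"] = prof);
}
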