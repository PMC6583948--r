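#include <Rcpp.h>
using namespace Rcpp;

// Individual-based death-birth-immigration process over S independent local
// communities of fixed size N. One event: a uniformly chosen individual dies
// and is replaced either by an immigrant drawn from the source pool (with
// probability m) or by the offspring of a parent drawn uniformly from the
// remaining N - 1 residents (with probability 1 - m). The two-taxon marginal
// of this update is the classical Moran-with-immigration birth-death chain.

static inline int draw_categorical(const std::vector<double>& cum) {
  double u = unif_rand();
  int lo = 0, hi = (int)cum.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cum[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// init: D x S integer matrix of taxon counts, every column summing to N.
// source: length-D relative abundances of the source pool (sum to 1).
// checkpoints: strictly increasing event counts (per community) at which the
// community state is recorded; the last entry is the total number of events.
// Returns an integer vector with dim c(D, S, length(checkpoints)).
// [[Rcpp::export(name = ".simulate_dbi")]]
IntegerVector simulate_dbi(IntegerMatrix init, NumericVector source,
                           double m, NumericVector checkpoints) {
  const int D = init.nrow(), S = init.ncol(), C = checkpoints.size();
  if (source.size() != D) stop("length(source) must equal nrow(init)");
  if (m < 0.0 || m > 1.0) stop("m must lie in [0, 1]");
  for (int c = 1; c < C; ++c)
    if (checkpoints[c] <= checkpoints[c - 1])
      stop("checkpoints must be strictly increasing");

  std::vector<double> cum(D);
  double acc = 0.0;
  for (int i = 0; i < D; ++i) { acc += source[i]; cum[i] = acc; }
  if (std::abs(acc - 1.0) > 1e-8) stop("source abundances must sum to 1");
  cum[D - 1] = 1.0;

  int N = 0;
  for (int i = 0; i < D; ++i) N += init(i, 0);
  if (N < 2) stop("community size N must be at least 2");

  IntegerVector out(static_cast<R_xlen_t>(D) * S * C);
  std::vector<int> pool(N);
  std::vector<int> counts(D);

  for (int s = 0; s < S; ++s) {
    int k = 0;
    for (int i = 0; i < D; ++i) {
      int ci = init(i, s);
      if (ci < 0) stop("negative count in community %d", s + 1);
      counts[i] = ci;
      for (int j = 0; j < ci; ++j) {
        if (k >= N) stop("community %d does not sum to N", s + 1);
        pool[k++] = i;
      }
    }
    if (k != N) stop("community %d does not sum to N", s + 1);

    double ev = 0.0;
    for (int c = 0; c < C; ++c) {
      const double target = checkpoints[c];
      while (ev < target) {
        int die = (int)(unif_rand() * N);
        if (die >= N) die = N - 1;
        int repl;
        if (unif_rand() < m) {
          repl = draw_categorical(cum);
        } else {
          int j = (int)(unif_rand() * (N - 1));
          if (j >= N - 1) j = N - 2;
          if (j >= die) ++j;  // parent uniform among the other N - 1
          repl = pool[j];
        }
        counts[pool[die]]--;
        counts[repl]++;
        pool[die] = repl;
        ev += 1.0;
      }
      R_xlen_t off = static_cast<R_xlen_t>(c) * D * S +
                     static_cast<R_xlen_t>(s) * D;
      for (int i = 0; i < D; ++i) out[off + i] = counts[i];
    }
    Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(D, S, C);
  return out;
}
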