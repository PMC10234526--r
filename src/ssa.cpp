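#include <Rcpp.h>
using namespace Rcpp;

// Gillespie direct method over a mass-action network.
// stoich: n_species x n_reactions net-change matrix.
// order/rate/s1/s2: propensity spec per reaction; s1, s2 are 0-based species
// indices (s < 0 means unused). Propensity = rate, rate*x[s1], or
// rate*x[s1]*x[s2]. Uses R's RNG so set.seed() governs reproducibility.
// Returns the state sampled on the regular grid `times` (state at each t).
// [[Rcpp::export(name = ".ssa_core")]]
IntegerMatrix ssa_core(IntegerMatrix stoich, IntegerVector order,
                       NumericVector rate, IntegerVector s1, IntegerVector s2,
                       IntegerVector x0, NumericVector times) {
  const int ns = stoich.nrow(), nr = stoich.ncol(), nt = times.size();
  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];
  std::vector<double> a(nr);
  IntegerMatrix out(nt, ns);
  double t = 0.0;
  int gi = 0;
  RNGScope scope;
  while (gi < nt) {
    double a0 = 0.0;
    for (int r = 0; r < nr; ++r) {
      double ar = rate[r];
      if (order[r] >= 1) ar *= x[s1[r]];
      if (order[r] == 2) ar *= x[s2[r]];
      a[r] = ar;
      a0 += ar;
    }
    double tnext;
    if (a0 <= 0.0) {
      tnext = R_PosInf;  // absorbing state: fill the rest of the grid
    } else {
      tnext = t + R::exp_rand() / a0;
    }
    while (gi < nt && times[gi] < tnext) {
      for (int i = 0; i < ns; ++i) out(gi, i) = (int)x[i];
      ++gi;
    }
    if (gi >= nt) break;
    if (!R_FINITE(tnext)) break;
    double u = unif_rand() * a0, cum = 0.0;
    int r = nr - 1;
    for (int k = 0; k < nr; ++k) {
      cum += a[k];
      if (u <= cum) { r = k; break; }
    }
    for (int i = 0; i < ns; ++i) x[i] += stoich(i, r);
    t = tnext;
  }
  return out;
}
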