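#include <Rcpp.h>
using namespace Rcpp;

// Inbreeding coefficients by the Meuwissen & Luo ancestor-tracing recursion
// on the factorisation A = T D T'.  sire/dam are 0-based indices into a
// parents-first (topological) ordering, -1 for unknown.  For animal i with
// both parents known, F_i = 0.5 * a(s_i, d_i) with
// a(s, d) = sum_j T_{s,j} T_{d,j} D_j, where D_j is the Mendelian-sampling
// variance of j (1, 0.75 - 0.25 F_p, or 0.5 - 0.25 (F_s + F_d) for 0/1/2
// known parents).
// [[Rcpp::export]]
NumericVector ml_inbreeding_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericVector F(n);
  std::vector<double> D(n), ls(n, 0.0), ld(n, 0.0);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s >= i || d >= i)
      stop("pedigree not sorted parents-first at position %d", i + 1);
    const double Fs = (s >= 0) ? F[s] : 0.0;
    const double Fd = (d >= 0) ? F[d] : 0.0;
    D[i] = 1.0 - 0.25 * ((s >= 0) + (d >= 0)) - 0.25 * (Fs + Fd);
    if (s < 0 || d < 0) { F[i] = 0.0; continue; }
    double asd = 0.0;
    ls[s] += 1.0;
    ld[d] += 1.0;
    for (int j = (s > d ? s : d); j >= 0; --j) {
      const double cs = ls[j], cd = ld[j];
      if (cs == 0.0 && cd == 0.0) continue;
      if (cs != 0.0 && cd != 0.0) asd += cs * cd * D[j];
      const int sj = sire[j], dj = dam[j];
      if (cs != 0.0) {
        if (sj >= 0) ls[sj] += 0.5 * cs;
        if (dj >= 0) ls[dj] += 0.5 * cs;
        ls[j] = 0.0;
      }
      if (cd != 0.0) {
        if (sj >= 0) ld[sj] += 0.5 * cd;
        if (dj >= 0) ld[dj] += 0.5 * cd;
        ld[j] = 0.0;
      }
    }
    F[i] = 0.5 * asd;
  }
  return F;
}

// Dense numerator relationship matrix by the tabular method.  Quadratic in
// n; callers guard the size.
// [[Rcpp::export]]
NumericMatrix tabular_a_cpp(IntegerVector sire, IntegerVector dam) {
  const int n = sire.size();
  NumericMatrix A(n, n);
  for (int i = 0; i < n; ++i) {
    const int s = sire[i], d = dam[i];
    if (s >= i || d >= i)
      stop("pedigree not sorted parents-first at position %d", i + 1);
    for (int j = 0; j < i; ++j) {
      double aij = 0.0;
      if (s >= 0) aij += A(j, s);
      if (d >= 0) aij += A(j, d);
      aij *= 0.5;
      A(i, j) = aij;
      A(j, i) = aij;
    }
    A(i, i) = 1.0 + ((s >= 0 && d >= 0) ? 0.5 * A(s, d) : 0.0);
  }
  return A;
}
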