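#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Weighted mutual information between protein column i and site column j for
// one pairing of the records (perm maps record k to the site row it is paired
// with). Codes: protein 0..19 / site 0..3, gaps < 0. Gapped cells are missing
// data for that column pair. Pseudocount mass kappa*N is distributed by the
// factorised transition model P(b->a) * Pnt(m->n), so that marginals of the
// joint frequencies equal the positional frequencies exactly.
static double pair_mi(const int* prot, const int* site,
                      const double* wtf, const double* wsite,
                      const int* perm, int nrec,
                      int i, int j, int np_rows, int ns_rows,
                      const double* P, const double* Pnt,
                      double kappa, double inv_log_base) {
  double Nij[80] = {0.0};
  double Ni[20] = {0.0};
  double Nj[4] = {0.0};
  double Neff = 0.0;
  const int* pc_col = prot + (std::size_t)i * np_rows;
  const int* sc_col = site + (std::size_t)j * ns_rows;
  for (int k = 0; k < nrec; ++k) {
    int a = pc_col[k];
    if (a < 0) continue;
    int k2 = perm[k];
    int n = sc_col[k2];
    if (n < 0) continue;
    double w = wtf[k] * wsite[k2];
    Nij[a * 4 + n] += w;
    Ni[a] += w;
    Nj[n] += w;
    Neff += w;
  }
  if (!(Neff > 0.0)) return NA_REAL;

  // T[b][n] = sum_m Nij[b][m] Pnt(m,n);   pij[a][n] = sum_b P(b,a) T[b][n]
  double pij[80] = {0.0};
  double pi_[20] = {0.0};
  double pj[4] = {0.0};
  if (kappa > 0.0) {
    double T[80];
    for (int b = 0; b < 20; ++b) {
      if (Ni[b] <= 0.0) continue;
      for (int n = 0; n < 4; ++n) {
        double s = 0.0;
        for (int m = 0; m < 4; ++m) s += Nij[b * 4 + m] * Pnt[m + 4 * n];
        T[b * 4 + n] = s;
      }
      for (int a = 0; a < 20; ++a) {
        double pba = P[b + 20 * a]; // column-major
        if (pba == 0.0) continue;
        pi_[a] += pba * Ni[b];
        for (int n = 0; n < 4; ++n) pij[a * 4 + n] += pba * T[b * 4 + n];
      }
    }
    for (int n = 0; n < 4; ++n) {
      double s = 0.0;
      for (int m = 0; m < 4; ++m) s += Nj[m] * Pnt[m + 4 * n];
      pj[n] = s;
    }
  }
  double denom = Neff * (1.0 + kappa);
  double fj[4];
  for (int n = 0; n < 4; ++n) fj[n] = (Nj[n] + kappa * pj[n]) / denom;

  double mi = 0.0;
  for (int a = 0; a < 20; ++a) {
    double fia = (Ni[a] + kappa * pi_[a]) / denom;
    if (fia <= 0.0) continue;
    for (int n = 0; n < 4; ++n) {
      double f = (Nij[a * 4 + n] + kappa * pij[a * 4 + n]) / denom;
      if (f > 0.0) mi += f * std::log(f / (fia * fj[n]));
    }
  }
  return mi * inv_log_base;
}

// [[Rcpp::export]]
NumericMatrix mi_matrix_cpp(IntegerMatrix prot, IntegerMatrix site,
                            NumericVector w_tf, NumericVector w_site,
                            IntegerVector perm, NumericMatrix P,
                            NumericMatrix Pnt, double kappa, double log_base) {
  int nrec = prot.nrow();
  int Lp = prot.ncol();
  int Ls = site.ncol();
  double inv_log_base = 1.0 / std::log(log_base);
  NumericMatrix out(Ls, Lp);
  std::vector<int> p0(nrec);
  for (int k = 0; k < nrec; ++k) p0[k] = perm[k] - 1; // 1-based from R
  for (int i = 0; i < Lp; ++i)
    for (int j = 0; j < Ls; ++j)
      out(j, i) = pair_mi(prot.begin(), site.begin(), w_tf.begin(),
                          w_site.begin(), p0.data(), nrec, i, j,
                          prot.nrow(), site.nrow(), P.begin(), Pnt.begin(),
                          kappa, inv_log_base);
  return out;
}

// Mean and (n-1)-denominator s.d. of MI per column pair across the supplied
// permutations (one row of `perms` per re-pairing, 1-based indices).
// [[Rcpp::export]]
List null_moments_cpp(IntegerMatrix prot, IntegerMatrix site,
                      NumericVector w_tf, NumericVector w_site,
                      IntegerMatrix perms, NumericMatrix P,
                      NumericMatrix Pnt, double kappa, double log_base) {
  int nrec = prot.nrow();
  int Lp = prot.ncol();
  int Ls = site.ncol();
  int nsh = perms.nrow();
  double inv_log_base = 1.0 / std::log(log_base);
  NumericMatrix msum(Ls, Lp), msum2(Ls, Lp);
  IntegerMatrix mcnt(Ls, Lp);
  std::vector<int> p0(nrec);
  for (int s = 0; s < nsh; ++s) {
    for (int k = 0; k < nrec; ++k) p0[k] = perms(s, k) - 1;
    for (int i = 0; i < Lp; ++i) {
      for (int j = 0; j < Ls; ++j) {
        double v = pair_mi(prot.begin(), site.begin(), w_tf.begin(),
                           w_site.begin(), p0.data(), nrec, i, j,
                           prot.nrow(), site.nrow(), P.begin(), Pnt.begin(),
                           kappa, inv_log_base);
        if (!ISNA(v)) {
          msum(j, i) += v;
          msum2(j, i) += v * v;
          mcnt(j, i) += 1;
        }
      }
    }
    if (s % 64 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix mean(Ls, Lp), sd(Ls, Lp);
  for (int i = 0; i < Lp; ++i) {
    for (int j = 0; j < Ls; ++j) {
      int c = mcnt(j, i);
      if (c < 2) {
        mean(j, i) = (c == 1) ? msum(j, i) : NA_REAL;
        sd(j, i) = NA_REAL;
      } else {
        double m = msum(j, i) / c;
        double var = (msum2(j, i) - c * m * m) / (c - 1);
        if (var < 0.0) var = 0.0;
        mean(j, i) = m;
        sd(j, i) = std::sqrt(var);
      }
    }
  }
  return List::create(_["mean"] = mean, _["sd"] = sd, _["n_used"] = mcnt);
}
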