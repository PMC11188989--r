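#include <Rcpp.h>
using namespace Rcpp;

// Assemble the Hermitian-symmetric complex spectrum of m real noise
// columns with amplitude shape M from pre-drawn standard normals:
// dc (m), nyq (m, even n only), re/im (half * m).  The inverse FFT of
// each column (done in R) yields real noise with spectrum M and unit
// variance for mean(M^2) == 1.
// [[Rcpp::export(name = ".hermitian_spectrum")]]
ComplexMatrix hermitian_spectrum(NumericVector M, int m, NumericVector dc,
                                 NumericVector nyq, NumericVector re,
                                 NumericVector im) {
  int n = M.size();
  int half = (n % 2 == 0) ? n / 2 - 1 : (n - 1) / 2;
  ComplexMatrix X(n, m);
  double sn = std::sqrt((double)n), sh = std::sqrt(n / 2.0);
  for (int j = 0; j < m; ++j) {
    Rcomplex *col = &X(0, j);
    col[0].r = M[0] * sn * dc[j];
    col[0].i = 0.0;
    const double *rej = &re[(R_xlen_t)j * half];
    const double *imj = &im[(R_xlen_t)j * half];
    for (int k = 1; k <= half; ++k) {
      double a = rej[k - 1] * M[k] * sh;
      double b = imj[k - 1] * M[k] * sh;
      col[k].r = a;       col[k].i = b;
      col[n - k].r = a;   col[n - k].i = -b;
    }
    if (n % 2 == 0) {
      col[n / 2].r = M[n / 2] * sn * nyq[j];
      col[n / 2].i = 0.0;
    }
  }
  return X;
}

// Fuse the per-chunk generator arithmetic in place:
// ind[, (tr-1)*nch + c] = (ind + shared[, tr]) * gvec + line(tr),
// where line(tr) = amp * sin(wt + phase[tr]) is shared by all channels
// of a trial.  Returns ind invisibly (modified in place).
// [[Rcpp::export(name = ".fuse_block")]]
NumericMatrix fuse_block(NumericMatrix ind, NumericMatrix sh, int nch,
                         NumericVector gvec, double amp,
                         NumericVector wt, NumericVector phase) {
  int n = ind.nrow();
  int nt = sh.ncol();
  std::vector<double> line(n);
  for (int tr = 0; tr < nt; ++tr) {
    const double *shc = &sh(0, tr);
    for (int i = 0; i < n; ++i) line[i] = amp * std::sin(wt[i] + phase[tr]);
    for (int c = 0; c < nch; ++c) {
      double *col = &ind(0, (R_xlen_t)tr * nch + c);
      for (int i = 0; i < n; ++i)
        col[i] = (col[i] + shc[i]) * gvec[i] + line[i];
    }
  }
  return ind;
}
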