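#include <Rcpp.h>
#include <array>
using namespace Rcpp;

// Direct-form II transposed IIR filters with caller-supplied initial
// state.  Coefficients are pre-normalized so a[0] == 1 and padded to a
// common length.  Fixed-order template instantiations keep the filter
// state in registers; the biquad (NZ=2) covers the notch cascades and
// NZ=8 the 4th-order band filters.
template <int NZ>
static void iir_filter_fixed(const double *b, const double *a,
                             const double *zinit,
                             const double *x, double *y, int n) {
  std::array<double, NZ> z;
  for (int j = 0; j < NZ; ++j) z[j] = zinit[j];
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < NZ - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[NZ - 1] = b[NZ] * xi - a[NZ] * yi;
    y[i] = yi;
  }
}

static void iir_filter_gen(const double *b, const double *a, int nz,
                           const double *zinit,
                           const double *x, double *y, int n) {
  std::vector<double> z(zinit, zinit + nz);
  for (int i = 0; i < n; ++i) {
    double xi = x[i];
    double yi = b[0] * xi + z[0];
    for (int j = 0; j < nz - 1; ++j)
      z[j] = b[j + 1] * xi + z[j + 1] - a[j + 1] * yi;
    z[nz - 1] = b[nz] * xi - a[nz] * yi;
    y[i] = yi;
  }
}

static void iir_filter(const std::vector<double> &b,
                       const std::vector<double> &a,
                       const std::vector<double> &zinit,
                       const double *x, double *y, int n) {
  int nz = (int)b.size() - 1;
  switch (nz) {
  case 2: iir_filter_fixed<2>(b.data(), a.data(), zinit.data(), x, y, n); break;
  case 4: iir_filter_fixed<4>(b.data(), a.data(), zinit.data(), x, y, n); break;
  case 6: iir_filter_fixed<6>(b.data(), a.data(), zinit.data(), x, y, n); break;
  case 8: iir_filter_fixed<8>(b.data(), a.data(), zinit.data(), x, y, n); break;
  default: iir_filter_gen(b.data(), a.data(), nz, zinit.data(), x, y, n);
  }
}

// One zero-phase (forward-backward) pass: odd-reflection padding of
// 3 * max(len(b), len(a)) samples at each end and steady-state initial
// conditions (zi, scaled by the first padded sample) on both passes --
// the scipy/MATLAB filtfilt convention, which suppresses edge
// transients.  buf holds the padded signal (pad | x | pad) and is
// overwritten; the result lands back in buf.
static void filtfilt_one(const std::vector<double> &b,
                         const std::vector<double> &a,
                         const std::vector<double> &zi,
                         std::vector<double> &buf,
                         std::vector<double> &tmp,
                         std::vector<double> &zwork,
                         int n, int pad) {
  int ntot = n + 2 * pad;
  // odd extension: 2*x[0] - x[pad..1], then x, then mirrored tail
  for (int i = 0; i < pad; ++i) {
    buf[i] = 2.0 * buf[pad] - buf[2 * pad - i];
    buf[pad + n + i] = 2.0 * buf[pad + n - 1] - buf[pad + n - 2 - i];
  }
  int nz = (int)zi.size();
  for (int j = 0; j < nz; ++j) zwork[j] = zi[j] * buf[0];
  iir_filter(b, a, zwork, buf.data(), tmp.data(), ntot);
  std::reverse(tmp.begin(), tmp.begin() + ntot);
  for (int j = 0; j < nz; ++j) zwork[j] = zi[j] * tmp[0];
  iir_filter(b, a, zwork, tmp.data(), buf.data(), ntot);
  std::reverse(buf.begin(), buf.begin() + ntot);
}

// Zero-phase filtering of each column of X by a cascade of filters
// (list of list(b, a, zi)), applied sequentially.
// [[Rcpp::export(name = ".filtfilt_cascade_cols")]]
NumericMatrix filtfilt_cascade_cols(List coefs, NumericMatrix X) {
  int n = X.nrow(), m = X.ncol();
  int nf = coefs.size();
  std::vector<std::vector<double>> bs(nf), as(nf), zis(nf);
  std::vector<int> pads(nf);
  int maxpad = 0, maxnz = 0;
  for (int q = 0; q < nf; ++q) {
    List co = coefs[q];
    NumericVector b = co["b"], a = co["a"], zi = co["zi"];
    if (a.size() < 1 || a[0] == 0.0) stop("invalid denominator coefficients");
    size_t len = std::max(b.size(), a.size());
    bs[q].assign(len, 0.0);
    as[q].assign(len, 0.0);
    for (int i = 0; i < b.size(); ++i) bs[q][i] = b[i] / a[0];
    for (int i = 0; i < a.size(); ++i) as[q][i] = a[i] / a[0];
    zis[q].assign(zi.begin(), zi.end());
    if ((int)zis[q].size() != (int)len - 1) stop("zi has wrong length");
    pads[q] = 3 * (int)len;
    maxpad = std::max(maxpad, pads[q]);
    maxnz = std::max(maxnz, (int)len - 1);
  }
  if (n <= maxpad) stop("signal too short for the filter padding");
  NumericMatrix out(n, m);
  std::vector<double> buf(n + 2 * maxpad), tmp(n + 2 * maxpad),
      zwork(maxnz);
  // a common (maximal) pad keeps every stage's result in place
  for (int j = 0; j < m; ++j) {
    const double *xi = &X(0, j);
    std::copy(xi, xi + n, buf.begin() + maxpad);
    for (int q = 0; q < nf; ++q)
      filtfilt_one(bs[q], as[q], zis[q], buf, tmp, zwork, n, maxpad);
    std::copy(buf.begin() + maxpad, buf.begin() + maxpad + n, &out(0, j));
  }
  return out;
}
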