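#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Reflect index into [0, n-1] (mirror boundary without repeating the edge
// sample twice, i.e. "reflect" a la scipy mode='mirror' degenerates for
// n == 1; guarded below).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * (n - 1) - i;
  }
  return i;
}

// Separable convolution: kernel kc along columns (x), kernel kr along rows (y).
// Kernels are assumed symmetric or antisymmetric sampled on [-h, h]; plain
// correlation is applied (sign conventions cancel in the Hessian products).
// Column pass runs as contiguous AXPY sweeps; row pass has an interior fast
// path, so the mirror handling only touches the margins.
static void sep_convolve(const NumericMatrix& src, NumericMatrix& dst,
                         const std::vector<double>& kr,
                         const std::vector<double>& kc,
                         NumericMatrix& tmp) {
  const int nr = src.nrow(), nc = src.ncol();
  const int hc = ((int)kc.size() - 1) / 2;
  const int hr = ((int)kr.size() - 1) / 2;
  const double* s = src.begin();
  double* t = tmp.begin();
  double* d = dst.begin();
  // along columns (x direction): tmp(.,j) = sum_k kc[k] * src(., j+k-hc)
  for (int j = 0; j < nc; ++j) {
    double* tj = t + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) tj[i] = 0.0;
    for (int k = -hc; k <= hc; ++k) {
      const double w = kc[k + hc];
      const double* sj = s + (size_t)reflect(j + k, nc) * nr;
      for (int i = 0; i < nr; ++i) tj[i] += w * sj[i];
    }
  }
  // along rows (y direction), contiguous within each column
  for (int j = 0; j < nc; ++j) {
    const double* tj = t + (size_t)j * nr;
    double* dj = d + (size_t)j * nr;
    const int lo = hr, hi = nr - hr;  // interior rows need no reflection
    for (int i = 0; i < lo && i < nr; ++i) {
      double acc = 0.0;
      for (int k = -hr; k <= hr; ++k) acc += kr[k + hr] * tj[reflect(i + k, nr)];
      dj[i] = acc;
    }
    for (int i = lo; i < hi; ++i) {
      double acc = 0.0;
      const double* p = tj + i - hr;
      for (int k = 0; k <= 2 * hr; ++k) acc += kr[k] * p[k];
      dj[i] = acc;
    }
    for (int i = hi > lo ? hi : lo; i < nr; ++i) {
      double acc = 0.0;
      for (int k = -hr; k <= hr; ++k) acc += kr[k + hr] * tj[reflect(i + k, nr)];
      dj[i] = acc;
    }
  }
}

static void gauss_kernels(double sigma, std::vector<double>& g,
                          std::vector<double>& dg, std::vector<double>& ddg) {
  int h = (int)std::ceil(3.0 * sigma);
  if (h < 1) h = 1;
  g.assign(2 * h + 1, 0.0);
  dg.assign(2 * h + 1, 0.0);
  ddg.assign(2 * h + 1, 0.0);
  const double s2 = sigma * sigma;
  double norm = 0.0;
  for (int k = -h; k <= h; ++k) {
    double v = std::exp(-0.5 * k * k / s2);
    g[k + h] = v;
    norm += v;
  }
  for (int k = -h; k <= h; ++k) {
    g[k + h] /= norm;
    dg[k + h] = -(double)k / s2 * g[k + h];
    ddg[k + h] = (k * (double)k / (s2 * s2) - 1.0 / s2) * g[k + h];
  }
}

//' @useDynLib hairmorph, .registration = TRUE
// [[Rcpp::export(name = ".ridge_response_cpp")]]
NumericMatrix ridge_response_cpp(NumericMatrix img, NumericVector sigmas) {
  const int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc), hxx(nr, nc), hyy(nr, nc), hxy(nr, nc),
      tmp(nr, nc);
  std::vector<double> g, dg, ddg;
  for (int s = 0; s < sigmas.size(); ++s) {
    const double sigma = sigmas[s];
    gauss_kernels(sigma, g, dg, ddg);
    sep_convolve(img, hxx, g, ddg, tmp);   // d2/dx2: ddg along cols, g along rows
    sep_convolve(img, hyy, ddg, g, tmp);   // d2/dy2
    sep_convolve(img, hxy, dg, dg, tmp);   // d2/dxdy
    const double s2 = sigma * sigma;       // gamma-normalization across scales
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        const double a = hxx(i, j), b = hyy(i, j), c = hxy(i, j);
        const double tr = 0.5 * (a + b);
        const double disc = std::sqrt(0.25 * (a - b) * (a - b) + c * c);
        // dark ridge on light ground: large positive principal second
        // derivative across the ridge
        double lam1 = tr + disc;
        double r = s2 * lam1;
        if (r > out(i, j)) out(i, j) = r;
      }
    }
  }
  return out;
}
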