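// Hot inner kernels: direct 2D convolution (forward and backward) for the
// small conv layers, and the windowed bilateral smoothness term.  Image
// layout matches base R: an H x W plane is column-major, pixel (i, j) at
// index j*H + i (0-based); a batch tensor stacks images as row blocks of an
// (N*H*W) x C matrix.  Weight layout: W is a (k^2 * Cin) x Cout matrix,
// rows ordered offset-major (dx fastest, then dy), channel within offset.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix cpp_conv_forward(const NumericMatrix& x, const NumericMatrix& W,
                               const NumericVector& b, int n, int h, int w, int k) {
  const int cin = x.ncol();
  const int cout = W.ncol();
  const int r = (k - 1) / 2;
  const int k2 = k * k;
  const int hw = h * w;
  NumericMatrix y(n * hw, cout);
  for (int img = 0; img < n; ++img) {
    const int base = img * hw;
    for (int co = 0; co < cout; ++co) {
      double* yc = &y(base, co);
      const double bc = b[co];
      for (int p = 0; p < hw; ++p) yc[p] = bc;
      for (int o = 0; o < k2; ++o) {
        const int dy = o / k - r;
        const int dx = o % k - r;
        const int jlo = std::max(0, -dx), jhi = std::min(w, w - dx);
        const int ilo = std::max(0, -dy), ihi = std::min(h, h - dy);
        for (int c = 0; c < cin; ++c) {
          const double wv = W(o * cin + c, co);
          if (wv == 0.0) continue;
          const double* xc = &x(base, c);
          for (int j = jlo; j < jhi; ++j) {
            double* yp = yc + j * h;
            const double* xq = xc + (j + dx) * h + dy;
            for (int i = ilo; i < ihi; ++i) yp[i] += wv * xq[i];
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
List cpp_conv_backward(const NumericMatrix& x, const NumericMatrix& W,
                       const NumericMatrix& gy, int n, int h, int w, int k) {
  const int cin = x.ncol();
  const int cout = W.ncol();
  const int r = (k - 1) / 2;
  const int k2 = k * k;
  const int hw = h * w;
  NumericMatrix gW(k2 * cin, cout);
  NumericVector gb(cout);
  NumericMatrix gx(n * hw, cin);
  for (int img = 0; img < n; ++img) {
    const int base = img * hw;
    for (int co = 0; co < cout; ++co) {
      const double* gyc = &gy(base, co);
      double acc = 0.0;
      for (int p = 0; p < hw; ++p) acc += gyc[p];
      gb[co] += acc;
      for (int o = 0; o < k2; ++o) {
        const int dy = o / k - r;
        const int dx = o % k - r;
        const int jlo = std::max(0, -dx), jhi = std::min(w, w - dx);
        const int ilo = std::max(0, -dy), ihi = std::min(h, h - dy);
        for (int c = 0; c < cin; ++c) {
          const double wv = W(o * cin + c, co);
          const double* xc = &x(base, c);
          double* gxc = &gx(base, c);
          double dot = 0.0;
          for (int j = jlo; j < jhi; ++j) {
            const double* gp = gyc + j * h;
            const double* xq = xc + (j + dx) * h + dy;
            double* gq = gxc + (j + dx) * h + dy;
            for (int i = ilo; i < ihi; ++i) {
              dot += gp[i] * xq[i];
              gq[i] += wv * gp[i];
            }
          }
          gW(o * cin + c, co) += dot;
        }
      }
    }
  }
  return List::create(_["gW"] = gW, _["gb"] = gb, _["gx"] = gx);
}

static inline double sgn(double x) { return (x > 0) - (x < 0); }

// Bilateral-weighted absolute illumination differences over a
// (2*window+1)^2 neighbourhood.  b and yuv are (H*W) x 3 matrices (the
// illumination map and the YUV-converted corrected input); returns the
// normalised value and, when wanted, gradients with respect to b and yuv.
// [[Rcpp::export]]
List cpp_smoothness(const NumericMatrix& b, const NumericMatrix& yuv,
                    int h, int w, double sigma, int window, bool want_grad) {
  const int nc = b.ncol();
  const double norm = 1.0 / (static_cast<double>(nc) * h * w);
  const double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  double val = 0.0;
  NumericMatrix gb, gyuv;
  if (want_grad) {
    gb = NumericMatrix(h * w, nc);
    gyuv = NumericMatrix(h * w, nc);
  }
  if (h == 1 && w == 1) {
    return List::create(_["val"] = 0.0, _["gb"] = gb, _["gyuv"] = gyuv);
  }
  for (int dy = -window; dy <= window; ++dy) {
    for (int dx = -window; dx <= window; ++dx) {
      if (dy == 0 && dx == 0) continue;
      const int jlo = std::max(0, -dx), jhi = std::min(w, w - dx);
      const int ilo = std::max(0, -dy), ihi = std::min(h, h - dy);
      for (int j = jlo; j < jhi; ++j) {
        for (int i = ilo; i < ihi; ++i) {
          const int p = j * h + i;
          const int q = (j + dx) * h + (i + dy);
          double d2 = 0.0;
          for (int c = 0; c < nc; ++c) {
            const double yd = yuv(p, c) - yuv(q, c);
            d2 += yd * yd;
          }
          const double wgt = std::exp(-d2 * inv2s2);
          double babs = 0.0;
          for (int c = 0; c < nc; ++c) {
            const double bd = b(p, c) - b(q, c);
            babs += std::fabs(bd);
            if (want_grad) {
              const double g = wgt * sgn(bd) * norm;
              gb(p, c) += g;
              gb(q, c) -= g;
            }
          }
          val += wgt * babs * norm;
          if (want_grad) {
            const double gw = babs * norm * wgt / (sigma * sigma);
            for (int c = 0; c < nc; ++c) {
              const double gy = -gw * (yuv(p, c) - yuv(q, c));
              gyuv(p, c) += gy;
              gyuv(q, c) -= gy;
            }
          }
        }
      }
    }
  }
  return List::create(_["val"] = val, _["gb"] = gb, _["gyuv"] = gyuv);
}
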