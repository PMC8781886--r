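// 3-D convolution primitives used by the network layers.
//
// Array conventions (R column-major):
//   feature maps  x : dim (T, H, W, C)
//   kernels       w : dim (kt, kh, kw, C_in, C_out)
//   outputs       y : dim (To, Ho, Wo, C_out)
// Convolution here is cross-correlation (the deep-learning convention);
// the nested-loop oracle on the R side follows the same convention.
//
// Implementation: im2col one output-time-slice at a time, then GEMM.
// Chunking keeps peak memory at Ho*Wo*K doubles per slice instead of
// materialising the full patch matrix for a 128-frame clip.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct ConvGeom {
  int T, H, W, Cin;
  int Kt, Kh, Kw, Cout;
  int st, sh, sw, pt, ph, pw;
  int To, Ho, Wo, K;
};

ConvGeom make_geom(const IntegerVector &xd, const IntegerVector &wd,
                   const IntegerVector &stride, const IntegerVector &pad) {
  ConvGeom g;
  g.T = xd[0]; g.H = xd[1]; g.W = xd[2]; g.Cin = xd[3];
  g.Kt = wd[0]; g.Kh = wd[1]; g.Kw = wd[2]; g.Cout = wd[4];
  if (wd[3] != g.Cin) stop("kernel expects %d input channels, got %d", wd[3], g.Cin);
  g.st = stride[0]; g.sh = stride[1]; g.sw = stride[2];
  g.pt = pad[0]; g.ph = pad[1]; g.pw = pad[2];
  g.To = (g.T + 2 * g.pt - g.Kt) / g.st + 1;
  g.Ho = (g.H + 2 * g.ph - g.Kh) / g.sh + 1;
  g.Wo = (g.W + 2 * g.pw - g.Kw) / g.sw + 1;
  if (g.To < 1 || g.Ho < 1 || g.Wo < 1)
    stop("kernel larger than padded input");
  g.K = g.Kt * g.Kh * g.Kw * g.Cin;
  return g;
}

// Patch matrix for one output time index `to`: (Ho*Wo) x K.
void im2col_slice(const double *x, const ConvGeom &g, int to, arma::mat &P) {
  P.zeros();
  const int HW = g.Ho * g.Wo;
  for (int c = 0; c < g.Cin; ++c) {
    for (int kw = 0; kw < g.Kw; ++kw) {
      for (int kh = 0; kh < g.Kh; ++kh) {
        for (int kt = 0; kt < g.Kt; ++kt) {
          const int t = to * g.st - g.pt + kt;
          if (t < 0 || t >= g.T) continue;
          const int col = kt + g.Kt * (kh + g.Kh * (kw + g.Kw * c));
          double *pcol = P.colptr(col);
          for (int wo = 0; wo < g.Wo; ++wo) {
            const int w = wo * g.sw - g.pw + kw;
            if (w < 0 || w >= g.W) continue;
            const double *xbase = x + (size_t)t +
              (size_t)g.T * ((size_t)g.H * ((size_t)w + (size_t)g.W * c));
            for (int ho = 0; ho < g.Ho; ++ho) {
              const int h = ho * g.sh - g.ph + kh;
              if (h < 0 || h >= g.H) continue;
              pcol[ho + g.Ho * wo] = xbase[(size_t)g.T * h];
            }
          }
        }
      }
    }
  }
  (void)HW;
}

// Scatter-add the gradient patch matrix back into gx (col2im).
void col2im_slice(double *gx, const ConvGeom &g, int to, const arma::mat &GP) {
  for (int c = 0; c < g.Cin; ++c) {
    for (int kw = 0; kw < g.Kw; ++kw) {
      for (int kh = 0; kh < g.Kh; ++kh) {
        for (int kt = 0; kt < g.Kt; ++kt) {
          const int t = to * g.st - g.pt + kt;
          if (t < 0 || t >= g.T) continue;
          const int col = kt + g.Kt * (kh + g.Kh * (kw + g.Kw * c));
          const double *pcol = GP.colptr(col);
          for (int wo = 0; wo < g.Wo; ++wo) {
            const int w = wo * g.sw - g.pw + kw;
            if (w < 0 || w >= g.W) continue;
            double *xbase = gx + (size_t)t +
              (size_t)g.T * ((size_t)g.H * ((size_t)w + (size_t)g.W * c));
            for (int ho = 0; ho < g.Ho; ++ho) {
              const int h = ho * g.sh - g.ph + kh;
              if (h < 0 || h >= g.H) continue;
              xbase[(size_t)g.T * h] += pcol[ho + g.Ho * wo];
            }
          }
        }
      }
    }
  }
}

} // namespace

// [[Rcpp::export(name = ".conv3d_fw")]]
NumericVector conv3d_fw(NumericVector x, NumericVector w, NumericVector bias,
                        IntegerVector stride, IntegerVector pad) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  if (xd.size() != 4) stop("input must be a 4-d array (T, H, W, C)");
  if (wd.size() != 5) stop("kernel must be a 5-d array (kt, kh, kw, Cin, Cout)");
  ConvGeom g = make_geom(xd, wd, stride, pad);

  const arma::mat Wm(const_cast<double *>(w.begin()), g.K, g.Cout, false, true);
  NumericVector y(static_cast<R_xlen_t>(g.To) * g.Ho * g.Wo * g.Cout);
  y.attr("dim") = IntegerVector::create(g.To, g.Ho, g.Wo, g.Cout);
  double *yp = y.begin();
  const int HW = g.Ho * g.Wo;
  const bool has_bias = bias.size() > 0;

  arma::mat P(HW, g.K), Y(HW, g.Cout);
  for (int to = 0; to < g.To; ++to) {
    im2col_slice(x.begin(), g, to, P);
    Y = P * Wm;
    for (int co = 0; co < g.Cout; ++co) {
      const double b = has_bias ? bias[co] : 0.0;
      const double *yc = Y.colptr(co);
      for (int r = 0; r < HW; ++r)
        yp[(size_t)to + (size_t)g.To * ((size_t)r + (size_t)HW * co)] = yc[r] + b;
    }
  }
  return y;
}

// [[Rcpp::export(name = ".conv3d_bw")]]
List conv3d_bw(NumericVector x, NumericVector w, NumericVector gy,
               IntegerVector stride, IntegerVector pad, bool has_bias) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  ConvGeom g = make_geom(xd, wd, stride, pad);
  IntegerVector gyd = gy.attr("dim");
  if (gyd[0] != g.To || gyd[1] != g.Ho || gyd[2] != g.Wo || gyd[3] != g.Cout)
    stop("gradient shape does not match the forward output shape");

  const arma::mat Wm(const_cast<double *>(w.begin()), g.K, g.Cout, false, true);
  NumericVector gx(x.size());
  gx.attr("dim") = xd;
  NumericVector gw(w.size());
  gw.attr("dim") = wd;
  arma::mat GW(gw.begin(), g.K, g.Cout, false, true);
  arma::vec gb(g.Cout, arma::fill::zeros);

  const int HW = g.Ho * g.Wo;
  arma::mat P(HW, g.K), G(HW, g.Cout), GP(HW, g.K);
  for (int to = 0; to < g.To; ++to) {
    for (int co = 0; co < g.Cout; ++co) {
      double *gc = G.colptr(co);
      for (int r = 0; r < HW; ++r)
        gc[r] = gy[(size_t)to + (size_t)g.To * ((size_t)r + (size_t)HW * co)];
    }
    im2col_slice(x.begin(), g, to, P);
    GW += P.t() * G;
    GP = G * Wm.t();
    col2im_slice(gx.begin(), g, to, GP);
    if (has_bias) gb += arma::sum(G, 0).t();
  }

  List out = List::create(Named("gx") = gx, Named("gw") = gw);
  if (has_bias) out["gb"] = NumericVector(gb.begin(), gb.end());
  return out;
}
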