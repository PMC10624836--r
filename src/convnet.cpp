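// Minimal fully convolutional network engine for the diffraction-to-phase
// surrogate. Layers are described by an integer matrix with one row per
// layer: (type, cin, cout). Types: 1 = 3x3 conv + ReLU, 2 = 3x3 conv +
// pi*tanh (output head), 3 = 2x2 max pool, 4 = 2x nearest upsample.
// Activations are arma::fcube(H, W, C*B) with slice index c + C*b, matching
// the column-major layout of an R array dim = c(H, W, C, B). Convolutions
// use zero padding ("same") via im2col + gemm. Parameters are packed per
// conv layer as [W (9*cin x cout), b (cout)], W row index = c*9 + k with k
// scanning the 3x3 window column-major (dy fastest).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int KK = 9;

// Batched im2col: rows of Xc are (b, pixel) pairs, b-major blocks of H*W;
// column index for input channel c, tap k is c*9 + k.
static void im2col(const arma::fcube& acts, int Cin, int B, arma::fmat& Xc) {
  const int H = acts.n_rows, W = acts.n_cols;
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Cin; ++c) {
      const arma::fmat& A = acts.slice(c + Cin * b);
      for (int k = 0; k < KK; ++k) {
        const int dy = k % 3 - 1, dx = k / 3 - 1;
        float* col = Xc.colptr(c * KK + k) + b * HW;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          float* dst = col + (size_t)w * H;
          if (ws < 0 || ws >= W) {
            std::fill(dst, dst + H, 0.0f);
            continue;
          }
          const float* src = A.colptr(ws);
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = 0; h < h0; ++h) dst[h] = 0.0;
          for (int h = h0; h < h1; ++h) dst[h] = src[h + dy];
          for (int h = h1; h < H; ++h) dst[h] = 0.0;
        }
      }
    }
  }
}

static void col2im_add(const arma::fmat& dXc, int Cin, int B,
                       arma::fcube& din) {
  const int H = din.n_rows, W = din.n_cols;
  const size_t HW = (size_t)H * W;
  for (int b = 0; b < B; ++b) {
    for (int c = 0; c < Cin; ++c) {
      arma::fmat& A = din.slice(c + Cin * b);
      for (int k = 0; k < KK; ++k) {
        const int dy = k % 3 - 1, dx = k / 3 - 1;
        const float* col = dXc.colptr(c * KK + k) + b * HW;
        for (int w = 0; w < W; ++w) {
          const int ws = w + dx;
          if (ws < 0 || ws >= W) continue;
          float* dst = A.colptr(ws);
          const float* src = col + (size_t)w * H;
          const int h0 = std::max(0, -dy), h1 = std::min(H, H - dy);
          for (int h = h0; h < h1; ++h) dst[h + dy] += src[h];
        }
      }
    }
  }
}

struct LayerIO {
  arma::fcube out;          // activation after this layer
  arma::ucube pool_arg;    // argmax (flat index within 2x2) for pools
};

// Forward pass. If `keep` is true every layer output is stored for backprop.
static void forward_pass(const arma::fcube& input, const arma::imat& layers,
                         const arma::fvec& params, int B,
                         std::vector<LayerIO>& ios, bool keep) {
  const int L = layers.n_rows;
  ios.resize(L);
  const arma::fcube* cur = &input;
  size_t off = 0;
  for (int l = 0; l < L; ++l) {
    const int type = layers(l, 0), cin = layers(l, 1), cout = layers(l, 2);
    const int H = cur->n_rows, W = cur->n_cols;
    if (type == 1 || type == 2) {
      const arma::fmat Wk(const_cast<float*>(params.memptr() + off),
                         KK * cin, cout, false, true);
      off += (size_t)KK * cin * cout;
      const arma::fvec bk(const_cast<float*>(params.memptr() + off),
                         cout, false, true);
      off += cout;
      ios[l].out.set_size(H, W, cout * B);
      const size_t HW = (size_t)H * W;
      arma::fmat Xc(HW * B, KK * cin);
      im2col(*cur, cin, B, Xc);
      arma::fmat Y = Xc * Wk;
      Y.each_row() += bk.t();
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < cout; ++c)
          std::copy(Y.colptr(c) + b * HW, Y.colptr(c) + (b + 1) * HW,
                    ios[l].out.slice_memptr(c + cout * b));
      if (type == 1) {
        ios[l].out.transform([](float v) { return v > 0.0f ? v : 0.0f; });
      } else {
        ios[l].out.transform([](float v) { return (float)(M_PI * std::tanh((double)v)); });
      }
    } else if (type == 3) {  // 2x2 max pool
      const int Ho = H / 2, Wo = W / 2, C = cin;
      ios[l].out.set_size(Ho, Wo, C * B);
      ios[l].pool_arg.set_size(Ho, Wo, C * B);
      for (arma::uword s = 0; s < cur->n_slices; ++s) {
        const arma::fmat& A = cur->slice(s);
        arma::fmat& O = ios[l].out.slice(s);
        arma::umat& G = ios[l].pool_arg.slice(s);
        for (int w = 0; w < Wo; ++w)
          for (int h = 0; h < Ho; ++h) {
            float best = A(2 * h, 2 * w); arma::uword arg = 0;
            const float v10 = A(2 * h + 1, 2 * w);
            const float v01 = A(2 * h, 2 * w + 1);
            const float v11 = A(2 * h + 1, 2 * w + 1);
            if (v10 > best) { best = v10; arg = 1; }
            if (v01 > best) { best = v01; arg = 2; }
            if (v11 > best) { best = v11; arg = 3; }
            O(h, w) = best; G(h, w) = arg;
          }
      }
    } else if (type == 4) {  // nearest-neighbour 2x upsample
      const int Ho = H * 2, Wo = W * 2, C = cin;
      ios[l].out.set_size(Ho, Wo, C * B);
      for (arma::uword s = 0; s < cur->n_slices; ++s) {
        const arma::fmat& A = cur->slice(s);
        arma::fmat& O = ios[l].out.slice(s);
        for (int w = 0; w < W; ++w)
          for (int h = 0; h < H; ++h) {
            const float v = A(h, w);
            O(2 * h, 2 * w) = v; O(2 * h + 1, 2 * w) = v;
            O(2 * h, 2 * w + 1) = v; O(2 * h + 1, 2 * w + 1) = v;
          }
      }
    } else {
      stop("unknown layer type");
    }
    cur = &ios[l].out;
    if (!keep && l > 0) ios[l - 1].pool_arg.reset();
  }
}

static arma::imat as_imat(const IntegerMatrix& m) {
  arma::imat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i) out(i, j) = m(i, j);
  return out;
}

// [[Rcpp::export]]
NumericVector nn_forward_cpp(NumericVector x, IntegerMatrix layers,
                             NumericVector params) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  arma::fcube input(H, W, (size_t)C * B);
  std::copy(x.begin(), x.end(), input.begin());
  arma::fvec par(params.size());
  std::copy(params.begin(), params.end(), par.begin());
  std::vector<LayerIO> ios;
  forward_pass(input, as_imat(layers), par, B, ios, false);
  const arma::fcube& out = ios.back().out;
  NumericVector y(out.begin(), out.end());
  const int Cout = out.n_slices / B;
  y.attr("dim") = IntegerVector::create(out.n_rows, out.n_cols, Cout, B);
  return y;
}

// [[Rcpp::export]]
List nn_loss_grad_cpp(NumericVector x, NumericVector target,
                      IntegerMatrix layers, NumericVector params) {
  IntegerVector d = x.attr("dim");
  const int H = d[0], W = d[1], C = d[2], B = d[3];
  arma::fcube input(H, W, (size_t)C * B);
  std::copy(x.begin(), x.end(), input.begin());
  arma::fvec par(params.size());
  std::copy(params.begin(), params.end(), par.begin());
  const arma::imat lay = as_imat(layers);
  const int L = lay.n_rows;

  std::vector<LayerIO> ios;
  forward_pass(input, lay, par, B, ios, true);
  arma::fcube& out = ios.back().out;
  if ((size_t)target.size() != out.n_elem)
    stop("target size does not match network output");
  arma::fcube tgt(out.n_rows, out.n_cols, out.n_slices);
  std::copy(target.begin(), target.end(), tgt.begin());

  const double n_el = (double)out.n_elem;
  double loss = (double)arma::accu(arma::abs(out - tgt)) / n_el;

  // parameter offsets per layer
  std::vector<size_t> offs(L, 0);
  size_t off = 0;
  for (int l = 0; l < L; ++l) {
    offs[l] = off;
    if (lay(l, 0) == 1 || lay(l, 0) == 2)
      off += (size_t)KK * lay(l, 1) * lay(l, 2) + lay(l, 2);
  }
  arma::fvec grad(params.size(), arma::fill::zeros);

  // dL/d(out)
  arma::fcube dcur(out.n_rows, out.n_cols, out.n_slices);
  for (arma::uword i = 0; i < out.n_elem; ++i) {
    const double diff = out(i) - tgt(i);
    dcur(i) = (diff > 0 ? 1.0 : (diff < 0 ? -1.0 : 0.0)) / n_el;
  }

  for (int l = L - 1; l >= 0; --l) {
    const int type = lay(l, 0), cin = lay(l, 1), cout = lay(l, 2);
    const arma::fcube& in_act = (l == 0) ? input : ios[l - 1].out;
    const int Hi = in_act.n_rows, Wi = in_act.n_cols;
    if (type == 1 || type == 2) {
      const arma::fcube& y = ios[l].out;
      // activation derivative
      if (type == 1) {
        for (arma::uword i = 0; i < y.n_elem; ++i)
          if (y(i) <= 0.0) dcur(i) = 0.0;
      } else {
        for (arma::uword i = 0; i < y.n_elem; ++i) {
          const double t = y(i) / M_PI;
          dcur(i) *= M_PI * (1.0 - t * t);
        }
      }
      const arma::fmat Wk(const_cast<float*>(par.memptr() + offs[l]),
                         KK * cin, cout, false, true);
      const size_t HW = (size_t)Hi * Wi;
      arma::fcube din(Hi, Wi, (size_t)cin * B, arma::fill::zeros);
      arma::fmat Xc(HW * B, KK * cin);
      im2col(in_act, cin, B, Xc);
      arma::fmat dY(HW * B, cout);
      for (int b = 0; b < B; ++b)
        for (int c = 0; c < cout; ++c)
          std::copy(dcur.slice_memptr(c + cout * b),
                    dcur.slice_memptr(c + cout * b) + HW,
                    dY.colptr(c) + b * HW);
      arma::fmat dW = Xc.t() * dY;
      arma::fvec db = arma::sum(dY, 0).t();
      arma::fmat dXc = dY * Wk.t();
      col2im_add(dXc, cin, B, din);
      std::copy(dW.begin(), dW.end(), grad.memptr() + offs[l]);
      std::copy(db.begin(), db.end(),
                grad.memptr() + offs[l] + (size_t)KK * cin * cout);
      dcur = din;
    } else if (type == 3) {
      arma::fcube din(Hi, Wi, in_act.n_slices, arma::fill::zeros);
      const arma::ucube& G = ios[l].pool_arg;
      const int Ho = Hi / 2, Wo = Wi / 2;
      for (arma::uword s = 0; s < in_act.n_slices; ++s) {
        arma::fmat& D = din.slice(s);
        const arma::fmat& U = dcur.slice(s);
        const arma::umat& Gs = G.slice(s);
        for (int w = 0; w < Wo; ++w)
          for (int h = 0; h < Ho; ++h) {
            const arma::uword a = Gs(h, w);
            D(2 * h + (a & 1u), 2 * w + (a >> 1)) += U(h, w);
          }
      }
      dcur = din;
    } else if (type == 4) {
      arma::fcube din(Hi, Wi, in_act.n_slices, arma::fill::zeros);
      for (arma::uword s = 0; s < in_act.n_slices; ++s) {
        arma::fmat& D = din.slice(s);
        const arma::fmat& U = dcur.slice(s);
        for (int w = 0; w < Wi; ++w)
          for (int h = 0; h < Hi; ++h)
            D(h, w) = U(2 * h, 2 * w) + U(2 * h + 1, 2 * w) +
                      U(2 * h, 2 * w + 1) + U(2 * h + 1, 2 * w + 1);
      }
      dcur = din;
    }
  }

  return List::create(_["loss"] = loss,
                      _["grad"] = NumericVector(grad.begin(), grad.end()));
}
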