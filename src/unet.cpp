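// Small encoder-decoder segmentation network with skip connections.
//
// Feature maps are stored as (H*W) x C matrices in R's column-major pixel
// order (index = row + col * H). Convolutions are 3x3 (zero padded) via
// im2col + GEMM; downsampling is 2x2 max pooling, upsampling nearest
// neighbour; the decoder concatenates the encoder skip at each stage. Heads
// are 1x1 convolutions returning logits (activations are applied in R).
// The object also carries Adam optimiser state so a training step is
// forward -> R-side loss gradients -> backward -> adam_step.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
typedef arma::fmat mat;
typedef arma::frowvec rowvec;
using arma::umat;
typedef float real_t;

struct ConvLayer {
  int k = 3, in = 0, out = 0;
  mat W; // (in*k*k) x out
  rowvec b;
  bool relu = true;
  // caches (training)
  mat cols; // k == 3
  mat Ain;  // k == 1
  mat Aout; // post-activation output
  int H = 0, Wd = 0;
  // gradients + Adam state
  mat dW, mW, vW;
  rowvec db, mb, vb;
};

static void im2col3(const mat &A, int H, int W, mat &cols) {
  const int C = A.n_cols;
  cols.zeros((size_t)H * W, (size_t)C * 9);
  for (int ch = 0; ch < C; ++ch) {
    const real_t *src = A.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int j = ch * 9 + (dc + 1) * 3 + (dr + 1);
        real_t *dst = cols.colptr(j);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = dr < 0 ? -dr : 0;
          const int r1 = dr > 0 ? H - dr : H;
          const real_t *s = src + (size_t)sc * H + dr;
          real_t *d = dst + (size_t)c * H;
          for (int r = r0; r < r1; ++r) d[r] = s[r];
        }
      }
    }
  }
}

static void col2im3(const mat &dcols, int H, int W, int C, mat &dA) {
  dA.zeros((size_t)H * W, C);
  for (int ch = 0; ch < C; ++ch) {
    real_t *dst = dA.colptr(ch);
    for (int dc = -1; dc <= 1; ++dc) {
      for (int dr = -1; dr <= 1; ++dr) {
        const int j = ch * 9 + (dc + 1) * 3 + (dr + 1);
        const real_t *s = dcols.colptr(j);
        for (int c = 0; c < W; ++c) {
          const int sc = c + dc;
          if (sc < 0 || sc >= W) continue;
          const int r0 = dr < 0 ? -dr : 0;
          const int r1 = dr > 0 ? H - dr : H;
          real_t *d = dst + (size_t)sc * H + dr;
          const real_t *s2 = s + (size_t)c * H;
          for (int r = r0; r < r1; ++r) d[r] += s2[r];
        }
      }
    }
  }
}

static mat conv_forward(ConvLayer &L, const mat &A, int H, int W, bool train) {
  mat Z;
  if (L.k == 3) {
    mat cols;
    im2col3(A, H, W, cols);
    Z = cols * L.W;
    if (train) L.cols = std::move(cols);
  } else {
    Z = A * L.W;
    if (train) L.Ain = A;
  }
  Z.each_row() += L.b;
  if (L.relu) Z.transform([](real_t x) { return x > 0.0f ? x : 0.0f; });
  if (train) {
    L.Aout = Z;
    L.H = H;
    L.Wd = W;
  }
  return Z;
}

static mat conv_backward(ConvLayer &L, mat dZ) {
  if (L.relu) dZ.elem(arma::find(L.Aout <= 0.0)).zeros();
  L.db = arma::sum(dZ, 0);
  if (L.k == 3) {
    L.dW = L.cols.t() * dZ;
    mat dcols = dZ * L.W.t();
    mat dA;
    col2im3(dcols, L.H, L.Wd, L.in, dA);
    return dA;
  }
  L.dW = L.Ain.t() * dZ;
  return dZ * L.W.t();
}

static mat maxpool2(const mat &A, int H, int W, umat &idx) {
  const int C = A.n_cols, H2 = H / 2, W2 = W / 2;
  mat out((size_t)H2 * W2, C);
  idx.set_size((size_t)H2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const real_t *src = A.colptr(ch);
    real_t *dst = out.colptr(ch);
    arma::uword *ix = idx.colptr(ch);
    for (int c = 0; c < W2; ++c) {
      for (int r = 0; r < H2; ++r) {
        const size_t p00 = (size_t)(2 * c) * H + 2 * r;
        const size_t cands[4] = {p00, p00 + 1, p00 + H, p00 + H + 1};
        size_t best = cands[0];
        for (int t = 1; t < 4; ++t)
          if (src[cands[t]] > src[best]) best = cands[t];
        dst[(size_t)c * H2 + r] = src[best];
        ix[(size_t)c * H2 + r] = best;
      }
    }
  }
  return out;
}

static mat maxpool2_backward(const mat &dOut, const umat &idx, int H, int W) {
  const int C = dOut.n_cols;
  mat dA((size_t)H * W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const real_t *s = dOut.colptr(ch);
    const arma::uword *ix = idx.colptr(ch);
    real_t *d = dA.colptr(ch);
    for (size_t p = 0; p < dOut.n_rows; ++p) d[ix[p]] += s[p];
  }
  return dA;
}

static mat upsample2(const mat &A, int H, int W) {
  const int C = A.n_cols, H2 = H * 2, W2 = W * 2;
  mat out((size_t)H2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const real_t *src = A.colptr(ch);
    real_t *dst = out.colptr(ch);
    for (int c = 0; c < W2; ++c) {
      const real_t *scol = src + (size_t)(c / 2) * H;
      real_t *dcol = dst + (size_t)c * H2;
      for (int r = 0; r < H2; ++r) dcol[r] = scol[r / 2];
    }
  }
  return out;
}

static mat upsample2_backward(const mat &dOut, int H, int W) {
  // H, W: the *small* (input) resolution
  const int C = dOut.n_cols, H2 = H * 2;
  mat dA((size_t)H * W, C, arma::fill::zeros);
  for (int ch = 0; ch < C; ++ch) {
    const real_t *s = dOut.colptr(ch);
    real_t *d = dA.colptr(ch);
    for (int c = 0; c < 2 * W; ++c) {
      real_t *dcol = d + (size_t)(c / 2) * H;
      const real_t *scol = s + (size_t)c * H2;
      for (int r = 0; r < H2; ++r) dcol[r / 2] += scol[r];
    }
  }
  return dA;
}

class UNet {
public:
  int in_ch, S, base;
  std::vector<int> head_out;
  std::vector<ConvLayer> convs; // 2S enc, 2 bottleneck, 2S dec, heads
  int n_body;
  // forward caches
  int H0 = 0, W0 = 0;
  std::vector<mat> skips;
  std::vector<umat> pool_idx;
  mat head_in;
  bool has_cache = false;
  long step_count = 0;

  UNet(int in_ch_, int S_, int base_, const std::vector<int> &head_out_)
      : in_ch(in_ch_), S(S_), base(base_), head_out(head_out_) {
    auto add = [&](int k, int in, int out, bool relu) {
      ConvLayer L;
      L.k = k;
      L.in = in;
      L.out = out;
      L.relu = relu;
      L.W.zeros((size_t)in * k * k, out);
      L.b.zeros(out);
      L.mW.zeros(arma::size(L.W));
      L.vW.zeros(arma::size(L.W));
      L.mb.zeros(out);
      L.vb.zeros(out);
      convs.push_back(std::move(L));
    };
    int prev = in_ch;
    for (int s = 0; s < S; ++s) {
      const int wch = base << s;
      add(3, prev, wch, true);
      add(3, wch, wch, true);
      prev = wch;
    }
    const int wB = base << S;
    add(3, prev, wB, true);
    add(3, wB, wB, true);
    int above = wB;
    for (int s = S - 1; s >= 0; --s) {
      const int wch = base << s;
      add(3, above + wch, wch, true);
      add(3, wch, wch, true);
      above = wch;
    }
    n_body = (int)convs.size();
    for (size_t i = 0; i < head_out.size(); ++i) add(1, base, head_out[i], false);
  }

  List forward(const arma::cube &img, bool train) {
    const int H = img.n_rows, W = img.n_cols;
    if ((int)img.n_slices != in_ch)
      stop("network expects %d input channels, got %d", in_ch, (int)img.n_slices);
    if (H % (1 << S) != 0 || W % (1 << S) != 0)
      stop("input size must be divisible by %d", 1 << S);
    H0 = H;
    W0 = W;
    mat A((size_t)H * W, in_ch);
    for (int ch = 0; ch < in_ch; ++ch) {
      const double *sp = img.slice(ch).memptr();
      real_t *dp = A.colptr(ch);
      for (size_t i = 0; i < (size_t)H * W; ++i) dp[i] = (real_t)sp[i];
    }

    skips.assign(S, mat());
    pool_idx.assign(S, umat());
    int h = H, w = W, li = 0;
    for (int s = 0; s < S; ++s) {
      A = conv_forward(convs[li++], A, h, w, train);
      A = conv_forward(convs[li++], A, h, w, train);
      skips[s] = A;
      umat idx;
      A = maxpool2(A, h, w, idx);
      pool_idx[s] = std::move(idx);
      h /= 2;
      w /= 2;
    }
    A = conv_forward(convs[li++], A, h, w, train);
    A = conv_forward(convs[li++], A, h, w, train);
    for (int s = S - 1; s >= 0; --s) {
      A = upsample2(A, h, w);
      h *= 2;
      w *= 2;
      A = arma::join_rows(A, skips[s]);
      A = conv_forward(convs[li++], A, h, w, train);
      A = conv_forward(convs[li++], A, h, w, train);
    }
    head_in = A;
    has_cache = train;
    List out(head_out.size());
    for (size_t i = 0; i < head_out.size(); ++i) {
      mat Z = conv_forward(convs[n_body + i], A, h, w, train);
      NumericVector arr(Z.begin(), Z.end());
      arr.attr("dim") = IntegerVector::create(H, W, head_out[i]);
      out[i] = arr;
    }
    if (!train) { // drop caches from eval passes
      skips.clear();
      pool_idx.clear();
    }
    return out;
  }

  void backward(const List &grad_heads) {
    if (!has_cache) stop("backward called without a cached training forward pass");
    if ((int)grad_heads.size() != (int)head_out.size())
      stop("expected %d head gradients", (int)head_out.size());
    mat dA((size_t)H0 * W0, base, arma::fill::zeros);
    for (size_t i = 0; i < head_out.size(); ++i) {
      NumericVector g(grad_heads[i]);
      if ((int)g.size() != H0 * W0 * head_out[i])
        stop("head gradient %d has wrong size", (int)i + 1);
      mat dZ((size_t)H0 * W0, head_out[i]);
      std::copy(g.begin(), g.end(), dZ.begin());
      dA += conv_backward(convs[n_body + i], dZ);
    }
    int li = n_body - 1;
    int h = H0, w = W0;
    std::vector<mat> dskips(S);
    for (int s = 0; s <= S - 1; ++s) {
      dA = conv_backward(convs[li--], dA); // dec conv2
      dA = conv_backward(convs[li--], dA); // dec conv1
      const int wch = base << s;
      const int above = (s == S - 1) ? (base << S) : (base << (s + 1));
      dskips[s] = dA.cols(above, above + wch - 1);
      dA = upsample2_backward(dA.cols(0, above - 1), h / 2, w / 2);
      h /= 2;
      w /= 2;
    }
    dA = conv_backward(convs[li--], dA); // bottleneck conv2
    dA = conv_backward(convs[li--], dA); // bottleneck conv1
    for (int s = S - 1; s >= 0; --s) {
      h *= 2;
      w *= 2;
      dA = maxpool2_backward(dA, pool_idx[s], h, w);
      dA += dskips[s];
      dA = conv_backward(convs[li--], dA);
      dA = conv_backward(convs[li--], dA);
    }
    has_cache = false;
  }

  void adam_step(double lr, double beta1, double beta2, double eps) {
    ++step_count;
    const double c1 = 1.0 - std::pow(beta1, (double)step_count);
    const double c2 = 1.0 - std::pow(beta2, (double)step_count);
    for (ConvLayer &L : convs) {
      if (L.dW.n_elem == 0) continue;
      L.mW = beta1 * L.mW + (1 - beta1) * L.dW;
      L.vW = beta2 * L.vW + (1 - beta2) * arma::square(L.dW);
      L.W -= lr * (L.mW / c1) / (arma::sqrt(L.vW / c2) + eps);
      L.mb = beta1 * L.mb + (1 - beta1) * L.db;
      L.vb = beta2 * L.vb + (1 - beta2) * arma::square(L.db);
      L.b -= lr * (L.mb / c1) / (arma::sqrt(L.vb / c2) + eps);
    }
  }
};

static UNet *get_net(SEXP ptr) {
  Rcpp::XPtr<UNet> p(ptr);
  if (!p) stop("network pointer is invalid");
  return p.get();
}

// [[Rcpp::export(name = ".unet_create")]]
SEXP unet_create(int in_ch, int stages, int base, IntegerVector head_out) {
  std::vector<int> ho(head_out.begin(), head_out.end());
  Rcpp::XPtr<UNet> p(new UNet(in_ch, stages, base, ho), true);
  return p;
}

// [[Rcpp::export(name = ".unet_set_weights")]]
void unet_set_weights(SEXP ptr, List weights) {
  UNet *net = get_net(ptr);
  if ((int)weights.size() != (int)net->convs.size())
    stop("expected %d weight tensors, got %d", (int)net->convs.size(),
         (int)weights.size());
  for (size_t i = 0; i < net->convs.size(); ++i) {
    List wl(weights[i]);
    NumericMatrix Wm(as<NumericMatrix>(wl["W"]));
    NumericVector bv(as<NumericVector>(wl["b"]));
    ConvLayer &L = net->convs[i];
    if ((int)Wm.nrow() != (int)L.W.n_rows || (int)Wm.ncol() != (int)L.W.n_cols)
      stop("weight %d has wrong shape (%d x %d, expected %d x %d)", (int)i + 1,
           (int)Wm.nrow(), (int)Wm.ncol(), (int)L.W.n_rows, (int)L.W.n_cols);
    if ((int)bv.size() != (int)L.b.n_elem)
      stop("bias %d has wrong length", (int)i + 1);
    L.W.set_size(Wm.nrow(), Wm.ncol());
    std::copy(Wm.begin(), Wm.end(), L.W.begin());
    L.b.set_size(bv.size());
    std::copy(bv.begin(), bv.end(), L.b.begin());
  }
}

// [[Rcpp::export(name = ".unet_get_weights")]]
List unet_get_weights(SEXP ptr) {
  UNet *net = get_net(ptr);
  List out(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); ++i) {
    const ConvLayer &L = net->convs[i];
    NumericMatrix Wm(L.W.n_rows, L.W.n_cols);
    std::copy(L.W.begin(), L.W.end(), Wm.begin());
    NumericVector bv(L.b.begin(), L.b.end());
    out[i] = List::create(Named("W") = Wm, Named("b") = bv);
  }
  return out;
}

// [[Rcpp::export(name = ".unet_forward")]]
List unet_forward(SEXP ptr, NumericVector img, bool train) {
  UNet *net = get_net(ptr);
  IntegerVector d(img.attr("dim"));
  if (d.size() != 3) stop("image must be an h x w x c array");
  arma::cube cimg(img.begin(), d[0], d[1], d[2], false);
  return net->forward(cimg, train);
}

// [[Rcpp::export(name = ".unet_backward")]]
void unet_backward(SEXP ptr, List grad_heads) {
  get_net(ptr)->backward(grad_heads);
}

// [[Rcpp::export(name = ".unet_get_grads")]]
List unet_get_grads(SEXP ptr) {
  UNet *net = get_net(ptr);
  List out(net->convs.size());
  for (size_t i = 0; i < net->convs.size(); ++i) {
    const ConvLayer &L = net->convs[i];
    NumericMatrix Wm(L.dW.n_rows, L.dW.n_cols);
    std::copy(L.dW.begin(), L.dW.end(), Wm.begin());
    NumericVector bv(L.db.begin(), L.db.end());
    out[i] = List::create(Named("W") = Wm, Named("b") = bv);
  }
  return out;
}

// [[Rcpp::export(name = ".unet_adam_step")]]
void unet_adam_step(SEXP ptr, double lr, double beta1, double beta2,
                    double eps) {
  get_net(ptr)->adam_step(lr, beta1, beta2, eps);
}

// [[Rcpp::export(name = ".unet_reset_optimizer")]]
void unet_reset_optimizer(SEXP ptr) {
  UNet *net = get_net(ptr);
  net->step_count = 0;
  for (ConvLayer &L : net->convs) {
    L.mW.zeros();
    L.vW.zeros();
    L.mb.zeros();
    L.vb.zeros();
  }
}
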