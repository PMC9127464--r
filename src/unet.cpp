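// Minimal encoder-decoder (U-Net) backend: single-precision im2col + GEMM
// convolutions, 2x2 max-pooling, 2x2 stride-2 transposed-conv upsampling,
// channel-concatenation skip connections, MSE loss, Adam updates.
//
// Activation layout: arma::fmat A(N, C) with N = B*h*w and column-major
// pixel index n = b*(h*w) + j*h + i (i = row, j = column within a tile).
// Weight layouts (must match the R-side initializer in R/unet.R):
//   conv3 (3x3, pad 1):    W (inC*9, outC), row r = c*9 + kj*3 + ki
//   tconv (2x2, stride 2): W (inC, 4*outC), column q = p*outC + o,
//                          p = dj*2 + di (di, dj in {0,1})
//   conv1 (1x1 output):    W (inC, outC)

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using arma::fmat;
using arma::fvec;
using arma::umat;

enum LayerType { CONV3 = 0, TCONV = 1, CONV1 = 2 };

struct Layer {
  int type, inC, outC;
  fmat W;
  fvec b;
  fmat mW, vW;
  fvec mb, vb;
  // caches for backward
  fmat col;  // conv3: im2col of input; tconv/conv1: the input itself
  fmat out;  // post-activation output (ReLU mask)
  fmat dW;
  fvec db;
};

static void im2col3(const fmat& A, int h, int w, int B, int C, fmat& col) {
  const int hw = h * w, N = B * hw;
  col.zeros(N, C * 9);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        float* dst = col.colptr(c * 9 + kj * 3 + ki);
        const int j0 = std::max(0, 1 - kj), j1 = std::min(w - 1, w - kj);
        const int i0 = std::max(0, 1 - ki), i1 = std::min(h - 1, h - ki);
        for (int b = 0; b < B; ++b) {
          const int off = b * hw;
          for (int j = j0; j <= j1; ++j) {
            const float* s = src + off + (j + kj - 1) * h + (ki - 1);
            float* d = dst + off + j * h;
            for (int i = i0; i <= i1; ++i) d[i] = s[i];
          }
        }
      }
    }
  }
}

static void col2im3(const fmat& dcol, int h, int w, int B, int C, fmat& dA) {
  const int hw = h * w;
  dA.zeros(B * hw, C);
  for (int c = 0; c < C; ++c) {
    float* dst = dA.colptr(c);
    for (int kj = 0; kj < 3; ++kj) {
      for (int ki = 0; ki < 3; ++ki) {
        const float* src = dcol.colptr(c * 9 + kj * 3 + ki);
        const int j0 = std::max(0, 1 - kj), j1 = std::min(w - 1, w - kj);
        const int i0 = std::max(0, 1 - ki), i1 = std::min(h - 1, h - ki);
        for (int b = 0; b < B; ++b) {
          const int off = b * hw;
          for (int j = j0; j <= j1; ++j) {
            float* d = dst + off + (j + kj - 1) * h + (ki - 1);
            const float* s = src + off + j * h;
            for (int i = i0; i <= i1; ++i) d[i] += s[i];
          }
        }
      }
    }
  }
}

class UNet {
 public:
  int inC, depth, base;
  std::vector<Layer> L;
  long step = 0;
  // forward caches
  std::vector<fmat> encOut;   // per-stage skip activations
  std::vector<umat> poolIdx;  // per-stage argmax source rows
  fmat lastOut;
  int fH = 0, fW = 0, fB = 0;

  UNet(int inC_, int depth_, int base_) : inC(inC_), depth(depth_), base(base_) {
    auto add = [&](int type, int ci, int co) {
      Layer l;
      l.type = type; l.inC = ci; l.outC = co;
      int wr = (type == CONV3) ? ci * 9 : ci;
      int wc = (type == TCONV) ? 4 * co : co;
      l.W.zeros(wr, wc); l.b.zeros(co);
      l.mW.zeros(wr, wc); l.vW.zeros(wr, wc);
      l.mb.zeros(co); l.vb.zeros(co);
      L.push_back(std::move(l));
    };
    int prev = inC;
    for (int s = 0; s < depth; ++s) {
      int ch = base << s;
      add(CONV3, prev, ch); add(CONV3, ch, ch);
      prev = ch;
    }
    int ch = base << depth;
    add(CONV3, prev, ch); add(CONV3, ch, ch);
    for (int s = depth - 1; s >= 0; --s) {
      int cs = base << s;
      add(TCONV, cs * 2, cs);
      add(CONV3, cs * 2, cs); add(CONV3, cs, cs);
    }
    add(CONV1, base, 1);
    encOut.resize(depth);
    poolIdx.resize(depth);
  }

  long n_params() const {
    long n = 0;
    for (const Layer& l : L) n += (long)l.W.n_elem + l.b.n_elem;
    return n;
  }

  fmat conv_fwd(Layer& l, const fmat& A, int h, int w, int B, bool train) {
    fmat Y;
    if (l.type == CONV3) {
      fmat col;
      im2col3(A, h, w, B, l.inC, col);
      Y = col * l.W;
      if (train) l.col = std::move(col);
    } else {  // CONV1
      Y = A * l.W;
      if (train) l.col = A;
    }
    Y.each_row() += l.b.t();
    if (l.type != CONV1) Y.transform([](float v) { return v > 0.f ? v : 0.f; });
    if (train) l.out = Y;
    return Y;
  }

  fmat conv_bwd(Layer& l, const fmat& dY, int h, int w, int B) {
    fmat dZ = dY;
    if (l.type != CONV1) dZ.elem(arma::find(l.out <= 0.f)).zeros();
    l.dW = l.col.t() * dZ;
    l.db = arma::sum(dZ, 0).t();
    if (l.type == CONV3) {
      fmat dcol = dZ * l.W.t();
      fmat dA;
      col2im3(dcol, h, w, B, l.inC, dA);
      return dA;
    }
    return dZ * l.W.t();
  }

  // input at h x w -> output at 2h x 2w
  fmat tconv_fwd(Layer& l, const fmat& A, int h, int w, int B, bool train) {
    const int oc = l.outC, hw = h * w, H2 = 2 * h, W2 = 2 * w;
    fmat Ycol = A * l.W;  // (N, 4*outC)
    fmat Y(B * H2 * W2, oc);
    for (int o = 0; o < oc; ++o) {
      float* dst = Y.colptr(o);
      for (int p = 0; p < 4; ++p) {
        const int di = p & 1, dj = p >> 1;
        const float* src = Ycol.colptr(p * oc + o);
        for (int b = 0; b < B; ++b) {
          const int offs = b * hw, offd = b * H2 * W2;
          for (int j = 0; j < w; ++j) {
            const float* s = src + offs + j * h;
            float* d = dst + offd + (2 * j + dj) * H2 + di;
            for (int i = 0; i < h; ++i) d[2 * i] = s[i];
          }
        }
      }
    }
    Y.each_row() += l.b.t();
    Y.transform([](float v) { return v > 0.f ? v : 0.f; });
    if (train) { l.col = A; l.out = Y; }
    return Y;
  }

  fmat tconv_bwd(Layer& l, const fmat& dY, int h, int w, int B) {
    // h, w are the *input* dims of the forward tconv
    const int oc = l.outC, hw = h * w, H2 = 2 * h, W2 = 2 * w;
    fmat dZ = dY;
    dZ.elem(arma::find(l.out <= 0.f)).zeros();
    l.db = arma::sum(dZ, 0).t();
    fmat dYcol(B * hw, 4 * oc);
    for (int o = 0; o < oc; ++o) {
      const float* src = dZ.colptr(o);
      for (int p = 0; p < 4; ++p) {
        const int di = p & 1, dj = p >> 1;
        float* dst = dYcol.colptr(p * oc + o);
        for (int b = 0; b < B; ++b) {
          const int offs = b * H2 * W2, offd = b * hw;
          for (int j = 0; j < w; ++j) {
            const float* s = src + offs + (2 * j + dj) * H2 + di;
            float* d = dst + offd + j * h;
            for (int i = 0; i < h; ++i) d[i] = s[2 * i];
          }
        }
      }
    }
    l.dW = l.col.t() * dYcol;
    return dYcol * l.W.t();
  }

  fmat pool_fwd(const fmat& A, int h, int w, int B, int C, umat& idx) {
    const int h2 = h / 2, w2 = w / 2, hw = h * w, hw2 = h2 * w2;
    fmat P(B * hw2, C);
    idx.set_size(B * hw2, C);
    for (int c = 0; c < C; ++c) {
      const float* src = A.colptr(c);
      float* dst = P.colptr(c);
      arma::uword* ix = idx.colptr(c);
      for (int b = 0; b < B; ++b) {
        for (int j2 = 0; j2 < w2; ++j2) {
          for (int i2 = 0; i2 < h2; ++i2) {
            const int n2 = b * hw2 + j2 * h2 + i2;
            int bestn = b * hw + (2 * j2) * h + 2 * i2;
            float best = src[bestn];
            const int cand[3] = {bestn + 1, bestn + h, bestn + h + 1};
            for (int k = 0; k < 3; ++k)
              if (src[cand[k]] > best) { best = src[cand[k]]; bestn = cand[k]; }
            dst[n2] = best;
            ix[n2] = (arma::uword)bestn;
          }
        }
      }
    }
    return P;
  }

  fmat pool_bwd(const fmat& dP, const umat& idx, int h, int w, int B, int C) {
    fmat dA(B * h * w, C, arma::fill::zeros);
    for (int c = 0; c < C; ++c) {
      const float* s = dP.colptr(c);
      const arma::uword* ix = idx.colptr(c);
      float* d = dA.colptr(c);
      const arma::uword n2 = dP.n_rows;
      for (arma::uword n = 0; n < n2; ++n) d[ix[n]] += s[n];
    }
    return dA;
  }

  fmat forward(const fmat& X, int H, int W, int B, bool train) {
    int h = H, w = W;
    fmat A = X;
    for (int s = 0; s < depth; ++s) {
      A = conv_fwd(L[2 * s], A, h, w, B, train);
      A = conv_fwd(L[2 * s + 1], A, h, w, B, train);
      encOut[s] = A;
      A = pool_fwd(A, h, w, B, L[2 * s + 1].outC, poolIdx[s]);
      h /= 2; w /= 2;
    }
    A = conv_fwd(L[2 * depth], A, h, w, B, train);
    A = conv_fwd(L[2 * depth + 1], A, h, w, B, train);
    for (int s = depth - 1; s >= 0; --s) {
      const int bd = 2 * depth + 2 + 3 * (depth - 1 - s);
      A = tconv_fwd(L[bd], A, h, w, B, train);
      h *= 2; w *= 2;
      A = arma::join_rows(encOut[s], A);  // [skip, up]
      A = conv_fwd(L[bd + 1], A, h, w, B, train);
      A = conv_fwd(L[bd + 2], A, h, w, B, train);
    }
    fmat Y = conv_fwd(L.back(), A, h, w, B, train);
    if (train) { lastOut = Y; fH = H; fW = W; fB = B; }
    return Y;
  }

  // backward from dY at full resolution; fills l.dW/l.db for every layer
  void backward(const fmat& dYfull) {
    int h = fH, w = fW, B = fB;
    fmat d = conv_bwd(L.back(), dYfull, h, w, B);
    std::vector<fmat> dskip(depth);
    for (int s = 0; s < depth; ++s) {
      const int bd = 2 * depth + 2 + 3 * (depth - 1 - s);
      d = conv_bwd(L[bd + 2], d, h, w, B);
      d = conv_bwd(L[bd + 1], d, h, w, B);
      const int cs = base << s;
      dskip[s] = d.cols(0, cs - 1);
      fmat dup = d.cols(cs, 2 * cs - 1);
      h /= 2; w /= 2;
      d = tconv_bwd(L[bd], dup, h, w, B);
    }
    d = conv_bwd(L[2 * depth + 1], d, h, w, B);
    d = conv_bwd(L[2 * depth], d, h, w, B);
    for (int s = depth - 1; s >= 0; --s) {
      const int ch = base << s;
      fmat dA = pool_bwd(d, poolIdx[s], h * 2, w * 2, B, ch);
      h *= 2; w *= 2;
      dA += dskip[s];
      d = conv_bwd(L[2 * s + 1], dA, h, w, B);
      d = conv_bwd(L[2 * s], d, h, w, B);
    }
  }

  void adam_step(float lr, float b1, float b2, float eps) {
    ++step;
    const float c1 = 1.f - std::pow(b1, (float)step);
    const float c2 = 1.f - std::pow(b2, (float)step);
    for (Layer& l : L) {
      l.mW = b1 * l.mW + (1.f - b1) * l.dW;
      l.vW = b2 * l.vW + (1.f - b2) * arma::square(l.dW);
      l.W -= lr * (l.mW / c1) / (arma::sqrt(l.vW / c2) + eps);
      l.mb = b1 * l.mb + (1.f - b1) * l.db;
      l.vb = b2 * l.vb + (1.f - b2) * arma::square(l.db);
      l.b -= lr * (l.mb / c1) / (arma::sqrt(l.vb / c2) + eps);
    }
  }

  void clear_caches() {
    for (Layer& l : L) { l.col.reset(); l.out.reset(); l.dW.reset(); l.db.reset(); }
    for (fmat& m : encOut) m.reset();
    lastOut.reset();
  }
};

// R array (H, W, C, B) -> fmat (B*H*W, C)
static fmat array_to_act(const Rcpp::NumericVector& x, int H, int W, int C, int B) {
  fmat A(B * H * W, C);
  const double* p = x.begin();
  const long hw = (long)H * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const double* s = p + ((long)b * C + c) * hw;
      float* d = A.colptr(c) + (long)b * hw;
      for (long n = 0; n < hw; ++n) d[n] = (float)s[n];
    }
  return A;
}

static Rcpp::NumericVector act_to_array(const fmat& A, int H, int W, int C, int B) {
  Rcpp::NumericVector out((R_xlen_t)H * W * C * B);
  out.attr("dim") = Rcpp::IntegerVector::create(H, W, C, B);
  double* p = out.begin();
  const long hw = (long)H * W;
  for (int b = 0; b < B; ++b)
    for (int c = 0; c < C; ++c) {
      const float* s = A.colptr(c) + (long)b * hw;
      double* d = p + ((long)b * C + c) * hw;
      for (long n = 0; n < hw; ++n) d[n] = (double)s[n];
    }
  return out;
}

// [[Rcpp::export]]
SEXP unet_create_ptr(int in_channels, int depth, int base_channels) {
  Rcpp::XPtr<UNet> p(new UNet(in_channels, depth, base_channels), true);
  return p;
}

// [[Rcpp::export]]
double unet_nparams_ptr(SEXP ptr) {
  Rcpp::XPtr<UNet> p(ptr);
  return (double)p->n_params();
}

// [[Rcpp::export]]
void unet_set_weights_ptr(SEXP ptr, Rcpp::List weights) {
  Rcpp::XPtr<UNet> p(ptr);
  if ((int)weights.size() != (int)p->L.size())
    Rcpp::stop("weight list has %d layers; network expects %d",
               (int)weights.size(), (int)p->L.size());
  for (size_t k = 0; k < p->L.size(); ++k) {
    Rcpp::List lw = weights[k];
    Rcpp::NumericMatrix W = lw["W"];
    Rcpp::NumericVector b = lw["b"];
    Layer& l = p->L[k];
    if ((int)W.nrow() != (int)l.W.n_rows || (int)W.ncol() != (int)l.W.n_cols)
      Rcpp::stop("layer %d: weight matrix is %dx%d, expected %dx%d", (int)k + 1,
                 W.nrow(), W.ncol(), (int)l.W.n_rows, (int)l.W.n_cols);
    if ((int)b.size() != (int)l.b.n_elem)
      Rcpp::stop("layer %d: bias length mismatch", (int)k + 1);
    for (arma::uword j = 0; j < l.W.n_cols; ++j)
      for (arma::uword i = 0; i < l.W.n_rows; ++i)
        l.W(i, j) = (float)W(i, j);
    for (arma::uword i = 0; i < l.b.n_elem; ++i) l.b(i) = (float)b[i];
    l.mW.zeros(); l.vW.zeros(); l.mb.zeros(); l.vb.zeros();
  }
  p->step = 0;
}

// [[Rcpp::export]]
Rcpp::List unet_get_weights_ptr(SEXP ptr) {
  Rcpp::XPtr<UNet> p(ptr);
  Rcpp::List out(p->L.size());
  for (size_t k = 0; k < p->L.size(); ++k) {
    const Layer& l = p->L[k];
    Rcpp::NumericMatrix W(l.W.n_rows, l.W.n_cols);
    for (arma::uword j = 0; j < l.W.n_cols; ++j)
      for (arma::uword i = 0; i < l.W.n_rows; ++i)
        W(i, j) = (double)l.W(i, j);
    Rcpp::NumericVector b(l.b.n_elem);
    for (arma::uword i = 0; i < l.b.n_elem; ++i) b[i] = (double)l.b(i);
    out[k] = Rcpp::List::create(Rcpp::Named("W") = W, Rcpp::Named("b") = b);
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::NumericVector unet_forward_ptr(SEXP ptr, Rcpp::NumericVector x) {
  Rcpp::XPtr<UNet> p(ptr);
  Rcpp::IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) Rcpp::stop("input must be a 4-d array (H, W, C, B)");
  const int H = dim[0], W = dim[1], C = dim[2], B = dim[3];
  if (C != p->inC) Rcpp::stop("input has %d channels; network expects %d", C, p->inC);
  if (H % (1 << p->depth) || W % (1 << p->depth))
    Rcpp::stop("tile size must be divisible by 2^depth");
  fmat A = array_to_act(x, H, W, C, B);
  fmat Y = p->forward(A, H, W, B, false);
  p->clear_caches();
  return act_to_array(Y, H, W, 1, B);
}

// [[Rcpp::export]]
bool unet_ptr_valid(SEXP ptr) {
  return TYPEOF(ptr) == EXTPTRSXP && R_ExternalPtrAddr(ptr) != NULL;
}

// MSE loss and per-layer gradients for one batch (finite-difference checks).
// [[Rcpp::export]]
Rcpp::List unet_lossgrad_ptr(SEXP ptr, Rcpp::NumericVector x,
                             Rcpp::NumericVector y) {
  Rcpp::XPtr<UNet> p(ptr);
  Rcpp::IntegerVector dx = x.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  fmat Xb = array_to_act(x, H, W, C, B);
  fmat Yb = array_to_act(y, H, W, 1, B);
  fmat pred = p->forward(Xb, H, W, B, true);
  fmat diff = pred - Yb;
  double loss = (double)arma::accu(arma::square(diff)) / (double)diff.n_elem;
  fmat dY = (2.0f / (float)diff.n_elem) * diff;
  p->backward(dY);
  Rcpp::List grads(p->L.size());
  for (size_t k = 0; k < p->L.size(); ++k) {
    const Layer& l = p->L[k];
    Rcpp::NumericMatrix dW(l.dW.n_rows, l.dW.n_cols);
    for (arma::uword j = 0; j < l.dW.n_cols; ++j)
      for (arma::uword i = 0; i < l.dW.n_rows; ++i)
        dW(i, j) = (double)l.dW(i, j);
    Rcpp::NumericVector db(l.db.n_elem);
    for (arma::uword i = 0; i < l.db.n_elem; ++i) db[i] = (double)l.db(i);
    grads[k] = Rcpp::List::create(Rcpp::Named("dW") = dW, Rcpp::Named("db") = db);
  }
  p->clear_caches();
  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("grads") = grads);
}

// Full training loop: X (H,W,C,B), Y (H,W,1,B). Returns mean MSE per epoch.
// [[Rcpp::export]]
Rcpp::NumericVector unet_fit_ptr(SEXP ptr, Rcpp::NumericVector x,
                                 Rcpp::NumericVector y, int epochs,
                                 int batch_size, double lr, double beta1,
                                 double beta2, double eps, int seed) {
  Rcpp::XPtr<UNet> p(ptr);
  Rcpp::IntegerVector dx = x.attr("dim"), dy = y.attr("dim");
  const int H = dx[0], W = dx[1], C = dx[2], B = dx[3];
  if (dy[0] != H || dy[1] != W || dy[2] != 1 || dy[3] != B)
    Rcpp::stop("target array must be (H, W, 1, B) matching the input");
  if (C != p->inC) Rcpp::stop("input has %d channels; network expects %d", C, p->inC);
  if (H % (1 << p->depth) || W % (1 << p->depth))
    Rcpp::stop("tile size must be divisible by 2^depth");
  const long hw = (long)H * W;
  fmat Xall = array_to_act(x, H, W, C, B);
  fmat Yall = array_to_act(y, H, W, 1, B);

  std::vector<int> order(B);
  for (int i = 0; i < B; ++i) order[i] = i;
  std::mt19937 rng((unsigned)seed);
  Rcpp::NumericVector history(epochs);

  for (int e = 0; e < epochs; ++e) {
    std::shuffle(order.begin(), order.end(), rng);
    double sse = 0.0;
    for (int start = 0; start < B; start += batch_size) {
      const int nb = std::min(batch_size, B - start);
      fmat Xb(nb * hw, C), Yb(nb * hw, 1);
      for (int k = 0; k < nb; ++k) {
        const int b = order[start + k];
        Xb.rows(k * hw, (k + 1) * hw - 1) = Xall.rows(b * hw, (b + 1) * hw - 1);
        Yb.rows(k * hw, (k + 1) * hw - 1) = Yall.rows(b * hw, (b + 1) * hw - 1);
      }
      fmat pred = p->forward(Xb, H, W, nb, true);
      fmat diff = pred - Yb;
      sse += (double)arma::accu(arma::square(diff));
      fmat dY = (2.0f / (float)diff.n_elem) * diff;
      p->backward(dY);
      p->adam_step((float)lr, (float)beta1, (float)beta2, (float)eps);
      Rcpp::checkUserInterrupt();
    }
    history[e] = sse / ((double)B * hw);
  }
  p->clear_caches();
  return history;
}
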