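// Compact convolutional network for mel-spectrogram image classification.
//
// Four conv blocks (3x3 'same' convolution, ReLU, 2x2/2 max pooling),
// dropout 0.25 after blocks 2 and 4, a dense ReLU layer with dropout 0.5,
// and a softmax output, trained with Adam on categorical cross-entropy.
// Convolutions are im2col + BLAS sgemm in single precision; all
// randomness (init, shuffling, dropout) comes from one mt19937 seeded
// from R, so a fixed seed reproduces training bit for bit on one thread.
//
// Activations are stored as (H*W) x C matrices with column-major spatial
// indexing (pixel p = row + H*col), which makes the flatten order stable
// and lets im2col/col2im run as contiguous memcpy/axpy strips.

#include <RcppArmadillo.h>
#include <random>
#include <cstring>

using namespace arma;

static const int NBLOCK = 4;

struct Net {
  int S, C, F, D, K;
  fmat Wc[NBLOCK];  // (9*Cin) x F
  fvec bc[NBLOCK];
  fmat Wd;          // flat x D
  fvec bd;
  fmat Wo;          // D x K
  fvec bo;

  int convIn(int b) const { return b == 0 ? C : F; }
  int side(int b) const { return S >> b; }           // input side of block b
  int flatLen() const { return (S >> NBLOCK) * (S >> NBLOCK) * F; }
};

static fmat asF(SEXP x) {
  Rcpp::NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  for (int j = 0; j < m.ncol(); ++j)
    for (int i = 0; i < m.nrow(); ++i)
      out(i, j) = (float)m(i, j);
  return out;
}

static fvec asFv(SEXP x) {
  Rcpp::NumericVector v(x);
  fvec out(v.size());
  for (int i = 0; i < v.size(); ++i) out(i) = (float)v[i];
  return out;
}

static Rcpp::NumericMatrix toR(const fmat& m) {
  Rcpp::NumericMatrix out(m.n_rows, m.n_cols);
  for (uword j = 0; j < m.n_cols; ++j)
    for (uword i = 0; i < m.n_rows; ++i)
      out(i, j) = m(i, j);
  return out;
}

static Rcpp::NumericVector toRv(const fvec& v) {
  Rcpp::NumericVector out(v.n_elem);
  for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
  return out;
}

static Net loadNet(Rcpp::List weights, int side, int channels) {
  Net net;
  net.S = side; net.C = channels;
  for (int b = 0; b < NBLOCK; ++b) {
    net.Wc[b] = asF(weights["Wc" + std::to_string(b + 1)]);
    net.bc[b] = asFv(weights["bc" + std::to_string(b + 1)]);
  }
  net.Wd = asF(weights["Wd"]);
  net.bd = asFv(weights["bd"]);
  net.Wo = asF(weights["Wo"]);
  net.bo = asFv(weights["bo"]);
  net.F = net.Wc[0].n_cols;
  net.D = net.Wd.n_cols;
  net.K = net.Wo.n_cols;
  if (side % (1 << NBLOCK) != 0)
    Rcpp::stop("input side must be divisible by %d", 1 << NBLOCK);
  if ((int)net.Wd.n_rows != net.flatLen())
    Rcpp::stop("dense weight rows (%d) do not match the flatten length (%d)",
               (int)net.Wd.n_rows, net.flatLen());
  return net;
}

static Rcpp::List saveNet(const Net& net) {
  Rcpp::List out;
  for (int b = 0; b < NBLOCK; ++b) {
    out["Wc" + std::to_string(b + 1)] = toR(net.Wc[b]);
    out["bc" + std::to_string(b + 1)] = toRv(net.bc[b]);
  }
  out["Wd"] = toR(net.Wd);
  out["bd"] = toRv(net.bd);
  out["Wo"] = toR(net.Wo);
  out["bo"] = toRv(net.bo);
  return out;
}

// ---- conv plumbing ---------------------------------------------------------

// 3x3 'same' im2col: column o*C+ch of `out` holds channel ch of A shifted
// by spatial offset o; out-of-image positions are zero.
static void im2col(const fmat& A, int H, int W, fmat& out) {
  const int C = A.n_cols;
  out.zeros(H * W, 9 * C);
  for (int o = 0; o < 9; ++o) {
    const int dr = o % 3 - 1, dc = o / 3 - 1;
    const int rlo = std::max(0, -dr), rhi = H - 1 - std::max(0, dr);
    const int clo = std::max(0, -dc), chi = W - 1 - std::max(0, dc);
    const int len = rhi - rlo + 1;
    for (int ch = 0; ch < C; ++ch) {
      const float* src = A.colptr(ch);
      float* dst = out.colptr(o * C + ch);
      for (int c = clo; c <= chi; ++c)
        std::memcpy(dst + (size_t)c * H + rlo,
                    src + (size_t)(c + dc) * H + rlo + dr,
                    sizeof(float) * len);
    }
  }
}

// Transpose of im2col: scatter-add the 9C gradient strips back to dA.
static void col2im(const fmat& dcol, int H, int W, int C, fmat& dA) {
  dA.zeros(H * W, C);
  for (int o = 0; o < 9; ++o) {
    const int dr = o % 3 - 1, dc = o / 3 - 1;
    const int rlo = std::max(0, -dr), rhi = H - 1 - std::max(0, dr);
    const int clo = std::max(0, -dc), chi = W - 1 - std::max(0, dc);
    const int len = rhi - rlo + 1;
    for (int ch = 0; ch < C; ++ch) {
      const float* src = dcol.colptr(o * C + ch);
      float* dst = dA.colptr(ch);
      for (int c = clo; c <= chi; ++c) {
        float* d = dst + (size_t)(c + dc) * H + rlo + dr;
        const float* s = src + (size_t)c * H + rlo;
        for (int i = 0; i < len; ++i) d[i] += s[i];
      }
    }
  }
}

// 2x2 stride-2 max pooling; idx records the winner (0..3) per output cell.
static void maxpool(const fmat& A, int H, int W, fmat& P,
                    Mat<unsigned char>& idx) {
  const int C = A.n_cols, H2 = H / 2, W2 = W / 2;
  P.set_size(H2 * W2, C);
  idx.set_size(H2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* a = A.colptr(ch);
    float* p = P.colptr(ch);
    unsigned char* ix = idx.colptr(ch);
    for (int c2 = 0; c2 < W2; ++c2) {
      const float* col0 = a + (size_t)(2 * c2) * H;
      const float* col1 = col0 + H;
      for (int r2 = 0; r2 < H2; ++r2) {
        const int r = 2 * r2;
        float best = col0[r]; unsigned char bi = 0;
        if (col0[r + 1] > best) { best = col0[r + 1]; bi = 1; }
        if (col1[r] > best) { best = col1[r]; bi = 2; }
        if (col1[r + 1] > best) { best = col1[r + 1]; bi = 3; }
        p[(size_t)c2 * H2 + r2] = best;
        ix[(size_t)c2 * H2 + r2] = bi;
      }
    }
  }
}

static void unpool(const fmat& dP, const Mat<unsigned char>& idx, int H2,
                   int W2, fmat& dA) {
  const int C = dP.n_cols, H = 2 * H2;
  dA.zeros((size_t)H * 2 * W2, C);
  for (int ch = 0; ch < C; ++ch) {
    const float* dp = dP.colptr(ch);
    const unsigned char* ix = idx.colptr(ch);
    float* da = dA.colptr(ch);
    for (int c2 = 0; c2 < W2; ++c2)
      for (int r2 = 0; r2 < H2; ++r2) {
        const unsigned char bi = ix[(size_t)c2 * H2 + r2];
        da[(size_t)(2 * c2 + bi / 2) * H + 2 * r2 + bi % 2] +=
          dp[(size_t)c2 * H2 + r2];
      }
  }
}

// ---- forward / backward ----------------------------------------------------

struct Trace {
  fmat col[NBLOCK];      // im2col input of each conv
  fmat relu[NBLOCK];     // post-ReLU conv output, (HW) x F
  Mat<unsigned char> poolIdx[NBLOCK];
  fmat pooled[NBLOCK];   // post-pool (post-dropout in training)
  fmat dropMask2, dropMask4;
  fvec h, z1, a1, dropMaskD, probs;
};

static fvec softmax(const fvec& z) {
  fvec e = exp(z - z.max());
  return e / accu(e);
}

static void forward(const Net& net, const fmat& x, bool train,
                    std::mt19937* rng, Trace& tr) {
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const fmat* cur = &x;
  for (int b = 0; b < NBLOCK; ++b) {
    const int H = net.side(b);
    im2col(*cur, H, H, tr.col[b]);
    tr.relu[b] = tr.col[b] * net.Wc[b];
    tr.relu[b].each_row() += net.bc[b].t();
    tr.relu[b].transform([](float v) { return v > 0.0f ? v : 0.0f; });
    maxpool(tr.relu[b], H, H, tr.pooled[b], tr.poolIdx[b]);
    if (train && (b == 1 || b == 3)) {
      const float keep = 0.75f;
      fmat& mask = (b == 1 ? tr.dropMask2 : tr.dropMask4);
      mask.set_size(tr.pooled[b].n_rows, tr.pooled[b].n_cols);
      for (uword i = 0; i < mask.n_elem; ++i)
        mask(i) = unif(*rng) < keep ? 1.0f / keep : 0.0f;
      tr.pooled[b] %= mask;
    }
    cur = &tr.pooled[b];
  }
  tr.h = vectorise(tr.pooled[NBLOCK - 1]);
  tr.z1 = net.Wd.t() * tr.h + net.bd;
  tr.a1 = clamp(tr.z1, 0.0f, std::numeric_limits<float>::max());
  if (train) {
    const float keep = 0.5f;
    tr.dropMaskD.set_size(net.D);
    for (int i = 0; i < net.D; ++i)
      tr.dropMaskD(i) = unif(*rng) < keep ? 1.0f / keep : 0.0f;
    tr.a1 %= tr.dropMaskD;
  }
  tr.probs = softmax(net.Wo.t() * tr.a1 + net.bo);
}

struct Grads {
  fmat Wc[NBLOCK]; fvec bc[NBLOCK];
  fmat Wd; fvec bd; fmat Wo; fvec bo;
  void zeroLike(const Net& n) {
    for (int b = 0; b < NBLOCK; ++b) {
      Wc[b].zeros(n.Wc[b].n_rows, n.Wc[b].n_cols);
      bc[b].zeros(n.bc[b].n_elem);
    }
    Wd.zeros(n.Wd.n_rows, n.Wd.n_cols); bd.zeros(n.bd.n_elem);
    Wo.zeros(n.Wo.n_rows, n.Wo.n_cols); bo.zeros(n.bo.n_elem);
  }
};

static void backward(const Net& net, const Trace& tr, int label, bool train,
                     Grads& g) {
  fvec dz2 = tr.probs;
  dz2(label) -= 1.0f;
  g.Wo += tr.a1 * dz2.t();
  g.bo += dz2;
  fvec da1 = net.Wo * dz2;
  if (train) da1 %= tr.dropMaskD;
  fvec dz1 = da1 % conv_to<fvec>::from(tr.z1 > 0.0f);
  g.Wd += tr.h * dz1.t();
  g.bd += dz1;
  fvec dh = net.Wd * dz1;
  const int sOut = net.S >> NBLOCK;
  fmat dPool(dh.memptr(), (size_t)sOut * sOut, net.F);  // copy
  for (int b = NBLOCK - 1; b >= 0; --b) {
    if (train && b == 1) dPool %= tr.dropMask2;
    if (train && b == 3) dPool %= tr.dropMask4;
    const int H = net.side(b);
    fmat dRelu;
    unpool(dPool, tr.poolIdx[b], H / 2, H / 2, dRelu);
    const fmat& relu = tr.relu[b];
    for (uword i = 0; i < dRelu.n_elem; ++i)
      if (relu(i) <= 0.0f) dRelu(i) = 0.0f;
    g.Wc[b] += tr.col[b].t() * dRelu;
    g.bc[b] += sum(dRelu, 0).t();
    if (b > 0) {
      fmat dCol = dRelu * net.Wc[b].t();
      col2im(dCol, H, H, net.convIn(b), dPool);
    }
  }
}

// ---- Adam ------------------------------------------------------------------

struct Adam {
  double lr, b1, b2, eps;
  long t = 0;
  std::vector<fmat> m, v;
  void init(const std::vector<fmat*>& params) {
    for (auto* p : params) {
      m.emplace_back(p->n_rows, p->n_cols, fill::zeros);
      v.emplace_back(p->n_rows, p->n_cols, fill::zeros);
    }
  }
  void step(std::vector<fmat*>& params, const std::vector<const fmat*>& grads) {
    ++t;
    const float a = (float)(lr * std::sqrt(1.0 - std::pow(b2, t)) /
                            (1.0 - std::pow(b1, t)));
    for (size_t i = 0; i < params.size(); ++i) {
      m[i] = (float)b1 * m[i] + (float)(1 - b1) * (*grads[i]);
      v[i] = (float)b2 * v[i] + (float)(1 - b2) * square(*grads[i]);
      *params[i] -= a * m[i] / (sqrt(v[i]) + (float)eps);
    }
  }
};

static fmat sliceImage(const double* src, int S, int C, int n) {
  fmat x((size_t)S * S, C);
  const double* p = src + (size_t)n * S * S * C;
  for (uword i = 0; i < x.n_elem; ++i) x(i) = (float)p[i];
  return x;
}

// ---- exported entry points -------------------------------------------------

// [[Rcpp::export(name = ".cnn_init")]]
Rcpp::List cnn_init(int side, int channels, int filters, int dense,
                    int classes, int seed) {
  if (side % (1 << NBLOCK) != 0)
    Rcpp::stop("input side must be divisible by %d", 1 << NBLOCK);
  std::mt19937 rng((unsigned)seed);
  auto glorot = [&](int rows, int cols, int fanIn, int fanOut) {
    const float lim = std::sqrt(6.0f / (fanIn + fanOut));
    std::uniform_real_distribution<float> u(-lim, lim);
    fmat w(rows, cols);
    for (uword i = 0; i < w.n_elem; ++i) w(i) = u(rng);
    return w;
  };
  Net net;
  net.S = side; net.C = channels; net.F = filters; net.D = dense;
  net.K = classes;
  for (int b = 0; b < NBLOCK; ++b) {
    const int cin = net.convIn(b);
    net.Wc[b] = glorot(9 * cin, filters, 9 * cin, 9 * filters);
    net.bc[b].zeros(filters);
  }
  const int flat = net.flatLen();
  net.Wd = glorot(flat, dense, flat, dense);
  net.bd.zeros(dense);
  net.Wo = glorot(dense, classes, dense, classes);
  net.bo.zeros(classes);
  return saveNet(net);
}

// [[Rcpp::export(name = ".cnn_train")]]
Rcpp::List cnn_train(Rcpp::List weights, Rcpp::NumericVector images,
                     Rcpp::IntegerVector labels, int side, int channels,
                     int epochs, int batch, double lr, double beta1,
                     double beta2, double adamEps, int seed) {
  Net net = loadNet(weights, side, channels);
  const int N = labels.size();
  if ((double)images.size() != (double)side * side * channels * N)
    Rcpp::stop("image array size does not match side/channels/labels");
  std::mt19937 rng((unsigned)seed);

  Adam adam; adam.lr = lr; adam.b1 = beta1; adam.b2 = beta2;
  adam.eps = adamEps;
  // parameter tensors in a fixed order; biases as column-matrix mirrors
  fmat bcM[NBLOCK], bdM, boM;
  for (int b = 0; b < NBLOCK; ++b) bcM[b] = net.bc[b];
  bdM = net.bd; boM = net.bo;
  std::vector<fmat*> params;
  for (int b = 0; b < NBLOCK; ++b) params.push_back(&net.Wc[b]);
  for (int b = 0; b < NBLOCK; ++b) params.push_back(&bcM[b]);
  params.push_back(&net.Wd); params.push_back(&bdM);
  params.push_back(&net.Wo); params.push_back(&boM);
  adam.init(params);

  // pre-convert all images to float once
  std::vector<fmat> X(N);
  for (int i = 0; i < N; ++i)
    X[i] = sliceImage(images.begin(), side, channels, i);

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  Rcpp::NumericVector epochLoss(epochs), epochAcc(epochs);
  Trace tr;
  Grads g;
  fmat scaled[NBLOCK + 2], bScaled[NBLOCK + 2];
  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle from the training RNG
    for (int i = N - 1; i > 0; --i) {
      std::uniform_int_distribution<int> d(0, i);
      std::swap(order[i], order[d(rng)]);
    }
    double lossSum = 0.0; int correct = 0;
    for (int start = 0; start < N; start += batch) {
      const int nb = std::min(batch, N - start);
      g.zeroLike(net);
      for (int k = 0; k < nb; ++k) {
        const int i = order[start + k];
        forward(net, X[i], true, &rng, tr);
        const float p = std::max(tr.probs(labels[i]), 1e-12f);
        lossSum += -std::log(p);
        if (tr.probs.index_max() == (uword)labels[i]) ++correct;
        backward(net, tr, labels[i], true, g);
      }
      const float inv = 1.0f / nb;
      for (int b = 0; b < NBLOCK; ++b) {
        scaled[b] = g.Wc[b] * inv;
        bScaled[b] = fmat(g.bc[b] * inv);
      }
      scaled[NBLOCK] = g.Wd * inv; bScaled[NBLOCK] = fmat(g.bd * inv);
      scaled[NBLOCK + 1] = g.Wo * inv; bScaled[NBLOCK + 1] = fmat(g.bo * inv);
      // order must match params: Wc1..4, bc1..4, Wd, bd, Wo, bo
      std::vector<const fmat*> gOrdered;
      for (int b = 0; b < NBLOCK; ++b) gOrdered.push_back(&scaled[b]);
      for (int b = 0; b < NBLOCK; ++b) gOrdered.push_back(&bScaled[b]);
      gOrdered.push_back(&scaled[NBLOCK]); gOrdered.push_back(&bScaled[NBLOCK]);
      gOrdered.push_back(&scaled[NBLOCK + 1]);
      gOrdered.push_back(&bScaled[NBLOCK + 1]);
      adam.step(params, gOrdered);
      // biases live in column-matrix mirrors for Adam; sync them back
      for (int b = 0; b < NBLOCK; ++b) net.bc[b] = bcM[b].col(0);
      net.bd = bdM.col(0); net.bo = boM.col(0);
      Rcpp::checkUserInterrupt();
    }
    epochLoss[ep] = lossSum / N;
    epochAcc[ep] = (double)correct / N;
  }
  return Rcpp::List::create(Rcpp::Named("weights") = saveNet(net),
                            Rcpp::Named("loss") = epochLoss,
                            Rcpp::Named("accuracy") = epochAcc);
}

// [[Rcpp::export(name = ".cnn_predict")]]
Rcpp::NumericMatrix cnn_predict(Rcpp::List weights,
                                Rcpp::NumericVector images, int side,
                                int channels, int n) {
  Net net = loadNet(weights, side, channels);
  Rcpp::NumericMatrix out(n, net.K);
  Trace tr;
  for (int i = 0; i < n; ++i) {
    fmat x = sliceImage(images.begin(), side, channels, i);
    forward(net, x, false, nullptr, tr);
    for (int k = 0; k < net.K; ++k) out(i, k) = tr.probs(k);
  }
  return out;
}

// [[Rcpp::export(name = ".cnn_gradcam")]]
Rcpp::List cnn_gradcam(Rcpp::List weights, Rcpp::NumericVector image,
                       int side, int channels, int targetClass) {
  Net net = loadNet(weights, side, channels);
  fmat x = sliceImage(image.begin(), side, channels, 0);
  Trace tr;
  forward(net, x, false, nullptr, tr);
  // gradient of the target-class logit w.r.t. the last conv activations
  fvec dz2(net.K, fill::zeros);
  dz2(targetClass) = 1.0f;
  fvec da1 = net.Wo * dz2;
  fvec dz1 = da1 % conv_to<fvec>::from(tr.z1 > 0.0f);
  fvec dh = net.Wd * dz1;
  const int sOut = net.S >> NBLOCK;
  fmat dPool(dh.memptr(), (size_t)sOut * sOut, net.F);
  const int sAct = net.side(NBLOCK - 1);
  fmat dA;
  unpool(dPool, tr.poolIdx[NBLOCK - 1], sOut, sOut, dA);
  const fmat& relu = tr.relu[NBLOCK - 1];
  for (uword i = 0; i < dA.n_elem; ++i)
    if (relu(i) <= 0.0f) dA(i) = 0.0f;
  // channel weights = spatial mean of gradients; cam = ReLU(sum w_k A_k)
  fvec w = sum(dA, 0).t() / (float)(sAct * sAct);
  fvec camVec = relu * w;
  camVec.transform([](float v) { return v > 0.0f ? v : 0.0f; });
  fmat cam(camVec.memptr(), sAct, sAct);
  return Rcpp::List::create(Rcpp::Named("cam") = toR(cam),
                            Rcpp::Named("probs") = toRv(tr.probs));
}
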