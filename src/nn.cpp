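// Convolutional network engine for the lightweight attention U-Net family.
//
// Single-precision throughout (standard practice for CNN training); tensors are
// arma::fcube (H x W x C), batches are std::vector<fcube>.  The graph is the
// fixed encoder/bottleneck/(midblock)/decoder topology of the model family,
// assembled from a configuration list.  All randomness (weight init, dropout)
// is driven by an explicit mt19937 seed with a Box-Muller normal sampler, so
// results are bit-reproducible across platforms for a given seed.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
#include <memory>

using namespace Rcpp;
using arma::fcube;
using arma::fmat;
using arma::fvec;

typedef std::vector<fcube> Batch;

// ------------------------------------------------------------------ RNG -----

struct Rng {
  std::mt19937 gen;
  bool have_spare = false;
  double spare = 0.0;
  explicit Rng(uint32_t seed) : gen(seed) {}
  double unif() {
    // 53-bit uniform in [0,1)
    uint64_t a = gen() >> 5, b = gen() >> 6;
    return (a * 67108864.0 + b) / 9007199254740992.0;
  }
  double normal() {
    if (have_spare) { have_spare = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif() - 1.0;
      v = 2.0 * unif() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double f = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * f; have_spare = true;
    return u * f;
  }
};

// ------------------------------------------------------------- parameters ---

struct Param {
  fvec w, g, m, v;   // value, gradient, Adam moments
  std::string name;
  bool trainable = true;
  void init(size_t n, const std::string& nm) {
    w.zeros(n); g.zeros(n); m.zeros(n); v.zeros(n); name = nm;
  }
};

// ------------------------------------------------------------------ im2col --

// Xcol: (H*W) x (k*k*Cin); column index = (dy*k+dx)*Cin + ci ; pixel row-major
static void im2col(const fcube& x, int k, fmat& out) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int pad = (k - 1) / 2;
  out.zeros(H * W, k * k * C);
  for (int dy = 0; dy < k; ++dy) {
    for (int dx = 0; dx < k; ++dx) {
      const int r0 = std::max(0, pad - dy), r1 = std::min(H, H + pad - dy);
      const int c0 = std::max(0, pad - dx), c1 = std::min(W, W + pad - dx);
      for (int ci = 0; ci < C; ++ci) {
        const int col = (dy * k + dx) * C + ci;
        const fmat& xs = x.slice(ci);
        for (int cc = c0; cc < c1; ++cc) {
          const int sc = cc + dx - pad;
          float* dst = out.colptr(col) + (size_t)cc * H;
          const float* src = xs.colptr(sc);
          for (int rr = r0; rr < r1; ++rr) dst[rr] = src[rr + dy - pad];
        }
      }
    }
  }
}

// adjoint of im2col: scatter-add columns back into an image
static void col2im(const fmat& cols, int k, int H, int W, int C, fcube& out) {
  const int pad = (k - 1) / 2;
  out.zeros(H, W, C);
  for (int dy = 0; dy < k; ++dy) {
    for (int dx = 0; dx < k; ++dx) {
      const int r0 = std::max(0, pad - dy), r1 = std::min(H, H + pad - dy);
      const int c0 = std::max(0, pad - dx), c1 = std::min(W, W + pad - dx);
      for (int ci = 0; ci < C; ++ci) {
        const int col = (dy * k + dx) * C + ci;
        fmat& os = out.slice(ci);
        for (int cc = c0; cc < c1; ++cc) {
          const int sc = cc + dx - pad;
          const float* src = cols.colptr(col) + (size_t)cc * H;
          float* dst = os.colptr(sc);
          for (int rr = r0; rr < r1; ++rr) dst[rr + dy - pad] += src[rr];
        }
      }
    }
  }
}

static fmat to_mat(const fcube& x) {  // (H*W) x C view-copy
  const int HW = x.n_rows * x.n_cols, C = x.n_slices;
  fmat m(HW, C);
  for (int c = 0; c < C; ++c)
    std::copy(x.slice(c).memptr(), x.slice(c).memptr() + HW, m.colptr(c));
  return m;
}

static fcube to_cube(const fmat& m, int H, int W) {
  fcube x(H, W, m.n_cols);
  for (size_t c = 0; c < m.n_cols; ++c)
    std::copy(m.colptr(c), m.colptr(c) + (size_t)H * W, x.slice(c).memptr());
  return x;
}

#include "conv3_inc.h"

// ------------------------------------------------------------------ layers --

struct Layer {
  std::vector<Param> params;
  virtual ~Layer() {}
  virtual void forward(const std::vector<const fcube*>& in, fcube& out,
                       bool train, Rng& rng, int sample) = 0;
  virtual void backward(const std::vector<const fcube*>& in, const fcube& out,
                        const fcube& dout, std::vector<fcube>& din,
                        int sample) = 0;
  // batch-wise backward; layers whose gradients couple samples (BatchNorm)
  // override this, everything else loops over the per-sample backward
  virtual void backward_batch(const std::vector<std::vector<const fcube*>>& ins,
                              const Batch& outs, const Batch& douts,
                              std::vector<std::vector<fcube>>& dins) {
    for (size_t s = 0; s < outs.size(); ++s)
      backward(ins[s], outs[s], douts[s], dins[s], (int)s);
  }
  virtual void start_batch(int n) {}  // reset per-batch caches
};

// conv (k=1 or 3, same padding, bias) + optional BatchNorm + optional ReLU
struct ConvBlock : Layer {
  int k, cin, cout;
  bool bn, relu;
  float momentum = 0.9f, eps = 1e-3f;  // moving-stats decay: fast-adapting convention
  fvec invstd;                       // per-channel, current batch
  std::vector<fcube> xhat;           // per-sample normalized pre-activations
  std::vector<fcube> pre;            // per-sample conv outputs (train+BN only)
  int nb = 0;
  bool training_pass = false;

  ConvBlock(int k_, int cin_, int cout_, bool bn_, bool relu_, Rng& rng,
            const std::string& nm)
      : k(k_), cin(cin_), cout(cout_), bn(bn_), relu(relu_) {
    params.resize(bn ? 4 : 2);
    params[0].init((size_t)k * k * cin * cout, nm + "_kernel");
    params[1].init(cout, nm + "_bias");
    const double sd = std::sqrt(2.0 / (k * k * cin));
    for (auto& w : params[0].w) w = (float)(rng.normal() * sd);
    if (bn) {
      params[2].init(2 * cout, nm + "_bn");        // gamma, beta
      params[3].init(2 * cout, nm + "_bn_stats");  // moving mean, moving var
      params[3].trainable = false;
      for (int c = 0; c < cout; ++c) { params[2].w[c] = 1.0f; params[3].w[cout + c] = 1.0f; }
    }
  }

  void start_batch(int n) override {
    nb = n;
    if (bn) { xhat.assign(n, fcube()); pre.assign(n, fcube()); }
  }

  void forward(const std::vector<const fcube*>& in, fcube& out, bool train,
               Rng& rng, int sample) override {
    const fcube& x = *in[0];
    const int H = x.n_rows, W = x.n_cols, HW = H * W;
    out.zeros(H, W, cout);
    if (k == 3)
      conv3_forward(x.memptr(), H, W, cin, params[0].w.memptr(), cout,
                    out.memptr());
    else
      sgemm('N', 'N', HW, cout, cin, 1.0f, x.memptr(), HW,
            params[0].w.memptr(), cin, 0.0f, out.memptr(), HW);
    for (int c = 0; c < cout; ++c) out.slice(c) += params[1].w[c];
    if (bn) {
      training_pass = train;
      if (train) {
        pre[sample] = out;           // normalized in finalize_bn
        return;
      }
      const float* mv = params[3].w.memptr();
      for (int c = 0; c < cout; ++c) {
        const float is = 1.0f / std::sqrt(mv[cout + c] + eps);
        out.slice(c) = (out.slice(c) - mv[c]) * (is * params[2].w[c]) +
                       params[2].w[cout + c];
      }
    }
    if (relu) out.transform([](float v) { return v > 0 ? v : 0.0f; });
  }

  // batchwise BN statistics + normalization (training mode)
  void finalize_bn(std::vector<fcube*>& outs) {
    if (!bn || !training_pass) return;
    const double n = (double)pre[0].n_rows * pre[0].n_cols * nb;
    fvec mean(cout, arma::fill::zeros), var(cout, arma::fill::zeros);
    for (int s = 0; s < nb; ++s)
      for (int c = 0; c < cout; ++c) mean[c] += arma::accu(pre[s].slice(c));
    mean /= n;
    for (int s = 0; s < nb; ++s)
      for (int c = 0; c < cout; ++c) {
        const fmat d = pre[s].slice(c) - mean[c];
        var[c] += arma::accu(d % d);
      }
    var /= n;
    invstd.set_size(cout);
    for (int c = 0; c < cout; ++c) invstd[c] = 1.0f / std::sqrt(var[c] + eps);
    float* mv = params[3].w.memptr();
    for (int c = 0; c < cout; ++c) {
      mv[c] = momentum * mv[c] + (1 - momentum) * mean[c];
      mv[cout + c] = momentum * mv[cout + c] + (1 - momentum) * var[c];
    }
    for (int s = 0; s < nb; ++s) {
      xhat[s].set_size(arma::size(pre[s]));
      for (int c = 0; c < cout; ++c)
        xhat[s].slice(c) = (pre[s].slice(c) - mean[c]) * invstd[c];
      fcube& y = *outs[s];
      y.set_size(arma::size(pre[s]));
      for (int c = 0; c < cout; ++c)
        y.slice(c) = xhat[s].slice(c) * params[2].w[c] + params[2].w[cout + c];
      if (relu) y.transform([](float v) { return v > 0 ? v : 0.0f; });
      pre[s].reset();
    }
  }

  void backward(const std::vector<const fcube*>& in, const fcube& out,
                const fcube& dout, std::vector<fcube>& din, int sample) override {
    fcube dy = masked_dy(out, dout);   // valid only without train-mode BN
    conv_backward(*in[0], dy, din[0]);
  }

  void backward_batch(const std::vector<std::vector<const fcube*>>& ins,
                      const Batch& outs, const Batch& douts,
                      std::vector<std::vector<fcube>>& dins) override {
    const int N = (int)outs.size();
    if (!bn || !training_pass) {
      for (int s = 0; s < N; ++s) {
        fcube dy = masked_dy(outs[s], douts[s]);
        conv_backward(*ins[s][0], dy, dins[s][0]);
      }
      return;
    }
    std::vector<fcube> dyv(N);
    const double n = (double)xhat[0].n_rows * xhat[0].n_cols * N;
    fvec s1(cout, arma::fill::zeros), s2(cout, arma::fill::zeros);
    for (int s = 0; s < N; ++s) {
      dyv[s] = masked_dy(outs[s], douts[s]);
      for (int c = 0; c < cout; ++c) {
        const double dg = arma::accu(dyv[s].slice(c) % xhat[s].slice(c));
        const double db = arma::accu(dyv[s].slice(c));
        params[2].g[c]        += dg;
        params[2].g[cout + c] += db;
        s1[c] += db * params[2].w[c];
        s2[c] += dg * params[2].w[c];
      }
    }
    for (int s = 0; s < N; ++s) {
      fcube dx(arma::size(dyv[s]));
      for (int c = 0; c < cout; ++c)
        dx.slice(c) = invstd[c] * (dyv[s].slice(c) * params[2].w[c] -
                      (float)(s1[c] / n) - xhat[s].slice(c) * (float)(s2[c] / n));
      conv_backward(*ins[s][0], dx, dins[s][0]);
    }
  }

  fcube masked_dy(const fcube& out, const fcube& dout) const {
    fcube dy = dout;
    if (relu) {
      const float* o = out.memptr();
      float* d = dy.memptr();
      for (size_t i = 0; i < dy.n_elem; ++i)
        if (o[i] <= 0) d[i] = 0;
    }
    return dy;
  }

  void conv_backward(const fcube& x, const fcube& dy, fcube& dx) {
    const int H = x.n_rows, W = x.n_cols, HW = H * W;
    dx.zeros(H, W, cin);
    if (k == 3) {
      conv3_backward(x.memptr(), dy.memptr(), H, W, cin, cout,
                     params[0].w.memptr(), params[0].g.memptr(), dx.memptr());
    } else {
      // dW += X^T dY ; dX = dY W^T
      sgemm('T', 'N', cin, cout, HW, 1.0f, x.memptr(), HW, dy.memptr(), HW,
            1.0f, params[0].g.memptr(), cin);
      sgemm('N', 'T', HW, cin, cout, 1.0f, dy.memptr(), HW,
            params[0].w.memptr(), cin, 1.0f, dx.memptr(), HW);
    }
    for (int c = 0; c < cout; ++c) params[1].g[c] += arma::accu(dy.slice(c));
  }
};

// Channel attention: GAP -> dense(C->C)+bias -> ReLU -> sigmoid -> scale.
// Weights are bounded to [0.5, 1) because sigmoid(relu(z)) >= sigmoid(0).
struct AttentionBlock : Layer {
  int C;
  std::vector<fvec> s_c, z_c, a_c;  // per-sample caches
  AttentionBlock(int C_, Rng& rng, const std::string& nm) : C(C_) {
    params.resize(2);
    params[0].init((size_t)C * C, nm + "_att_kernel");
    params[1].init(C, nm + "_att_bias");
    const double sd = std::sqrt(2.0 / C);
    for (auto& w : params[0].w) w = (float)(rng.normal() * sd);
  }
  void start_batch(int n) override {
    s_c.assign(n, fvec()); z_c.assign(n, fvec()); a_c.assign(n, fvec());
  }
  void forward(const std::vector<const fcube*>& in, fcube& out, bool train,
               Rng& rng, int sample) override {
    const fcube& x = *in[0];
    fvec s(C);
    for (int c = 0; c < C; ++c) s[c] = arma::accu(x.slice(c)) / (x.n_rows * x.n_cols);
    fmat Wm(params[0].w.memptr(), C, C, false, true);
    fvec z = Wm * s + params[1].w;
    fvec r = z; r.transform([](float v) { return v > 0 ? v : 0.0f; });
    fvec a = 1.0f / (1.0f + arma::exp(-r));
    out = x;
    for (int c = 0; c < C; ++c) out.slice(c) *= a[c];
    s_c[sample] = s; z_c[sample] = z; a_c[sample] = a;
  }
  void backward(const std::vector<const fcube*>& in, const fcube& out,
                const fcube& dout, std::vector<fcube>& din, int sample) override {
    const fcube& x = *in[0];
    const fvec& s = s_c[sample];
    const fvec& z = z_c[sample];
    const fvec& a = a_c[sample];
    fvec da(C);
    for (int c = 0; c < C; ++c) da[c] = arma::accu(dout.slice(c) % x.slice(c));
    din[0] = dout;
    for (int c = 0; c < C; ++c) din[0].slice(c) *= a[c];
    fvec dz = da % a % (1.0f - a);
    for (int c = 0; c < C; ++c) if (z[c] <= 0) dz[c] = 0;  // relu gate
    fmat Wm(params[0].w.memptr(), C, C, false, true);
    fmat dWm(params[0].g.memptr(), C, C, false, true);
    dWm += dz * s.t();
    params[1].g += dz;
    fvec ds = Wm.t() * dz;
    const float inv = 1.0f / (x.n_rows * x.n_cols);
    for (int c = 0; c < C; ++c) din[0].slice(c) += ds[c] * inv;
  }
};

struct MaxPool2 : Layer {
  std::vector<arma::ucube> idx;  // argmax in 2x2 window, 0..3
  void start_batch(int n) override { idx.assign(n, arma::ucube()); }
  void forward(const std::vector<const fcube*>& in, fcube& out, bool, Rng&,
               int sample) override {
    const fcube& x = *in[0];
    const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
    out.set_size(H, W, C);
    idx[sample].set_size(H, W, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          float best = x(2 * i, 2 * j, c); unsigned bi = 0;
          const float v1 = x(2 * i + 1, 2 * j, c);
          const float v2 = x(2 * i, 2 * j + 1, c);
          const float v3 = x(2 * i + 1, 2 * j + 1, c);
          if (v1 > best) { best = v1; bi = 1; }
          if (v2 > best) { best = v2; bi = 2; }
          if (v3 > best) { best = v3; bi = 3; }
          out(i, j, c) = best; idx[sample](i, j, c) = bi;
        }
  }
  void backward(const std::vector<const fcube*>& in, const fcube&,
                const fcube& dout, std::vector<fcube>& din, int sample) override {
    const fcube& x = *in[0];
    din[0].zeros(x.n_rows, x.n_cols, x.n_slices);
    const int H = dout.n_rows, W = dout.n_cols, C = dout.n_slices;
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const unsigned bi = idx[sample](i, j, c);
          din[0](2 * i + (bi & 1u), 2 * j + (bi >> 1), c) += dout(i, j, c);
        }
  }
};

struct UpNearest2 : Layer {
  void forward(const std::vector<const fcube*>& in, fcube& out, bool, Rng&,
               int) override {
    const fcube& x = *in[0];
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    out.set_size(2 * H, 2 * W, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          const float v = x(i, j, c);
          out(2 * i, 2 * j, c) = v; out(2 * i + 1, 2 * j, c) = v;
          out(2 * i, 2 * j + 1, c) = v; out(2 * i + 1, 2 * j + 1, c) = v;
        }
  }
  void backward(const std::vector<const fcube*>& in, const fcube&,
                const fcube& dout, std::vector<fcube>& din, int) override {
    const fcube& x = *in[0];
    const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
    din[0].set_size(H, W, C);
    for (int c = 0; c < C; ++c)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i)
          din[0](i, j, c) = dout(2 * i, 2 * j, c) + dout(2 * i + 1, 2 * j, c) +
                            dout(2 * i, 2 * j + 1, c) + dout(2 * i + 1, 2 * j + 1, c);
  }
};

// Transposed 3x3 stride-2 convolution ('same'; output doubles the grid):
// y[2i+a-1, 2j+b-1] += x[i,j,:] . W[a,b,:,co]
struct ConvTranspose : Layer {
  int cin, cout;
  ConvTranspose(int cin_, int cout_, Rng& rng, const std::string& nm)
      : cin(cin_), cout(cout_) {
    params.resize(2);
    params[0].init((size_t)9 * cin * cout, nm + "_tkernel");
    params[1].init(cout, nm + "_tbias");
    const double sd = std::sqrt(2.0 / (9.0 * cin));
    for (auto& w : params[0].w) w = (float)(rng.normal() * sd);
  }
  void forward(const std::vector<const fcube*>& in, fcube& out, bool, Rng&,
               int) override {
    const fcube& x = *in[0];
    const int H = x.n_rows, W = x.n_cols;
    out.zeros(2 * H, 2 * W, cout);
    fmat xm = to_mat(x);  // HW x cin
    fmat Wm(params[0].w.memptr(), (size_t)9 * cin, cout, false, true);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        fmat Wab = Wm.rows((size_t)(a * 3 + b) * cin, (size_t)(a * 3 + b) * cin + cin - 1);
        fmat yab = xm * Wab;  // HW x cout
        for (int co = 0; co < cout; ++co) {
          fmat ys(yab.colptr(co), H, W, false, true);
          for (int j = 0; j < W; ++j) {
            const int oj = 2 * j + b - 1;
            if (oj < 0 || oj >= 2 * W) continue;
            for (int i = 0; i < H; ++i) {
              const int oi = 2 * i + a - 1;
              if (oi < 0 || oi >= 2 * H) continue;
              out(oi, oj, co) += ys(i, j);
            }
          }
        }
      }
    for (int co = 0; co < cout; ++co) out.slice(co) += params[1].w[co];
  }
  void backward(const std::vector<const fcube*>& in, const fcube&,
                const fcube& dout, std::vector<fcube>& din, int) override {
    const fcube& x = *in[0];
    const int H = x.n_rows, W = x.n_cols;
    fmat xm = to_mat(x);
    fmat Wm(params[0].w.memptr(), (size_t)9 * cin, cout, false, true);
    fmat dWm(params[0].g.memptr(), (size_t)9 * cin, cout, false, true);
    din[0].zeros(H, W, cin);
    fmat dxm(H * W, cin, arma::fill::zeros);
    for (int a = 0; a < 3; ++a)
      for (int b = 0; b < 3; ++b) {
        // gather dy at offset grid -> dyab (HW x cout)
        fmat dyab(H * W, cout, arma::fill::zeros);
        for (int co = 0; co < cout; ++co) {
          fmat ds(dyab.colptr(co), H, W, false, true);
          for (int j = 0; j < W; ++j) {
            const int oj = 2 * j + b - 1;
            if (oj < 0 || oj >= 2 * W) continue;
            for (int i = 0; i < H; ++i) {
              const int oi = 2 * i + a - 1;
              if (oi < 0 || oi >= 2 * H) continue;
              ds(i, j) = dout(oi, oj, co);
            }
          }
        }
        dWm.rows((size_t)(a * 3 + b) * cin, (size_t)(a * 3 + b) * cin + cin - 1) +=
            xm.t() * dyab;
        dxm += dyab * Wm.rows((size_t)(a * 3 + b) * cin,
                              (size_t)(a * 3 + b) * cin + cin - 1).t();
      }
    din[0] = to_cube(dxm, H, W);
    fvec db(params[1].g.memptr(), cout, false, true);
    for (int co = 0; co < cout; ++co) db[co] += arma::accu(dout.slice(co));
  }
};

struct Dropout : Layer {
  double rate;
  std::vector<fcube> mask;
  explicit Dropout(double r) : rate(r) {}
  void start_batch(int n) override { mask.assign(n, fcube()); }
  void forward(const std::vector<const fcube*>& in, fcube& out, bool train,
               Rng& rng, int sample) override {
    const fcube& x = *in[0];
    if (!train || rate <= 0) { out = x; return; }
    mask[sample].set_size(arma::size(x));
    const float scale = 1.0f / (1.0f - (float)rate);
    for (auto& m : mask[sample]) m = rng.unif() < rate ? 0.0f : scale;
    out = x % mask[sample];
  }
  void backward(const std::vector<const fcube*>& in, const fcube&,
                const fcube& dout, std::vector<fcube>& din, int sample) override {
    if (mask[sample].n_elem == 0) din[0] = dout;
    else din[0] = dout % mask[sample];
  }
};

struct Add : Layer {
  void forward(const std::vector<const fcube*>& in, fcube& out, bool, Rng&,
               int) override {
    out = *in[0] + *in[1];
  }
  void backward(const std::vector<const fcube*>& in, const fcube&,
                const fcube& dout, std::vector<fcube>& din, int) override {
    din[0] = dout; din[1] = dout;
  }
};

struct ConcatC : Layer {
  void forward(const std::vector<const fcube*>& in, fcube& out, bool, Rng&,
               int) override {
    out = arma::join_slices(*in[0], *in[1]);
  }
  void backward(const std::vector<const fcube*>& in, const fcube&,
                const fcube& dout, std::vector<fcube>& din, int) override {
    const int c0 = in[0]->n_slices, c1 = in[1]->n_slices;
    din[0] = dout.slices(0, c0 - 1);
    din[1] = dout.slices(c0, c0 + c1 - 1);
  }
};

struct Sigmoid : Layer {
  void forward(const std::vector<const fcube*>& in, fcube& out, bool, Rng&,
               int) override {
    out = 1.0f / (1.0f + arma::exp(-*in[0]));
  }
  void backward(const std::vector<const fcube*>& in, const fcube& out,
                const fcube& dout, std::vector<fcube>& din, int) override {
    din[0] = dout % out % (1.0f - out);
  }
};

// ------------------------------------------------------------------ graph ---

struct Node {
  std::unique_ptr<Layer> layer;
  std::vector<int> in;    // input node ids (-1 = network input)
  Batch out;              // per-sample outputs of the latest forward
  Batch grad;             // accumulated output gradients during backward
};

struct Net {
  std::vector<Node> nodes;
  Rng rng;
  long step = 0;  // Adam timestep
  int in_ch = 3, out_ch = 3, input_h = 0, input_w = 0;

  explicit Net(uint32_t seed) : rng(seed) {}

  int add(Layer* l, std::initializer_list<int> in) {
    Node n; n.layer.reset(l); n.in = in;
    nodes.push_back(std::move(n));
    return (int)nodes.size() - 1;
  }
  int add(Layer* l, std::vector<int> in) {
    Node n; n.layer.reset(l); n.in = std::move(in);
    nodes.push_back(std::move(n));
    return (int)nodes.size() - 1;
  }

  double param_count(bool with_stats) const {
    double t = 0;
    for (const auto& n : nodes)
      for (const auto& p : n.layer->params)
        if (p.trainable || with_stats) t += p.w.n_elem;
    return t;
  }

  void forward_batch(const Batch& x, bool train, Batch& out) {
    const int N = x.size();
    for (auto& n : nodes) {
      n.layer->start_batch(N);
      n.out.assign(N, fcube());
    }
    for (size_t k = 0; k < nodes.size(); ++k) {
      Node& nd = nodes[k];
      for (int s = 0; s < N; ++s) {
        std::vector<const fcube*> ins;
        for (int id : nd.in) ins.push_back(id < 0 ? &x[s] : &nodes[id].out[s]);
        nd.layer->forward(ins, nd.out[s], train, rng, s);
      }
      // batchwise BN normalization (training mode)
      if (auto cb = dynamic_cast<ConvBlock*>(nd.layer.get())) {
        if (train && cb->bn) {
          std::vector<fcube*> outs;
          for (int s = 0; s < N; ++s) outs.push_back(&nd.out[s]);
          cb->finalize_bn(outs);
        }
      }
    }
    out = nodes.back().out;
  }

  // backward from loss gradient on final output (gradients land in params)
  void backward_batch(const Batch& x, const Batch& dloss) {
    const int N = x.size();
    for (auto& n : nodes) n.grad.assign(N, fcube());
    nodes.back().grad = dloss;
    for (int k = (int)nodes.size() - 1; k >= 0; --k) {
      Node& nd = nodes[k];
      for (int s = 0; s < N; ++s)
        if (nd.grad[s].n_elem == 0) nd.grad[s].zeros(arma::size(nd.out[s]));
      std::vector<std::vector<const fcube*>> ins(N);
      std::vector<std::vector<fcube>> dins(N);
      for (int s = 0; s < N; ++s) {
        for (int id : nd.in) ins[s].push_back(id < 0 ? &x[s] : &nodes[id].out[s]);
        dins[s].resize(nd.in.size());
      }
      nd.layer->backward_batch(ins, nd.out, nd.grad, dins);
      for (int s = 0; s < N; ++s)
        for (size_t j = 0; j < nd.in.size(); ++j) {
          const int id = nd.in[j];
          if (id < 0) continue;
          if (nodes[id].grad[s].n_elem == 0) nodes[id].grad[s] = std::move(dins[s][j]);
          else nodes[id].grad[s] += dins[s][j];
        }
      nd.out.clear(); nd.grad.clear();  // free as we go
    }
  }

  void zero_grads() {
    for (auto& n : nodes)
      for (auto& p : n.layer->params) p.g.zeros();
  }

  void adam_step(double lr, double b1, double b2, double eps) {
    ++step;
    const double bc1 = 1.0 - std::pow(b1, (double)step);
    const double bc2 = 1.0 - std::pow(b2, (double)step);
    for (auto& n : nodes)
      for (auto& p : n.layer->params) {
        if (!p.trainable) continue;
        p.m = (float)b1 * p.m + (float)(1 - b1) * p.g;
        p.v = (float)b2 * p.v + (float)(1 - b2) * (p.g % p.g);
        for (size_t i = 0; i < p.w.n_elem; ++i) {
          const double mh = p.m[i] / bc1, vh = p.v[i] / bc2;
          p.w[i] -= (float)(lr * mh / (std::sqrt(vh) + eps));
        }
      }
  }
};

// ----------------------------------------------------------- construction ---

// cfg fields (all widths in channels):
//   enc_widths (int vec, length = depth), bott_width, dec_widths, mirror_widths,
//   in_ch, out_ch, head_k, attention (bool), bottleneck_attention (bool),
//   skip_add (bool), up_transpose (bool), midblock (int vec: narrowing widths
//   after the entry conv, e.g. c(64,32,16); length 0 = no midblock),
//   dropout (double)
static Net* build_net(List cfg, uint32_t seed) {
  std::unique_ptr<Net> net(new Net(seed));
  IntegerVector enc = cfg["enc_widths"], dec = cfg["dec_widths"],
                mirror = cfg["mirror_widths"], mid = cfg["midblock"];
  const int bott = as<int>(cfg["bott_width"]);
  const int in_ch = as<int>(cfg["in_ch"]), out_ch = as<int>(cfg["out_ch"]);
  const int head_k = as<int>(cfg["head_k"]);
  const bool att = as<bool>(cfg["attention"]);
  const bool batt = as<bool>(cfg["bottleneck_attention"]);
  const bool addskip = as<bool>(cfg["skip_add"]);
  const bool transpose = as<bool>(cfg["up_transpose"]);
  const double drop = as<double>(cfg["dropout"]);
  net->in_ch = in_ch; net->out_ch = out_ch;
  const int depth = enc.size();
  Rng& rng = net->rng;

  int x = -1;
  std::vector<int> skips;
  char nm[64];
  for (int i = 0; i < depth; ++i) {
    const int w = enc[i];
    snprintf(nm, 64, "enc%d_c1", i + 1);
    x = net->add(new ConvBlock(3, i == 0 ? in_ch : enc[i - 1], w, true, true, rng, nm), {x});
    snprintf(nm, 64, "enc%d_c2", i + 1);
    x = net->add(new ConvBlock(3, w, w, true, true, rng, nm), {x});
    if (att) {
      snprintf(nm, 64, "enc%d", i + 1);
      x = net->add(new AttentionBlock(w, rng, nm), {x});
    }
    skips.push_back(x);
    x = net->add(new MaxPool2(), {x});
    x = net->add(new Dropout(drop), {x});
  }
  snprintf(nm, 64, "bott_c1");
  x = net->add(new ConvBlock(3, enc[depth - 1], bott, true, true, rng, nm), {x});
  snprintf(nm, 64, "bott_c2");
  x = net->add(new ConvBlock(3, bott, bott, true, true, rng, nm), {x});
  if (att && batt) x = net->add(new AttentionBlock(bott, rng, "bott"), {x});

  if (mid.size() > 0) {
    const int mid_in = x;
    // entry conv at bottleneck width, then narrowing convs with attention,
    // then restore conv back to bottleneck width; plain conv+ReLU (no BN)
    x = net->add(new ConvBlock(3, bott, bott, false, true, rng, "mid_entry"), {x});
    int prev = bott;
    for (int i = 0; i < mid.size(); ++i) {
      snprintf(nm, 64, "mid_n%d", i + 1);
      x = net->add(new ConvBlock(3, prev, mid[i], false, true, rng, nm), {x});
      snprintf(nm, 64, "mid%d", i + 1);
      x = net->add(new AttentionBlock(mid[i], rng, nm), {x});
      prev = mid[i];
    }
    x = net->add(new ConvBlock(3, prev, bott, false, true, rng, "mid_restore"), {x});
    x = net->add(new Add(), {x, mid_in});
    x = net->add(new AttentionBlock(bott, rng, "mid_out"), {x});
  }

  int cur = mid.size() > 0 ? bott : bott;
  cur = bott;
  for (int j = 0; j < depth; ++j) {
    const int w = dec[j];
    const int skip_id = skips[depth - 1 - j];
    const int skip_w = enc[depth - 1 - j];
    if (transpose) {
      snprintf(nm, 64, "dec%d_up", j + 1);
      x = net->add(new ConvTranspose(cur, mirror[j], rng, nm), {x});
      cur = mirror[j];
    } else {
      x = net->add(new UpNearest2(), {x});
    }
    x = net->add(new Dropout(drop), {x});
    int conv_in;
    if (addskip) {
      x = net->add(new Add(), {x, skip_id});
      conv_in = cur;  // == skip_w by construction
    } else {
      x = net->add(new ConcatC(), {x, skip_id});
      conv_in = cur + skip_w;
    }
    snprintf(nm, 64, "dec%d_c1", j + 1);
    x = net->add(new ConvBlock(3, conv_in, w, true, true, rng, nm), {x});
    snprintf(nm, 64, "dec%d_c2", j + 1);
    x = net->add(new ConvBlock(3, w, w, true, true, rng, nm), {x});
    if (att) {
      snprintf(nm, 64, "dec%d", j + 1);
      x = net->add(new AttentionBlock(w, rng, nm), {x});
    }
    cur = w;
  }
  x = net->add(new ConvBlock(head_k, cur, out_ch, false, false, rng, "head"), {x});
  x = net->add(new Sigmoid(), {x});
  return net.release();
}

// --------------------------------------------------------------- R interface

static Batch r_to_batch(const NumericVector& x) {
  IntegerVector dim = x.attr("dim");
  if (dim.size() != 4) stop("expected a 4-d array [H, W, C, N]");
  const int H = dim[0], W = dim[1], C = dim[2], N = dim[3];
  Batch b(N);
  const double* p = x.begin();
  for (int s = 0; s < N; ++s) {
    b[s].set_size(H, W, C);
    for (size_t i = 0; i < (size_t)H * W * C; ++i)
      b[s][i] = (float)p[(size_t)s * H * W * C + i];
  }
  return b;
}

static NumericVector batch_to_r(const Batch& b) {
  const int H = b[0].n_rows, W = b[0].n_cols, C = b[0].n_slices, N = b.size();
  NumericVector out((size_t)H * W * C * N);
  for (int s = 0; s < N; ++s)
    for (size_t i = 0; i < (size_t)H * W * C; ++i)
      out[(size_t)s * H * W * C + i] = b[s][i];
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  return out;
}

// soft dice over all pixels & channels of one sample
static double soft_dice(const fcube& p, const fcube& g, double smooth) {
  double num = 0, sp = 0, sg = 0;
  for (size_t i = 0; i < p.n_elem; ++i) {
    num += (double)p[i] * g[i]; sp += p[i]; sg += g[i];
  }
  return (2.0 * num + smooth) / (sp + sg + smooth);
}

// hard dice on channel-mean maps at threshold 0.5
static double hard_dice(const fcube& p, const fcube& g) {
  const int H = p.n_rows, W = p.n_cols, C = p.n_slices;
  double inter = 0, a = 0, b = 0;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      double mp = 0, mg = 0;
      for (int c = 0; c < C; ++c) { mp += p(i, j, c); mg += g(i, j, c); }
      const bool bp = mp / C >= 0.5, bg = mg / C >= 0.5;
      inter += bp && bg; a += bp; b += bg;
    }
  if (a + b == 0) return 1.0;
  return 2.0 * inter / (a + b);
}

// [[Rcpp::export]]
SEXP nn_build(List cfg, int seed) {
  Net* net = build_net(cfg, (uint32_t)seed);
  XPtr<Net> ptr(net, true);
  return ptr;
}

// [[Rcpp::export]]
double nn_param_count(SEXP netp, bool include_stats = true) {
  XPtr<Net> net(netp);
  return net->param_count(include_stats);
}

// [[Rcpp::export]]
NumericVector nn_forward(SEXP netp, NumericVector x, bool train = false) {
  XPtr<Net> net(netp);
  Batch b = r_to_batch(x), out;
  net->forward_batch(b, train, out);
  NumericVector res = batch_to_r(out);
  for (auto& n : net->nodes) { n.out.clear(); n.grad.clear(); }
  return res;
}

// [[Rcpp::export]]
List nn_train_batch(SEXP netp, NumericVector x, NumericVector y,
                    std::string loss, double lr, double beta1, double beta2,
                    double eps, double smooth = 1e-6) {
  XPtr<Net> net(netp);
  Batch bx = r_to_batch(x), by = r_to_batch(y), out;
  const int N = bx.size();
  net->zero_grads();
  net->forward_batch(bx, true, out);
  Batch dloss(N);
  double total = 0, dsum = 0;
  for (int s = 0; s < N; ++s) {
    const fcube& p = out[s];
    const fcube& g = by[s];
    dloss[s].set_size(arma::size(p));
    if (loss == "dice") {
      double num = 0, sp = 0, sg = 0;
      for (size_t i = 0; i < p.n_elem; ++i) {
        num += (double)p[i] * g[i]; sp += p[i]; sg += g[i];
      }
      const double Num = 2.0 * num + smooth, Den = sp + sg + smooth;
      total += 1.0 - Num / Den;
      const double inv = 1.0 / ((double)N);
      for (size_t i = 0; i < p.n_elem; ++i)
        dloss[s][i] = (float)(-inv * (2.0 * g[i] * Den - Num) / (Den * Den));
    } else {  // mse
      double sse = 0;
      for (size_t i = 0; i < p.n_elem; ++i) {
        const double d = p[i] - g[i]; sse += d * d;
      }
      total += sse / p.n_elem;
      const double k = 2.0 / ((double)p.n_elem * N);
      for (size_t i = 0; i < p.n_elem; ++i)
        dloss[s][i] = (float)(k * (p[i] - g[i]));
    }
    dsum += hard_dice(p, by[s]);
  }
  net->backward_batch(bx, dloss);
  net->adam_step(lr, beta1, beta2, eps);
  for (auto& n : net->nodes) { n.out.clear(); n.grad.clear(); }
  return List::create(_["loss"] = total / N, _["dice"] = dsum / N);
}

// [[Rcpp::export]]
List nn_eval(SEXP netp, NumericVector x, NumericVector y, std::string loss,
             double smooth = 1e-6) {
  XPtr<Net> net(netp);
  Batch bx = r_to_batch(x), by = r_to_batch(y), out;
  net->forward_batch(bx, false, out);
  double total = 0, dsum = 0;
  const int N = bx.size();
  for (int s = 0; s < N; ++s) {
    if (loss == "dice") total += 1.0 - soft_dice(out[s], by[s], smooth);
    else {
      double sse = 0;
      for (size_t i = 0; i < out[s].n_elem; ++i) {
        const double d = out[s][i] - by[s][i]; sse += d * d;
      }
      total += sse / out[s].n_elem;
    }
    dsum += hard_dice(out[s], by[s]);
  }
  for (auto& n : net->nodes) { n.out.clear(); n.grad.clear(); }
  return List::create(_["loss"] = total / N, _["dice"] = dsum / N);
}

// [[Rcpp::export]]
List nn_get_weights(SEXP netp) {
  XPtr<Net> net(netp);
  List out;
  CharacterVector names;
  for (auto& n : net->nodes)
    for (auto& p : n.layer->params) {
      NumericVector v(p.w.n_elem);
      for (size_t i = 0; i < p.w.n_elem; ++i) v[i] = p.w[i];
      out.push_back(v);
      names.push_back(p.name);
    }
  out.attr("names") = names;
  return out;
}

// [[Rcpp::export]]
void nn_set_weights(SEXP netp, List w) {
  XPtr<Net> net(netp);
  size_t k = 0;
  for (auto& n : net->nodes)
    for (auto& p : n.layer->params) {
      if (k >= (size_t)w.size()) stop("weight list too short");
      NumericVector v = w[k++];
      if ((size_t)v.size() != p.w.n_elem) stop("weight size mismatch at %s", p.name.c_str());
      for (size_t i = 0; i < p.w.n_elem; ++i) p.w[i] = (float)v[i];
    }
}

// [[Rcpp::export]]
void nn_reset_optimizer(SEXP netp) {
  XPtr<Net> net(netp);
  net->step = 0;
  for (auto& n : net->nodes)
    for (auto& p : n.layer->params) { p.m.zeros(); p.v.zeros(); }
}

// [[Rcpp::export]]
List nn_get_grads(SEXP netp) {
  XPtr<Net> net(netp);
  List out;
  CharacterVector names;
  for (auto& n : net->nodes)
    for (auto& p : n.layer->params) {
      NumericVector v(p.g.n_elem);
      for (size_t i = 0; i < p.g.n_elem; ++i) v[i] = p.g[i];
      out.push_back(v);
      names.push_back(p.name);
    }
  out.attr("names") = names;
  return out;
}
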