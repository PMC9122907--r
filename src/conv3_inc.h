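static void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb, float beta,
                  float* C, int ldc) {
  const arma::blas_int m_ = m, n_ = n, k_ = k, lda_ = lda, ldb_ = ldb, ldc_ = ldc;
  arma::blas::gemm<float>(&ta, &tb, &m_, &n_, &k_, &alpha, A, &lda_, B, &ldb_,
                          &beta, C, &ldc_);
}

// 3x3 same-padding convolution as 9 accumulated offset GEMMs on the
// flattened (H*W x C) pixel-major views, with per-tap border corrections.
// Weight layout: (9*Cin x Cout), rows ordered (dy*3+dx)*Cin + ci.
//
// For a tap (dy,dx) the source pixel of output p = r + c*H is
// p + off with off = (dy-1) + (dx-1)*H; cropping p to keep p+off in
// [0, HW) handles the column (dx) border exactly, while the row (dy)
// border wraps into the adjacent column for at most one row per column,
// which is corrected by a small gather/GEMM/scatter.

struct Tap { int off, pstart, plen; std::vector<int> fix; };

static void conv3_taps(int H, int W, std::vector<Tap>& taps) {
  const long HW = (long)H * W;
  taps.clear();
  for (int dy = 0; dy < 3; ++dy)
    for (int dx = 0; dx < 3; ++dx) {
      Tap t;
      t.off = (dy - 1) + (dx - 1) * H;
      t.pstart = std::max(0, -t.off);
      const long pend = HW - std::max(0, t.off);
      t.plen = (int)std::max(0L, pend - t.pstart);
      // outputs whose true source row is outside the image, but whose
      // flattened read wraps to an in-range pixel of the adjacent column:
      // those contributions must be subtracted again
      if (dy == 0) {            // source row -1 wraps to row H-1 of column sc-1
        for (int c = 0; c < W; ++c) {
          const int sc = c + dx - 1;
          if (sc >= 1 && sc <= W) {
            const int p = c * H;
            if (p >= t.pstart && p < t.pstart + t.plen) t.fix.push_back(p);
          }
        }
      } else if (dy == 2) {     // source row H wraps to row 0 of column sc+1
        for (int c = 0; c < W; ++c) {
          const int sc = c + dx - 1;
          if (sc >= -1 && sc <= W - 2) {
            const int p = (H - 1) + c * H;
            if (p >= t.pstart && p < t.pstart + t.plen) t.fix.push_back(p);
          }
        }
      }
      taps.push_back(t);
    }
}

// y (HW x Cout, zero-initialised) += conv3(x) with weights Wm (9*Cin x Cout)
static void conv3_forward(const float* x, int H, int W, int cin,
                          const float* Wm, int cout, float* y) {
  const int HW = H * W;
  std::vector<Tap> taps;
  conv3_taps(H, W, taps);
  arma::fmat gat, sub;
  for (int q = 0; q < 9; ++q) {
    const Tap& t = taps[q];
    if (t.plen <= 0) continue;
    const float* Wq = Wm + (size_t)q * cin;
    sgemm('N', 'N', t.plen, cout, cin, 1.0f, x + t.pstart + t.off, HW,
          Wq, 9 * cin, 1.0f, y + t.pstart, HW);
    const int nf = (int)t.fix.size();
    if (nf > 0) {
      gat.set_size(nf, cin);
      for (int ci = 0; ci < cin; ++ci)
        for (int i = 0; i < nf; ++i)
          gat(i, ci) = x[t.fix[i] + t.off + (size_t)ci * HW];
      sub.set_size(nf, cout);
      sgemm('N', 'N', nf, cout, cin, 1.0f, gat.memptr(), nf, Wq, 9 * cin,
            0.0f, sub.memptr(), nf);
      for (int co = 0; co < cout; ++co)
        for (int i = 0; i < nf; ++i)
          y[t.fix[i] + (size_t)co * HW] -= sub(i, co);
    }
  }
}

// dx (HW x Cin, zero-initialised) += conv3^T(dy); dW += x^T (x) dy
static void conv3_backward(const float* x, const float* dy, int H, int W,
                           int cin, int cout, const float* Wm, float* dWm,
                           float* dx) {
  const int HW = H * W;
  std::vector<Tap> taps;
  conv3_taps(H, W, taps);
  arma::fmat gat, sub, dyfix;
  for (int q = 0; q < 9; ++q) {
    const Tap& t = taps[q];
    if (t.plen <= 0) continue;
    const float* Wq = Wm + (size_t)q * cin;
    float* dWq = dWm + (size_t)q * cin;
    // dW_q += X[p+off]^T * dY[p]
    sgemm('T', 'N', cin, cout, t.plen, 1.0f, x + t.pstart + t.off, HW,
          dy + t.pstart, HW, 1.0f, dWq, 9 * cin);
    // dX[p+off] += dY[p] * W_q^T
    sgemm('N', 'T', t.plen, cin, cout, 1.0f, dy + t.pstart, HW,
          Wq, 9 * cin, 1.0f, dx + t.pstart + t.off, HW);
    const int nf = (int)t.fix.size();
    if (nf > 0) {
      gat.set_size(nf, cin);
      dyfix.set_size(nf, cout);
      for (int ci = 0; ci < cin; ++ci)
        for (int i = 0; i < nf; ++i)
          gat(i, ci) = x[t.fix[i] + t.off + (size_t)ci * HW];
      for (int co = 0; co < cout; ++co)
        for (int i = 0; i < nf; ++i)
          dyfix(i, co) = dy[t.fix[i] + (size_t)co * HW];
      // undo the wrapped contributions
      sgemm('T', 'N', cin, cout, nf, -1.0f, gat.memptr(), nf,
            dyfix.memptr(), nf, 1.0f, dWq, 9 * cin);
      sub.set_size(nf, cin);
      sgemm('N', 'T', nf, cin, cout, 1.0f, dyfix.memptr(), nf, Wq, 9 * cin,
            0.0f, sub.memptr(), nf);
      for (int ci = 0; ci < cin; ++ci)
        for (int i = 0; i < nf; ++i)
          dx[t.fix[i] + t.off + (size_t)ci * HW] -= sub(i, ci);
    }
  }
}

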