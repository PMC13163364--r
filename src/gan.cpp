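// Native implementation of the prior-conditioned 3D adversarial network:
// residual 3D U-Net generator, conditional 3D PatchGAN discriminator,
// BCE-with-logits + weighted L1 objectives, Adam, and the alternating
// training loop. Single-precision; convolutions are im2col + GEMM.
//
// Tensor convention: a volume with C channels on a (D, H, W) lattice is an
// arma::fmat of size (N x C), N = D*H*W, whose row v holds voxel
// v = z + D*(y + H*x) — matching R's array order for dim c(D, H, W) with
// axis order (z, y, x). Channels-last keeps stride-1 im2col down to one
// long memcpy per (offset, channel) plus boundary fix-ups, and gives the
// GEMMs a tall M dimension. All strided resampling acts on (H, W) only;
// the slice axis z is never downsampled.
#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
using Rcpp::List;
using Rcpp::NumericMatrix;
using Rcpp::NumericVector;
using Rcpp::IntegerVector;
using Rcpp::stop;

namespace {

struct Param {
  fmat w, g, m, v;
  void init(int r, int c) { w.zeros(r, c); g.zeros(r, c); m.zeros(r, c); v.zeros(r, c); }
};

// ---- im2col / col2im for 3x3x3 kernels, padding 1 ----
// Offsets are ordered k = ((kx+1)*3 + (ky+1))*3 + (kz+1); P column k*Cin + c
// holds channel c sampled at offset (kz, ky, kx).

// stride 1: per (offset, channel) one shifted memcpy, then zero the rows
// whose source voxel falls outside the volume on the z, y or x axis.
// Writes into a caller-owned buffer so repeated passes reuse warm memory.
void im2col_s1(const fmat& X, int D, int H, int W, fmat& P) {
  const int Cin = X.n_cols;
  const size_t N = X.n_rows;
  P.set_size(N, (size_t)27 * Cin);
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz) {
        const int k = ((kx + 1) * 3 + (ky + 1)) * 3 + (kz + 1);
        const ptrdiff_t delta = kz + (ptrdiff_t)D * (ky + (ptrdiff_t)H * kx);
        const size_t lo = delta < 0 ? (size_t)(-delta) : 0;
        const size_t hi = delta > 0 ? N - (size_t)delta : N;
        for (int c = 0; c < Cin; ++c) {
          float* dst = P.colptr((size_t)k * Cin + c);
          const float* src = X.colptr(c);
          if (lo) std::memset(dst, 0, lo * sizeof(float));
          if (hi < N) std::memset(dst + hi, 0, (N - hi) * sizeof(float));
          std::memcpy(dst + lo, src + lo + delta, (hi - lo) * sizeof(float));
          if (kz == 1) { for (size_t p = D - 1; p < N; p += D) dst[p] = 0.0f; }
          else if (kz == -1) { for (size_t p = 0; p < N; p += D) dst[p] = 0.0f; }
          if (ky == 1) {
            for (int x = 0; x < W; ++x)
              std::memset(dst + (size_t)D * (H - 1 + (size_t)H * x), 0, D * sizeof(float));
          } else if (ky == -1) {
            for (int x = 0; x < W; ++x)
              std::memset(dst + (size_t)D * ((size_t)H * x), 0, D * sizeof(float));
          }
          if (kx == 1) std::memset(dst + (size_t)D * H * (W - 1), 0, (size_t)D * H * sizeof(float));
          else if (kx == -1) std::memset(dst, 0, (size_t)D * H * sizeof(float));
        }
      }
}

// adjoint of im2col_s1; dP is scratch (its invalid rows are zeroed in place)
fmat col2im_s1(fmat& dP, int Cin, int D, int H, int W) {
  const size_t N = (size_t)D * H * W;
  fmat dX(N, Cin, fill::zeros);
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz) {
        const int k = ((kx + 1) * 3 + (ky + 1)) * 3 + (kz + 1);
        const ptrdiff_t delta = kz + (ptrdiff_t)D * (ky + (ptrdiff_t)H * kx);
        const size_t lo = delta < 0 ? (size_t)(-delta) : 0;
        const size_t hi = delta > 0 ? N - (size_t)delta : N;
        for (int c = 0; c < Cin; ++c) {
          float* dp = dP.colptr((size_t)k * Cin + c);
          if (kz == 1) { for (size_t p = D - 1; p < N; p += D) dp[p] = 0.0f; }
          else if (kz == -1) { for (size_t p = 0; p < N; p += D) dp[p] = 0.0f; }
          if (ky == 1) {
            for (int x = 0; x < W; ++x)
              std::memset(dp + (size_t)D * (H - 1 + (size_t)H * x), 0, D * sizeof(float));
          } else if (ky == -1) {
            for (int x = 0; x < W; ++x)
              std::memset(dp + (size_t)D * ((size_t)H * x), 0, D * sizeof(float));
          }
          if (kx == 1) std::memset(dp + (size_t)D * H * (W - 1), 0, (size_t)D * H * sizeof(float));
          else if (kx == -1) std::memset(dp, 0, (size_t)D * H * sizeof(float));
          float* dx = dX.colptr(c);
          const float* s = dp + lo;
          float* d = dx + lo + delta;
          const size_t n = hi - lo;
          for (size_t i = 0; i < n; ++i) d[i] += s[i];
        }
      }
  return dX;
}

// stride (1, 2, 2): gather/scatter contiguous z-runs per in-plane position
void im2col_st(const fmat& X, int D, int H, int W, int Ho, int Wo, fmat& P) {
  const int Cin = X.n_cols;
  const size_t No = (size_t)D * Ho * Wo;
  P.zeros(No, (size_t)27 * Cin);
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz) {
        const int k = ((kx + 1) * 3 + (ky + 1)) * 3 + (kz + 1);
        const int z0 = std::max(0, -kz), z1 = std::min(D, D - kz);
        if (z1 <= z0) continue;
        for (int c = 0; c < Cin; ++c) {
          float* dst = P.colptr((size_t)k * Cin + c);
          const float* src = X.colptr(c);
          for (int xo = 0; xo < Wo; ++xo) {
            const int ix = 2 * xo + kx;
            if (ix < 0 || ix >= W) continue;
            for (int yo = 0; yo < Ho; ++yo) {
              const int iy = 2 * yo + ky;
              if (iy < 0 || iy >= H) continue;
              std::memcpy(dst + z0 + (size_t)D * (yo + (size_t)Ho * xo),
                          src + z0 + kz + (size_t)D * (iy + (size_t)H * ix),
                          (z1 - z0) * sizeof(float));
            }
          }
        }
      }
}

fmat col2im_st(const fmat& dP, int Cin, int D, int H, int W, int Ho, int Wo) {
  fmat dX((size_t)D * H * W, Cin, fill::zeros);
  for (int kx = -1; kx <= 1; ++kx)
    for (int ky = -1; ky <= 1; ++ky)
      for (int kz = -1; kz <= 1; ++kz) {
        const int k = ((kx + 1) * 3 + (ky + 1)) * 3 + (kz + 1);
        const int z0 = std::max(0, -kz), z1 = std::min(D, D - kz);
        if (z1 <= z0) continue;
        for (int c = 0; c < Cin; ++c) {
          const float* dp = dP.colptr((size_t)k * Cin + c);
          float* dx = dX.colptr(c);
          for (int xo = 0; xo < Wo; ++xo) {
            const int ix = 2 * xo + kx;
            if (ix < 0 || ix >= W) continue;
            for (int yo = 0; yo < Ho; ++yo) {
              const int iy = 2 * yo + ky;
              if (iy < 0 || iy >= H) continue;
              const float* s = dp + z0 + (size_t)D * (yo + (size_t)Ho * xo);
              float* d = dx + z0 + kz + (size_t)D * (iy + (size_t)H * ix);
              for (int z = 0; z < z1 - z0; ++z) d[z] += s[z];
            }
          }
        }
      }
  return dX;
}

// C(MxN) = A(MxK) * B(KxN) for small K (inner dimension a handful of
// channels), where the BLAS GEMM underperforms: i-tiled axpy accumulation.
void gemm_smallk(const fmat& A, const fmat& B, fmat& C) {
  const uword M = A.n_rows, K = A.n_cols, N = B.n_cols;
  C.set_size(M, N);
  const uword TILE = 1024;
  for (uword i0 = 0; i0 < M; i0 += TILE) {
    const uword len = std::min(TILE, M - i0);
    for (uword n = 0; n < N; ++n) {
      float* c = C.colptr(n) + i0;
      const float* a0 = A.colptr(0) + i0;
      const float b0 = B(0, n);
      for (uword i = 0; i < len; ++i) c[i] = a0[i] * b0;
      for (uword k = 1; k < K; ++k) {
        const float* a = A.colptr(k) + i0;
        const float bkn = B(k, n);
        for (uword i = 0; i < len; ++i) c[i] += a[i] * bkn;
      }
    }
  }
}

// ---- layers ----

struct Conv {
  int Cin = 0, Cout = 0, k = 3, stride = 1;  // stride applies to (H, W)
  Param W, b;  // W: (k^3*Cin x Cout), b: (1 x Cout)
  int Di = 0, Hi = 0, Wi = 0, Ho = 0, Wo = 0;
  fmat Xc;          // input cache, 1x1x1 convolutions only
  fmat Pbuf, dPbuf; // persistent im2col buffers; Pbuf doubles as the
                    // backward cache (backward always directly follows the
                    // forward pass of the same sample)

  void init(int cin, int cout, int kk, int s, std::mt19937& rng) {
    Cin = cin; Cout = cout; k = kk; stride = s;
    const int fan = kk * kk * kk * cin;
    W.init(fan, cout);
    const float sd = std::sqrt(2.0f / (float)fan);
    std::normal_distribution<float> nd(0.0f, sd);
    for (uword i = 0; i < W.w.n_elem; ++i) W.w[i] = nd(rng);
    b.init(1, cout);
  }

  fmat forward(const fmat& X, int D, int H, int Wd, bool cache) {
    Di = D; Hi = H; Wi = Wd; Ho = H / stride; Wo = Wd / stride;
    fmat Y;
    if (k == 1) {
      if (cache) Xc = X;
      Y = X * W.w;
    } else {
      if (stride == 1) im2col_s1(X, D, H, Wd, Pbuf);
      else im2col_st(X, D, H, Wd, Ho, Wo, Pbuf);
      Y = Pbuf * W.w;
    }
    Y.each_row() += b.w.row(0);
    return Y;
  }

  // need_dx: the input gradient is wanted (false for the first layer);
  // accum: accumulate weight gradients (false when backpropagating through
  // a frozen network, e.g. the discriminator during the generator step)
  fmat backward(const fmat& dY, bool need_dx = true, bool accum = true) {
    if (accum) b.g += sum(dY, 0);
    if (k == 1) {
      if (accum) W.g += Xc.t() * dY;
      if (!need_dx) return fmat();
      return dY * W.w.t();
    }
    if (accum) W.g += Pbuf.t() * dY;
    if (!need_dx) return fmat();
    if (Cout <= 16) gemm_smallk(dY, fmat(W.w.t()), dPbuf);
    else dPbuf = dY * W.w.t();
    if (stride == 1) return col2im_s1(dPbuf, Cin, Di, Hi, Wi);
    return col2im_st(dPbuf, Cin, Di, Hi, Wi, Ho, Wo);
  }

  void params(std::vector<Param*>& v) { v.push_back(&W); v.push_back(&b); }
};

struct BNorm {
  Param g, b;  // (1 x C)
  frowvec rmean, rvar;
  fmat xh;
  frowvec istd;
  static constexpr float mom = 0.1f, eps = 1e-5f;

  void init(int C) {
    g.init(1, C); g.w.ones();
    b.init(1, C);
    rmean.zeros(C); rvar.ones(C);
  }

  fmat forward(const fmat& X, bool train) {
    if (train) {
      const frowvec mu = mean(X, 0);
      const frowvec va = var(X, 1, 0);  // 1/N normalisation
      istd = 1.0f / sqrt(va + eps);
      xh = X;
      xh.each_row() -= mu;
      xh.each_row() %= istd;
      rmean = (1.0f - mom) * rmean + mom * mu;
      rvar = (1.0f - mom) * rvar + mom * va;
      fmat Y = xh;
      Y.each_row() %= g.w.row(0);
      Y.each_row() += b.w.row(0);
      return Y;
    }
    const frowvec is = 1.0f / sqrt(rvar + eps);
    fmat Y = X;
    Y.each_row() -= rmean;
    Y.each_row() %= (is % g.w.row(0));
    Y.each_row() += b.w.row(0);
    return Y;
  }

  fmat backward(const fmat& dY) {
    const float N = (float)dY.n_rows;
    const frowvec dg = sum(dY % xh, 0);
    const frowvec db = sum(dY, 0);
    g.g += dg;
    b.g += db;
    fmat dX = N * dY;
    dX.each_row() -= db;
    fmat t = xh;
    t.each_row() %= dg;
    dX -= t;
    dX.each_row() %= (g.w.row(0) % istd) / N;
    return dX;
  }

  void params(std::vector<Param*>& v) { v.push_back(&g); v.push_back(&b); }
};

struct ReluL {
  fmat yc;
  fmat forward(const fmat& X, bool cache) {
    fmat Y = X;
    Y.for_each([](float& e) { if (e < 0.0f) e = 0.0f; });
    if (cache) yc = Y;
    return Y;
  }
  fmat backward(const fmat& dY) {
    fmat dX = dY;
    const float* y = yc.memptr();
    float* d = dX.memptr();
    for (uword i = 0; i < dX.n_elem; ++i)
      if (y[i] <= 0.0f) d[i] = 0.0f;
    return dX;
  }
};

// Trilinear x(1,2,2) upsampling (align_corners = false convention); only the
// in-plane axes are interpolated, the slice axis passes through.
struct Upsample {
  int Di = 0, Hi = 0, Wi = 0;
  fmat forward(const fmat& X, int D, int H, int W) {
    Di = D; Hi = H; Wi = W;
    const int Ho = 2 * H, Wo = 2 * W;
    fmat Y((size_t)D * Ho * Wo, X.n_cols);
    for (int xo = 0; xo < Wo; ++xo) {
      const float fx = 0.5f * (xo + 0.5f) - 0.5f;
      const int x0 = (int)std::floor(fx);
      const float wx = fx - x0;
      const int xa = std::min(std::max(x0, 0), W - 1);
      const int xb = std::min(std::max(x0 + 1, 0), W - 1);
      for (int yo = 0; yo < Ho; ++yo) {
        const float fy = 0.5f * (yo + 0.5f) - 0.5f;
        const int y0 = (int)std::floor(fy);
        const float wy = fy - y0;
        const int ya = std::min(std::max(y0, 0), H - 1);
        const int yb = std::min(std::max(y0 + 1, 0), H - 1);
        const size_t o = (size_t)D * (yo + (size_t)Ho * xo);
        const size_t aa = (size_t)D * (ya + (size_t)H * xa);
        const size_t ba = (size_t)D * (yb + (size_t)H * xa);
        const size_t ab = (size_t)D * (ya + (size_t)H * xb);
        const size_t bb = (size_t)D * (yb + (size_t)H * xb);
        Y.rows(o, o + D - 1) =
          (1 - wy) * (1 - wx) * X.rows(aa, aa + D - 1) +
          wy * (1 - wx) * X.rows(ba, ba + D - 1) +
          (1 - wy) * wx * X.rows(ab, ab + D - 1) +
          wy * wx * X.rows(bb, bb + D - 1);
      }
    }
    return Y;
  }
  fmat backward(const fmat& dY) {
    const int D = Di, H = Hi, W = Wi;
    const int Ho = 2 * H, Wo = 2 * W;
    fmat dX((size_t)D * H * W, dY.n_cols, fill::zeros);
    for (int xo = 0; xo < Wo; ++xo) {
      const float fx = 0.5f * (xo + 0.5f) - 0.5f;
      const int x0 = (int)std::floor(fx);
      const float wx = fx - x0;
      const int xa = std::min(std::max(x0, 0), W - 1);
      const int xb = std::min(std::max(x0 + 1, 0), W - 1);
      for (int yo = 0; yo < Ho; ++yo) {
        const float fy = 0.5f * (yo + 0.5f) - 0.5f;
        const int y0 = (int)std::floor(fy);
        const float wy = fy - y0;
        const int ya = std::min(std::max(y0, 0), H - 1);
        const int yb = std::min(std::max(y0 + 1, 0), H - 1);
        const size_t o = (size_t)D * (yo + (size_t)Ho * xo);
        const size_t aa = (size_t)D * (ya + (size_t)H * xa);
        const size_t ba = (size_t)D * (yb + (size_t)H * xa);
        const size_t ab = (size_t)D * (ya + (size_t)H * xb);
        const size_t bb = (size_t)D * (yb + (size_t)H * xb);
        const fmat d = dY.rows(o, o + D - 1);
        dX.rows(aa, aa + D - 1) += (1 - wy) * (1 - wx) * d;
        dX.rows(ba, ba + D - 1) += wy * (1 - wx) * d;
        dX.rows(ab, ab + D - 1) += (1 - wy) * wx * d;
        dX.rows(bb, bb + D - 1) += wy * wx * d;
      }
    }
    return dX;
  }
};

// Two conv-norm-ReLU units with an identity shortcut.
struct ResBlock {
  Conv c1, c2;
  BNorm n1, n2;
  ReluL r1, r2;
  void init(int ch, std::mt19937& rng) {
    c1.init(ch, ch, 3, 1, rng);
    c2.init(ch, ch, 3, 1, rng);
    n1.init(ch);
    n2.init(ch);
  }
  fmat forward(const fmat& X, int D, int H, int W, bool train) {
    fmat h = r1.forward(n1.forward(c1.forward(X, D, H, W, train), train), train);
    h = n2.forward(c2.forward(h, D, H, W, train), train);
    h += X;
    return r2.forward(h, train);
  }
  fmat backward(const fmat& dY) {
    fmat d = r2.backward(dY);
    fmat dX = d;  // identity branch
    fmat dh = c2.backward(n2.backward(d));
    dh = r1.backward(dh);
    dX += c1.backward(n1.backward(dh));
    return dX;
  }
  void params(std::vector<Param*>& v) {
    c1.params(v); n1.params(v); c2.params(v); n2.params(v);
  }
  void bns(std::vector<BNorm*>& v) { v.push_back(&n1); v.push_back(&n2); }
};

// ---- generator: residual 3D U-Net ----
// Encoder: stem conv + residual block per level, strided 3x3x3 downsampling
// between levels. Decoder: trilinear upsampling, skip concatenation, a
// 1x1x1 channel-mixing projection, then a residual decoding block (which
// carries the spatial 3x3x3 filtering).

struct Generator {
  int levels = 4, in_ch = 3;
  std::vector<int> ch;
  Conv stem; BNorm stem_bn; ReluL stem_r;
  std::vector<ResBlock> enc;
  std::vector<Conv> down; std::vector<BNorm> down_bn; std::vector<ReluL> down_r;
  std::vector<Upsample> up; std::vector<Conv> fuse; std::vector<BNorm> fuse_bn;
  std::vector<ReluL> fuse_r; std::vector<ResBlock> dec;
  Conv head;
  std::vector<fmat> skip;
  int D0 = 0, H0 = 0, W0 = 0;

  void build(int inch, int base, int maxc, int nlev, std::mt19937& rng) {
    in_ch = inch; levels = nlev;
    ch.resize(nlev);
    for (int l = 0; l < nlev; ++l) ch[l] = std::min(base << l, maxc);
    stem.init(inch, ch[0], 3, 1, rng);
    stem_bn.init(ch[0]);
    enc.resize(nlev);
    for (int l = 0; l < nlev; ++l) enc[l].init(ch[l], rng);
    down.resize(nlev); down_bn.resize(nlev); down_r.resize(nlev);
    for (int l = 1; l < nlev; ++l) {
      down[l].init(ch[l - 1], ch[l], 3, 2, rng);
      down_bn[l].init(ch[l]);
    }
    up.resize(nlev); fuse.resize(nlev); fuse_bn.resize(nlev); fuse_r.resize(nlev);
    dec.resize(nlev);
    for (int l = 1; l < nlev; ++l) {
      fuse[l].init(ch[l] + ch[l - 1], ch[l - 1], 1, 1, rng);
      fuse_bn[l].init(ch[l - 1]);
      dec[l].init(ch[l - 1], rng);
    }
    head.init(ch[0], 1, 1, 1, rng);
  }

  fmat forward(const fmat& X, int D, int H, int W, bool train) {
    D0 = D; H0 = H; W0 = W;
    skip.assign(levels, fmat());
    fmat h = stem_r.forward(stem_bn.forward(stem.forward(X, D, H, W, train), train), train);
    h = enc[0].forward(h, D, H, W, train);
    skip[0] = h;  // skips are consumed by the decoder in both modes
    int Hl = H, Wl = W;
    for (int l = 1; l < levels; ++l) {
      h = down_r[l].forward(down_bn[l].forward(down[l].forward(h, D, Hl, Wl, train), train), train);
      Hl /= 2; Wl /= 2;
      h = enc[l].forward(h, D, Hl, Wl, train);
      if (l < levels - 1) skip[l] = h;
    }
    for (int l = levels - 1; l >= 1; --l) {
      h = up[l].forward(h, D, Hl, Wl);
      Hl *= 2; Wl *= 2;
      h = join_rows(h, skip[l - 1]);
      h = fuse_r[l].forward(fuse_bn[l].forward(fuse[l].forward(h, D, Hl, Wl, train), train), train);
      h = dec[l].forward(h, D, Hl, Wl, train);
    }
    return head.forward(h, D, H, W, train);
  }

  fmat backward(const fmat& dY) {
    fmat dh = head.backward(dY);
    std::vector<fmat> dskip(levels);
    for (int l = 1; l < levels; ++l) {
      dh = dec[l].backward(dh);
      fmat dcat = fuse[l].backward(fuse_bn[l].backward(fuse_r[l].backward(dh)));
      dskip[l - 1] = dcat.cols(ch[l], dcat.n_cols - 1);
      fmat du = dcat.cols(0, ch[l] - 1);
      dh = up[l].backward(du);
    }
    for (int l = levels - 1; l >= 1; --l) {
      dh = enc[l].backward(dh);
      dh = down[l].backward(down_bn[l].backward(down_r[l].backward(dh)));
      dh += dskip[l - 1];
    }
    dh = enc[0].backward(dh);
    // the input gradient is never consumed
    return stem.backward(stem_bn.backward(stem_r.backward(dh)), false);
  }

  void params(std::vector<Param*>& v) {
    stem.params(v); stem_bn.params(v);
    for (int l = 0; l < levels; ++l) enc[l].params(v);
    for (int l = 1; l < levels; ++l) { down[l].params(v); down_bn[l].params(v); }
    for (int l = 1; l < levels; ++l) { fuse[l].params(v); fuse_bn[l].params(v); dec[l].params(v); }
    head.params(v);
  }
  void bns(std::vector<BNorm*>& v) {
    v.push_back(&stem_bn);
    for (int l = 0; l < levels; ++l) enc[l].bns(v);
    for (int l = 1; l < levels; ++l) v.push_back(&down_bn[l]);
    for (int l = 1; l < levels; ++l) { v.push_back(&fuse_bn[l]); dec[l].bns(v); }
  }
};

// ---- discriminator: conditional 3D PatchGAN ----

struct Discriminator {
  int in_ch = 4, blocks = 3;
  std::vector<int> ch;
  std::vector<Conv> conv;
  std::vector<BNorm> bn;
  std::vector<ReluL> rl;
  Conv fin;

  void build(int inch, int base, int maxc, int nblocks, std::mt19937& rng) {
    in_ch = inch; blocks = nblocks;
    ch.resize(nblocks);
    for (int b = 0; b < nblocks; ++b) ch[b] = std::min(base << b, maxc);
    conv.resize(nblocks); bn.resize(nblocks); rl.resize(nblocks);
    int c = inch;
    for (int b = 0; b < nblocks; ++b) {
      conv[b].init(c, ch[b], 3, 2, rng);
      bn[b].init(ch[b]);
      c = ch[b];
    }
    fin.init(c, 1, 3, 1, rng);
  }

  fmat forward(const fmat& X, int D, int H, int W, bool train) {
    fmat h = X;
    int Hl = H, Wl = W;
    for (int b = 0; b < blocks; ++b) {
      h = rl[b].forward(bn[b].forward(conv[b].forward(h, D, Hl, Wl, train), train), train);
      Hl /= 2; Wl /= 2;
    }
    return fin.forward(h, D, Hl, Wl, train);
  }

  fmat backward(const fmat& dY, bool accum = true) {
    fmat dh = fin.backward(dY, true, accum);
    for (int b = blocks - 1; b >= 0; --b)
      dh = conv[b].backward(bn[b].backward(rl[b].backward(dh)), true, accum);
    return dh;
  }

  void params(std::vector<Param*>& v) {
    for (int b = 0; b < blocks; ++b) { conv[b].params(v); bn[b].params(v); }
    fin.params(v);
  }
  void bns(std::vector<BNorm*>& v) {
    for (int b = 0; b < blocks; ++b) v.push_back(&bn[b]);
  }
};

// ---- losses / optimiser ----

double bce_logits(const fmat& Z, float target, fmat& dZ) {
  // numerically stable mean BCE with logits; dZ = (sigmoid(z) - t) / N
  const float N = (float)Z.n_elem;
  double L = 0.0;
  dZ.set_size(Z.n_rows, Z.n_cols);
  const float* z = Z.memptr();
  float* d = dZ.memptr();
  for (uword i = 0; i < Z.n_elem; ++i) {
    const float zi = z[i];
    L += std::max(zi, 0.0f) - zi * target + std::log1p(std::exp(-std::fabs(zi)));
    d[i] = (1.0f / (1.0f + std::exp(-zi)) - target) / N;
  }
  return L / N;
}

void adam_step(std::vector<Param*>& ps, double lr, double b1, double b2,
               double eps, int t) {
  const float bc1 = (float)(1.0 - std::pow(b1, t));
  const float bc2 = (float)(1.0 - std::pow(b2, t));
  for (Param* p : ps) {
    p->m = (float)b1 * p->m + (float)(1.0 - b1) * p->g;
    p->v = (float)b2 * p->v + (float)(1.0 - b2) * square(p->g);
    p->w -= (float)lr * (p->m / bc1) / (sqrt(p->v / bc2) + (float)eps);
  }
}

void zero_grads(std::vector<Param*>& ps) {
  for (Param* p : ps) p->g.zeros();
}

// ---- weight (de)serialisation ----

List export_net(std::vector<Param*>& ps, std::vector<BNorm*>& bs) {
  List w(ps.size()), rs(bs.size());
  for (size_t i = 0; i < ps.size(); ++i) {
    w[i] = NumericMatrix(ps[i]->w.n_rows, ps[i]->w.n_cols,
                         conv_to<mat>::from(ps[i]->w).memptr());
  }
  for (size_t i = 0; i < bs.size(); ++i) {
    mat m(2, bs[i]->rmean.n_elem);
    m.row(0) = conv_to<rowvec>::from(bs[i]->rmean);
    m.row(1) = conv_to<rowvec>::from(bs[i]->rvar);
    rs[i] = NumericMatrix(m.n_rows, m.n_cols, m.memptr());
  }
  return List::create(Rcpp::_["w"] = w, Rcpp::_["bn"] = rs);
}

void import_net(const List& net, std::vector<Param*>& ps, std::vector<BNorm*>& bs) {
  List w = net["w"], rs = net["bn"];
  if ((size_t)w.size() != ps.size() || (size_t)rs.size() != bs.size())
    stop("weight list does not match the network configuration");
  for (size_t i = 0; i < ps.size(); ++i) {
    NumericMatrix m = w[i];
    if ((uword)m.nrow() != ps[i]->w.n_rows || (uword)m.ncol() != ps[i]->w.n_cols)
      stop("weight matrix %d has the wrong shape", (int)i + 1);
    ps[i]->w = conv_to<fmat>::from(Rcpp::as<mat>(m));
  }
  for (size_t i = 0; i < bs.size(); ++i) {
    NumericMatrix m = rs[i];
    for (int j = 0; j < m.ncol(); ++j) {
      bs[i]->rmean[j] = (float)m(0, j);
      bs[i]->rvar[j] = (float)m(1, j);
    }
  }
}

struct GanConfig {
  int in_ch, base, max_ch, levels, d_base, d_max_ch, d_blocks;
  double lr, beta1, beta2, eps, lambda_rec;
  int epochs;
};

GanConfig read_cfg(const List& cfg) {
  GanConfig c;
  c.in_ch = cfg["in_ch"]; c.base = cfg["base"]; c.max_ch = cfg["max_ch"];
  c.levels = cfg["levels"]; c.d_base = cfg["d_base"]; c.d_max_ch = cfg["d_max_ch"];
  c.d_blocks = cfg["d_blocks"]; c.lr = cfg["lr"]; c.beta1 = cfg["beta1"];
  c.beta2 = cfg["beta2"]; c.eps = cfg["eps"]; c.lambda_rec = cfg["lambda_rec"];
  c.epochs = cfg["epochs"];
  return c;
}

// R sends condition volumes as (N x C) matrices, masks as length-N vectors
fmat as_fmat(const NumericMatrix& m) {
  return conv_to<fmat>::from(Rcpp::as<mat>(m));
}

fmat sigmoid_of(const fmat& Z) {
  fmat S = Z;
  S.for_each([](float& e) { e = 1.0f / (1.0f + std::exp(-e)); });
  return S;
}

double dice_of(const fmat& s, const fmat& y) {
  // threshold at 0.5 (>= goes to foreground)
  double inter = 0, np = 0, nr = 0;
  const float* a = s.memptr();
  const float* b = y.memptr();
  for (uword i = 0; i < s.n_elem; ++i) {
    const bool p = a[i] >= 0.5f, r = b[i] >= 0.5f;
    inter += (p && r); np += p; nr += r;
  }
  if (np + nr == 0) return 1.0;
  return 2.0 * inter / (np + nr);
}

}  // namespace

// Initialise generator + discriminator weights for a given configuration.
// [[Rcpp::export]]
List cpp_gan_init(List cfg, int seed) {
  GanConfig c = read_cfg(cfg);
  std::mt19937 rng((uint32_t)seed);
  Generator G;
  G.build(c.in_ch, c.base, c.max_ch, c.levels, rng);
  Discriminator D;
  D.build(c.in_ch + 1, c.d_base, c.d_max_ch, c.d_blocks, rng);
  std::vector<Param*> gp, dp;
  std::vector<BNorm*> gb, db;
  G.params(gp); G.bns(gb); D.params(dp); D.bns(db);
  return List::create(Rcpp::_["gen"] = export_net(gp, gb),
                      Rcpp::_["disc"] = export_net(dp, db));
}

// Generator forward pass (eval mode); returns the logit volume.
// [[Rcpp::export]]
NumericVector cpp_gen_forward(List weights, List cfg, NumericMatrix cond,
                              IntegerVector dims) {
  GanConfig c = read_cfg(cfg);
  std::mt19937 rng(1u);
  Generator G;
  G.build(c.in_ch, c.base, c.max_ch, c.levels, rng);
  std::vector<Param*> gp; std::vector<BNorm*> gb;
  G.params(gp); G.bns(gb);
  import_net(weights["gen"], gp, gb);
  fmat X = as_fmat(cond);
  fmat Y = G.forward(X, dims[0], dims[1], dims[2], false);
  NumericVector out(Y.n_elem);
  for (uword i = 0; i < Y.n_elem; ++i) out[i] = Y[i];
  out.attr("dim") = dims;
  return out;
}

// Discriminator forward pass on (mask, condition) concatenation.
// [[Rcpp::export]]
List cpp_disc_forward(List weights, List cfg, NumericVector mask,
                      NumericMatrix cond, IntegerVector dims) {
  GanConfig c = read_cfg(cfg);
  std::mt19937 rng(1u);
  Discriminator D;
  D.build(c.in_ch + 1, c.d_base, c.d_max_ch, c.d_blocks, rng);
  std::vector<Param*> dp; std::vector<BNorm*> db;
  D.params(dp); D.bns(db);
  import_net(weights["disc"], dp, db);
  fmat X = join_rows(conv_to<fmat>::from(Rcpp::as<vec>(mask)), as_fmat(cond));
  fmat Y = D.forward(X, dims[0], dims[1], dims[2], false);
  const int f = 1 << c.d_blocks;
  IntegerVector odims = IntegerVector::create(dims[0], dims[1] / f, dims[2] / f);
  NumericVector out(Y.n_elem);
  for (uword i = 0; i < Y.n_elem; ++i) out[i] = Y[i];
  out.attr("dim") = odims;
  return List::create(Rcpp::_["logits"] = out, Rcpp::_["dims"] = odims);
}

// Alternating adversarial training (batch size 1, one D step then one G step
// per sample). Returns final weights, the best-validation-Dice generator
// snapshot, and the per-epoch history.
// [[Rcpp::export]]
List cpp_gan_train(List cfg, List conds, List masks, IntegerVector dims,
                   int seed, List val_conds, List val_masks) {
  GanConfig c = read_cfg(cfg);
  const int D = dims[0], H = dims[1], W = dims[2];
  const int ntr = conds.size(), nval = val_conds.size();
  if (ntr < 1) stop("at least one training pair is required");

  std::vector<fmat> Xs(ntr), Ys(ntr);
  for (int i = 0; i < ntr; ++i) {
    Xs[i] = as_fmat(conds[i]);
    NumericVector m = masks[i];
    Ys[i] = conv_to<fmat>::from(Rcpp::as<vec>(m));
  }
  std::vector<fmat> Xv(nval), Yv(nval);
  for (int i = 0; i < nval; ++i) {
    Xv[i] = as_fmat(val_conds[i]);
    NumericVector m = val_masks[i];
    Yv[i] = conv_to<fmat>::from(Rcpp::as<vec>(m));
  }

  std::mt19937 rng((uint32_t)seed);
  Generator G;
  G.build(c.in_ch, c.base, c.max_ch, c.levels, rng);
  Discriminator Dn;
  Dn.build(c.in_ch + 1, c.d_base, c.d_max_ch, c.d_blocks, rng);
  std::vector<Param*> gp, dp;
  std::vector<BNorm*> gb, db;
  G.params(gp); G.bns(gb); Dn.params(dp); Dn.bns(db);

  mat hist(c.epochs, 5);
  hist.fill(datum::nan);
  int tg = 0, td = 0;
  double best_val = -1.0;
  int best_epoch = 0;
  std::vector<fmat> best_w;
  std::vector<frowvec> best_rm, best_rv;
  auto snapshot = [&]() {
    best_w.clear(); best_rm.clear(); best_rv.clear();
    for (Param* p : gp) best_w.push_back(p->w);
    for (BNorm* b : gb) { best_rm.push_back(b->rmean); best_rv.push_back(b->rvar); }
  };

  std::vector<int> order(ntr);
  for (int i = 0; i < ntr; ++i) order[i] = i;

  for (int ep = 0; ep < c.epochs; ++ep) {
    Rcpp::checkUserInterrupt();
    std::shuffle(order.begin(), order.end(), rng);
    double sd_loss = 0, sadv = 0, sl1 = 0;
    for (int ii = 0; ii < ntr; ++ii) {
      const int i = order[ii];
      const fmat& X = Xs[i];
      const fmat& y = Ys[i];

      // generator forward (training mode; caches reused for the G step)
      fmat logit = G.forward(X, D, H, W, true);
      fmat s = sigmoid_of(logit);

      // --- D step (fake detached) ---
      zero_grads(dp);
      fmat dz;
      fmat zr = Dn.forward(join_rows(y, X), D, H, W, true);
      double l_real = bce_logits(zr, 1.0f, dz);
      Dn.backward(0.5f * dz);
      fmat zf = Dn.forward(join_rows(s, X), D, H, W, true);
      double l_fake = bce_logits(zf, 0.0f, dz);
      Dn.backward(0.5f * dz);
      adam_step(dp, c.lr, c.beta1, c.beta2, c.eps, ++td);
      const double loss_d = 0.5 * (l_real + l_fake);

      // --- G step ---
      zero_grads(gp);
      fmat zf2 = Dn.forward(join_rows(s, X), D, H, W, true);
      double l_adv = bce_logits(zf2, 1.0f, dz);
      fmat dIn = Dn.backward(dz, false);  // D frozen during the G step
      fmat diff = s - y;
      const double l1 = accu(abs(diff)) / (double)diff.n_elem;
      fmat ds = dIn.col(0) +
        (float)(c.lambda_rec / (double)diff.n_elem) * sign(diff);
      fmat dlogit = ds % s % (1.0f - s);
      G.backward(dlogit);
      adam_step(gp, c.lr, c.beta1, c.beta2, c.eps, ++tg);

      if (!std::isfinite(loss_d) || !std::isfinite(l_adv) || !std::isfinite(l1))
        stop("non-finite loss at epoch %d, sample %d", ep + 1, i + 1);
      sd_loss += loss_d; sadv += l_adv; sl1 += l1;
    }
    hist(ep, 0) = ep + 1;
    hist(ep, 1) = sd_loss / ntr;
    hist(ep, 2) = sadv / ntr;
    hist(ep, 3) = sl1 / ntr;
    if (nval > 0) {
      double vd = 0;
      for (int i = 0; i < nval; ++i) {
        fmat lg = G.forward(Xv[i], D, H, W, false);
        vd += dice_of(sigmoid_of(lg), Yv[i]);
      }
      vd /= nval;
      hist(ep, 4) = vd;
      if (vd > best_val) { best_val = vd; best_epoch = ep + 1; snapshot(); }
    }
  }
  if (nval == 0) { best_epoch = c.epochs; snapshot(); }

  List final_w = List::create(Rcpp::_["gen"] = export_net(gp, gb),
                              Rcpp::_["disc"] = export_net(dp, db));
  // restore the best snapshot into G and export it
  {
    size_t k = 0;
    for (Param* p : gp) p->w = best_w[k++];
    k = 0;
    for (BNorm* b : gb) { b->rmean = best_rm[k]; b->rvar = best_rv[k]; ++k; }
  }
  List best = List::create(Rcpp::_["gen"] = export_net(gp, gb),
                           Rcpp::_["disc"] = final_w["disc"]);
  return List::create(Rcpp::_["weights"] = best,
                      Rcpp::_["final_weights"] = final_w,
                      Rcpp::_["history"] = NumericMatrix(hist.n_rows, hist.n_cols, hist.memptr()),
                      Rcpp::_["best_epoch"] = best_epoch,
                      Rcpp::_["best_val_dice"] = best_val);
}
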