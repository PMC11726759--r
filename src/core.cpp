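// Numerical kernels: separable periodic DWT, trilinear sampling with
// gradients, im2col 3D convolution, grey-scale morphology min/max filters,
// batched matrix multiply, surface-distance helper.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int imod(int a, int n) { int r = a % n; return r < 0 ? r + n : r; }
static inline int iclamp(int a, int lo, int hi) { return a < lo ? lo : (a > hi ? hi : a); }

// ---------------------------------------------------------------------------
// 1D analysis step along one axis of a 3D array, periodic boundary,
// decimation by 2.  a[k] = sum_m lo[m] x[(2k+m) mod N]; likewise d with hi.
// [[Rcpp::export]]
List cpp_dwt_axis(NumericVector x, IntegerVector dims, NumericVector lo,
                  NumericVector hi, int axis) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  int d[3] = {d0, d1, d2};
  int s[3] = {1, d0, d0 * d1};
  int N = d[axis];
  int Nh = N / 2;
  int L = lo.size();
  int od[3] = {d0, d1, d2};
  od[axis] = Nh;
  NumericVector a(od[0] * od[1] * od[2]), dd(od[0] * od[1] * od[2]);
  int os[3] = {1, od[0], od[0] * od[1]};
  int ax1 = (axis + 1) % 3, ax2 = (axis + 2) % 3;
  for (int j2 = 0; j2 < d[ax2]; ++j2) {
    for (int j1 = 0; j1 < d[ax1]; ++j1) {
      int base = j1 * s[ax1] + j2 * s[ax2];
      int obase = j1 * os[ax1] + j2 * os[ax2];
      for (int k = 0; k < Nh; ++k) {
        double sa = 0.0, sd = 0.0;
        for (int m = 0; m < L; ++m) {
          double xv = x[base + imod(2 * k + m, N) * s[axis]];
          sa += lo[m] * xv;
          sd += hi[m] * xv;
        }
        a[obase + k * os[axis]] = sa;
        dd[obase + k * os[axis]] = sd;
      }
    }
  }
  a.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  dd.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return List::create(_["a"] = a, _["d"] = dd);
}

// Adjoint (= inverse, filters orthonormal) of cpp_dwt_axis.
// [[Rcpp::export]]
NumericVector cpp_idwt_axis(NumericVector a, NumericVector d, IntegerVector dims_half,
                            NumericVector lo, NumericVector hi, int axis) {
  int hd[3] = {dims_half[0], dims_half[1], dims_half[2]};
  int od[3] = {hd[0], hd[1], hd[2]};
  od[axis] = 2 * hd[axis];
  int N = od[axis];
  int Nh = hd[axis];
  int L = lo.size();
  NumericVector y(od[0] * od[1] * od[2]);
  int hs[3] = {1, hd[0], hd[0] * hd[1]};
  int os[3] = {1, od[0], od[0] * od[1]};
  int ax1 = (axis + 1) % 3, ax2 = (axis + 2) % 3;
  for (int j2 = 0; j2 < hd[ax2]; ++j2) {
    for (int j1 = 0; j1 < hd[ax1]; ++j1) {
      int hbase = j1 * hs[ax1] + j2 * hs[ax2];
      int obase = j1 * os[ax1] + j2 * os[ax2];
      for (int k = 0; k < Nh; ++k) {
        double av = a[hbase + k * hs[axis]];
        double dv = d[hbase + k * hs[axis]];
        for (int m = 0; m < L; ++m) {
          y[obase + imod(2 * k + m, N) * os[axis]] += lo[m] * av + hi[m] * dv;
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(od[0], od[1], od[2]);
  return y;
}

// ---------------------------------------------------------------------------
// Trilinear / nearest sampling of a channel-last volume [H,W,L,C] at n
// arbitrary (possibly fractional) voxel coordinates; border clamp.
// coords: n x 3 (0-based).  Returns n x C (column-major).
// [[Rcpp::export]]
NumericVector cpp_sample3(NumericVector img, IntegerVector idims,
                          NumericMatrix coords, bool nearest) {
  int H = idims[0], W = idims[1], Lz = idims[2], C = idims[3];
  int HW = H * W, HWL = H * W * Lz;
  int n = coords.nrow();
  NumericVector out(n * (R_xlen_t)C);
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1), pz = coords(i, 2);
    if (px < 0) px = 0; if (px > H - 1) px = H - 1;
    if (py < 0) py = 0; if (py > W - 1) py = W - 1;
    if (pz < 0) pz = 0; if (pz > Lz - 1) pz = Lz - 1;
    if (nearest) {
      int i0 = (int)std::lround(px), j0 = (int)std::lround(py), k0 = (int)std::lround(pz);
      i0 = iclamp(i0, 0, H - 1); j0 = iclamp(j0, 0, W - 1); k0 = iclamp(k0, 0, Lz - 1);
      int base = i0 + H * j0 + HW * k0;
      for (int c = 0; c < C; ++c) out[i + (R_xlen_t)n * c] = img[base + HWL * c];
    } else {
      int i0 = (int)std::floor(px), j0 = (int)std::floor(py), k0 = (int)std::floor(pz);
      i0 = iclamp(i0, 0, H - 1); j0 = iclamp(j0, 0, W - 1); k0 = iclamp(k0, 0, Lz - 1);
      int i1 = iclamp(i0 + 1, 0, H - 1), j1 = iclamp(j0 + 1, 0, W - 1), k1 = iclamp(k0 + 1, 0, Lz - 1);
      double fx = px - i0, fy = py - j0, fz = pz - k0;
      double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
      double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
      double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
      double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
      int b000 = i0 + H * j0 + HW * k0, b100 = i1 + H * j0 + HW * k0;
      int b010 = i0 + H * j1 + HW * k0, b110 = i1 + H * j1 + HW * k0;
      int b001 = i0 + H * j0 + HW * k1, b101 = i1 + H * j0 + HW * k1;
      int b011 = i0 + H * j1 + HW * k1, b111 = i1 + H * j1 + HW * k1;
      for (int c = 0; c < C; ++c) {
        R_xlen_t co = (R_xlen_t)HWL * c;
        out[i + (R_xlen_t)n * c] =
          w000 * img[b000 + co] + w100 * img[b100 + co] +
          w010 * img[b010 + co] + w110 * img[b110 + co] +
          w001 * img[b001 + co] + w101 * img[b101 + co] +
          w011 * img[b011 + co] + w111 * img[b111 + co];
      }
    }
  }
  return out;
}

// Gradient of cpp_sample3 (trilinear) w.r.t. the image: scatter-add.
// [[Rcpp::export]]
NumericVector cpp_sample3_bwd_img(IntegerVector idims, NumericMatrix coords,
                                  NumericVector gout) {
  int H = idims[0], W = idims[1], Lz = idims[2], C = idims[3];
  int HW = H * W, HWL = H * W * Lz;
  int n = coords.nrow();
  NumericVector gimg((R_xlen_t)HWL * C);
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1), pz = coords(i, 2);
    if (px < 0) px = 0; if (px > H - 1) px = H - 1;
    if (py < 0) py = 0; if (py > W - 1) py = W - 1;
    if (pz < 0) pz = 0; if (pz > Lz - 1) pz = Lz - 1;
    int i0 = iclamp((int)std::floor(px), 0, H - 1);
    int j0 = iclamp((int)std::floor(py), 0, W - 1);
    int k0 = iclamp((int)std::floor(pz), 0, Lz - 1);
    int i1 = iclamp(i0 + 1, 0, H - 1), j1 = iclamp(j0 + 1, 0, W - 1), k1 = iclamp(k0 + 1, 0, Lz - 1);
    double fx = px - i0, fy = py - j0, fz = pz - k0;
    double w[8] = {(1 - fx) * (1 - fy) * (1 - fz), fx * (1 - fy) * (1 - fz),
                   (1 - fx) * fy * (1 - fz), fx * fy * (1 - fz),
                   (1 - fx) * (1 - fy) * fz, fx * (1 - fy) * fz,
                   (1 - fx) * fy * fz, fx * fy * fz};
    int b[8] = {i0 + H * j0 + HW * k0, i1 + H * j0 + HW * k0,
                i0 + H * j1 + HW * k0, i1 + H * j1 + HW * k0,
                i0 + H * j0 + HW * k1, i1 + H * j0 + HW * k1,
                i0 + H * j1 + HW * k1, i1 + H * j1 + HW * k1};
    for (int c = 0; c < C; ++c) {
      double g = gout[i + (R_xlen_t)n * c];
      R_xlen_t co = (R_xlen_t)HWL * c;
      for (int q = 0; q < 8; ++q) gimg[b[q] + co] += w[q] * g;
    }
  }
  return gimg;
}

// Gradient of cpp_sample3 (trilinear) w.r.t. the coordinates; zero where the
// coordinate was clamped at the border.
// [[Rcpp::export]]
NumericMatrix cpp_sample3_bwd_coords(NumericVector img, IntegerVector idims,
                                     NumericMatrix coords, NumericVector gout) {
  int H = idims[0], W = idims[1], Lz = idims[2], C = idims[3];
  int HW = H * W, HWL = H * W * Lz;
  int n = coords.nrow();
  NumericMatrix gc(n, 3);
  for (int i = 0; i < n; ++i) {
    double px = coords(i, 0), py = coords(i, 1), pz = coords(i, 2);
    bool inx = (px > 0 && px < H - 1), iny = (py > 0 && py < W - 1), inz = (pz > 0 && pz < Lz - 1);
    if (px < 0) px = 0; if (px > H - 1) px = H - 1;
    if (py < 0) py = 0; if (py > W - 1) py = W - 1;
    if (pz < 0) pz = 0; if (pz > Lz - 1) pz = Lz - 1;
    int i0 = iclamp((int)std::floor(px), 0, H - 1);
    int j0 = iclamp((int)std::floor(py), 0, W - 1);
    int k0 = iclamp((int)std::floor(pz), 0, Lz - 1);
    int i1 = iclamp(i0 + 1, 0, H - 1), j1 = iclamp(j0 + 1, 0, W - 1), k1 = iclamp(k0 + 1, 0, Lz - 1);
    double fx = px - i0, fy = py - j0, fz = pz - k0;
    int b000 = i0 + H * j0 + HW * k0, b100 = i1 + H * j0 + HW * k0;
    int b010 = i0 + H * j1 + HW * k0, b110 = i1 + H * j1 + HW * k0;
    int b001 = i0 + H * j0 + HW * k1, b101 = i1 + H * j0 + HW * k1;
    int b011 = i0 + H * j1 + HW * k1, b111 = i1 + H * j1 + HW * k1;
    double gx = 0, gy = 0, gz = 0;
    for (int c = 0; c < C; ++c) {
      R_xlen_t co = (R_xlen_t)HWL * c;
      double g = gout[i + (R_xlen_t)n * c];
      double v000 = img[b000 + co], v100 = img[b100 + co], v010 = img[b010 + co],
             v110 = img[b110 + co], v001 = img[b001 + co], v101 = img[b101 + co],
             v011 = img[b011 + co], v111 = img[b111 + co];
      gx += g * ((1 - fy) * (1 - fz) * (v100 - v000) + fy * (1 - fz) * (v110 - v010) +
                 (1 - fy) * fz * (v101 - v001) + fy * fz * (v111 - v011));
      gy += g * ((1 - fx) * (1 - fz) * (v010 - v000) + fx * (1 - fz) * (v110 - v100) +
                 (1 - fx) * fz * (v011 - v001) + fx * fz * (v111 - v101));
      gz += g * ((1 - fx) * (1 - fy) * (v001 - v000) + fx * (1 - fy) * (v101 - v100) +
                 (1 - fx) * fy * (v011 - v010) + fx * fy * (v111 - v110));
    }
    gc(i, 0) = inx ? gx : 0.0;
    gc(i, 1) = iny ? gy : 0.0;
    gc(i, 2) = inz ? gz : 0.0;
  }
  return gc;
}

// ---------------------------------------------------------------------------
// im2col for 3x3x3-style 3D convolution, zero padding.
static arma::mat im2col3(const double *x, int H, int W, int Lz, int Ci,
                         int k0, int k1, int k2, const int *stride, const int *pad,
                         int Ho, int Wo, int Lo) {
  int Nout = Ho * Wo * Lo;
  int K = k0 * k1 * k2 * Ci;
  arma::mat M(K, Nout, arma::fill::zeros);
  int HW = H * W, HWL = H * W * Lz;
  for (int ko = 0; ko < Lo; ++ko) {
    for (int jo = 0; jo < Wo; ++jo) {
      for (int io = 0; io < Ho; ++io) {
        int col = io + Ho * jo + Ho * Wo * ko;
        double *dst = M.colptr(col);
        int iz = ko * stride[2] - pad[2], iy = jo * stride[1] - pad[1], ix = io * stride[0] - pad[0];
        for (int ci = 0; ci < Ci; ++ci) {
          R_xlen_t co = (R_xlen_t)HWL * ci;
          for (int c = 0; c < k2; ++c) {
            int z = iz + c;
            for (int b = 0; b < k1; ++b) {
              int y = iy + b;
              for (int a = 0; a < k0; ++a) {
                int xx = ix + a;
                double v = 0.0;
                if (xx >= 0 && xx < H && y >= 0 && y < W && z >= 0 && z < Lz)
                  v = x[xx + H * y + HW * z + co];
                dst[a + k0 * (b + k1 * (c + k2 * ci))] = v;
              }
            }
          }
        }
      }
    }
  }
  return M;
}

// Forward 3D convolution; x [H,W,L,Ci], w [k0,k1,k2,Ci,Co], b [Co].
// [[Rcpp::export]]
NumericVector cpp_conv3_fwd(NumericVector x, IntegerVector xd, NumericVector w,
                            IntegerVector wd, NumericVector b, IntegerVector stride,
                            IntegerVector pad) {
  int H = xd[0], W = xd[1], Lz = xd[2], Ci = xd[3];
  int k0 = wd[0], k1 = wd[1], k2 = wd[2], Co = wd[4];
  int Ho = (H + 2 * pad[0] - k0) / stride[0] + 1;
  int Wo = (W + 2 * pad[1] - k1) / stride[1] + 1;
  int Lo = (Lz + 2 * pad[2] - k2) / stride[2] + 1;
  arma::mat M = im2col3(x.begin(), H, W, Lz, Ci, k0, k1, k2, stride.begin(), pad.begin(), Ho, Wo, Lo);
  arma::mat Wm(w.begin(), k0 * k1 * k2 * Ci, Co, false);
  arma::mat out = M.t() * Wm;                       // Nout x Co
  for (int c = 0; c < Co; ++c) out.col(c) += b[c];
  NumericVector res(out.begin(), out.end());
  res.attr("dim") = IntegerVector::create(Ho, Wo, Lo, Co);
  return res;
}

// Backward 3D convolution: returns gx, gw, gb.
// [[Rcpp::export]]
List cpp_conv3_bwd(NumericVector x, IntegerVector xd, NumericVector w,
                   IntegerVector wd, NumericVector gout, IntegerVector stride,
                   IntegerVector pad, bool need_gx, bool need_gw) {
  int H = xd[0], W = xd[1], Lz = xd[2], Ci = xd[3];
  int k0 = wd[0], k1 = wd[1], k2 = wd[2], Co = wd[4];
  int Ho = (H + 2 * pad[0] - k0) / stride[0] + 1;
  int Wo = (W + 2 * pad[1] - k1) / stride[1] + 1;
  int Lo = (Lz + 2 * pad[2] - k2) / stride[2] + 1;
  int Nout = Ho * Wo * Lo;
  int K = k0 * k1 * k2 * Ci;
  arma::mat G(gout.begin(), Nout, Co, false);
  List res;
  NumericVector gb(Co);
  for (int c = 0; c < Co; ++c) gb[c] = arma::accu(G.col(c));
  res["gb"] = gb;
  if (need_gw) {
    arma::mat M = im2col3(x.begin(), H, W, Lz, Ci, k0, k1, k2, stride.begin(), pad.begin(), Ho, Wo, Lo);
    arma::mat GW = M * G;                            // K x Co
    NumericVector gw(GW.begin(), GW.end());
    gw.attr("dim") = wd;
    res["gw"] = gw;
  }
  if (need_gx) {
    arma::mat Wm(w.begin(), K, Co, false);
    arma::mat GC = Wm * G.t();                       // K x Nout
    NumericVector gx((R_xlen_t)H * W * Lz * Ci);
    int HW = H * W, HWL = H * W * Lz;
    for (int ko = 0; ko < Lo; ++ko) {
      for (int jo = 0; jo < Wo; ++jo) {
        for (int io = 0; io < Ho; ++io) {
          int col = io + Ho * jo + Ho * Wo * ko;
          const double *src = GC.colptr(col);
          int iz = ko * stride[2] - pad[2], iy = jo * stride[1] - pad[1], ix = io * stride[0] - pad[0];
          for (int ci = 0; ci < Ci; ++ci) {
            R_xlen_t coff = (R_xlen_t)HWL * ci;
            for (int c = 0; c < k2; ++c) {
              int z = iz + c;
              if (z < 0 || z >= Lz) continue;
              for (int bq = 0; bq < k1; ++bq) {
                int y = iy + bq;
                if (y < 0 || y >= W) continue;
                for (int a = 0; a < k0; ++a) {
                  int xx = ix + a;
                  if (xx < 0 || xx >= H) continue;
                  gx[xx + H * y + HW * z + coff] += src[a + k0 * (bq + k1 * (c + k2 * ci))];
                }
              }
            }
          }
        }
      }
    }
    gx.attr("dim") = xd;
    res["gx"] = gx;
  }
  return res;
}

// ---------------------------------------------------------------------------
// Grey-scale min/max filter over an arbitrary offset set, replicate border.
// [[Rcpp::export]]
NumericVector cpp_minmax3(NumericVector x, IntegerVector dims, IntegerMatrix off,
                          bool do_max) {
  int H = dims[0], W = dims[1], Lz = dims[2];
  int HW = H * W;
  int m = off.nrow();
  NumericVector out((R_xlen_t)HW * Lz);
  for (int k = 0; k < Lz; ++k) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        double best = do_max ? R_NegInf : R_PosInf;
        for (int q = 0; q < m; ++q) {
          int ii = iclamp(i + off(q, 0), 0, H - 1);
          int jj = iclamp(j + off(q, 1), 0, W - 1);
          int kk = iclamp(k + off(q, 2), 0, Lz - 1);
          double v = x[ii + H * jj + HW * kk];
          if (do_max) { if (v > best) best = v; } else { if (v < best) best = v; }
        }
        out[i + H * j + HW * k] = best;
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Batched matrix multiply over cube slices: C_b = op(A_b) * op(B_b).
// [[Rcpp::export]]
arma::cube cpp_bmm(arma::cube A, arma::cube B, bool tA, bool tB) {
  int nb = A.n_slices;
  int r = tA ? A.n_cols : A.n_rows;
  int c = tB ? B.n_rows : B.n_cols;
  arma::cube out(r, c, nb);
  for (int b = 0; b < nb; ++b) {
    if (!tA && !tB) out.slice(b) = A.slice(b) * B.slice(b);
    else if (tA && !tB) out.slice(b) = A.slice(b).t() * B.slice(b);
    else if (!tA && tB) out.slice(b) = A.slice(b) * B.slice(b).t();
    else out.slice(b) = A.slice(b).t() * B.slice(b).t();
  }
  return out;
}

// ---------------------------------------------------------------------------
// For each row of A (n x 3), the minimum Euclidean distance to rows of B,
// with per-axis scaling (spacing in mm).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix A, NumericMatrix B, NumericVector scale) {
  int n = A.nrow(), m = B.nrow();
  double sx = scale[0], sy = scale[1], sz = scale[2];
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    double ax = A(i, 0) * sx, ay = A(i, 1) * sy, az = A(i, 2) * sz;
    for (int j = 0; j < m; ++j) {
      double dx = ax - B(j, 0) * sx, dy = ay - B(j, 1) * sy, dz = az - B(j, 2) * sz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// ---------------------------------------------------------------------------
// Softmax over the 2nd dimension of a cube [r, c, B] (attention rows), and
// its backward pass.
// [[Rcpp::export]]
NumericVector cpp_softmax2_fwd(NumericVector x, IntegerVector dims) {
  int r = dims[0], c = dims[1], B = dims[2];
  NumericVector out((R_xlen_t)r * c * B);
  for (int b = 0; b < B; ++b) {
    R_xlen_t off = (R_xlen_t)b * r * c;
    for (int i = 0; i < r; ++i) {
      double mx = R_NegInf;
      for (int j = 0; j < c; ++j) {
        double v = x[off + i + (R_xlen_t)r * j];
        if (v > mx) mx = v;
      }
      double s = 0.0;
      for (int j = 0; j < c; ++j) {
        double e = std::exp(x[off + i + (R_xlen_t)r * j] - mx);
        out[off + i + (R_xlen_t)r * j] = e;
        s += e;
      }
      double inv = 1.0 / s;
      for (int j = 0; j < c; ++j) out[off + i + (R_xlen_t)r * j] *= inv;
    }
  }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_softmax2_bwd(NumericVector y, NumericVector g, IntegerVector dims) {
  int r = dims[0], c = dims[1], B = dims[2];
  NumericVector out((R_xlen_t)r * c * B);
  for (int b = 0; b < B; ++b) {
    R_xlen_t off = (R_xlen_t)b * r * c;
    for (int i = 0; i < r; ++i) {
      double s = 0.0;
      for (int j = 0; j < c; ++j) {
        R_xlen_t k = off + i + (R_xlen_t)r * j;
        s += g[k] * y[k];
      }
      for (int j = 0; j < c; ++j) {
        R_xlen_t k = off + i + (R_xlen_t)r * j;
        out[k] = y[k] * (g[k] - s);
      }
    }
  }
  out.attr("dim") = dims;
  return out;
}
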