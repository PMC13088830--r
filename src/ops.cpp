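// Low-level numerical kernels: trilinear/nearest affine resampling,
// separable convolution, 3D connected components and morphology,
// brute-force nearest-neighbour matching, and 2D convolution layers
// (im2col + GEMM) used by the nested-U segmentation network.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Affine resampling: for each 0-based output index v = (i,j,k), the source
// continuous 0-based index is s = A v + b; trilinear or nearest lookup.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_affine_resample(const arma::cube& src,
                               const arma::ivec& dim_out,
                               const arma::mat& A,
                               const arma::vec& b,
                               const bool linear,
                               const double fill) {
  const int nx = src.n_rows, ny = src.n_cols, nz = src.n_slices;
  const int ox = dim_out(0), oy = dim_out(1), oz = dim_out(2);
  arma::cube out(ox, oy, oz);
  for (int k = 0; k < oz; ++k) {
    for (int j = 0; j < oy; ++j) {
      for (int i = 0; i < ox; ++i) {
        const double sx = A(0,0)*i + A(0,1)*j + A(0,2)*k + b(0);
        const double sy = A(1,0)*i + A(1,1)*j + A(1,2)*k + b(1);
        const double sz = A(2,0)*i + A(2,1)*j + A(2,2)*k + b(2);
        double val;
        if (!linear) {
          const int ix = (int) std::lround(sx);
          const int iy = (int) std::lround(sy);
          const int iz = (int) std::lround(sz);
          if (ix < 0 || iy < 0 || iz < 0 || ix >= nx || iy >= ny || iz >= nz)
            val = fill;
          else
            val = src(ix, iy, iz);
        } else {
          if (sx < 0 || sy < 0 || sz < 0 ||
              sx > nx - 1 || sy > ny - 1 || sz > nz - 1) {
            val = fill;
          } else {
            int x0 = (int) std::floor(sx), y0 = (int) std::floor(sy),
                z0 = (int) std::floor(sz);
            if (x0 == nx - 1) --x0;
            if (y0 == ny - 1) --y0;
            if (z0 == nz - 1) --z0;
            if (x0 < 0) x0 = 0;
            if (y0 < 0) y0 = 0;
            if (z0 < 0) z0 = 0;
            const double fx = sx - x0, fy = sy - y0, fz = sz - z0;
            const double c000 = src(x0,   y0,   z0);
            const double c100 = src(x0+1, y0,   z0);
            const double c010 = src(x0,   y0+1, z0);
            const double c110 = src(x0+1, y0+1, z0);
            const double c001 = src(x0,   y0,   z0+1);
            const double c101 = src(x0+1, y0,   z0+1);
            const double c011 = src(x0,   y0+1, z0+1);
            const double c111 = src(x0+1, y0+1, z0+1);
            const double c00 = c000*(1-fx) + c100*fx;
            const double c10 = c010*(1-fx) + c110*fx;
            const double c01 = c001*(1-fx) + c101*fx;
            const double c11 = c011*(1-fx) + c111*fx;
            const double c0 = c00*(1-fy) + c10*fy;
            const double c1 = c01*(1-fy) + c11*fy;
            val = c0*(1-fz) + c1*fz;
          }
        }
        out(i, j, k) = val;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Separable 1D convolution along one axis (0=x rows, 1=y cols, 2=z slices);
// edge handling by clamping (replicate border).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
arma::cube cpp_convolve_axis(const arma::cube& src, const arma::vec& kernel,
                             const int axis) {
  const int nx = src.n_rows, ny = src.n_cols, nz = src.n_slices;
  const int kl = kernel.n_elem;
  const int half = kl / 2;
  arma::cube out(nx, ny, nz, arma::fill::zeros);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double acc = 0.0;
        for (int t = 0; t < kl; ++t) {
          int ii = i, jj = j, kk = k;
          const int off = t - half;
          if (axis == 0) { ii = i + off; ii = ii < 0 ? 0 : (ii >= nx ? nx-1 : ii); }
          else if (axis == 1) { jj = j + off; jj = jj < 0 ? 0 : (jj >= ny ? ny-1 : jj); }
          else { kk = k + off; kk = kk < 0 ? 0 : (kk >= nz ? nz-1 : kk); }
          acc += kernel(t) * src(ii, jj, kk);
        }
        out(i, j, k) = acc;
      }
  return out;
}

// ---------------------------------------------------------------------------
// 3D connected-component labelling (6 or 26 connectivity), BFS flood fill.
// Input: integer 0/1 array; output: integer labels 0 (background), 1..n.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label_components(const IntegerVector& mask,
                                   const IntegerVector& dims,
                                   const int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t) nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || labels[s] != 0) continue;
    ++next_label;
    labels[s] = next_label;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int ci = cur % nx;
      const int cj = (cur / nx) % ny;
      const int ck = cur / ((R_xlen_t) nx * ny);
      for (const auto& o : offs) {
        const int ii = ci + o[0], jj = cj + o[1], kk = ck + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const R_xlen_t idx = ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk);
        if (mask[idx] != 0 && labels[idx] == 0) {
          labels[idx] = next_label;
          stack.push_back(idx);
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// ---------------------------------------------------------------------------
// Binary dilation by a 3x3x3 box (26-neighbourhood) or cross (6), iterated.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_dilate(const IntegerVector& mask, const IntegerVector& dims,
                         const int iterations, const int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t) nx * ny * nz;
  IntegerVector cur = clone(mask);
  std::vector<std::array<int,3>> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        const int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back({dx, dy, dz});
      }
  for (int it = 0; it < iterations; ++it) {
    IntegerVector nxt = clone(cur);
    for (R_xlen_t s = 0; s < n; ++s) {
      if (cur[s] == 0) continue;
      const int ci = s % nx;
      const int cj = (s / nx) % ny;
      const int ck = s / ((R_xlen_t) nx * ny);
      for (const auto& o : offs) {
        const int ii = ci + o[0], jj = cj + o[1], kk = ck + o[2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        nxt[ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk)] = 1;
      }
    }
    cur = nxt;
  }
  return cur;
}

// ---------------------------------------------------------------------------
// Surface voxels: foreground with >= 1 face-adjacent background neighbour
// (out-of-bounds counts as background).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_surface_voxels(const IntegerVector& mask,
                                 const IntegerVector& dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t) nx * ny * nz;
  IntegerVector out(n, 0);
  const int dxs[6] = {1,-1,0,0,0,0};
  const int dys[6] = {0,0,1,-1,0,0};
  const int dzs[6] = {0,0,0,0,1,-1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0) continue;
    const int ci = s % nx;
    const int cj = (s / nx) % ny;
    const int ck = s / ((R_xlen_t) nx * ny);
    for (int t = 0; t < 6; ++t) {
      const int ii = ci + dxs[t], jj = cj + dys[t], kk = ck + dzs[t];
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
        out[s] = 1; break;
      }
      if (mask[ii + (R_xlen_t) nx * (jj + (R_xlen_t) ny * kk)] == 0) {
        out[s] = 1; break;
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Brute-force nearest neighbour: for each query row, the index (1-based) of
// the closest reference row and the Euclidean distance. Blocked GEMM.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_nn_match(const arma::mat& query, const arma::mat& ref) {
  const arma::uword nq = query.n_rows, nr = ref.n_rows;
  arma::uvec idx(nq);
  arma::vec dist(nq);
  const arma::vec ref_sq = arma::sum(arma::square(ref), 1);
  const arma::uword block = 1024;
  for (arma::uword start = 0; start < nq; start += block) {
    const arma::uword end = std::min(start + block, nq) - 1;
    const arma::mat Q = query.rows(start, end);
    const arma::vec q_sq = arma::sum(arma::square(Q), 1);
    arma::mat D = -2.0 * Q * ref.t();
    D.each_row() += ref_sq.t();
    D.each_col() += q_sq;
    for (arma::uword r = 0; r < D.n_rows; ++r) {
      arma::uword best;
      const double d = D.row(r).min(best);
      idx(start + r) = best + 1;
      dist(start + r) = std::sqrt(std::max(0.0, d));
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// ---------------------------------------------------------------------------
// 2D convolution layers for the segmentation network. Input feature maps are
// cubes (H, W, C); weights are (9*Cin) x Cout matrices for 3x3 kernels with
// zero padding 1, stride 1. im2col + GEMM.
// ---------------------------------------------------------------------------

static arma::mat im2col3x3(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::mat M(H * W, 9 * C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    const arma::mat& plane = x.slice(c);
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = c * 9 + (dw + 1) * 3 + (dh + 1);
        // source rows/cols valid where 0 <= h+dh < H, 0 <= w+dw < W
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(W, W - dw);
        for (int w = w0; w < w1; ++w) {
          double* dst = M.colptr(col) + (R_xlen_t) w * H;
          const double* srcp = plane.colptr(w + dw);
          for (int h = h0; h < h1; ++h) dst[h] = srcp[h + dh];
        }
      }
    }
  }
  return M;
}

// Fused 3x3 conv + ReLU. The im2col matrix is kept on the C++ heap and
// handed back as an external pointer so the backward pass can reuse it
// without a copy into R.
// [[Rcpp::export]]
List cpp_conv2d_fwd(const arma::cube& x, const arma::mat& W,
                    const arma::rowvec& b) {
  const int H = x.n_rows, Wd = x.n_cols;
  const int Cout = W.n_cols;
  arma::mat* M = new arma::mat(im2col3x3(x));
  arma::mat Y = (*M) * W;
  Y.each_row() += b;
  Y.transform([](double v) { return v > 0.0 ? v : 0.0; });
  arma::cube out(H, Wd, Cout);
  std::memcpy(out.memptr(), Y.memptr(), sizeof(double) * Y.n_elem);
  XPtr<arma::mat> Mp(M, true);
  return List::create(_["a"] = out, _["M"] = Mp);
}

// Backward through ReLU + conv using the cached im2col matrix; `a` is the
// activated forward output (used as the ReLU mask).
// [[Rcpp::export]]
List cpp_conv2d_bwd(SEXP Mptr, const arma::mat& W, const arma::cube& dy_in,
                    const arma::cube& a, const int Cin) {
  XPtr<arma::mat> Mp(Mptr);
  const arma::mat& M = *Mp;
  const int H = dy_in.n_rows, Wd = dy_in.n_cols;
  const int Cout = dy_in.n_slices;
  arma::cube dy = dy_in;
  for (arma::uword i = 0; i < dy.n_elem; ++i)
    if (a(i) <= 0.0) dy(i) = 0.0;
  arma::mat dY((double*) dy.memptr(), (R_xlen_t) H * Wd, Cout, false, true);
  arma::mat dW = M.t() * dY;
  arma::rowvec db = arma::sum(dY, 0);
  arma::mat dM = dY * W.t();          // (H*W) x (9*Cin)
  // col2im: scatter-add back to input gradient
  arma::cube dx(H, Wd, Cin, arma::fill::zeros);
  for (int c = 0; c < Cin; ++c) {
    arma::mat& plane = dx.slice(c);
    for (int dw = -1; dw <= 1; ++dw) {
      for (int dh = -1; dh <= 1; ++dh) {
        const int col = c * 9 + (dw + 1) * 3 + (dh + 1);
        const int h0 = std::max(0, -dh), h1 = std::min(H, H - dh);
        const int w0 = std::max(0, -dw), w1 = std::min(Wd, Wd - dw);
        for (int w = w0; w < w1; ++w) {
          const double* srcp = dM.colptr(col) + (R_xlen_t) w * H;
          double* dst = plane.colptr(w + dw);
          for (int h = h0; h < h1; ++h) dst[h + dh] += srcp[h];
        }
      }
    }
  }
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// Max pooling 2x2 stride 2 (odd trailing row/col handled by clamped window).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(const arma::cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  const int Ho = (H + 1) / 2, Wo = (W + 1) / 2;
  arma::cube y(Ho, Wo, C);
  arma::ucube amax(Ho, Wo, C);   // linear index into the input plane
  for (int c = 0; c < C; ++c)
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io) {
        double best = -std::numeric_limits<double>::infinity();
        arma::uword bidx = 0;
        for (int dj = 0; dj < 2; ++dj)
          for (int di = 0; di < 2; ++di) {
            const int i = 2 * io + di, j = 2 * jo + dj;
            if (i >= H || j >= W) continue;
            const double v = x(i, j, c);
            if (v > best) { best = v; bidx = i + (arma::uword) H * j; }
          }
        y(io, jo, c) = best;
        amax(io, jo, c) = bidx;
      }
  return List::create(_["y"] = y, _["argmax"] = amax);
}

// [[Rcpp::export]]
arma::cube cpp_maxpool2_bwd(const arma::cube& dy, const arma::ucube& amax,
                            const int H, const int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c) {
    double* plane = dx.slice_memptr(c);
    for (int jo = 0; jo < Wo; ++jo)
      for (int io = 0; io < Ho; ++io)
        plane[amax(io, jo, c)] += dy(io, jo, c);
  }
  return dx;
}

// Nearest-neighbour upsampling to an explicit target size (factor ~2).
// [[Rcpp::export]]
arma::cube cpp_upsample2_fwd(const arma::cube& x, const int Ho, const int Wo) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  arma::cube y(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      const int js = std::min(j / 2, W - 1);
      for (int i = 0; i < Ho; ++i)
        y(i, j, c) = x(std::min(i / 2, H - 1), js, c);
    }
  return y;
}

// [[Rcpp::export]]
arma::cube cpp_upsample2_bwd(const arma::cube& dy, const int H, const int W) {
  const int Ho = dy.n_rows, Wo = dy.n_cols, C = dy.n_slices;
  arma::cube dx(H, W, C, arma::fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j) {
      const int js = std::min(j / 2, W - 1);
      for (int i = 0; i < Ho; ++i)
        dx(std::min(i / 2, H - 1), js, c) += dy(i, j, c);
    }
  return dx;
}
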