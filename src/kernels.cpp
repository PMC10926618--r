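// Low-level numeric kernels for the segmentation engine.
//
// Tensor layout convention (matches R arrays, column-major):
//   feature maps are dim (H, W, C, N)  -- height fastest.
// Convolution weights are dim (kh, kw, Cin, Cout), biases length Cout.
//
// conv2d uses im2col + BLAS gemm (through Armadillo); the col matrix is
// (H*W) x (kh*kw*Cin) so the gemm output lands directly in (H, W, Cout)
// column-major order with no transpose pass.

#include <RcppArmadillo.h>
#include <map>
#include <cstdint>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline NumericVector alloc4(int H, int W, int C, int N) {
  NumericVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static inline IntegerVector alloc4i(int H, int W, int C, int N) {
  IntegerVector y((R_xlen_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  return y;
}

static inline void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-D (H, W, C, N) array");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// Fill the im2col matrix for one sample. Stride is always 1 here;
// downsampling in the network is done by pooling, not strided conv.
static void im2col(const double* x, int H, int W, int C,
                   int kh, int kw, int pad, arma::mat& col) {
  const int npix = H * W;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * npix;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        double* dst = col.colptr((size_t)c * kh * kw + (size_t)dw * kh + dh);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) {
            std::fill(dst + (size_t)w * H, dst + (size_t)(w + 1) * H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            int sh = h + dh - pad;
            dst[(size_t)w * H + h] = (sh < 0 || sh >= H) ? 0.0 : src[sh];
          }
        }
      }
    }
  }
}

static void col2im_acc(const arma::mat& dcol, int H, int W, int C,
                       int kh, int kw, int pad, double* dx) {
  const int npix = H * W;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx + (size_t)c * npix;
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const double* src = dcol.colptr((size_t)c * kh * kw + (size_t)dw * kh + dh);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          double* dst = dxc + (size_t)sw * H;
          for (int h = 0; h < H; ++h) {
            int sh = h + dh - pad;
            if (sh >= 0 && sh < H) dst[sh] += src[(size_t)w * H + h];
          }
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".conv2d_fwd")]]
NumericVector conv2d_fwd(NumericVector x, NumericVector wt, NumericVector bias,
                         int kh, int kw, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = wt.attr("dim");
  if (wd.size() != 4 || wd[0] != kh || wd[1] != kw || wd[2] != C)
    stop("weight dims do not match input");
  const int Cout = wd[3];
  const int npix = H * W, K = kh * kw * C;
  NumericVector y = alloc4(H, W, Cout, N);
  arma::mat Wm(const_cast<double*>(&wt[0]), K, Cout, false, true);
  arma::mat col(npix, K);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)n * npix * C, H, W, C, kh, kw, pad, col);
    arma::mat Ym(&y[0] + (size_t)n * npix * Cout, npix, Cout, false, true);
    Ym = col * Wm;
    for (int co = 0; co < Cout; ++co) Ym.col(co) += bias[co];
  }
  return y;
}

// [[Rcpp::export(name = ".conv2d_bwd")]]
List conv2d_bwd(NumericVector x, NumericVector wt, NumericVector dy,
                int kh, int kw, int pad) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  IntegerVector wd = wt.attr("dim");
  const int Cout = wd[3];
  const int npix = H * W, K = kh * kw * C;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dw = alloc4(kh, kw, C, Cout);
  NumericVector db(Cout);
  arma::mat Wm(const_cast<double*>(&wt[0]), K, Cout, false, true);
  arma::mat dWm(&dw[0], K, Cout, false, true);
  arma::mat col(npix, K), dcol(npix, K);
  for (int n = 0; n < N; ++n) {
    im2col(&x[0] + (size_t)n * npix * C, H, W, C, kh, kw, pad, col);
    arma::mat dYm(const_cast<double*>(&dy[0]) + (size_t)n * npix * Cout,
                  npix, Cout, false, true);
    dWm += col.t() * dYm;
    dcol = dYm * Wm.t();
    col2im_acc(dcol, H, W, C, kh, kw, pad, &dx[0] + (size_t)n * npix * C);
    for (int co = 0; co < Cout; ++co) db[co] += arma::accu(dYm.col(co));
  }
  return List::create(_["dx"] = dx, _["dw"] = dw, _["db"] = db);
}

// 2x2 max pool, stride 2. Returns pooled values and 1-based argmax
// linear indices into the input array (for the backward scatter).
// [[Rcpp::export(name = ".maxpool2_fwd")]]
List maxpool2_fwd(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (H % 2 || W % 2) stop("max-pool input dims must be even");
  const int Ho = H / 2, Wo = W / 2;
  NumericVector y = alloc4(Ho, Wo, C, N);
  IntegerVector idx = alloc4i(Ho, Wo, C, N);
  size_t o = 0;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t base = ((size_t)n * C + c) * H * W;
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h, ++o) {
          size_t i00 = base + (size_t)(2 * w) * H + 2 * h;
          size_t best = i00; double bv = x[i00];
          size_t cand[3] = { i00 + 1, i00 + (size_t)H, i00 + (size_t)H + 1 };
          for (int t = 0; t < 3; ++t)
            if (x[cand[t]] > bv) { bv = x[cand[t]]; best = cand[t]; }
          y[o] = bv; idx[o] = (int)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export(name = ".maxpool2_bwd")]]
NumericVector maxpool2_bwd(NumericVector dy, IntegerVector idx,
                           IntegerVector in_dim) {
  NumericVector dx = alloc4(in_dim[0], in_dim[1], in_dim[2], in_dim[3]);
  for (R_xlen_t i = 0; i < dy.size(); ++i) dx[idx[i] - 1] += dy[i];
  return dx;
}

struct LinW { int i0, i1; double w0, w1; };

static std::vector<LinW> lin_weights(int in, int out) {
  std::vector<LinW> v(out);
  double scale = (double)in / out;
  for (int i = 0; i < out; ++i) {
    double s = (i + 0.5) * scale - 0.5;
    if (s < 0) s = 0;
    if (s > in - 1) s = in - 1;
    int i0 = (int)std::floor(s);
    int i1 = std::min(i0 + 1, in - 1);
    double f = s - i0;
    v[i] = { i0, i1, 1.0 - f, f };
  }
  return v;
}

// Bilinear resize to (Ho, Wo); half-pixel-centre sampling (align_corners
// false), edges clamped. The backward pass is the exact transpose.
// [[Rcpp::export(name = ".resize_bilinear_fwd")]]
NumericVector resize_bilinear_fwd(NumericVector x, int Ho, int Wo) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  std::vector<LinW> rh = lin_weights(H, Ho), rw = lin_weights(W, Wo);
  NumericVector y = alloc4(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[0] + ((size_t)n * C + c) * H * W;
      double* ys = &y[0] + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const LinW& ww = rw[w];
        for (int h = 0; h < Ho; ++h) {
          const LinW& wh = rh[h];
          ys[(size_t)w * Ho + h] =
            ww.w0 * (wh.w0 * xs[(size_t)ww.i0 * H + wh.i0] +
                     wh.w1 * xs[(size_t)ww.i0 * H + wh.i1]) +
            ww.w1 * (wh.w0 * xs[(size_t)ww.i1 * H + wh.i0] +
                     wh.w1 * xs[(size_t)ww.i1 * H + wh.i1]);
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".resize_bilinear_bwd")]]
NumericVector resize_bilinear_bwd(NumericVector dy, int H, int W) {
  int Ho, Wo, C, N; get_dims4(dy, Ho, Wo, C, N);
  std::vector<LinW> rh = lin_weights(H, Ho), rw = lin_weights(W, Wo);
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = &dx[0] + ((size_t)n * C + c) * H * W;
      const double* ys = &dy[0] + ((size_t)n * C + c) * Ho * Wo;
      for (int w = 0; w < Wo; ++w) {
        const LinW& ww = rw[w];
        for (int h = 0; h < Ho; ++h) {
          const LinW& wh = rh[h];
          double g = ys[(size_t)w * Ho + h];
          xs[(size_t)ww.i0 * H + wh.i0] += ww.w0 * wh.w0 * g;
          xs[(size_t)ww.i0 * H + wh.i1] += ww.w0 * wh.w1 * g;
          xs[(size_t)ww.i1 * H + wh.i0] += ww.w1 * wh.w0 * g;
          xs[(size_t)ww.i1 * H + wh.i1] += ww.w1 * wh.w1 * g;
        }
      }
    }
  return dx;
}

// Adaptive average pool to (b, b): bin i covers rows
// floor(i*H/b) .. ceil((i+1)*H/b) - 1.
// [[Rcpp::export(name = ".adapt_avgpool_fwd")]]
NumericVector adapt_avgpool_fwd(NumericVector x, int b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  if (b > H || b > W) stop("pooling grid larger than input spatial size");
  NumericVector y = alloc4(b, b, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[0] + ((size_t)n * C + c) * H * W;
      double* ys = &y[0] + ((size_t)n * C + c) * b * b;
      for (int bw = 0; bw < b; ++bw) {
        int w0 = (bw * W) / b, w1 = ((bw + 1) * W + b - 1) / b;
        for (int bh = 0; bh < b; ++bh) {
          int h0 = (bh * H) / b, h1 = ((bh + 1) * H + b - 1) / b;
          double s = 0;
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) s += xs[(size_t)w * H + h];
          ys[(size_t)bw * b + bh] = s / ((w1 - w0) * (h1 - h0));
        }
      }
    }
  return y;
}

// [[Rcpp::export(name = ".adapt_avgpool_bwd")]]
NumericVector adapt_avgpool_bwd(NumericVector dy, int H, int W) {
  int b, b2, C, N; get_dims4(dy, b, b2, C, N);
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      double* xs = &dx[0] + ((size_t)n * C + c) * H * W;
      const double* ys = &dy[0] + ((size_t)n * C + c) * b * b;
      for (int bw = 0; bw < b; ++bw) {
        int w0 = (bw * W) / b, w1 = ((bw + 1) * W + b - 1) / b;
        for (int bh = 0; bh < b; ++bh) {
          int h0 = (bh * H) / b, h1 = ((bh + 1) * H + b - 1) / b;
          double g = ys[(size_t)bw * b + bh] / ((w1 - w0) * (h1 - h0));
          for (int w = w0; w < w1; ++w)
            for (int h = h0; h < h1; ++h) xs[(size_t)w * H + h] += g;
        }
      }
    }
  return dx;
}

// Non-local means on a single grayscale image. Patch distances are
// Gaussian-weighted squared differences; the centre pixel gets weight 1.
// [[Rcpp::export(name = ".nlm_cpp")]]
NumericMatrix nlm_cpp(NumericMatrix img, int patch_radius, int search_radius,
                      double h) {
  const int H = img.nrow(), W = img.ncol();
  const int pr = patch_radius, sr = search_radius;
  NumericMatrix out(H, W);
  const int pw = 2 * pr + 1;
  // Gaussian patch kernel, sigma = patch_radius (flat-ish, standard choice)
  std::vector<double> ker(pw * pw);
  double sig = std::max(1.0, (double)pr), ks = 0;
  for (int a = -pr; a <= pr; ++a)
    for (int bq = -pr; bq <= pr; ++bq) {
      double v = std::exp(-(a * a + bq * bq) / (2.0 * sig * sig));
      ker[(a + pr) * pw + (bq + pr)] = v; ks += v;
    }
  for (auto& v : ker) v /= ks;
  const double h2 = h * h;
  auto at = [&](int r, int c) {  // reflect padding
    if (r < 0) r = -r; if (r >= H) r = 2 * H - 2 - r;
    if (c < 0) c = -c; if (c >= W) c = 2 * W - 2 - c;
    return img(r, c);
  };
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double wsum = 0, acc = 0;
      for (int dc = -sr; dc <= sr; ++dc)
        for (int dr = -sr; dr <= sr; ++dr) {
          double d2 = 0;
          for (int a = -pr; a <= pr; ++a)
            for (int bq = -pr; bq <= pr; ++bq) {
              double diff = at(r + a, c + bq) - at(r + dr + a, c + dc + bq);
              d2 += ker[(a + pr) * pw + (bq + pr)] * diff * diff;
            }
          double w = (dr == 0 && dc == 0) ? 1.0 : std::exp(-d2 / h2);
          wsum += w; acc += w * at(r + dr, c + dc);
        }
      out(r, c) = acc / wsum;
    }
  return out;
}

// ---- Marching tetrahedra iso-surface extraction --------------------------
//
// Each cell of the voxel grid is split into 6 tetrahedra around the main
// diagonal; each tetrahedron contributes 0-2 triangles of the level-`level`
// iso-surface. Vertices are interpolated on grid edges and deduplicated by
// an (endpoint, endpoint) edge key, so the mesh is watertight with shared
// vertices. Triangles are oriented with outward normals (away from the
// super-level set), which makes the divergence-theorem volume positive.

struct MTState {
  std::map<std::pair<int64_t, int64_t>, int> edge_vertex;
  std::vector<double> verts;   // x,y,z triples (grid index coordinates)
  std::vector<int> faces;      // 1-based vertex ids, triples
};

static int edge_point(MTState& st, const double* vol, int nx, int ny,
                      int64_t l1, int64_t l2, double level) {
  if (l1 > l2) std::swap(l1, l2);
  auto key = std::make_pair(l1, l2);
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double v1 = vol[l1], v2 = vol[l2];
  double t = (level - v1) / (v2 - v1);
  if (!std::isfinite(t)) t = 0.5;
  if (t < 0) t = 0; if (t > 1) t = 1;
  auto coord = [&](int64_t l, int ax) {
    int64_t x = l % nx, y = (l / nx) % ny, z = l / ((int64_t)nx * ny);
    return ax == 0 ? (double)x : ax == 1 ? (double)y : (double)z;
  };
  for (int ax = 0; ax < 3; ++ax)
    st.verts.push_back(coord(l1, ax) + t * (coord(l2, ax) - coord(l1, ax)));
  int id = (int)(st.verts.size() / 3);
  st.edge_vertex[key] = id;
  return id;
}

static void emit_tri(MTState& st, int a, int b, int c, const double* inside_pt) {
  // orient so the normal points away from the inside reference point
  const double* A = &st.verts[3 * (a - 1)];
  const double* B = &st.verts[3 * (b - 1)];
  const double* C = &st.verts[3 * (c - 1)];
  double u[3] = { B[0] - A[0], B[1] - A[1], B[2] - A[2] };
  double v[3] = { C[0] - A[0], C[1] - A[1], C[2] - A[2] };
  double nrm[3] = { u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                    u[0] * v[1] - u[1] * v[0] };
  double cen[3] = { (A[0] + B[0] + C[0]) / 3, (A[1] + B[1] + C[1]) / 3,
                    (A[2] + B[2] + C[2]) / 3 };
  double d = nrm[0] * (inside_pt[0] - cen[0]) + nrm[1] * (inside_pt[1] - cen[1]) +
             nrm[2] * (inside_pt[2] - cen[2]);
  if (d > 0) std::swap(b, c);
  st.faces.push_back(a); st.faces.push_back(b); st.faces.push_back(c);
}

static void do_tet(MTState& st, const double* vol, int nx, int ny,
                   const int64_t lin[4], double level) {
  bool in[4]; int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = vol[lin[i]] > level; nin += in[i]; }
  if (nin == 0 || nin == 4) return;
  int pos[4], neg[4], np = 0, nn = 0;
  for (int i = 0; i < 4; ++i) (in[i] ? pos[np++] : neg[nn++]) = i;
  auto pt = [&](int64_t l, double* out) {
    out[0] = (double)(l % nx); out[1] = (double)((l / nx) % ny);
    out[2] = (double)(l / ((int64_t)nx * ny));
  };
  double ref[3] = { 0, 0, 0 }, tmp[3];
  for (int i = 0; i < np; ++i) {
    pt(lin[pos[i]], tmp);
    ref[0] += tmp[0] / np; ref[1] += tmp[1] / np; ref[2] += tmp[2] / np;
  }
  if (nin == 1 || nin == 3) {
    int apex = (nin == 1) ? pos[0] : neg[0];
    int others[3], k = 0;
    for (int i = 0; i < 4; ++i) if (i != apex) others[k++] = i;
    int p1 = edge_point(st, vol, nx, ny, lin[apex], lin[others[0]], level);
    int p2 = edge_point(st, vol, nx, ny, lin[apex], lin[others[1]], level);
    int p3 = edge_point(st, vol, nx, ny, lin[apex], lin[others[2]], level);
    emit_tri(st, p1, p2, p3, ref);
  } else {  // 2 in, 2 out -> quad
    int a = pos[0], b = pos[1], c = neg[0], d = neg[1];
    int pac = edge_point(st, vol, nx, ny, lin[a], lin[c], level);
    int pad = edge_point(st, vol, nx, ny, lin[a], lin[d], level);
    int pbd = edge_point(st, vol, nx, ny, lin[b], lin[d], level);
    int pbc = edge_point(st, vol, nx, ny, lin[b], lin[c], level);
    emit_tri(st, pac, pad, pbd, ref);
    emit_tri(st, pac, pbd, pbc, ref);
  }
}

// [[Rcpp::export(name = ".march_tets")]]
List march_tets(NumericVector vol, double level) {
  IntegerVector d = vol.attr("dim");
  if (d.size() != 3) stop("expected a 3-D array");
  const int nx = d[0], ny = d[1], nz = d[2];
  MTState st;
  const double* v = &vol[0];
  // 6-tet split of the unit cube around diagonal (0,0,0)-(1,1,1)
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}
  };
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        int64_t corner[8];
        for (int k = 0; k < 8; ++k) {
          int cx = x + (k & 1), cy = y + ((k >> 1) & 1), cz = z + ((k >> 2) & 1);
          corner[k] = (int64_t)cz * nx * ny + (int64_t)cy * nx + cx;
        }
        // quick reject: all same side
        bool any_in = false, any_out = false;
        for (int k = 0; k < 8; ++k)
          (v[corner[k]] > level ? any_in : any_out) = true;
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int64_t lin[4] = { corner[tets[t][0]], corner[tets[t][1]],
                             corner[tets[t][2]], corner[tets[t][3]] };
          do_tet(st, v, nx, ny, lin, level);
        }
      }
  const int nv = (int)(st.verts.size() / 3), nf = (int)(st.faces.size() / 3);
  NumericMatrix V(nv, 3);
  IntegerMatrix Fm(nf, 3);
  for (int i = 0; i < nv; ++i)
    for (int j = 0; j < 3; ++j) V(i, j) = st.verts[3 * i + j];
  for (int i = 0; i < nf; ++i)
    for (int j = 0; j < 3; ++j) Fm(i, j) = st.faces[3 * i + j];
  return List::create(_["vertices"] = V, _["faces"] = Fm);
}

// ---- channel-wise helpers for batch norm, concat and gating --------------

// per-channel mean of x and of x^2 over (H, W, N)
// [[Rcpp::export(name = ".chan_moments")]]
List chan_moments(NumericVector x) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t npix = (size_t)H * W;
  NumericVector mean(C), msq(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[0] + ((size_t)n * C + c) * npix;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < npix; ++i) { s += xs[i]; s2 += xs[i] * xs[i]; }
      mean[c] += s; msq[c] += s2;
    }
  const double m = (double)npix * N;
  for (int c = 0; c < C; ++c) { mean[c] /= m; msq[c] /= m; }
  return List::create(_["mean"] = mean, _["msq"] = msq);
}

// y = a[c] * x + b[c]
// [[Rcpp::export(name = ".chan_affine")]]
NumericVector chan_affine(NumericVector x, NumericVector a, NumericVector b) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t npix = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* xs = &x[0] + ((size_t)n * C + c) * npix;
      double* ys = &y[0] + ((size_t)n * C + c) * npix;
      const double ac = a[c], bc = b[c];
      for (size_t i = 0; i < npix; ++i) ys[i] = ac * xs[i] + bc;
    }
  return y;
}

// per-channel sum(g) and sum(g * h)
// [[Rcpp::export(name = ".chan_dots")]]
List chan_dots(NumericVector g, NumericVector h) {
  int H, W, C, N; get_dims4(g, H, W, C, N);
  const size_t npix = (size_t)H * W;
  NumericVector sg(C), sgh(C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* gs = &g[0] + ((size_t)n * C + c) * npix;
      const double* hs = &h[0] + ((size_t)n * C + c) * npix;
      double s = 0, s2 = 0;
      for (size_t i = 0; i < npix; ++i) { s += gs[i]; s2 += gs[i] * hs[i]; }
      sg[c] += s; sgh[c] += s2;
    }
  return List::create(_["sum_g"] = sg, _["sum_gh"] = sgh);
}

// dx = coef[c] * (g - mg[c] - xhat * mgx[c])
// [[Rcpp::export(name = ".bn_dx")]]
NumericVector bn_dx(NumericVector g, NumericVector xhat, NumericVector coef,
                    NumericVector mg, NumericVector mgx) {
  int H, W, C, N; get_dims4(g, H, W, C, N);
  const size_t npix = (size_t)H * W;
  NumericVector dx = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * npix;
      const double* gs = &g[0] + off;
      const double* hs = &xhat[0] + off;
      double* ds = &dx[0] + off;
      const double cc = coef[c], m1 = mg[c], m2 = mgx[c];
      for (size_t i = 0; i < npix; ++i) ds[i] = cc * (gs[i] - m1 - hs[i] * m2);
    }
  return dx;
}

// channel concatenation of a list of (H, W, Ci, N) arrays
// [[Rcpp::export(name = ".concat_c")]]
NumericVector concat_c(List xs) {
  const int K = xs.size();
  std::vector<NumericVector> v(K);
  std::vector<int> chans(K);
  int H = 0, W = 0, N = 0, Ct = 0;
  for (int k = 0; k < K; ++k) {
    v[k] = as<NumericVector>(xs[k]);
    int h, w, c, n; get_dims4(v[k], h, w, c, n);
    if (k == 0) { H = h; W = w; N = n; }
    chans[k] = c; Ct += c;
  }
  NumericVector y = alloc4(H, W, Ct, N);
  const size_t npix = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    size_t off = (size_t)n * Ct * npix;
    for (int k = 0; k < K; ++k) {
      const double* src = &v[k][0] + (size_t)n * chans[k] * npix;
      std::copy(src, src + (size_t)chans[k] * npix, &y[0] + off);
      off += (size_t)chans[k] * npix;
    }
  }
  return y;
}

// inverse of concat_c: split g back into chunks of `sizes` channels
// [[Rcpp::export(name = ".split_c")]]
List split_c(NumericVector g, IntegerVector sizes) {
  int H, W, Ct, N; get_dims4(g, H, W, Ct, N);
  const int K = sizes.size();
  const size_t npix = (size_t)H * W;
  List out(K);
  std::vector<NumericVector> v(K);
  for (int k = 0; k < K; ++k) v[k] = alloc4(H, W, sizes[k], N);
  for (int n = 0; n < N; ++n) {
    size_t off = (size_t)n * Ct * npix;
    for (int k = 0; k < K; ++k) {
      double* dst = &v[k][0] + (size_t)n * sizes[k] * npix;
      std::copy(&g[0] + off, &g[0] + off + (size_t)sizes[k] * npix, dst);
      off += (size_t)sizes[k] * npix;
    }
  }
  for (int k = 0; k < K; ++k) out[k] = v[k];
  return out;
}

// y = x * q with q broadcast over channels; bwd returns dx and dq
// [[Rcpp::export(name = ".gate_fwd")]]
NumericVector gate_fwd(NumericVector x, NumericVector q) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t npix = (size_t)H * W;
  NumericVector y = alloc4(H, W, C, N);
  for (int n = 0; n < N; ++n) {
    const double* qs = &q[0] + (size_t)n * npix;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * npix;
      for (size_t i = 0; i < npix; ++i) y[off + i] = x[off + i] * qs[i];
    }
  }
  return y;
}

// [[Rcpp::export(name = ".gate_bwd")]]
List gate_bwd(NumericVector g, NumericVector x, NumericVector q) {
  int H, W, C, N; get_dims4(x, H, W, C, N);
  const size_t npix = (size_t)H * W;
  NumericVector dx = alloc4(H, W, C, N);
  NumericVector dq = alloc4(H, W, 1, N);
  for (int n = 0; n < N; ++n) {
    const double* qs = &q[0] + (size_t)n * npix;
    double* dqs = &dq[0] + (size_t)n * npix;
    for (int c = 0; c < C; ++c) {
      const size_t off = ((size_t)n * C + c) * npix;
      for (size_t i = 0; i < npix; ++i) {
        dx[off + i] = g[off + i] * qs[i];
        dqs[i] += g[off + i] * x[off + i];
      }
    }
  }
  return List::create(_["dx"] = dx, _["dq"] = dq);
}
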