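// Low-level numeric kernels: 3D convolution (forward + backward), 2x pooling
// and upsampling, grid resampling, 3D connected components, surface-voxel
// extraction and point-set distances, and a content hash. All arrays are
// column-major R arrays; volumes are (D, H, W) and feature maps (D, H, W, C).

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>

using namespace Rcpp;

static inline int idx3(int i, int j, int k, int D, int H) {
  return i + D * (j + (long)H * k);
}

// x: (D,H,W,Cin); w: (K,K,K,Cin,Cout), K odd; b: length Cout.
// Zero padding of (K-1)/2 so the spatial shape is preserved.
// [[Rcpp::export]]
NumericVector conv3d_fwd(NumericVector x, NumericVector w, NumericVector b,
                         IntegerVector xdim, IntegerVector wdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  const int K = wdim[0], Co = wdim[4];
  const int P = (K - 1) / 2;
  NumericVector y((R_xlen_t)D * H * W * Co);
  y.attr("dim") = IntegerVector::create(D, H, W, Co);
  const double *px = x.begin(), *pw = w.begin(), *pb = b.begin();
  double *py = y.begin();
  const long spat = (long)D * H * W;
  for (int co = 0; co < Co; ++co) {
    double *yo = py + co * spat;
    for (long v = 0; v < spat; ++v) yo[v] = pb[co];
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + ci * spat;
      const double *wc = pw + (long)K * K * K * (ci + (long)Ci * co);
      for (int dk = 0; dk < K; ++dk) {
        for (int dj = 0; dj < K; ++dj) {
          for (int di = 0; di < K; ++di) {
            const double wv = wc[di + K * (dj + K * dk)];
            if (wv == 0.0) continue;
            const int oi = di - P, oj = dj - P, ok = dk - P;
            const int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
            const int j0 = std::max(0, -oj), j1 = std::min(H, H - oj);
            const int k0 = std::max(0, -ok), k1 = std::min(W, W - ok);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                const double *xr = xc + idx3(0, j + oj, k + ok, D, H) + oi;
                double *yr = yo + idx3(0, j, k, D, H);
                for (int i = i0; i < i1; ++i) yr[i] += wv * xr[i];
              }
          }
        }
      }
    }
  }
  return y;
}

// Gradients of conv3d_fwd w.r.t. input, weights and bias.
// [[Rcpp::export]]
List conv3d_bwd(NumericVector x, NumericVector w, NumericVector gy,
                IntegerVector xdim, IntegerVector wdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], Ci = xdim[3];
  const int K = wdim[0], Co = wdim[4];
  const int P = (K - 1) / 2;
  NumericVector gx((R_xlen_t)D * H * W * Ci);
  gx.attr("dim") = IntegerVector::create(D, H, W, Ci);
  NumericVector gw(w.size());
  gw.attr("dim") = w.attr("dim");
  NumericVector gb(Co);
  const double *px = x.begin(), *pw = w.begin(), *pg = gy.begin();
  double *pgx = gx.begin(), *pgw = gw.begin(), *pgb = gb.begin();
  const long spat = (long)D * H * W;
  for (int co = 0; co < Co; ++co) {
    const double *gyo = pg + co * spat;
    double s = 0.0;
    for (long v = 0; v < spat; ++v) s += gyo[v];
    pgb[co] += s;
    for (int ci = 0; ci < Ci; ++ci) {
      const double *xc = px + ci * spat;
      double *gxc = pgx + ci * spat;
      const double *wc = pw + (long)K * K * K * (ci + (long)Ci * co);
      double *gwc = pgw + (long)K * K * K * (ci + (long)Ci * co);
      for (int dk = 0; dk < K; ++dk) {
        for (int dj = 0; dj < K; ++dj) {
          for (int di = 0; di < K; ++di) {
            const double wv = wc[di + K * (dj + K * dk)];
            double acc = 0.0;
            const int oi = di - P, oj = dj - P, ok = dk - P;
            const int i0 = std::max(0, -oi), i1 = std::min(D, D - oi);
            const int j0 = std::max(0, -oj), j1 = std::min(H, H - oj);
            const int k0 = std::max(0, -ok), k1 = std::min(W, W - ok);
            for (int k = k0; k < k1; ++k)
              for (int j = j0; j < j1; ++j) {
                const double *xr = xc + idx3(0, j + oj, k + ok, D, H) + oi;
                double *gxr = gxc + idx3(0, j + oj, k + ok, D, H) + oi;
                const double *gyr = gyo + idx3(0, j, k, D, H);
                for (int i = i0; i < i1; ++i) {
                  acc += xr[i] * gyr[i];
                  gxr[i] += wv * gyr[i];
                }
              }
            gwc[di + K * (dj + K * dk)] += acc;
          }
        }
      }
    }
  }
  return List::create(_["gx"] = gx, _["gw"] = gw, _["gb"] = gb);
}

// 2x2x2 average pooling; spatial dims must be even.
// [[Rcpp::export]]
NumericVector avgpool2_fwd(NumericVector x, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int d = D / 2, h = H / 2, w = W / 2;
  NumericVector y((R_xlen_t)d * h * w * C);
  y.attr("dim") = IntegerVector::create(d, h, w, C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (long)c * D * H * W;
    double *yc = py + (long)c * d * h * w;
    for (int k = 0; k < w; ++k)
      for (int j = 0; j < h; ++j)
        for (int i = 0; i < d; ++i) {
          double s = 0.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                s += xc[idx3(2 * i + di, 2 * j + dj, 2 * k + dk, D, H)];
          yc[idx3(i, j, k, d, h)] = s / 8.0;
        }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector avgpool2_bwd(NumericVector gy, IntegerVector xdim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2], C = xdim[3];
  const int d = D / 2, h = H / 2, w = W / 2;
  NumericVector gx((R_xlen_t)D * H * W * C);
  gx.attr("dim") = IntegerVector::create(D, H, W, C);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = pg + (long)c * d * h * w;
    double *xc = px + (long)c * D * H * W;
    for (int k = 0; k < w; ++k)
      for (int j = 0; j < h; ++j)
        for (int i = 0; i < d; ++i) {
          const double g = gc[idx3(i, j, k, d, h)] / 8.0;
          for (int dk = 0; dk < 2; ++dk)
            for (int dj = 0; dj < 2; ++dj)
              for (int di = 0; di < 2; ++di)
                xc[idx3(2 * i + di, 2 * j + dj, 2 * k + dk, D, H)] = g;
        }
  }
  return gx;
}

// Nearest-neighbour 2x upsampling.
// [[Rcpp::export]]
NumericVector upsample2_fwd(NumericVector x, IntegerVector xdim) {
  const int d = xdim[0], h = xdim[1], w = xdim[2], C = xdim[3];
  const int D = 2 * d, H = 2 * h, W = 2 * w;
  NumericVector y((R_xlen_t)D * H * W * C);
  y.attr("dim") = IntegerVector::create(D, H, W, C);
  const double *px = x.begin();
  double *py = y.begin();
  for (int c = 0; c < C; ++c) {
    const double *xc = px + (long)c * d * h * w;
    double *yc = py + (long)c * D * H * W;
    for (int k = 0; k < W; ++k)
      for (int j = 0; j < H; ++j)
        for (int i = 0; i < D; ++i)
          yc[idx3(i, j, k, D, H)] = xc[idx3(i / 2, j / 2, k / 2, d, h)];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector upsample2_bwd(NumericVector gy, IntegerVector xdim) {
  const int d = xdim[0], h = xdim[1], w = xdim[2], C = xdim[3];
  const int D = 2 * d, H = 2 * h, W = 2 * w;
  NumericVector gx((R_xlen_t)d * h * w * C);
  gx.attr("dim") = IntegerVector::create(d, h, w, C);
  const double *pg = gy.begin();
  double *px = gx.begin();
  for (int c = 0; c < C; ++c) {
    const double *gc = pg + (long)c * D * H * W;
    double *xc = px + (long)c * d * h * w;
    for (int k = 0; k < W; ++k)
      for (int j = 0; j < H; ++j)
        for (int i = 0; i < D; ++i)
          xc[idx3(i / 2, j / 2, k / 2, d, h)] += gc[idx3(i, j, k, D, H)];
  }
  return gx;
}

// Resample a (D,H,W) volume from in_spacing to out_spacing (mm per voxel).
// Voxel i sits at physical coordinate i * spacing; output coordinates are
// mapped back and clamped to the input grid.
// [[Rcpp::export]]
NumericVector resample_trilinear(NumericVector x, IntegerVector xdim,
                                 NumericVector in_sp, NumericVector out_sp,
                                 IntegerVector odim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int d = odim[0], h = odim[1], w = odim[2];
  NumericVector y(Dimension(d, h, w));
  const double *px = x.begin();
  double *py = y.begin();
  for (int k = 0; k < w; ++k) {
    double zk = k * out_sp[2] / in_sp[2];
    int k0 = (int)std::floor(zk); double fk = zk - k0;
    if (k0 >= W - 1) { k0 = W - 1; fk = 0.0; }
    if (k0 < 0) { k0 = 0; fk = 0.0; }
    int k1 = std::min(k0 + 1, W - 1);
    for (int j = 0; j < h; ++j) {
      double zj = j * out_sp[1] / in_sp[1];
      int j0 = (int)std::floor(zj); double fj = zj - j0;
      if (j0 >= H - 1) { j0 = H - 1; fj = 0.0; }
      if (j0 < 0) { j0 = 0; fj = 0.0; }
      int j1 = std::min(j0 + 1, H - 1);
      for (int i = 0; i < d; ++i) {
        double zi = i * out_sp[0] / in_sp[0];
        int i0 = (int)std::floor(zi); double fi = zi - i0;
        if (i0 >= D - 1) { i0 = D - 1; fi = 0.0; }
        if (i0 < 0) { i0 = 0; fi = 0.0; }
        int i1 = std::min(i0 + 1, D - 1);
        double v =
          (1 - fi) * (1 - fj) * (1 - fk) * px[idx3(i0, j0, k0, D, H)] +
          fi * (1 - fj) * (1 - fk) * px[idx3(i1, j0, k0, D, H)] +
          (1 - fi) * fj * (1 - fk) * px[idx3(i0, j1, k0, D, H)] +
          fi * fj * (1 - fk) * px[idx3(i1, j1, k0, D, H)] +
          (1 - fi) * (1 - fj) * fk * px[idx3(i0, j0, k1, D, H)] +
          fi * (1 - fj) * fk * px[idx3(i1, j0, k1, D, H)] +
          (1 - fi) * fj * fk * px[idx3(i0, j1, k1, D, H)] +
          fi * fj * fk * px[idx3(i1, j1, k1, D, H)];
        py[idx3(i, j, k, d, h)] = v;
      }
    }
  }
  return y;
}

// Nearest-neighbour resampling for label masks.
// [[Rcpp::export]]
IntegerVector resample_nearest(IntegerVector x, IntegerVector xdim,
                               NumericVector in_sp, NumericVector out_sp,
                               IntegerVector odim) {
  const int D = xdim[0], H = xdim[1], W = xdim[2];
  const int d = odim[0], h = odim[1], w = odim[2];
  IntegerVector y(Dimension(d, h, w));
  const int *px = x.begin();
  int *py = y.begin();
  for (int k = 0; k < w; ++k) {
    int kk = (int)std::lround(k * out_sp[2] / in_sp[2]);
    kk = std::min(std::max(kk, 0), W - 1);
    for (int j = 0; j < h; ++j) {
      int jj = (int)std::lround(j * out_sp[1] / in_sp[1]);
      jj = std::min(std::max(jj, 0), H - 1);
      for (int i = 0; i < d; ++i) {
        int ii = (int)std::lround(i * out_sp[0] / in_sp[0]);
        ii = std::min(std::max(ii, 0), D - 1);
        py[idx3(i, j, k, d, h)] = px[idx3(ii, jj, kk, D, H)];
      }
    }
  }
  return y;
}

// Label connected foreground components of a binary (D,H,W) mask.
// connectivity is 6 (faces) or 26 (faces, edges, corners).
// [[Rcpp::export]]
List cc_label3d(IntegerVector mask, IntegerVector mdim, int connectivity) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const long n = (long)D * H * W;
  IntegerVector lab(Dimension(D, H, W));
  const int *pm = mask.begin();
  int *pl = lab.begin();
  std::vector<long> stack;
  std::vector<int> sizes;
  int ncomp = 0;
  for (long s = 0; s < n; ++s) {
    if (pm[s] == 0 || pl[s] != 0) continue;
    ++ncomp;
    int sz = 0;
    pl[s] = ncomp;
    stack.push_back(s);
    while (!stack.empty()) {
      long v = stack.back();
      stack.pop_back();
      ++sz;
      int i = (int)(v % D);
      int j = (int)((v / D) % H);
      int k = (int)(v / ((long)D * H));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int man = std::abs(di) + std::abs(dj) + std::abs(dk);
            if (connectivity == 6 && man > 1) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || ii >= D || jj < 0 || jj >= H || kk < 0 || kk >= W)
              continue;
            long u = idx3(ii, jj, kk, D, H);
            if (pm[u] != 0 && pl[u] == 0) {
              pl[u] = ncomp;
              stack.push_back(u);
            }
          }
    }
    sizes.push_back(sz);
  }
  return List::create(_["labels"] = lab, _["n_components"] = ncomp,
                      _["sizes"] = wrap(sizes));
}

// Surface voxels: foreground voxels with at least one of their six
// face-neighbours background; voxels on the array boundary count as surface
// (the outside is treated as background). Returns 0-based (i,j,k) rows.
// [[Rcpp::export]]
IntegerMatrix surface_voxels(IntegerVector mask, IntegerVector mdim) {
  const int D = mdim[0], H = mdim[1], W = mdim[2];
  const int *pm = mask.begin();
  std::vector<int> out;
  for (int k = 0; k < W; ++k)
    for (int j = 0; j < H; ++j)
      for (int i = 0; i < D; ++i) {
        if (pm[idx3(i, j, k, D, H)] == 0) continue;
        bool surf = false;
        const int off[6][3] = {{1, 0, 0}, {-1, 0, 0}, {0, 1, 0},
                               {0, -1, 0}, {0, 0, 1}, {0, 0, -1}};
        for (int t = 0; t < 6 && !surf; ++t) {
          int ii = i + off[t][0], jj = j + off[t][1], kk = k + off[t][2];
          if (ii < 0 || ii >= D || jj < 0 || jj >= H || kk < 0 || kk >= W)
            surf = true;
          else if (pm[idx3(ii, jj, kk, D, H)] == 0)
            surf = true;
        }
        if (surf) {
          out.push_back(i);
          out.push_back(j);
          out.push_back(k);
        }
      }
  const int np = (int)(out.size() / 3);
  IntegerMatrix m(np, 3);
  for (int r = 0; r < np; ++r)
    for (int c = 0; c < 3; ++c) m(r, c) = out[3 * r + c];
  return m;
}

// For each row of a (physical mm coordinates), the Euclidean distance to the
// nearest row of b.
// [[Rcpp::export]]
NumericVector nn_distances(NumericMatrix a, NumericMatrix b) {
  const int na = a.nrow(), nb = b.nrow();
  NumericVector out(na);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf;
    const double ax = a(i, 0), ay = a(i, 1), az = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      double dx = ax - b(j, 0), dy = ay - b(j, 1), dz = az - b(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// FNV-1a 64-bit hash of a raw vector, as a 16-character hex string.
// [[Rcpp::export]]
std::string fnv1a64(RawVector bytes) {
  uint64_t h = 1469598103934665603ULL;
  const uint64_t prime = 1099511628211ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (uint64_t)bytes[i];
    h *= prime;
  }
  char buf[17];
  std::snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
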