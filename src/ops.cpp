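// Low-level array kernels: convolution support (im2col/col2im), pooling,
// upsampling, in-plane rotation/resize, Gaussian smoothing, 3D connected
// components and per-slice Euclidean distance transforms.
//
// Array layouts follow R column-major order:
//   2D feature maps: (H, W, C)      index h + H*(w + W*c)
//   3D feature maps: (D, H, W, C)   index d + D*(h + H*(w + W*c))
//   CT volumes:      (nz, ny, nx)   index z + nz*(y + ny*x)
// All convolutions are stride 1 with zero "same" padding.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// ---------------------------------------------------------------- im2col 2D
// [[Rcpp::export]]
NumericMatrix cpp_im2col2d(NumericVector x, int H, int W, int C, int k) {
  int pad = k / 2;
  NumericMatrix out(H * W, k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int j = dh + k * (dw + k * c);
        double *col = &out(0, j);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int sh = h + dh - pad;
            if (sh < 0 || sh >= H) continue;
            col[h + H * w] = x[sh + H * (sw + W * c)];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im2d(NumericMatrix cols, int H, int W, int C, int k) {
  int pad = k / 2;
  NumericVector out(H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        int j = dh + k * (dw + k * c);
        double *col = &cols(0, j);
        for (int w = 0; w < W; ++w) {
          int sw = w + dw - pad;
          if (sw < 0 || sw >= W) continue;
          for (int h = 0; h < H; ++h) {
            int sh = h + dh - pad;
            if (sh < 0 || sh >= H) continue;
            out[sh + H * (sw + W * c)] += col[h + H * w];
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------- im2col 3D
// [[Rcpp::export]]
NumericMatrix cpp_im2col3d(NumericVector x, int D, int H, int W, int C, int k) {
  int pad = k / 2;
  NumericMatrix out(D * H * W, k * k * k * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        for (int dd = 0; dd < k; ++dd) {
          int j = dd + k * (dh + k * (dw + k * c));
          double *col = &out(0, j);
          for (int w = 0; w < W; ++w) {
            int sw = w + dw - pad;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + dh - pad;
              if (sh < 0 || sh >= H) continue;
              for (int d = 0; d < D; ++d) {
                int sd = d + dd - pad;
                if (sd < 0 || sd >= D) continue;
                col[d + D * (h + H * w)] = x[sd + D * (sh + H * (sw + W * c))];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_col2im3d(NumericMatrix cols, int D, int H, int W, int C, int k) {
  int pad = k / 2;
  NumericVector out(D * H * W * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < k; ++dw) {
      for (int dh = 0; dh < k; ++dh) {
        for (int dd = 0; dd < k; ++dd) {
          int j = dd + k * (dh + k * (dw + k * c));
          double *col = &cols(0, j);
          for (int w = 0; w < W; ++w) {
            int sw = w + dw - pad;
            if (sw < 0 || sw >= W) continue;
            for (int h = 0; h < H; ++h) {
              int sh = h + dh - pad;
              if (sh < 0 || sh >= H) continue;
              for (int d = 0; d < D; ++d) {
                int sd = d + dd - pad;
                if (sd < 0 || sd >= D) continue;
                out[sd + D * (sh + H * (sw + W * c))] += col[d + D * (h + H * w)];
              }
            }
          }
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------- max pool
// 2D pool 2x2 stride 2. Returns pooled values and flat argmax indices (0-based
// into the input array) for the backward pass.
// [[Rcpp::export]]
List cpp_maxpool2d(NumericVector x, int H, int W, int C) {
  int Ho = H / 2, Wo = W / 2;
  NumericVector y(Ho * Wo * C);
  IntegerVector idx(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h) {
        double best = -std::numeric_limits<double>::infinity();
        int bi = 0;
        for (int dw = 0; dw < 2; ++dw)
          for (int dh = 0; dh < 2; ++dh) {
            int i = (2 * h + dh) + H * ((2 * w + dw) + W * c);
            if (x[i] > best) { best = x[i]; bi = i; }
          }
        int o = h + Ho * (w + Wo * c);
        y[o] = best; idx[o] = bi;
      }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool_bw(NumericVector dy, IntegerVector idx, int n_in) {
  NumericVector dx(n_in);
  for (int i = 0; i < dy.size(); ++i) dx[idx[i]] += dy[i];
  return dx;
}

// 3D pool with per-axis factors (pd, ph, pw), stride equal to pool size.
// [[Rcpp::export]]
List cpp_maxpool3d(NumericVector x, int D, int H, int W, int C,
                   int pd, int ph, int pw) {
  int Do = D / pd, Ho = H / ph, Wo = W / pw;
  NumericVector y(Do * Ho * Wo * C);
  IntegerVector idx(Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d) {
          double best = -std::numeric_limits<double>::infinity();
          int bi = 0;
          for (int dw = 0; dw < pw; ++dw)
            for (int dh = 0; dh < ph; ++dh)
              for (int dd = 0; dd < pd; ++dd) {
                int i = (pd * d + dd) +
                        D * ((ph * h + dh) + H * ((pw * w + dw) + W * c));
                if (x[i] > best) { best = x[i]; bi = i; }
              }
          int o = d + Do * (h + Ho * (w + Wo * c));
          y[o] = best; idx[o] = bi;
        }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// ------------------------------------------------------------- upsampling
// Nearest-neighbour x2 (2D in-plane).
// [[Rcpp::export]]
NumericVector cpp_upsample2d(NumericVector x, int H, int W, int C) {
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector y(Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        y[h + Ho * (w + Wo * c)] = x[(h / 2) + H * ((w / 2) + W * c)];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample2d_bw(NumericVector dy, int H, int W, int C) {
  // H, W are the *input* (coarse) dims; dy has dims (2H, 2W, C)
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        dx[(h / 2) + H * ((w / 2) + W * c)] += dy[h + Ho * (w + Wo * c)];
  return dx;
}

// Nearest-neighbour x2 along all three axes.
// [[Rcpp::export]]
NumericVector cpp_upsample3d(NumericVector x, int D, int H, int W, int C) {
  int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector y((double)Do * Ho * Wo * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          y[d + Do * (h + Ho * (w + Wo * c))] =
            x[(d / 2) + D * ((h / 2) + H * ((w / 2) + W * c))];
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_upsample3d_bw(NumericVector dy, int D, int H, int W, int C) {
  int Do = 2 * D, Ho = 2 * H, Wo = 2 * W;
  NumericVector dx(D * H * W * C);
  for (int c = 0; c < C; ++c)
    for (int w = 0; w < Wo; ++w)
      for (int h = 0; h < Ho; ++h)
        for (int d = 0; d < Do; ++d)
          dx[(d / 2) + D * ((h / 2) + H * ((w / 2) + W * c))] +=
            dy[d + Do * (h + Ho * (w + Wo * c))];
  return dx;
}

// ------------------------------------------------------ geometric resampling
// Rotate a (ny, nx) slice by `angle` degrees (counter-clockwise in array
// coordinates) about the slice centre. bilinear = 0 -> nearest neighbour.
// Out-of-range samples take `fill`.
// [[Rcpp::export]]
NumericMatrix cpp_rotate2d(NumericMatrix x, double angle, int bilinear,
                           double fill) {
  int ny = x.nrow(), nx = x.ncol();
  NumericMatrix out(ny, nx);
  double th = angle * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double cy = (ny - 1) / 2.0, cx = (nx - 1) / 2.0;
  for (int xx = 0; xx < nx; ++xx) {
    for (int yy = 0; yy < ny; ++yy) {
      // inverse map: rotate output coords by -angle
      double dy = yy - cy, dx = xx - cx;
      double sy = ct * dy + st * dx + cy;
      double sx = -st * dy + ct * dx + cx;
      double v = fill;
      if (bilinear) {
        int y0 = (int)std::floor(sy), x0 = (int)std::floor(sx);
        double fy = sy - y0, fx = sx - x0;
        double acc = 0.0; bool ok = true;
        for (int b = 0; b < 2 && ok; ++b)
          for (int a = 0; a < 2; ++a) {
            int yi = y0 + a, xi = x0 + b;
            double wgt = (a ? fy : 1 - fy) * (b ? fx : 1 - fx);
            if (wgt == 0.0) continue;
            if (yi < 0 || yi >= ny || xi < 0 || xi >= nx) {
              acc += wgt * fill;
            } else acc += wgt * x(yi, xi);
          }
        v = acc;
      } else {
        int yi = (int)std::lround(sy), xi = (int)std::lround(sx);
        if (yi >= 0 && yi < ny && xi >= 0 && xi < nx) v = x(yi, xi);
      }
      out(yy, xx) = v;
    }
  }
  return out;
}

// Resize a (ny, nx) slice to (oy, ox); centre-aligned sampling as used by
// standard image zoom. bilinear = 0 -> nearest neighbour (for masks).
// [[Rcpp::export]]
NumericMatrix cpp_resize2d(NumericMatrix x, int oy, int ox, int bilinear) {
  int ny = x.nrow(), nx = x.ncol();
  NumericMatrix out(oy, ox);
  double sy = (double)ny / oy, sx = (double)nx / ox;
  for (int xx = 0; xx < ox; ++xx) {
    double srcx = (xx + 0.5) * sx - 0.5;
    for (int yy = 0; yy < oy; ++yy) {
      double srcy = (yy + 0.5) * sy - 0.5;
      if (bilinear) {
        int y0 = (int)std::floor(srcy), x0 = (int)std::floor(srcx);
        double fy = srcy - y0, fx = srcx - x0;
        double acc = 0.0;
        for (int b = 0; b < 2; ++b)
          for (int a = 0; a < 2; ++a) {
            int yi = std::min(std::max(y0 + a, 0), ny - 1);
            int xi = std::min(std::max(x0 + b, 0), nx - 1);
            acc += (a ? fy : 1 - fy) * (b ? fx : 1 - fx) * x(yi, xi);
          }
        out(yy, xx) = acc;
      } else {
        int yi = std::min(std::max((int)std::lround(srcy), 0), ny - 1);
        int xi = std::min(std::max((int)std::lround(srcx), 0), nx - 1);
        out(yy, xx) = x(yi, xi);
      }
    }
  }
  return out;
}

// ------------------------------------------------------- Gaussian smoothing
// Separable Gaussian blur of a (ny, nx) slice, reflected edges.
// [[Rcpp::export]]
NumericMatrix cpp_gauss2d(NumericMatrix x, double sigma) {
  int ny = x.nrow(), nx = x.ncol();
  if (sigma <= 0) return clone(x);
  int r = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> kern(2 * r + 1);
  double s = 0;
  for (int i = -r; i <= r; ++i) {
    kern[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += kern[i + r];
  }
  for (double &v : kern) v /= s;
  NumericMatrix tmp(ny, nx), out(ny, nx);
  for (int xx = 0; xx < nx; ++xx)
    for (int yy = 0; yy < ny; ++yy) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int yi = yy + i;
        if (yi < 0) yi = -yi - 1;
        if (yi >= ny) yi = 2 * ny - yi - 1;
        acc += kern[i + r] * x(yi, xx);
      }
      tmp(yy, xx) = acc;
    }
  for (int xx = 0; xx < nx; ++xx)
    for (int yy = 0; yy < ny; ++yy) {
      double acc = 0;
      for (int i = -r; i <= r; ++i) {
        int xi = xx + i;
        if (xi < 0) xi = -xi - 1;
        if (xi >= nx) xi = 2 * nx - xi - 1;
        acc += kern[i + r] * tmp(yy, xi);
      }
      out(yy, xx) = acc;
    }
  return out;
}

// ------------------------------------------------- 3D connected components
// 26-connectivity labelling of a binary (nz, ny, nx) volume.
// [[Rcpp::export]]
IntegerVector cpp_label3d(IntegerVector mask, int nz, int ny, int nx) {
  IntegerVector lab(mask.size());
  int next = 0;
  std::vector<int> stack;
  for (int x0 = 0; x0 < nx; ++x0)
    for (int y0 = 0; y0 < ny; ++y0)
      for (int z0 = 0; z0 < nz; ++z0) {
        int i0 = z0 + nz * (y0 + ny * x0);
        if (!mask[i0] || lab[i0]) continue;
        ++next;
        lab[i0] = next;
        stack.push_back(i0);
        while (!stack.empty()) {
          int i = stack.back(); stack.pop_back();
          int z = i % nz, r = i / nz, y = r % ny, x = r / ny;
          for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
              for (int dz = -1; dz <= 1; ++dz) {
                if (!dx && !dy && !dz) continue;
                int zz = z + dz, yy = y + dy, xx = x + dx;
                if (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                    xx < 0 || xx >= nx) continue;
                int j = zz + nz * (yy + ny * xx);
                if (mask[j] && !lab[j]) { lab[j] = next; stack.push_back(j); }
              }
        }
      }
  return lab;
}

// --------------------------------------------- Euclidean distance transform
// Exact 1D squared-distance transform (lower envelope of parabolas).
static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Euclidean distance (in pixels) from every pixel of a (ny, nx) slice to the
// nearest nonzero pixel. All-zero input gives a large finite value everywhere.
// [[Rcpp::export]]
NumericMatrix cpp_edt2d(IntegerMatrix m) {
  int ny = m.nrow(), nx = m.ncol();
  const double BIG = 1e12;
  NumericMatrix g(ny, nx);
  std::vector<double> f(std::max(ny, nx)), d(std::max(ny, nx));
  for (int x = 0; x < nx; ++x) {
    for (int y = 0; y < ny; ++y) f[y] = m(y, x) ? 0.0 : BIG;
    f.resize(ny); d.resize(ny);
    dt1d(f, d);
    for (int y = 0; y < ny; ++y) g(y, x) = d[y];
    f.resize(std::max(ny, nx)); d.resize(std::max(ny, nx));
  }
  NumericMatrix out(ny, nx);
  for (int y = 0; y < ny; ++y) {
    for (int x = 0; x < nx; ++x) f[x] = g(y, x);
    f.resize(nx); d.resize(nx);
    dt1d(f, d);
    for (int x = 0; x < nx; ++x) out(y, x) = std::sqrt(d[x]);
    f.resize(std::max(ny, nx)); d.resize(std::max(ny, nx));
  }
  return out;
}

// ----------------------------------------------- batched 3D conv support
// Same layouts as above, with N sample-major blocks stacked along rows.
// [[Rcpp::export]]
NumericMatrix cpp_im2col3d_batch(NumericMatrix X, int N, int D, int H, int W,
                                 int C, int k) {
  int pad = k / 2, npx = D * H * W;
  NumericMatrix out((double)N * npx, k * k * k * C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double *src = &X(n * npx, c);
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh)
          for (int dd = 0; dd < k; ++dd) {
            int j = dd + k * (dh + k * (dw + k * c));
            double *col = &out(n * npx, j);
            for (int w = 0; w < W; ++w) {
              int sw = w + dw - pad;
              if (sw < 0 || sw >= W) continue;
              for (int h = 0; h < H; ++h) {
                int sh = h + dh - pad;
                if (sh < 0 || sh >= H) continue;
                for (int d = 0; d < D; ++d) {
                  int sd = d + dd - pad;
                  if (sd < 0 || sd >= D) continue;
                  col[d + D * (h + H * w)] = src[sd + D * (sh + H * sw)];
                }
              }
            }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im3d_batch(NumericMatrix cols, int N, int D, int H,
                                 int W, int C, int k) {
  int pad = k / 2, npx = D * H * W;
  NumericMatrix out((double)N * npx, C);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      double *dst = &out(n * npx, c);
      for (int dw = 0; dw < k; ++dw)
        for (int dh = 0; dh < k; ++dh)
          for (int dd = 0; dd < k; ++dd) {
            int j = dd + k * (dh + k * (dw + k * c));
            const double *col = &cols(n * npx, j);
            for (int w = 0; w < W; ++w) {
              int sw = w + dw - pad;
              if (sw < 0 || sw >= W) continue;
              for (int h = 0; h < H; ++h) {
                int sh = h + dh - pad;
                if (sh < 0 || sh >= H) continue;
                for (int d = 0; d < D; ++d) {
                  int sd = d + dd - pad;
                  if (sd < 0 || sd >= D) continue;
                  dst[sd + D * (sh + H * sw)] += col[d + D * (h + H * w)];
                }
              }
            }
          }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_maxpool3d_batch(NumericMatrix X, int N, int D, int H, int W, int C,
                         int pd, int ph, int pw) {
  int Do = D / pd, Ho = H / ph, Wo = W / pw;
  int npx = D * H * W, opx = Do * Ho * Wo;
  NumericMatrix Y((double)N * opx, C);
  IntegerMatrix idx((double)N * opx, C);  // row index into X per sample block
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *src = &X(n * npx, c);
      double *dst = &Y(n * opx, c);
      int *ix = &idx(n * opx, c);
      for (int w = 0; w < Wo; ++w)
        for (int h = 0; h < Ho; ++h)
          for (int d = 0; d < Do; ++d) {
            double best = -std::numeric_limits<double>::infinity();
            int bi = 0;
            for (int dw = 0; dw < pw; ++dw)
              for (int dh = 0; dh < ph; ++dh)
                for (int dd = 0; dd < pd; ++dd) {
                  int i = (pd * d + dd) +
                          D * ((ph * h + dh) + H * (pw * w + dw));
                  if (src[i] > best) { best = src[i]; bi = i; }
                }
            dst[d + Do * (h + Ho * w)] = best;
            ix[d + Do * (h + Ho * w)] = bi;
          }
    }
  return List::create(_["y"] = Y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool3d_batch_bw(NumericMatrix dY, IntegerMatrix idx,
                                     int N, int npx_in, int opx) {
  int C = dY.ncol();
  NumericMatrix dX((double)N * npx_in, C);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double *dy = &dY(n * opx, c);
      const int *ix = &idx(n * opx, c);
      double *dx = &dX(n * npx_in, c);
      for (int i = 0; i < opx; ++i) dx[ix[i]] += dy[i];
    }
  return dX;
}
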