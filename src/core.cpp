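#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Images are R matrices indexed [row = y + 1, col = x + 1], grey values 0-255.
// All pixel coordinates are 0-based with the origin at the top-left pixel
// center, x rightward, y downward.

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// Bilinear sample with clamp-to-border.
static inline double bilinear(const NumericMatrix &img, double x, double y) {
  const int h = img.nrow(), w = img.ncol();
  x = clampd(x, 0.0, w - 1.0);
  y = clampd(y, 0.0, h - 1.0);
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  int x1 = x0 + 1 < w ? x0 + 1 : x0;
  int y1 = y0 + 1 < h ? y0 + 1 : y0;
  double fx = x - x0, fy = y - y0;
  return (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1)) +
         fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
}

// Minimum-eigenvalue (Shi-Tomasi) corner response. Sobel gradients, 3x3 box
// accumulation of the structure tensor. A 2-pixel border is left at zero.
// [[Rcpp::export]]
NumericMatrix cpp_min_eig_response(const NumericMatrix &img) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix gx(h, w), gy(h, w), out(h, w);
  for (int y = 1; y < h - 1; ++y) {
    for (int x = 1; x < w - 1; ++x) {
      gx(y, x) = (img(y - 1, x + 1) + 2 * img(y, x + 1) + img(y + 1, x + 1) -
                  img(y - 1, x - 1) - 2 * img(y, x - 1) - img(y + 1, x - 1)) / 8.0;
      gy(y, x) = (img(y + 1, x - 1) + 2 * img(y + 1, x) + img(y + 1, x + 1) -
                  img(y - 1, x - 1) - 2 * img(y - 1, x) - img(y - 1, x + 1)) / 8.0;
    }
  }
  for (int y = 2; y < h - 2; ++y) {
    for (int x = 2; x < w - 2; ++x) {
      double sxx = 0, syy = 0, sxy = 0;
      for (int dy = -1; dy <= 1; ++dy) {
        for (int dx = -1; dx <= 1; ++dx) {
          double ix = gx(y + dy, x + dx), iy = gy(y + dy, x + dx);
          sxx += ix * ix; syy += iy * iy; sxy += ix * iy;
        }
      }
      double tr = sxx + syy;
      double d = std::sqrt((sxx - syy) * (sxx - syy) + 4.0 * sxy * sxy);
      out(y, x) = 0.5 * (tr - d);
    }
  }
  return out;
}

// 2x downsample with 2x2 box averaging (odd trailing row/col duplicated).
static NumericMatrix downsample2(const NumericMatrix &img) {
  const int h = img.nrow(), w = img.ncol();
  const int oh = (h + 1) / 2, ow = (w + 1) / 2;
  NumericMatrix out(oh, ow);
  for (int y = 0; y < oh; ++y) {
    int y0 = 2 * y, y1 = std::min(2 * y + 1, h - 1);
    for (int x = 0; x < ow; ++x) {
      int x0 = 2 * x, x1 = std::min(2 * x + 1, w - 1);
      out(y, x) = 0.25 * (img(y0, x0) + img(y0, x1) + img(y1, x0) + img(y1, x1));
    }
  }
  return out;
}

// Sample a side x side patch of bilinear values centered at (cx, cy) into
// out (row-major). The four interpolation weights are constant across the
// patch, so they are computed once; border samples clamp.
static void sample_patch(const NumericMatrix &img, double cx, double cy,
                         int side, double *out) {
  const int h = img.nrow(), w = img.ncol();
  const int hs = side / 2;
  const double x0d = cx - hs, y0d = cy - hs;
  const int bx = (int)std::floor(x0d), by = (int)std::floor(y0d);
  const double fx = x0d - bx, fy = y0d - by;
  const double w00 = (1 - fx) * (1 - fy), w10 = fx * (1 - fy);
  const double w01 = (1 - fx) * fy, w11 = fx * fy;
  if (bx >= 0 && by >= 0 && bx + side < w && by + side < h) {
    const double *base = &img(0, 0);
    for (int r = 0; r < side; ++r) {
      const double *c0 = base + (size_t)(bx) * h + (by + r);
      for (int c = 0; c < side; ++c) {
        const double *p = c0 + (size_t)c * h;
        out[r * side + c] = w00 * p[0] + w01 * p[1] + w10 * p[h] + w11 * p[h + 1];
      }
    }
  } else {
    for (int r = 0; r < side; ++r)
      for (int c = 0; c < side; ++c)
        out[r * side + c] = bilinear(img, x0d + c, y0d + r);
  }
}

// Pyramidal Lucas-Kanade tracking of sparse points from prev to next.
// pts: n x 2 matrix of (x, y). Returns n x 3: (x, y, status).
// Status 0 flags points whose spatial-gradient matrix is near singular or
// whose window leaves the image at full resolution.
// [[Rcpp::export]]
NumericMatrix cpp_klt_track(const NumericMatrix &prev, const NumericMatrix &nxt,
                            const NumericMatrix &pts, int win = 21, int levels = 3,
                            int max_iter = 20, double eps = 0.03) {
  const int n = pts.nrow();
  const int hw = win / 2;
  const int pad = win + 2;  // template patch with a 1-px gradient rim
  std::vector<NumericMatrix> pyr_prev, pyr_next;
  pyr_prev.push_back(prev); pyr_next.push_back(nxt);
  for (int l = 1; l < levels; ++l) {
    if (pyr_prev.back().nrow() < 2 * win || pyr_prev.back().ncol() < 2 * win) break;
    pyr_prev.push_back(downsample2(pyr_prev.back()));
    pyr_next.push_back(downsample2(pyr_next.back()));
  }
  const int nlev = (int)pyr_prev.size();
  NumericMatrix out(n, 3);
  std::vector<double> P(pad * pad), Ix(win * win), Iy(win * win),
      Tv(win * win), Bv(win * win);

  for (int i = 0; i < n; ++i) {
    double px = pts(i, 0), py = pts(i, 1);
    double dx = 0, dy = 0;
    bool ok = true;
    for (int l = nlev - 1; l >= 0; --l) {
      const NumericMatrix &A = pyr_prev[l];
      const NumericMatrix &B = pyr_next[l];
      const double s = std::pow(2.0, l);
      const double qx = px / s, qy = py / s;
      // template and its gradient via central differences on one padded patch
      sample_patch(A, qx, qy, pad, P.data());
      double gxx = 0, gyy = 0, gxy = 0;
      for (int r = 0; r < win; ++r) {
        for (int c = 0; c < win; ++c) {
          const int pr = r + 1, pc = c + 1;
          const double ix = 0.5 * (P[pr * pad + pc + 1] - P[pr * pad + pc - 1]);
          const double iy = 0.5 * (P[(pr + 1) * pad + pc] - P[(pr - 1) * pad + pc]);
          const int k = r * win + c;
          Ix[k] = ix; Iy[k] = iy; Tv[k] = P[pr * pad + pc];
          gxx += ix * ix; gyy += iy * iy; gxy += ix * iy;
        }
      }
      double det = gxx * gyy - gxy * gxy;
      double min_eig = 0.5 * ((gxx + gyy) -
        std::sqrt((gxx - gyy) * (gxx - gyy) + 4 * gxy * gxy));
      if (det <= 1e-8 || min_eig / (win * win) < 1e-4) { ok = false; break; }
      bool converged = false;
      for (int it = 0; it < max_iter; ++it) {
        sample_patch(B, qx + dx, qy + dy, win, Bv.data());
        double bx = 0, by = 0;
        for (int k = 0; k < win * win; ++k) {
          const double diff = Tv[k] - Bv[k];
          bx += diff * Ix[k]; by += diff * Iy[k];
        }
        double ddx = (gyy * bx - gxy * by) / det;
        double ddy = (gxx * by - gxy * bx) / det;
        dx += ddx; dy += ddy;
        if (ddx * ddx + ddy * ddy < eps * eps) { converged = true; break; }
      }
      // divergence at full resolution counts as tracker failure
      if (l == 0 && !converged) ok = false;
      if (l > 0) { dx *= 2; dy *= 2; }
    }
    double nx = px + dx, ny = py + dy;
    if (ok) {
      // window must stay inside the full-resolution frame
      if (nx - hw < -0.5 || ny - hw < -0.5 ||
          nx + hw > nxt.ncol() - 0.5 || ny + hw > nxt.nrow() - 0.5) ok = false;
    }
    out(i, 0) = nx; out(i, 1) = ny; out(i, 2) = ok ? 1.0 : 0.0;
  }
  return out;
}

static inline bool point_in_poly(double px, double py,
                                 const NumericVector &vx, const NumericVector &vy) {
  const int n = vx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((vy[i] > py) != (vy[j] > py)) &&
        (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]))
      inside = !inside;
  }
  return inside;
}

// Even-odd rasterization: pixel belongs to the polygon when its center lies
// inside. Returns a logical mask of the full frame.
// [[Rcpp::export]]
LogicalMatrix cpp_polygon_mask(int h, int w, const NumericVector &vx,
                               const NumericVector &vy) {
  LogicalMatrix out(h, w);
  int x0 = std::max(0, (int)std::floor(Rcpp::min(vx)));
  int x1 = std::min(w - 1, (int)std::ceil(Rcpp::max(vx)));
  int y0 = std::max(0, (int)std::floor(Rcpp::min(vy)));
  int y1 = std::min(h - 1, (int)std::ceil(Rcpp::max(vy)));
  for (int y = y0; y <= y1; ++y)
    for (int x = x0; x <= x1; ++x)
      if (point_in_poly((double)x, (double)y, vx, vy)) out(y, x) = true;
  return out;
}

// Mean grey value over pixels whose centers fall inside the polygon.
// Returns c(mean, n_pixels); mean is NA when no pixel center is enclosed.
// [[Rcpp::export]]
NumericVector cpp_polygon_mean(const NumericMatrix &img, const NumericVector &vx,
                               const NumericVector &vy) {
  const int h = img.nrow(), w = img.ncol();
  int x0 = std::max(0, (int)std::floor(Rcpp::min(vx)));
  int x1 = std::min(w - 1, (int)std::ceil(Rcpp::max(vx)));
  int y0 = std::max(0, (int)std::floor(Rcpp::min(vy)));
  int y1 = std::min(h - 1, (int)std::ceil(Rcpp::max(vy)));
  double s = 0; long n = 0;
  for (int y = y0; y <= y1; ++y)
    for (int x = x0; x <= x1; ++x)
      if (point_in_poly((double)x, (double)y, vx, vy)) { s += img(y, x); ++n; }
  return NumericVector::create(n > 0 ? s / n : NA_REAL, (double)n);
}

// Resample a source image under an inverse similarity map: output pixel
// (x, y) takes the bilinear sample of src at
//   u = a*x - b*y + tx,  v = b*x + a*y + ty.
// [[Rcpp::export]]
NumericMatrix cpp_similarity_sample(const NumericMatrix &src, int h, int w,
                                    double a, double b, double tx, double ty) {
  NumericMatrix out(h, w);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      out(y, x) = bilinear(src, a * x - b * y + tx, b * x + a * y + ty);
  return out;
}
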