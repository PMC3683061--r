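#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear interpolation of a column-major H x W matrix at (x, y), 1-based
// pixel coordinates; returns 0 contribution flag via *ok when outside.
static inline double bilin(const double *m, int H, int W, double x, double y) {
  if (x < 1.0) x = 1.0; if (x > W - 1e-9) x = W - 1e-9;
  if (y < 1.0) y = 1.0; if (y > H - 1e-9) y = H - 1e-9;
  int x0 = (int)std::floor(x); if (x0 > W - 1) x0 = W - 1;
  int y0 = (int)std::floor(y); if (y0 > H - 1) y0 = H - 1;
  double fx = x - x0, fy = y - y0;
  const double *c0 = m + (size_t)(x0 - 1) * H + (y0 - 1);
  const double *c1 = c0 + H;
  return (1 - fy) * (1 - fx) * c0[0] + fy * (1 - fx) * c0[1] +
         (1 - fy) * fx * c1[0] + fy * fx * c1[1];
}

// Dominant gradient orientation per keypoint: 36-bin histogram over a
// 15 x 15 sample grid spanning +/- 4.5 sigma, Gaussian weighted (1.5 sigma),
// circularly smoothed twice with a 3-tap box; returns the peak bin centre.
// [[Rcpp::export]]
NumericVector cpp_orientation(NumericMatrix gx, NumericMatrix gy,
                              NumericVector x, NumericVector y, double sigma) {
  const int H = gx.nrow(), W = gx.ncol();
  const int nk = x.size();
  const double *px = REAL(gx), *py = REAL(gy);
  NumericVector out(nk);
  const int G = 15;
  std::vector<double> offs(G);
  for (int i = 0; i < G; ++i) offs[i] = (-4.5 + 9.0 * i / (G - 1)) * sigma;
  const double s2 = 2.0 * (1.5 * sigma) * (1.5 * sigma);
  for (int k = 0; k < nk; ++k) {
    double hist[36] = {0.0};
    for (int a = 0; a < G; ++a) {
      for (int b = 0; b < G; ++b) {
        double dx = offs[a], dy = offs[b];
        double sx = x[k] + dx, sy = y[k] + dy;
        if (sx < 1 || sx > W || sy < 1 || sy > H) continue;
        double vx = bilin(px, H, W, sx, sy);
        double vy = bilin(py, H, W, sx, sy);
        double mag = std::sqrt(vx * vx + vy * vy) *
          std::exp(-(dx * dx + dy * dy) / s2);
        double ang = std::atan2(vy, vx);
        if (ang < 0) ang += 2 * M_PI;
        int bin = (int)(ang / (2 * M_PI) * 36.0); if (bin > 35) bin = 35;
        hist[bin] += mag;
      }
    }
    for (int pass = 0; pass < 2; ++pass) {
      double tmp[36];
      for (int i = 0; i < 36; ++i)
        tmp[i] = (hist[(i + 35) % 36] + hist[i] + hist[(i + 1) % 36]) / 3.0;
      std::copy(tmp, tmp + 36, hist);
    }
    int peak = 0;
    for (int i = 1; i < 36; ++i) if (hist[i] > hist[peak]) peak = i;
    out[k] = (peak + 0.5) * 2 * M_PI / 36.0;
  }
  return out;
}

// 4x4 spatial cells x 8 orientation bins SIFT descriptor from a rotated
// 16x16 sample grid (spacing sigma), bilinear spatial / linear orientation
// soft assignment, Gaussian spatial weight, L2 norm -> 0.2 clip -> renorm,
// quantized to integers in [0, 255]. Keypoints whose window leaves the
// raster get ok = false.
// [[Rcpp::export]]
List cpp_descriptors(NumericMatrix gx, NumericMatrix gy,
                     NumericVector x, NumericVector y, double sigma,
                     NumericVector theta) {
  const int H = gx.nrow(), W = gx.ncol();
  const int nk = x.size();
  const double *pgx = REAL(gx), *pgy = REAL(gy);
  IntegerMatrix D(nk, 128);
  LogicalVector ok(nk);
  for (int k = 0; k < nk; ++k) {
    double ct = std::cos(theta[k]), st = std::sin(theta[k]);
    double acc[128] = {0.0};
    bool inside = true;
    for (int a = 0; a < 16 && inside; ++a) {
      double u = -7.5 + a;
      for (int b = 0; b < 16; ++b) {
        double v = -7.5 + b;
        double sx = x[k] + sigma * (ct * u - st * v);
        double sy = y[k] + sigma * (st * u + ct * v);
        if (sx < 2 || sx > W - 1 || sy < 2 || sy > H - 1) { inside = false; break; }
        double vx = bilin(pgx, H, W, sx, sy);
        double vy = bilin(pgy, H, W, sx, sy);
        double ang = std::atan2(vy, vx) - theta[k];
        ang -= std::floor(ang / (2 * M_PI)) * 2 * M_PI;  // wrap to [0, 2pi)
        double mag = std::sqrt(vx * vx + vy * vy) *
          std::exp(-(u * u + v * v) / (2.0 * 64.0));
        double cu = (u + 8.0) / 4.0 - 0.5;   // [-0.5, 3.5]
        double cv = (v + 8.0) / 4.0 - 0.5;
        double ob = ang / (2 * M_PI) * 8.0;
        int u0 = (int)std::floor(cu), v0 = (int)std::floor(cv),
            o0 = (int)std::floor(ob);
        double fu = cu - u0, fv = cv - v0, fo = ob - o0;
        for (int du = 0; du <= 1; ++du) {
          int uu = u0 + du;
          if (uu < 0 || uu > 3) continue;
          double wu = du ? fu : 1 - fu;
          for (int dv = 0; dv <= 1; ++dv) {
            int vv = v0 + dv;
            if (vv < 0 || vv > 3) continue;
            double wv = dv ? fv : 1 - fv;
            for (int dto = 0; dto <= 1; ++dto) {
              int oo = (o0 + dto) % 8;
              double wo = dto ? fo : 1 - fo;
              acc[(vv * 4 + uu) * 8 + oo] += mag * wu * wv * wo;
            }
          }
        }
      }
    }
    ok[k] = inside;
    double nrm = 0;
    for (int i = 0; i < 128; ++i) nrm += acc[i] * acc[i];
    nrm = std::sqrt(nrm); if (nrm == 0) nrm = 1;
    for (int i = 0; i < 128; ++i) {
      acc[i] /= nrm; if (acc[i] > 0.2) acc[i] = 0.2;
    }
    nrm = 0;
    for (int i = 0; i < 128; ++i) nrm += acc[i] * acc[i];
    nrm = std::sqrt(nrm); if (nrm == 0) nrm = 1;
    for (int i = 0; i < 128; ++i) {
      int q = (int)std::floor(acc[i] / nrm * 512.0);
      D(k, i) = q > 255 ? 255 : q;
    }
  }
  return List::create(_["desc"] = D, _["ok"] = ok);
}
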