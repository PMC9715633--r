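#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// 8-connected component labelling by iterative flood fill.
// Returns an integer matrix: 0 = background, 1..n = component id.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      stack.push_back(y + x * H);
      lab(y, x) = next;
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cy = idx % H, cx = idx / H;
        for (int dx = -1; dx <= 1; ++dx) {
          for (int dy = -1; dy <= 1; ++dy) {
            if (dx == 0 && dy == 0) continue;
            int ny = cy + dy, nx = cx + dx;
            if (ny < 0 || ny >= H || nx < 0 || nx >= W) continue;
            if (mask(ny, nx) && lab(ny, nx) == 0) {
              lab(ny, nx) = next;
              stack.push_back(ny + nx * H);
            }
          }
        }
      }
    }
  }
  return lab;
}

static const double INF = std::numeric_limits<double>::infinity();

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every true pixel to the nearest
// false pixel; pixels outside the image count as background.
// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt(const LogicalMatrix& mask) {
  const int H = mask.nrow() + 2, W = mask.ncol() + 2;  // pad with background
  std::vector<double> g(H * W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) {
      bool inside = (x > 0 && x < W - 1 && y > 0 && y < H - 1);
      g[y + x * H] = (inside && mask(y - 1, x - 1)) ? INF : 0.0;
    }
  // columns
  std::vector<double> f(std::max(H, W)), d(std::max(H, W));
  for (int x = 0; x < W; ++x) {
    for (int y = 0; y < H; ++y) f[y] = g[y + x * H];
    dt1d(f, d, H);
    for (int y = 0; y < H; ++y) g[y + x * H] = d[y];
  }
  // rows
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) f[x] = g[y + x * H];
    dt1d(f, d, W);
    for (int x = 0; x < W; ++x) g[y + x * H] = d[x];
  }
  NumericMatrix out(mask.nrow(), mask.ncol());
  for (int x = 0; x < mask.ncol(); ++x)
    for (int y = 0; y < mask.nrow(); ++y)
      out(y, x) = std::sqrt(g[(y + 1) + (x + 1) * H]);
  return out;
}

static inline int at(const IntegerMatrix& m, int y, int x) {
  if (y < 0 || y >= m.nrow() || x < 0 || x >= m.ncol()) return 0;
  return m(y, x);
}

// Zhang-Suen thinning to a 1-px skeleton.
// [[Rcpp::export(name = ".thin_mask")]]
LogicalMatrix thin_mask(const LogicalMatrix& mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) img(y, x) = mask(y, x) ? 1 : 0;
  bool changed = true;
  std::vector<int> kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int x = 0; x < W; ++x) {
        for (int y = 0; y < H; ++y) {
          if (!img(y, x)) continue;
          int p2 = at(img, y - 1, x),     p3 = at(img, y - 1, x + 1);
          int p4 = at(img, y, x + 1),     p5 = at(img, y + 1, x + 1);
          int p6 = at(img, y + 1, x),     p7 = at(img, y + 1, x - 1);
          int p8 = at(img, y, x - 1),     p9 = at(img, y - 1, x - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(y + x * H);
        }
      }
      if (!kill.empty()) changed = true;
      for (int idx : kill) img(idx % H, idx / H) = 0;
    }
  }
  LogicalMatrix out(H, W);
  for (int x = 0; x < W; ++x)
    for (int y = 0; y < H; ++y) out(y, x) = img(y, x) == 1;
  return out;
}

// Stamp anti-aliased disks of radius r at (xs, ys) (1-based, fractional)
// onto canvas, accumulating coverage as max(old, clamp(r + 0.5 - dist)).
// [[Rcpp::export(name = ".stamp_disks")]]
NumericMatrix stamp_disks(NumericMatrix canvas, const NumericVector& xs,
                          const NumericVector& ys, double r) {
  const int H = canvas.nrow(), W = canvas.ncol();
  const int rad = (int)std::ceil(r + 1.0);
  for (int i = 0; i < xs.size(); ++i) {
    double cx = xs[i] - 1.0, cy = ys[i] - 1.0;  // 0-based centres
    int x0 = std::max(0, (int)std::floor(cx) - rad);
    int x1 = std::min(W - 1, (int)std::ceil(cx) + rad);
    int y0 = std::max(0, (int)std::floor(cy) - rad);
    int y1 = std::min(H - 1, (int)std::ceil(cy) + rad);
    for (int x = x0; x <= x1; ++x) {
      for (int y = y0; y <= y1; ++y) {
        double dx = x - cx, dy = y - cy;
        double d = std::sqrt(dx * dx + dy * dy);
        double cov = r + 0.5 - d;
        if (cov <= 0) continue;
        if (cov > 1) cov = 1;
        if (cov > canvas(y, x)) canvas(y, x) = cov;
      }
    }
  }
  return canvas;
}
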