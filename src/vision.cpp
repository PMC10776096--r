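#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <random>
using namespace Rcpp;

// Matrices are indexed (row = y, col = x); pixel coordinates reported to R are
// 0-based with origin at the image top-left, y increasing downward.

static inline double px(const NumericMatrix& m, int y, int x) {
  // reflect-101 border handling
  int h = m.nrow(), w = m.ncol();
  if (y < 0) y = -y; else if (y >= h) y = 2 * h - 2 - y;
  if (x < 0) x = -x; else if (x >= w) x = 2 * w - 2 - x;
  return m(y, x);
}

// Canny edge detector: 3x3 Sobel, L1 gradient magnitude, non-maximum
// suppression along the quantized gradient direction, hysteresis between
// `low` and `high` thresholds (8-connectivity).
// [[Rcpp::export]]
LogicalMatrix canny_cpp(NumericMatrix img, double low, double high) {
  int h = img.nrow(), w = img.ncol();
  std::vector<double> gx(h * w), gy(h * w), mag(h * w);
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double a = px(img, y - 1, x - 1), b = px(img, y - 1, x), c = px(img, y - 1, x + 1);
      double d = px(img, y, x - 1), f = px(img, y, x + 1);
      double g = px(img, y + 1, x - 1), hh = px(img, y + 1, x), i = px(img, y + 1, x + 1);
      double sx = (c + 2 * f + i) - (a + 2 * d + g);
      double sy = (g + 2 * hh + i) - (a + 2 * b + c);
      gx[y * w + x] = sx;
      gy[y * w + x] = sy;
      mag[y * w + x] = std::fabs(sx) + std::fabs(sy);
    }
  }
  // 0 = no edge, 1 = weak candidate, 2 = strong
  std::vector<unsigned char> state(h * w, 0);
  const double TG22 = 0.4142135623730951; // tan(22.5 deg)
  const double TG67 = 2.414213562373095;  // tan(67.5 deg)
  for (int y = 0; y < h; ++y) {
    for (int x = 0; x < w; ++x) {
      double m = mag[y * w + x];
      if (m <= low) continue;
      double ax = std::fabs(gx[y * w + x]), ay = std::fabs(gy[y * w + x]);
      double m1, m2;
      if (ay < TG22 * ax) { // gradient ~horizontal -> edge vertical, compare x neighbours
        m1 = (x > 0) ? mag[y * w + x - 1] : 0;
        m2 = (x < w - 1) ? mag[y * w + x + 1] : 0;
      } else if (ay > TG67 * ax) { // gradient ~vertical, compare y neighbours
        m1 = (y > 0) ? mag[(y - 1) * w + x] : 0;
        m2 = (y < h - 1) ? mag[(y + 1) * w + x] : 0;
      } else {
        int s = (gx[y * w + x] * gy[y * w + x] > 0) ? 1 : -1;
        int y1 = y - s, y2 = y + s;
        m1 = (y1 >= 0 && y1 < h && x > 0) ? mag[y1 * w + x - 1] : 0;
        m2 = (y2 >= 0 && y2 < h && x < w - 1) ? mag[y2 * w + x + 1] : 0;
      }
      if (m > m1 && m >= m2)
        state[y * w + x] = (m > high) ? 2 : 1;
    }
  }
  // hysteresis: BFS from strong pixels through weak ones
  LogicalMatrix out(h, w);
  std::vector<int> stack;
  stack.reserve(h * w / 8);
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (state[y * w + x] == 2) { out(y, x) = true; stack.push_back(y * w + x); }
  while (!stack.empty()) {
    int p = stack.back(); stack.pop_back();
    int y = p / w, x = p % w;
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int yy = y + dy, xx = x + dx;
        if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
        if (state[yy * w + xx] == 1 && !out(yy, xx)) {
          out(yy, xx) = true;
          stack.push_back(yy * w + xx);
        }
      }
  }
  return out;
}

// Probabilistic Hough line transform (randomized point selection, incremental
// voting, line walking with gap tolerance, vote removal for accepted lines).
// Deterministic for a fixed `seed`. Returns an n x 4 integer matrix with rows
// (x1, y1, x2, y2) in 0-based pixel coordinates.
// [[Rcpp::export]]
IntegerMatrix hough_prob_cpp(LogicalMatrix edges, int threshold,
                             double min_len, double max_gap, int seed,
                             int theta_res_deg = 1) {
  int h = edges.nrow(), w = edges.ncol();
  int numangle = 180 / theta_res_deg;
  int rmax = (int)std::ceil(std::sqrt((double)w * w + (double)h * h));
  int numrho = 2 * rmax + 1;
  std::vector<double> tcos(numangle), tsin(numangle);
  for (int k = 0; k < numangle; ++k) {
    double th = k * theta_res_deg * M_PI / 180.0;
    tcos[k] = std::cos(th);
    tsin[k] = std::sin(th);
  }
  std::vector<int> accum((size_t)numangle * numrho, 0);
  std::vector<unsigned char> mask(h * w, 0), voted(h * w, 0);
  std::vector<std::pair<int,int>> pts; // (x, y)
  for (int y = 0; y < h; ++y)
    for (int x = 0; x < w; ++x)
      if (edges(y, x)) { mask[y * w + x] = 1; pts.push_back(std::make_pair(x, y)); }

  std::mt19937 rng((unsigned)seed);
  std::vector<int> out; // x1,y1,x2,y2 quadruples
  size_t count = pts.size();
  double gap_lim = max_gap;

  while (count > 0) {
    size_t idx = rng() % count;
    int x0 = pts[idx].first, y0 = pts[idx].second;
    pts[idx] = pts[--count];
    if (!mask[y0 * w + x0]) continue;
    // vote
    int best = 0, best_k = 0;
    for (int k = 0; k < numangle; ++k) {
      int r = (int)std::lround(x0 * tcos[k] + y0 * tsin[k]) + rmax;
      int v = ++accum[(size_t)k * numrho + r];
      if (v > best) { best = v; best_k = k; }
    }
    voted[y0 * w + x0] = 1;
    if (best < threshold) continue;

    // walk along the line direction (perpendicular to the normal at best_k)
    double dx = -tsin[best_k], dy = tcos[best_k];
    if (std::fabs(dx) >= std::fabs(dy)) {
      double s = std::fabs(dx);
      dy /= s; dx = (dx > 0) ? 1.0 : -1.0;
    } else {
      double s = std::fabs(dy);
      dx /= s; dy = (dy > 0) ? 1.0 : -1.0;
    }
    int ex[2] = {x0, x0}, ey[2] = {y0, y0};
    for (int dir = 0; dir < 2; ++dir) {
      double sx = (dir == 0) ? dx : -dx, sy = (dir == 0) ? dy : -dy;
      double cx = x0, cy = y0;
      double gap = 0;
      for (;;) {
        cx += sx; cy += sy;
        int ix = (int)std::lround(cx), iy = (int)std::lround(cy);
        if (ix < 0 || ix >= w || iy < 0 || iy >= h) break;
        if (mask[iy * w + ix]) {
          gap = 0;
          ex[dir] = ix; ey[dir] = iy;
        } else {
          gap += 1;
          if (gap > gap_lim) break;
        }
      }
    }
    double len = std::sqrt((double)(ex[0] - ex[1]) * (ex[0] - ex[1]) +
                           (double)(ey[0] - ey[1]) * (ey[0] - ey[1]));
    bool good = len >= min_len;
    if (!good) continue;

    // clear the line's pixels and remove their votes
    for (int dir = 0; dir < 2; ++dir) {
      double sx = (dir == 0) ? dx : -dx, sy = (dir == 0) ? dy : -dy;
      double cx = x0, cy = y0;
      for (;;) {
        int ix = (int)std::lround(cx), iy = (int)std::lround(cy);
        if (mask[iy * w + ix]) {
          if (voted[iy * w + ix]) {
            for (int k = 0; k < numangle; ++k) {
              int r = (int)std::lround(ix * tcos[k] + iy * tsin[k]) + rmax;
              --accum[(size_t)k * numrho + r];
            }
            voted[iy * w + ix] = 0;
          }
          mask[iy * w + ix] = 0;
        }
        if (ix == ex[dir] && iy == ey[dir]) break;
        cx += sx; cy += sy;
        int nx = (int)std::lround(cx), ny = (int)std::lround(cy);
        if (nx < 0 || nx >= w || ny < 0 || ny >= h) break;
      }
    }
    out.push_back(ex[0]); out.push_back(ey[0]);
    out.push_back(ex[1]); out.push_back(ey[1]);
  }

  int n = (int)out.size() / 4;
  IntegerMatrix segs(n, 4);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 4; ++j)
      segs(i, j) = out[i * 4 + j];
  colnames(segs) = CharacterVector::create("x1", "y1", "x2", "y2");
  return segs;
}

// Normalized cross-correlation of a template against every valid position.
// Returns an (h-th+1) x (w-tw+1) matrix of scores in [-1, 1]; positions where
// the image patch has zero variance score 0.
// [[Rcpp::export]]
NumericMatrix ncc_match_cpp(NumericMatrix img, NumericMatrix tpl) {
  int h = img.nrow(), w = img.ncol();
  int th = tpl.nrow(), tw = tpl.ncol();
  if (th > h || tw > w) stop("template larger than image");
  int n = th * tw;
  double tmean = 0;
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) tmean += tpl(i, j);
  tmean /= n;
  double tvar = 0;
  std::vector<double> tz(n);
  for (int j = 0; j < tw; ++j)
    for (int i = 0; i < th; ++i) {
      double z = tpl(i, j) - tmean;
      tz[j * th + i] = z;
      tvar += z * z;
    }
  if (tvar <= 0) stop("template has zero variance");
  NumericMatrix out(h - th + 1, w - tw + 1);
  for (int y = 0; y <= h - th; ++y) {
    for (int x = 0; x <= w - tw; ++x) {
      double s = 0, s2 = 0, cross = 0;
      for (int j = 0; j < tw; ++j)
        for (int i = 0; i < th; ++i) {
          double v = img(y + i, x + j);
          s += v; s2 += v * v;
          cross += v * tz[j * th + i];
        }
      double ivar = s2 - s * s / n;
      out(y, x) = (ivar > 1e-12) ? cross / std::sqrt(ivar * tvar) : 0.0;
    }
  }
  return out;
}
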