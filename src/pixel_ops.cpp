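#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Sliding-window median with replicate border padding, via a running 256-bin
// histogram per row. Works for any window side >= 1, including even sides:
// the output pixel sits at offset ((side-1)/2, (side-1)/2) within the window,
// and the lower median (the ceil(n/2)-th smallest of n values) is returned,
// which for odd n is the ordinary median.
// [[Rcpp::export]]
IntegerMatrix median_filter_cpp(const IntegerMatrix& img, int side) {
  const int H = img.nrow(), W = img.ncol();
  const int lo = (side - 1) / 2, hi = side - 1 - lo;
  const int n = side * side, k = (n + 1) / 2;
  IntegerMatrix out(H, W);
  std::vector<int> hist(256);

  for (int r = 0; r < H; ++r) {
    std::fill(hist.begin(), hist.end(), 0);
    for (int dr = -lo; dr <= hi; ++dr) {
      int rr = std::min(std::max(r + dr, 0), H - 1);
      for (int dc = -lo; dc <= hi; ++dc) {
        int cc = std::min(std::max(dc, 0), W - 1);
        ++hist[img(rr, cc)];
      }
    }
    for (int c = 0; c < W; ++c) {
      if (c > 0) {
        int c_out = std::min(std::max(c - 1 - lo, 0), W - 1);
        int c_in  = std::min(std::max(c + hi, 0), W - 1);
        for (int dr = -lo; dr <= hi; ++dr) {
          int rr = std::min(std::max(r + dr, 0), H - 1);
          --hist[img(rr, c_out)];
          ++hist[img(rr, c_in)];
        }
      }
      int cum = 0, med = 255;
      for (int v = 0; v < 256; ++v) {
        cum += hist[v];
        if (cum >= k) { med = v; break; }
      }
      out(r, c) = med;
    }
  }
  return out;
}

static inline int n_neighbours(int connectivity) {
  return connectivity == 8 ? 8 : 4;
}

static const int DR8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
static const int DC8[8] = {0, 0, -1, 1, -1, 1, -1, 1};

// Breadth-first region growing with seed-fixed similarity: a pixel joins the
// region iff it is connected to the seed through pixels whose intensity
// differs from the seed intensity by at most `tol`. Aborts (overflow = true)
// once the region exceeds max_frac of the image area.
// [[Rcpp::export]]
List region_grow_cpp(const IntegerMatrix& img, int seed_r, int seed_c,
                     int tol, int connectivity, double max_frac) {
  const int H = img.nrow(), W = img.ncol();
  const int nn = n_neighbours(connectivity);
  const double total = (double)H * (double)W;
  LogicalMatrix mask(H, W);
  std::vector<int> queue;
  queue.reserve(1024);

  const int sv = img(seed_r, seed_c);
  mask(seed_r, seed_c) = true;
  queue.push_back(seed_r + seed_c * H);
  R_xlen_t head = 0;
  int count = 1;
  bool overflow = false;

  while (head < (R_xlen_t)queue.size()) {
    int idx = queue[head++];
    int r = idx % H, c = idx / H;
    for (int j = 0; j < nn; ++j) {
      int rr = r + DR8[j], cc = c + DC8[j];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      if (mask(rr, cc)) continue;
      if (std::abs(img(rr, cc) - sv) > tol) continue;
      mask(rr, cc) = true;
      queue.push_back(rr + cc * H);
      ++count;
      if ((double)count / total > max_frac) { overflow = true; break; }
    }
    if (overflow) break;
  }
  return List::create(_["mask"] = mask,
                      _["overflow"] = overflow,
                      _["fraction"] = (double)count / total);
}

// Connected-component labeling of a logical mask (labels 1..n in order of
// first row-major encounter; 0 = background).
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(const LogicalMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  const int nn = n_neighbours(connectivity);
  IntegerMatrix lab(H, W);
  std::vector<int> queue;
  int next = 0;

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      queue.clear();
      queue.push_back(r + c * H);
      size_t head = 0;
      while (head < queue.size()) {
        int idx = queue[head++];
        int pr = idx % H, pc = idx / H;
        for (int j = 0; j < nn; ++j) {
          int rr = pr + DR8[j], cc = pc + DC8[j];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (!mask(rr, cc) || lab(rr, cc)) continue;
          lab(rr, cc) = next;
          queue.push_back(rr + cc * H);
        }
      }
    }
  }
  return lab;
}
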