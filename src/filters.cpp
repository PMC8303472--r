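#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <deque>
using namespace Rcpp;

// Median filter with replicate (clamp-to-edge) border padding.
// k must be odd; output pixel = median of the k x k neighbourhood.
// Values are 8-bit intensities, so a counting median over 256 bins is exact.
// [[Rcpp::export(name = ".median_filter_cpp")]]
IntegerMatrix median_filter_cpp(IntegerMatrix img, int k) {
  const int nr = img.nrow(), nc = img.ncol(), h = k / 2;
  const int win = k * k, mid = win / 2; // 0-based index of the median element
  IntegerMatrix out(nr, nc);
  std::vector<int> hist(256);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      std::fill(hist.begin(), hist.end(), 0);
      for (int dj = -h; dj <= h; ++dj) {
        int cj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = -h; di <= h; ++di) {
          int ci = std::min(std::max(i + di, 0), nr - 1);
          ++hist[img(ci, cj)];
        }
      }
      int acc = 0, v = 0;
      for (v = 0; v < 256; ++v) {
        acc += hist[v];
        if (acc > mid) break;
      }
      out(i, j) = v;
    }
  }
  return out;
}

// Binary dilation with a k x k square structuring element, repeated iter times.
// Any value > 0 counts as foreground; output is {0, 255}.
// [[Rcpp::export(name = ".dilate_cpp")]]
IntegerMatrix dilate_cpp(IntegerMatrix mask, int k, int iter) {
  const int nr = mask.nrow(), nc = mask.ncol(), h = k / 2;
  IntegerMatrix cur(nr, nc), nxt(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      cur(i, j) = mask(i, j) > 0 ? 255 : 0;
  for (int it = 0; it < iter; ++it) {
    for (int j = 0; j < nc; ++j) {
      for (int i = 0; i < nr; ++i) {
        int val = 0;
        for (int dj = -h; dj <= h && !val; ++dj) {
          int cj = j + dj;
          if (cj < 0 || cj >= nc) continue;
          for (int di = -h; di <= h; ++di) {
            int ci = i + di;
            if (ci < 0 || ci >= nr) continue;
            if (cur(ci, cj) > 0) { val = 255; break; }
          }
        }
        nxt(i, j) = val;
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}

// 8-connected component labelling of a binary image (> 0 is foreground).
// Labels are 1..n in order of first (column-major) encounter; background 0.
// [[Rcpp::export(name = ".label8_cpp")]]
IntegerMatrix label8_cpp(IntegerMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::deque<std::pair<int, int> > q;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (mask(i, j) <= 0 || lab(i, j) != 0) continue;
      lab(i, j) = ++next;
      q.push_back(std::make_pair(i, j));
      while (!q.empty()) {
        int ci = q.front().first, cj = q.front().second;
        q.pop_front();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || ni >= nr || nj < 0 || nj >= nc) continue;
            if (mask(ni, nj) > 0 && lab(ni, nj) == 0) {
              lab(ni, nj) = next;
              q.push_back(std::make_pair(ni, nj));
            }
          }
        }
      }
    }
  }
  return lab;
}
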