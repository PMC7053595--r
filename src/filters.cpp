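#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// Reflect an index into [0, n) using half-sample symmetry:
// (d c b a | a b c d), the convention used by most rank-filter code.
static inline int reflect_index(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - 1 - i;
  }
  return i;
}

//' Disk-shaped median filter with reflective border handling
//'
//' @param x numeric matrix
//' @param radius integer radius of the circular structuring element; a pixel
//'   (dr, dc) belongs to the disk when dr^2 + dc^2 <= radius^2
//' @return filtered matrix of the same shape
//' @keywords internal
// [[Rcpp::export]]
NumericMatrix disk_median_cpp(NumericMatrix x, int radius) {
  const int nr = x.nrow(), nc = x.ncol();
  // disk offsets (symmetric about the centre => odd count => exact median)
  std::vector<int> dr, dc;
  const int r2 = radius * radius;
  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j)
      if (i * i + j * j <= r2) { dr.push_back(i); dc.push_back(j); }
  const int k = (int)dr.size();
  const int mid = k / 2;  // k is odd

  NumericMatrix out(nr, nc);

  // Fast path: integer-valued images in [0, 65535] use Huang's sliding
  // two-level histogram (the common case for 8/16-bit microscopy data).
  bool integral = true;
  double vmax = 0;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    double v = x[i];
    if (v != std::floor(v) || v < 0) { integral = false; break; }
    if (v > vmax) vmax = v;
  }
  if (integral && vmax <= 65535.0) {
    // reflect-pad so the sliding window never tests borders
    const int pr = nr + 2 * radius, pc = nc + 2 * radius;
    std::vector<unsigned short> pad((size_t)pr * pc);
    for (int c = 0; c < pc; ++c) {
      int cc = reflect_index(c - radius, nc);
      for (int r = 0; r < pr; ++r) {
        int rr = reflect_index(r - radius, nr);
        pad[(size_t)c * pr + r] = (unsigned short)x(rr, cc);
      }
    }
    // per-row-offset disk half-width
    std::vector<int> halfw(2 * radius + 1);
    for (int d = -radius; d <= radius; ++d)
      halfw[d + radius] = (int)std::floor(std::sqrt((double)(r2 - d * d)));

    std::vector<int> coarse(256), fine(65536);
    for (int r = 0; r < nr; ++r) {
      std::fill(coarse.begin(), coarse.end(), 0);
      std::fill(fine.begin(), fine.end(), 0);
      // initialise window at output column 0 (padded centre column = radius)
      for (int d = -radius; d <= radius; ++d) {
        const unsigned short *col0 = &pad[0];
        int rr = r + radius + d;
        for (int c = radius - halfw[d + radius]; c <= radius + halfw[d + radius]; ++c) {
          unsigned short v = pad[(size_t)c * pr + rr];
          ++coarse[v >> 8]; ++fine[v];
        }
        (void)col0;
      }
      for (int c = 0; c < nc; ++c) {
        if (c > 0) {
          // slide: centre moved from c-1 to c (padded centre column c+radius)
          for (int d = -radius; d <= radius; ++d) {
            int rr = r + radius + d, w = halfw[d + radius];
            unsigned short vout = pad[(size_t)(c - 1 + radius - w) * pr + rr];
            unsigned short vin = pad[(size_t)(c + radius + w) * pr + rr];
            --coarse[vout >> 8]; --fine[vout];
            ++coarse[vin >> 8]; ++fine[vin];
          }
        }
        // k-th smallest (k = mid, 0-based) via coarse then fine scan
        int need = mid + 1, acc = 0, bucket = 0;
        while (acc + coarse[bucket] < need) { acc += coarse[bucket]; ++bucket; }
        int v = bucket << 8;
        while (acc + fine[v] < need) { acc += fine[v]; ++v; }
        out(r, c) = v;
      }
    }
    return out;
  }

  // generic path: gather + nth_element per pixel
  std::vector<double> buf(k);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      for (int t = 0; t < k; ++t) {
        int rr = reflect_index(r + dr[t], nr);
        int cc = reflect_index(c + dc[t], nc);
        buf[t] = x(rr, cc);
      }
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      out(r, c) = buf[mid];
    }
  }
  return out;
}

//' Connected-component labelling of a binary mask
//'
//' Labels are assigned in raster-scan order (column-major storage, but the
//' scan runs row by row) of each component's first-encountered pixel, so the
//' numbering is reproducible across runs.
//'
//' @param mask logical matrix
//' @param connectivity 4 or 8
//' @return integer matrix, 0 = background, 1..n = component ids
//' @keywords internal
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::fill(lab.begin(), lab.end(), 0);

  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int *dr = (connectivity == 8) ? dr8 : dr4;
  const int *dc = (connectivity == 8) ? dc8 : dc4;
  const int nn = (connectivity == 8) ? 8 : 4;

  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int t = 0; t < nn; ++t) {
          int rr = p.first + dr[t], cc = p.second + dc[t];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}
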