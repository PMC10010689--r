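#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// --- conditional disc-median filter ("remove outliers") -------------------
//
// A pixel is replaced by the median of the disc of given radius centred on
// it only when its value exceeds that median by more than `threshold`; the
// disc is truncated at the image border. Median of an even-sized
// neighbourhood is the mean of the two central order statistics, matching
// stats::median. Integer-valued images (the 8/16-bit case) use an exact
// sliding two-level histogram (Huang's algorithm); anything else falls back
// to a direct per-pixel nth_element.

static NumericMatrix remove_outliers_naive(const NumericMatrix& img,
                                           int radius, double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  std::vector<int> off_r, off_c;
  const double r2 = (double)radius * radius;
  for (int dr = -radius; dr <= radius; ++dr)
    for (int dc = -radius; dc <= radius; ++dc)
      if ((double)dr * dr + (double)dc * dc <= r2) {
        off_r.push_back(dr);
        off_c.push_back(dc);
      }
  const int ndisc = (int)off_r.size();
  NumericMatrix out(nr, nc);
  std::vector<double> buf(ndisc);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int n = 0;
      for (int k = 0; k < ndisc; ++k) {
        const int rr = r + off_r[k], cc = c + off_c[k];
        if (rr >= 0 && rr < nr && cc >= 0 && cc < nc) buf[n++] = img(rr, cc);
      }
      const int mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.begin() + n);
      double med = buf[mid];
      if (n % 2 == 0) {
        const double lo = *std::max_element(buf.begin(), buf.begin() + mid);
        med = 0.5 * (med + lo);
      }
      const double v = img(r, c);
      out(r, c) = (v - med > threshold) ? med : v;
    }
  }
  return out;
}

struct SlidingHist {
  std::vector<int> coarse; // 256 bins of 256 values
  std::vector<int> fine;   // 65536 bins
  int n;
  SlidingHist() : coarse(256, 0), fine(65536, 0), n(0) {}
  void reset() {
    std::fill(coarse.begin(), coarse.end(), 0);
    std::fill(fine.begin(), fine.end(), 0);
    n = 0;
  }
  inline void add(int v) { ++fine[v]; ++coarse[v >> 8]; ++n; }
  inline void remove(int v) { --fine[v]; --coarse[v >> 8]; --n; }
  // k-th smallest, 1-based
  inline int kth(int k) const {
    int c = 0;
    int acc = 0;
    for (;; ++c) {
      if (acc + coarse[c] >= k) break;
      acc += coarse[c];
    }
    int f = c << 8;
    for (;; ++f) {
      acc += fine[f];
      if (acc >= k) return f;
    }
  }
  inline double median() const {
    const int k = n / 2;
    if (n % 2 == 1) return (double)kth(k + 1);
    const int hi = kth(k + 1);
    const int lo = kth(k);
    return 0.5 * (hi + lo);
  }
};

static NumericMatrix remove_outliers_hist(const NumericMatrix& img,
                                          int radius, double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  // half-width of the disc at each row offset
  std::vector<int> xe(2 * radius + 1);
  for (int dr = -radius; dr <= radius; ++dr) {
    xe[dr + radius] =
        (int)std::floor(std::sqrt((double)radius * radius - (double)dr * dr));
  }
  NumericMatrix out(nr, nc);
  SlidingHist h;
  std::vector<int> iv(nr * (size_t)nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      iv[r + (size_t)c * nr] = (int)img(r, c);
  for (int r = 0; r < nr; ++r) {
    h.reset();
    // build the disc around (r, 0)
    for (int dr = -radius; dr <= radius; ++dr) {
      const int rr = r + dr;
      if (rr < 0 || rr >= nr) continue;
      const int w = xe[dr + radius];
      for (int cc = 0; cc <= std::min(w, nc - 1); ++cc)
        h.add(iv[rr + (size_t)cc * nr]);
    }
    for (int c = 0; c < nc; ++c) {
      if (c > 0) {
        // slide the disc one column to the right
        for (int dr = -radius; dr <= radius; ++dr) {
          const int rr = r + dr;
          if (rr < 0 || rr >= nr) continue;
          const int w = xe[dr + radius];
          const int c_out = c - 1 - w;
          const int c_in = c + w;
          if (c_out >= 0) h.remove(iv[rr + (size_t)c_out * nr]);
          if (c_in < nc) h.add(iv[rr + (size_t)c_in * nr]);
        }
      }
      const double med = h.median();
      const double v = img(r, c);
      out(r, c) = (v - med > threshold) ? med : v;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix remove_outliers_disc_cpp(NumericMatrix img, int radius,
                                       double threshold) {
  const int nr = img.nrow(), nc = img.ncol();
  if (radius < 1) stop("radius must be >= 1");
  if (radius >= nr && radius >= nc) stop("radius exceeds both image dimensions");
  bool integral = true;
  for (int i = 0; i < nr * nc; ++i) {
    const double v = img[i];
    if (v < 0 || v > 65535 || v != std::floor(v)) {
      integral = false;
      break;
    }
  }
  return integral ? remove_outliers_hist(img, radius, threshold)
                  : remove_outliers_naive(img, radius, threshold);
}

// 8-connected component labelling of a logical mask by iterative flood fill.
// Labels are consecutive positive integers assigned in column-major scan
// order of each component's first-encountered pixel, so the result is
// deterministic.
// [[Rcpp::export]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc); // zero-initialised
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(r + c * nr);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back();
        stack.pop_back();
        const int pr = idx % nr, pc = idx / nr;
        for (int dr = -1; dr <= 1; ++dr) {
          for (int dc = -1; dc <= 1; ++dc) {
            if (dr == 0 && dc == 0) continue;
            const int rr = pr + dr, cc = pc + dc;
            if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
            if (mask(rr, cc) && lab(rr, cc) == 0) {
              lab(rr, cc) = next;
              stack.push_back(rr + cc * nr);
            }
          }
        }
      }
    }
  }
  return lab;
}
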