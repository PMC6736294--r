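#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment with affine gaps.
// A gap run of length L costs gap_open + L * gap_extend (Biostrings
// convention). The band is a corridor of half-width `band` around the main
// diagonal, automatically widened by the sequence length difference so the
// corridor always reaches (n, m). With band >= max(n, m) this is the full DP.
// Tie-breaking prefers diagonal, then vertical (gap in b), then horizontal.
// [[Rcpp::export]]
List nw_align_cpp(std::string a, std::string b, double match, double mismatch,
                  double gap_open, double gap_extend, int band) {
  const int n = (int)a.size(), m = (int)b.size();
  if (band < 0) stop("band must be >= 0");
  const double NEG = -1e18;
  const double go = gap_open, ge = gap_extend;

  if (n == 0 || m == 0) {
    std::string ga(m, '-'), gb(n, '-');
    std::string a1 = (n == 0) ? ga : a;
    std::string a2 = (n == 0) ? b : gb;
    int cols = std::max(n, m);
    double sc = (cols == 0) ? 0.0 : -(go + cols * ge);
    return List::create(_["score"] = sc, _["aligned1"] = a1,
                        _["aligned2"] = a2, _["matches"] = 0,
                        _["columns"] = cols, _["gap_columns"] = cols);
  }

  int band_l = band + std::max(0, n - m);
  int band_r = band + std::max(0, m - n);
  if (band_l > n) band_l = n;
  if (band_r > m) band_r = m;
  const int W = band_l + band_r + 1;
  if ((double)3 * (n + 1) * W > 6e8)
    stop("alignment band too wide for sequence length");

  std::vector<double> Mp(W, NEG), Xp(W, NEG), Yp(W, NEG);
  std::vector<double> Mc(W, NEG), Xc(W, NEG), Yc(W, NEG);
  // traceback: predecessor state per (state, i, offset); 0=M 1=X 2=Y
  // 254 = alignment start, 255 = unreachable
  std::vector<uint8_t> tb((size_t)3 * (n + 1) * W, 255);
  auto TB = [&](int st, int i, int off) -> uint8_t & {
    return tb[((size_t)st * (n + 1) + i) * W + off];
  };
  auto lo_of = [&](int i) { return std::max(0, i - band_l); };
  auto hi_of = [&](int i) { return std::min(m, i + band_r); };

  // row 0
  {
    int hi = hi_of(0);
    for (int j = 0; j <= hi; ++j) {
      if (j == 0) {
        Mp[0] = 0.0;
        TB(0, 0, 0) = 254;
      } else {
        Yp[j] = -(go + j * ge);
        TB(2, 0, j) = (j == 1) ? 0 : 2;
      }
    }
  }

  int lo_prev = 0, hi_prev = hi_of(0);
  for (int i = 1; i <= n; ++i) {
    const int lo = lo_of(i), hi = hi_of(i);
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Xc.begin(), Xc.end(), NEG);
    std::fill(Yc.begin(), Yc.end(), NEG);
    for (int j = lo; j <= hi; ++j) {
      const int off = j - lo;
      // M: diagonal from (i-1, j-1)
      if (j >= 1 && j - 1 >= lo_prev && j - 1 <= hi_prev) {
        const int op = j - 1 - lo_prev;
        double best = Mp[op]; uint8_t arg = 0;
        if (Xp[op] > best) { best = Xp[op]; arg = 1; }
        if (Yp[op] > best) { best = Yp[op]; arg = 2; }
        if (best > NEG / 2) {
          double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
          Mc[off] = best + s;
          TB(0, i, off) = arg;
        }
      }
      // X: vertical from (i-1, j), consumes a[i-1]
      if (j >= lo_prev && j <= hi_prev) {
        const int op = j - lo_prev;
        double cm = Mp[op] - go - ge, cx = Xp[op] - ge, cy = Yp[op] - go - ge;
        double best = cm; uint8_t arg = 0;
        if (cx > best) { best = cx; arg = 1; }
        if (cy > best) { best = cy; arg = 2; }
        if (best > NEG / 2) { Xc[off] = best; TB(1, i, off) = arg; }
      }
      // Y: horizontal from (i, j-1), consumes b[j-1]
      if (j >= 1 && j - 1 >= lo) {
        const int ol = off - 1;
        double cm = Mc[ol] - go - ge, cx = Xc[ol] - go - ge, cy = Yc[ol] - ge;
        double best = cm; uint8_t arg = 0;
        if (cx > best) { best = cx; arg = 1; }
        if (cy > best) { best = cy; arg = 2; }
        if (best > NEG / 2) { Yc[off] = best; TB(2, i, off) = arg; }
      }
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
    lo_prev = lo; hi_prev = hi;
  }

  const int off_end = m - lo_of(n);
  double best = Mp[off_end]; int state = 0;
  if (Xp[off_end] > best) { best = Xp[off_end]; state = 1; }
  if (Yp[off_end] > best) { best = Yp[off_end]; state = 2; }
  if (best < NEG / 2) stop("no alignment within band");

  std::string a1, a2;
  a1.reserve(n + m); a2.reserve(n + m);
  int i = n, j = m;
  while (!(i == 0 && j == 0)) {
    const int off = j - lo_of(i);
    uint8_t prev = TB(state, i, off);
    if (prev == 255) stop("internal traceback error");
    if (state == 0) {
      a1.push_back(a[i - 1]); a2.push_back(b[j - 1]); --i; --j;
    } else if (state == 1) {
      a1.push_back(a[i - 1]); a2.push_back('-'); --i;
    } else {
      a1.push_back('-'); a2.push_back(b[j - 1]); --j;
    }
    if (prev == 254) break;
    state = prev;
  }
  std::reverse(a1.begin(), a1.end());
  std::reverse(a2.begin(), a2.end());

  int matches = 0, gap_cols = 0;
  for (size_t c = 0; c < a1.size(); ++c) {
    if (a1[c] == '-' || a2[c] == '-') ++gap_cols;
    else if (a1[c] == a2[c]) ++matches;
  }
  return List::create(_["score"] = best, _["aligned1"] = a1,
                      _["aligned2"] = a2, _["matches"] = matches,
                      _["columns"] = (int)a1.size(),
                      _["gap_columns"] = gap_cols);
}
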