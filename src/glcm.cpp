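#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Eight Haralick-style summaries of a gray-level co-occurrence matrix given
// as an aggregated list of (i, j, count) cells. Levels are 0-based.
static void glcm_stats(const std::vector<int>& ii, const std::vector<int>& jj,
                       const std::vector<double>& cnt, int levels,
                       double* out /* 8 doubles */) {
  double total = 0.0;
  for (double c : cnt) total += c;
  double con = 0, dis = 0, hom = 0, asm_ = 0, ent = 0;
  std::vector<double> pi(levels, 0.0), pj(levels, 0.0);
  size_t n = cnt.size();
  for (size_t k = 0; k < n; ++k) {
    double p = cnt[k] / total;
    int d = ii[k] - jj[k];
    con += p * d * d;
    dis += p * std::abs(d);
    hom += p / (1.0 + d * d);
    asm_ += p * p;
    if (p > 0) ent -= p * std::log(p);
    pi[ii[k]] += p;
    pj[jj[k]] += p;
  }
  double mui = 0, muj = 0;
  for (int l = 0; l < levels; ++l) { mui += l * pi[l]; muj += l * pj[l]; }
  double vari = 0, varj = 0;
  for (int l = 0; l < levels; ++l) {
    vari += (l - mui) * (l - mui) * pi[l];
    varj += (l - muj) * (l - muj) * pj[l];
  }
  double cor = 0.0;
  double denom = std::sqrt(vari) * std::sqrt(varj);
  if (denom > 0) {
    double cov = 0;
    for (size_t k = 0; k < n; ++k) {
      double p = cnt[k] / total;
      cov += (ii[k] - mui) * (jj[k] - muj) * p;
    }
    cor = cov / denom;
  }
  // marginal mean/variance of the reference pixel (row marginal)
  out[0] = con; out[1] = cor; out[2] = dis; out[3] = ent;
  out[4] = hom; out[5] = mui; out[6] = asm_; out[7] = vari;
}

// Accumulate co-occurrence pairs of quantized image `q` (NA-coded as -1)
// restricted to rows [r0,r1] x cols [c0,c1], over the given offsets
// (symmetric: both directions counted).
static bool collect_pairs(const IntegerMatrix& q, int r0, int r1, int c0,
                          int c1, const IntegerMatrix& offs, bool symmetric,
                          std::vector<long long>& codes, int levels) {
  codes.clear();
  int nr = q.nrow(), nc = q.ncol();
  for (int o = 0; o < offs.nrow(); ++o) {
    int dr = offs(o, 0), dc = offs(o, 1);
    for (int r = r0; r <= r1; ++r) {
      int r2 = r + dr;
      if (r2 < 0 || r2 >= nr || r2 < r0 || r2 > r1) continue;
      for (int c = c0; c <= c1; ++c) {
        int c2 = c + dc;
        if (c2 < 0 || c2 >= nc || c2 < c0 || c2 > c1) continue;
        int a = q(r, c), b = q(r2, c2);
        if (a < 0 || b < 0) continue;
        codes.push_back((long long)a * levels + b);
        if (symmetric) codes.push_back((long long)b * levels + a);
      }
    }
  }
  return !codes.empty();
}

static void aggregate_codes(std::vector<long long>& codes, int levels,
                            std::vector<int>& ii, std::vector<int>& jj,
                            std::vector<double>& cnt) {
  std::sort(codes.begin(), codes.end());
  ii.clear(); jj.clear(); cnt.clear();
  size_t k = 0, n = codes.size();
  while (k < n) {
    size_t k2 = k;
    while (k2 < n && codes[k2] == codes[k]) ++k2;
    ii.push_back((int)(codes[k] / levels));
    jj.push_back((int)(codes[k] % levels));
    cnt.push_back((double)(k2 - k));
    k = k2;
  }
}

// [[Rcpp::export(name = ".glcm_window_cpp")]]
NumericMatrix glcm_window_cpp(IntegerMatrix q, int levels,
                              IntegerMatrix offsets, bool symmetric) {
  std::vector<long long> codes;
  std::vector<int> ii, jj;
  std::vector<double> cnt;
  NumericMatrix out(1, 8);
  if (!collect_pairs(q, 0, q.nrow() - 1, 0, q.ncol() - 1, offsets, symmetric,
                     codes, levels)) {
    std::fill(out.begin(), out.end(), NA_REAL);
    return out;
  }
  aggregate_codes(codes, levels, ii, jj, cnt);
  double s[8];
  glcm_stats(ii, jj, cnt, levels, s);
  for (int m = 0; m < 8; ++m) out(0, m) = s[m];
  return out;
}

// Per-pixel windowed GLCM metrics. `q` is the globally quantized image
// (NA -> -1). Windows are truncated at the image edges. Returns an
// (nr*nc) x 8 matrix in column-major pixel order.
// [[Rcpp::export(name = ".glcm_pixel_cpp")]]
NumericMatrix glcm_pixel_cpp(IntegerMatrix q, int levels, int window,
                             IntegerMatrix offsets, bool symmetric) {
  int nr = q.nrow(), nc = q.ncol();
  int h = window / 2;
  NumericMatrix out(nr * nc, 8);
  std::vector<long long> codes;
  std::vector<int> ii, jj;
  std::vector<double> cnt;
  double s[8];
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int idx = c * nr + r;
      if (q(r, c) < 0) {
        for (int m = 0; m < 8; ++m) out(idx, m) = NA_REAL;
        continue;
      }
      int r0 = std::max(0, r - h), r1 = std::min(nr - 1, r + h);
      int c0 = std::max(0, c - h), c1 = std::min(nc - 1, c + h);
      if (!collect_pairs(q, r0, r1, c0, c1, offsets, symmetric, codes,
                         levels)) {
        for (int m = 0; m < 8; ++m) out(idx, m) = NA_REAL;
        continue;
      }
      aggregate_codes(codes, levels, ii, jj, cnt);
      glcm_stats(ii, jj, cnt, levels, s);
      for (int m = 0; m < 8; ++m) out(idx, m) = s[m];
    }
  }
  return out;
}
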