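#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Sequences arrive encoded 0=A, 1=C, 2=G, 3=T. Pairing is assessed in the
// reverse-complement register: miRNA position 1 pairs the 3'-most site base.

static inline int pair_state(int m, int s) {
  // 0 = match, 1 = wobble (G:U), 2 = mismatch
  if (s == 3 - m) return 0;
  if ((m == 2 && s == 3) || (m == 3 && s == 2)) return 1;
  return 2;
}

struct ScanParams {
  double mismatch, wobble, gap, seed_factor;
  int seed_lo, seed_hi, max_bulge;
};

static inline double col_penalty(int state, int mpos, const ScanParams &p) {
  double base = 0.0;
  if (state == 1) base = p.wobble;
  else if (state == 2) base = p.mismatch;
  else if (state == 3) base = p.gap;   // bulge column
  if (base > 0.0 && mpos >= p.seed_lo && mpos <= p.seed_hi)
    base *= p.seed_factor;
  return base;
}

// Score one miRNA/site configuration. d = site length - miRNA length.
// d == 0: bulge-free; d > 0: target bulge of d nt inserted before miRNA
// position j; d < 0: |d| consecutive miRNA positions starting at j are
// bulged (unpaired). Site indices are 0-based within the window.
// abort_at: once the running penalty exceeds this bound the exact value no
// longer matters (the window cannot be retained) and scoring stops early.
static double config_score(const int *site, int L, const int *mir, int M,
                           int d, int j, const ScanParams &p,
                           double abort_at) {
  double sc = 0.0;
  if (d == 0) {
    for (int i = 1; i <= M; ++i) {
      sc += col_penalty(pair_state(mir[i - 1], site[L - i]), i, p);
      if (sc > abort_at) return sc;
    }
  } else if (d > 0) {
    for (int b = 0; b < d; ++b) sc += col_penalty(3, j, p);
    if (sc > abort_at) return sc;
    for (int i = 1; i <= M; ++i) {
      int sidx = (i < j) ? (L - i) : (L - i - d);
      sc += col_penalty(pair_state(mir[i - 1], site[sidx]), i, p);
      if (sc > abort_at) return sc;
    }
  } else {
    int bl = -d;
    for (int i = 1; i <= M; ++i) {
      if (i >= j && i < j + bl) { sc += col_penalty(3, i, p); }
      else {
        int sidx = (i < j) ? (L - i) : (L - i + bl);
        sc += col_penalty(pair_state(mir[i - 1], site[sidx]), i, p);
      }
      if (sc > abort_at) return sc;
    }
  }
  return sc;
}

// Best configuration for a fixed site window; returns score and writes the
// winning (d, j). Ties resolved: bulge-free first, then smallest j.
static double best_config(const int *site, int L, const int *mir, int M,
                          const ScanParams &p, double cutoff, int *best_j) {
  int d = L - M;
  double best = std::numeric_limits<double>::infinity();
  *best_j = 0;
  if (d == 0) {
    best = config_score(site, L, mir, M, 0, 0, p, cutoff);
  } else if (d > 0) {
    for (int j = 2; j <= M; ++j) {
      double sc = config_score(site, L, mir, M, d, j, p, cutoff);
      if (sc < best - 1e-12) { best = sc; *best_j = j; }
    }
  } else {
    int bl = -d;
    for (int j = 2; j <= M - bl; ++j) {
      double sc = config_score(site, L, mir, M, d, j, p, cutoff);
      if (sc < best - 1e-12) { best = sc; *best_j = j; }
    }
  }
  return best;
}

// [[Rcpp::export(name = ".scan_windows_cpp")]]
DataFrame scan_windows_cpp(IntegerVector tx, IntegerVector mir,
                           double cutoff, double mismatch, double wobble,
                           double gap, int seed_lo, int seed_hi,
                           double seed_factor, int max_bulge) {
  ScanParams p{mismatch, wobble, gap, seed_factor, seed_lo, seed_hi,
               max_bulge};
  int N = tx.size(), M = mir.size();
  std::vector<int> txv(tx.begin(), tx.end()), mv(mir.begin(), mir.end());
  std::vector<int> starts, lens, js;
  std::vector<double> scores;
  for (int d = -max_bulge; d <= max_bulge; ++d) {
    int L = M + d;
    if (L < 1 || (d < 0 && M + d < 2)) continue;
    for (int s = 0; s + L <= N; ++s) {
      int bj;
      double sc = best_config(&txv[s], L, &mv[0], M, p, cutoff, &bj);
      if (sc <= cutoff + 1e-9) {
        starts.push_back(s + 1);   // 1-based
        lens.push_back(L);
        js.push_back(bj);
        scores.push_back(sc);
      }
    }
  }
  return DataFrame::create(_["start"] = starts, _["len"] = lens,
                           _["bulge_j"] = js, _["score"] = scores);
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment with affine gaps, iterated with masking to
// report all non-overlapping homology patches with score >= min_score.
// A gap of length k costs gap_open + k * gap_ext (both negative).

// [[Rcpp::export(name = ".sw_patches_cpp")]]
DataFrame sw_patches_cpp(IntegerVector a, IntegerVector b, double match,
                         double mismatch, double gap_open, double gap_ext,
                         double min_score, int max_patches) {
  const double NEG = -1e18;
  int n = a.size(), m = b.size();
  std::vector<char> mask_a(n, 0), mask_b(m, 0);
  std::vector<double> H((n + 1) * (m + 1)), E((n + 1) * (m + 1)),
      F((n + 1) * (m + 1));
  std::vector<int> pa_s, pa_e, pb_s, pb_e, plen, nmatch, ncols;
  std::vector<double> pscore;

  auto idx = [m](int i, int j) { return i * (m + 1) + j; };

  for (int iter = 0; iter < max_patches; ++iter) {
    // forward DP
    double best = 0.0;
    int bi = -1, bj = -1;
    for (int j = 0; j <= m; ++j) { H[idx(0, j)] = 0; E[idx(0, j)] = NEG; F[idx(0, j)] = NEG; }
    for (int i = 1; i <= n; ++i) {
      H[idx(i, 0)] = 0; E[idx(i, 0)] = NEG; F[idx(i, 0)] = NEG;
      for (int j = 1; j <= m; ++j) {
        double s = (mask_a[i - 1] || mask_b[j - 1])
                       ? NEG
                       : (a[i - 1] == b[j - 1] ? match : mismatch);
        double e = std::max(H[idx(i, j - 1)] + gap_open + gap_ext,
                            E[idx(i, j - 1)] + gap_ext);
        double f = std::max(H[idx(i - 1, j)] + gap_open + gap_ext,
                            F[idx(i - 1, j)] + gap_ext);
        double h = H[idx(i - 1, j - 1)] + s;
        h = std::max(h, std::max(e, f));
        h = std::max(h, 0.0);
        E[idx(i, j)] = e; F[idx(i, j)] = f; H[idx(i, j)] = h;
        if (h > best + 1e-9) { best = h; bi = i; bj = j; }
      }
    }
    if (best < min_score - 1e-9 || bi < 0) break;

    // traceback from (bi, bj), state machine over H/E/F
    int i = bi, j = bj, state = 0;  // 0=H, 1=E (gap in a), 2=F (gap in b)
    int ae = bi, be = bj, nm = 0, nc = 0;
    while (true) {
      if (state == 0) {
        if (H[idx(i, j)] <= 0.0) break;
        double s = (mask_a[i - 1] || mask_b[j - 1])
                       ? NEG
                       : (a[i - 1] == b[j - 1] ? match : mismatch);
        if (i > 0 && j > 0 &&
            std::abs(H[idx(i, j)] - (H[idx(i - 1, j - 1)] + s)) < 1e-9) {
          if (a[i - 1] == b[j - 1]) ++nm;
          ++nc; --i; --j;
        } else if (std::abs(H[idx(i, j)] - E[idx(i, j)]) < 1e-9) {
          state = 1;
        } else {
          state = 2;
        }
      } else if (state == 1) {
        ++nc;
        if (std::abs(E[idx(i, j)] - (H[idx(i, j - 1)] + gap_open + gap_ext)) <
            1e-9) {
          --j; state = 0;
        } else {
          --j;
        }
      } else {
        ++nc;
        if (std::abs(F[idx(i, j)] - (H[idx(i - 1, j)] + gap_open + gap_ext)) <
            1e-9) {
          --i; state = 0;
        } else {
          --i;
        }
      }
    }
    int as = i + 1, bs = j + 1;  // 1-based starts
    pa_s.push_back(as); pa_e.push_back(ae);
    pb_s.push_back(bs); pb_e.push_back(be);
    plen.push_back(be - bs + 1);
    nmatch.push_back(nm); ncols.push_back(nc);
    pscore.push_back(best);
    for (int k = as - 1; k < ae; ++k) mask_a[k] = 1;
    for (int k = bs - 1; k < be; ++k) mask_b[k] = 1;
  }
  return DataFrame::create(
      _["a_start"] = pa_s, _["a_end"] = pa_e, _["b_start"] = pb_s,
      _["b_end"] = pb_e, _["length"] = plen, _["n_match"] = nmatch,
      _["n_cols"] = ncols, _["score"] = pscore);
}
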