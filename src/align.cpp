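#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Needleman-Wunsch with linear gap penalty, fixed scoring (+1 match, -1
// mismatch, -2 per gapped column). Identity = identical columns / total
// columns of the optimal-score alignment. Traceback tie-break is
// deterministic: diagonal, then gap-in-b (up), then gap-in-a (left).

static const int MATCH = 1, MISMATCH = -1, GAP = -2;
static const int NEG = -1000000000;

// [[Rcpp::export(name = ".cx_align_global")]]
List cx_align_global(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("global alignment requires non-empty sequences");
  std::vector<int> prev(m + 1), cur(m + 1);
  // full score matrix for traceback (n, m are amplicon scale: fine)
  std::vector<int> S((size_t)(n + 1) * (m + 1));
  for (int j = 0; j <= m; ++j) S[j] = GAP * j;
  for (int i = 1; i <= n; ++i) {
    S[(size_t)i * (m + 1)] = GAP * i;
    for (int j = 1; j <= m; ++j) {
      int diag = S[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                 (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
      int up   = S[(size_t)(i - 1) * (m + 1) + j] + GAP;
      int left = S[(size_t)i * (m + 1) + (j - 1)] + GAP;
      S[(size_t)i * (m + 1) + j] = std::max(diag, std::max(up, left));
    }
  }
  // traceback
  std::string aa, ab;
  aa.reserve(n + m); ab.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int here = S[(size_t)i * (m + 1) + j];
    if (i > 0 && j > 0 &&
        here == S[(size_t)(i - 1) * (m + 1) + (j - 1)] +
                    (a[i - 1] == b[j - 1] ? MATCH : MISMATCH)) {
      aa.push_back(a[i - 1]); ab.push_back(b[j - 1]); --i; --j;
    } else if (i > 0 && here == S[(size_t)(i - 1) * (m + 1) + j] + GAP) {
      aa.push_back(a[i - 1]); ab.push_back('-'); --i;
    } else {
      aa.push_back('-'); ab.push_back(b[j - 1]); --j;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(ab.begin(), ab.end());
  int ncols = aa.size(), nid = 0;
  for (int k = 0; k < ncols; ++k)
    if (aa[k] != '-' && aa[k] == ab[k]) ++nid;
  return List::create(
      _["score"] = S[(size_t)n * (m + 1) + m],
      _["identity"] = (double)nid / ncols, _["ncols"] = ncols,
      _["nmatch"] = nid, _["aligned_a"] = aa, _["aligned_b"] = ab);
}

// Banded decision: is global identity >= thr? Any alignment with identity
// >= thr has at most g <= (1-thr)/thr * max(n,m) gapped columns, so its path
// stays within |i - j| <= |n-m| + g; a band of that half-width therefore
// contains every alignment capable of reaching thr. Inside the band the
// optimal-score alignment's identity is computed exactly.
// [[Rcpp::export(name = ".cx_identity_ge")]]
bool cx_identity_ge(std::string a, std::string b, double thr) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("global alignment requires non-empty sequences");
  int mx = std::max(n, m), mn = std::min(n, m);
  if ((double)mn / mx < thr) return false;  // length bound on identity
  int w = std::abs(n - m) + (int)((1.0 - thr) / thr * mx) + 2;
  // rows i = 0..n, columns j restricted to [i - w, i + w]
  int width = 2 * w + 1;
  std::vector<int> S((size_t)(n + 1) * width, NEG);
  auto idx = [&](int i, int j) { return (size_t)i * width + (j - i + w); };
  for (int j = 0; j <= std::min(m, w); ++j) S[idx(0, j)] = GAP * j;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - w), jhi = std::min(m, i + w);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG;
      if (j == 0) best = GAP * i;
      else {
        if (j - 1 >= i - 1 - w && j - 1 <= i - 1 + w && S[idx(i - 1, j - 1)] > NEG) {
          int v = S[idx(i - 1, j - 1)] + (a[i - 1] == b[j - 1] ? MATCH : MISMATCH);
          best = std::max(best, v);
        }
        if (j >= i - 1 - w && j <= i - 1 + w && i >= 1 && S[idx(i - 1, j)] > NEG)
          best = std::max(best, S[idx(i - 1, j)] + GAP);
        if (j - 1 >= i - w && S[idx(i, j - 1)] > NEG)
          best = std::max(best, S[idx(i, j - 1)] + GAP);
      }
      S[idx(i, j)] = best;
    }
  }
  if (S[idx(n, m)] <= NEG) return false;
  // traceback within band, count identity
  int i = n, j = m, ncols = 0, nid = 0;
  while (i > 0 || j > 0) {
    int here = S[idx(i, j)];
    bool can_diag = i > 0 && j > 0 && (j - 1) >= (i - 1) - w && (j - 1) <= (i - 1) + w;
    if (can_diag && here == S[idx(i - 1, j - 1)] +
                                (a[i - 1] == b[j - 1] ? MATCH : MISMATCH)) {
      if (a[i - 1] == b[j - 1]) ++nid;
      --i; --j;
    } else if (i > 0 && j >= (i - 1) - w && j <= (i - 1) + w &&
               ((j == 0 && here == GAP * i) || here == S[idx(i - 1, j)] + GAP)) {
      --i;
    } else {
      --j;
    }
    ++ncols;
  }
  return (double)nid / ncols >= thr;
}

// Hamming mismatch count for equal-length sequences (fast path used in tests)
// [[Rcpp::export(name = ".cx_hamming")]]
int cx_hamming(std::string a, std::string b) {
  if (a.size() != b.size()) stop("hamming distance requires equal lengths");
  int d = 0;
  for (size_t k = 0; k < a.size(); ++k)
    if (a[k] != b[k]) ++d;
  return d;
}

// ---- greedy clustering hot path -------------------------------------------
// Exact decisions ("optimal-alignment identity >= thr") via a cascade:
//  1. equal lengths: Hamming accept. If the gap-free alignment reaches thr,
//     the optimal-score alignment's identity can only be higher (adding G gap
//     columns raises matches by >= 3G/4 while columns grow by G/2).
//  2. banded Levenshtein reject: any alignment with identity >= thr performs
//     at most dmax = floor(2(1-thr)max(n,m)/(1+thr)) edit operations, so an
//     edit distance above dmax excludes the threshold.
//  3. otherwise the banded scoring DP (identity of the optimal alignment).

static int lev_banded(const std::string &a, const std::string &b, int k) {
  // Levenshtein distance with cutoff k; returns k+1 if distance exceeds k
  const int n = a.size(), m = b.size();
  if (std::abs(n - m) > k) return k + 1;
  int w = k;
  int width = 2 * w + 1;
  std::vector<int> prev(width, k + 1), cur(width, k + 1);
  // row 0
  for (int j = 0; j <= std::min(m, w); ++j) prev[j + w] = j;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - w), jhi = std::min(m, i + w);
    int rowmin = k + 1;
    std::fill(cur.begin(), cur.end(), k + 1);
    for (int j = jlo; j <= jhi; ++j) {
      int off = j - i + w;
      int best = k + 1;
      if (j == 0) best = i;
      else {
        int diag = prev[off];  // (i-1, j-1): offset (j-1)-(i-1)+w = off
        if (diag <= k) best = std::min(best, diag + (a[i-1] == b[j-1] ? 0 : 1));
        if (off + 1 < width && prev[off + 1] <= k)   // (i-1, j)
          best = std::min(best, prev[off + 1] + 1);
        if (off - 1 >= 0 && cur[off - 1] <= k)       // (i, j-1)
          best = std::min(best, cur[off - 1] + 1);
      }
      cur[off] = best;
      rowmin = std::min(rowmin, best);
    }
    if (rowmin > k) return k + 1;
    std::swap(prev, cur);
  }
  int off = m - n + w;
  return (off >= 0 && off < width) ? prev[off] : k + 1;
}

// sorted 2-bit-packed 8-mer multiset of a sequence (non-ACGT k-mers skipped)
static const int QK = 8;
static std::vector<uint32_t> qgrams(const std::string &s) {
  std::vector<uint32_t> out;
  const int n = s.size();
  if (n < QK) return out;
  out.reserve(n - QK + 1);
  for (int i = 0; i + QK <= n; ++i) {
    uint32_t v = 0;
    bool ok = true;
    for (int j = 0; j < QK; ++j) {
      int code;
      switch (s[i + j]) {
        case 'A': code = 0; break; case 'C': code = 1; break;
        case 'G': code = 2; break; case 'T': code = 3; break;
        default: code = 0; ok = false;
      }
      v = (v << 2) | code;
    }
    if (ok) out.push_back(v);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// multiset intersection size of two sorted k-mer lists
static int qcommon(const std::vector<uint32_t> &a,
                   const std::vector<uint32_t> &b) {
  size_t i = 0, j = 0; int c = 0;
  while (i < a.size() && j < b.size()) {
    if (a[i] < b[j]) ++i;
    else if (a[i] > b[j]) ++j;
    else { ++c; ++i; ++j; }
  }
  return c;
}

static bool identity_ge_impl(const std::string &a, const std::string &b,
                             double thr,
                             const std::vector<uint32_t> *qa = nullptr,
                             const std::vector<uint32_t> *qb = nullptr) {
  const int n = a.size(), m = b.size();
  int mx = std::max(n, m), mn = std::min(n, m);
  if ((double)mn / mx < thr) return false;
  if (n == m) {
    int mlimit = (int)(n * (1.0 - thr) + 1e-9);
    int d = 0;
    for (int i = 0; i < n && d <= mlimit; ++i) if (a[i] != b[i]) ++d;
    if (d <= mlimit) return true;  // gap-free alignment already reaches thr
  }
  if (qa && qb && mn >= QK) {
    // q-gram lemma: one edit destroys at most QK q-grams, so
    // ed >= (max(|Qa|, |Qb|) - common) / QK
    int dmax_q = (int)(2.0 * (1.0 - thr) * mx / (1.0 + thr) + 1e-9);
    int qmax = std::max(qa->size(), qb->size());
    int lb = (qmax - qcommon(*qa, *qb) + QK - 1) / QK;
    if (lb > dmax_q) return false;
  }
  int dmax = (int)(2.0 * (1.0 - thr) * mx / (1.0 + thr) + 1e-9);
  if (lev_banded(a, b, dmax) > dmax) return false;
  return cx_identity_ge(a, b, thr);
}

// [[Rcpp::export(name = ".cx_greedy_assign")]]
IntegerVector cx_greedy_assign(CharacterVector seqs, double thr) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  std::vector<std::vector<uint32_t>> q(n);
  for (int i = 0; i < n; ++i) {
    s[i] = as<std::string>(seqs[i]);
    q[i] = qgrams(s[i]);
  }
  std::vector<int> centroid;  // read index of each cluster centroid
  IntegerVector assign(n);
  for (int i = 0; i < n; ++i) {
    int placed = 0;
    for (size_t c = 0; c < centroid.size(); ++c) {
      int ci = centroid[c];
      const std::string &cs = s[ci];
      int la = s[i].size(), lb = cs.size();
      if ((double)std::min(la, lb) / std::max(la, lb) < thr) continue;
      if (identity_ge_impl(s[i], cs, thr, &q[i], &q[ci])) {
        placed = c + 1; break;
      }
    }
    if (placed == 0) {
      centroid.push_back(i);
      placed = centroid.size();
    }
    assign[i] = placed;
  }
  return assign;
}
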