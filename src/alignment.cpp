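#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
using namespace Rcpp;

// Residue coding: characters are mapped to row indices of the substitution
// matrix; anything absent from the matrix alphabet, plus the explicit
// ambiguity codes 'X' and '*', maps to -1 and scores 0 against everything
// (neutral ambiguity rule).
static std::vector<int> build_lookup(const std::vector<std::string>& alphabet) {
  std::vector<int> lut(256, -1);
  for (size_t k = 0; k < alphabet.size(); ++k) {
    if (alphabet[k].size() == 1) {
      unsigned char c = alphabet[k][0];
      if (c == 'X' || c == '*') continue;
      lut[c] = (int)k;
    }
  }
  return lut;
}

static inline int pair_score(const IntegerMatrix& m, int a, int b) {
  if (a < 0 || b < 0) return 0;
  return m(a, b);
}

static std::vector<int> encode(const std::string& s, const std::vector<int>& lut) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = lut[(unsigned char)s[i]];
  return v;
}

// Smith-Waterman, affine gaps, score only. A gap of length L costs
// gap_open + gap_extend * L (open charged once, extend per residue).
static int sw_score_core(const std::vector<int>& q, const std::vector<int>& s,
                         const IntegerMatrix& mat, int gap_open, int gap_extend) {
  const int m = (int)q.size(), n = (int)s.size();
  const int gfirst = gap_open + gap_extend;
  std::vector<int> H(n + 1, 0), E(n + 1, 0);
  int best = 0;
  for (int i = 1; i <= m; ++i) {
    int Hdiag = 0;  // H[i-1][j-1]
    int F = 0;      // gap in subject (vertical), reset per row
    for (int j = 1; j <= n; ++j) {
      E[j] = std::max(H[j] - gfirst, E[j] - gap_extend);        // gap in query
      F = std::max(H[j - 1] - gfirst, F - gap_extend);
      int h = Hdiag + pair_score(mat, q[i - 1], s[j - 1]);
      h = std::max(h, std::max(E[j], F));
      h = std::max(h, 0);
      Hdiag = H[j];
      H[j] = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".cpp_sw_score")]]
int cpp_sw_score(std::string query, std::string subject, IntegerMatrix mat,
                 std::vector<std::string> alphabet, int gap_open, int gap_extend) {
  std::vector<int> lut = build_lookup(alphabet);
  return sw_score_core(encode(query, lut), encode(subject, lut), mat,
                       gap_open, gap_extend);
}

// [[Rcpp::export(name = ".cpp_sw_score_vec")]]
IntegerVector cpp_sw_score_vec(std::string query, std::vector<std::string> subjects,
                               IntegerMatrix mat, std::vector<std::string> alphabet,
                               int gap_open, int gap_extend) {
  std::vector<int> lut = build_lookup(alphabet);
  std::vector<int> q = encode(query, lut);
  IntegerVector out(subjects.size());
  for (size_t k = 0; k < subjects.size(); ++k) {
    out[k] = sw_score_core(q, encode(subjects[k], lut), mat, gap_open, gap_extend);
  }
  return out;
}

// Full Smith-Waterman with traceback. Among all maximal cells the alignment
// whose (query start, subject start) is lexicographically smallest is
// reported (deterministic tie-break); within a traceback, diagonal moves are
// preferred over gaps in the query, over gaps in the subject.
// [[Rcpp::export(name = ".cpp_sw_align")]]
List cpp_sw_align(std::string query, std::string subject, IntegerMatrix mat,
                  std::vector<std::string> alphabet, int gap_open, int gap_extend) {
  std::vector<int> lut = build_lookup(alphabet);
  std::vector<int> q = encode(query, lut), s = encode(subject, lut);
  const int m = (int)q.size(), n = (int)s.size();
  const int gfirst = gap_open + gap_extend;
  const int NEG = INT_MIN / 4;

  std::vector<std::vector<int>> H(m + 1, std::vector<int>(n + 1, 0));
  std::vector<std::vector<int>> E(m + 1, std::vector<int>(n + 1, NEG));
  std::vector<std::vector<int>> F(m + 1, std::vector<int>(n + 1, NEG));
  int best = 0;
  std::vector<std::pair<int,int>> argmax;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      E[i][j] = std::max(H[i][j - 1] - gfirst, E[i][j - 1] - gap_extend);
      F[i][j] = std::max(H[i - 1][j] - gfirst, F[i - 1][j] - gap_extend);
      int h = H[i - 1][j - 1] + pair_score(mat, q[i - 1], s[j - 1]);
      h = std::max(h, std::max(E[i][j], F[i][j]));
      h = std::max(h, 0);
      H[i][j] = h;
      if (h > best) { best = h; argmax.clear(); }
      if (h == best && h > 0) argmax.push_back(std::make_pair(i, j));
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["length"] = 0,
                        _["matches"] = 0, _["gaps"] = 0, _["gap_opens"] = 0);
  }

  int bqs = INT_MAX, bss = INT_MAX, bqe = 0, bse = 0;
  int blen = 0, bmatch = 0, bgaps = 0, bgo = 0;
  for (size_t k = 0; k < argmax.size(); ++k) {
    int i = argmax[k].first, j = argmax[k].second;
    int qe = i, se = j;
    int len = 0, match = 0, gaps = 0, gapopens = 0;
    // traceback: state 0 = H, 1 = E (gap in query), 2 = F (gap in subject)
    int state = 0;
    while (!(state == 0 && H[i][j] == 0)) {
      if (state == 0) {
        int sc = pair_score(mat, q[i - 1], s[j - 1]);
        if (i >= 1 && j >= 1 && H[i][j] == H[i - 1][j - 1] + sc) {
          if (q[i - 1] >= 0 && q[i - 1] == s[j - 1]) ++match;
          --i; --j; ++len;
        } else if (H[i][j] == F[i][j]) {
          state = 2;
        } else {
          state = 1;
        }
      } else if (state == 1) { // E: gap in query, consume subject
        ++len; ++gaps;
        if (E[i][j] == H[i][j - 1] - gfirst) { ++gapopens; --j; state = 0; }
        else { --j; }
      } else {               // F: gap in subject, consume query
        ++len; ++gaps;
        if (F[i][j] == H[i - 1][j] - gfirst) { ++gapopens; --i; state = 0; }
        else { --i; }
      }
    }
    int qs = i + 1, ss = j + 1;
    if (qs < bqs || (qs == bqs && ss < bss)) {
      bqs = qs; bss = ss; bqe = qe; bse = se;
      blen = len; bmatch = match; bgaps = gaps; bgo = gapopens;
    }
  }
  return List::create(_["score"] = best, _["qstart"] = bqs, _["qend"] = bqe,
                      _["sstart"] = bss, _["send"] = bse, _["length"] = blen,
                      _["matches"] = bmatch, _["gaps"] = bgaps,
                      _["gap_opens"] = bgo);
}

// Best ungapped (single-diagonal) local alignment. When word_size > 0 only
// diagonals carrying an exact identity run of at least word_size residues
// are extended (BLAST-style seeding for the transcript-support mode).
// Deterministic tie-break: smallest query start, then subject start.
// [[Rcpp::export(name = ".cpp_ungapped_best")]]
List cpp_ungapped_best(std::string query, std::string subject, IntegerMatrix mat,
                       std::vector<std::string> alphabet, int word_size) {
  std::vector<int> lut = build_lookup(alphabet);
  std::vector<int> q = encode(query, lut), s = encode(subject, lut);
  const int m = (int)q.size(), n = (int)s.size();
  int best = 0, bqs = 0, bqe = 0, bss = 0, bse = 0, bmatch = 0, blen = 0;
  for (int d = -(m - 1); d <= n - 1; ++d) {
    int i0 = d < 0 ? -d : 0;           // 0-based offsets into q and s
    int j0 = d < 0 ? 0 : d;
    int L = std::min(m - i0, n - j0);
    if (L <= 0) continue;
    if (word_size > 0) {
      int run = 0; bool seeded = false;
      for (int t = 0; t < L; ++t) {
        if (q[i0 + t] >= 0 && q[i0 + t] == s[j0 + t]) {
          if (++run >= word_size) { seeded = true; break; }
        } else run = 0;
      }
      if (!seeded) continue;
    }
    // Kadane max-sum segment with identity bookkeeping
    int cur = 0, curstart = 0, curmatch = 0;
    for (int t = 0; t < L; ++t) {
      int sc = pair_score(mat, q[i0 + t], s[j0 + t]);
      if (cur <= 0 && sc > 0) { cur = 0; curstart = t; curmatch = 0; }
      cur += sc;
      if (q[i0 + t] >= 0 && q[i0 + t] == s[j0 + t]) ++curmatch;
      if (cur < 0) { cur = 0; curmatch = 0; curstart = t + 1; }
      if (cur > best ||
          (cur == best && cur > 0 &&
           (i0 + curstart + 1 < bqs ||
            (i0 + curstart + 1 == bqs && j0 + curstart + 1 < bss)))) {
        best = cur;
        bqs = i0 + curstart + 1; bqe = i0 + t + 1;
        bss = j0 + curstart + 1; bse = j0 + t + 1;
        bmatch = curmatch; blen = t - curstart + 1;
      }
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["qstart"] = NA_INTEGER,
                        _["qend"] = NA_INTEGER, _["sstart"] = NA_INTEGER,
                        _["send"] = NA_INTEGER, _["length"] = 0, _["matches"] = 0);
  }
  return List::create(_["score"] = best, _["qstart"] = bqs, _["qend"] = bqe,
                      _["sstart"] = bss, _["send"] = bse, _["length"] = blen,
                      _["matches"] = bmatch);
}
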