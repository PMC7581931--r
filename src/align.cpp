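#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap local (Smith-Waterman) alignment with full traceback statistics.
//
// Scoring convention: a substitution scores `match` when the two bases are
// identical members of {A,C,G,T} and `mismatch` otherwise (N never matches
// anything, including N). A gap of length L scores gap_open + L * gap_extend,
// i.e. the opening penalty is charged in addition to the per-base extension.
//
// Tie-breaking is deterministic: the best cell is the first maximum in
// row-major order (smallest query position, then smallest reference
// position); during traceback the preference order is substitution, then
// gap-in-reference (query base unmatched), then gap-in-query, and opening a
// gap is preferred over extending when scores tie.

namespace {

const int NEG_INF = -1000000000;

inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

struct AlnResult {
  int score;
  int qstart, qend, sstart, send; // 1-based inclusive; 0 when no alignment
  int matches, mismatches, gap_openings, gap_bases, aligned_length;
};

AlnResult sw_core(const std::string& q, const std::string& s,
                  int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int)q.size(), m = (int)s.size();
  // H: best score of local alignment ending at (i, j) (1-based over bases).
  // E: ending with a gap in the query (consumes s[j]); F: gap in the
  // reference (consumes q[i]).
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Eprev(m + 1, NEG_INF);
  std::vector<int> Ecur(m + 1, NEG_INF), Fcur(m + 1, NEG_INF), Fprev(m + 1, NEG_INF);
  // traceback codes per cell: tbH 0=stop,1=diag,2=fromF(up),3=fromE(left)
  //                           tbE/tbF 1=open(from H), 2=extend
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);
  auto idx = [m](int i, int j) { return (size_t)i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Ecur[0] = NEG_INF;
    Fcur[0] = NEG_INF;
    Hcur[0] = 0;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query, moving left along s
      int e_open = (Hcur[j - 1] == NEG_INF) ? NEG_INF : Hcur[j - 1] + gap_open + gap_extend;
      int e_ext = (Ecur[j - 1] == NEG_INF) ? NEG_INF : Ecur[j - 1] + gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[idx(i, j)] = 1; }
      else                 { Ecur[j] = e_ext;  tbE[idx(i, j)] = 2; }
      // F: gap in reference, moving up along q
      int f_open = (Hprev[j] == NEG_INF) ? NEG_INF : Hprev[j] + gap_open + gap_extend;
      int f_ext = (Fprev[j] == NEG_INF) ? NEG_INF : Fprev[j] + gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[idx(i, j)] = 1; }
      else                 { Fcur[j] = f_ext;  tbF[idx(i, j)] = 2; }
      // H
      bool eq = (q[i - 1] == s[j - 1]) && is_acgt(q[i - 1]);
      int diag = Hprev[j - 1] + (eq ? match : mismatch);
      int h = 0; unsigned char tb = 0;
      if (diag >= h) { h = diag; tb = 1; }
      if (Fcur[j] > h) { h = Fcur[j]; tb = 2; }
      if (Ecur[j] > h) { h = Ecur[j]; tb = 3; }
      if (h <= 0) { h = 0; tb = 0; }
      Hcur[j] = h;
      tbH[idx(i, j)] = tb;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  AlnResult r{best, 0, 0, 0, 0, 0, 0, 0, 0, 0};
  if (best <= 0) { r.score = 0; return r; }

  // Traceback from (bi, bj) in state H.
  int i = bi, j = bj, state = 0; // 0 = H, 1 = E, 2 = F
  r.qend = bi; r.send = bj;
  while (true) {
    if (state == 0) {
      unsigned char tb = tbH[idx(i, j)];
      if (tb == 0) break;
      if (tb == 1) {
        bool eq = (q[i - 1] == s[j - 1]) && is_acgt(q[i - 1]);
        if (eq) ++r.matches; else ++r.mismatches;
        r.qstart = i; r.sstart = j;
        --i; --j;
        if (i == 0 || j == 0) break;
        if (tbH[idx(i, j)] == 0) break;
      } else if (tb == 2) {
        state = 2;
      } else {
        state = 1;
      }
    } else if (state == 1) { // E: gap in query, consumed s[j]
      ++r.gap_bases;
      unsigned char tb = tbE[idx(i, j)];
      --j;
      if (tb == 1) { ++r.gap_openings; state = 0; }
    } else { // F: gap in reference, consumed q[i]
      ++r.gap_bases;
      unsigned char tb = tbF[idx(i, j)];
      --i;
      if (tb == 1) { ++r.gap_openings; state = 0; }
    }
  }
  r.aligned_length = r.matches + r.mismatches + r.gap_bases;
  return r;
}

NumericVector as_vec(const AlnResult& r) {
  return NumericVector::create(
      _["score"] = r.score, _["query_start"] = r.qstart, _["query_end"] = r.qend,
      _["ref_start"] = r.sstart, _["ref_end"] = r.send, _["matches"] = r.matches,
      _["mismatches"] = r.mismatches, _["gap_openings"] = r.gap_openings,
      _["aligned_length"] = r.aligned_length);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_sw_align(std::string query, std::string reference,
                           int match, int mismatch, int gap_open, int gap_extend) {
  return as_vec(sw_core(query, reference, match, mismatch, gap_open, gap_extend));
}

// [[Rcpp::export]]
NumericMatrix cpp_sw_align_batch(std::string query, CharacterVector references,
                                 int match, int mismatch, int gap_open, int gap_extend) {
  const int n = references.size();
  NumericMatrix out(n, 9);
  colnames(out) = CharacterVector::create(
      "score", "query_start", "query_end", "ref_start", "ref_end",
      "matches", "mismatches", "gap_openings", "aligned_length");
  for (int k = 0; k < n; ++k) {
    std::string ref = as<std::string>(references[k]);
    AlnResult r = sw_core(query, ref, match, mismatch, gap_open, gap_extend);
    out(k, 0) = r.score; out(k, 1) = r.qstart; out(k, 2) = r.qend;
    out(k, 3) = r.sstart; out(k, 4) = r.send; out(k, 5) = r.matches;
    out(k, 6) = r.mismatches; out(k, 7) = r.gap_openings; out(k, 8) = r.aligned_length;
  }
  return out;
}
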