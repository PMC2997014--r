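#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap local alignment (Smith-Waterman) on integer-encoded sequences
// (A=0,C=1,G=2,T=3, negative = ambiguous; ambiguous bases always mismatch).
// A gap of length L costs gap_open + L * gap_ext (both positive numbers).
// Returns 0-based half-open intervals on both sequences plus column counts
// from the traceback so callers can derive percent identity.

static inline int subst(int a, int b, int match, int mismatch) {
  if (a < 0 || b < 0) return mismatch;
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b,
                  int match, int mismatch, int gap_open, int gap_ext) {
  const int n = a.size(), m = b.size();
  const int NEG = -1000000000;
  const int go = gap_open + gap_ext;  // cost of opening a length-1 gap

  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG); // gap in b (vertical)
  // traceback: 0 stop, 1 diag, 2 from E (gap in query, move left is wrong —
  // here E = gap consuming a only), 3 from F (gap consuming b only)
  // Fcur computed rowwise.
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0); // 1 = extend
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int F = NEG;
    Hcur[0] = 0; Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t at = (size_t)i * (m + 1) + j;
      // E: gap consuming a (vertical move, from row i-1 same column)
      int e_open = Hprev[j] - go, e_ext = Eprev[j] - gap_ext;
      int E = (e_ext > e_open) ? e_ext : e_open;
      tbE[at] = (e_ext > e_open) ? 1 : 0;
      // F: gap consuming b (horizontal move, same row)
      int f_open = Hcur[j - 1] - go, f_ext = F - gap_ext;
      int Fv = (f_ext > f_open) ? f_ext : f_open;
      tbF[at] = (f_ext > f_open) ? 1 : 0;
      F = Fv;
      int diag = Hprev[j - 1] + subst(a[i - 1], b[j - 1], match, mismatch);
      int h = 0; unsigned char mv = 0;
      if (diag > h) { h = diag; mv = 1; }
      if (E > h)    { h = E;    mv = 2; }
      if (Fv > h)   { h = Fv;   mv = 3; }
      Hcur[j] = h; Ecur[j] = E; tbH[at] = mv;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }

  // traceback from (bi, bj)
  int i = bi, j = bj;
  int matches = 0, mismatches = 0, gaps = 0, gap_opens = 0, cols = 0;
  int state = 0; // 0 = in H
  while (i > 0 && j > 0) {
    size_t at = (size_t)i * (m + 1) + j;
    if (state == 0) {
      unsigned char mv = tbH[at];
      if (mv == 0) break;
      if (mv == 1) {
        ++cols;
        if (a[i - 1] >= 0 && a[i - 1] == b[j - 1]) ++matches; else ++mismatches;
        --i; --j;
      } else if (mv == 2) state = 2;
      else state = 3;
    } else if (state == 2) {
      ++cols; ++gaps;
      if (tbE[at] == 0) { state = 0; ++gap_opens; }
      --i;
    } else {
      ++cols; ++gaps;
      if (tbF[at] == 0) { state = 0; ++gap_opens; }
      --j;
    }
  }

  return List::create(_["score"] = best,
                      _["q_start"] = i, _["q_end"] = bi,
                      _["s_start"] = j, _["s_end"] = bj,
                      _["matches"] = matches, _["mismatches"] = mismatches,
                      _["gaps"] = gaps, _["gap_opens"] = gap_opens,
                      _["aln_len"] = cols);
}

// Two-way ungapped X-drop extension of an exact seed of length w at
// (qpos, spos), 0-based. Returns the extended interval and its score.
// [[Rcpp::export]]
List xdrop_extend_cpp(IntegerVector a, IntegerVector b,
                      int qpos, int spos, int w,
                      int match, int mismatch, int xdrop) {
  const int n = a.size(), m = b.size();
  int score = w * match;
  // right
  int i = qpos + w, j = spos + w, cur = score, bestr = score;
  int qe = qpos + w, se = spos + w;
  while (i < n && j < m) {
    cur += subst(a[i], b[j], match, mismatch);
    ++i; ++j;
    if (cur > bestr) { bestr = cur; qe = i; se = j; }
    if (bestr - cur > xdrop) break;
  }
  // left
  int qi = qpos, sj = spos, bestl = bestr; cur = bestr;
  int qs = qpos, ss = spos;
  while (qi > 0 && sj > 0) {
    cur += subst(a[qi - 1], b[sj - 1], match, mismatch);
    --qi; --sj;
    if (cur > bestl) { bestl = cur; qs = qi; ss = sj; }
    if (bestl - cur > xdrop) break;
  }
  return List::create(_["score"] = bestl,
                      _["q_start"] = qs, _["q_end"] = qe,
                      _["s_start"] = ss, _["s_end"] = se);
}
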