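#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gotoh local alignment (affine gaps, BLAST convention: a gap of length L
// costs gap_open + L * gap_ext) between an integer-encoded query and
// subject, under an integer substitution matrix.  Locally optimal
// alignments are reported iteratively: after each traceback the aligned
// query interval is masked and the DP is rerun, until the best score drops
// below min_score or max_hits alignments have been reported.  Exhaustive
// and deterministic; sized for desk-scale scans (frames of a few kb
// against a small curated panel).

struct Aln {
  int score, q0, q1, s0, s1, ident, cols;
};

static bool sw_best(const std::vector<int>& q, const std::vector<int>& s,
                    const IntegerMatrix& mat, int go, int ge,
                    const std::vector<char>& qmask, Aln& out) {
  const int n = q.size(), m = s.size();
  const int NEG = -100000000;
  const int openc = go + ge;  // cost of a gap of length 1
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0), Fcol(m + 1, NEG);
  // traceback codes for H: 0 stop, 1 diag, 2 from E (gap in query,
  // horizontal), 3 from F (gap in subject, vertical); tbE/tbF: 1 => the
  // gap state extended a previous gap state, 0 => it opened from H
  std::vector<uint8_t> tbH((size_t)(n + 1) * (m + 1), 0),
      tbE((size_t)(n + 1) * (m + 1), 0), tbF((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    int Ecur = NEG;
    Hcur[0] = 0;
    const bool masked = qmask[i - 1] != 0;
    const int qi = q[i - 1];
    const size_t row = (size_t)i * (m + 1);
    for (int j = 1; j <= m; ++j) {
      // E[i][j]: gap in query, depends on same row, previous column
      const int e_open = Hcur[j - 1] - openc;
      const int e_ext = Ecur - ge;
      int E;
      if (e_ext > e_open) { E = e_ext; tbE[row + j] = 1; }
      else { E = e_open; tbE[row + j] = 0; }
      // F[i][j]: gap in subject, depends on previous row, same column
      const int f_open = Hprev[j] - openc;
      const int f_ext = Fcol[j] - ge;
      int F;
      if (f_ext > f_open) { F = f_ext; tbF[row + j] = 1; }
      else { F = f_open; tbF[row + j] = 0; }
      const int diag = masked ? NEG : Hprev[j - 1] + mat(qi, s[j - 1]);
      int h = 0; uint8_t code = 0;
      if (diag > h) { h = diag; code = 1; }
      if (E > h) { h = E; code = 2; }
      if (F > h) { h = F; code = 3; }
      Hcur[j] = h; tbH[row + j] = code;
      Ecur = E; Fcol[j] = F;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
  }
  if (best <= 0) return false;
  // traceback from the best cell
  int i = bi, j = bj, ident = 0, cols = 0;
  const int q1 = bi, s1 = bj;
  int state = 0;  // 0 = H, 2 = E, 3 = F
  while (i > 0 && j > 0) {
    const size_t row = (size_t)i * (m + 1);
    if (state == 0) {
      const uint8_t c = tbH[row + j];
      if (c == 0) break;
      if (c == 1) {
        ++cols;
        if (q[i - 1] == s[j - 1]) ++ident;
        --i; --j;
      } else if (c == 2) state = 2;
      else state = 3;
    } else if (state == 2) {  // gap in query: consume a subject column
      const uint8_t c = tbE[row + j];
      ++cols; --j;
      state = c ? 2 : 0;
    } else {  // gap in subject: consume a query row
      const uint8_t c = tbF[row + j];
      ++cols; --i;
      state = c ? 3 : 0;
    }
  }
  out.score = best;
  out.q0 = i + 1; out.q1 = q1;  // 1-based inclusive residue positions
  out.s0 = j + 1; out.s1 = s1;
  out.ident = ident; out.cols = cols;
  return true;
}

// [[Rcpp::export]]
DataFrame sw_all_hits_cpp(IntegerVector q, IntegerVector s,
                          IntegerMatrix mat, int gap_open, int gap_ext,
                          int min_score, int max_hits) {
  std::vector<int> qv(q.begin(), q.end()), sv(s.begin(), s.end());
  std::vector<char> qmask(qv.size(), 0);
  std::vector<int> score, q0, q1, s0, s1, ident, cols;
  for (int h = 0; h < max_hits; ++h) {
    if (qv.empty() || sv.empty()) break;
    Aln a;
    if (!sw_best(qv, sv, mat, gap_open, gap_ext, qmask, a)) break;
    if (a.score < min_score) break;
    score.push_back(a.score);
    q0.push_back(a.q0); q1.push_back(a.q1);
    s0.push_back(a.s0); s1.push_back(a.s1);
    ident.push_back(a.ident); cols.push_back(a.cols);
    for (int i = a.q0 - 1; i < a.q1; ++i) qmask[i] = 1;
  }
  return DataFrame::create(_["score"] = score, _["q_start"] = q0,
                           _["q_end"] = q1, _["s_start"] = s0,
                           _["s_end"] = s1, _["n_ident"] = ident,
                           _["cols"] = cols);
}
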