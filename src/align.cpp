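#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment with affine gap penalties, Smith-Waterman style, with a
// traceback that emits a SAM-convention CIGAR (S soft-clips for unaligned
// query ends, M/I/D inside) and an MD string describing reference mismatches
// and deletions. Scores: match > 0; mismatch, gap_open, gap_extend <= 0.
// A gap of length L costs gap_open + L * gap_extend.
//
// Traceback ties are broken deterministically (diagonal, then insertion,
// then deletion) so repeated runs give byte-identical output.

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(const std::string& query, const std::string& ref,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  const int n = (int) query.size();
  const int m = (int) ref.size();
  if (n == 0 || m == 0)
    return List::create(_["score"] = 0.0, _["mapped"] = false);

  const double NEG = -1e18;
  // H: best ending in match/mismatch or overall; E: gap consuming ref (D);
  // F: gap consuming query (I).
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<double> Fprev(m + 1, NEG), Fcur(m + 1, NEG);
  // traceback codes per cell: which matrix the cell max came from
  // 0 = stop (local zero), 1 = diag, 2 = I (from F), 3 = D (from E)
  std::vector<unsigned char> tbH((size_t)(n + 1) * (m + 1), 0);
  // for E/F: whether the gap was opened (1) or extended (0)
  std::vector<unsigned char> tbE((size_t)(n + 1) * (m + 1), 0);
  std::vector<unsigned char> tbF((size_t)(n + 1) * (m + 1), 0);

  double best = 0.0;
  int bi = 0, bj = 0;

  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0.0; Ecur[0] = NEG; Fcur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      size_t idx = (size_t) i * (m + 1) + j;
      // E: deletion from reference (consumes ref base j)
      double e_open = Hcur[j - 1] + gap_open + gap_extend;
      double e_ext  = Ecur[j - 1] + gap_extend;
      if (e_open >= e_ext) { Ecur[j] = e_open; tbE[idx] = 1; }
      else                 { Ecur[j] = e_ext;  tbE[idx] = 0; }
      // F: insertion to reference (consumes query base i)
      double f_open = Hprev[j] + gap_open + gap_extend;
      double f_ext  = Fprev[j] + gap_extend;
      if (f_open >= f_ext) { Fcur[j] = f_open; tbF[idx] = 1; }
      else                 { Fcur[j] = f_ext;  tbF[idx] = 0; }
      // H
      double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      double h = 0.0; unsigned char code = 0;
      if (diag > h)    { h = diag;    code = 1; }
      if (Fcur[j] > h) { h = Fcur[j]; code = 2; }
      if (Ecur[j] > h) { h = Ecur[j]; code = 3; }
      Hcur[j] = h; tbH[idx] = code;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }

  if (best <= 0.0)
    return List::create(_["score"] = 0.0, _["mapped"] = false);

  // Full traceback needs the H matrix values; with only two rows kept we
  // re-run the DP storing the codes (already stored above) -- the codes alone
  // determine the path, since each code fixes the predecessor cell and
  // matrix (E/F extension codes chain within their own matrix).
  std::string ops;            // reversed path of 'M', 'I', 'D'
  std::string md_ref;         // reference bases along the path (for MD)
  std::string md_kind;        // '=', 'X' (mismatch), 'D' per path column
  int i = bi, j = bj;
  int state = 0;              // 0 = in H, 2 = in F(I), 3 = in E(D)
  while (i > 0 || j > 0) {
    size_t idx = (size_t) i * (m + 1) + j;
    if (state == 0) {
      unsigned char code = tbH[idx];
      if (code == 0) break;               // local alignment start
      if (code == 1) {
        ops.push_back('M');
        md_ref.push_back(ref[j - 1]);
        md_kind.push_back(query[i - 1] == ref[j - 1] ? '=' : 'X');
        --i; --j;
      } else {
        state = (int) code;               // enter gap matrix
      }
    } else if (state == 2) {              // F: insertion, consumes query
      ops.push_back('I');
      bool opened = tbF[idx] == 1;
      --i;
      if (opened) state = 0;
    } else {                              // E: deletion, consumes ref
      ops.push_back('D');
      md_ref.push_back(ref[j - 1]);
      md_kind.push_back('D');
      bool opened = tbE[idx] == 1;
      --j;
      if (opened) state = 0;
    }
  }

  int q_start = i + 1;                    // 1-based first aligned query base
  int r_start = j + 1;                    // 1-based first aligned ref base

  // Build CIGAR from the reversed op path, adding soft clips.
  std::string cigar;
  int left_clip = q_start - 1;
  int right_clip = n - bi;
  if (left_clip > 0) cigar += std::to_string(left_clip) + "S";
  int run = 0; char cur = 0;
  for (int k = (int) ops.size() - 1; k >= 0; --k) {
    char c = ops[k];
    if (c == cur) { ++run; }
    else {
      if (run > 0) cigar += std::to_string(run) + std::string(1, cur);
      cur = c; run = 1;
    }
  }
  if (run > 0) cigar += std::to_string(run) + std::string(1, cur);
  if (right_clip > 0) cigar += std::to_string(right_clip) + "S";

  // Build MD from the reversed per-column record (M and D columns only).
  std::string md;
  int match_run = 0;
  bool in_del = false;
  for (int k = (int) md_kind.size() - 1; k >= 0; --k) {
    char kind = md_kind[k];
    char rb = md_ref[k];
    if (kind == '=') { ++match_run; in_del = false; }
    else if (kind == 'X') {
      md += std::to_string(match_run); match_run = 0; in_del = false;
      md.push_back(rb);
    } else {                              // deletion column
      if (!in_del) { md += std::to_string(match_run); match_run = 0; md.push_back('^'); in_del = true; }
      md.push_back(rb);
    }
  }
  md += std::to_string(match_run);

  return List::create(
    _["score"] = best,
    _["mapped"] = true,
    _["ref_start"] = r_start,
    _["query_start"] = q_start,
    _["query_end"] = bi,
    _["cigar"] = cigar,
    _["md"] = md);
}
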