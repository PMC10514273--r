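#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Overlap merger for a read pair. s2rc/q2rc are the reverse-complemented
// second mate and its (reversed) qualities. Scans candidate overlap lengths
// from the longest possible down to min_overlap and accepts the first
// (longest) whose mismatch rate is <= max_mismatch_rate. Disagreements are
// resolved by the higher-quality base (first mate wins ties); merged
// quality is the max of the two mates at overlap columns.

// [[Rcpp::export(name = ".merge_overlap_cpp")]]
List merge_overlap_cpp(const std::string& s1, const std::string& s2rc,
                       const IntegerVector& q1, const IntegerVector& q2rc,
                       int min_overlap, double max_mismatch_rate) {
  const int n1 = (int) s1.size();
  const int n2 = (int) s2rc.size();
  if (n1 == 0 || n2 == 0)
    return List::create(_["merged"] = false, _["reason"] = "empty_read");
  const int max_ov = std::min(n1, n2);
  if (max_ov < min_overlap)
    return List::create(_["merged"] = false, _["reason"] = "too_short");

  for (int L = max_ov; L >= min_overlap; --L) {
    // overlap: last L bases of s1 vs first L bases of s2rc
    int mm = 0;
    const int off = n1 - L;
    const int allowed = (int) std::floor(max_mismatch_rate * L + 1e-9);
    for (int k = 0; k < L; ++k) {
      if (s1[off + k] != s2rc[k]) {
        if (++mm > allowed) break;
      }
    }
    if (mm > allowed) continue;

    const int mlen = n1 + n2 - L;
    std::string seq(mlen, 'N');
    IntegerVector qual(mlen);
    for (int k = 0; k < off; ++k) { seq[k] = s1[k]; qual[k] = q1[k]; }
    for (int k = 0; k < L; ++k) {
      char b1 = s1[off + k], b2 = s2rc[k];
      int a = q1[off + k], b = q2rc[k];
      seq[off + k] = (b1 == b2) ? b1 : (a >= b ? b1 : b2);
      qual[off + k] = std::max(a, b);
    }
    for (int k = L; k < n2; ++k) { seq[off + k] = s2rc[k]; qual[off + k] = q2rc[k]; }
    return List::create(
      _["merged"] = true,
      _["seq"] = seq,
      _["qual"] = qual,
      _["overlap"] = L,
      _["mismatches"] = mm);
  }
  return List::create(_["merged"] = false, _["reason"] = "no_overlap");
}
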