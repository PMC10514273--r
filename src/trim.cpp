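#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
using namespace Rcpp;

// Exogenous-sequence trimming scan (bbduk-style): any read window matching a
// length-k subsequence of an exogenous sequence, or a length >= mink match
// anchored at a read end, is removed together with everything outward of it
// (toward the nearer read end). Returns, per read, the 1-based retained
// region [keep_start, keep_end] (keep_start > keep_end means empty read).

static inline int hamming_leq(const char* a, const char* b, int n, int maxmm) {
  int mm = 0;
  for (int i = 0; i < n; ++i) {
    if (a[i] != b[i] && ++mm > maxmm) return maxmm + 1;
  }
  return mm;
}

// [[Rcpp::export(name = ".exo_trim_scan_cpp")]]
IntegerMatrix exo_trim_scan_cpp(const CharacterVector& reads,
                                const CharacterVector& kmers,
                                const CharacterVector& end_prefixes,
                                const CharacterVector& end_suffixes,
                                const CharacterVector& full_exo,
                                int k, int mink, int hdist) {
  std::unordered_set<std::string> kset, pset, sset;
  for (R_xlen_t i = 0; i < kmers.size(); ++i) kset.insert(as<std::string>(kmers[i]));
  for (R_xlen_t i = 0; i < end_prefixes.size(); ++i) pset.insert(as<std::string>(end_prefixes[i]));
  for (R_xlen_t i = 0; i < end_suffixes.size(); ++i) sset.insert(as<std::string>(end_suffixes[i]));
  std::vector<std::string> fullv;
  for (R_xlen_t i = 0; i < full_exo.size(); ++i) fullv.push_back(as<std::string>(full_exo[i]));

  const R_xlen_t n = reads.size();
  IntegerMatrix out(n, 2);
  for (R_xlen_t r = 0; r < n; ++r) {
    const std::string s = as<std::string>(reads[r]);
    const int len = (int) s.size();
    int keep_start = 1, keep_end = len;
    // full k-mer hits anywhere in the read
    if (len >= k && !kset.empty()) {
      for (int pos = 0; pos + k <= len; ++pos) {
        if (kset.count(s.substr(pos, k))) {
          int mstart = pos + 1, mend = pos + k;   // 1-based
          int left_out = mstart - 1, right_out = len - mend;
          if (left_out <= right_out) {
            if (mend + 1 > keep_start) keep_start = mend + 1;
          } else {
            if (mstart - 1 < keep_end) keep_end = mstart - 1;
          }
        }
      }
    }
    // complete exogenous sequence at a read end, tolerating up to hdist
    // substitutions (sequencing errors inside a primer must not leave it
    // behind to be soft-clipped later)
    for (const auto& e : fullv) {
      const int Le = (int) e.size();
      if (Le > len) continue;
      if (hamming_leq(s.data(), e.data(), Le, hdist) <= hdist) {
        if (Le + 1 > keep_start) keep_start = Le + 1;
      }
      if (hamming_leq(s.data() + (len - Le), e.data(), Le, hdist) <= hdist) {
        if (len - Le < keep_end) keep_end = len - Le;
      }
    }
    // end-anchored shorter matches, longest first: read prefix vs exogenous
    // suffixes (partial primer hanging off the 5' end) ...
    for (int L = std::min(k - 1, len); L >= mink; --L) {
      if (sset.count(s.substr(0, L))) {
        if (L + 1 > keep_start) keep_start = L + 1;
        break;
      }
    }
    // ... and read suffix vs exogenous prefixes (3' end)
    for (int L = std::min(k - 1, len); L >= mink; --L) {
      if (pset.count(s.substr(len - L, L))) {
        if (len - L < keep_end) keep_end = len - L;
        break;
      }
    }
    out(r, 0) = keep_start;
    out(r, 1) = keep_end;
  }
  return out;
}

// 3' quality trim: length retained after removing the maximal suffix of
// bases with Phred quality < q. Qualities are Phred+33 encoded strings.

// [[Rcpp::export(name = ".qtrim3_cpp")]]
IntegerVector qtrim3_cpp(const CharacterVector& quals, int q) {
  const R_xlen_t n = quals.size();
  IntegerVector out(n);
  for (R_xlen_t r = 0; r < n; ++r) {
    const std::string s = as<std::string>(quals[r]);
    int keep = (int) s.size();
    while (keep > 0 && ((int) s[keep - 1] - 33) < q) --keep;
    out[r] = keep;
  }
  return out;
}

// Shared k-mer counts between each read and each reference sequence, used to
// shortlist candidate references before full local alignment.

// [[Rcpp::export(name = ".kmer_hits_cpp")]]
IntegerMatrix kmer_hits_cpp(const CharacterVector& reads,
                            const CharacterVector& refs, int k) {
  const R_xlen_t nr = reads.size(), nf = refs.size();
  std::vector<std::unordered_set<std::string>> refsets(nf);
  for (R_xlen_t j = 0; j < nf; ++j) {
    const std::string rs = as<std::string>(refs[j]);
    for (int pos = 0; pos + k <= (int) rs.size(); ++pos)
      refsets[j].insert(rs.substr(pos, k));
  }
  IntegerMatrix out(nr, nf);
  for (R_xlen_t i = 0; i < nr; ++i) {
    const std::string s = as<std::string>(reads[i]);
    const int len = (int) s.size();
    std::vector<std::string> qk;
    qk.reserve(std::max(0, len - k + 1));
    for (int pos = 0; pos + k <= len; ++pos) qk.push_back(s.substr(pos, k));
    for (R_xlen_t j = 0; j < nf; ++j) {
      int hits = 0;
      for (const auto& km : qk) if (refsets[j].count(km)) ++hits;
      out(i, j) = hits;
    }
  }
  return out;
}
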