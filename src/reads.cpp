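#include <Rcpp.h>
#include <string>
using namespace Rcpp;

static inline char comp(char b) {
  switch (b) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string out(s.rbegin(), s.rend());
  for (std::size_t i = 0; i < out.size(); ++i) out[i] = comp(out[i]);
  return out;
}

// Merge read pairs by their best ungapped 3' overlap.
// r2/q2 are in sequencer orientation; r2 is reverse-complemented (and q2
// reversed) internally. Qualities are Phred+33 strings. At mismatching
// overlap positions the higher-quality base wins (tie: read 1) and the
// consensus quality is the larger of the two.
// status: 0 = merged, 1 = overlap shorter than min_overlap,
//         2 = mismatch fraction above threshold, 3 = empty read.
// [[Rcpp::export(name = ".merge_pairs_cpp")]]
List merge_pairs_cpp(CharacterVector r1, CharacterVector q1,
                     CharacterVector r2, CharacterVector q2,
                     int min_overlap, double max_mismatch_frac) {
  R_xlen_t n = r1.size();
  if (q1.size() != n || r2.size() != n || q2.size() != n)
    stop("input vectors must have equal length");
  if (min_overlap < 1) stop("min_overlap must be >= 1");
  CharacterVector mseq(n), mqual(n);
  IntegerVector overlap(n), status(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s1 = as<std::string>(r1[i]);
    std::string a1 = as<std::string>(q1[i]);
    std::string s2 = revcomp(as<std::string>(r2[i]));
    std::string a2 = as<std::string>(q2[i]);
    std::reverse(a2.begin(), a2.end());
    if (s1.empty() || s2.empty()) { status[i] = 3; continue; }
    if (s1.size() != a1.size() || s2.size() != a2.size())
      stop("sequence/quality length mismatch at record %d", (int)(i + 1));
    const int n1 = s1.size(), n2 = s2.size();
    const int omax = std::min(n1, n2);
    // best overlap by matching bases among overlaps meeting the mismatch
    // constraint (an unconstrained maximum favours long spurious overlaps
    // whose absolute match count exceeds a shorter perfect one); ties go
    // to the longer overlap
    int best_o = -1, best_match = -1;
    for (int o = omax; o >= min_overlap; --o) {
      int match = 0;
      const char *p1 = s1.data() + (n1 - o);
      const char *p2 = s2.data();
      for (int k = 0; k < o; ++k) match += (p1[k] == p2[k]);
      if ((double)(o - match) / o > max_mismatch_frac) continue;
      if (match > best_match) { best_match = match; best_o = o; }
    }
    if (best_o < 0) { status[i] = (omax >= min_overlap) ? 2 : 1; continue; }
    const int o = best_o;
    std::string ms = s1.substr(0, n1 - o);
    std::string mq = a1.substr(0, n1 - o);
    ms.reserve(n1 + n2 - o); mq.reserve(n1 + n2 - o);
    for (int k = 0; k < o; ++k) {
      char b1 = s1[n1 - o + k], b2 = s2[k];
      char c1 = a1[n1 - o + k], c2 = a2[k];
      if (b1 == b2 || c1 >= c2) ms.push_back(b1); else ms.push_back(b2);
      mq.push_back(c1 >= c2 ? c1 : c2);
    }
    ms.append(s2, o, std::string::npos);
    mq.append(a2, o, std::string::npos);
    mseq[i] = ms; mqual[i] = mq;
    overlap[i] = o; status[i] = 0;
  }
  return List::create(_["seq"] = mseq, _["qual"] = mqual,
                      _["overlap"] = overlap, _["status"] = status);
}

// Per-read mean Phred score and fraction of bases below q, from Phred+33
// quality strings.
// [[Rcpp::export(name = ".phred_stats_cpp")]]
NumericMatrix phred_stats_cpp(CharacterVector qual, int q) {
  R_xlen_t n = qual.size();
  NumericMatrix out(n, 2);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(qual[i]);
    if (s.empty()) { out(i, 0) = NA_REAL; out(i, 1) = NA_REAL; continue; }
    long sum = 0; int below = 0;
    for (char c : s) {
      int ph = (int)c - 33;
      sum += ph;
      below += (ph < q);
    }
    out(i, 0) = (double)sum / s.size();
    out(i, 1) = (double)below / s.size();
  }
  return out;
}

// Substitute bases at 1-based (read, position) coordinates; used by the
// sequencing-error model. read_idx/pos/base have one entry per error.
// [[Rcpp::export(name = ".inject_errors_cpp")]]
CharacterVector inject_errors_cpp(CharacterVector seqs, IntegerVector read_idx,
                                  IntegerVector pos, CharacterVector base) {
  R_xlen_t ne = read_idx.size();
  if (pos.size() != ne || base.size() != ne)
    stop("error coordinate vectors must have equal length");
  std::vector<std::string> s(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) s[i] = as<std::string>(seqs[i]);
  for (R_xlen_t e = 0; e < ne; ++e) {
    int ri = read_idx[e] - 1, pi = pos[e] - 1;
    if (ri < 0 || ri >= (int)s.size() || pi < 0 || pi >= (int)s[ri].size())
      stop("error coordinate out of range");
    s[ri][pi] = as<std::string>(base[e])[0];
  }
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out[i] = s[i];
  return out;
}
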