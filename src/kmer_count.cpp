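#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// 2-bit base codes; -1 for anything that is not A/C/G/T (N etc.)
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Canonical k-mer counting over a set of reads. Rolling 2-bit encoding of
// the forward k-mer and its reverse complement; windows containing a non-ACGT
// base are skipped. k is limited to 31 so a k-mer fits in 62 bits.
// Returns the multiplicity histogram (m -> number of distinct k-mers seen m
// times), the total number of k-mer instances counted, and the number of
// distinct canonical k-mers.
// [[Rcpp::export]]
List kmer_hist_cpp(CharacterVector seqs, int k, int cap) {
  if (k < 3 || k > 31) stop("k must be between 3 and 31");
  std::unordered_map<uint64_t, uint32_t> counts;
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
  const int shift_rc = 2 * (k - 1);
  double total = 0.0;

  for (R_xlen_t s = 0; s < seqs.size(); ++s) {
    const char *p = CHAR(STRING_ELT(seqs, s));
    uint64_t fwd = 0, rc = 0;
    int valid = 0; // length of current run of ACGT bases
    for (const char *q = p; *q; ++q) {
      int c = base_code(*q);
      if (c < 0) { valid = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)c) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - c) << shift_rc);
      if (++valid >= k) {
        uint64_t canon = fwd < rc ? fwd : rc;
        ++counts[canon];
        total += 1.0;
      }
    }
  }

  // histogram of multiplicities, excess binned at cap
  std::unordered_map<uint32_t, double> hist;
  for (auto &kv : counts) {
    uint32_t m = kv.second;
    if ((int)m > cap) m = (uint32_t)cap;
    hist[m] += 1.0;
  }
  std::vector<uint32_t> ms;
  ms.reserve(hist.size());
  for (auto &kv : hist) ms.push_back(kv.first);
  std::sort(ms.begin(), ms.end());
  IntegerVector mult(ms.size());
  NumericVector cnt(ms.size());
  for (size_t i = 0; i < ms.size(); ++i) {
    mult[i] = (int)ms[i];
    cnt[i] = hist[ms[i]];
  }
  return List::create(_["multiplicity"] = mult, _["count"] = cnt,
                      _["total_kmers"] = total,
                      _["distinct_kmers"] = (double)counts.size());
}
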