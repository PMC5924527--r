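#include <Rcpp.h>
#include <string>
using namespace Rcpp;

// Ungapped scan of one linker orientation against a read at every offset,
// including partial overhangs at the read ends as long as the aligned span
// is at least min_core. Updates the best candidate in place. A candidate
// qualifies when matches/aligned_length >= min_identity AND the longest run
// of consecutive matching bases (the "continuous core") is >= min_core.
// Tie-break: more matches wins; then smaller read_start; then the candidate
// scanned first (callers scan the + strand first).
struct Cand {
  bool found = false;
  int read_start = 0, read_end = 0, matches = 0, aligned = 0, run = 0;
  int strand = 0; // 0 = '+', 1 = '-'
};

static void scan_orientation(const char *read, int rlen, const char *link,
                             int llen, int min_core, double min_identity,
                             int strand, Cand &best) {
  for (int off = -(llen - min_core); off <= rlen - min_core; ++off) {
    int a = off > 0 ? off : 0;           // aligned span on read: [a, b)
    int b = off + llen < rlen ? off + llen : rlen;
    int aligned = b - a;
    if (aligned < min_core) continue;
    int matches = 0, run = 0, best_run = 0;
    for (int i = a; i < b; ++i) {
      char rc_ = read[i], lc = link[i - off];
      // N never matches; comparison is case-sensitive on uppercased input
      bool eq = (rc_ == lc) && rc_ != 'N';
      if (eq) { ++matches; if (++run > best_run) best_run = run; }
      else run = 0;
    }
    if (best_run < min_core) continue;
    if ((double)matches < min_identity * (double)aligned) continue;
    if (!best.found || matches > best.matches ||
        (matches == best.matches && a < best.read_start)) {
      best.found = true;
      best.read_start = a; best.read_end = b;
      best.matches = matches; best.aligned = aligned;
      best.run = best_run; best.strand = strand;
    }
  }
}

// Best qualifying linker match per read. Returns parallel vectors with
// found=FALSE rows zeroed. Reads shorter than min_core yield no match.
// [[Rcpp::export]]
List linker_scan_cpp(CharacterVector reads, std::string linker,
                     std::string linker_rc, int min_core,
                     double min_identity, bool both_strands) {
  R_xlen_t n = reads.size();
  LogicalVector found(n);
  IntegerVector rs(n), re(n), matches(n), aligned(n), run(n);
  CharacterVector strand(n);
  int llen = (int)linker.size();
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, i));
    int rlen = (int)LENGTH(STRING_ELT(reads, i));
    Cand best;
    if (rlen >= min_core) {
      scan_orientation(r, rlen, linker.c_str(), llen, min_core,
                       min_identity, 0, best);
      if (both_strands)
        scan_orientation(r, rlen, linker_rc.c_str(), llen, min_core,
                         min_identity, 1, best);
    }
    found[i] = best.found;
    rs[i] = best.read_start; re[i] = best.read_end;
    matches[i] = best.matches; aligned[i] = best.aligned; run[i] = best.run;
    strand[i] = best.strand == 0 ? "+" : "-";
  }
  return List::create(_["found"] = found, _["read_start"] = rs,
                      _["read_end"] = re, _["matches"] = matches,
                      _["aligned_length"] = aligned,
                      _["longest_exact_run"] = run, _["strand"] = strand);
}
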