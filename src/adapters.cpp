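// 3' adapter trimming: find the leftmost read position where a prefix of
// the adapter aligns to the read suffix with at most one mismatch per ten
// bases of overlap, overlap at least min_overlap. Everything 5' of that
// position is the insert.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".trim_adapter_cpp")]]
CharacterVector trim_adapter_cpp(CharacterVector reads, std::string adapter,
                                 int min_overlap) {
  int n = reads.size();
  int alen = (int)adapter.size();
  CharacterVector out(n);
  for (int r = 0; r < n; ++r) {
    if (reads[r] == NA_STRING) { out[r] = NA_STRING; continue; }
    std::string s = as<std::string>(reads[r]);
    int rlen = (int)s.size();
    int found = -1;
    for (int p = 0; p <= rlen - min_overlap; ++p) {
      int ov = std::min(rlen - p, alen);
      int allowed = ov / 10;
      int mm = 0;
      bool ok = true;
      for (int k = 0; k < ov; ++k) {
        if (s[p + k] != adapter[k] && ++mm > allowed) { ok = false; break; }
      }
      if (ok) { found = p; break; }
    }
    if (found < 0) {
      out[r] = NA_STRING; // no adapter: insert longer than read, discard
    } else {
      out[r] = s.substr(0, found);
    }
  }
  return out;
}
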