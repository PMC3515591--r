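// Fast inner loops for tag/reference comparison:
//  - best known-miRNA hit per tag over end offsets (isomiR window)
//  - prefilter of transcript windows by weighted duplex mismatches

#include <Rcpp.h>
using namespace Rcpp;

// Best hit of each tag against the db: fewest mismatches in the overlap,
// ties -> smallest |offset|, then lowest db index (db pre-sorted by id in
// R). Overhangs beyond max_shift on either end disqualify an offset.
// [[Rcpp::export(name = ".match_known_cpp")]]
IntegerMatrix match_known_cpp(CharacterVector tags, CharacterVector db,
                              int max_mm, int max_shift) {
  int nt = tags.size(), nd = db.size();
  std::vector<std::string> dbs(nd);
  for (int d = 0; d < nd; ++d) dbs[d] = as<std::string>(db[d]);
  IntegerMatrix out(nt, 3); // db index (1-based, 0 = none), mm, offset
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    int Lt = (int)tag.size();
    int best_d = 0, best_mm = max_mm + 1, best_o = 0;
    for (int d = 0; d < nd; ++d) {
      const std::string& mat = dbs[d];
      int Lm = (int)mat.size();
      for (int o = -max_shift; o <= max_shift; ++o) {
        // tag index i (0-based) faces mature index i + o
        int i0 = std::max(0, -o);
        int i1 = std::min(Lt - 1, Lm - 1 - o);
        if (i1 < i0) continue;
        int left = std::abs(o);
        int right = std::abs(Lm - o - Lt);
        if (left > max_shift || right > max_shift) continue;
        int mm = 0;
        for (int i = i0; i <= i1 && mm <= max_mm; ++i)
          if (tag[i] != mat[i + o]) ++mm;
        if (mm > max_mm) continue;
        bool better = mm < best_mm ||
          (mm == best_mm && best_d > 0 &&
           std::abs(o) < std::abs(best_o));
        if (best_d == 0) better = true;
        if (better) { best_d = d + 1; best_mm = mm; best_o = o; }
      }
    }
    out(t, 0) = best_d;
    out(t, 1) = best_d ? best_mm : NA_INTEGER;
    out(t, 2) = best_d ? best_o : NA_INTEGER;
  }
  return out;
}

static bool is_wc(char m, char t) {
  return (m == 'A' && t == 'T') || (m == 'T' && t == 'A') ||
         (m == 'C' && t == 'G') || (m == 'G' && t == 'C');
}
static bool is_wobble(char m, char t) {
  return (m == 'G' && t == 'T') || (m == 'T' && t == 'G');
}

// Window start positions (1-based) where the weighted duplex mismatch
// count (mismatch 1, G:U wobble 0.5) is at most max_weighted. miRNA
// position i (5'->3') faces window position L - i + 1.
// [[Rcpp::export(name = ".target_prefilter_cpp")]]
IntegerVector target_prefilter_cpp(std::string mirna, std::string transcript,
                                   double max_weighted) {
  int L = (int)mirna.size(), Tn = (int)transcript.size();
  std::vector<int> keep;
  if (Tn >= L) {
    int max_half = (int)(2.0 * max_weighted + 0.5); // weights in half units
    for (int s = 0; s + L <= Tn; ++s) {
      int half = 0;
      for (int i = 0; i < L; ++i) {
        char m = mirna[i], t = transcript[s + L - 1 - i];
        if (is_wc(m, t)) continue;
        half += is_wobble(m, t) ? 1 : 2;
        if (half > max_half) break;
      }
      if (half <= max_half) keep.push_back(s + 1);
    }
  }
  return wrap(keep);
}

// First matching reference class per tag (1-based index into class_texts,
// 0 = none): exact substring of the class text in either orientation.
// Class texts are reference sequences joined with 'N' separators.
// [[Rcpp::export(name = ".ref_class_cpp")]]
IntegerVector ref_class_cpp(CharacterVector tags, CharacterVector class_texts) {
  int nt = tags.size(), nc = class_texts.size();
  std::vector<std::string> texts(nc);
  for (int c = 0; c < nc; ++c) texts[c] = as<std::string>(class_texts[c]);
  IntegerVector out(nt);
  for (int t = 0; t < nt; ++t) {
    std::string tag = as<std::string>(tags[t]);
    int L = (int)tag.size();
    std::string rc(L, 'N');
    for (int i = 0; i < L; ++i) {
      char ch = tag[L - 1 - i];
      rc[i] = ch == 'A' ? 'T' : ch == 'T' ? 'A' : ch == 'C' ? 'G'
            : ch == 'G' ? 'C' : 'N';
    }
    int cls = 0;
    for (int c = 0; c < nc && cls == 0; ++c) {
      if (texts[c].find(tag) != std::string::npos ||
          texts[c].find(rc) != std::string::npos) cls = c + 1;
    }
    out[t] = cls;
  }
  return out;
}
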