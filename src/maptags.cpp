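// Ungapped tag-to-genome mapping with up to max_mm substitutions, both
// strands. Seed-and-extend with a 6-mer genome index: each tag is split
// into max_mm + 1 segments, so every alignment with <= max_mm mismatches
// has at least one mismatch-free segment (pigeonhole) whose leading 6-mer
// is found in the index; candidates are verified by direct comparison.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <set>
using namespace Rcpp;

static const int K = 6;

static inline int code2(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default: return -1;
  }
}

static char comp(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default: return 'N';
  }
}

struct Hit {
  int scaffold, start, strand, mm; // strand 0 = '+', 1 = '-'
  bool operator<(const Hit& o) const {
    if (scaffold != o.scaffold) return scaffold < o.scaffold;
    if (start != o.start) return start < o.start;
    return strand < o.strand;
  }
};

// [[Rcpp::export(name = ".map_tags_cpp")]]
DataFrame map_tags_cpp(CharacterVector tags, CharacterVector scaffolds,
                       int max_mm) {
  int ns = scaffolds.size();
  std::vector<std::string> seqs(ns);
  for (int s = 0; s < ns; ++s) seqs[s] = as<std::string>(scaffolds[s]);

  // 6-mer index over all scaffolds
  std::unordered_map<int, std::vector<std::pair<int, int>>> index;
  for (int s = 0; s < ns; ++s) {
    const std::string& g = seqs[s];
    int n = (int)g.size();
    int code = 0, valid = 0;
    for (int i = 0; i < n; ++i) {
      int b = code2(g[i]);
      if (b < 0) { valid = 0; code = 0; continue; }
      code = ((code << 2) | b) & ((1 << (2 * K)) - 1);
      if (++valid >= K) index[code].push_back({s, i - K + 1});
    }
  }

  std::vector<int> out_tag, out_scaffold, out_start, out_mm;
  std::vector<int> out_strand;

  for (int t = 0; t < tags.size(); ++t) {
    std::string fwd = as<std::string>(tags[t]);
    int L = (int)fwd.size();
    if (L < K) continue;
    std::string rev(L, 'N');
    for (int i = 0; i < L; ++i) rev[L - 1 - i] = comp(fwd[i]);
    std::set<Hit> hits;
    if (L < K * (max_mm + 1)) {
      // too short for pigeonhole seeding: direct scan
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& pat = strand == 0 ? fwd : rev;
        for (int s = 0; s < ns; ++s) {
          const std::string& g = seqs[s];
          for (int start = 0; start + L <= (int)g.size(); ++start) {
            int mm = 0;
            for (int i = 0; i < L && mm <= max_mm; ++i)
              if (g[start + i] != pat[i]) ++mm;
            if (mm <= max_mm) hits.insert({s, start, strand, mm});
          }
        }
      }
      for (const Hit& h : hits) {
        out_tag.push_back(t + 1);
        out_scaffold.push_back(h.scaffold + 1);
        out_start.push_back(h.start + 1);
        out_strand.push_back(h.strand);
        out_mm.push_back(h.mm);
      }
      continue;
    }
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& pat = strand == 0 ? fwd : rev;
      int nseg = max_mm + 1;
      for (int seg = 0; seg < nseg; ++seg) {
        int off = seg * L / nseg; // segment start within pattern
        if (off + K > L) off = L - K;
        int code = 0;
        bool ok = true;
        for (int i = 0; i < K; ++i) {
          int b = code2(pat[off + i]);
          if (b < 0) { ok = false; break; }
          code = (code << 2) | b;
        }
        if (!ok) continue;
        auto it = index.find(code);
        if (it == index.end()) continue;
        for (auto& pc : it->second) {
          int s = pc.first;
          int start = pc.second - off; // candidate alignment start (0-based)
          if (start < 0 || start + L > (int)seqs[s].size()) continue;
          const std::string& g = seqs[s];
          int mm = 0;
          for (int i = 0; i < L && mm <= max_mm; ++i)
            if (g[start + i] != pat[i]) ++mm;
          if (mm <= max_mm) hits.insert({s, start, strand, mm});
        }
      }
    }
    for (const Hit& h : hits) {
      out_tag.push_back(t + 1);
      out_scaffold.push_back(h.scaffold + 1);
      out_start.push_back(h.start + 1);
      out_strand.push_back(h.strand);
      out_mm.push_back(h.mm);
    }
  }
  return DataFrame::create(
    _["tag"] = out_tag, _["scaffold"] = out_scaffold,
    _["start"] = out_start, _["strand"] = out_strand, _["mm"] = out_mm
  );
}
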