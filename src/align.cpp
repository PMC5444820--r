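#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
using namespace Rcpp;

// Hamming-only matching of reads against a panel of fixed 50-nt probe
// sequences, allowing up to `max_mm` mismatches (default 2, the rule used
// for ligated-probe panels). Uses a pigeonhole chunk index: a read within
// max_mm mismatches of a probe must match at least one of max_mm+1 disjoint
// chunks exactly, so candidate probes are found by hashing chunks instead of
// scanning the whole panel. Partial reads of length >= min_len are compared
// against probe prefixes over their full length; shorter reads are
// unmapped. Ties at the best distance are reported as ambiguous.

typedef std::unordered_map<std::string, std::vector<int> > ChunkMap;

static void build_index(const std::vector<std::string>& probes,
                        const int* starts, const int* widths, int nchunk,
                        std::vector<ChunkMap>& maps) {
  maps.assign(nchunk, ChunkMap());
  for (int p = 0; p < (int)probes.size(); ++p) {
    for (int c = 0; c < nchunk; ++c) {
      maps[c][probes[p].substr(starts[c], widths[c])].push_back(p);
    }
  }
}

static inline int hamming_prefix(const std::string& a, const std::string& b,
                                 int len, int bail) {
  int mm = 0;
  for (int i = 0; i < len; ++i) {
    if (a[i] != b[i]) { if (++mm > bail) return mm; }
  }
  return mm;
}

// [[Rcpp::export]]
List align_reads_cpp(CharacterVector reads, CharacterVector probes,
                     int max_mm = 2, int min_len = 40) {
  int np = probes.size(), nr = reads.size();
  std::vector<std::string> pv(np);
  for (int i = 0; i < np; ++i) pv[i] = as<std::string>(probes[i]);

  // full-length chunks over the 50-mer and partial chunks within the first
  // 39 nt (so they are complete for any read of length >= min_len = 40)
  const int full_starts[3] = {0, 17, 34}, full_widths[3] = {17, 17, 16};
  const int part_starts[3] = {0, 13, 26}, part_widths[3] = {13, 13, 13};
  std::vector<ChunkMap> full_maps, part_maps;
  build_index(pv, full_starts, full_widths, 3, full_maps);
  build_index(pv, part_starts, part_widths, 3, part_maps);

  IntegerVector idx(nr, 0), nmm(nr, NA_INTEGER);
  LogicalVector tie(nr, false);
  std::vector<int> cand;
  std::vector<char> seen(np, 0);

  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reads[r]);
    int len = (int)s.size();
    if (len < min_len) continue;
    int L = len < 50 ? len : 50;
    const std::vector<ChunkMap>& maps = (L >= 50) ? full_maps : part_maps;
    const int* starts = (L >= 50) ? full_starts : part_starts;
    const int* widths = (L >= 50) ? full_widths : part_widths;

    cand.clear();
    for (int c = 0; c < 3; ++c) {
      ChunkMap::const_iterator it =
        maps[c].find(s.substr(starts[c], widths[c]));
      if (it == maps[c].end()) continue;
      for (size_t k = 0; k < it->second.size(); ++k) {
        int p = it->second[k];
        if (!seen[p]) { seen[p] = 1; cand.push_back(p); }
      }
    }

    int best = max_mm + 1, best_p = -1; bool is_tie = false;
    for (size_t k = 0; k < cand.size(); ++k) {
      int mm = hamming_prefix(s, pv[cand[k]], L, max_mm);
      if (mm < best) { best = mm; best_p = cand[k]; is_tie = false; }
      else if (mm == best) is_tie = true;
      seen[cand[k]] = 0;
    }
    if (best <= max_mm && best_p >= 0) {
      if (is_tie) { tie[r] = true; }
      else { idx[r] = best_p + 1; nmm[r] = best; }
    }
  }
  return List::create(_["index"] = idx, _["mismatches"] = nmm,
                      _["tie"] = tie);
}

// Chimera classification: a full-length (50 nt) read whose first 25 nt match
// the downstream half of probe A and last 25 nt match the upstream half of a
// *different* probe B, each half within `max_half_mm` mismatches. Halves are
// matched by a 2-chunk pigeonhole index (13+12 nt), valid for max_half_mm = 1.
// Ambiguous halves (tied best distance) fail classification.

static int best_half(const std::string& half,
                     const std::vector<std::string>& halves,
                     std::vector<ChunkMap>& maps,
                     const int* starts, const int* widths,
                     int max_mm, std::vector<char>& seen) {
  std::vector<int> cand;
  for (int c = 0; c < 2; ++c) {
    ChunkMap::const_iterator it =
      maps[c].find(half.substr(starts[c], widths[c]));
    if (it == maps[c].end()) continue;
    for (size_t k = 0; k < it->second.size(); ++k) {
      int p = it->second[k];
      if (!seen[p]) { seen[p] = 1; cand.push_back(p); }
    }
  }
  int best = max_mm + 1, best_p = -1; bool is_tie = false;
  for (size_t k = 0; k < cand.size(); ++k) {
    int mm = hamming_prefix(half, halves[cand[k]], 25, max_mm);
    if (mm < best) { best = mm; best_p = cand[k]; is_tie = false; }
    else if (mm == best) is_tie = true;
    seen[cand[k]] = 0;
  }
  if (best > max_mm || is_tie) return -1;
  return best_p;
}

// [[Rcpp::export]]
List chimera_scan_cpp(CharacterVector reads, CharacterVector probes,
                      int max_half_mm = 1) {
  int np = probes.size(), nr = reads.size();
  std::vector<std::string> down(np), up(np);
  for (int i = 0; i < np; ++i) {
    std::string p = as<std::string>(probes[i]);
    down[i] = p.substr(0, 25);
    up[i] = p.substr(25, 25);
  }
  const int starts[2] = {0, 13}, widths[2] = {13, 12};
  std::vector<ChunkMap> dmaps, umaps;
  build_index(down, starts, widths, 2, dmaps);
  build_index(up, starts, widths, 2, umaps);

  IntegerVector ia(nr, 0), ib(nr, 0);
  std::vector<char> seen(np, 0);
  for (int r = 0; r < nr; ++r) {
    std::string s = as<std::string>(reads[r]);
    if ((int)s.size() != 50) continue;
    int a = best_half(s.substr(0, 25), down, dmaps, starts, widths,
                      max_half_mm, seen);
    if (a < 0) continue;
    int b = best_half(s.substr(25, 25), up, umaps, starts, widths,
                      max_half_mm, seen);
    if (b < 0 || b == a) continue;
    ia[r] = a + 1; ib[r] = b + 1;
  }
  return List::create(_["down_index"] = ia, _["up_index"] = ib);
}
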