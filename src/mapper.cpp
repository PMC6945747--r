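#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
using namespace Rcpp;

// Gapless seed-and-extend read placement against a set of reference contigs.
// Seeds are exact k-mers at staggered offsets; the placement with maximal
// seed support wins, ties broken by smallest reference position, then
// forward strand. Substitution-only by design: the simulator emits no indels.

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;
  }
}

static inline char comp_base(char c) {
  switch (c) {
    case 'A': case 'a': return 'T';
    case 'C': case 'c': return 'G';
    case 'G': case 'g': return 'C';
    case 'T': case 't': return 'A';
    default: return 'N';
  }
}

struct Candidate {
  long long pos;   // global start
  int votes;
  bool fwd;
};

// best candidate per strand given seed hit start positions
static void best_candidate(std::vector<long long> &cand, bool fwd, Candidate &best) {
  if (cand.empty()) return;
  std::sort(cand.begin(), cand.end());
  size_t i = 0;
  while (i < cand.size()) {
    size_t j = i;
    while (j < cand.size() && cand[j] == cand[i]) ++j;
    int votes = (int)(j - i);
    bool better = votes > best.votes ||
      (votes == best.votes &&
       (cand[i] < best.pos || (cand[i] == best.pos && fwd && !best.fwd)));
    if (better) { best.pos = cand[i]; best.votes = votes; best.fwd = fwd; }
    i = j;
  }
}

// [[Rcpp::export]]
List cpp_map_reads(CharacterVector reads, CharacterVector refs,
                   int k, double max_mismatch_fraction) {
  int nref = refs.size();
  std::string global;
  std::vector<long long> offset(nref + 1, 0);
  for (int i = 0; i < nref; ++i) {
    global += std::string(refs[i]);
    offset[i + 1] = (long long)global.size();
  }
  long long G = (long long)global.size();
  std::vector<int> gcode(G);
  for (long long i = 0; i < G; ++i) gcode[i] = base_code(global[i]);

  // k-mer index (2-bit rolling encoding, k <= 31)
  if (k > 31) stop("seed length k must be <= 31");
  std::unordered_map<uint64_t, std::vector<int64_t>> index;
  index.reserve((size_t)G);
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < nref; ++r) {
    long long lo = offset[r], hi = offset[r + 1];
    uint64_t h = 0; int run = 0;
    for (long long i = lo; i < hi; ++i) {
      int c = gcode[i];
      if (c > 3) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= k) index[h].push_back(i - k + 1);
    }
  }

  int n = reads.size();
  IntegerVector out_ref(n), out_start(n), out_len(n), out_mm(n), out_strand(n);
  LogicalVector out_mapped(n);
  std::vector<int> mm_read; std::vector<int> mm_ref; std::vector<int> mm_pos;
  std::vector<char> mm_base;

  std::vector<long long> cand_f, cand_r;
  for (int ri = 0; ri < n; ++ri) {
    std::string rd = std::string(reads[ri]);
    int len = (int)rd.size();
    out_len[ri] = len;
    out_mapped[ri] = false;
    out_ref[ri] = NA_INTEGER; out_start[ri] = NA_INTEGER;
    out_mm[ri] = NA_INTEGER; out_strand[ri] = NA_INTEGER;
    if (len < k) continue;

    std::string rc(len, 'N');
    for (int i = 0; i < len; ++i) rc[i] = comp_base(rd[len - 1 - i]);

    // staggered seed offsets: 0, k, 2k, ..., plus the final k-mer
    std::vector<int> offs;
    for (int o = 0; o + k <= len; o += k) offs.push_back(o);
    if (offs.empty() || offs.back() != len - k) offs.push_back(len - k);

    Candidate best; best.pos = -1; best.votes = 0; best.fwd = true;
    for (int strand = 0; strand < 2; ++strand) {
      const std::string &seq = strand == 0 ? rd : rc;
      std::vector<long long> &cand = strand == 0 ? cand_f : cand_r;
      cand.clear();
      for (size_t oi = 0; oi < offs.size(); ++oi) {
        int o = offs[oi];
        uint64_t h = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int c = base_code(seq[o + i]);
          if (c > 3) { ok = false; break; }
          h = (h << 2) | (uint64_t)c;
        }
        if (!ok) continue;
        auto it = index.find(h & mask);
        if (it == index.end()) continue;
        for (size_t j = 0; j < it->second.size(); ++j) {
          long long start = it->second[j] - o;
          // placement must lie fully inside one contig
          int r = (int)(std::upper_bound(offset.begin(), offset.end(),
                                         it->second[j]) - offset.begin()) - 1;
          if (start < offset[r] || start + len > offset[r + 1]) continue;
          cand.push_back(start);
        }
      }
      best_candidate(cand, strand == 0, best);
    }
    if (best.votes == 0) continue;

    const std::string &seq = best.fwd ? rd : rc;
    long long start = best.pos;
    int r = (int)(std::upper_bound(offset.begin(), offset.end(), start) -
                  offset.begin()) - 1;
    int mm = 0;
    for (int i = 0; i < len; ++i)
      if (base_code(seq[i]) > 3 || gcode[start + i] > 3 ||
          base_code(seq[i]) != gcode[start + i]) ++mm;
    if ((double)mm / (double)len > max_mismatch_fraction) continue;

    out_mapped[ri] = true;
    out_ref[ri] = r + 1;
    out_start[ri] = (int)(start - offset[r]);
    out_mm[ri] = mm;
    out_strand[ri] = best.fwd ? 1 : -1;
    for (int i = 0; i < len; ++i) {
      if (base_code(seq[i]) > 3 || gcode[start + i] > 3 ||
          base_code(seq[i]) != gcode[start + i]) {
        mm_read.push_back(ri + 1);
        mm_ref.push_back(r + 1);
        mm_pos.push_back((int)(start + i - offset[r]));
        mm_base.push_back(toupper(seq[i]));
      }
    }
  }

  CharacterVector mb(mm_base.size());
  for (size_t i = 0; i < mm_base.size(); ++i) mb[i] = std::string(1, mm_base[i]);
  return List::create(
    _["ref"] = out_ref, _["start"] = out_start, _["aligned_length"] = out_len,
    _["n_mismatch"] = out_mm, _["strand"] = out_strand, _["mapped"] = out_mapped,
    _["mm_read"] = IntegerVector(mm_read.begin(), mm_read.end()),
    _["mm_ref"] = IntegerVector(mm_ref.begin(), mm_ref.end()),
    _["mm_pos"] = IntegerVector(mm_pos.begin(), mm_pos.end()),
    _["mm_base"] = mb);
}
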