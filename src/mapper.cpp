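// Exact-match paired-end read mapper for error-free synthetic reads.
// A read maps wherever the full read matches the reference exactly; matches
// are found by a k-mer seed on the first k bases followed by full-length
// verification, so the seed is complete for exact full-length matching.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

const int FLAG_PAIRED = 0x1, FLAG_PROPER = 0x2, FLAG_REV = 0x10,
          FLAG_MREV = 0x20, FLAG_FIRST = 0x40, FLAG_SECOND = 0x80,
          FLAG_SECONDARY = 0x100;

inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default: return 'N';
  }
}

struct Hit {
  int chrom;   // 0-based chromosome index
  int pos;     // 0-based start
  bool rev;    // read matched in reverse-complement orientation
};

struct KmerIndex {
  int k;
  std::vector<std::string> seqs;
  // (kmer, chrom<<32 | pos), sorted for binary search
  std::vector<std::pair<uint64_t, uint64_t> > tab;

  void build(const CharacterVector& chrom_seqs, int k_) {
    k = k_;
    seqs.clear();
    tab.clear();
    size_t total = 0;
    for (int c = 0; c < chrom_seqs.size(); ++c) {
      seqs.push_back(as<std::string>(chrom_seqs[c]));
      if (seqs.back().size() >= (size_t)k) total += seqs.back().size() - k + 1;
    }
    tab.reserve(total);
    for (size_t c = 0; c < seqs.size(); ++c) {
      const std::string& s = seqs[c];
      if (s.size() < (size_t)k) continue;
      uint64_t kmer = 0, mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
      int valid = 0;
      for (size_t i = 0; i < s.size(); ++i) {
        int b = base2bits(s[i]);
        if (b < 0) { valid = 0; kmer = 0; continue; }
        kmer = ((kmer << 2) | (uint64_t)b) & mask;
        if (++valid >= k) {
          size_t pos = i - k + 1;
          tab.push_back(std::make_pair(kmer, ((uint64_t)c << 32) | pos));
        }
      }
    }
    std::sort(tab.begin(), tab.end());
  }

  // all full-length exact matches of `read` (given orientation), capped
  void matches(const std::string& read, bool rev, int cap,
               std::vector<Hit>& out) const {
    if ((int)read.size() < k) return;
    uint64_t kmer = 0;
    for (int i = 0; i < k; ++i) {
      int b = base2bits(read[i]);
      if (b < 0) return;
      kmer = (kmer << 2) | (uint64_t)b;
    }
    std::pair<uint64_t, uint64_t> lo(kmer, 0), hi(kmer, ~0ULL);
    std::vector<std::pair<uint64_t, uint64_t> >::const_iterator it =
        std::lower_bound(tab.begin(), tab.end(), lo);
    std::vector<std::pair<uint64_t, uint64_t> >::const_iterator en =
        std::upper_bound(tab.begin(), tab.end(), hi);
    for (; it != en; ++it) {
      int c = (int)(it->second >> 32);
      size_t p = (size_t)(it->second & 0xffffffffULL);
      const std::string& s = seqs[c];
      if (p + read.size() > s.size()) continue;
      if (std::memcmp(s.data() + p, read.data(), read.size()) == 0) {
        Hit h; h.chrom = c; h.pos = (int)p; h.rev = rev;
        out.push_back(h);
        if ((int)out.size() >= cap) return;
      }
    }
  }
};

std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i) r[s.size() - 1 - i] = comp(s[i]);
  return r;
}

inline bool hit_less(const Hit& a, const Hit& b) {
  if (a.chrom != b.chrom) return a.chrom < b.chrom;
  if (a.pos != b.pos) return a.pos < b.pos;
  return a.rev < b.rev;
}

} // namespace

//' @noRd
// [[Rcpp::export]]
DataFrame cpp_exact_map_pairs(CharacterVector chrom_seqs,
                              CharacterVector reads1, CharacterVector reads2,
                              int k, int max_insert, int max_hits) {
  if (reads1.size() != reads2.size())
    stop("mate vectors differ in length");
  KmerIndex idx;
  idx.build(chrom_seqs, k);

  std::vector<int> o_frag, o_mate, o_flag, o_chrom, o_start, o_end;
  size_t n = reads1.size();
  o_frag.reserve(2 * n); o_mate.reserve(2 * n); o_flag.reserve(2 * n);
  o_chrom.reserve(2 * n); o_start.reserve(2 * n); o_end.reserve(2 * n);

  std::vector<Hit> h1, h2;
  for (size_t i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(reads1[i]);
    std::string r2 = as<std::string>(reads2[i]);
    if ((int)r1.size() < k || (int)r2.size() < k)
      stop("seed length k exceeds read length");
    h1.clear(); h2.clear();
    idx.matches(r1, false, max_hits, h1);
    idx.matches(revcomp(r1), true, max_hits, h1);
    idx.matches(r2, false, max_hits, h2);
    idx.matches(revcomp(r2), true, max_hits, h2);
    std::sort(h1.begin(), h1.end(), hit_less);
    std::sort(h2.begin(), h2.end(), hit_less);

    // proper pair: same chromosome, converging orientation, insert bound.
    // Ties between equally good placements (e.g. the two identical copies
    // left by a duplication-deletion exchange) are broken uniformly at
    // random via R's RNG, as read aligners do, so coverage is not biased
    // towards one copy; seed the R session for reproducibility.
    std::vector<std::pair<int, int> > cand;
    for (size_t a = 0; a < h1.size(); ++a) {
      for (size_t b = 0; b < h2.size(); ++b) {
        if (h1[a].chrom != h2[b].chrom) continue;
        if (h1[a].rev == h2[b].rev) continue;
        int fw_pos, rv_end;
        if (!h1[a].rev) { // r1 forward, r2 reverse, r2 downstream
          fw_pos = h1[a].pos;
          rv_end = h2[b].pos + (int)r2.size();
          if (h2[b].pos < h1[a].pos) continue;
        } else {          // r2 forward, r1 reverse, r1 downstream
          fw_pos = h2[b].pos;
          rv_end = h1[a].pos + (int)r1.size();
          if (h1[a].pos < h2[b].pos) continue;
        }
        if (rv_end - fw_pos > max_insert) continue;
        cand.push_back(std::make_pair((int)a, (int)b));
      }
    }
    int best1 = -1, best2 = -1;
    if (!cand.empty()) {
      size_t pick = cand.size() == 1 ? 0 :
        (size_t)(unif_rand() * (double)cand.size());
      if (pick >= cand.size()) pick = cand.size() - 1;
      best1 = cand[pick].first;
      best2 = cand[pick].second;
    }

    bool proper = best1 >= 0;
    int prim1 = proper ? best1 : (h1.empty() ? -1 : 0);
    int prim2 = proper ? best2 : (h2.empty() ? -1 : 0);

    for (int mate = 1; mate <= 2; ++mate) {
      const std::vector<Hit>& hh = (mate == 1) ? h1 : h2;
      const std::vector<Hit>& other = (mate == 1) ? h2 : h1;
      int prim = (mate == 1) ? prim1 : prim2;
      int oprim = (mate == 1) ? prim2 : prim1;
      int len = (mate == 1) ? (int)r1.size() : (int)r2.size();
      if (prim < 0) continue; // unmapped mate: no record emitted
      for (size_t a = 0; a < hh.size(); ++a) {
        int flag = FLAG_PAIRED | ((mate == 1) ? FLAG_FIRST : FLAG_SECOND);
        if (hh[a].rev) flag |= FLAG_REV;
        if (oprim >= 0 && other[oprim].rev) flag |= FLAG_MREV;
        if ((int)a == prim) {
          if (proper) flag |= FLAG_PROPER;
        } else {
          flag |= FLAG_SECONDARY;
        }
        o_frag.push_back((int)i + 1);
        o_mate.push_back(mate);
        o_flag.push_back(flag);
        o_chrom.push_back(hh[a].chrom + 1);
        o_start.push_back(hh[a].pos);
        o_end.push_back(hh[a].pos + len);
      }
    }
  }

  return DataFrame::create(
      Named("fragment") = o_frag, Named("mate") = o_mate,
      Named("flag") = o_flag, Named("chrom") = o_chrom,
      Named("start") = o_start, Named("end") = o_end);
}
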