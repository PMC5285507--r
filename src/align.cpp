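// Exact ungapped seed-and-extend alignment and adapter-trim scanning.
//
// Completeness argument for the seeding: an alignment with at most
// max_mismatches mismatches leaves at least one of (max_mismatches + 1)
// disjoint tag chunks mismatch-free (pigeonhole); the k-mer at the start of
// that chunk then occurs exactly in the reference, so looking up the chunk
// starts in a k-mer index and verifying every candidate offset misses no
// qualifying locus. Tags too short for the chunked seeding fall back to a
// brute-force scan of every offset.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const int KIDX = 6;  // index k-mer size

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;    // N and anything else never matches
  }
}

// encode a k-mer starting at s[pos]; returns false if it contains non-ACGT
static inline bool encode_kmer(const std::string& s, size_t pos, int k,
                               uint32_t& out) {
  uint32_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[pos + i]);
    if (c < 0) return false;
    v = (v << 2) | (uint32_t)c;
  }
  out = v;
  return true;
}

static inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

// mismatches of tag vs ref at offset start, early exit beyond cap
static inline int count_mm(const std::string& ref, size_t start,
                           const std::string& tag, int cap) {
  int mm = 0;
  for (size_t i = 0; i < tag.size(); ++i) {
    if (ref[start + i] != tag[i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

struct KmerIndex {
  // key -> packed (ref_id << 40 | pos); references well below 2^40
  std::unordered_map<uint32_t, std::vector<uint64_t> > map;
  const std::vector<std::string>* refs;

  void build(const std::vector<std::string>& r) {
    refs = &r;
    for (size_t ri = 0; ri < r.size(); ++ri) {
      const std::string& s = r[ri];
      if ((int)s.size() < KIDX) continue;
      for (size_t p = 0; p + KIDX <= s.size(); ++p) {
        uint32_t key;
        if (encode_kmer(s, p, KIDX, key)) {
          map[key].push_back(((uint64_t)ri << 40) | (uint64_t)p);
        }
      }
    }
  }
};

struct Hit {
  int tag;     // 1-based tag index
  int ref;     // 1-based reference index
  int pos;     // 0-based start on the forward reference
  char strand;
  int mm;
  double score;
};

static void align_one_orientation(const std::string& tag, char strand,
                                  int tag_idx, const KmerIndex& idx,
                                  int max_mm, double penalty, double match,
                                  double min_frac, std::vector<Hit>& out) {
  const std::vector<std::string>& refs = *idx.refs;
  int len = (int)tag.size();
  int nchunk = max_mm + 1;
  int chunk = len / nchunk;
  std::vector<uint64_t> cand;  // packed (ref << 40 | start)

  if (chunk >= KIDX) {
    for (int c = 0; c < nchunk; ++c) {
      size_t off = (size_t)(c * chunk);
      uint32_t key;
      if (!encode_kmer(tag, off, KIDX, key)) continue;
      auto it = idx.map.find(key);
      if (it == idx.map.end()) continue;
      for (uint64_t packed : it->second) {
        int ri = (int)(packed >> 40);
        long rpos = (long)(packed & 0xFFFFFFFFFFULL);
        long start = rpos - (long)off;
        if (start < 0 || start + len > (long)refs[ri].size()) continue;
        cand.push_back(((uint64_t)ri << 40) | (uint64_t)start);
      }
    }
    std::sort(cand.begin(), cand.end());
    cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  } else {
    // brute force every offset of every reference
    for (size_t ri = 0; ri < refs.size(); ++ri) {
      if ((long)refs[ri].size() < len) continue;
      for (long start = 0; start + len <= (long)refs[ri].size(); ++start) {
        cand.push_back(((uint64_t)ri << 40) | (uint64_t)start);
      }
    }
  }

  double min_score = min_frac * len;
  for (uint64_t packed : cand) {
    int ri = (int)(packed >> 40);
    long start = (long)(packed & 0xFFFFFFFFFFULL);
    int mm = count_mm(refs[ri], (size_t)start, tag, max_mm);
    if (mm > max_mm) continue;
    double score = match * (len - mm) - penalty * mm;
    if (score < min_score) continue;
    out.push_back(Hit{tag_idx, ri + 1, (int)start, strand, mm, score});
  }
}

// [[Rcpp::export]]
DataFrame cpp_align_tags(CharacterVector tags, CharacterVector refs,
                         int seed_length, int max_mismatches,
                         double mismatch_penalty, double match_score,
                         double min_score_fraction) {
  std::vector<std::string> refv(refs.size());
  for (int i = 0; i < refs.size(); ++i) refv[i] = as<std::string>(refs[i]);
  KmerIndex idx;
  idx.build(refv);

  std::vector<Hit> hits;
  for (int t = 0; t < tags.size(); ++t) {
    std::string tag = as<std::string>(tags[t]);
    if ((int)tag.size() < seed_length) continue;  // unmapped by contract
    align_one_orientation(tag, '+', t + 1, idx, max_mismatches,
                          mismatch_penalty, match_score, min_score_fraction,
                          hits);
    align_one_orientation(revcomp(tag), '-', t + 1, idx, max_mismatches,
                          mismatch_penalty, match_score, min_score_fraction,
                          hits);
  }

  int n = (int)hits.size();
  IntegerVector tagc(n), refc(n), posc(n), mmc(n);
  CharacterVector strc(n);
  NumericVector scoc(n);
  for (int i = 0; i < n; ++i) {
    tagc[i] = hits[i].tag;
    refc[i] = hits[i].ref;
    posc[i] = hits[i].pos;
    strc[i] = std::string(1, hits[i].strand);
    mmc[i] = hits[i].mm;
    scoc[i] = hits[i].score;
  }
  return DataFrame::create(_["tag"] = tagc, _["ref"] = refc, _["pos"] = posc,
                           _["strand"] = strc, _["mismatches"] = mmc,
                           _["score"] = scoc,
                           _["stringsAsFactors"] = false);
}

// leftmost position where a prefix of the adapter occupies the read suffix
// with <= max_mm mismatches over an overlap >= min_overlap; returns the
// read length when no such position exists.
// [[Rcpp::export]]
IntegerVector cpp_trim_positions(CharacterVector reads, std::string adapter,
                                 int min_overlap, int max_mm) {
  int alen = (int)adapter.size();
  IntegerVector out(reads.size());
  for (int i = 0; i < reads.size(); ++i) {
    std::string r = as<std::string>(reads[i]);
    int L = (int)r.size();
    int cut = L;
    for (int p = 0; p <= L - min_overlap; ++p) {
      int ov = std::min(L - p, alen);
      if (ov < min_overlap) break;
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < ov; ++j) {
        if (r[p + j] != adapter[j]) {
          if (++mm > max_mm) { ok = false; break; }
        }
      }
      if (ok) { cut = p; break; }
    }
    out[i] = cut;
  }
  return out;
}
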