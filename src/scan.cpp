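#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
using namespace Rcpp;

// Bitmask encoding for matching: A=1, C=2, G=4, T=8.
// N and any other character encode to 0 and never match an IUPAC letter;
// the strand separator '$' encodes to 16 and never matches either, so no
// occurrence can span it.
static inline int enc_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case '$': return 16;
    default:  return 0;
  }
}

static void encode_seq(const char *s, std::vector<int> &out) {
  out.clear();
  for (const char *p = s; *p; ++p) out.push_back(enc_mask(*p));
}

// Exact-word enumeration with sequence-level presence counts.
// sets: list of character vectors (one per condition); len: word length.
// Returns list(words = character vector, counts = integer matrix words x sets).
// Only words composed purely of A/C/G/T are enumerated (2-bit packed code).
// [[Rcpp::export]]
List enum_words_sets_c(List sets, int len) {
  if (len < 1 || len > 31) stop("word length must be in 1..31");
  std::unordered_map<uint64_t, std::vector<int> > tab;
  const int n_sets = sets.size();
  std::vector<int> codes;
  for (int si = 0; si < n_sets; ++si) {
    CharacterVector seqs = sets[si];
    for (int qi = 0; qi < seqs.size(); ++qi) {
      const char *s = CHAR(STRING_ELT(seqs, qi));
      encode_seq(s, codes);
      const int L = (int)codes.size();
      std::unordered_set<uint64_t> seen;
      uint64_t code = 0;
      int valid = 0; // number of consecutive ACGT chars ending here
      for (int t = 0; t < L; ++t) {
        int m = codes[t];
        int b;
        switch (m) { case 1: b = 0; break; case 2: b = 1; break;
                     case 4: b = 2; break; case 8: b = 3; break;
                     default: b = -1; }
        if (b < 0) { valid = 0; code = 0; continue; }
        code = ((code << 2) | (uint64_t)b) & ((1ULL << (2 * len)) - 1);
        if (++valid >= len) seen.insert(code);
      }
      for (uint64_t w : seen) {
        auto it = tab.find(w);
        if (it == tab.end()) {
          std::vector<int> cnt(n_sets, 0);
          cnt[si] = 1;
          tab.emplace(w, std::move(cnt));
        } else it->second[si] += 1;
      }
    }
  }
  const int n_words = (int)tab.size();
  CharacterVector words(n_words);
  IntegerMatrix counts(n_words, n_sets);
  int i = 0;
  std::string buf(len, 'A');
  const char *ACGT = "ACGT";
  for (auto &kv : tab) {
    uint64_t w = kv.first;
    for (int p = len - 1; p >= 0; --p) { buf[p] = ACGT[w & 3]; w >>= 2; }
    words[i] = buf;
    for (int si = 0; si < n_sets; ++si) counts(i, si) = kv.second[si];
    ++i;
  }
  return List::create(_["words"] = words, _["counts"] = counts);
}

static inline bool match_at(const std::vector<int> &seq, int pos,
                            const int *mask, int len) {
  for (int k = 0; k < len; ++k)
    if (!(seq[pos + k] & mask[k])) return false;
  return true;
}

// Sequence-level presence counts of IUPAC words (bitmask rows of `masks`)
// in each set. Returns integer matrix n_words x n_sets.
// [[Rcpp::export]]
IntegerMatrix count_words_sets_c(List sets, IntegerMatrix masks) {
  const int n_words = masks.nrow(), len = masks.ncol(), n_sets = sets.size();
  IntegerMatrix counts(n_words, n_sets);
  std::vector< std::vector<int> > wmask(n_words, std::vector<int>(len));
  for (int w = 0; w < n_words; ++w)
    for (int k = 0; k < len; ++k) wmask[w][k] = masks(w, k);
  std::vector<int> codes;
  for (int si = 0; si < n_sets; ++si) {
    CharacterVector seqs = sets[si];
    for (int qi = 0; qi < seqs.size(); ++qi) {
      encode_seq(CHAR(STRING_ELT(seqs, qi)), codes);
      const int L = (int)codes.size();
      if (L < len) continue;
      for (int w = 0; w < n_words; ++w) {
        const int *mk = wmask[w].data();
        for (int t = 0; t + len <= L; ++t) {
          if (match_at(codes, t, mk, len)) { counts(w, si) += 1; break; }
        }
      }
    }
  }
  return counts;
}

// Masked variant used during generalization rounds: a generalization
// matches every sequence its generating specializations match, so only the
// complement needs scanning. `known`: n_words x n_total_seqs (sequences
// flattened over sets in order) marking sequences already known to match.
// Returns counts (including known) and the full per-sequence hit matrix.
// [[Rcpp::export]]
List count_words_sets_masked_c(List sets, IntegerMatrix masks,
                               LogicalMatrix known) {
  const int n_words = masks.nrow(), len = masks.ncol(), n_sets = sets.size();
  IntegerMatrix counts(n_words, n_sets);
  LogicalMatrix hits(known.nrow(), known.ncol());
  std::vector< std::vector<int> > wmask(n_words, std::vector<int>(len));
  for (int w = 0; w < n_words; ++w)
    for (int k = 0; k < len; ++k) wmask[w][k] = masks(w, k);
  std::vector<int> codes;
  int offset = 0;
  for (int si = 0; si < n_sets; ++si) {
    CharacterVector seqs = sets[si];
    for (int qi = 0; qi < seqs.size(); ++qi) {
      const int gq = offset + qi;
      bool encoded = false;
      for (int w = 0; w < n_words; ++w) {
        if (known(w, gq)) { counts(w, si) += 1; hits(w, gq) = true; continue; }
        if (!encoded) { encode_seq(CHAR(STRING_ELT(seqs, qi)), codes);
                        encoded = true; }
        const int L = (int)codes.size();
        if (L < len) continue;
        const int *mk = wmask[w].data();
        for (int t = 0; t + len <= L; ++t) {
          if (match_at(codes, t, mk, len)) {
            counts(w, si) += 1; hits(w, gq) = true; break;
          }
        }
      }
    }
    offset += seqs.size();
  }
  return List::create(_["counts"] = counts, _["hits"] = hits);
}

// 0-based start positions of all (possibly overlapping) matches of one
// IUPAC word in each sequence. Returns a list of integer vectors.
// [[Rcpp::export]]
List match_positions_c(CharacterVector seqs, IntegerVector mask) {
  const int len = mask.size();
  std::vector<int> mk(mask.begin(), mask.end());
  List out(seqs.size());
  std::vector<int> codes;
  for (int qi = 0; qi < seqs.size(); ++qi) {
    encode_seq(CHAR(STRING_ELT(seqs, qi)), codes);
    const int L = (int)codes.size();
    std::vector<int> hits;
    for (int t = 0; t + len <= L; ++t)
      if (match_at(codes, t, mk.data(), len)) hits.push_back(t);
    out[qi] = IntegerVector(hits.begin(), hits.end());
  }
  return out;
}
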