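#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

// 2-bit DNA encoding; k-mers up to k=31 fit a uint64. Anything outside
// {A,C,G,T} (notably N) breaks the current window.
static inline int base2bit(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static inline char bit2base(int b) { return "ACGT"[b & 3]; }

// Append the canonical (strand-symmetric) codes of all N-free k-mers of s.
static void canon_codes(const std::string& s, int k, std::vector<uint64_t>& out) {
  int n = (int)s.size();
  if (n < k) return;
  uint64_t mask = (1ULL << (2 * k)) - 1;
  uint64_t fwd = 0, rev = 0;
  int run = 0, shift = 2 * (k - 1);
  for (int i = 0; i < n; ++i) {
    int b = base2bit(s[i]);
    if (b < 0) { run = 0; fwd = 0; rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) out.push_back(fwd < rev ? fwd : rev);
  }
}

static std::string decode_kmer(uint64_t code, int k) {
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = bit2base((int)(code & 3)); code >>= 2; }
  return s;
}

// Distinct canonical k-mers over a set of sequences, lexicographically sorted.
// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    canon_codes(as<std::string>(seqs[i]), k, codes);
  std::sort(codes.begin(), codes.end());
  codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
  CharacterVector out(codes.size());
  for (size_t i = 0; i < codes.size(); ++i) out[i] = decode_kmer(codes[i], k);
  return out;
}

// For each read, the number of DISTINCT canonical k-mers shared with the index.
// [[Rcpp::export]]
IntegerVector cpp_kmer_hit_counts(CharacterVector reads, CharacterVector index_kmers, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_set<uint64_t> idx;
  idx.reserve(index_kmers.size() * 2 + 8);
  std::vector<uint64_t> tmp;
  for (R_xlen_t i = 0; i < index_kmers.size(); ++i) {
    tmp.clear();
    canon_codes(as<std::string>(index_kmers[i]), k, tmp);
    for (uint64_t c : tmp) idx.insert(c);
  }
  IntegerVector out(reads.size());
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    codes.clear();
    canon_codes(as<std::string>(reads[i]), k, codes);
    std::sort(codes.begin(), codes.end());
    codes.erase(std::unique(codes.begin(), codes.end()), codes.end());
    int hits = 0;
    for (uint64_t c : codes) if (idx.count(c)) ++hits;
    out[i] = hits;
  }
  return out;
}

// Multiplicity of every distinct canonical k-mer across all sequences
// (k-mer spectrum input). Values returned in sorted k-mer order.
// [[Rcpp::export]]
IntegerVector cpp_kmer_multiplicities(CharacterVector seqs, int k) {
  if (k < 1 || k > 31) stop("k must be in [1, 31]");
  std::unordered_map<uint64_t, int> cnt;
  std::vector<uint64_t> codes;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    codes.clear();
    canon_codes(as<std::string>(seqs[i]), k, codes);
    for (uint64_t c : codes) ++cnt[c];
  }
  std::vector<std::pair<uint64_t, int>> v(cnt.begin(), cnt.end());
  std::sort(v.begin(), v.end());
  IntegerVector out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = v[i].second;
  return out;
}
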