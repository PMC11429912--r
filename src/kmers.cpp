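// Canonical k-mer presence set (2-bit rolling encoding, k <= 31) and
// assembly scan for k-mers absent from a trusted read set. This is the core
// primitive of the k-mer based quality-value assessment: an assembly k-mer
// never seen in the reads is flagged as a probable error.
#include <Rcpp.h>
#include <unordered_set>
#include <cstdint>
using namespace Rcpp;

static inline int base2bits(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

// Feed one sequence's canonical k-mers into the set.
static void add_kmers(const std::string& s, int k,
                      std::unordered_set<uint64_t>& set) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  const int shift = 2 * (k - 1);
  for (size_t i = 0; i < s.size(); ++i) {
    int b = base2bits(s[i]);
    if (b < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) set.insert(fwd < rev ? fwd : rev);
  }
}

// [[Rcpp::export(name = ".kmer_set_build")]]
SEXP kmer_set_build(CharacterVector seqs, int k) {
  if (k < 2 || k > 31) stop("k must be in 2..31");
  auto* set = new std::unordered_set<uint64_t>();
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) total += LENGTH(STRING_ELT(seqs, i));
  set->reserve(total / 8 + 1024);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    add_kmers(std::string(CHAR(STRING_ELT(seqs, i))), k, *set);
  }
  XPtr<std::unordered_set<uint64_t>> ptr(set, true);
  ptr.attr("k") = k;
  return ptr;
}

// [[Rcpp::export(name = ".kmer_set_size")]]
double kmer_set_size(SEXP ptr) {
  XPtr<std::unordered_set<uint64_t>> p(ptr);
  return (double)p->size();
}

// 1-based start positions of assembly k-mers absent from the set.
// K-mers containing non-ACGT characters are skipped (never reported).
// [[Rcpp::export(name = ".kmer_missing_positions")]]
IntegerVector kmer_missing_positions(SEXP ptr, std::string seq, int k) {
  XPtr<std::unordered_set<uint64_t>> p(ptr);
  std::vector<int> out;
  const uint64_t mask = ((1ULL << (2 * k)) - 1);
  const int shift = 2 * (k - 1);
  uint64_t fwd = 0, rev = 0;
  int run = 0;
  for (size_t i = 0; i < seq.size(); ++i) {
    int b = base2bits(seq[i]);
    if (b < 0) { run = 0; fwd = rev = 0; continue; }
    fwd = ((fwd << 2) | (uint64_t)b) & mask;
    rev = (rev >> 2) | ((uint64_t)(3 - b) << shift);
    if (++run >= k) {
      uint64_t canon = fwd < rev ? fwd : rev;
      if (p->find(canon) == p->end()) out.push_back((int)(i - k + 2));
    }
  }
  return wrap(out);
}
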