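#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <cstdint>

using namespace Rcpp;

// Exact k-mer membership index over bait sequences, strand-symmetric.
// k-mers are packed 2 bits per base, first base in the highest bits, so
// numeric order on codes equals lexicographic order on strings and the
// canonical form (min of forward and reverse complement) matches the
// string definition. Windows containing any non-ACGT character are skipped.

class KmerIndex {
public:
    int k;
    std::unordered_set<uint64_t> kmers;
    explicit KmerIndex(int k_) : k(k_) {}
};

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// Calls fun(canonical_code) for every valid k-window of s.
template <typename F>
static void each_canonical_kmer(const std::string& s, int k, F fun) {
    const size_t n = s.size();
    if ((int)n < k) return;
    const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1ULL);
    const int shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int valid = 0;  // number of consecutive valid bases ending here
    for (size_t i = 0; i < n; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << shift);
        if (++valid >= k) fun(fwd < rev ? fwd : rev);
    }
}

// [[Rcpp::export(name = ".kmer_index_build")]]
SEXP kmer_index_build(CharacterVector seqs, int k) {
    if (k < 1 || k > 31) stop("k must be between 1 and 31");
    XPtr<KmerIndex> ptr(new KmerIndex(k), true);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        each_canonical_kmer(s, k, [&](uint64_t code) { ptr->kmers.insert(code); });
    }
    return ptr;
}

// [[Rcpp::export(name = ".kmer_index_size")]]
double kmer_index_size(SEXP xp) {
    XPtr<KmerIndex> ptr(xp);
    return (double)ptr->kmers.size();
}

// Number of index hits among the k-windows of each sequence.
// [[Rcpp::export(name = ".kmer_index_hits")]]
IntegerVector kmer_index_hits(SEXP xp, CharacterVector seqs) {
    XPtr<KmerIndex> ptr(xp);
    const int k = ptr->k;
    IntegerVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        int hits = 0;
        each_canonical_kmer(s, k, [&](uint64_t code) {
            if (ptr->kmers.count(code)) ++hits;
        });
        out[i] = hits;
    }
    return out;
}

// [[Rcpp::export(name = ".kmer_index_k")]]
int kmer_index_k(SEXP xp) {
    XPtr<KmerIndex> ptr(xp);
    return ptr->k;
}

// Membership test for explicit k-mer strings (canonicalized internally).
// Windows with non-ACGT characters are never members.
// [[Rcpp::export(name = ".kmer_index_has")]]
LogicalVector kmer_index_has(SEXP xp, CharacterVector kmers) {
    XPtr<KmerIndex> ptr(xp);
    const int k = ptr->k;
    LogicalVector out(kmers.size());
    for (R_xlen_t i = 0; i < kmers.size(); ++i) {
        std::string s = as<std::string>(kmers[i]);
        bool found = false;
        if ((int)s.size() == k) {
            each_canonical_kmer(s, k, [&](uint64_t code) {
                if (ptr->kmers.count(code)) found = true;
            });
        }
        out[i] = found;
    }
    return out;
}
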