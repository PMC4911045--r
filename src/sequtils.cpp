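#include <Rcpp.h>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

std::string rc_string(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp_base(c);
    return r;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = rc_string(as<std::string>(seqs[i]));
    out.attr("names") = seqs.attr("names");
    return out;
}

// Longest L with prefix(seq, L) == suffix(seq, L), min_len <= L <= len/2.
// [[Rcpp::export(name = ".end_overlap_cpp")]]
int end_overlap_cpp(std::string seq, int min_len) {
    const int n = (int)seq.size();
    for (int L = n / 2; L >= min_len; --L)
        if (seq.compare(0, L, seq, n - L, L) == 0) return L;
    return 0;
}

// Longest o with suffix(a, o) == prefix(b, o), o >= min_len.
// [[Rcpp::export(name = ".suffix_prefix_cpp")]]
int suffix_prefix_cpp(std::string a, std::string b, int min_len) {
    const int na = (int)a.size(), nb = (int)b.size();
    for (int o = std::min(na, nb); o >= min_len; --o)
        if (a.compare(na - o, o, b, 0, o) == 0) return o;
    return 0;
}

// Lexicographically least rotation (two-pointer duel, linear time).
// [[Rcpp::export(name = ".least_rotation_cpp")]]
std::string least_rotation_cpp(std::string s) {
    const int n = (int)s.size();
    if (n == 0) return s;
    std::string t = s + s;
    int i = 0, j = 1, k = 0;
    while (i < n && j < n && k < n) {
        char a = t[i + k], b = t[j + k];
        if (a == b) { ++k; continue; }
        if (a > b) i = i + k + 1; else j = j + k + 1;
        if (i == j) ++j;
        k = 0;
    }
    return t.substr(std::min(i, j), n);
}
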