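#include <Rcpp.h>
#include <string>
#include <vector>
#include <queue>
#include <unordered_map>
#include <algorithm>
#include <cstring>
#include <cstdint>

using namespace Rcpp;

std::string rc_string(const std::string& s);  // sequtils.cpp

// ---------------------------------------------------------------------------
// Deterministic greedy exact-overlap assembler.
//
// All sequences are kept in canonical orientation (lexicographic min of the
// sequence and its reverse complement). The algorithm collapses duplicate and
// contained reads, then repeatedly merges the pair of active sequences with
// the longest exact suffix-prefix overlap >= min_overlap, considering both
// orientations. Ties on overlap length break on the canonical form of the
// would-be merged sequence (a precomputed 16-byte prefix key, then a lazy
// capped comparison), then on the constituents, which makes the result a
// function of the input multiset only, independent of input order.
// ---------------------------------------------------------------------------

namespace {

constexpr size_t KEYLEN = 16;
constexpr size_t CMP_CAP = 4096;  // tie-break prefix-compare cap

struct ASeq {
    std::string fwd;  // canonical orientation
    std::string rc;
    long reads;
    bool alive;
};

// Suffix of orient(a, ao) of length o equals prefix of orient(b, bo);
// containment candidates: orient(b, bo) occurs inside orient(a, ao) at p.
struct Cand {
    int o;
    int a, b;
    int p;
    uint8_t ao, bo;
    bool containment;
    uint8_t key[KEYLEN];  // first bytes of the canonical merged sequence
};

static inline char comp_char(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
    }
}

struct State {
    std::vector<ASeq> seqs;

    const std::string& orient(int id, uint8_t o) const {
        return o ? seqs[id].rc : seqs[id].fwd;
    }

    struct View {
        const std::string* A;
        const std::string* B;
        size_t keep;  // chars taken from A
        size_t len;
        char at(size_t i) const { return i < keep ? (*A)[i] : (*B)[i - keep]; }
    };

    View view(const Cand& c) const {
        const std::string& A = orient(c.a, c.ao);
        const std::string& B = orient(c.b, c.bo);
        if (c.containment) return View{&A, &B, A.size(), A.size()};
        size_t keep = A.size() - (size_t)c.o;
        return View{&A, &B, keep, keep + B.size()};
    }

    static bool rc_smaller(const View& v) {
        for (size_t i = 0; i < v.len; ++i) {
            char f = v.at(i);
            char r = comp_char(v.at(v.len - 1 - i));
            if (r < f) return true;
            if (f < r) return false;
        }
        return false;
    }

    static char canon_at(const View& v, bool flip, size_t i) {
        return flip ? comp_char(v.at(v.len - 1 - i)) : v.at(i);
    }

    void fill_key(Cand& c) const {
        View v = view(c);
        bool flip = rc_smaller(v);
        size_t n = std::min(v.len, KEYLEN);
        for (size_t i = 0; i < n; ++i)
            c.key[i] = (uint8_t)canon_at(v, flip, i);
        for (size_t i = n; i < KEYLEN; ++i) c.key[i] = 0;  // shorter sorts first
    }

    // true if x orders strictly before y at equal overlap length
    bool tie_before(const Cand& x, const Cand& y) const {
        int kc = std::memcmp(x.key, y.key, KEYLEN);
        if (kc) return kc < 0;
        View vx = view(x), vy = view(y);
        bool fx = rc_smaller(vx), fy = rc_smaller(vy);
        size_t n = std::min({vx.len, vy.len, CMP_CAP});
        for (size_t i = KEYLEN; i < n; ++i) {
            char cx = canon_at(vx, fx, i), cy = canon_at(vy, fy, i);
            if (cx != cy) return cx < cy;
        }
        if (vx.len != vy.len) return vx.len < vy.len;
        int c = seqs[x.a].fwd.compare(seqs[y.a].fwd);
        if (c) return c < 0;
        c = seqs[x.b].fwd.compare(seqs[y.b].fwd);
        if (c) return c < 0;
        if (x.ao != y.ao) return x.ao < y.ao;
        if (x.bo != y.bo) return x.bo < y.bo;
        if (x.a != y.a) return x.a < y.a;
        if (x.b != y.b) return x.b < y.b;
        return x.p < y.p;
    }
};

// max-heap comparator: returns true when x has lower priority than y
struct HeapCmp {
    const State* st;
    bool operator()(const Cand& x, const Cand& y) const {
        if (x.o != y.o) return x.o < y.o;
        return st->tie_before(y, x);
    }
};

// polynomial rolling hash over a window of length m
struct RollHash {
    uint64_t base = 1099511628211ULL;
    uint64_t pow_m = 1;
    int m;
    explicit RollHash(int m_) : m(m_) {
        for (int i = 0; i < m; ++i) pow_m *= base;
    }
    uint64_t full(const std::string& s, size_t p) const {
        uint64_t h = 0;
        for (int i = 0; i < m; ++i) h = h * base + (uint8_t)s[p + i];
        return h;
    }
    uint64_t roll(uint64_t h, char out, char in) const {
        return h * base - (uint64_t)(uint8_t)out * pow_m + (uint8_t)in;
    }
};

}  // namespace

// [[Rcpp::export(name = ".greedy_assemble_cpp")]]
List greedy_assemble_cpp(CharacterVector reads, int min_overlap) {
    if (min_overlap < 1) stop("min_overlap must be >= 1");
    const int m = min_overlap;

    // 1. canonical dedup
    std::unordered_map<std::string, long> uniq;
    for (R_xlen_t i = 0; i < reads.size(); ++i) {
        std::string s = as<std::string>(reads[i]);
        if (s.empty()) continue;
        std::string r = rc_string(s);
        uniq[s <= r ? s : r] += 1;
    }
    if (uniq.empty()) stop("no reads to assemble");

    std::vector<std::pair<std::string, long>> items(uniq.begin(), uniq.end());
    std::sort(items.begin(), items.end());  // canonical id order

    State st;
    st.seqs.reserve(items.size() * 2);
    for (auto& it : items) {
        ASeq a;
        a.fwd = it.first;
        a.rc = rc_string(it.first);
        a.reads = it.second;
        a.alive = true;
        st.seqs.push_back(std::move(a));
    }

    RollHash rh(m);

    // 2. containment collapse (longer sequences absorb shorter ones)
    {
        std::vector<int> order(st.seqs.size());
        for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
        std::stable_sort(order.begin(), order.end(), [&](int x, int y) {
            if (st.seqs[x].fwd.size() != st.seqs[y].fwd.size())
                return st.seqs[x].fwd.size() > st.seqs[y].fwd.size();
            return st.seqs[x].fwd < st.seqs[y].fwd;
        });
        std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> windex;
        std::vector<int> kept;
        for (int id : order) {
            ASeq& s = st.seqs[id];
            bool absorbed = false;
            int host = -1;
            const int len = (int)s.fwd.size();
            if (len >= m) {
                for (uint8_t o = 0; o < 2 && !absorbed; ++o) {
                    const std::string& q = o ? s.rc : s.fwd;
                    auto it = windex.find(rh.full(q, 0));
                    if (it == windex.end()) continue;
                    for (auto& pr : it->second) {
                        const std::string& t = st.seqs[pr.first].fwd;
                        int pos = pr.second;
                        if (pos + len <= (int)t.size() &&
                            t.compare(pos, len, q) == 0) {
                            absorbed = true;
                            host = pr.first;
                            break;
                        }
                    }
                }
            } else {
                for (int kid : kept) {
                    const std::string& t = st.seqs[kid].fwd;
                    if (t.find(s.fwd) != std::string::npos ||
                        t.find(s.rc) != std::string::npos) {
                        absorbed = true;
                        host = kid;
                        break;
                    }
                }
            }
            if (absorbed) {
                st.seqs[host].reads += s.reads;
                s.alive = false;
            } else {
                if (len >= m)
                    for (int p = 0; p + m <= len; ++p)
                        windex[rh.full(s.fwd, p)].push_back({id, p});
                kept.push_back(id);
            }
        }
    }

    // 3. candidate machinery
    HeapCmp cmp{&st};
    std::priority_queue<Cand, std::vector<Cand>, HeapCmp> heap(cmp);
    // first m-window of each orientation -> (id, orientation)
    std::unordered_map<uint64_t, std::vector<std::pair<int, uint8_t>>> pmap;

    auto register_prefixes = [&](int id) {
        const ASeq& s = st.seqs[id];
        if ((int)s.fwd.size() < m) return;
        pmap[rh.full(s.fwd, 0)].push_back({id, 0});
        pmap[rh.full(s.rc, 0)].push_back({id, 1});
    };

    auto push_cand = [&](Cand c) {
        st.fill_key(c);
        heap.push(c);
    };

    // scan orient(a, ao) as left partner against all registered prefixes
    auto scan_left = [&](int a, uint8_t ao) {
        const std::string& A = st.orient(a, ao);
        const int lenA = (int)A.size();
        if (lenA < m) return;
        uint64_t h = rh.full(A, 0);
        for (int p = 0;; ++p) {
            auto it = pmap.find(h);
            if (it != pmap.end()) {
                for (auto& pr : it->second) {
                    int b = pr.first;
                    if (b == a || !st.seqs[b].alive) continue;
                    uint8_t bo = pr.second;
                    const std::string& B = st.orient(b, bo);
                    const int lenB = (int)B.size();
                    int o = lenA - p;
                    if (o > lenB) {
                        // possible containment of B inside A at offset p
                        if (p + lenB <= lenA && A.compare(p, lenB, B) == 0)
                            push_cand(Cand{lenB, a, b, p, ao, bo, true, {}});
                    } else if (A.compare(p, o, B, 0, o) == 0) {
                        push_cand(Cand{o, a, b, p, ao, bo, o == lenB, {}});
                    }
                }
            }
            if (p + m >= lenA) break;
            h = rh.roll(h, A[p], A[p + m]);
        }
    };

    for (size_t i = 0; i < st.seqs.size(); ++i)
        if (st.seqs[i].alive) register_prefixes((int)i);
    for (size_t i = 0; i < st.seqs.size(); ++i) {
        if (st.seqs[i].alive) {
            scan_left((int)i, 0);
            scan_left((int)i, 1);
        }
    }

    // 4. greedy merge loop
    while (!heap.empty()) {
        Cand c = heap.top();
        heap.pop();
        if (!st.seqs[c.a].alive || !st.seqs[c.b].alive) continue;

        if (c.containment) {
            // absorb: content of a unchanged, so its candidates stay valid
            st.seqs[c.a].reads += st.seqs[c.b].reads;
            st.seqs[c.b].alive = false;
            continue;
        }

        const std::string& A = st.orient(c.a, c.ao);
        const std::string& B = st.orient(c.b, c.bo);
        std::string merged = A.substr(0, A.size() - (size_t)c.o) + B;
        std::string mrc = rc_string(merged);
        ASeq ns;
        if (mrc < merged) { ns.fwd = std::move(mrc); ns.rc = std::move(merged); }
        else { ns.fwd = std::move(merged); ns.rc = std::move(mrc); }
        ns.reads = st.seqs[c.a].reads + st.seqs[c.b].reads;
        ns.alive = true;
        st.seqs[c.a].alive = false;
        st.seqs[c.b].alive = false;
        int nid = (int)st.seqs.size();
        st.seqs.push_back(std::move(ns));
        register_prefixes(nid);
        scan_left(nid, 0);
        scan_left(nid, 1);
        if (st.seqs.size() % 4096 == 0) Rcpp::checkUserInterrupt();
    }

    // 5. collect contigs: length desc, then sequence
    std::vector<int> out;
    for (size_t i = 0; i < st.seqs.size(); ++i)
        if (st.seqs[i].alive) out.push_back((int)i);
    std::sort(out.begin(), out.end(), [&](int x, int y) {
        if (st.seqs[x].fwd.size() != st.seqs[y].fwd.size())
            return st.seqs[x].fwd.size() > st.seqs[y].fwd.size();
        return st.seqs[x].fwd < st.seqs[y].fwd;
    });

    CharacterVector contigs(out.size());
    NumericVector nreads(out.size());
    for (size_t i = 0; i < out.size(); ++i) {
        contigs[i] = st.seqs[out[i]].fwd;
        nreads[i] = (double)st.seqs[out[i]].reads;
    }
    return List::create(_["seq"] = contigs, _["reads_used"] = nreads);
}
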