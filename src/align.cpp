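#include <Rcpp.h>
#include <string>
#include <vector>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Semi-global affine-gap alignment: global in the query, leading and trailing
// target positions are free. Terminal query gaps are permitted but pay the
// normal affine cost, so a query longer than the alignable part of the target
// still yields a well-defined (partial) result.
//
// Scoring: match +1, mismatch -2, gap of length L costs 4 + L
// (open -4, extend -1; opening a gap therefore costs -5 for its first base).
// Gap-state to gap-state transitions (Iq <-> It) are disallowed.
// ---------------------------------------------------------------------------

static const int MATCH = 1;
static const int MISMATCH = -2;
static const int GOPEN = 5;   // cost of the first base of a gap
static const int GEXT = 1;
static const int NEG = INT_MIN / 4;

// traceback byte layout per cell:
//   bits 0-1 : M source   (0=M, 1=Iq, 2=It, 3=start)
//   bits 2-3 : Iq source  (0=M, 1=Iq, 2=start)
//   bit  4   : It source  (0=M, 1=It)

// [[Rcpp::export(name = ".sg_align_cpp")]]
List sg_align_cpp(std::string query, std::string target) {
    const int m = (int)query.size();
    const int n = (int)target.size();
    if (m < 1 || n < 1) stop("query and target must be non-empty");
    const double cells = (double)(m + 1) * (double)(n + 1);
    if (cells > 5e8) stop("alignment problem too large");

    std::vector<uint8_t> tb((size_t)(m + 1) * (n + 1), 0);
    std::vector<int> pM(n + 1), pIq(n + 1), pIt(n + 1);
    std::vector<int> cM(n + 1), cIq(n + 1), cIt(n + 1);

    // row 0: nothing aligned; M/Iq/It undefined (start handled in row 1)
    for (int j = 0; j <= n; ++j) { pM[j] = NEG; pIq[j] = NEG; pIt[j] = NEG; }

    for (int i = 1; i <= m; ++i) {
        uint8_t* tbrow = &tb[(size_t)i * (n + 1)];
        cM[0] = NEG;
        cIt[0] = NEG;
        // Iq in column 0: all-query-gap chain from (0,0)
        if (i == 1) { cIq[0] = -GOPEN; tbrow[0] |= (2 << 2); }
        else {
            if (pIq[0] - GEXT >= pM[0] - GOPEN) { cIq[0] = pIq[0] - GEXT; tbrow[0] |= (1 << 2); }
            else { cIq[0] = pM[0] - GOPEN; tbrow[0] |= (0 << 2); }
        }
        const char qc = query[i - 1];
        for (int j = 1; j <= n; ++j) {
            // M
            int best, src;
            if (i == 1) { best = 0; src = 3; }
            else {
                best = pM[j - 1]; src = 0;
                if (pIq[j - 1] > best) { best = pIq[j - 1]; src = 1; }
                if (pIt[j - 1] > best) { best = pIt[j - 1]; src = 2; }
            }
            int s = (qc == target[j - 1]) ? MATCH : MISMATCH;
            cM[j] = (best <= NEG / 2) ? NEG : best + s;
            uint8_t code = (uint8_t)src;
            // Iq
            int vIq, sIq;
            if (i == 1) { vIq = -GOPEN; sIq = 2; }
            else {
                vIq = pM[j] - GOPEN; sIq = 0;
                if (pIq[j] - GEXT > vIq) { vIq = pIq[j] - GEXT; sIq = 1; }
            }
            cIq[j] = (vIq <= NEG / 2) ? NEG : vIq;
            code |= (uint8_t)(sIq << 2);
            // It
            int vIt = cM[j - 1] - GOPEN, sIt = 0;
            if (cIt[j - 1] - GEXT > vIt) { vIt = cIt[j - 1] - GEXT; sIt = 1; }
            cIt[j] = (vIt <= NEG / 2) ? NEG : vIt;
            code |= (uint8_t)(sIt << 4);
            tbrow[j] = code;
        }
        std::swap(pM, cM); std::swap(pIq, cIq); std::swap(pIt, cIt);
    }

    // best final cell: max over j of M[m][j] and Iq[m][j]; leftmost j,
    // M preferred over Iq on ties
    int best = NEG, bj = 0, bstate = 0;  // 0=M, 1=Iq
    for (int j = 0; j <= n; ++j) {
        if (pM[j] > best) { best = pM[j]; bj = j; bstate = 0; }
        if (pIq[j] > best) { best = pIq[j]; bj = j; bstate = 1; }
    }

    // traceback
    int i = m, j = bj, state = bstate;
    long matches = 0, columns = 0;
    int firstM_q = 0, lastM_q = 0, firstM_t = 0, lastM_t = 0;
    long inner_cols = 0;
    bool done = false;
    std::vector<uint8_t> cols;  // 0=M match,1=M mismatch,2=Iq,3=It (reversed)
    cols.reserve((size_t)m + 16);
    while (!done) {
        uint8_t code = tb[(size_t)i * (n + 1) + j];
        if (state == 0) {  // M consumes q_i, t_j
            bool is_match = (query[i - 1] == target[j - 1]);
            cols.push_back(is_match ? 0 : 1);
            if (lastM_q == 0) { lastM_q = i; lastM_t = j; }
            firstM_q = i; firstM_t = j;
            int src = code & 3;
            --i; --j;
            if (src == 3 || i == 0) done = true;
            else state = src;
        } else if (state == 1) {  // Iq consumes q_i
            cols.push_back(2);
            int src = (code >> 2) & 3;
            --i;
            if (src == 2 || i == 0) done = true;
            else state = src;
        } else {  // It consumes t_j
            cols.push_back(3);
            int src = (code >> 4) & 1;
            --j;
            state = src == 0 ? 0 : 2;
        }
    }

    // cols is in reverse path order; count matches and columns between the
    // first and last M column (terminal query-gap runs excluded)
    int first_m_idx = -1, last_m_idx = -1;
    long aligned = 0;  // query bases in match/mismatch columns
    for (int k2 = 0; k2 < (int)cols.size(); ++k2)
        if (cols[k2] <= 1) { if (last_m_idx < 0) last_m_idx = k2; first_m_idx = k2; }
    if (first_m_idx >= 0) {
        for (int k2 = last_m_idx; k2 <= first_m_idx; ++k2) {
            ++inner_cols;
            if (cols[k2] == 0) ++matches;
            if (cols[k2] <= 1) ++aligned;
        }
        columns = inner_cols;
    }

    bool full = (firstM_q == 1 && lastM_q == m);
    int tstart = (firstM_t > 0) ? firstM_t - 1 : 0;  // 0-based
    int tend = (lastM_t > 0) ? lastM_t : 0;          // half-open

    return List::create(
        _["score"] = best,
        _["target_start"] = tstart,
        _["target_end"] = tend,
        _["query_aligned"] = (double)aligned,
        _["matches"] = (double)matches,
        _["columns"] = (double)columns,
        _["full_query"] = full);
}
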