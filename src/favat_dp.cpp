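#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Three-profile global alignment with affine gap costs, maximised
// sum-of-pairs objective over the three pairwise projections.
//
// Column shapes, in traceback-preference order (lower index preferred):
//   0 rrr, 1 rr-, 2 r-r, 3 -rr, 4 r--, 5 -r-, 6 --r
// Pairwise projection states per shape: 3 = residue/residue (RR),
// 2 = residue/gap (RG), 1 = gap/residue (GR), 0 = gap/gap (GG).
//
// Gap model (quasi-natural): a GG projected column costs nothing; an RG/GR
// column costs GEP when the immediately preceding column has the same
// projected state, otherwise GOP.  With free end gaps each projection is
// additionally split into lead/mid/trail phases: gap columns before the
// first RR column or after the last one cost nothing.

static const int D1[7] = {1, 1, 1, 0, 1, 0, 0};
static const int D2[7] = {1, 1, 0, 1, 0, 1, 0};
static const int D3[7] = {1, 0, 1, 1, 0, 0, 1};

static inline int pair_state(int shape, int pair) {
    switch (pair) {
    case 0: return 2 * D1[shape] + D2[shape];
    case 1: return 2 * D1[shape] + D3[shape];
    default: return 2 * D2[shape] + D3[shape];
    }
}

struct StateTable {
    int nstates;
    bool end_free;
    std::vector<int> shape;          // shape of each state
    std::vector<int> phase;          // packed phases (0 if !end_free)
    std::vector<unsigned char> ok;   // state validity
    std::vector<double> base;        // base[q * nstates + s], -inf if illegal
    std::vector<double> base_start;  // from the virtual origin state
};

static inline int phase_of(int packed, int pair) {
    static const int div_[3] = {1, 3, 9};
    return (packed / div_[pair]) % 3;
}

static StateTable build_states(double gop, double gep, bool end_free) {
    const double NEG = -std::numeric_limits<double>::infinity();
    StateTable st;
    st.end_free = end_free;
    st.nstates = end_free ? 7 * 27 : 7;
    st.shape.resize(st.nstates);
    st.phase.resize(st.nstates);
    st.ok.assign(st.nstates, 1);
    for (int s = 0; s < st.nstates; ++s) {
        st.shape[s] = s % 7;
        st.phase[s] = s / 7;
        if (end_free) {
            for (int p = 0; p < 3; ++p) {
                int f = pair_state(st.shape[s], p);
                if (f == 3 && phase_of(st.phase[s], p) != 1) st.ok[s] = 0;
            }
        }
    }
    st.base.assign((size_t)st.nstates * st.nstates, NEG);
    st.base_start.assign(st.nstates, NEG);

    for (int s = 0; s < st.nstates; ++s) {
        if (!st.ok[s]) continue;
        // from the virtual start: all phases at lead, no previous column
        double c0 = 0.0; bool legal0 = true;
        for (int p = 0; p < 3; ++p) {
            int f = pair_state(st.shape[s], p);
            int ph = end_free ? phase_of(st.phase[s], p) : 1;
            if (end_free && ph == 1 && f != 3) {
                // entering mid on a non-RR column is never useful but legal
                if (f == 1 || f == 2) c0 -= gop;
            } else if (!end_free) {
                if (f == 1 || f == 2) c0 -= gop;
            }
            // lead (ph 0) and trail (ph 2) gap columns are free
        }
        if (legal0) st.base_start[s] = c0;

        for (int q = 0; q < st.nstates; ++q) {
            if (!st.ok[q]) continue;
            double c = 0.0; bool legal = true;
            for (int p = 0; p < 3; ++p) {
                int f = pair_state(st.shape[s], p);
                int e = pair_state(st.shape[q], p);
                int phs = end_free ? phase_of(st.phase[s], p) : 1;
                int phq = end_free ? phase_of(st.phase[q], p) : 1;
                if (end_free) {
                    if (phs < phq) { legal = false; break; }
                    if (f == 3 && phq == 2) { legal = false; break; }
                }
                if (f == 1 || f == 2) {
                    if (phs == 1) {
                        if (phq == 1) c -= (e == f) ? gep : gop;
                        else c -= gop;   // entering mid on a gap column
                    }
                    // phs 0 or 2: free end gap
                }
            }
            if (legal) st.base[(size_t)q * st.nstates + s] = c;
        }
    }
    return st;
}

// [[Rcpp::export(name = ".favat_dp")]]
List favat_dp(NumericMatrix sp12, NumericMatrix sp13, NumericMatrix sp23,
              double gop, double gep, bool end_free) {
    const int n1 = sp12.nrow(), n2 = sp12.ncol(), n3 = sp13.ncol();
    if (sp13.nrow() != n1 || sp23.nrow() != n2 || sp23.ncol() != n3)
        stop("inconsistent pair-score matrix dimensions");
    if (n1 < 1 || n2 < 1 || n3 < 1) stop("profiles must have at least one column");

    const double NEG = -std::numeric_limits<double>::infinity();
    StateTable st = build_states(gop, gep, end_free);
    const int ns = st.nstates;
    const unsigned char FROM_START = 255, NOWHERE = 254;

    const size_t plane = (size_t)(n2 + 1) * (n3 + 1) * ns;
    std::vector<double> prev(plane, NEG), cur(plane, NEG);
    std::vector<uint8_t> bp((size_t)(n1 + 1) * plane, NOWHERE);

    // sparse predecessor lists per state
    std::vector<std::vector<std::pair<int, double> > > preds(ns);
    for (int s = 0; s < ns; ++s)
        for (int q = 0; q < ns; ++q) {
            double b = st.base[(size_t)q * ns + s];
            if (b > NEG) preds[s].push_back(std::make_pair(q, b));
        }

    for (int i = 0; i <= n1; ++i) {
        std::fill(cur.begin(), cur.end(), NEG);
        for (int j = 0; j <= n2; ++j) {
            for (int k = 0; k <= n3; ++k) {
                if (i == 0 && j == 0 && k == 0) continue;
                const size_t cell = ((size_t)j * (n3 + 1) + k) * ns;
                for (int s = 0; s < ns; ++s) {
                    if (!st.ok[s]) continue;
                    const int u = st.shape[s];
                    const int pi = i - D1[u], pj = j - D2[u], pk = k - D3[u];
                    if (pi < 0 || pj < 0 || pk < 0) continue;
                    double spterm = 0.0;
                    if (D1[u] && D2[u]) spterm += sp12(i - 1, j - 1);
                    if (D1[u] && D3[u]) spterm += sp13(i - 1, k - 1);
                    if (D2[u] && D3[u]) spterm += sp23(j - 1, k - 1);
                    double best = NEG;
                    uint8_t arg = NOWHERE;
                    if (pi == 0 && pj == 0 && pk == 0) {
                        if (st.base_start[s] > NEG) { best = st.base_start[s]; arg = FROM_START; }
                    } else {
                        const double *pp = (D1[u] ? prev.data() : cur.data())
                            + ((size_t)pj * (n3 + 1) + pk) * ns;
                        const std::vector<std::pair<int, double> > &pl = preds[s];
                        for (size_t t = 0; t < pl.size(); ++t) {
                            const double v = pp[pl[t].first];
                            if (v == NEG) continue;
                            const double cand = v + pl[t].second;
                            if (cand > best) { best = cand; arg = (uint8_t)pl[t].first; }
                        }
                    }
                    if (arg != NOWHERE) {
                        cur[cell + s] = best + spterm;
                        bp[(size_t)i * plane + cell + s] = arg;
                    }
                }
            }
        }
        std::swap(prev, cur);
    }
    // after the final swap, 'prev' holds plane i = n1
    const size_t lastcell = ((size_t)n2 * (n3 + 1) + n3) * ns;
    double best = NEG; int bs = -1;
    for (int s = 0; s < ns; ++s)
        if (prev[lastcell + s] > best) { best = prev[lastcell + s]; bs = s; }
    if (bs < 0) stop("no complete alignment found (internal error)");

    std::vector<int> shapes;
    int i = n1, j = n2, k = n3, s = bs;
    while (true) {
        const int u = st.shape[s];
        shapes.push_back(u + 1);
        const uint8_t b = bp[(((size_t)i * (n2 + 1) + j) * (n3 + 1) + k) * ns + s];
        i -= D1[u]; j -= D2[u]; k -= D3[u];
        if (b == FROM_START) break;
        if (b == NOWHERE) stop("broken traceback (internal error)");
        s = b;
    }
    if (i != 0 || j != 0 || k != 0) stop("traceback did not reach the origin");
    std::reverse(shapes.begin(), shapes.end());
    return List::create(_["score"] = best, _["shapes"] = IntegerVector(shapes.begin(), shapes.end()));
}
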