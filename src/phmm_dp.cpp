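#include <Rcpp.h>
#include <cmath>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Profile-HMM local-alignment dynamic programming.
//
// Scores are log-odds in bits.  Match emissions arrive as an L x 21 matrix of
// log2(e_j(a) / bg(a)); column 20 is the unknown residue 'X' (log-odds 0).
// Insert states emit at background (log-odds 0).  Transitions arrive as an
// (L-1) x 7 matrix of log2 probabilities in the order
//   M->M, M->I, M->D, I->M, I->I, D->M, D->D
// where row j holds transitions leaving column j (1-based).  Local mode:
// uniform entry log2(1/L) into any match state, free exit from any match
// state.  Delete states never flank the aligned core.

static const double NEG_INF = -1.0e30;

static inline void encode_seq(const char *s, int n, int *out) {
    // ACDEFGHIKLMNPQRSTVWY -> 0..19, everything else -> 20
    static int lut[256];
    static bool init = false;
    if (!init) {
        for (int i = 0; i < 256; ++i) lut[i] = 20;
        const char *alpha = "ACDEFGHIKLMNPQRSTVWY";
        for (int i = 0; i < 20; ++i) {
            lut[(unsigned char)alpha[i]] = i;
            lut[(unsigned char)tolower(alpha[i])] = i;
        }
        init = true;
    }
    for (int i = 0; i < n; ++i) out[i] = lut[(unsigned char)s[i]];
}

// flat profile: emissions residue-major (21 rows of L), transitions as 7
// contiguous arrays of length L-1
struct FlatHmm {
    int L;
    std::vector<double> em;  // em[a * L + (j-1)]
    std::vector<double> tmm, tmi, tmd, tim, tii, tdm, tdd;
    double entry;
    void init(const NumericMatrix &matchLO, const NumericMatrix &transLO,
              double entryLO) {
        L = matchLO.nrow();
        entry = entryLO;
        em.resize(21 * L);
        for (int a = 0; a < 21; ++a)
            for (int j = 0; j < L; ++j) em[a * L + j] = matchLO(j, a);
        int n = L > 1 ? L - 1 : 0;
        tmm.resize(n); tmi.resize(n); tmd.resize(n); tim.resize(n);
        tii.resize(n); tdm.resize(n); tdd.resize(n);
        for (int j = 0; j < n; ++j) {
            tmm[j] = transLO(j, 0); tmi[j] = transLO(j, 1);
            tmd[j] = transLO(j, 2); tim[j] = transLO(j, 3);
            tii[j] = transLO(j, 4); tdm[j] = transLO(j, 5);
            tdd[j] = transLO(j, 6);
        }
    }
};

struct Workspace {
    std::vector<double> vM, vI, vD, nM, nI, nD;
    std::vector<int> sM, sI, sD, tM, tI, tD;
    std::vector<int> enc;
    void ensure(int L, int n) {
        if ((int)vM.size() < L + 1) {
            vM.resize(L + 1); vI.resize(L + 1); vD.resize(L + 1);
            nM.resize(L + 1); nI.resize(L + 1); nD.resize(L + 1);
            sM.resize(L + 1); sI.resize(L + 1); sD.resize(L + 1);
            tM.resize(L + 1); tI.resize(L + 1); tD.resize(L + 1);
        }
        if ((int)enc.size() < n) enc.resize(n);
    }
};

// Viterbi over one encoded segment with start-pointer propagation; returns
// best score and [start, end) 0-based residue interval.
static void viterbi_one(const FlatHmm &h, const int *x, int n, Workspace &w,
                        double *best, int *bstart, int *bend) {
    const int L = h.L;
    double *vM = w.vM.data(), *vI = w.vI.data(), *vD = w.vD.data();
    double *nM = w.nM.data(), *nI = w.nI.data(), *nD = w.nD.data();
    int *sM = w.sM.data(), *sI = w.sI.data(), *sD = w.sD.data();
    int *tM = w.tM.data(), *tI = w.tI.data(), *tD = w.tD.data();
    for (int j = 0; j <= L; ++j) {
        vM[j] = vI[j] = vD[j] = NEG_INF;
        sM[j] = sI[j] = sD[j] = -1;
    }
    double bsc = NEG_INF; int ba = 0, bb = 0;
    const double entry = h.entry;

    for (int i = 1; i <= n; ++i) {
        const double *erow = &h.em[x[i - 1] * L];  // erow[j-1], j = 1..L
        // j = 1: no predecessor column
        nM[1] = entry + erow[0]; tM[1] = i - 1;
        nD[1] = NEG_INF; tD[1] = -1;
        if (L > 1) {
            double cM = vM[1] + h.tmi[0], cI = vI[1] + h.tii[0];
            if (cM >= cI) { nI[1] = cM; tI[1] = sM[1]; }
            else          { nI[1] = cI; tI[1] = sI[1]; }
        } else { nI[1] = NEG_INF; tI[1] = -1; }
        if (nM[1] > bsc) { bsc = nM[1]; ba = tM[1]; bb = i; }
        for (int j = 2; j <= L; ++j) {
            const int k = j - 2;  // transition row leaving column j-1
            double sc = entry; int st = i - 1;
            double c = vM[j - 1] + h.tmm[k];
            if (c > sc) { sc = c; st = sM[j - 1]; }
            c = vI[j - 1] + h.tim[k];
            if (c > sc) { sc = c; st = sI[j - 1]; }
            c = vD[j - 1] + h.tdm[k];
            if (c > sc) { sc = c; st = sD[j - 1]; }
            sc += erow[j - 1];
            nM[j] = sc; tM[j] = st;
            if (j < L) {
                double cM = vM[j] + h.tmi[j - 1], cI = vI[j] + h.tii[j - 1];
                if (cM >= cI) { nI[j] = cM; tI[j] = sM[j]; }
                else          { nI[j] = cI; tI[j] = sI[j]; }
            } else { nI[j] = NEG_INF; tI[j] = -1; }
            double dM = nM[j - 1] + h.tmd[k], dD = nD[j - 1] + h.tdd[k];
            if (dM >= dD) { nD[j] = dM; tD[j] = tM[j - 1]; }
            else          { nD[j] = dD; tD[j] = tD[j - 1]; }
            if (sc > bsc) { bsc = sc; ba = st; bb = i; }
        }
        std::swap(vM, nM); std::swap(vI, nI); std::swap(vD, nD);
        std::swap(sM, tM); std::swap(sI, tI); std::swap(sD, tD);
        // keep workspace pointers consistent (swap local aliases only)
    }
    *best = bsc; *bstart = ba; *bend = bb;
}

// [[Rcpp::export(name = ".cpp_viterbi_batch")]]
NumericMatrix cpp_viterbi_batch(std::string concat, IntegerVector seg_start,
                                IntegerVector seg_len, NumericMatrix matchLO,
                                NumericMatrix transLO, double entryLO) {
    const int nseg = seg_start.size();
    if (matchLO.ncol() != 21) stop("matchLO must have 21 columns");
    if (matchLO.nrow() > 1 &&
        (transLO.nrow() != matchLO.nrow() - 1 || transLO.ncol() != 7))
        stop("transLO must be (L-1) x 7");
    FlatHmm h;
    h.init(matchLO, transLO, entryLO);
    Workspace w;

    NumericMatrix out(nseg, 3);
    for (int s = 0; s < nseg; ++s) {
        int n = seg_len[s];
        int off = seg_start[s];
        if (off < 0 || off + n > (int)concat.size()) stop("segment out of range");
        double sc; int a, b;
        if (n == 0) { sc = NEG_INF; a = 0; b = 0; }
        else {
            w.ensure(h.L, n);
            encode_seq(concat.data() + off, n, w.enc.data());
            viterbi_one(h, w.enc.data(), n, w, &sc, &a, &b);
        }
        out(s, 0) = sc; out(s, 1) = a; out(s, 2) = b;
    }
    return out;
}

static inline double lse2(double a, double b) {
    if (a == NEG_INF) return b;
    if (b == NEG_INF) return a;
    if (a > b) return a + log1p(exp(b - a));
    return b + log1p(exp(a - b));
}

// [[Rcpp::export(name = ".cpp_forward")]]
double cpp_forward(std::string seq, NumericMatrix matchLO,
                   NumericMatrix transLO, double entryLO) {
    // log-sum over all local paths; computed in nats, returned in bits
    const double LN2 = M_LN2;
    FlatHmm h;
    h.init(matchLO, transLO, entryLO);
    const int L = h.L;
    const int n = seq.size();
    if (n == 0) return NEG_INF;
    std::vector<int> x(n);
    encode_seq(seq.data(), n, x.data());

    std::vector<double> fM(L + 1, NEG_INF), fI(L + 1, NEG_INF), fD(L + 1, NEG_INF);
    std::vector<double> gM(L + 1, NEG_INF), gI(L + 1, NEG_INF), gD(L + 1, NEG_INF);
    double total = NEG_INF;
    const double entry_n = h.entry * LN2;

    for (int i = 1; i <= n; ++i) {
        const double *erow = &h.em[x[i - 1] * L];
        for (int j = 1; j <= L; ++j) {
            double acc = entry_n;
            if (j > 1) {
                const int k = j - 2;
                acc = lse2(acc, fM[j - 1] + h.tmm[k] * LN2);
                acc = lse2(acc, fI[j - 1] + h.tim[k] * LN2);
                acc = lse2(acc, fD[j - 1] + h.tdm[k] * LN2);
            }
            gM[j] = acc + erow[j - 1] * LN2;
            if (j < L)
                gI[j] = lse2(fM[j] + h.tmi[j - 1] * LN2,
                             fI[j] + h.tii[j - 1] * LN2);
            else gI[j] = NEG_INF;
            if (j > 1)
                gD[j] = lse2(gM[j - 1] + h.tmd[j - 2] * LN2,
                             gD[j - 1] + h.tdd[j - 2] * LN2);
            else gD[j] = NEG_INF;
            total = lse2(total, gM[j]);  // free exit
        }
        fM.swap(gM); fI.swap(gI); fD.swap(gD);
    }
    return total / LN2;
}
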