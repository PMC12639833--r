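#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Isobaric block equality is symbolic (N vs GG share an elemental
// composition), so residue-mass sums agree to float rounding only.
static const double BLOCK_TOL = 1e-6;
static const double TOTAL_TOL = 2e-5;

// Decompose the suffix of A starting at 0-based position ai against a prefix
// of B into mass blocks (each side <= 2 residues, equal mass per block).
// Because every block conserves mass, the number of B residues consumed at
// any state is uniquely determined by the number of A residues consumed, so
// the DP is linear in the suffix length.  Returns the maximum block count
// (finest granularity) or -1; on success fills bConsumed and, if blocksOut is
// non-null, the per-block (lenA, lenB) pairs in order.
static int decompose_blocks(const std::vector<double>& mA, int ai,
                            const std::vector<double>& mB,
                            int* bConsumed,
                            std::vector<std::pair<int, int> >* blocksOut) {
    const int nB = (int)mB.size();
    const int lenA = (int)mA.size() - ai;
    std::vector<double> cumA(lenA + 1, 0.0);
    for (int i = 0; i < lenA; ++i) cumA[i + 1] = cumA[i] + mA[ai + i];

    std::vector<int> best(lenA + 1, -1), bAt(lenA + 1, -1),
        par(lenA + 1, -1), parLa(lenA + 1, 0), parLb(lenA + 1, 0);
    best[0] = 0; bAt[0] = 0;
    for (int a = 0; a <= lenA; ++a) {
        if (best[a] < 0) continue;
        const int b = bAt[a];
        for (int la = 1; la <= 2 && a + la <= lenA; ++la) {
            double ma = cumA[a + la] - cumA[a];
            double mb = 0.0;
            for (int lb = 1; lb <= 2 && b + lb <= nB; ++lb) {
                mb += mB[b + lb - 1];
                if (std::fabs(ma - mb) < BLOCK_TOL && best[a + la] < best[a] + 1) {
                    best[a + la] = best[a] + 1;
                    bAt[a + la] = b + lb;
                    par[a + la] = a; parLa[a + la] = la; parLb[a + la] = lb;
                }
            }
        }
    }
    if (best[lenA] < 0) return -1;
    if (bConsumed) *bConsumed = bAt[lenA];
    if (blocksOut) {
        blocksOut->clear();
        int a = lenA;
        while (a > 0) {
            blocksOut->push_back(std::make_pair(parLa[a], parLb[a]));
            a = par[a];
        }
        std::reverse(blocksOut->begin(), blocksOut->end());
    }
    return best[lenA];
}

// Maximal suffix(A)/prefix(B) overlap decomposable into mass blocks.
// Scans suffix starts from longest to shortest; the first decomposable
// overlap is the maximal one.  Returns NULL when none exists or when the
// maximal decomposable overlap has fewer than minBlocks blocks.
// [[Rcpp::export]]
SEXP cpp_align_blocks(NumericVector massA, NumericVector massB, int minBlocks) {
    const int nA = massA.size(), nB = massB.size();
    std::vector<double> mA(massA.begin(), massA.end());
    std::vector<double> mB(massB.begin(), massB.end());
    std::vector<double> cumB(nB + 1, 0.0);
    for (int j = 0; j < nB; ++j) cumB[j + 1] = cumB[j] + mB[j];
    std::vector<double> cumA(nA + 1, 0.0);
    for (int i = 0; i < nA; ++i) cumA[i + 1] = cumA[i] + mA[i];
    const double totalA = cumA[nA];

    for (int ai = 0; ai < nA; ++ai) {
        const double suf = totalA - cumA[ai];
        // unique B prefix with this mass, if any
        int k = -1;
        for (int j = 1; j <= nB; ++j) {
            if (std::fabs(cumB[j] - suf) < TOTAL_TOL) { k = j; break; }
            if (cumB[j] > suf + TOTAL_TOL) break;
        }
        if (k < 0) continue;
        int bCons = 0;
        std::vector<std::pair<int, int> > blocks;
        int nb = decompose_blocks(mA, ai, mB, &bCons, &blocks);
        if (nb < 0) continue;
        if (nb < minBlocks) return R_NilValue;
        IntegerMatrix bm(nb, 2);
        for (int t = 0; t < nb; ++t) { bm(t, 0) = blocks[t].first; bm(t, 1) = blocks[t].second; }
        return List::create(_["aStart"] = ai + 1, _["bConsumed"] = bCons,
                            _["blockCount"] = nb, _["blocks"] = bm);
    }
    return R_NilValue;
}

// Build the directed overlap graph over all peptides: edge u -> v when the
// maximal suffix(u)/prefix(v) overlap decomposes into >= minBlocks mass
// blocks and v extends beyond the overlap (proper extension).  Suffix masses
// are hashed against all peptide prefix masses so only mass-compatible pairs
// are aligned.  Optionally accumulates positional confidence across edges:
// one-to-one blocks contribute the neighbour's positional score, multi
// residue blocks contribute the neighbour's ALC; the accumulated score is
// min(1, base + mean(contributions)).
// [[Rcpp::export]]
List cpp_build_graph(List resMass, List conf, NumericVector alc,
                     int minBlocks, bool accumulate) {
    const int n = resMass.size();
    std::vector<std::vector<double> > M(n), C(n), cum(n);
    for (int i = 0; i < n; ++i) {
        NumericVector v = resMass[i];
        M[i].assign(v.begin(), v.end());
        NumericVector c = conf[i];
        C[i].assign(c.begin(), c.end());
        cum[i].resize(M[i].size() + 1, 0.0);
        for (size_t j = 0; j < M[i].size(); ++j) cum[i][j + 1] = cum[i][j] + M[i][j];
    }

    // prefix-mass hash: key = round(mass * 1e3); values (peptide, k) with
    // k < len (a proper extension must contribute new residues)
    std::unordered_map<long long, std::vector<std::pair<int, int> > > pre;
    for (int j = 0; j < n; ++j) {
        const int len = (int)M[j].size();
        for (int k = minBlocks; k < len; ++k) {
            long long key = (long long)std::llround(cum[j][k] * 1e3);
            pre[key].push_back(std::make_pair(j, k));
        }
    }

    std::vector<int> eFrom, eTo, eAStart, eBCons, eNBlocks;
    std::vector<double> accSum, accCnt;
    std::vector<int> accOff(n + 1, 0);
    if (accumulate) {
        int tot = 0;
        for (int i = 0; i < n; ++i) { accOff[i] = tot; tot += (int)M[i].size(); }
        accOff[n] = tot;
        accSum.assign(tot, 0.0);
        accCnt.assign(tot, 0.0);
    }
    std::vector<std::pair<int, int> > blocks;

    for (int a = 0; a < n; ++a) {
        const int nA = (int)M[a].size();
        std::unordered_set<int> done;
        for (int ai = 0; ai + minBlocks <= nA; ++ai) {
            const double suf = cum[a][nA] - cum[a][ai];
            long long key = (long long)std::llround(suf * 1e3);
            for (long long kk = key - 1; kk <= key + 1; ++kk) {
                std::unordered_map<long long, std::vector<std::pair<int, int> > >::iterator it = pre.find(kk);
                if (it == pre.end()) continue;
                for (size_t q = 0; q < it->second.size(); ++q) {
                    const int b = it->second[q].first;
                    const int k = it->second[q].second;
                    if (b == a || done.count(b)) continue;
                    if (std::fabs(cum[b][k] - suf) >= TOTAL_TOL) continue;
                    int bCons = 0;
                    int nb = decompose_blocks(M[a], ai, M[b], &bCons, accumulate ? &blocks : (std::vector<std::pair<int, int> >*)0);
                    if (nb < 0) continue;           // not decomposable at this offset
                    done.insert(b);                 // maximal decomposable overlap found
                    if (nb < minBlocks) continue;
                    eFrom.push_back(a + 1); eTo.push_back(b + 1);
                    eAStart.push_back(ai + 1); eBCons.push_back(bCons);
                    eNBlocks.push_back(nb);
                    if (accumulate) {
                        int ap = ai, bp = 0;
                        for (size_t t = 0; t < blocks.size(); ++t) {
                            const int la = blocks[t].first, lb = blocks[t].second;
                            const bool oneone = (la == 1 && lb == 1);
                            for (int x = 0; x < la; ++x) {
                                double cb = oneone ? C[b][bp] : alc[b];
                                accSum[accOff[a] + ap + x] += cb;
                                accCnt[accOff[a] + ap + x] += 1.0;
                            }
                            for (int y = 0; y < lb; ++y) {
                                double ca = oneone ? C[a][ap] : alc[a];
                                accSum[accOff[b] + bp + y] += ca;
                                accCnt[accOff[b] + bp + y] += 1.0;
                            }
                            ap += la; bp += lb;
                        }
                    }
                }
            }
        }
    }

    List acc(n);
    if (accumulate) {
        for (int i = 0; i < n; ++i) {
            const int len = (int)M[i].size();
            NumericVector v(len);
            for (int p = 0; p < len; ++p) {
                double add = accCnt[accOff[i] + p] > 0 ?
                    accSum[accOff[i] + p] / accCnt[accOff[i] + p] : 0.0;
                v[p] = std::min(1.0, C[i][p] + add);
            }
            acc[i] = v;
        }
    } else {
        for (int i = 0; i < n; ++i) acc[i] = conf[i];
    }

    return List::create(
        _["from"] = wrap(eFrom), _["to"] = wrap(eTo),
        _["aStart"] = wrap(eAStart), _["bConsumed"] = wrap(eBCons),
        _["nBlocks"] = wrap(eNBlocks), _["acc"] = acc);
}
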