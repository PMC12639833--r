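#include <Rcpp.h>
#include <vector>
#include <unordered_set>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Bounded-priority-queue dynamic program over the peptide overlap graph.
//
// Paths are grown peptide-by-peptide along forward edges; each partial path
// lives in the bucket of its discretized total residue mass (index =
// round(mass / width)) and buckets keep at most `capacity` paths ordered by
// the path score s(p) = T + (NA - NU), where T is the number of middle-down
// fragment masses (PRMs for the forward direction, SRMs for the reverse)
// matching the path's internal prefix masses within ppm tolerance, NA is the
// path mass divided by the averagine residue mass, and NU the number of
// realized residues whose accumulated confidence falls below `lowConf`.
// Buckets are processed in ascending mass order; every extension adds at
// least one residue (>= 57 Da >> width), so all insertions into a bucket
// precede its processing.  Two paths in one bucket ending in the same
// peptide with exactly equal mass have identical extension behaviour and
// pointwise-additive score increments, so the lower-scoring one is
// dominated and dropped; this prunes the many co-indexed re-decompositions
// of one realized prefix without affecting the optimum.
//
// Several target masses can be assembled in one sweep (the pipeline
// amortizes one DP per subunit type and direction over all subunit
// masses): terminal candidates are accepted paths within `massTol` Da of
// any target and are ranked per target; a configurable penalty applies
// when the final peptide is not in the end set.

struct PathNode {
    int pep;        // peptide id (0-based)
    int parent;     // arena index of parent, -1 for a start peptide
    int bFrom;      // first residue of pep contributing new residues (0-based)
    int T;
    int NU;
    int nPep;
    double mass;
    double score;   // T + mass/avgResMass - NU
};

struct Cand { int node; int target; double finalScore; bool endOk; };

class FragIndex {
    std::vector<double> frags;
    std::vector<int> binStart;   // first fragment index >= each 1-Da bin
    int nBins;
public:
    FragIndex(NumericVector f, double maxMass) {
        frags.assign(f.begin(), f.end());
        std::sort(frags.begin(), frags.end());
        nBins = (int)(maxMass + 16.0);
        binStart.assign(nBins + 1, 0);
        int j = 0;
        const int n = (int)frags.size();
        for (int b = 0; b <= nBins; ++b) {
            while (j < n && frags[j] < (double)b) ++j;
            binStart[b] = j;
        }
    }
    // exact ppm-window count via a short linear scan anchored at the
    // 1-Da bin of the window start
    inline int count(double m, double tolPpm) const {
        const double tol = tolPpm * 1e-6 * m;
        const double lo = m - tol, hi = m + tol;
        long b = (long)lo;
        if (b < 0) b = 0;
        if (b >= nBins) return 0;
        int i = binStart[b];
        const int n = (int)frags.size();
        while (i < n && frags[i] < lo) ++i;
        int c = 0;
        while (i < n && frags[i] <= hi) { ++c; ++i; }
        return c;
    }
};

// [[Rcpp::export]]
List cpp_dp_assemble(List resMass, List accConf,
                     IntegerVector edgeFrom, IntegerVector edgeTo,
                     IntegerVector edgeBFrom,
                     IntegerVector starts, IntegerVector ends,
                     NumericVector fragMass, double tolPpm,
                     NumericVector targets, double width, int capacity,
                     double massTol, double lowConf, double penalty,
                     double avgResMass, int topK, double beamMargin) {
    const int n = resMass.size();
    const int nT = targets.size();
    std::vector<std::vector<double> > M(n), cum(n);
    std::vector<std::vector<int> > lowCnt(n);
    for (int i = 0; i < n; ++i) {
        NumericVector v = resMass[i]; M[i].assign(v.begin(), v.end());
        NumericVector c = accConf[i];
        const int len = (int)M[i].size();
        cum[i].resize(len + 1, 0.0);
        lowCnt[i].resize(len + 1, 0);
        for (int r = 0; r < len; ++r) {
            cum[i][r + 1] = cum[i][r] + M[i][r];
            lowCnt[i][r + 1] = lowCnt[i][r] + (c[r] < lowConf ? 1 : 0);
        }
    }
    double upper = 0.0;
    for (int t = 0; t < nT; ++t) upper = std::max(upper, targets[t]);
    upper += massTol;
    FragIndex fidx(fragMass, upper + 32.0);

    struct Edge { int to; int bFrom; double addMass; int addNU; };
    std::vector<std::vector<Edge> > adj(n);
    for (int e = 0; e < edgeFrom.size(); ++e) {
        Edge ed;
        ed.to = edgeTo[e] - 1;
        ed.bFrom = edgeBFrom[e] - 1;
        const int len = (int)M[ed.to].size();
        ed.addMass = cum[ed.to][len] - cum[ed.to][ed.bFrom];
        ed.addNU = lowCnt[ed.to][len] - lowCnt[ed.to][ed.bFrom];
        adj[edgeFrom[e] - 1].push_back(ed);
    }
    std::unordered_set<int> endSet;
    for (int i = 0; i < ends.size(); ++i) endSet.insert(ends[i] - 1);

    // beam pruning support: best accepted score per 50-Da mass window.
    // The beam is a heuristic: an extension is skipped when even gaining
    // one fragment match per new boundary it would trail the best accepted
    // score at comparable mass by more than the margin.
    const double winW = 50.0;
    std::vector<double> winBest((size_t)(upper / winW) + 3, -1e18);

    // candidate-zone lookup: bucket index -> target id (+1), 0 if none
    const long nBuckets = (long)std::llround(upper / width) + 2;
    std::vector<int> targetOf(nBuckets, 0);
    for (int t = 0; t < nT; ++t) {
        long lo = (long)std::floor((targets[t] - massTol) / width);
        long hi = (long)std::ceil((targets[t] + massTol) / width);
        for (long b = std::max(lo, 0L); b <= std::min(hi, nBuckets - 1); ++b)
            targetOf[b] = t + 1;
    }

    std::vector<PathNode> arena;
    typedef std::vector<int> Bucket;        // arena indices, score-desc
    std::vector<Bucket> buckets(nBuckets);
    std::vector<Cand> cands;

    struct Inserter {
        std::vector<PathNode>& arena;
        std::vector<Bucket>& buckets;
        std::vector<Cand>& cands;
        std::unordered_set<int>& endSet;
        std::vector<int>& targetOf;
        std::vector<double>& winBest;
        NumericVector targets;
        double width, massTol, penalty, upper;
        int capacity;
        long nBuckets;
        void operator()(const PathNode& nd) {
            if (nd.mass > upper) return;
            long idx = (long)std::llround(nd.mass / width);
            if (idx < 0 || idx >= nBuckets) return;
            Bucket& bk = buckets[idx];
            for (size_t j = 0; j < bk.size(); ++j) {
                const PathNode& o = arena[bk[j]];
                if (o.pep == nd.pep && std::fabs(o.mass - nd.mass) < 1e-9) {
                    if (o.score >= nd.score) return;
                    bk.erase(bk.begin() + j);
                    break;
                }
            }
            size_t pos = 0;
            for (; pos < bk.size(); ++pos) {
                const PathNode& o = arena[bk[pos]];
                if (nd.score > o.score ||
                    (nd.score == o.score && (nd.T > o.T ||
                     (nd.T == o.T && nd.nPep < o.nPep)))) break;
            }
            if ((int)pos >= capacity) return;
            arena.push_back(nd);
            bk.insert(bk.begin() + pos, (int)arena.size() - 1);
            if ((int)bk.size() > capacity) bk.pop_back();
            size_t w = (size_t)(nd.mass / 50.0);
            if (w < winBest.size() && nd.score > winBest[w])
                winBest[w] = nd.score;
            if (targetOf[idx] > 0) {    // fast zone check, then all targets
                for (int t = 0; t < targets.size(); ++t) {
                    if (std::fabs(nd.mass - targets[t]) <= massTol) {
                        Cand c; c.node = (int)arena.size() - 1; c.target = t;
                        c.endOk = endSet.count(nd.pep) > 0;
                        c.finalScore = nd.score - (c.endOk ? 0.0 : penalty);
                        cands.push_back(c);
                    }
                }
            }
        }
    } insert_node = { arena, buckets, cands, endSet, targetOf, winBest,
                      targets, width, massTol, penalty, upper, capacity,
                      nBuckets };

    for (int s = 0; s < starts.size(); ++s) {
        const int p = starts[s] - 1;
        const int len = (int)M[p].size();
        PathNode nd; nd.pep = p; nd.parent = -1; nd.bFrom = 0; nd.nPep = 1;
        nd.mass = cum[p][len]; nd.NU = lowCnt[p][len]; nd.T = 0;
        for (int r = 1; r < len; ++r) nd.T += fidx.count(cum[p][r], tolPpm);
        nd.score = nd.T + nd.mass / avgResMass - nd.NU;
        insert_node(nd);
    }

    for (long idx = 0; idx < nBuckets; ++idx) {
        if (buckets[idx].empty()) continue;
        Bucket bk = buckets[idx];        // content final by now
        for (size_t q = 0; q < bk.size(); ++q) {
            const PathNode cur = arena[bk[q]];
            if (beamMargin < 1e17) {
                size_t w = (size_t)(cur.mass / winW);
                if (w < winBest.size() && cur.score < winBest[w] - beamMargin)
                    continue;
            }
            const std::vector<Edge>& out = adj[cur.pep];
            for (size_t e = 0; e < out.size(); ++e) {
                const Edge& ed = out[e];
                const double newMass = cur.mass + ed.addMass;
                if (newMass > upper) continue;
                const int v = ed.to;
                const int lenV = (int)M[v].size();
                if (beamMargin < 1e17) {
                    // skip extensions that cannot come within the beam
                    // margin of the best accepted score at comparable mass
                    size_t w = (size_t)(newMass / winW);
                    double best = winBest[w];
                    if (w + 1 < winBest.size() && winBest[w + 1] > best)
                        best = winBest[w + 1];
                    if (w >= 1 && winBest[w - 1] > best)
                        best = winBest[w - 1];
                    double ub = cur.score + ed.addMass / avgResMass +
                        (double)(lenV - ed.bFrom + 1);
                    if (ub < best - beamMargin) continue;
                }
                PathNode nd; nd.pep = v; nd.parent = bk[q]; nd.bFrom = ed.bFrom;
                nd.nPep = cur.nPep + 1;
                nd.mass = newMass;
                nd.NU = cur.NU + ed.addNU;
                // previous path total becomes an internal boundary
                nd.T = cur.T + fidx.count(cur.mass, tolPpm);
                const double base = cur.mass - cum[v][ed.bFrom];
                for (int r = ed.bFrom + 1; r < lenV; ++r)
                    nd.T += fidx.count(base + cum[v][r], tolPpm);
                nd.score = nd.T + nd.mass / avgResMass - nd.NU;
                insert_node(nd);
            }
        }
    }

    // rank candidates per target: penalized score desc, then T desc, then
    // fewer peptides
    List out(nT);
    for (int t = 0; t < nT; ++t) {
        std::vector<int> ord;
        for (size_t i = 0; i < cands.size(); ++i)
            if (cands[i].target == t) ord.push_back((int)i);
        std::sort(ord.begin(), ord.end(), [&](int x, int y) {
            if (cands[x].finalScore != cands[y].finalScore)
                return cands[x].finalScore > cands[y].finalScore;
            const PathNode& a = arena[cands[x].node];
            const PathNode& b = arena[cands[y].node];
            if (a.T != b.T) return a.T > b.T;
            return a.nPep < b.nPep;
        });
        const int nOut = std::min((int)ord.size(), topK);
        List res(nOut);
        for (int i = 0; i < nOut; ++i) {
            const Cand& c = cands[ord[i]];
            std::vector<int> peps, bfroms;
            int cur = c.node;
            while (cur >= 0) {
                peps.push_back(arena[cur].pep + 1);
                bfroms.push_back(arena[cur].bFrom + 1);
                cur = arena[cur].parent;
            }
            std::reverse(peps.begin(), peps.end());
            std::reverse(bfroms.begin(), bfroms.end());
            const PathNode& nd = arena[c.node];
            res[i] = List::create(
                _["peptides"] = wrap(peps), _["bFrom"] = wrap(bfroms),
                _["mass"] = nd.mass, _["T"] = nd.T, _["NU"] = nd.NU,
                _["score"] = nd.score, _["finalScore"] = c.finalScore,
                _["endOk"] = c.endOk);
        }
        out[t] = res;
    }
    out.attr("stats") = NumericVector::create(
        _["arenaSize"] = (double)arena.size(),
        _["nCandidates"] = (double)cands.size());
    return out;
}
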