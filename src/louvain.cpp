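#include <Rcpp.h>
#include <vector>
#include <map>
#include <random>

using namespace Rcpp;

// Two-phase Louvain community detection with a resolution parameter.
//
// Phase 1 (local moving): repeatedly sweep the nodes in a seeded shuffled
// order, moving each node to the neighboring community with the largest
// positive modularity gain, until a full sweep makes no move.
// Phase 2: aggregate communities into a supergraph (inter-community weights
// summed, intra-community weight as a self loop) and repeat on the
// aggregate.  Stops when a level produces no move.
//
// Modularity convention: Q = sum_c [ e_c/m - gamma * (d_c/(2m))^2 ] with
// e_c the within-community edge weight (each undirected edge once, self
// loops once), d_c the community degree sum (self loops count twice),
// m the total edge weight.

namespace {

struct Graph {
    int n;
    std::vector<std::vector<std::pair<int, double> > > adj; // both directions
    std::vector<double> selfw;                              // self loops
    std::vector<double> deg;                                // k_i
    double m;                                               // total weight

    void finalize() {
        deg.assign(n, 0.0);
        m = 0.0;
        for (int i = 0; i < n; ++i) {
            double s = 2.0 * selfw[i];
            for (size_t e = 0; e < adj[i].size(); ++e) s += adj[i][e].second;
            deg[i] = s;
            m += selfw[i];
        }
        for (int i = 0; i < n; ++i)
            for (size_t e = 0; e < adj[i].size(); ++e) m += 0.5 * adj[i][e].second;
    }
};

// deterministic Fisher-Yates so results do not depend on the stdlib's
// distribution implementation
void shuffleOrder(std::vector<int>& ord, std::mt19937& rng) {
    for (int i = (int)ord.size() - 1; i > 0; --i) {
        int j = (int)(rng() % (unsigned)(i + 1));
        std::swap(ord[i], ord[j]);
    }
}

// Local moving, optionally starting from a given assignment (`comm` used
// as the initial partition when `warmStart`).  Candidate targets are the
// neighboring communities, the current one, and an empty community (so a
// node whose membership has negative gain can become a singleton).
bool oneLevel(const Graph& g, double gamma, std::mt19937& rng,
              std::vector<int>& comm, bool warmStart = false) {
    const int n = g.n;
    std::vector<double> tot(n, 0.0);
    std::vector<int> size(n, 0);
    if (!warmStart) {
        comm.resize(n);
        for (int i = 0; i < n; ++i) comm[i] = i;
    }
    for (int i = 0; i < n; ++i) { tot[comm[i]] += g.deg[i]; size[comm[i]]++; }
    if (g.m <= 0.0) return false;
    const double m = g.m;

    std::vector<int> freeIds;
    for (int c = 0; c < n; ++c) if (size[c] == 0) freeIds.push_back(c);

    std::vector<int> ord(n);
    for (int i = 0; i < n; ++i) ord[i] = i;

    std::vector<double> w2c(n, 0.0);
    std::vector<int> touched;
    bool any = false, movedInPass = true;
    while (movedInPass) {
        movedInPass = false;
        shuffleOrder(ord, rng);
        for (int oi = 0; oi < n; ++oi) {
            const int i = ord[oi];
            const int cOld = comm[i];
            touched.clear();
            for (size_t e = 0; e < g.adj[i].size(); ++e) {
                const int j = g.adj[i][e].first;
                const int c = comm[j];
                if (w2c[c] == 0.0) touched.push_back(c);
                w2c[c] += g.adj[i][e].second;
            }
            if (w2c[cOld] == 0.0) touched.push_back(cOld);
            tot[cOld] -= g.deg[i];
            size[cOld]--;
            const double coef = gamma * g.deg[i] / (2.0 * m * m);
            int best = cOld;
            double bestGain = w2c[cOld] / m - coef * tot[cOld];
            for (size_t t = 0; t < touched.size(); ++t) {
                const int c = touched[t];
                if (c == cOld) continue;
                const double gain = w2c[c] / m - coef * tot[c];
                if (gain > bestGain + 1e-12) { bestGain = gain; best = c; }
            }
            // isolating the node (empty community) has gain 0
            if (size[cOld] > 0 && 0.0 > bestGain + 1e-12 && !freeIds.empty()) {
                best = freeIds.back();
            }
            if (best != cOld) {
                if (size[best] == 0 && !freeIds.empty() &&
                    best == freeIds.back())
                    freeIds.pop_back();
                if (size[cOld] == 0) freeIds.push_back(cOld);
            }
            tot[best] += g.deg[i];
            size[best]++;
            comm[i] = best;
            if (best != cOld) { movedInPass = true; any = true; }
            for (size_t t = 0; t < touched.size(); ++t) w2c[touched[t]] = 0.0;
        }
    }
    return any;
}

Graph aggregate(const Graph& g, const std::vector<int>& comm, int nComm) {
    Graph a;
    a.n = nComm;
    a.adj.assign(nComm, std::vector<std::pair<int, double> >());
    a.selfw.assign(nComm, 0.0);
    std::vector<std::map<int, double> > acc(nComm);
    for (int i = 0; i < g.n; ++i) {
        a.selfw[comm[i]] += g.selfw[i];
        for (size_t e = 0; e < g.adj[i].size(); ++e) {
            const int j = g.adj[i][e].first;
            if (j < i) continue; // each undirected edge once
            const double w = g.adj[i][e].second;
            const int ci = comm[i], cj = comm[j];
            if (ci == cj) a.selfw[ci] += w;
            else acc[std::min(ci, cj)][std::max(ci, cj)] += w;
        }
    }
    for (int ci = 0; ci < nComm; ++ci)
        for (std::map<int, double>::const_iterator it = acc[ci].begin();
             it != acc[ci].end(); ++it) {
            a.adj[ci].push_back(std::make_pair(it->first, it->second));
            a.adj[it->first].push_back(std::make_pair(ci, it->second));
        }
    a.finalize();
    return a;
}

int renumber(std::vector<int>& comm) {
    std::map<int, int> seen;
    for (size_t i = 0; i < comm.size(); ++i) {
        std::map<int, int>::iterator it = seen.find(comm[i]);
        if (it == seen.end()) {
            int id = (int)seen.size();
            seen[comm[i]] = id;
            comm[i] = id;
        } else comm[i] = it->second;
    }
    return (int)seen.size();
}

} // namespace

double partitionQ(const Graph& g, const std::vector<int>& comm,
                  double gamma) {
    if (g.m <= 0.0) return 0.0;
    int nc = 0;
    for (size_t i = 0; i < comm.size(); ++i) nc = std::max(nc, comm[i] + 1);
    std::vector<double> ec(nc, 0.0), dc(nc, 0.0);
    for (int i = 0; i < g.n; ++i) {
        dc[comm[i]] += g.deg[i];
        ec[comm[i]] += g.selfw[i];
        for (size_t e = 0; e < g.adj[i].size(); ++e) {
            const int j = g.adj[i][e].first;
            if (j < i || comm[j] != comm[i]) continue;
            ec[comm[i]] += g.adj[i][e].second;
        }
    }
    double q = 0.0;
    for (int c = 0; c < nc; ++c) {
        const double d = dc[c] / (2.0 * g.m);
        q += ec[c] / g.m - gamma * d * d;
    }
    return q;
}

// One full Louvain run: repeated (local moving + aggregation), then a
// single-node refinement sweep on the original graph from the final
// partition (groups frozen by aggregation can release boundary nodes).
std::vector<int> louvainRun(const Graph& g, double gamma,
                            std::mt19937& rng) {
    const int n = g.n;
    std::vector<int> assign(n);
    for (int i = 0; i < n; ++i) assign[i] = i;
    renumber(assign);

    Graph cur = g;
    for (;;) {
        std::vector<int> comm;
        bool improved = oneLevel(cur, gamma, rng, comm);
        if (!improved) break;
        int nComm = renumber(comm);
        for (int i = 0; i < n; ++i) assign[i] = comm[assign[i]];
        if (nComm == cur.n) break;
        cur = aggregate(cur, comm, nComm);
    }
    oneLevel(g, gamma, rng, assign, /*warmStart=*/true);
    renumber(assign);
    return assign;
}

// edges: ei, ej 0-based endpoints (i != j, each undirected edge once), ew
// weights.  Returns 0-based community labels for the n nodes.  `restarts`
// full runs with independent shuffle streams are performed and the best
// partition by modularity is kept (greedy local moving is order-dependent
// and tiny graphs can trap a single run in a poor local optimum).
// [[Rcpp::export(".louvainCpp")]]
IntegerVector louvainCpp(const int n, const IntegerVector& ei,
                         const IntegerVector& ej, const NumericVector& ew,
                         const double gamma, const int seed,
                         const int restarts) {
    Graph g;
    g.n = n;
    g.adj.assign(n, std::vector<std::pair<int, double> >());
    g.selfw.assign(n, 0.0);
    for (int e = 0; e < ei.size(); ++e) {
        const int i = ei[e], j = ej[e];
        if (i < 0 || j < 0 || i >= n || j >= n) stop("edge endpoint out of range");
        const double w = ew[e];
        if (w <= 0) continue;
        if (i == j) { g.selfw[i] += w; continue; }
        g.adj[i].push_back(std::make_pair(j, w));
        g.adj[j].push_back(std::make_pair(i, w));
    }
    g.finalize();

    std::mt19937 rng((unsigned)seed);
    std::vector<int> best = louvainRun(g, gamma, rng);
    double bestQ = partitionQ(g, best, gamma);
    for (int r = 1; r < restarts; ++r) {
        std::vector<int> cand = louvainRun(g, gamma, rng);
        const double q = partitionQ(g, cand, gamma);
        if (q > bestQ + 1e-12) { best = cand; bestQ = q; }
    }
    return IntegerVector(best.begin(), best.end());
}
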