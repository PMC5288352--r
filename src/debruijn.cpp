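#include <Rcpp.h>
#include <unordered_map>
#include <string>
#include <vector>
#include <array>
#include <map>
#include <algorithm>
#include "kmer_encode.h"
using namespace Rcpp;

std::string revcomp_str(const std::string& s); // kmer_core.cpp

namespace {

// Bidirected de Bruijn graph on canonical k-mers. A node handle packs
// (id, orientation): h = 2*id + dir, dir 0 = canonical encoding, dir 1
// = its reverse complement. flip(h) = h ^ 1. Adjacency (4 candidate
// out-edges per oriented node) is precomputed once; removals only
// deactivate nodes, and degree checks filter on the active flag.
struct Graph {
    int k;
    std::vector<u128> key;   // canonical k-mer, id order (sorted)
    std::vector<u128> rck;   // reverse complements
    std::vector<double> cnt;
    std::vector<char> active;
    std::vector<int> adj;    // handle*4 + base -> handle or -1
    std::unordered_map<u128, int, U128Hash> id;

    u128 enc_of(int h) const {
        return (h & 1) ? rck[h >> 1] : key[h >> 1];
    }
    void build_adjacency() {
        u128 mask = kmer_mask(k);
        int n = (int)key.size();
        adj.assign((size_t)2 * n * 4, -1);
        for (int i = 0; i < n; ++i) {
            for (int dir = 0; dir < 2; ++dir) {
                int h = 2 * i + dir;
                u128 base = (enc_of(h) << 2) & mask;
                for (int b = 0; b < 4; ++b) {
                    u128 nx = base | (u128)(unsigned)b;
                    u128 nr = rc_kmer(nx, k);
                    u128 c = nx < nr ? nx : nr;
                    auto it = id.find(c);
                    if (it == id.end()) continue;
                    adj[(size_t)h * 4 + b] =
                        2 * it->second + (c == nx ? 0 : 1);
                }
            }
        }
    }
    void succ(int h, std::vector<int>& out) const {
        out.clear();
        for (int b = 0; b < 4; ++b) {
            int t = adj[(size_t)h * 4 + b];
            if (t >= 0 && active[t >> 1]) out.push_back(t);
        }
    }
    int outdeg(int h) const {
        int d = 0;
        for (int b = 0; b < 4; ++b) {
            int t = adj[(size_t)h * 4 + b];
            if (t >= 0 && active[t >> 1]) ++d;
        }
        return d;
    }
    int indeg(int h) const { return outdeg(h ^ 1); }
};

struct Unitig {
    std::vector<int> path;  // node handles
    std::string seq;
    double meancov;
    bool circular;
    int first() const { return path.front(); }
    int last() const { return path.back(); }
};

void spell(const Graph& g, Unitig& u) {
    u.seq = decode_kmer(g.enc_of(u.path[0]), g.k);
    u.seq.reserve(g.k + u.path.size());
    for (size_t i = 1; i < u.path.size(); ++i)
        u.seq += KMER_DEC[(unsigned)(g.enc_of(u.path[i]) & 3)];
    double s = 0;
    for (int h : u.path) s += g.cnt[h >> 1];
    u.meancov = s / u.path.size();
}

bool is_path_start(const Graph& g, int h, std::vector<int>& scratch) {
    g.succ(h ^ 1, scratch); // predecessors (flipped)
    if (scratch.size() != 1) return true;
    int pred = scratch[0] ^ 1;
    return g.outdeg(pred) != 1;
}

std::vector<Unitig> build_unitigs(const Graph& g) {
    int n = (int)g.key.size();
    std::vector<char> visited(n, 0);
    std::vector<Unitig> out;
    std::vector<int> scratch, sc2;
    for (int i = 0; i < n; ++i) {
        if (!g.active[i] || visited[i]) continue;
        for (int dir = 0; dir < 2; ++dir) {
            if (visited[i]) break;
            int h = 2 * i + dir;
            if (!is_path_start(g, h, scratch)) continue;
            Unitig u; u.circular = false;
            u.path.push_back(h);
            visited[i] = 1;
            int cur = h;
            while (true) {
                g.succ(cur, scratch);
                if (scratch.size() != 1) break;
                int nh = scratch[0];
                if (visited[nh >> 1]) break;
                g.succ(nh ^ 1, sc2);
                if (sc2.size() != 1) break; // indeg(nh) != 1
                u.path.push_back(nh);
                visited[nh >> 1] = 1;
                cur = nh;
            }
            spell(g, u);
            out.push_back(std::move(u));
        }
    }
    // remaining nodes lie on simple cycles
    for (int i = 0; i < n; ++i) {
        if (!g.active[i] || visited[i]) continue;
        Unitig u; u.circular = true;
        int h = 2 * i;
        u.path.push_back(h);
        visited[i] = 1;
        int cur = h;
        std::vector<int> scratch2;
        while (true) {
            g.succ(cur, scratch2);
            if (scratch2.size() != 1) { u.circular = false; break; }
            int nh = scratch2[0];
            if (nh == h) break; // closed the cycle
            if (visited[nh >> 1]) { u.circular = false; break; }
            u.path.push_back(nh);
            visited[nh >> 1] = 1;
            cur = nh;
        }
        spell(g, u);
        out.push_back(std::move(u));
    }
    return out;
}

double weighted_median_mult(const Graph& g) {
    std::map<double, double> w; // multiplicity -> total instances
    double total = 0;
    for (size_t i = 0; i < g.cnt.size(); ++i) {
        if (!g.active[i]) continue;
        w[g.cnt[i]] += g.cnt[i];
        total += g.cnt[i];
    }
    double acc = 0;
    for (auto& kv : w) {
        acc += kv.second;
        if (acc >= total / 2) return kv.first;
    }
    return 1.0;
}

// edit distance with early abort; returns cap+1 when exceeding cap.
// bubble paths are short (~2k bases) so full DP rows are fine.
int edit_distance_capped(const std::string& a, const std::string& b,
                         int cap) {
    int n = (int)a.size(), m = (int)b.size();
    if (std::abs(n - m) > cap) return cap + 1;
    if (n > 10000 || m > 10000) return cap + 1;
    std::vector<int> prev(m + 1), cur(m + 1);
    for (int j = 0; j <= m; ++j) prev[j] = j;
    for (int i = 1; i <= n; ++i) {
        cur[0] = i;
        int best = cur[0];
        for (int j = 1; j <= m; ++j) {
            int d = prev[j - 1] + (a[i-1] != b[j-1]);
            d = std::min(d, cur[j-1] + 1);
            d = std::min(d, prev[j] + 1);
            cur[j] = d;
            if (d < best) best = d;
        }
        std::swap(prev, cur);
        if (best > cap) return cap + 1;
    }
    return prev[m] > cap ? cap + 1 : prev[m];
}

} // namespace

// De Bruijn assembly of reads at word size k: canonical k-mer graph,
// tip clipping (dead-end unitigs shorter than 2k with coverage below
// tip_cov_frac times the instance-weighted median multiplicity), bubble
// popping (parallel unitigs between the same flanking nodes differing
// by <= bubble_diff edits; highest coverage kept), and emission of
// maximal non-branching paths. Deterministic: node ids follow sorted
// k-mer order. k must be odd and <= 63.
// [[Rcpp::export]]
List cpp_assemble(CharacterVector seqs, int k, double tip_cov_frac = 0.1,
                  int bubble_diff = 3, int max_rounds = 10) {
    if (k < 3 || k > 63 || k % 2 == 0)
        stop("k must be odd and between 3 and 63");
    Graph g;
    g.k = k;
    {
        std::unordered_map<u128, int, U128Hash> counts;
        for (R_xlen_t i = 0; i < seqs.size(); ++i) {
            std::string s = as<std::string>(seqs[i]);
            for_each_canon(s, k, [&](u128 c) { counts[c]++; });
        }
        g.key.reserve(counts.size());
        for (auto& kv : counts) g.key.push_back(kv.first);
        std::sort(g.key.begin(), g.key.end());
        size_t n = g.key.size();
        g.cnt.resize(n);
        g.rck.resize(n);
        g.active.assign(n, 1);
        g.id.reserve(n * 2);
        for (size_t i = 0; i < n; ++i) {
            g.id[g.key[i]] = (int)i;
            g.cnt[i] = counts[g.key[i]];
            g.rck[i] = rc_kmer(g.key[i], k);
        }
    }
    if (g.key.empty())
        return List::create(_["seq"] = CharacterVector(0),
                            _["cov"] = NumericVector(0),
                            _["circular"] = LogicalVector(0));

    double med = weighted_median_mult(g);
    // abundance cutoff at the spectrum valley: the least-populated
    // multiplicity below the weighted median (ties -> smallest), so a
    // clean low-coverage read set keeps everything while an errored
    // high-coverage one sheds the error spike before graph cleaning
    {
        std::map<int, int> h;
        for (size_t i = 0; i < g.cnt.size(); ++i)
            h[(int)g.cnt[i]]++;
        int lim = std::max(1, (int)med);
        int valley = 1; int best = INT32_MAX;
        for (int m = 1; m <= lim; ++m) {
            auto it = h.find(m);
            int hm = (it == h.end()) ? 0 : it->second;
            if (hm < best) { best = hm; valley = m; }
        }
        if (valley > 1)
            for (size_t i = 0; i < g.cnt.size(); ++i)
                if (g.cnt[i] < valley) g.active[i] = 0;
    }
    g.build_adjacency();

    double tip_thresh = tip_cov_frac * med;

    for (int round = 0; round < max_rounds; ++round) {
        std::vector<Unitig> us = build_unitigs(g);
        int removed = 0;
        // tips: short low-coverage dead ends; "hairs" (dead-end paths
        // far below the coverage median, e.g. from reads with several
        // clustered errors) are clipped regardless of length
        for (auto& u : us) {
            if (u.circular) continue;
            bool dead_head = g.indeg(u.first()) == 0;
            bool dead_tail = g.outdeg(u.last()) == 0;
            if (!dead_head && !dead_tail) continue;
            bool tip = (int)u.seq.size() < 2 * k &&
                u.meancov < tip_thresh;
            bool hair = u.meancov < 0.5 * tip_thresh;
            if (tip || hair) {
                for (int h : u.path) g.active[h >> 1] = 0;
                ++removed;
            }
        }
        if (removed) continue; // recompact before bubble search
        // bubbles: group unitigs by flanking (pred, succ) node pair
        std::vector<int> scratch;
        std::map<std::pair<int,int>, std::vector<size_t>> groups;
        std::vector<char> flipped(us.size(), 0);
        for (size_t i = 0; i < us.size(); ++i) {
            Unitig& u = us[i];
            if (u.circular) continue;
            g.succ(u.first() ^ 1, scratch);
            if (scratch.size() != 1) continue;
            int A = scratch[0] ^ 1;
            g.succ(u.last(), scratch);
            if (scratch.size() != 1) continue;
            int B = scratch[0];
            std::pair<int,int> fwd(A, B), rev(B ^ 1, A ^ 1);
            if (rev < fwd) { groups[rev].push_back(i); flipped[i] = 1; }
            else groups[fwd].push_back(i);
        }
        for (auto& kv : groups) {
            auto& idx = kv.second;
            if (idx.size() < 2) continue;
            std::sort(idx.begin(), idx.end(), [&](size_t a, size_t b) {
                if (us[a].meancov != us[b].meancov)
                    return us[a].meancov > us[b].meancov;
                return us[a].seq < us[b].seq;
            });
            std::string keepseq = flipped[idx[0]] ?
                revcomp_str(us[idx[0]].seq) : us[idx[0]].seq;
            for (size_t j = 1; j < idx.size(); ++j) {
                std::string s = flipped[idx[j]] ?
                    revcomp_str(us[idx[j]].seq) : us[idx[j]].seq;
                if (edit_distance_capped(s, keepseq, bubble_diff)
                        <= bubble_diff) {
                    for (int h : us[idx[j]].path)
                        g.active[h >> 1] = 0;
                    ++removed;
                }
            }
        }
        if (!removed) break;
    }

    std::vector<Unitig> us = build_unitigs(g);
    // canonical orientation per contig, deterministic ordering; a
    // circular contig is spelled once around the cycle (the spelled
    // walk repeats its first k-1 bases at the end — drop them)
    struct Out { std::string seq; double cov; bool circ; };
    std::vector<Out> outs;
    for (auto& u : us) {
        std::string s = u.seq;
        if (u.circular && (int)s.size() > k - 1)
            s = s.substr(0, s.size() - (k - 1));
        std::string rc = revcomp_str(s);
        outs.push_back({std::min(s, rc), u.meancov, u.circular});
    }
    std::sort(outs.begin(), outs.end(), [](const Out& a, const Out& b) {
        if (a.seq.size() != b.seq.size())
            return a.seq.size() > b.seq.size();
        return a.seq < b.seq;
    });
    int n = (int)outs.size();
    CharacterVector seq(n);
    NumericVector cov(n);
    LogicalVector circ(n);
    for (int i = 0; i < n; ++i) {
        seq[i] = outs[i].seq;
        cov[i] = outs[i].cov;
        circ[i] = outs[i].circ;
    }
    return List::create(_["seq"] = seq, _["cov"] = cov,
                        _["circular"] = circ);
}
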