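#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
#include <array>
#include "kmer_encode.h"
using namespace Rcpp;

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
    }
}

static inline bool valid_base(char c) {
    return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

std::string revcomp_str(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (auto& c : r) c = comp_base(c);
    return r;
}

// canonical form: lexicographic min of k-mer and its reverse complement
static inline std::string canon_kmer(const std::string& s) {
    std::string r = revcomp_str(s);
    return (s <= r) ? s : r;
}

// positions (0-based) at which a valid (ACGT-only) k-mer starts
static void valid_starts(const std::string& s, int k, std::vector<int>& out) {
    out.clear();
    int n = (int)s.size();
    if (n < k) return;
    int run = 0; // length of current valid run ending at i
    for (int i = 0; i < n; ++i) {
        run = valid_base(s[i]) ? run + 1 : 0;
        if (run >= k) out.push_back(i - k + 1);
    }
}

// [[Rcpp::export]]
SEXP cpp_kmer_counts(CharacterVector seqs, int k) {
    if (k < 1 || k > 63) stop("k must be between 1 and 63");
    std::unordered_map<u128, int, U128Hash> counts;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        for_each_canon(s, k, [&](u128 c) { counts[c]++; });
    }
    std::vector<u128> keys;
    keys.reserve(counts.size());
    for (auto& kv : counts) keys.push_back(kv.first);
    std::sort(keys.begin(), keys.end());
    CharacterVector km(keys.size());
    IntegerVector ct(keys.size());
    for (size_t i = 0; i < keys.size(); ++i) {
        km[i] = decode_kmer(keys[i], k);
        ct[i] = counts[keys[i]];
    }
    return List::create(_["kmer"] = km, _["count"] = ct);
}

// [[Rcpp::export]]
NumericVector cpp_mean_qual(CharacterVector quals, int offset = 33) {
    NumericVector out(quals.size());
    for (R_xlen_t i = 0; i < quals.size(); ++i) {
        std::string q = as<std::string>(quals[i]);
        if (q.empty()) { out[i] = NA_REAL; continue; }
        double s = 0;
        for (char c : q) s += (double)((unsigned char)c - offset);
        out[i] = s / q.size();
    }
    return out;
}

// number of k-mer positions per sequence whose canonical k-mer is in `baits`
// [[Rcpp::export]]
IntegerVector cpp_bait_hits(CharacterVector seqs, CharacterVector baits, int k) {
    if (k < 1 || k > 63) stop("k must be between 1 and 63");
    std::unordered_set<u128, U128Hash> bait;
    bait.reserve(baits.size() * 2);
    for (R_xlen_t i = 0; i < baits.size(); ++i) {
        std::string b = as<std::string>(baits[i]);
        u128 x = encode_kmer(b);
        u128 r = rc_kmer(x, k);
        bait.insert(x < r ? x : r);
    }
    IntegerVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        std::string s = as<std::string>(seqs[i]);
        int hits = 0;
        for_each_canon(s, k, [&](u128 c) { hits += (int)bait.count(c); });
        out[i] = hits;
    }
    return out;
}

// Maximal exact-match anchors between two sequences, seeded at k-mers that
// occur exactly once in the query (forward strand) and exactly once in the
// target (one strand only: a k-mer present on both target strands is skipped
// as ambiguous). Seeds on a common diagonal are merged and then extended
// outward base-by-base; contained anchors are dropped. 1-based coordinates.
// [[Rcpp::export]]
DataFrame cpp_anchors(std::string q, std::string t, int k) {
    int qn = (int)q.size(), tn = (int)t.size();
    struct Occ { int count; int pos; };
    std::unordered_map<std::string, Occ> qmap, tmap;
    std::vector<int> starts;
    valid_starts(q, k, starts);
    for (int p : starts) {
        auto& o = qmap[q.substr(p, k)];
        o.count++; o.pos = p;
    }
    valid_starts(t, k, starts);
    for (int p : starts) {
        auto& o = tmap[t.substr(p, k)];
        o.count++; o.pos = p;
    }
    // seeds
    std::vector<std::array<int,2>> plus, minus; // {qpos, tpos} 0-based starts
    valid_starts(q, k, starts);
    for (int p : starts) {
        std::string x = q.substr(p, k);
        auto qi = qmap.find(x);
        if (qi == qmap.end() || qi->second.count != 1) continue;
        std::string xr = revcomp_str(x);
        auto tf = tmap.find(x);
        auto tr = tmap.find(xr);
        bool fwd = (tf != tmap.end() && tf->second.count == 1);
        bool rev = (tr != tmap.end() && tr->second.count == 1);
        // both may fire (e.g. inside an inverted repeat); chaining later
        // keeps the collinear-consistent subset
        if (fwd) plus.push_back({p, tf->second.pos});
        if (rev) minus.push_back({p, tr->second.pos});
    }
    struct Block { int qs, qe, ts, te; char strand; };
    std::vector<Block> blocks;
    // merge '+' runs (same diagonal, consecutive)
    std::sort(plus.begin(), plus.end());
    for (size_t i = 0; i < plus.size(); ) {
        size_t j = i;
        while (j + 1 < plus.size() &&
               plus[j+1][0] == plus[j][0] + 1 &&
               plus[j+1][1] == plus[j][1] + 1) ++j;
        blocks.push_back({plus[i][0], plus[j][0] + k - 1,
                          plus[i][1], plus[j][1] + k - 1, '+'});
        i = j + 1;
    }
    // merge '-' runs (anti-diagonal: q +1 <-> t -1)
    std::sort(minus.begin(), minus.end());
    for (size_t i = 0; i < minus.size(); ) {
        size_t j = i;
        while (j + 1 < minus.size() &&
               minus[j+1][0] == minus[j][0] + 1 &&
               minus[j+1][1] == minus[j][1] - 1) ++j;
        blocks.push_back({minus[i][0], minus[j][0] + k - 1,
                          minus[j][1], minus[i][1] + k - 1, '-'});
        i = j + 1;
    }
    // maximal extension
    for (auto& b : blocks) {
        if (b.strand == '+') {
            while (b.qs > 0 && b.ts > 0 && q[b.qs-1] == t[b.ts-1] &&
                   valid_base(q[b.qs-1])) { --b.qs; --b.ts; }
            while (b.qe + 1 < qn && b.te + 1 < tn && q[b.qe+1] == t[b.te+1] &&
                   valid_base(q[b.qe+1])) { ++b.qe; ++b.te; }
        } else {
            while (b.qs > 0 && b.te + 1 < tn &&
                   q[b.qs-1] == comp_base(t[b.te+1]) &&
                   valid_base(q[b.qs-1])) { --b.qs; ++b.te; }
            while (b.qe + 1 < qn && b.ts > 0 &&
                   q[b.qe+1] == comp_base(t[b.ts-1]) &&
                   valid_base(q[b.qe+1])) { ++b.qe; --b.ts; }
        }
    }
    // dedupe + drop contained
    std::sort(blocks.begin(), blocks.end(), [](const Block& a, const Block& b) {
        if (a.qs != b.qs) return a.qs < b.qs;
        if (a.qe != b.qe) return a.qe > b.qe;
        if (a.ts != b.ts) return a.ts < b.ts;
        return a.strand < b.strand;
    });
    std::vector<Block> keep;
    for (auto& b : blocks) {
        bool contained = false;
        for (auto& o : keep) {
            if (o.strand == b.strand &&
                o.qs <= b.qs && o.qe >= b.qe &&
                o.ts <= b.ts && o.te >= b.te) { contained = true; break; }
        }
        if (!contained && !(keep.size() &&
                            keep.back().qs == b.qs && keep.back().qe == b.qe &&
                            keep.back().ts == b.ts && keep.back().te == b.te &&
                            keep.back().strand == b.strand))
            keep.push_back(b);
    }
    int n = (int)keep.size();
    IntegerVector qs(n), qe(n), ts(n), te(n);
    CharacterVector st(n);
    for (int i = 0; i < n; ++i) {
        qs[i] = keep[i].qs + 1; qe[i] = keep[i].qe + 1;
        ts[i] = keep[i].ts + 1; te[i] = keep[i].te + 1;
        st[i] = std::string(1, keep[i].strand);
    }
    return DataFrame::create(_["qstart"] = qs, _["qend"] = qe,
                             _["tstart"] = ts, _["tend"] = te,
                             _["strand"] = st,
                             _["stringsAsFactors"] = false);
}

// Inverted-repeat match blocks within one sequence: pairs of disjoint spans
// (s1..e1, s2..e2), s2 > e1, with seq[s1..e1] equal to the reverse
// complement of seq[s2..e2]. Seeded at canonical k-mers occurring exactly
// twice on opposite strands, merged along anti-diagonals and extended
// maximally. 1-based coordinates, sorted by decreasing length.
// [[Rcpp::export]]
DataFrame cpp_inverted_matches(std::string s, int k) {
    struct Occ { int count; int pos1; int pos2; int str1; int str2; };
    std::unordered_map<std::string, Occ> occ;
    std::vector<int> starts;
    valid_starts(s, k, starts);
    for (int p : starts) {
        std::string x = s.substr(p, k);
        std::string xr = revcomp_str(x);
        bool is_fwd = (x <= xr);
        std::string c = is_fwd ? x : xr;
        auto& o = occ[c];
        o.count++;
        if (o.count == 1) { o.pos1 = p; o.str1 = is_fwd; }
        else if (o.count == 2) { o.pos2 = p; o.str2 = is_fwd; }
    }
    // seeds: {left start, right start} with left span == rc(right span)
    std::vector<std::array<int,2>> seeds;
    for (auto& kv : occ) {
        const Occ& o = kv.second;
        if (o.count != 2 || o.str1 == o.str2) continue;
        int a = std::min(o.pos1, o.pos2), b = std::max(o.pos1, o.pos2);
        if (b > a + k - 1) seeds.push_back({a, b});
    }
    std::sort(seeds.begin(), seeds.end());
    struct Block { int qs, qe, ts, te; };
    std::vector<Block> blocks;
    for (size_t i = 0; i < seeds.size(); ) {
        size_t j = i;
        while (j + 1 < seeds.size() &&
               seeds[j+1][0] == seeds[j][0] + 1 &&
               seeds[j+1][1] == seeds[j][1] - 1) ++j;
        blocks.push_back({seeds[i][0], seeds[j][0] + k - 1,
                          seeds[j][1], seeds[i][1] + k - 1});
        i = j + 1;
    }
    int n = (int)s.size();
    for (auto& b : blocks) {
        while (b.qs > 0 && b.te + 1 < n &&
               valid_base(s[b.qs-1]) && s[b.qs-1] == comp_base(s[b.te+1])) {
            --b.qs; ++b.te;
        }
        while (b.qe + 1 < b.ts - 1 &&
               valid_base(s[b.qe+1]) && s[b.qe+1] == comp_base(s[b.ts-1])) {
            ++b.qe; --b.ts;
        }
    }
    // dedupe/drop contained
    std::sort(blocks.begin(), blocks.end(), [](const Block& a, const Block& b) {
        int la = a.qe - a.qs, lb = b.qe - b.qs;
        if (la != lb) return la > lb;
        return a.qs < b.qs;
    });
    std::vector<Block> keep;
    for (auto& b : blocks) {
        bool contained = false;
        for (auto& o : keep)
            if (o.qs <= b.qs && o.qe >= b.qe && o.ts <= b.ts && o.te >= b.te) {
                contained = true; break;
            }
        if (!contained) keep.push_back(b);
    }
    int m = (int)keep.size();
    IntegerVector s1(m), e1(m), s2(m), e2(m), len(m);
    for (int i = 0; i < m; ++i) {
        s1[i] = keep[i].qs + 1; e1[i] = keep[i].qe + 1;
        s2[i] = keep[i].ts + 1; e2[i] = keep[i].te + 1;
        len[i] = keep[i].qe - keep[i].qs + 1;
    }
    return DataFrame::create(_["start1"] = s1, _["end1"] = e1,
                             _["start2"] = s2, _["end2"] = e2,
                             _["length"] = len,
                             _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
    CharacterVector out(seqs.size());
    for (R_xlen_t i = 0; i < seqs.size(); ++i)
        out[i] = revcomp_str(as<std::string>(seqs[i]));
    return out;
}
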