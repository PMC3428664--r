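#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

// Bases outside {A,C,G,T} (i.e. N) never match anything, including another N.
static inline bool base_mismatch(char a, char b) {
    return a != b || a == 'N' || b == 'N';
}

static inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

static std::string revcomp(const std::string& s) {
    std::string r(s.rbegin(), s.rend());
    for (char& c : r) c = comp_base(c);
    return r;
}

static inline int code2(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
    }
}

// Hamming distance with early abort once the count exceeds `limit`.
static int mismatches_upto(const char* a, const char* b, int len, int limit) {
    int m = 0;
    for (int i = 0; i < len; ++i) {
        if (base_mismatch(a[i], b[i]) && ++m > limit) return m;
    }
    return m;
}

struct RefIndex {
    std::string seq;                    // concatenated unigene sequences
    std::vector<long long> uni_start;   // global start of each unigene
    std::vector<int> uni_len;
    int k;                              // seed length; 0 => exhaustive scan
    std::unordered_map<uint32_t, std::vector<long long>> kmers;

    // unigene containing global position g (g must lie inside one)
    int unigene_of(long long g) const {
        size_t lo = std::upper_bound(uni_start.begin(), uni_start.end(), g) -
                    uni_start.begin();
        return (int)lo - 1;
    }
};

static void build_index(RefIndex& ix, const std::vector<std::string>& refs, int k) {
    ix.k = k;
    long long off = 0;
    for (size_t u = 0; u < refs.size(); ++u) {
        ix.uni_start.push_back(off);
        ix.uni_len.push_back((int)refs[u].size());
        ix.seq += refs[u];
        off += (long long)refs[u].size();
    }
    if (k <= 0) return;
    ix.kmers.reserve(ix.seq.size());
    const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
    for (size_t u = 0; u < refs.size(); ++u) {
        const std::string& s = refs[u];
        if ((int)s.size() < k) continue;
        uint32_t code = 0;
        int valid = 0; // bases accumulated since last N
        for (size_t i = 0; i < s.size(); ++i) {
            int c = code2(s[i]);
            if (c < 0) { valid = 0; code = 0; continue; }
            code = ((code << 2) | (uint32_t)c) & mask;
            if (++valid >= k)
                ix.kmers[code].push_back(ix.uni_start[u] + (long long)(i + 1 - k));
        }
    }
}

struct Best {
    int mm = INT_MAX;
    long long start = -1;
    int strand = 0;     // 0 = forward, 1 = reverse
    int n_best = 0;

    // Reservoir update: keeps a uniform choice over all minimal placements
    // seen so far, matching the documented random tie-break of the aligner
    // this component emulates.
    void offer(int mm_new, long long g, int strand_new) {
        if (mm_new < mm) {
            mm = mm_new; start = g; strand = strand_new; n_best = 1;
        } else if (mm_new == mm) {
            ++n_best;
            if (unif_rand() < 1.0 / (double)n_best) { start = g; strand = strand_new; }
        }
    }
};

// Candidate placements for one oriented read via pigeonhole seeding:
// the read is cut into (cap+1) blocks; any placement with <= cap mismatches
// matches at least one block exactly, so the first k bases of each block are
// looked up in the k-mer index.
static void seed_candidates(const RefIndex& ix, const std::string& read, int cap,
                            std::vector<long long>& out) {
    const int L = (int)read.size();
    const int nblocks = cap + 1;
    const int bl = L / nblocks;
    for (int q = 0; q < nblocks; ++q) {
        const int off = q * bl;
        if (off + ix.k > L) break;
        uint32_t code = 0;
        bool ok = true;
        for (int i = 0; i < ix.k; ++i) {
            int c = code2(read[off + i]);
            if (c < 0) { ok = false; break; }
            code = (code << 2) | (uint32_t)c;
        }
        if (!ok) continue;
        auto it = ix.kmers.find(code);
        if (it == ix.kmers.end()) continue;
        for (long long hit : it->second) {
            long long g = hit - off;
            int u = ix.unigene_of(hit);
            if (g < ix.uni_start[u]) continue;
            if (g + L > ix.uni_start[u] + ix.uni_len[u]) continue;
            out.push_back(g);
        }
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
}

// [[Rcpp::export]]
List cpp_align_reads(CharacterVector read_seqs, CharacterVector ref_seqs,
                     int max_mismatches) {
    const int nr = read_seqs.size();
    const int nu = ref_seqs.size();
    std::vector<std::string> refs(nu);
    for (int u = 0; u < nu; ++u) refs[u] = as<std::string>(ref_seqs[u]);

    int min_len = INT_MAX;
    for (int i = 0; i < nr; ++i) {
        int L = LENGTH(STRING_ELT(read_seqs, i));
        if (L < min_len) min_len = L;
    }
    if (nr == 0) min_len = 0;

    // Seed length from the shortest read; below 6 the index buys nothing,
    // fall back to an exhaustive scan (also exact, just slower).
    int k = min_len / (max_mismatches + 1);
    if (k > 15) k = 15;
    if (k < 6) k = 0;

    RefIndex ix;
    build_index(ix, refs, k);

    IntegerVector out_uni(nr, NA_INTEGER), out_start(nr, NA_INTEGER),
        out_mm(nr, NA_INTEGER);
    CharacterVector out_strand(nr, NA_STRING);
    LogicalVector out_tie(nr, NA_LOGICAL);

    std::vector<long long> cand;
    for (int i = 0; i < nr; ++i) {
        const std::string fwd = as<std::string>(read_seqs[i]);
        const int L = (int)fwd.size();
        if (L == 0) continue;
        const std::string rev = revcomp(fwd);
        Best best;

        if (ix.k > 0) {
            for (int s = 0; s < 2; ++s) {
                const std::string& oriented = (s == 0) ? fwd : rev;
                cand.clear();
                seed_candidates(ix, oriented, max_mismatches, cand);
                for (long long g : cand) {
                    int limit = std::min(max_mismatches, best.mm);
                    int mm = mismatches_upto(ix.seq.data() + g, oriented.data(), L, limit);
                    if (mm <= limit) best.offer(mm, g, s);
                }
            }
        } else {
            for (int u = 0; u < nu; ++u) {
                const int M = ix.uni_len[u];
                if (L > M) continue;
                const char* rp = ix.seq.data() + ix.uni_start[u];
                for (int s = 0; s < 2; ++s) {
                    const std::string& oriented = (s == 0) ? fwd : rev;
                    for (int o = 0; o + L <= M; ++o) {
                        int limit = std::min(max_mismatches, best.mm);
                        int mm = mismatches_upto(rp + o, oriented.data(), L, limit);
                        if (mm <= limit) best.offer(mm, ix.uni_start[u] + o, s);
                    }
                }
            }
        }

        if (best.n_best > 0) {
            int u = ix.unigene_of(best.start);
            out_uni[i] = u + 1;
            out_start[i] = (int)(best.start - ix.uni_start[u]);
            out_strand[i] = (best.strand == 0) ? "+" : "-";
            out_mm[i] = best.mm;
            out_tie[i] = best.n_best > 1;
        }
    }

    return List::create(_["unigene_idx"] = out_uni, _["start"] = out_start,
                        _["strand"] = out_strand, _["mismatches"] = out_mm,
                        _["tie_broken"] = out_tie);
}

// [[Rcpp::export]]
List cpp_build_pileup(IntegerVector uni_idx, IntegerVector start,
                      CharacterVector strand, CharacterVector read_seqs,
                      CharacterVector read_quals, CharacterVector ref_seqs,
                      int qual_offset) {
    const int nrec = uni_idx.size();
    const int nu = ref_seqs.size();
    std::vector<std::string> refs(nu);
    for (int u = 0; u < nu; ++u) refs[u] = as<std::string>(ref_seqs[u]);

    // lazily allocated per-unigene accumulators: 5 bases x length
    std::vector<std::vector<int>> counts(nu), quals(nu);

    for (int r = 0; r < nrec; ++r) {
        const int u = uni_idx[r] - 1;
        if (u < 0 || u >= nu) stop("pileup: unigene index out of range");
        const std::string s = as<std::string>(read_seqs[r]);
        const std::string q = as<std::string>(read_quals[r]);
        const int L = (int)s.size();
        if ((int)q.size() != L) stop("pileup: read/quality length mismatch");
        const int M = (int)refs[u].size();
        const int st = start[r];
        if (st < 0 || st + L > M)
            stop("pileup: alignment record extends beyond unigene '%d'", u + 1);
        const bool rev = (as<std::string>(strand[r]) == "-");
        if (counts[u].empty()) {
            counts[u].assign(5 * M, 0);
            quals[u].assign(5 * M, 0);
        }
        for (int j = 0; j < L; ++j) {
            char ch; int qv;
            if (!rev) { ch = s[j]; qv = (int)q[j] - qual_offset; }
            else      { ch = comp_base(s[L - 1 - j]); qv = (int)q[L - 1 - j] - qual_offset; }
            int b;
            switch (ch) {
            case 'A': b = 0; break; case 'C': b = 1; break;
            case 'G': b = 2; break; case 'T': b = 3; break;
            default:  b = 4; break;
            }
            const int pos = st + j;
            counts[u][5 * pos + b] += 1;
            quals[u][5 * pos + b] += (qv > 0 ? qv : 0);
        }
    }

    // emit covered columns in (unigene, position) order
    long long ncol = 0;
    for (int u = 0; u < nu; ++u) {
        if (counts[u].empty()) continue;
        const int M = (int)refs[u].size();
        for (int p = 0; p < M; ++p) {
            int d = 0;
            for (int b = 0; b < 5; ++b) d += counts[u][5 * p + b];
            if (d > 0) ++ncol;
        }
    }

    IntegerVector o_uni((R_xlen_t)ncol), o_pos((R_xlen_t)ncol), o_depth((R_xlen_t)ncol);
    CharacterVector o_ref((R_xlen_t)ncol);
    IntegerMatrix o_counts((R_xlen_t)ncol, 5), o_quals((R_xlen_t)ncol, 5);
    R_xlen_t i = 0;
    for (int u = 0; u < nu; ++u) {
        if (counts[u].empty()) continue;
        const int M = (int)refs[u].size();
        for (int p = 0; p < M; ++p) {
            int d = 0;
            for (int b = 0; b < 5; ++b) d += counts[u][5 * p + b];
            if (d == 0) continue;
            o_uni[i] = u + 1;
            o_pos[i] = p;
            o_ref[i] = std::string(1, refs[u][p]);
            o_depth[i] = d;
            for (int b = 0; b < 5; ++b) {
                o_counts(i, b) = counts[u][5 * p + b];
                o_quals(i, b) = quals[u][5 * p + b];
            }
            ++i;
        }
    }
    return List::create(_["unigene_idx"] = o_uni, _["pos"] = o_pos,
                        _["ref"] = o_ref, _["depth"] = o_depth,
                        _["counts"] = o_counts, _["quals"] = o_quals);
}
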