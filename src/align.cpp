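#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>
#include <climits>

using namespace Rcpp;

// BLASTN-like local alignment of genome fragments against reference contigs:
// exact k-mer seeding, diagonal grouping, Smith-Waterman (affine gaps) over
// the seeded window, traceback for identity and query coverage. Scores:
// match/mismatch are integers, a gap of length L costs gap_open + L*gap_ext.

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4; // ambiguity codes never match anything
    }
}

static std::vector<int> encode(const std::string& s) {
    std::vector<int> v(s.size());
    for (size_t i = 0; i < s.size(); ++i) v[i] = base_code(s[i]);
    return v;
}

static std::vector<int> revcomp(const std::vector<int>& v) {
    std::vector<int> r(v.size());
    for (size_t i = 0; i < v.size(); ++i) {
        int c = v[v.size() - 1 - i];
        r[i] = (c < 4) ? 3 - c : 4;
    }
    return r;
}

struct KmerIndex {
    int k;
    std::unordered_map<std::uint64_t, std::vector<int> > pos;
    void build(const std::vector<int>& seq, int k_) {
        k = k_;
        pos.clear();
        if ((int)seq.size() < k) return;
        std::uint64_t key = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
        int run = 0; // length of current ambiguity-free run
        for (size_t i = 0; i < seq.size(); ++i) {
            if (seq[i] > 3) { run = 0; key = 0; continue; }
            key = ((key << 2) | (std::uint64_t)seq[i]) & mask;
            if (++run >= k) pos[key].push_back((int)(i + 1 - k));
        }
    }
};

struct AlnStats {
    int score;
    int matches;
    int columns;
    int q_start, q_end; // 0-based, half-open on the (possibly revcomp) fragment
    bool found;
};

// Smith-Waterman with affine gaps over frag x window, score only.
static int sw_score(const std::vector<int>& q, const std::vector<int>& r,
                    int r_lo, int r_hi,
                    int match, int mismatch, int gap_open, int gap_ext) {
    int n = r_hi - r_lo;
    int m = (int)q.size();
    if (n <= 0 || m <= 0) return 0;
    std::vector<int> H(n + 1, 0), E(n + 1, INT_MIN / 4);
    int best = 0;
    int go = gap_open + gap_ext;
    for (int i = 1; i <= m; ++i) {
        int Hdiag = 0, F = INT_MIN / 4, Hprev = 0;
        for (int j = 1; j <= n; ++j) {
            E[j] = std::max(H[j] - go, E[j] - gap_ext);
            F = std::max(Hprev - go, F - gap_ext);
            int qi = q[i - 1], rj = r[r_lo + j - 1];
            int s = (qi < 4 && qi == rj) ? match : mismatch;
            int h = std::max(0, std::max(Hdiag + s, std::max(E[j], F)));
            Hdiag = H[j];
            H[j] = h;
            Hprev = h;
            if (h > best) best = h;
        }
    }
    return best;
}

// Full traceback variant (used once per fragment on the winning window).
static AlnStats sw_traceback(const std::vector<int>& q, const std::vector<int>& r,
                             int r_lo, int r_hi,
                             int match, int mismatch, int gap_open, int gap_ext) {
    AlnStats st; st.score = 0; st.matches = 0; st.columns = 0;
    st.q_start = 0; st.q_end = 0; st.found = false;
    int n = r_hi - r_lo, m = (int)q.size();
    if (n <= 0 || m <= 0) return st;
    const int NEG = INT_MIN / 4, go = gap_open + gap_ext;
    std::vector<int> H((m + 1) * (n + 1), 0), E((m + 1) * (n + 1), NEG),
        F((m + 1) * (n + 1), NEG);
    int besti = 0, bestj = 0, best = 0;
    for (int i = 1; i <= m; ++i) {
        for (int j = 1; j <= n; ++j) {
            int idx = i * (n + 1) + j;
            E[idx] = std::max(H[idx - 1] - go, E[idx - 1] - gap_ext);
            F[idx] = std::max(H[idx - (n + 1)] - go, F[idx - (n + 1)] - gap_ext);
            int qi = q[i - 1], rj = r[r_lo + j - 1];
            int s = (qi < 4 && qi == rj) ? match : mismatch;
            int h = std::max(0, std::max(H[idx - (n + 1) - 1] + s,
                                         std::max(E[idx], F[idx])));
            H[idx] = h;
            if (h > best) { best = h; besti = i; bestj = j; }
        }
    }
    if (best <= 0) return st;
    st.score = best; st.found = true;
    // traceback: state 0 = H, 1 = E (gap in query), 2 = F (gap in reference)
    int i = besti, j = bestj, state = 0;
    st.q_end = besti;
    while (i > 0 && j > 0) {
        int idx = i * (n + 1) + j;
        if (state == 0) {
            if (H[idx] == 0) break;
            int qi = q[i - 1], rj = r[r_lo + j - 1];
            int s = (qi < 4 && qi == rj) ? match : mismatch;
            if (H[idx] == H[idx - (n + 1) - 1] + s) {
                st.columns++;
                if (qi < 4 && qi == rj) st.matches++;
                --i; --j;
            } else if (H[idx] == E[idx]) {
                state = 1;
            } else {
                state = 2;
            }
        } else if (state == 1) { // gap in query, consume reference
            st.columns++;
            if (E[idx] == H[idx - 1] - go) state = 0;
            --j;
        } else { // gap in reference, consume query
            st.columns++;
            if (F[idx] == H[idx - (n + 1)] - go) state = 0;
            --i;
        }
    }
    st.q_start = i;
    return st;
}

struct Candidate {
    int contig, strand; // strand: 0 = '+', 1 = '-'
    int lo, hi;         // reference window
    int score;
};

// [[Rcpp::export(name = ".fragment_hits_cpp")]]
DataFrame fragment_hits_cpp(CharacterVector fragments, CharacterVector contigs,
                            double min_identity, double min_alignable,
                            int seed_k, int band,
                            int match, int mismatch, int gap_open, int gap_ext) {
    int nf = fragments.size(), nc = contigs.size();
    std::vector<std::vector<int> > refs(nc);
    std::vector<KmerIndex> idx(nc);
    for (int c = 0; c < nc; ++c) {
        refs[c] = encode(std::string(CHAR(STRING_ELT(contigs, c))));
        idx[c].build(refs[c], seed_k);
    }

    NumericVector identity(nf, NA_REAL), alignable(nf, NA_REAL), score(nf, NA_REAL);
    CharacterVector strand(nf, NA_STRING);
    IntegerVector hit_contig(nf, NA_INTEGER);
    LogicalVector found(nf, false);

    std::uint64_t mask = (seed_k < 32) ? ((1ULL << (2 * seed_k)) - 1) : ~0ULL;

    for (int f = 0; f < nf; ++f) {
        std::vector<int> fwd = encode(std::string(CHAR(STRING_ELT(fragments, f))));
        std::vector<int> rev = revcomp(fwd);
        int flen = (int)fwd.size();
        Candidate best; best.score = 0; best.contig = -1;

        for (int s = 0; s < 2; ++s) {
            const std::vector<int>& q = (s == 0) ? fwd : rev;
            // fragment k-mers
            std::vector<std::pair<int, std::uint64_t> > qk; // (pos, key)
            {
                std::uint64_t key = 0; int run = 0;
                for (int i = 0; i < flen; ++i) {
                    if (q[i] > 3) { run = 0; key = 0; continue; }
                    key = ((key << 2) | (std::uint64_t)q[i]) & mask;
                    if (++run >= seed_k) qk.push_back(std::make_pair(i + 1 - seed_k, key));
                }
            }
            for (int c = 0; c < nc; ++c) {
                std::vector<int> diags;
                for (size_t t = 0; t < qk.size(); ++t) {
                    std::unordered_map<std::uint64_t, std::vector<int> >::const_iterator
                        it = idx[c].pos.find(qk[t].second);
                    if (it == idx[c].pos.end()) continue;
                    for (size_t u = 0; u < it->second.size(); ++u)
                        diags.push_back(it->second[u] - qk[t].first);
                }
                if (diags.empty()) continue;
                std::sort(diags.begin(), diags.end());
                diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
                int rlen = (int)refs[c].size();
                size_t g0 = 0;
                for (size_t g = 1; g <= diags.size(); ++g) {
                    if (g == diags.size() || diags[g] - diags[g - 1] > band) {
                        int lo = std::max(0, diags[g0] - band);
                        int hi = std::min(rlen, diags[g - 1] + flen + band);
                        int sc = sw_score(q, refs[c], lo, hi,
                                          match, mismatch, gap_open, gap_ext);
                        if (sc > best.score) {
                            best.score = sc; best.contig = c; best.strand = s;
                            best.lo = lo; best.hi = hi;
                        }
                        g0 = g;
                    }
                }
            }
        }

        if (best.contig >= 0) {
            const std::vector<int>& q = (best.strand == 0) ? fwd : rev;
            AlnStats st = sw_traceback(q, refs[best.contig], best.lo, best.hi,
                                       match, mismatch, gap_open, gap_ext);
            if (st.found && st.columns > 0) {
                double id = 100.0 * (double)st.matches / (double)st.columns;
                double af = (double)(st.q_end - st.q_start) / (double)flen;
                if (id >= min_identity && af >= min_alignable) {
                    identity[f] = id;
                    alignable[f] = af;
                    score[f] = st.score;
                    strand[f] = (best.strand == 0) ? "+" : "-";
                    hit_contig[f] = best.contig + 1;
                    found[f] = true;
                }
            }
        }
    }

    return DataFrame::create(
        Named("found") = found,
        Named("identity") = identity,
        Named("alignable_fraction") = alignable,
        Named("score") = score,
        Named("strand") = strand,
        Named("ref_contig") = hit_contig,
        Named("stringsAsFactors") = false);
}
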