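// Core numeric kernels: canonical k-mer counting, pairwise profile
// distances, community read simulation and windowed k-mer containment.
// k-mers are 2-bit packed (A=0, C=1, G=2, T=3) into 64-bit words, so the
// numeric order of packed codes equals lexicographic order of the strings
// and k is capped at 31.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;  // N or anything else breaks the window
    }
}

static const char DECODE[4] = {'A', 'C', 'G', 'T'};

// Open-addressing counter for packed k-mers (linear probing); much
// faster than unordered_map on the hot counting path.
struct FlatCounter {
    static constexpr uint64_t EMPTY = ~0ULL;
    std::vector<uint64_t> keys;
    std::vector<double> vals;
    size_t mask = 0, used = 0;

    explicit FlatCounter(size_t expect = 64) {
        size_t cap = 64;
        while (cap < expect * 2) cap <<= 1;
        keys.assign(cap, EMPTY);
        vals.assign(cap, 0.0);
        mask = cap - 1;
    }
    static inline size_t hash64(uint64_t x) {
        x ^= x >> 33; x *= 0xff51afd7ed558ccdULL;
        x ^= x >> 33; x *= 0xc4ceb9fe1a85ec53ULL;
        x ^= x >> 33;
        return (size_t)x;
    }
    void grow() {
        std::vector<uint64_t> ok; ok.swap(keys);
        std::vector<double> ov; ov.swap(vals);
        size_t cap = (mask + 1) << 1;
        keys.assign(cap, EMPTY);
        vals.assign(cap, 0.0);
        mask = cap - 1;
        used = 0;
        for (size_t i = 0; i < ok.size(); ++i)
            if (ok[i] != EMPTY) add(ok[i], ov[i]);
    }
    inline void add(uint64_t key, double w) {
        size_t i = hash64(key) & mask;
        while (true) {
            if (keys[i] == key) { vals[i] += w; return; }
            if (keys[i] == EMPTY) {
                keys[i] = key; vals[i] = w;
                if (++used * 10 > (mask + 1) * 7) grow();
                return;
            }
            i = (i + 1) & mask;
        }
    }
    inline bool contains(uint64_t key) const {
        size_t i = hash64(key) & mask;
        while (true) {
            if (keys[i] == key) return true;
            if (keys[i] == EMPTY) return false;
            i = (i + 1) & mask;
        }
    }
    template <typename F> void for_each(F f) const {
        for (size_t i = 0; i < keys.size(); ++i)
            if (keys[i] != EMPTY) f(keys[i], vals[i]);
    }
};

static std::string decode_kmer(uint64_t code, int k) {
    std::string s(k, 'A');
    for (int i = k - 1; i >= 0; --i) {
        s[i] = DECODE[code & 3ULL];
        code >>= 2;
    }
    return s;
}

// Scan one sequence, adding each canonical k-mer window to `counts`.
// Windows containing non-ACGT characters are skipped.
static void scan_sequence(const char* seq, size_t len, int k,
                          FlatCounter& counts) {
    const uint64_t mask = (k < 32) ? ((1ULL << (2 * k)) - 1ULL) : ~0ULL;
    const int rc_shift = 2 * (k - 1);
    uint64_t fwd = 0, rev = 0;
    int filled = 0;
    for (size_t i = 0; i < len; ++i) {
        int c = base_code(seq[i]);
        if (c < 0) { filled = 0; fwd = 0; rev = 0; continue; }
        fwd = ((fwd << 2) | (uint64_t)c) & mask;
        rev = (rev >> 2) | ((uint64_t)(3 - c) << rc_shift);
        if (++filled >= k) {
            counts.add(std::min(fwd, rev), 1.0);
        }
    }
}

// [[Rcpp::export(name = ".cpp_count_kmers")]]
List cpp_count_kmers(CharacterVector seqs, int k, int min_abundance) {
    if (k < 1 || k > 31) stop("k must be in [1, 31]");
    size_t windows = 0;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        int len = LENGTH(STRING_ELT(seqs, i));
        if (len >= k) windows += (size_t)(len - k + 1);
    }
    FlatCounter counts(windows / 2 + 16);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        scan_sequence(s, LENGTH(STRING_ELT(seqs, i)), k, counts);
    }
    std::vector<std::pair<uint64_t, double>> kept;
    kept.reserve(counts.used);
    counts.for_each([&](uint64_t key, double v) {
        if (v >= (double)min_abundance) kept.emplace_back(key, v);
    });
    std::sort(kept.begin(), kept.end());
    R_xlen_t n = (R_xlen_t)kept.size();
    NumericVector cnt(n);
    CharacterVector nm(n);
    double total = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        nm[i] = decode_kmer(kept[i].first, k);
        cnt[i] = kept[i].second;
        total += kept[i].second;
    }
    cnt.attr("names") = nm;
    return List::create(_["counts"] = cnt, _["total"] = total);
}

// Re-pack the (sorted, canonical) k-mer names of a profile to codes.
static void pack_profile(CharacterVector nm, NumericVector cnt, int k,
                         std::vector<uint64_t>& codes,
                         std::vector<double>& vals) {
    R_xlen_t n = nm.size();
    codes.resize(n);
    vals.resize(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        const char* s = CHAR(STRING_ELT(nm, i));
        uint64_t code = 0;
        for (int j = 0; j < k; ++j) code = (code << 2) | (uint64_t)base_code(s[j]);
        codes[i] = code;
        vals[i] = cnt[i];
    }
}

// Sorted-merge accumulation of sum(min), sum(max) and the two totals.
static void pair_sums(const std::vector<uint64_t>& ca, const std::vector<double>& va,
                      const std::vector<uint64_t>& cb, const std::vector<double>& vb,
                      double& smin, double& smax) {
    size_t i = 0, j = 0;
    smin = 0.0; smax = 0.0;
    while (i < ca.size() && j < cb.size()) {
        if (ca[i] == cb[j]) {
            smin += std::min(va[i], vb[j]);
            smax += std::max(va[i], vb[j]);
            ++i; ++j;
        } else if (ca[i] < cb[j]) {
            smax += va[i]; ++i;
        } else {
            smax += vb[j]; ++j;
        }
    }
    for (; i < ca.size(); ++i) smax += va[i];
    for (; j < cb.size(); ++j) smax += vb[j];
}

// profiles: list of named numeric vectors (canonical k-mer -> count),
// names sorted lexicographically. metric: "ab_jaccard" or "bray_curtis".
// [[Rcpp::export(name = ".cpp_distance_matrix")]]
NumericMatrix cpp_distance_matrix(List profiles, int k, std::string metric) {
    int n = profiles.size();
    std::vector<std::vector<uint64_t>> codes(n);
    std::vector<std::vector<double>> vals(n);
    std::vector<double> totals(n, 0.0);
    for (int i = 0; i < n; ++i) {
        NumericVector cnt = profiles[i];
        CharacterVector nm = cnt.attr("names");
        pack_profile(nm, cnt, k, codes[i], vals[i]);
        for (double v : vals[i]) totals[i] += v;
    }
    NumericMatrix out(n, n);
    bool bc = (metric == "bray_curtis");
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double smin, smax, d;
            pair_sums(codes[i], vals[i], codes[j], vals[j], smin, smax);
            if (bc) {
                double tot = totals[i] + totals[j];
                d = (tot > 0.0) ? 1.0 - 2.0 * smin / tot : 0.0;
            } else {
                d = (smax > 0.0) ? 1.0 - smin / smax : 0.0;
            }
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Fast path used for whole distance matrices: profiles as packed-code
// vectors (doubles; exact for k <= 26 since 2k bits fit the mantissa),
// skipping string materialization of the k-mer keys.
// [[Rcpp::export(name = ".cpp_count_kmer_codes")]]
List cpp_count_kmer_codes(CharacterVector seqs, int k, int min_abundance) {
    if (k < 1 || k > 26) stop("code path requires k in [1, 26]");
    size_t windows = 0;
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        int len = LENGTH(STRING_ELT(seqs, i));
        if (len >= k) windows += (size_t)(len - k + 1);
    }
    FlatCounter counts(windows / 2 + 16);
    for (R_xlen_t i = 0; i < seqs.size(); ++i) {
        const char* s = CHAR(STRING_ELT(seqs, i));
        scan_sequence(s, LENGTH(STRING_ELT(seqs, i)), k, counts);
    }
    std::vector<std::pair<uint64_t, double>> kept;
    kept.reserve(counts.used);
    counts.for_each([&](uint64_t key, double v) {
        if (v >= (double)min_abundance) kept.emplace_back(key, v);
    });
    std::sort(kept.begin(), kept.end());
    R_xlen_t n = (R_xlen_t)kept.size();
    NumericVector codes(n), cnt(n);
    double total = 0.0;
    for (R_xlen_t i = 0; i < n; ++i) {
        codes[i] = (double)kept[i].first;
        cnt[i] = kept[i].second;
        total += kept[i].second;
    }
    return List::create(_["codes"] = codes, _["counts"] = cnt,
                        _["total"] = total);
}

// profiles: list of List(codes, counts) from cpp_count_kmer_codes.
// [[Rcpp::export(name = ".cpp_distance_matrix_codes")]]
NumericMatrix cpp_distance_matrix_codes(List profiles, std::string metric) {
    int n = profiles.size();
    std::vector<std::vector<uint64_t>> codes(n);
    std::vector<std::vector<double>> vals(n);
    std::vector<double> totals(n, 0.0);
    for (int i = 0; i < n; ++i) {
        List p = profiles[i];
        NumericVector pc = p["codes"], pv = p["counts"];
        codes[i].resize(pc.size());
        vals[i].resize(pv.size());
        for (R_xlen_t j = 0; j < pc.size(); ++j) {
            codes[i][j] = (uint64_t)pc[j];
            vals[i][j] = pv[j];
            totals[i] += pv[j];
        }
    }
    NumericMatrix out(n, n);
    bool bc = (metric == "bray_curtis");
    for (int i = 0; i < n; ++i) {
        for (int j = i + 1; j < n; ++j) {
            double smin, smax, d;
            pair_sums(codes[i], vals[i], codes[j], vals[j], smin, smax);
            if (bc) {
                double tot = totals[i] + totals[j];
                d = (tot > 0.0) ? 1.0 - 2.0 * smin / tot : 0.0;
            } else {
                d = (smax > 0.0) ? 1.0 - smin / smax : 0.0;
            }
            out(i, j) = d;
            out(j, i) = d;
        }
    }
    return out;
}

// Draw reads from a pool of genomes. Uses R's RNG so results are
// reproducible under set.seed(). probs must sum to 1 (selection is by
// inverse CDF); substitution errors are uniform over the 3 other bases.
// [[Rcpp::export(name = ".cpp_simulate_reads")]]
List cpp_simulate_reads(CharacterVector genomes, NumericVector probs,
                        int n_reads, int read_len, double error_rate) {
    int ng = genomes.size();
    std::vector<std::string> gs(ng);
    for (int i = 0; i < ng; ++i) gs[i] = as<std::string>(genomes[i]);
    for (int i = 0; i < ng; ++i)
        if ((int)gs[i].size() < read_len)
            stop("read_length exceeds the length of genome %d", i + 1);
    std::vector<double> cum(ng);
    double acc = 0.0;
    for (int i = 0; i < ng; ++i) { acc += probs[i]; cum[i] = acc; }

    CharacterVector reads(n_reads);
    IntegerVector origin(n_reads), start(n_reads);
    LogicalVector fwd(n_reads);
    std::string buf;
    for (int r = 0; r < n_reads; ++r) {
        double u = unif_rand() * acc;
        int g = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
        if (g >= ng) g = ng - 1;
        const std::string& G = gs[g];
        int maxs = (int)G.size() - read_len;
        int s = (int)(unif_rand() * (maxs + 1));
        if (s > maxs) s = maxs;
        bool forward = unif_rand() < 0.5;
        buf.assign(G, s, read_len);
        if (!forward) {
            std::reverse(buf.begin(), buf.end());
            for (char& c : buf) {
                switch (c) {
                case 'A': c = 'T'; break; case 'T': c = 'A'; break;
                case 'C': c = 'G'; break; case 'G': c = 'C'; break;
                default: break;
                }
            }
        }
        if (error_rate > 0.0) {
            for (int p = 0; p < read_len; ++p) {
                if (unif_rand() < error_rate) {
                    int cur = base_code(buf[p]);
                    if (cur < 0) continue;
                    int sub = (int)(unif_rand() * 3.0);
                    if (sub > 2) sub = 2;
                    buf[p] = DECODE[(cur + 1 + sub) & 3];
                }
            }
        }
        reads[r] = buf;
        origin[r] = g + 1;
        start[r] = s;
        fwd[r] = forward;
    }
    return List::create(_["reads"] = reads, _["origin"] = origin,
                        _["start"] = start, _["forward"] = fwd);
}

// Substitute each base with probability `rate` (uniform over the other 3
// bases); returns the mutated sequences and realized substitution counts.
// [[Rcpp::export(name = ".cpp_mutate_sequences")]]
List cpp_mutate_sequences(CharacterVector seqs, double rate) {
    R_xlen_t n = seqs.size();
    CharacterVector out(n);
    IntegerVector nsub(n);
    for (R_xlen_t i = 0; i < n; ++i) {
        std::string s = as<std::string>(seqs[i]);
        int m = 0;
        if (rate > 0.0) {
            for (size_t p = 0; p < s.size(); ++p) {
                if (unif_rand() < rate) {
                    int cur = base_code(s[p]);
                    if (cur < 0) continue;
                    int sub = (int)(unif_rand() * 3.0);
                    if (sub > 2) sub = 2;
                    s[p] = DECODE[(cur + 1 + sub) & 3];
                    ++m;
                }
            }
        }
        out[i] = s;
        nsub[i] = m;
    }
    return List::create(_["seq"] = out, _["n_substitutions"] = nsub);
}

// Per-window containment: tile each query sequence into non-overlapping
// full windows and report, per window, the fraction of its canonical
// k-mers found in the reference k-mer set.
// [[Rcpp::export(name = ".cpp_window_containment")]]
NumericVector cpp_window_containment(CharacterVector query,
                                     CharacterVector reference,
                                     int window, int k) {
    size_t ref_len = 0;
    for (R_xlen_t i = 0; i < reference.size(); ++i)
        ref_len += (size_t)LENGTH(STRING_ELT(reference, i));
    FlatCounter ref(ref_len / 2 + 16);
    for (R_xlen_t i = 0; i < reference.size(); ++i) {
        const char* s = CHAR(STRING_ELT(reference, i));
        scan_sequence(s, LENGTH(STRING_ELT(reference, i)), k, ref);
    }
    std::vector<double> js;
    for (R_xlen_t i = 0; i < query.size(); ++i) {
        const char* s = CHAR(STRING_ELT(query, i));
        int len = LENGTH(STRING_ELT(query, i));
        int nwin = len / window;
        for (int w = 0; w < nwin; ++w) {
            FlatCounter wcounts((size_t)window);
            scan_sequence(s + (size_t)w * window, window, k, wcounts);
            if (wcounts.used == 0) { js.push_back(0.0); continue; }
            size_t hit = 0;
            wcounts.for_each([&](uint64_t key, double) {
                if (ref.contains(key)) ++hit;
            });
            js.push_back((double)hit / (double)wcounts.used);
        }
    }
    return NumericVector(js.begin(), js.end());
}
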