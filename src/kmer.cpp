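#include <Rcpp.h>
#include <string>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cctype>

using namespace Rcpp;

static inline char complement(char c) {
    switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return 'N';
    }
}

// lexicographically smaller of kmer and its reverse complement
static std::string canonical(const std::string& kmer) {
    const size_t k = kmer.size();
    std::string rc(k, 'N');
    for (size_t i = 0; i < k; ++i) rc[k - 1 - i] = complement(kmer[i]);
    return (rc < kmer) ? rc : kmer;
}

// Count canonical k-mers over a set of reads. Windows containing a
// non-ACGT symbol are skipped; reads shorter than k contribute nothing.
// Returns a list with sorted frequencies and the number of distinct
// canonical k-mers observed at each frequency.
// [[Rcpp::export]]
List count_canonical_kmers_cpp(CharacterVector reads, int k) {
    if (k < 1) stop("k must be >= 1");
    std::unordered_map<std::string, long long> counts;

    for (R_xlen_t r = 0; r < reads.size(); ++r) {
        std::string s = as<std::string>(reads[r]);
        const int n = (int) s.size();
        if (n < k) continue;
        for (int i = 0; i < n; ++i) s[i] = (char) std::toupper((unsigned char) s[i]);
        int last_bad = -1; // most recent index holding a non-ACGT symbol
        for (int i = 0; i < n; ++i) {
            const char c = s[i];
            if (c != 'A' && c != 'C' && c != 'G' && c != 'T') last_bad = i;
            if (i >= k - 1 && last_bad <= i - k) {
                ++counts[canonical(s.substr(i - k + 1, k))];
            }
        }
    }

    std::unordered_map<long long, long long> hist;
    for (const auto& kv : counts) ++hist[kv.second];

    std::vector<long long> freqs;
    freqs.reserve(hist.size());
    for (const auto& kv : hist) freqs.push_back(kv.first);
    std::sort(freqs.begin(), freqs.end());

    NumericVector f(freqs.size()), cnt(freqs.size());
    for (size_t i = 0; i < freqs.size(); ++i) {
        f[i] = (double) freqs[i];
        cnt[i] = (double) hist[freqs[i]];
    }
    return List::create(_["frequency"] = f, _["count"] = cnt);
}

// Per-read base tallies used by compute_read_stats(): length, #G+#C and
// #A+#C+#G+#T (ambiguous symbols count toward length only).
// [[Rcpp::export]]
List read_base_tallies_cpp(CharacterVector reads) {
    const R_xlen_t n = reads.size();
    NumericVector len(n), gc(n), acgt(n);
    for (R_xlen_t r = 0; r < n; ++r) {
        const char* s = CHAR(STRING_ELT(reads, r));
        double L = 0, g = 0, a = 0;
        for (const char* p = s; *p; ++p) {
            ++L;
            const char c = (char) std::toupper((unsigned char) *p);
            if (c == 'G' || c == 'C') { ++g; ++a; }
            else if (c == 'A' || c == 'T') ++a;
        }
        len[r] = L; gc[r] = g; acgt[r] = a;
    }
    return List::create(_["length"] = len, _["gc"] = gc, _["acgt"] = acgt);
}
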