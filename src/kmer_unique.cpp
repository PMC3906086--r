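#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Exact k-mer uniqueness flags over a genome, counting occurrences of each
// k-mer together with its reverse complement (both-strand counting).
// k-mers are 2-bit packed into a 128-bit word, so k <= 64 is exact with no
// hashing approximation. Positions whose k-mer contains N are never unique,
// and a palindromic k-mer (equal to its own reverse complement) hits its own
// site on both strands, hence is never unique either.

typedef unsigned __int128 u128;

struct U128Hash {
    std::size_t operator()(const u128 &x) const {
        const std::uint64_t lo = (std::uint64_t)x;
        const std::uint64_t hi = (std::uint64_t)(x >> 64);
        std::uint64_t h = lo ^ (hi * 0x9e3779b97f4a7c15ULL);
        h ^= h >> 33; h *= 0xff51afd7ed558ccdULL; h ^= h >> 33;
        return (std::size_t)h;
    }
};

static inline int base_code(char c) {
    switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;  // N or anything else
    }
}

// [[Rcpp::export(name = ".kmerUniqueFlags")]]
List kmerUniqueFlags(CharacterVector seqs, int k) {
    if (k < 1 || k > 64)
        stop("k must be between 1 and 64");
    const int nchrom = seqs.size();
    const u128 mask = (k == 64) ? ~(u128)0 >> 0 // 2k = 128 bits
                                : (((u128)1) << (2 * k)) - 1;
    const int shift_rc = 2 * (k - 1);

    std::unordered_map<u128, std::uint32_t, U128Hash> counts;
    {   // reserve roughly the number of k-mer positions
        std::size_t total = 0;
        for (int c = 0; c < nchrom; ++c) {
            R_xlen_t L = LENGTH(STRING_ELT(seqs, c));
            if (L >= k) total += (std::size_t)(L - k + 1);
        }
        counts.reserve(total);
    }

    // pass 1: count canonical k-mers genome-wide
    for (int c = 0; c < nchrom; ++c) {
        const char *s = CHAR(STRING_ELT(seqs, c));
        const R_xlen_t L = LENGTH(STRING_ELT(seqs, c));
        if (L < k) continue;
        u128 fwd = 0, rc = 0;
        R_xlen_t run = 0;  // length of current N-free suffix
        for (R_xlen_t i = 0; i < L; ++i) {
            int code = base_code(s[i]);
            if (code < 0) { run = 0; fwd = 0; rc = 0; continue; }
            fwd = ((fwd << 2) | (u128)code) & mask;
            rc = (rc >> 2) | ((u128)(3 - code) << shift_rc);
            if (++run >= k) {
                u128 canon = fwd < rc ? fwd : rc;
                ++counts[canon];
            }
        }
    }

    // pass 2: a position is unique iff its canonical k-mer was seen once
    // and the k-mer is not its own reverse complement
    List out(nchrom);
    for (int c = 0; c < nchrom; ++c) {
        const char *s = CHAR(STRING_ELT(seqs, c));
        const R_xlen_t L = LENGTH(STRING_ELT(seqs, c));
        const R_xlen_t npos = (L >= k) ? L - k + 1 : 0;
        LogicalVector flags(npos, FALSE);
        if (npos > 0) {
            u128 fwd = 0, rc = 0;
            R_xlen_t run = 0;
            for (R_xlen_t i = 0; i < L; ++i) {
                int code = base_code(s[i]);
                if (code < 0) { run = 0; fwd = 0; rc = 0; continue; }
                fwd = ((fwd << 2) | (u128)code) & mask;
                rc = (rc >> 2) | ((u128)(3 - code) << shift_rc);
                if (++run >= k) {
                    if (fwd != rc) {
                        u128 canon = fwd < rc ? fwd : rc;
                        if (counts[canon] == 1) flags[i - k + 1] = TRUE;
                    }
                }
            }
        }
        out[c] = flags;
    }
    out.attr("names") = seqs.attr("names");
    return out;
}
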