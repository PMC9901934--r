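#include <Rcpp.h>
using namespace Rcpp;

// Sliding-window variant calling: slide a window of reference length L
// over each read, count mismatches at every offset, and keep the offset
// with the fewest mismatches (ties broken by the smallest offset). Reads
// whose best window still exceeds max_report mismatches get no genotype.
//
// Returns, per read:
//   offset   : 0-based count of bases 5' of the best window (-1 if the
//              read is shorter than L)
//   mismatch : mismatch count of the best window (NA if offset is -1)
//   genotype : "pos:alt[,pos:alt]" (0-based) or "WT"; empty string when
//              mismatch > max_report
// [[Rcpp::export]]
List cpp_call_variants(CharacterVector reads, std::string ref,
                       int max_report) {
    const int n = reads.size();
    const int L = ref.size();
    IntegerVector offset(n), mismatch(n);
    CharacterVector genotype(n);

    for (int r = 0; r < n; ++r) {
        const char *s = CHAR(STRING_ELT(reads, r));
        int len = LENGTH(STRING_ELT(reads, r));
        if (len < L) {
            offset[r] = -1;
            mismatch[r] = NA_INTEGER;
            genotype[r] = "";
            continue;
        }
        int best = L + 1, best_off = 0;
        for (int off = 0; off + L <= len; ++off) {
            int cnt = 0;
            for (int i = 0; i < L; ++i) {
                if (s[off + i] != ref[i] && ++cnt >= best) break;
            }
            if (cnt < best) {  // strict: first offset wins ties
                best = cnt;
                best_off = off;
                if (best == 0) break;
            }
        }
        offset[r] = best_off;
        mismatch[r] = best;
        if (best == 0) {
            genotype[r] = "WT";
        } else if (best <= max_report) {
            std::string g;
            char buf[16];
            for (int i = 0; i < L; ++i) {
                if (s[best_off + i] != ref[i]) {
                    snprintf(buf, sizeof(buf), "%d:%c", i, s[best_off + i]);
                    if (!g.empty()) g += ",";
                    g += buf;
                }
            }
            genotype[r] = g;
        } else {
            genotype[r] = "";
        }
    }
    return List::create(_["offset"] = offset,
                        _["mismatch"] = mismatch,
                        _["genotype"] = genotype);
}
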