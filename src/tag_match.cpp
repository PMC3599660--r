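#include <Rcpp.h>
using namespace Rcpp;

// Best 3' adapter start for each read: maximize overlap, then minimize
// mismatches, then leftmost. A match must span >= min_overlap bases of the
// adapter (the adapter may run off the read end) with a mismatch count
// <= floor(max_rate * overlap). Returns the 0-based insert length (adapter
// start position), or -1 when no acceptable match exists.
// [[Rcpp::export]]
IntegerVector trim_adapter_pos(CharacterVector reads, std::string adapter,
                               int min_overlap, double max_rate) {
    const int n = reads.size();
    const int la = (int) adapter.size();
    IntegerVector out(n);
    for (int i = 0; i < n; ++i) {
        SEXP s = STRING_ELT(reads, i);
        const char *r = CHAR(s);
        const int L = (int) LENGTH(s);
        int bestP = -1, bestO = -1, bestM = INT_MAX;
        for (int p = 0; p + min_overlap <= L; ++p) {
            const int o = std::min(la, L - p);
            const int allowed = (int) std::floor(max_rate * o + 1e-9);
            int m = 0;
            bool ok = true;
            for (int j = 0; j < o; ++j) {
                if (r[p + j] != adapter[j] && ++m > allowed) { ok = false; break; }
            }
            if (!ok) continue;
            if (o > bestO || (o == bestO && m < bestM)) {
                bestO = o; bestM = m; bestP = p;
            }
        }
        out[i] = bestP;
    }
    return out;
}

// Best hit of each tag against a set of reference sequences, allowing
// ungapped alignments at start offsets in [-max_shift, max_shift] (offset =
// tag start minus reference start). A hit needs overlap >=
// min(len(tag), len(ref)) - max_shift and <= max_sub mismatches on the
// overlap. Ties: fewer mismatches, then smaller |offset|, then negative
// offset, then earlier reference. Returns an n x 3 matrix
// (ref index 1-based or 0 for none, mismatches, offset).
// [[Rcpp::export]]
IntegerMatrix match_tags_best(CharacterVector tags, CharacterVector refs,
                              int max_sub, int max_shift) {
    const int n = tags.size(), nr = refs.size();
    IntegerMatrix out(n, 3);
    for (int i = 0; i < n; ++i) {
        SEXP ts = STRING_ELT(tags, i);
        const char *t = CHAR(ts);
        const int lt = (int) LENGTH(ts);
        int bref = 0, bm = INT_MAX, boff = 0;
        for (int k = 0; k < nr; ++k) {
            SEXP rs = STRING_ELT(refs, k);
            const char *r = CHAR(rs);
            const int lr = (int) LENGTH(rs);
            const int need = std::min(lt, lr) - max_shift;
            for (int s = -max_shift; s <= max_shift; ++s) {
                const int i0 = std::max(0, -s);
                const int iend = std::min(lt, lr - s);
                const int ov = iend - i0;
                if (ov < need || ov <= 0) continue;
                int m = 0;
                bool ok = true;
                for (int j = i0; j < iend; ++j) {
                    if (t[j] != r[j + s] && ++m > max_sub) { ok = false; break; }
                }
                if (!ok) continue;
                const bool better =
                    bref == 0 ||
                    m < bm ||
                    (m == bm && (std::abs(s) < std::abs(boff) ||
                                 (std::abs(s) == std::abs(boff) && s < boff)));
                if (better) { bref = k + 1; bm = m; boff = s; }
            }
        }
        out(i, 0) = bref;
        out(i, 1) = (bref == 0) ? NA_INTEGER : bm;
        out(i, 2) = (bref == 0) ? NA_INTEGER : boff;
    }
    return out;
}

// Full-tag containment match: the whole tag must align inside a reference
// with <= max_mm mismatches (no indels). Returns an n x 2 matrix
// (ref index 1-based or 0, mismatches). Ties: fewer mismatches, then
// earlier reference, then leftmost position.
// [[Rcpp::export]]
IntegerMatrix contain_match_best(CharacterVector tags, CharacterVector refs,
                                 int max_mm) {
    const int n = tags.size(), nr = refs.size();
    IntegerMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        SEXP ts = STRING_ELT(tags, i);
        const char *t = CHAR(ts);
        const int lt = (int) LENGTH(ts);
        int bref = 0, bm = INT_MAX;
        for (int k = 0; k < nr && bm > 0; ++k) {
            SEXP rs = STRING_ELT(refs, k);
            const char *r = CHAR(rs);
            const int lr = (int) LENGTH(rs);
            for (int p = 0; p + lt <= lr; ++p) {
                int m = 0;
                bool ok = true;
                for (int j = 0; j < lt; ++j) {
                    if (t[j] != r[p + j] && ++m > max_mm) { ok = false; break; }
                }
                if (ok && m < bm) { bref = k + 1; bm = m; }
                if (bm == 0) break;
            }
        }
        out(i, 0) = bref;
        out(i, 1) = (bref == 0) ? NA_INTEGER : bm;
    }
    return out;
}
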