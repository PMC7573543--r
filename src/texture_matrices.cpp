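#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Gray-level matrices on a discretized ROI. Convention throughout:
// lv(r, c) in {0, 1..nbins}; 0 marks out-of-mask pixels and never
// participates in any pair, run, zone or neighbourhood.

// [[Rcpp::export(name = ".cppGlcm")]]
NumericMatrix cppGlcm(IntegerMatrix lv, int nbins, IntegerMatrix offsets) {
    int nr = lv.nrow(), nc = lv.ncol();
    NumericMatrix counts(nbins, nbins);
    for (int k = 0; k < offsets.nrow(); ++k) {
        int dr = offsets(k, 0), dc = offsets(k, 1);
        for (int r = 0; r < nr; ++r) {
            int r2 = r + dr;
            if (r2 < 0 || r2 >= nr) continue;
            for (int c = 0; c < nc; ++c) {
                int c2 = c + dc;
                if (c2 < 0 || c2 >= nc) continue;
                int a = lv(r, c), b = lv(r2, c2);
                if (a > 0 && b > 0) {
                    counts(a - 1, b - 1) += 1.0;  // symmetrized: count both orders
                    counts(b - 1, a - 1) += 1.0;
                }
            }
        }
    }
    return counts;
}

// Maximal same-level runs inside the mask, one matrix summed over directions.
// [[Rcpp::export(name = ".cppGlrlm")]]
NumericMatrix cppGlrlm(IntegerMatrix lv, int nbins, IntegerMatrix offsets) {
    int nr = lv.nrow(), nc = lv.ncol();
    int maxlen = std::max(nr, nc);
    NumericMatrix counts(nbins, maxlen);
    for (int k = 0; k < offsets.nrow(); ++k) {
        int dr = offsets(k, 0), dc = offsets(k, 1);
        for (int r = 0; r < nr; ++r) {
            for (int c = 0; c < nc; ++c) {
                int a = lv(r, c);
                if (a <= 0) continue;
                // run starts here iff the predecessor along (dr,dc) differs
                int rp = r - dr, cp = c - dc;
                if (rp >= 0 && rp < nr && cp >= 0 && cp < nc && lv(rp, cp) == a)
                    continue;
                int len = 1, r2 = r + dr, c2 = c + dc;
                while (r2 >= 0 && r2 < nr && c2 >= 0 && c2 < nc && lv(r2, c2) == a) {
                    ++len; r2 += dr; c2 += dc;
                }
                counts(a - 1, len - 1) += 1.0;
            }
        }
    }
    return counts;
}

// 8-connected zones of equal level; returns one (level, size) row per zone.
// [[Rcpp::export(name = ".cppGlszmZones")]]
IntegerMatrix cppGlszmZones(IntegerMatrix lv) {
    int nr = lv.nrow(), nc = lv.ncol();
    std::vector<bool> seen((size_t) nr * nc, false);
    std::vector<int> zlevel, zsize;
    std::vector<int> stack;
    for (int c0 = 0; c0 < nc; ++c0) {
        for (int r0 = 0; r0 < nr; ++r0) {
            int a = lv(r0, c0);
            size_t id0 = (size_t) c0 * nr + r0;
            if (a <= 0 || seen[id0]) continue;
            int size = 0;
            stack.clear();
            stack.push_back((int) id0);
            seen[id0] = true;
            while (!stack.empty()) {
                int id = stack.back(); stack.pop_back();
                int r = id % nr, c = id / nr;
                ++size;
                for (int dr = -1; dr <= 1; ++dr) {
                    for (int dc = -1; dc <= 1; ++dc) {
                        if (dr == 0 && dc == 0) continue;
                        int r2 = r + dr, c2 = c + dc;
                        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
                        size_t id2 = (size_t) c2 * nr + r2;
                        if (!seen[id2] && lv(r2, c2) == a) {
                            seen[id2] = true;
                            stack.push_back((int) id2);
                        }
                    }
                }
            }
            zlevel.push_back(a);
            zsize.push_back(size);
        }
    }
    IntegerMatrix out((int) zlevel.size(), 2);
    for (int i = 0; i < (int) zlevel.size(); ++i) {
        out(i, 0) = zlevel[i];
        out(i, 1) = zsize[i];
    }
    return out;
}

// Amadasun-King table with mask-restricted 3x3 neighbourhoods: n_i counts
// in-mask pixels of level i having >= 1 in-mask neighbour, s_i sums
// |i - mean(neighbours)| over those pixels.
// [[Rcpp::export(name = ".cppNgtdm")]]
List cppNgtdm(IntegerMatrix lv, int nbins) {
    int nr = lv.nrow(), nc = lv.ncol();
    NumericVector n(nbins), s(nbins);
    for (int r = 0; r < nr; ++r) {
        for (int c = 0; c < nc; ++c) {
            int a = lv(r, c);
            if (a <= 0) continue;
            double sum = 0.0; int cnt = 0;
            for (int dr = -1; dr <= 1; ++dr) {
                for (int dc = -1; dc <= 1; ++dc) {
                    if (dr == 0 && dc == 0) continue;
                    int r2 = r + dr, c2 = c + dc;
                    if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
                    int b = lv(r2, c2);
                    if (b > 0) { sum += b; ++cnt; }
                }
            }
            if (cnt > 0) {
                n[a - 1] += 1.0;
                s[a - 1] += std::abs((double) a - sum / cnt);
            }
        }
    }
    return List::create(_["n"] = n, _["s"] = s);
}
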