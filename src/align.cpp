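#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Gotoh three-state global alignment with affine gap costs:
// a gap run of length L costs gap_open + (L-1) * gap_extend.
// States: 0 = M (substitution column), 1 = X (gap in query row, reference
// base consumed), 2 = Y (gap in reference row, query base consumed).
// Ties are broken by state preference M > X > Y, both when choosing a
// cell's best predecessor and when choosing the final state, which yields
// the documented deterministic traceback (substitution over gap, then
// gap-in-query over gap-in-reference).

static const double NEG_INF = -1e30;

static inline int best3(double m, double x, double y, double &val) {
    // strict preference order M > X > Y on ties
    val = m; int s = 0;
    if (x > val) { val = x; s = 1; }
    if (y > val) { val = y; s = 2; }
    return s;
}

// [[Rcpp::export(name = "gotoh_align")]]
List gotoh_align(IntegerVector ref, IntegerVector query,
                 NumericMatrix sub, double gap_open, double gap_extend) {
    const int m = ref.size(), n = query.size();
    const size_t W = (size_t)n + 1;

    std::vector<uint8_t> tbM((size_t)(m + 1) * W), tbX((size_t)(m + 1) * W),
        tbY((size_t)(m + 1) * W);
    std::vector<double> M0(W), X0(W), Y0(W), M1(W), X1(W), Y1(W);

    M0[0] = 0.0; X0[0] = NEG_INF; Y0[0] = NEG_INF;
    for (int j = 1; j <= n; ++j) {
        M0[j] = NEG_INF; X0[j] = NEG_INF;
        Y0[j] = gap_open + (j - 1) * gap_extend;
        tbY[j] = (j == 1) ? 0 : 2;
    }

    for (int i = 1; i <= m; ++i) {
        M1[0] = NEG_INF; Y1[0] = NEG_INF;
        X1[0] = gap_open + (i - 1) * gap_extend;
        tbX[(size_t)i * W] = (i == 1) ? 0 : 1;
        const int ri = ref[i - 1] - 1;  // 1-based codes from R
        for (int j = 1; j <= n; ++j) {
            double v;
            // M: consume ref[i], query[j]
            int s = best3(M0[j - 1], X0[j - 1], Y0[j - 1], v);
            M1[j] = v + sub(ri, query[j - 1] - 1);
            tbM[(size_t)i * W + j] = (uint8_t)s;
            // X: consume ref[i], gap in query row
            s = best3(M0[j] + gap_open, X0[j] + gap_extend,
                      Y0[j] + gap_open, v);
            X1[j] = v;
            tbX[(size_t)i * W + j] = (uint8_t)s;
            // Y: consume query[j], gap in reference row
            s = best3(M1[j - 1] + gap_open, X1[j - 1] + gap_open,
                      Y1[j - 1] + gap_extend, v);
            Y1[j] = v;
            tbY[(size_t)i * W + j] = (uint8_t)s;
        }
        std::swap(M0, M1); std::swap(X0, X1); std::swap(Y0, Y1);
    }

    double score;
    int state = best3(M0[n], X0[n], Y0[n], score);

    // traceback
    std::vector<int> rpath, qpath;
    rpath.reserve(m + n); qpath.reserve(m + n);
    int i = m, j = n;
    while (i > 0 || j > 0) {
        if (state == 0) {
            uint8_t prev = tbM[(size_t)i * W + j];
            rpath.push_back(ref[i - 1]); qpath.push_back(query[j - 1]);
            --i; --j; state = prev;
        } else if (state == 1) {
            uint8_t prev = tbX[(size_t)i * W + j];
            rpath.push_back(ref[i - 1]); qpath.push_back(0);
            --i; state = prev;
        } else {
            uint8_t prev = tbY[(size_t)i * W + j];
            rpath.push_back(0); qpath.push_back(query[j - 1]);
            --j; state = prev;
        }
    }
    std::reverse(rpath.begin(), rpath.end());
    std::reverse(qpath.begin(), qpath.end());

    return List::create(_["score"] = score,
                        _["ref_path"] = IntegerVector(rpath.begin(), rpath.end()),
                        _["query_path"] = IntegerVector(qpath.begin(), qpath.end()));
}
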