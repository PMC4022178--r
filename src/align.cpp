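#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh three-state recursion) with a fixed,
// fully deterministic traceback. A gap of length k costs gap_open + k *
// gap_extend (the first gapped residue pays both open and extend, matching
// the BLAST convention for "existence 11, extension 1").
//
// States: M = a_i aligned to b_j; X = a_i against a gap (vertical move,
// consuming a); Y = b_j against a gap (horizontal move, consuming b).
// All ties are broken with priority M > X > Y, and in local mode an
// extension is preferred over restarting the alignment, so outputs are
// bit-reproducible across platforms.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

enum Ptr : unsigned char { FROM_M = 0, FROM_X = 1, FROM_Y = 2, FROM_START = 3 };

static inline int best3(double m, double x, double y, double& out) {
    // tie priority M > X > Y
    out = m;
    int who = FROM_M;
    if (x > out) { out = x; who = FROM_X; }
    if (y > out) { out = y; who = FROM_Y; }
    return who;
}

// a, b: 1-based residue codes (1..n_alpha); sub: n_alpha x n_alpha scores;
// x_code: code of the ambiguity residue X (0 if absent) — X never counts as
// a match. Returns alignment bookkeeping; coverage is derived in R.
// [[Rcpp::export(name = ".align_pair_cpp")]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix sub,
                    double gap_open, double gap_extend, bool local,
                    int x_code) {
    const int n = a.size(), m = b.size();
    if (n < 1 || m < 1) stop("sequences must be non-empty");
    const int W = m + 1;
    const double go = gap_open, ge = gap_extend;

    std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
        Y((n + 1) * W, NEG_INF);
    std::vector<unsigned char> pM((n + 1) * W, FROM_START),
        pX((n + 1) * W, FROM_START), pY((n + 1) * W, FROM_START);

#define IDX(i, j) ((i) * W + (j))

    if (!local) {
        M[IDX(0, 0)] = 0.0;
        for (int i = 1; i <= n; ++i) {
            X[IDX(i, 0)] = -(go + i * ge);
            pX[IDX(i, 0)] = (i == 1) ? FROM_M : FROM_X;
        }
        for (int j = 1; j <= m; ++j) {
            Y[IDX(0, j)] = -(go + j * ge);
            pY[IDX(0, j)] = (j == 1) ? FROM_M : FROM_Y;
        }
    }

    for (int i = 1; i <= n; ++i) {
        const int ai = a[i - 1] - 1;
        for (int j = 1; j <= m; ++j) {
            const int bj = b[j - 1] - 1;
            const double s = sub(ai, bj);
            double best;
            int who = best3(M[IDX(i - 1, j - 1)], X[IDX(i - 1, j - 1)],
                            Y[IDX(i - 1, j - 1)], best);
            if (local) {
                // prefer extending (M > X > Y) over restarting
                if (best < 0.0) { best = 0.0; who = FROM_START; }
            }
            if (best > NEG_INF) {
                M[IDX(i, j)] = s + best;
                pM[IDX(i, j)] = (unsigned char) who;
            }

            who = best3(M[IDX(i - 1, j)] - (go + ge),
                        X[IDX(i - 1, j)] - ge,
                        Y[IDX(i - 1, j)] - (go + ge), best);
            if (best > NEG_INF) {
                X[IDX(i, j)] = best;
                pX[IDX(i, j)] = (unsigned char) who;
            }

            who = best3(M[IDX(i, j - 1)] - (go + ge),
                        X[IDX(i, j - 1)] - (go + ge),
                        Y[IDX(i, j - 1)] - ge, best);
            if (best > NEG_INF) {
                Y[IDX(i, j)] = best;
                pY[IDX(i, j)] = (unsigned char) who;
            }
        }
    }

    int ei, ej, state;
    double score;
    if (local) {
        // best M cell; ties -> smallest i, then smallest j
        score = 0.0;
        ei = ej = 0;
        state = FROM_M;
        for (int i = 1; i <= n; ++i)
            for (int j = 1; j <= m; ++j)
                if (M[IDX(i, j)] > score) { score = M[IDX(i, j)]; ei = i; ej = j; }
        if (score <= 0.0) {
            return List::create(
                _["score"] = 0.0, _["n_matches"] = 0, _["n_columns"] = 0,
                _["n_respair"] = 0, _["aligned_len_a"] = 0,
                _["aligned_len_b"] = 0, _["start_a"] = 0, _["end_a"] = 0,
                _["start_b"] = 0, _["end_b"] = 0);
        }
    } else {
        ei = n; ej = m;
        state = best3(M[IDX(n, m)], X[IDX(n, m)], Y[IDX(n, m)], score);
    }

    // traceback
    int i = ei, j = ej;
    long n_matches = 0, n_columns = 0, n_respair = 0, len_a = 0, len_b = 0;
    while (true) {
        if (local && state == FROM_M && i == 0) break;  // unreachable guard
        unsigned char prev;
        if (state == FROM_M) {
            prev = pM[IDX(i, j)];
            ++n_columns; ++n_respair; ++len_a; ++len_b;
            if (a[i - 1] == b[j - 1] && a[i - 1] != x_code) ++n_matches;
            --i; --j;
            if (local && prev == FROM_START) break;
        } else if (state == FROM_X) {
            prev = pX[IDX(i, j)];
            ++n_columns; ++len_a;
            --i;
        } else {
            prev = pY[IDX(i, j)];
            ++n_columns; ++len_b;
            --j;
        }
        state = prev;
        if (!local && i == 0 && j == 0) break;
    }

    const int start_a = local ? (i + 1) : 1;
    const int start_b = local ? (j + 1) : 1;
    return List::create(
        _["score"] = score, _["n_matches"] = (double) n_matches,
        _["n_columns"] = (double) n_columns, _["n_respair"] = (double) n_respair,
        _["aligned_len_a"] = (double) len_a, _["aligned_len_b"] = (double) len_b,
        _["start_a"] = start_a, _["end_a"] = local ? ei : n,
        _["start_b"] = start_b, _["end_b"] = local ? ej : m);
#undef IDX
}
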