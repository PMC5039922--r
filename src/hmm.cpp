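#include <Rcpp.h>
using namespace Rcpp;

// States: 0 = N (balanced), 1 = A1 (haplotype 1 in excess), 2 = A2.
// z: concordance indicator per marker, coded 1 / 0 / -1 (missing).
// A missing marker is uninformative: emission 1 in every state.
static inline double emit(int s, int z, double g) {
    if (z < 0) return 1.0;
    if (s == 0) return 0.5;
    if (s == 1) return (z == 1) ? g : 1.0 - g;
    return (z == 0) ? g : 1.0 - g;
}

// Scaled forward-backward over independent runs (chromosomes). Each run is
// initialised at `init` (the stationary distribution). Returns per-marker
// state posteriors, the observed-data log-likelihood, and the Baum-Welch
// sufficient statistics for the concordance emission probability gamma:
//   gamma_num = sum_t P(A1|z)1{z_t=1} + P(A2|z)1{z_t=0}
//   gamma_den = sum_t P(A1|z) + P(A2|z)      (non-missing t only)
// [[Rcpp::export]]
List hmm_forward_backward_cpp(IntegerVector z, IntegerVector run_id,
                              NumericMatrix trans, NumericVector init,
                              double gamma) {
    const int n = z.size();
    NumericMatrix alpha(n, 3), post(n, 3);
    NumericVector scale(n);
    double loglik = 0.0;

    for (int t = 0; t < n; ++t) {
        const bool newrun = (t == 0) || (run_id[t] != run_id[t - 1]);
        double c = 0.0;
        for (int s = 0; s < 3; ++s) {
            double pred = newrun
                ? init[s]
                : trans(0, s) * alpha(t - 1, 0) +
                  trans(1, s) * alpha(t - 1, 1) +
                  trans(2, s) * alpha(t - 1, 2);
            double v = pred * emit(s, z[t], gamma);
            alpha(t, s) = v;
            c += v;
        }
        for (int s = 0; s < 3; ++s) alpha(t, s) /= c;
        scale[t] = c;
        loglik += std::log(c);
    }

    std::vector<double> beta(3, 1.0), betn(3);
    double gnum = 0.0, gden = 0.0;
    for (int t = n - 1; t >= 0; --t) {
        if (t == n - 1 || run_id[t + 1] != run_id[t])
            beta[0] = beta[1] = beta[2] = 1.0;
        double tot = 0.0;
        for (int s = 0; s < 3; ++s) {
            double v = alpha(t, s) * beta[s];
            post(t, s) = v;
            tot += v;
        }
        for (int s = 0; s < 3; ++s) post(t, s) /= tot;
        if (z[t] >= 0) {
            if (z[t] == 1) gnum += post(t, 1); else gnum += post(t, 2);
            gden += post(t, 1) + post(t, 2);
        }
        if (t > 0 && run_id[t - 1] == run_id[t]) {
            for (int s = 0; s < 3; ++s) {
                double v = 0.0;
                for (int s2 = 0; s2 < 3; ++s2)
                    v += trans(s, s2) * emit(s2, z[t], gamma) * beta[s2];
                betn[s] = v / scale[t];
            }
            beta = betn;
        }
    }

    return List::create(_["posterior"] = post, _["loglik"] = loglik,
                        _["gamma_num"] = gnum, _["gamma_den"] = gden);
}

// Viterbi over independent runs; ties broken toward the lowest state index,
// i.e. toward N (conservative calling). Returns 0-based state codes.
// [[Rcpp::export]]
IntegerVector hmm_viterbi_cpp(IntegerVector z, IntegerVector run_id,
                              NumericMatrix trans, NumericVector init,
                              double gamma) {
    const int n = z.size();
    NumericMatrix d(n, 3);
    IntegerMatrix bp(n, 3);
    IntegerVector path(n);
    double lt[3][3], li[3];
    for (int i = 0; i < 3; ++i) {
        li[i] = std::log(init[i]);
        for (int j = 0; j < 3; ++j) lt[i][j] = std::log(trans(i, j));
    }

    for (int t = 0; t < n; ++t) {
        const bool newrun = (t == 0) || (run_id[t] != run_id[t - 1]);
        for (int s = 0; s < 3; ++s) {
            double le = std::log(emit(s, z[t], gamma));
            if (newrun) {
                d(t, s) = li[s] + le;
                bp(t, s) = -1;
            } else {
                int best = 0;
                double bv = d(t - 1, 0) + lt[0][s];
                for (int sp = 1; sp < 3; ++sp) {
                    double v = d(t - 1, sp) + lt[sp][s];
                    if (v > bv) { bv = v; best = sp; }
                }
                d(t, s) = bv + le;
                bp(t, s) = best;
            }
        }
    }

    int t = n - 1;
    while (t >= 0) {
        int end = t;  // last index of this run
        int best = 0;
        for (int s = 1; s < 3; ++s)
            if (d(end, s) > d(end, best)) best = s;
        path[end] = best;
        int u = end;
        while (bp(u, path[u]) >= 0) {
            path[u - 1] = bp(u, path[u]);
            --u;
        }
        t = u - 1;
    }
    return path;
}
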