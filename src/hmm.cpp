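#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-state HMM recursions over one chromosome/strand track.
// State 0 = non-transcribed (N), state 1 = transcribed (T).
// All inputs are natural-log probabilities; emissions are pre-computed
// per window.  Log-densities are expected to be floored upstream (no -Inf).

static const double NEG_FLOOR = -1e12;

static inline double lse2(double a, double b) {
    if (a < b) { double t = a; a = b; b = t; }
    if (b <= NEG_FLOOR) return a;
    return a + log1p(exp(b - a));
}

// Forward-backward pass.
// ln_* : log transition probabilities (nn = N->N, nt = N->T, tn = T->N, tt = T->T)
// li0, li1: log initial probabilities for N and T.
// Returns total log-likelihood, per-window posterior P(T), and the expected
// counts needed by the Baum-Welch M-step for the N->T transition:
//   exp_nt = E[# transitions N->T], exp_n = E[# windows in N, excluding the last].
// [[Rcpp::export(name = ".fb2_cpp")]]
List fb2_cpp(NumericVector le0, NumericVector le1,
             double lnn, double lnt, double ltn, double ltt,
             double li0, double li1) {
    const int L = le0.size();
    if (L == 0) stop("empty observation sequence");
    NumericVector a0(L), a1(L), b0(L), b1(L), post1(L);

    a0[0] = li0 + le0[0];
    a1[0] = li1 + le1[0];
    for (int t = 1; t < L; ++t) {
        a0[t] = lse2(a0[t - 1] + lnn, a1[t - 1] + ltn) + le0[t];
        a1[t] = lse2(a0[t - 1] + lnt, a1[t - 1] + ltt) + le1[t];
    }
    const double ll = lse2(a0[L - 1], a1[L - 1]);

    b0[L - 1] = 0.0;
    b1[L - 1] = 0.0;
    for (int t = L - 2; t >= 0; --t) {
        b0[t] = lse2(lnn + le0[t + 1] + b0[t + 1], lnt + le1[t + 1] + b1[t + 1]);
        b1[t] = lse2(ltn + le0[t + 1] + b0[t + 1], ltt + le1[t + 1] + b1[t + 1]);
    }

    double exp_nt = 0.0, exp_n = 0.0;
    for (int t = 0; t < L; ++t) {
        post1[t] = exp(a1[t] + b1[t] - ll);
        if (post1[t] > 1.0) post1[t] = 1.0;
        if (t < L - 1) {
            double g0 = exp(a0[t] + b0[t] - ll);
            if (g0 > 1.0) g0 = 1.0;
            exp_n += g0;
            exp_nt += exp(a0[t] + lnt + le1[t + 1] + b1[t + 1] - ll);
        }
    }
    return List::create(_["loglik"] = ll, _["post1"] = post1,
                        _["exp_nt"] = exp_nt, _["exp_n"] = exp_n);
}

// Viterbi decoding.  Ties are broken in favour of the non-transcribed state,
// both when choosing a predecessor and when choosing the final state, so the
// decoder is deterministic and conservative.
// [[Rcpp::export(name = ".viterbi2_cpp")]]
List viterbi2_cpp(NumericVector le0, NumericVector le1,
                  double lnn, double lnt, double ltn, double ltt,
                  double li0, double li1) {
    const int L = le0.size();
    if (L == 0) stop("empty observation sequence");
    NumericVector d0(L), d1(L);
    IntegerVector p0(L), p1(L), path(L);

    d0[0] = li0 + le0[0];
    d1[0] = li1 + le1[0];
    for (int t = 1; t < L; ++t) {
        // into N: prefer predecessor N on ties (>=)
        double fromN = d0[t - 1] + lnn, fromT = d1[t - 1] + ltn;
        if (fromN >= fromT) { d0[t] = fromN + le0[t]; p0[t] = 0; }
        else                { d0[t] = fromT + le0[t]; p0[t] = 1; }
        // into T
        fromN = d0[t - 1] + lnt; fromT = d1[t - 1] + ltt;
        if (fromN >= fromT) { d1[t] = fromN + le1[t]; p1[t] = 0; }
        else                { d1[t] = fromT + le1[t]; p1[t] = 1; }
    }
    int s = (d0[L - 1] >= d1[L - 1]) ? 0 : 1;
    double logjoint = (s == 0) ? d0[L - 1] : d1[L - 1];
    path[L - 1] = s;
    for (int t = L - 1; t > 0; --t) {
        s = (s == 0) ? p0[t] : p1[t];
        path[t - 1] = s;
    }
    return List::create(_["path"] = path, _["log_joint"] = logjoint);
}
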