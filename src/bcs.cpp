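#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Mark bias-clustered substitutions among sorted SND positions.
//
// A substitution is a BCS iff it is weak-to-strong (ws) and lies inside at
// least one width-`w` interval containing >= min_subs SNDs of which a
// fraction >= min_frac are ws. This is evaluated over *all* integer window
// offsets, implemented by enumerating every distinct window content: the
// content of any window is a contiguous run i..j of the sorted positions,
// and run i..j is realisable iff an integer start s exists with
//   max(pos[j]-w+1, pos[i-1]+1) <= s <= min(pos[i], pos[j+1]-w).
// Enumerating realisable runs is therefore exactly equivalent to the
// exhaustive scan, at O(n * max-SNDs-per-window) cost.
static int bcs_core(const int* pos, const int* ws, int n,
                    int w, int min_subs, double min_frac,
                    char* out, int* win_start) {
    for (int i = 0; i < n; ++i) out[i] = 0;
    std::vector<int> cumws(n + 1, 0);
    for (int i = 0; i < n; ++i) cumws[i + 1] = cumws[i] + (ws[i] ? 1 : 0);
    for (int i = 0; i < n; ++i) {
        for (int j = i; j < n && pos[j] - pos[i] <= w - 1; ++j) {
            int cnt = j - i + 1;
            if (cnt < min_subs) continue;
            long lo = (long)pos[j] - w + 1;
            if (i > 0 && (long)pos[i - 1] + 1 > lo) lo = (long)pos[i - 1] + 1;
            long hi = (long)pos[i];
            if (j < n - 1 && (long)pos[j + 1] - w < hi) hi = (long)pos[j + 1] - w;
            if (lo > hi) continue;  // no window has exactly this content
            int wsc = cumws[j + 1] - cumws[i];
            if ((double)wsc + 1e-9 < min_frac * (double)cnt) continue;
            for (int k = i; k <= j; ++k) {
                if (ws[k] && !out[k]) {
                    out[k] = 1;
                    if (win_start) win_start[k] = (int)hi;
                }
            }
        }
    }
    int total = 0;
    for (int i = 0; i < n; ++i) total += out[i];
    return total;
}

// [[Rcpp::export]]
List bcs_flags_cpp(IntegerVector pos, LogicalVector ws, int window,
                   int min_subs, double min_ws_frac) {
    int n = pos.size();
    std::vector<char> out(n > 0 ? n : 1);
    IntegerVector win_start(n, NA_INTEGER);
    std::vector<int> wstart(n > 0 ? n : 1, NA_INTEGER);
    bcs_core(n ? &pos[0] : NULL, n ? LOGICAL(ws) : NULL, n,
             window, min_subs, min_ws_frac,
             out.data(), wstart.data());
    LogicalVector is_bcs(n);
    for (int i = 0; i < n; ++i) {
        is_bcs[i] = out[i] != 0;
        if (out[i]) win_start[i] = wstart[i];
    }
    return List::create(_["is_bcs"] = is_bcs, _["window_start"] = win_start);
}

// [[Rcpp::export]]
int bcs_count_cpp(IntegerVector pos, LogicalVector ws, int window,
                  int min_subs, double min_ws_frac) {
    int n = pos.size();
    std::vector<char> out(n > 0 ? n : 1);
    return bcs_core(n ? &pos[0] : NULL, n ? LOGICAL(ws) : NULL, n,
                    window, min_subs, min_ws_frac, out.data(), NULL);
}

// Mean BCS count over n_perm uniform permutations of the ws labels across
// the given positions (positions and the total ws count are preserved).
// Uses R's RNG so results are reproducible under set.seed().
// [[Rcpp::export]]
double expected_bcs_perm_cpp(IntegerVector pos, int n_ws, int window,
                             int min_subs, double min_ws_frac, int n_perm) {
    int n = pos.size();
    if (n == 0 || n_ws <= 0 || n_perm <= 0) return 0.0;
    if (n_ws > n) stop("more ws labels than positions");
    std::vector<int> ws(n), idx(n);
    std::vector<char> out(n);
    double total = 0.0;
    for (int r = 0; r < n_perm; ++r) {
        for (int i = 0; i < n; ++i) { idx[i] = i; ws[i] = 0; }
        for (int i = 0; i < n_ws; ++i) {  // partial Fisher-Yates draw
            int j = i + (int)(unif_rand() * (double)(n - i));
            if (j >= n) j = n - 1;
            std::swap(idx[i], idx[j]);
            ws[idx[i]] = 1;
        }
        total += bcs_core(&pos[0], ws.data(), n, window, min_subs,
                          min_ws_frac, out.data(), NULL);
    }
    return total / (double)n_perm;
}
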