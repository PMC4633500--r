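#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>

// Minimum-energy RNA secondary structure under a simplified nearest-
// neighbour model, all energies in tenths of kcal/mol (integer DP):
//   pair GC -30, AU -20, GU -10
//   stacking bonus -5 for each pair whose inward neighbour is also a pair
//   hairpin-loop occurrence +30 (>= 3 unpaired nt enclosed)
//   bulge / internal-loop occurrence +10 (unpaired span capped at MAXLOOP)
//   multiloop occurrence +10
//   exterior loop free
// Non-crossing structures only; canonical pairs (GC, AU, GU) only.

namespace {

const int INF = 100000000;
const int MAXLOOP = 30;     // max unpaired nt in a bulge/internal loop
const int MINHP = 3;        // min unpaired nt in a hairpin loop
const int E_PAIR_GC = -30, E_PAIR_AU = -20, E_PAIR_GU = -10;
const int E_STACK = -5, E_HAIRPIN = 30, E_INTERNAL = 10, E_MULTI = 10;

inline int base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
    }
}

inline int pair_energy(int a, int b) {
    if ((a == 2 && b == 1) || (a == 1 && b == 2)) return E_PAIR_GC;
    if ((a == 0 && b == 3) || (a == 3 && b == 0)) return E_PAIR_AU;
    if ((a == 2 && b == 3) || (a == 3 && b == 2)) return E_PAIR_GU;
    return INF;
}

struct FoldDP {
    int n;
    std::vector<int> code;
    std::vector<int> V, WM, WE;   // n*n flattened, row-major
    std::vector<int> pairtab;     // 0-based partner or -1

    int &v(int i, int j) { return V[i * n + j]; }
    int &wm(int i, int j) { return WM[i * n + j]; }
    int &we(int i, int j) { return WE[i * n + j]; }

    int wm_at(int i, int j) { return (i > j) ? INF : WM[i * n + j]; }

    explicit FoldDP(const std::string &seq) {
        n = (int)seq.size();
        code.resize(n);
        for (int i = 0; i < n; ++i) code[i] = base_code(seq[i]);
        V.assign((size_t)n * n, INF);
        WM.assign((size_t)n * n, INF);
        WE.assign((size_t)n * n, 0);
        pairtab.assign(n, -1);
        fill();
    }

    // energy of best structure on [i, j] with (i, j) paired; INF if impossible
    int compute_v(int i, int j) {
        int pe = pair_energy(code[i], code[j]);
        if (pe >= INF) return INF;
        if (j - i - 1 < MINHP) return INF;
        int best = E_HAIRPIN;                       // hairpin loop
        if (v(i + 1, j - 1) < INF)                  // stacked pair
            best = std::min(best, E_STACK + v(i + 1, j - 1));
        // bulge / internal loop enclosing inner pair (k, l)
        for (int k = i + 1; k <= j - 1; ++k) {
            int left = k - i - 1;
            if (left > MAXLOOP) break;
            for (int l = j - 1; l > k; --l) {
                int right = j - l - 1;
                if (left + right > MAXLOOP) break;
                if (left == 0 && right == 0) continue;  // that is a stack
                if (v(k, l) < INF)
                    best = std::min(best, E_INTERNAL + v(k, l));
            }
        }
        // multiloop: >= 2 branches inside
        for (int k = i + 1; k < j - 1; ++k) {
            int a = wm_at(i + 1, k), b = wm_at(k + 1, j - 1);
            if (a < INF && b < INF)
                best = std::min(best, E_MULTI + a + b);
        }
        return pe + best;
    }

    void fill() {
        for (int span = 1; span < n; ++span) {
            for (int i = 0; i + span < n; ++i) {
                int j = i + span;
                v(i, j) = compute_v(i, j);
                // WM: segment with >= 1 branch, unpaired positions free
                int m = v(i, j);
                m = std::min(m, wm_at(i + 1, j));
                m = std::min(m, wm_at(i, j - 1));
                for (int k = i; k < j; ++k) {
                    int a = wm_at(i, k), b = wm_at(k + 1, j);
                    if (a < INF && b < INF) m = std::min(m, a + b);
                }
                wm(i, j) = m;
            }
        }
        // exterior: WE[i][j] = best energy of region [i, j], empty allowed
        for (int i = n - 1; i >= 0; --i) {
            for (int j = i; j < n; ++j) {
                int best = (i + 1 <= j) ? we(i + 1, j) : 0;  // i unpaired
                for (int k = i + MINHP + 1; k <= j; ++k) {
                    if (v(i, k) >= INF) continue;
                    int rest = (k + 1 <= j) ? we(k + 1, j) : 0;
                    best = std::min(best, v(i, k) + rest);
                }
                we(i, j) = best;
            }
        }
    }

    void trace_ext(int i, int j) {
        while (i <= j) {
            int target = we(i, j);
            bool advanced = false;
            for (int k = i + MINHP + 1; k <= j; ++k) {
                if (v(i, k) >= INF) continue;
                int rest = (k + 1 <= j) ? we(k + 1, j) : 0;
                if (v(i, k) + rest == target) {
                    trace_v(i, k);
                    i = k + 1;
                    advanced = true;
                    break;
                }
            }
            if (!advanced) ++i;   // i unpaired
        }
    }

    void trace_v(int i, int j) {
        pairtab[i] = j;
        pairtab[j] = i;
        int pe = pair_energy(code[i], code[j]);
        int target = v(i, j) - pe;
        // canonical order: stack, internal (k asc, l desc), hairpin, multi
        if (j - i - 1 >= 2 && v(i + 1, j - 1) < INF &&
            E_STACK + v(i + 1, j - 1) == target) {
            trace_v(i + 1, j - 1);
            return;
        }
        for (int k = i + 1; k <= j - 1; ++k) {
            int left = k - i - 1;
            if (left > MAXLOOP) break;
            for (int l = j - 1; l > k; --l) {
                int right = j - l - 1;
                if (left + right > MAXLOOP) break;
                if (left == 0 && right == 0) continue;
                if (v(k, l) < INF && E_INTERNAL + v(k, l) == target) {
                    trace_v(k, l);
                    return;
                }
            }
        }
        if (target == E_HAIRPIN) return;   // hairpin loop, nothing inside
        for (int k = i + 1; k < j - 1; ++k) {
            int a = wm_at(i + 1, k), b = wm_at(k + 1, j - 1);
            if (a < INF && b < INF && E_MULTI + a + b == target) {
                trace_wm(i + 1, k);
                trace_wm(k + 1, j - 1);
                return;
            }
        }
        Rcpp::stop("fold traceback failed (V)");
    }

    void trace_wm(int i, int j) {
        int target = wm(i, j);
        if (v(i, j) < INF && v(i, j) == target) {
            trace_v(i, j);
            return;
        }
        if (i + 1 <= j && wm_at(i + 1, j) == target) {
            trace_wm(i + 1, j);
            return;
        }
        if (i <= j - 1 && wm_at(i, j - 1) == target) {
            trace_wm(i, j - 1);
            return;
        }
        for (int k = i; k < j; ++k) {
            int a = wm_at(i, k), b = wm_at(k + 1, j);
            if (a < INF && b < INF && a + b == target) {
                trace_wm(i, k);
                trace_wm(k + 1, j);
                return;
            }
        }
        Rcpp::stop("fold traceback failed (WM)");
    }
};

}  // namespace

// [[Rcpp::export(name = ".fold_rna_cpp")]]
Rcpp::List fold_rna_cpp(std::string seq) {
    int n = (int)seq.size();
    for (int i = 0; i < n; ++i)
        if (base_code(seq[i]) < 0)
            Rcpp::stop("invalid character in RNA sequence: '%c'", seq[i]);
    if (n == 0)
        return Rcpp::List::create(
            Rcpp::Named("dot_bracket") = "",
            Rcpp::Named("mfe") = 0.0,
            Rcpp::Named("pair_table") = Rcpp::IntegerVector(0));
    FoldDP dp(seq);
    int e = dp.we(0, n - 1);
    if (e < 0) dp.trace_ext(0, n - 1);   // empty structure if e == 0
    std::string db(n, '.');
    Rcpp::IntegerVector pt(n);
    for (int i = 0; i < n; ++i) {
        if (dp.pairtab[i] >= 0) db[i] = (dp.pairtab[i] > i) ? '(' : ')';
        pt[i] = dp.pairtab[i] + 1;   // 1-based, 0 = unpaired
    }
    return Rcpp::List::create(
        Rcpp::Named("dot_bracket") = db,
        Rcpp::Named("mfe") = (e >= INF ? 0 : e) / 10.0,
        Rcpp::Named("pair_table") = pt);
}
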