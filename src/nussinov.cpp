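#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Pair weights for the simplified stacking-free energy model:
// GC = 3, AU = 2, GU (wobble) = 1, everything else unpairable.
static int pairWeight(char a, char b) {
    if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 3;
    if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return 2;
    if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 1;
    return 0;
}

// Nussinov-style base-pair maximisation over non-crossing structures with a
// minimum hairpin loop of `minloop` unpaired bases. Decomposition: either j
// is unpaired, or j pairs with some k in [i, j - minloop - 1]. Returns the
// optimal total pair weight and a dot-bracket traceback.
// [[Rcpp::export(name = ".nussinovFold")]]
List nussinovFold(std::string seq, int minloop = 3) {
    int n = (int) seq.size();
    for (int i = 0; i < n; ++i) if (seq[i] == 'T') seq[i] = 'U';
    std::vector<std::vector<int> > E(n + 1, std::vector<int>(n + 1, 0));
    // E[i][j] over 0-based closed [i, j]
    for (int len = minloop + 2; len <= n; ++len) {
        for (int i = 0; i + len - 1 < n; ++i) {
            int j = i + len - 1;
            int best = E[i][j - 1];  // j unpaired
            for (int k = i; k <= j - minloop - 1; ++k) {
                int w = pairWeight(seq[k], seq[j]);
                if (w == 0) continue;
                int cand = w + (k > i ? E[i][k - 1] : 0) + E[k + 1][j - 1];
                if (cand > best) best = cand;
            }
            E[i][j] = best;
        }
    }
    std::string db(n, '.');
    // iterative traceback
    std::vector<std::pair<int, int> > stack;
    if (n > 0) stack.push_back(std::make_pair(0, n - 1));
    while (!stack.empty()) {
        int i = stack.back().first, j = stack.back().second;
        stack.pop_back();
        if (j - i < minloop + 1) continue;
        if (E[i][j] == E[i][j - 1]) {
            stack.push_back(std::make_pair(i, j - 1));
            continue;
        }
        for (int k = i; k <= j - minloop - 1; ++k) {
            int w = pairWeight(seq[k], seq[j]);
            if (w == 0) continue;
            int cand = w + (k > i ? E[i][k - 1] : 0) + E[k + 1][j - 1];
            if (cand == E[i][j]) {
                db[k] = '(';
                db[j] = ')';
                if (k > i) stack.push_back(std::make_pair(i, k - 1));
                stack.push_back(std::make_pair(k + 1, j - 1));
                break;
            }
        }
    }
    int e = (n > 0) ? E[0][n - 1] : 0;
    return List::create(_["structure"] = db, _["energy"] = -((double) e));
}
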