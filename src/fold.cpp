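#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Pair weights for the folding-stability proxy: GC = -3, AU = -2, GU = -1,
// everything else unpairable. T is treated as U.
static inline double pair_w(char a, char b) {
  if (a == 'T') a = 'U';
  if (b == 'T') b = 'U';
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0;  // sentinel: not pairable
}

// Weighted Nussinov-style minimisation over nested structures with a
// minimum hairpin loop of 3 unpaired nucleotides (j - i > 3 for a pair).
// Returns the minimum total weight; 0 means no favourable pairing.
// [[Rcpp::export(name = ".fold_energy_cpp")]]
double fold_energy_cpp(std::string seq) {
  const int n = (int)seq.size();
  if (n < 5) return 0.0;
  std::vector<double> E((size_t)n * n, 0.0);
  for (int len = 5; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      const int j = i + len - 1;
      double best = E[(size_t)(i + 1) * n + j];               // i unpaired
      double v = E[(size_t)i * n + (j - 1)];                  // j unpaired
      if (v < best) best = v;
      double w = pair_w(seq[(size_t)i], seq[(size_t)j]);
      if (w < 0.0) {                                          // i pairs j
        v = w + (j - 1 >= i + 1 ? E[(size_t)(i + 1) * n + (j - 1)] : 0.0);
        if (v < best) best = v;
      }
      for (int k = i; k < j; ++k) {                           // bifurcation
        v = E[(size_t)i * n + k] + E[(size_t)(k + 1) * n + j];
        if (v < best) best = v;
      }
      E[(size_t)i * n + j] = best;
    }
  }
  return E[(size_t)0 * n + (n - 1)];
}
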