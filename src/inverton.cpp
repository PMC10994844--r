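#include <Rcpp.h>
using namespace Rcpp;

// DNA complement; anything outside ACGT maps to a sentinel that never
// matches, so ambiguity codes always count as mismatches.
static inline char cmpl(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
    default:  return '\0';
  }
}

// Length-dependent mismatch budget: 0 for arms <= 11 bp, 1 for 12-19 bp,
// 2 above 19 bp.
static inline int mm_budget(int arm) {
  if (arm <= 11) return 0;
  if (arm <= 19) return 1;
  return 2;
}

// Anchor-walk scanner. For every (left-arm inner end e, spacer s) the arm
// pair is grown outwards; position e-t pairs with r0+t, so the mismatch
// count is cumulative in the arm length. For each anchor only the longest
// valid arm per mismatch level is emitted (shorter ones are contained with
// equal mismatches and would be suppressed anyway); containment across
// anchors is resolved later in R.
// [[Rcpp::export(name = ".ir_scan_cpp")]]
DataFrame ir_scan_cpp(std::string seq, int arm_min, int arm_max,
                      int spacer_min, int spacer_max) {
  const int L = (int)seq.size();
  std::vector<int> out_l, out_a, out_s, out_m;

  for (int e = arm_min - 1; e < L; ++e) {
    int smax = spacer_max;
    for (int s = spacer_min; s <= smax; ++s) {
      const int r0 = e + s + 1;
      if (r0 >= L) break;
      int mm = 0;
      int best_a[3] = {0, 0, 0};  // longest valid arm per mismatch count
      int best_m[3] = {0, 0, 0};
      const int tmax = std::min(arm_max, std::min(e + 1, L - r0));
      for (int t = 0; t < tmax; ++t) {
        char c = cmpl(seq[(size_t)(e - t)]);
        if (seq[(size_t)(r0 + t)] != c || c == '\0') ++mm;
        if (mm > 2) break;
        const int a = t + 1;
        if (a >= arm_min && mm <= mm_budget(a)) {
          best_a[mm] = a;
          best_m[mm] = mm;
        }
      }
      // keep the longest arm at each realised mismatch level; drop a level
      // whose arm is not longer than a higher level with <= mismatches
      // (impossible here since levels are increasing in a), and drop a
      // level whose arm equals a later level's shorter prefix.
      for (int m = 0; m < 3; ++m) {
        if (best_a[m] == 0) continue;
        bool dominated = false;
        for (int m2 = 0; m2 < 3; ++m2) {
          if (m2 == m || best_a[m2] == 0) continue;
          if (best_a[m2] >= best_a[m] && best_m[m2] <= best_m[m]) {
            dominated = true;
            break;
          }
        }
        if (!dominated) {
          out_l.push_back(e - best_a[m] + 1);
          out_a.push_back(best_a[m]);
          out_s.push_back(s);
          out_m.push_back(best_m[m]);
        }
      }
    }
  }
  return DataFrame::create(_["left0"] = out_l, _["arm"] = out_a,
                           _["spacer"] = out_s, _["mismatches"] = out_m);
}

// Naive reference enumerator: every (left start, arm length, spacer) triple
// is checked by direct character comparison against the reverse complement.
// No maximality logic; used as an independent oracle (suppression is done
// by its R wrapper). The only shortcut is abandoning a triple once the
// mismatch count exceeds the largest possible budget.
// [[Rcpp::export(name = ".ir_enum_cpp")]]
DataFrame ir_enum_cpp(std::string seq, int arm_min, int arm_max,
                      int spacer_min, int spacer_max) {
  const int L = (int)seq.size();
  std::vector<int> out_l, out_a, out_s, out_m;

  for (int l = 0; l < L; ++l) {
    for (int a = arm_min; a <= arm_max; ++a) {
      for (int s = spacer_min; s <= spacer_max; ++s) {
        const int r = l + a + s;      // right arm start
        if (r + a > L) break;
        int mm = 0;
        for (int t = 0; t < a; ++t) {
          // right arm must equal the reverse complement of the left arm:
          // R[t] == complement(Larm[a - 1 - t])
          char c = cmpl(seq[(size_t)(l + a - 1 - t)]);
          if (seq[(size_t)(r + t)] != c || c == '\0') ++mm;
          if (mm > 2) break;
        }
        if (mm <= mm_budget(a)) {
          out_l.push_back(l);
          out_a.push_back(a);
          out_s.push_back(s);
          out_m.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["left0"] = out_l, _["arm"] = out_a,
                           _["spacer"] = out_s, _["mismatches"] = out_m);
}
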