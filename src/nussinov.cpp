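#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Maximum base-pairing secondary structure (Nussinov) with a minimum
// hairpin loop and G-U wobble pairs.  N never pairs.  Returns the
// dot-bracket structure and the pair count; used as the thermodynamics-free
// fallback folding engine.

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'U': return 3;
    default:  return 4;  // N / anything else: unpairable
  }
}

static inline bool can_pair(int a, int b) {
  if (a > 3 || b > 3) return false;
  // A-U, G-C, G-U (both orientations)
  return (a == 0 && b == 3) || (a == 3 && b == 0) ||
         (a == 2 && b == 1) || (a == 1 && b == 2) ||
         (a == 2 && b == 3) || (a == 3 && b == 2);
}

// [[Rcpp::export(name = ".nussinov_fold")]]
List nussinov_fold(std::string seq, int min_loop = 3) {
  const int n = (int) seq.size();
  std::vector<int> b(n);
  for (int i = 0; i < n; ++i) b[i] = base_code(seq[i]);

  // dp[i*n + j] = max pairs in i..j (0-based, inclusive)
  std::vector<int> dp((size_t) n * n, 0);
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = dp[(size_t) i * n + (j - 1)];
      for (int k = i; k <= j - min_loop - 1; ++k) {
        if (!can_pair(b[k], b[j])) continue;
        int left = (k > i) ? dp[(size_t) i * n + (k - 1)] : 0;
        int inner = (k + 1 <= j - 1) ? dp[(size_t)(k + 1) * n + (j - 1)] : 0;
        int cand = left + inner + 1;
        if (cand > best) best = cand;
      }
      dp[(size_t) i * n + j] = best;
    }
  }

  // traceback
  std::vector<int> partner(n, -1);
  std::vector<std::pair<int, int> > stack;
  if (n > 0) stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (dp[(size_t) i * n + j] == dp[(size_t) i * n + (j - 1)]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      if (!can_pair(b[k], b[j])) continue;
      int left = (k > i) ? dp[(size_t) i * n + (k - 1)] : 0;
      int inner = (k + 1 <= j - 1) ? dp[(size_t)(k + 1) * n + (j - 1)] : 0;
      if (left + inner + 1 == dp[(size_t) i * n + j]) {
        partner[k] = j;
        partner[j] = k;
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }

  std::string struct_(n, '.');
  int npairs = 0;
  LogicalVector paired(n);
  for (int i = 0; i < n; ++i) {
    if (partner[i] > i) {
      struct_[i] = '(';
      ++npairs;
    } else if (partner[i] >= 0) {
      struct_[i] = ')';
    }
    paired[i] = partner[i] >= 0;
  }
  return List::create(_["structure"] = struct_,
                      _["n_pairs"] = npairs,
                      _["paired"] = paired);
}
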