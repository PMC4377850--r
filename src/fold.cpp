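#include <Rcpp.h>
#include <vector>
#include <string>

// Weighted Nussinov-style dynamic program over nested secondary structures.
// Per-pair stacking-free energies: G:C -3, A:U -2, G:U -1 (kcal/mol,
// documented constants); minimum hairpin loop length enforced between any
// paired bases. Traceback prefers closing a pair, then leaving the 5' base
// unpaired, then the 3' base, then the smallest bifurcation point, so the
// reported structure is deterministic.

static double pair_energy(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return -3.0;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return -2.0;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return -1.0;
  return 1.0; // not pairable
}

// [[Rcpp::export]]
Rcpp::List fold_backend_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::string structure(n, '.');
  if (n == 0)
    return Rcpp::List::create(Rcpp::Named("structure") = structure,
                              Rcpp::Named("mfe") = 0.0);

  std::vector<std::vector<double>> E(n, std::vector<double>(n, 0.0));

  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      double best = E[i + 1][j];                 // i unpaired
      if (E[i][j - 1] < best) best = E[i][j - 1]; // j unpaired
      double e = pair_energy(seq[i], seq[j]);
      if (e < 0 && j - i - 1 >= min_loop) {
        double cand = e + (i + 1 <= j - 1 ? E[i + 1][j - 1] : 0.0);
        if (cand < best) best = cand;
      }
      for (int k = i + 1; k < j; ++k) {
        double cand = E[i][k] + E[k + 1][j];
        if (cand < best) best = cand;
      }
      E[i][j] = best;
    }
  }

  // iterative traceback
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    double target = E[i][j];
    double e = pair_energy(seq[i], seq[j]);
    if (e < 0 && j - i - 1 >= min_loop &&
        target == e + (i + 1 <= j - 1 ? E[i + 1][j - 1] : 0.0)) {
      structure[i] = '(';
      structure[j] = ')';
      stack.push_back(std::make_pair(i + 1, j - 1));
      continue;
    }
    if (target == E[i + 1][j]) {
      stack.push_back(std::make_pair(i + 1, j));
      continue;
    }
    if (target == E[i][j - 1]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i + 1; k < j; ++k) {
      if (target == E[i][k] + E[k + 1][j]) {
        stack.push_back(std::make_pair(i, k));
        stack.push_back(std::make_pair(k + 1, j));
        break;
      }
    }
  }

  return Rcpp::List::create(Rcpp::Named("structure") = structure,
                            Rcpp::Named("mfe") = E[0][n - 1]);
}
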