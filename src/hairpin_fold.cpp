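// Stem-loop restricted minimum-energy folding.
//
// The structure space is a single hairpin: one terminal loop closed by a
// stem that may contain bulges and interior loops (no multiloops, no
// pseudoknots).  Energies use a documented constant scale:
//   pair strengths   s(GC) = 3.3, s(AU) = 0.9, s(GU) = 1.0  (kcal/mol)
//   stacked pairs    contribute -(s1 + s2) / 2 per stack
//   interior/bulge   +1.0 opening + 0.3 per unpaired nucleotide
//   hairpin loop     +0.5 + 0.1 per loop nucleotide (3 <= loop <= max_loop)
// Isolated pairs carry no stabilizing term of their own, so unstructured
// sequences fold to an energy of zero.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// base codes: A=0 C=1 G=2 U=3, -1 otherwise
static inline int code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'U': case 'u': case 'T': case 't': return 3;
    default: return -1;
  }
}

// pair strength; 0.0 when the two bases cannot pair
static inline double pair_strength(int a, int b) {
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3.3;  // G:C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 0.9;  // A:U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1.0;  // G:U
  return 0.0;
}

// [[Rcpp::export(name = ".hairpin_fold_cpp")]]
List hairpin_fold_cpp(std::string seq, int min_loop = 3, int max_loop = 30,
                      int max_bulge = 6, double interior_open = 1.0,
                      double interior_per_nt = 0.3, double hairpin_open = 0.5,
                      double hairpin_per_nt = 0.1) {
  const int n = (int) seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) {
    s[i] = code(seq[i]);
    if (s[i] < 0) stop("non-ACGU character at position %d", i + 1);
  }

  // E[i][j]: min energy of a hairpin on [i..j] given that (i,j) pair.
  // choice encodes traceback: -1 = hairpin close; otherwise k * n + l for
  // the inner pair (k, l).
  std::vector<std::vector<double>> E(n, std::vector<double>(n, INF));
  std::vector<std::vector<int>> choice(n, std::vector<int>(n, -2));

  for (int span = min_loop + 2; span <= n; ++span) {
    for (int i = 0; i + span - 1 < n; ++i) {
      int j = i + span - 1;
      if (pair_strength(s[i], s[j]) == 0.0) continue;
      double best = INF;
      int bc = -2;
      int loop_len = j - i - 1;
      if (loop_len >= min_loop && loop_len <= max_loop) {
        best = hairpin_open + hairpin_per_nt * loop_len;
        bc = -1;
      }
      int amax = std::min(max_bulge, j - i - 2);
      for (int a = 0; a <= amax; ++a) {
        int k = i + 1 + a;
        int bmax = std::min(max_bulge, j - k - 2);
        for (int b = 0; b <= bmax; ++b) {
          int l = j - 1 - b;
          if (k >= l) continue;
          double inner = E[k][l];
          if (!std::isfinite(inner)) continue;
          double cand;
          if (a == 0 && b == 0) {
            cand = inner - 0.5 * (pair_strength(s[i], s[j]) +
                                  pair_strength(s[k], s[l]));
          } else {
            cand = inner + interior_open + interior_per_nt * (a + b);
          }
          if (cand < best) { best = cand; bc = k * n + l; }
        }
      }
      if (std::isfinite(best)) { E[i][j] = best; choice[i][j] = bc; }
    }
  }

  double mfe = 0.0;
  int bi = -1, bj = -1;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      if (E[i][j] < mfe) { mfe = E[i][j]; bi = i; bj = j; }
    }
  }

  IntegerVector pairs(n, 0);  // 1-based partner, 0 = unpaired
  std::string db(n, '.');
  int loop_start = NA_INTEGER, loop_end = NA_INTEGER;
  if (bi >= 0) {
    int i = bi, j = bj;
    while (true) {
      pairs[i] = j + 1; pairs[j] = i + 1;
      db[i] = '('; db[j] = ')';
      int c = choice[i][j];
      if (c == -1) { loop_start = i + 2; loop_end = j; break; }  // 1-based loop span
      i = c / n; j = c % n;
    }
  }

  return List::create(
    _["mfe"] = mfe,
    _["structure"] = db,
    _["pairs"] = pairs,
    _["loop_start"] = loop_start,
    _["loop_end"] = loop_end
  );
}
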