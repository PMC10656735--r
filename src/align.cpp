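#include <Rcpp.h>
#include <climits>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Affine-gap pairwise alignment (Gotoh) in two modes:
//   semiglobal: global alignment with free terminal gaps on BOTH sequences
//   local:      Smith-Waterman
//
// Scoring contract (mirrored by the R test oracle):
//  - a match scores `match` only when the two characters are equal AND both
//    are unambiguous A/C/G/T; any ambiguity code (incl. N) scores `mismatch`
//    even against itself, so identity never inflates.
//  - a gap of length L costs gap_open + (L-1)*gap_extend.
//  - end cell: maximum score over the last row and last column (semiglobal)
//    or the whole matrix (local); ties prefer larger i+j, then larger i.
//  - traceback tie-break: diagonal > gap-in-b (consume a) > gap-in-a;
//    within a gap state, closing the gap (open move) is preferred over
//    extending on equal score.

static const int NEG = INT_MIN / 4;

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// [[Rcpp::export]]
List align_cpp(std::string a, std::string b, int match, int mismatch,
               int gap_open, int gap_extend, bool local) {
  const size_t n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((n + 1) * (m + 1) > 400000000ULL)
    stop("alignment problem too large; window the subject first");

  std::vector<int> H((n + 1) * (m + 1), 0);
  std::vector<int> E((n + 1) * (m + 1), NEG); // gap in a (consumes b)
  std::vector<int> F((n + 1) * (m + 1), NEG); // gap in b (consumes a)
  const size_t W = m + 1;

  for (size_t i = 1; i <= n; ++i) {
    const char ca = a[i - 1];
    for (size_t j = 1; j <= m; ++j) {
      const size_t k = i * W + j;
      int e = std::max(H[k - 1] + gap_open, E[k - 1] + gap_extend);
      int f = std::max(H[k - W] + gap_open, F[k - W] + gap_extend);
      const char cb = b[j - 1];
      int s = (ca == cb && is_acgt(ca)) ? match : mismatch;
      int d = H[k - W - 1] + s;
      int h = std::max(d, std::max(e, f));
      if (local && h < 0) h = 0;
      H[k] = h; E[k] = e; F[k] = f;
    }
  }

  // locate end cell
  size_t bi = 0, bj = 0;
  int best = local ? 0 : NEG;
  auto consider = [&](size_t i, size_t j) {
    int h = H[i * W + j];
    if (h > best ||
        (h == best && (i + j > bi + bj || (i + j == bi + bj && i > bi)))) {
      best = h; bi = i; bj = j;
    }
  };
  if (local) {
    for (size_t i = 0; i <= n; ++i)
      for (size_t j = 0; j <= m; ++j) consider(i, j);
  } else {
    for (size_t j = 0; j <= m; ++j) consider(n, j);
    for (size_t i = 0; i <= n; ++i) consider(i, m);
  }

  // traceback with explicit state (0 = H, 1 = F gap-in-b, 2 = E gap-in-a)
  std::string aa, bb;
  size_t i = bi, j = bj;
  int state = 0;
  while (true) {
    const size_t k = i * W + j;
    if (state == 0) {
      if (local && H[k] == 0) break;
      if (i == 0 || j == 0) break;
      const char ca = a[i - 1], cb = b[j - 1];
      int s = (ca == cb && is_acgt(ca)) ? match : mismatch;
      if (H[k] == H[k - W - 1] + s) {
        aa.push_back(ca); bb.push_back(cb); --i; --j;
      } else if (H[k] == F[k]) {
        state = 1;
      } else {
        state = 2;
      }
    } else if (state == 1) {
      aa.push_back(a[i - 1]); bb.push_back('-');
      bool open = (F[k] == H[k - W] + gap_open);
      --i;
      state = open ? 0 : 1;
    } else {
      aa.push_back('-'); bb.push_back(b[j - 1]);
      bool open = (E[k] == H[k - 1] + gap_open);
      --j;
      state = open ? 0 : 2;
    }
  }
  std::reverse(aa.begin(), aa.end());
  std::reverse(bb.begin(), bb.end());

  const bool empty = aa.empty();
  return List::create(
    _["score"] = best,
    _["a_aligned"] = aa,
    _["b_aligned"] = bb,
    _["a_start"] = empty ? 0 : (int)(i + 1),
    _["a_end"] = empty ? 0 : (int)bi,
    _["b_start"] = empty ? 0 : (int)(j + 1),
    _["b_end"] = empty ? 0 : (int)bj);
}
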