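#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base codes: A=0, C=1, G=2, T=3; anything else = -1 (caller filters N).
static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

// Rejection reason codes shared with the R wrapper:
// 0 accepted, 1 score, 2 anchor, 3 coverage, 4 no_seed.

// Seed-and-extend alignment of a batch of reads against one reference.
// Seeds are k-mer placements whose k pairings all score +1 under the
// asymmetric matrix (or literal string equality when literal_seed). A read
// is accepted iff some seed's gapless full-read extension has score equal
// to the read length, implied reference start 1, and covers the evaluation
// window [w1, w2]. Rejected reads report the extension verdict of the
// lexicographically first seed (read offset, then reference offset).
// [[Rcpp::export(name = ".cpp_align_batch")]]
List cpp_align_batch(CharacterVector reads, std::string reference, int k,
                     IntegerMatrix score, int w1, int w2, bool literal_seed) {
  const int n = reads.size();
  const int Lref = reference.size();
  std::vector<int> refc(Lref);
  for (int j = 0; j < Lref; ++j) refc[j] = base_code(reference[j]);

  IntegerVector out_start(n, NA_INTEGER);
  IntegerVector out_score(n, NA_INTEGER);
  IntegerVector out_reason(n);
  LogicalVector out_seeded(n);

  for (int r = 0; r < n; ++r) {
    const char *rd = CHAR(STRING_ELT(reads, r));
    const int Lr = LENGTH(STRING_ELT(reads, r));
    std::vector<int> rc(Lr);
    for (int i = 0; i < Lr; ++i) rc[i] = base_code(rd[i]);

    if (Lr < k) { out_reason[r] = 4; continue; }

    // Anchored placement (reference start 1): the only placement the
    // retention filters can accept.
    bool anchored_ok = false;
    int anchored_score = NA_INTEGER;
    if (Lr <= Lref) {
      int sc = 0;
      for (int i = 0; i < Lr; ++i) sc += score(rc[i], refc[i]);
      anchored_score = sc;
      anchored_ok = (sc == Lr) && (Lr >= w2) && (w1 >= 1);
    }
    if (anchored_ok) {
      // every anchored k-window is all +1, hence a seed exists
      out_start[r] = 1;
      out_score[r] = anchored_score;
      out_reason[r] = 0;
      out_seeded[r] = true;
      continue;
    }

    // Lexicographically first seed (i, j), 0-based here.
    int si = -1, sj = -1;
    for (int i = 0; i + k <= Lr && si < 0; ++i) {
      for (int j = 0; j + k <= Lref; ++j) {
        bool hit = true;
        for (int t = 0; t < k; ++t) {
          if (literal_seed ? (rc[i + t] != refc[j + t])
                           : (score(rc[i + t], refc[j + t]) != 1)) {
            hit = false;
            break;
          }
        }
        if (hit) { si = i; sj = j; break; }
      }
    }
    if (si < 0) { out_reason[r] = 4; continue; }
    out_seeded[r] = true;

    // Extension verdict of that first seed.
    const int start = sj - si + 1;  // 1-based implied reference start
    if (start < 1 || start + Lr - 1 > Lref) {
      out_reason[r] = 3;  // runs off the reference
      out_start[r] = start;
      continue;
    }
    int sc = 0;
    for (int i = 0; i < Lr; ++i) sc += score(rc[i], refc[start - 1 + i]);
    out_start[r] = start;
    out_score[r] = sc;
    if (sc != Lr)                       out_reason[r] = 1;  // score
    else if (start != 1)                out_reason[r] = 2;  // anchor
    else                                out_reason[r] = 3;  // window coverage
  }

  return List::create(_["reference_start"] = out_start,
                      _["score"] = out_score,
                      _["reason"] = out_reason,
                      _["seeded"] = out_seeded);
}
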