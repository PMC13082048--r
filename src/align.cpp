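#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Affine-gap Smith-Waterman (Gotoh) over character sequences.
//
// Gap convention: the FIRST position of a gap scores `gap_open` and every
// subsequent position scores `gap_extend` (a gap of length L scores
// gap_open + (L-1)*gap_extend). This matches the scoring used by common
// Python local aligners, not the (open+extend) first-position convention.
//
// Tie-break for the reported reference interval: among all cells attaining
// the maximal score, the alignment with the smallest reference start wins,
// then the one with the smallest reference end (shortest interval).
//
// Returns c(score, ref_start, ref_end) with 1-based closed coordinates;
// start/end are 0 when the best score is 0 (no positive-scoring alignment).
// [[Rcpp::export]]
NumericVector cpp_local_align(std::string query, std::string ref,
                              double match, double mismatch,
                              double gap_open, double gap_extend) {
  const int n = query.size(), m = ref.size();
  const double NEG = -1e300;

  // per-row rolling arrays; origin = 0-based ref column where the local
  // alignment started (first consumed ref position), or -1 if none yet
  std::vector<double> Hprev(m + 1, 0.0), H(m + 1, 0.0);
  std::vector<double> Eprev(m + 1, NEG), E(m + 1, NEG);   // gap in query (consumes ref)
  std::vector<double> F(m + 1, NEG);                       // gap in ref (consumes query)
  std::vector<int> oHprev(m + 1, -1), oH(m + 1, -1);
  std::vector<int> oE(m + 1, -1), oF(m + 1, -1);

  double best = 0.0;
  int best_start = -1, best_end = -1;

  for (int i = 1; i <= n; ++i) {
    H[0] = 0.0; E[0] = NEG; oH[0] = -1; oE[0] = -1;
    for (int j = 1; j <= m; ++j) {
      // E: gap in query ending at (i,j); consumes ref[j-1]
      double e_open = H[j - 1] + gap_open;
      double e_ext  = E[j - 1] + gap_extend;
      if (e_open >= e_ext) { E[j] = e_open; oE[j] = oH[j - 1]; }
      else                 { E[j] = e_ext;  oE[j] = oE[j - 1]; }
      // an E path must have consumed at least one ref position already;
      // if it starts the alignment, its origin is this column
      if (oE[j] < 0) oE[j] = j - 1;

      // F: gap in ref ending at (i,j); consumes query[i-1], ref col unchanged
      double f_open = Hprev[j] + gap_open;
      double f_ext  = F[j] + gap_extend;
      int of;
      if (f_open >= f_ext) { F[j] = f_open; of = oHprev[j]; }
      else                 { F[j] = f_ext;  of = oF[j]; }
      oF[j] = of;

      // H: best ending at (i,j)
      double s = (query[i - 1] == ref[j - 1]) ? match : mismatch;
      double diag = Hprev[j - 1] + s;
      int odiag = (oHprev[j - 1] < 0) ? (j - 1) : oHprev[j - 1];

      double h = 0.0; int oh = -1;
      if (diag > h || (diag == h && diag > 0)) { h = diag; oh = odiag; }
      if (E[j] > h) { h = E[j]; oh = oE[j]; }
      else if (E[j] == h && h > 0 && oE[j] >= 0 && (oh < 0 || oE[j] < oh)) oh = oE[j];
      if (F[j] > h) { h = F[j]; oh = oF[j]; }
      else if (F[j] == h && h > 0 && oF[j] >= 0 && (oh < 0 || oF[j] < oh)) oh = oF[j];
      H[j] = h; oH[j] = (h <= 0.0) ? -1 : oh;

      if (h > best) {
        best = h; best_start = oH[j]; best_end = j - 1;
      } else if (h == best && best > 0.0) {
        if (oH[j] >= 0 && (oH[j] < best_start ||
            (oH[j] == best_start && (j - 1) < best_end))) {
          best_start = oH[j]; best_end = j - 1;
        }
      }
    }
    std::swap(Hprev, H); std::swap(oHprev, oH); std::swap(Eprev, E);
  }

  NumericVector out(3);
  out[0] = best;
  out[1] = (best > 0.0) ? best_start + 1 : 0;  // 1-based
  out[2] = (best > 0.0) ? best_end + 1 : 0;
  return out;
}
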