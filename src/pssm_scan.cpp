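#include <Rcpp.h>
using namespace Rcpp;

// Ungapped sliding-window scores of a profile over an encoded protein.
//
// scores: L x 20 log-odds matrix (bits); seq: 1-based residue column
// indices, NA for X/unknown (which contributes 0). Returns one score per
// window start (length n - L + 1), or an empty vector if the protein is
// shorter than the profile.
// [[Rcpp::export]]
NumericVector pssm_window_scores(NumericMatrix scores, IntegerVector seq) {
  const int L = scores.nrow();
  const int n = seq.size();
  if (n < L) return NumericVector(0);
  const int W = n - L + 1;
  NumericVector out(W);
  for (int i = 0; i < W; ++i) {
    double s = 0.0;
    for (int j = 0; j < L; ++j) {
      const int a = seq[i + j];
      if (a != NA_INTEGER) s += scores(j, a - 1);
    }
    out[i] = s;
  }
  return out;
}
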