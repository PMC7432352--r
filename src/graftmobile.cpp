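#include <Rcpp.h>
using namespace Rcpp;

// Count mismatches between each read and a target slice of equal length.
// read_idx / target_idx are 1-based into reads / targets; offsets are 0-based
// starts on the target. Counting stops early once `cap` is exceeded, so the
// returned value is min(true mismatches, cap + 1).
// [[Rcpp::export]]
IntegerVector cpp_count_mismatches(CharacterVector reads,
                                   IntegerVector read_idx,
                                   CharacterVector targets,
                                   IntegerVector target_idx,
                                   IntegerVector offsets,
                                   int cap) {
  R_xlen_t n = read_idx.size();
  IntegerVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *r = CHAR(STRING_ELT(reads, read_idx[i] - 1));
    const char *t = CHAR(STRING_ELT(targets, target_idx[i] - 1));
    const char *s = t + offsets[i];
    int mm = 0;
    for (; *r != '\0'; ++r, ++s) {
      if (*r != *s) {
        if (++mm > cap) break;
      }
    }
    out[i] = mm;
  }
  return out;
}

// Smith-Waterman local alignment score with affine gaps.
// a and b are 1-based indices into the rows/columns of the substitution
// matrix. A gap of length k costs gap_open + k * gap_ext.
// [[Rcpp::export]]
double cpp_sw_affine(IntegerVector a, IntegerVector b,
                     NumericMatrix submat,
                     double gap_open, double gap_ext) {
  int n = a.size(), m = b.size();
  if (n == 0 || m == 0) return 0.0;
  std::vector<double> H(m + 1, 0.0), E(m + 1, R_NegInf);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double diag = 0.0;       // H[i-1][0]
    double F = R_NegInf;     // gap in b (vertical) for current row
    double Hprev = 0.0;      // H[i][0]
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      E[j] = std::max(E[j] - gap_ext, H[j] - gap_open - gap_ext);
      F = std::max(F - gap_ext, Hprev - gap_open - gap_ext);
      double h = diag + submat(ai, b[j - 1] - 1);
      h = std::max(h, E[j]);
      h = std::max(h, F);
      h = std::max(h, 0.0);
      diag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}
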