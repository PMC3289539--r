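#include <Rcpp.h>
using namespace Rcpp;

// Best ungapped local-alignment segment per diagonal of a short query
// against one strand of a chromosome. Codes: A/C/G/T -> 1..4, 0 never
// matches. Diagonal d (1..L+m-1): subject position of query base j is
// d + j - m (1-based). Returns 0-based half-open spans.
// [[Rcpp::export(name = ".diagonalHitsCpp")]]
DataFrame diagonalHitsCpp(IntegerVector qcode, IntegerVector subjCode,
                          double match, double mismatch, double minScore) {
  const int m = qcode.size();
  const int L = subjCode.size();
  std::vector<double> score;
  std::vector<int> qs, qe, ss, se;
  if (L >= 1) {
    const int D = L + m - 1;
    for (int d = 1; d <= D; ++d) {
      double H = 0.0, best = 0.0;
      int bj = 0, sj = 1, cur = 1;
      for (int j = 1; j <= m; ++j) {
        const int p = d + j - m;
        double s = mismatch;
        if (p >= 1 && p <= L && qcode[j - 1] > 0 &&
            subjCode[p - 1] == qcode[j - 1])
          s = match;
        if (H == 0.0) cur = j;
        H += s;
        if (H < 0.0) H = 0.0;
        if (H > best) { best = H; bj = j; sj = cur; }
      }
      if (best >= minScore) {
        score.push_back(best);
        qs.push_back(sj - 1);
        qe.push_back(bj);
        ss.push_back(d + sj - m - 1);
        se.push_back(d + bj - m);
      }
    }
  }
  return DataFrame::create(_["score"] = score,
                           _["qStart"] = qs, _["qEnd"] = qe,
                           _["sStart"] = ss, _["sEnd"] = se);
}
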