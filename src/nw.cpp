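#include <Rcpp.h>
#include <vector>
#include <string>

// Global (Needleman-Wunsch) alignment with linear gap penalty.
//
// Deterministic tie-breaking during traceback: prefer the diagonal
// (match/mismatch) move, then gap-in-sample (reference base unmatched),
// then gap-in-reference.  'N' against anything scores 0 (neutral).
//
// Memory: rolling score rows plus a full byte traceback matrix, so an
// n x m problem needs ~(n+1)*(m+1) bytes; intended for amplicon-scale
// windows (a few kb), not chromosome-scale alignment.

// [[Rcpp::export(name = ".nw_align_cpp")]]
Rcpp::List nw_align_cpp(std::string ref, std::string sample,
                        int match, int mismatch, int gap) {
  const int n = ref.size(), m = sample.size();
  if (n == 0 || m == 0)
    Rcpp::stop("sequences must be non-empty");

  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1));
  std::vector<int> prev(m + 1), cur(m + 1);
  const unsigned char DIAG = 1, UP = 2, LEFT = 3;  // UP = gap in sample

  prev[0] = 0;
  for (int j = 1; j <= m; ++j) {
    prev[j] = j * gap;
    tb[j] = LEFT;
  }
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    tb[(size_t)i * (m + 1)] = UP;
    const char a = ref[i - 1];
    for (int j = 1; j <= m; ++j) {
      const char b = sample[j - 1];
      const int sub = (a == 'N' || b == 'N') ? 0 : (a == b ? match : mismatch);
      const int d = prev[j - 1] + sub;
      const int u = prev[j] + gap;
      const int l = cur[j - 1] + gap;
      int best = d;
      unsigned char move = DIAG;
      if (u > best) { best = u; move = UP; }
      if (l > best) { best = l; move = LEFT; }
      cur[j] = best;
      tb[(size_t)i * (m + 1) + j] = move;
    }
    std::swap(prev, cur);
  }
  const int score = prev[m];

  std::string ar, as;
  ar.reserve(n + m); as.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char move;
    if (i == 0) move = LEFT;
    else if (j == 0) move = UP;
    else move = tb[(size_t)i * (m + 1) + j];
    if (move == DIAG) {
      ar.push_back(ref[i - 1]); as.push_back(sample[j - 1]);
      --i; --j;
    } else if (move == UP) {
      ar.push_back(ref[i - 1]); as.push_back('-');
      --i;
    } else {
      ar.push_back('-'); as.push_back(sample[j - 1]);
      --j;
    }
  }
  std::reverse(ar.begin(), ar.end());
  std::reverse(as.begin(), as.end());
  return Rcpp::List::create(Rcpp::Named("aligned_ref") = ar,
                            Rcpp::Named("aligned_sample") = as,
                            Rcpp::Named("score") = score);
}
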