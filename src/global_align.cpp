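#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh global alignment with affine gap costs, maximising score.
// A gap run of length L costs gap_open + (L - 1) * gap_extend (the opening
// charge covers the first gap position).  Characters absent from the
// substitution matrix score 0 against everything.  Traceback ties are broken
// deterministically: diagonal, then gap-in-b (consume a), then gap-in-a.

static const double NEG = -1e18;

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string a, std::string b, NumericMatrix score,
               CharacterVector residues, double gap_open, double gap_extend) {
  const int n = (int)a.size(), m = (int)b.size();
  std::vector<int> code(256, -1);
  for (int k = 0; k < residues.size(); ++k) {
    std::string r = as<std::string>(residues[k]);
    if (!r.empty()) code[(unsigned char)r[0]] = k;
  }
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG), Y((n + 1) * W, NEG);
  // traceback: predecessor state (0 = M, 1 = X, 2 = Y), -1 = boundary
  std::vector<signed char> tM((n + 1) * W, -1), tX((n + 1) * W, -1), tY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = -(gap_open + (i - 1) * gap_extend);
    tX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = -(gap_open + (j - 1) * gap_extend);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const int ia = code[(unsigned char)a[i - 1]];
    for (int j = 1; j <= m; ++j) {
      const int ib = code[(unsigned char)b[j - 1]];
      const double s = (ia < 0 || ib < 0) ? 0.0 : score(ia, ib);
      const int cur = i * W + j, diag = (i - 1) * W + (j - 1),
                up = (i - 1) * W + j, left = i * W + (j - 1);
      // M: preference M > X > Y on ties
      double best = M[diag]; signed char st = 0;
      if (X[diag] > best) { best = X[diag]; st = 1; }
      if (Y[diag] > best) { best = Y[diag]; st = 2; }
      M[cur] = best + s; tM[cur] = st;
      // X: consume a[i], gap in b
      best = M[up] - gap_open; st = 0;
      if (X[up] - gap_extend > best) { best = X[up] - gap_extend; st = 1; }
      if (Y[up] - gap_open > best) { best = Y[up] - gap_open; st = 2; }
      X[cur] = best; tX[cur] = st;
      // Y: consume b[j], gap in a
      best = M[left] - gap_open; st = 0;
      if (X[left] - gap_open > best) { best = X[left] - gap_open; st = 1; }
      if (Y[left] - gap_extend > best) { best = Y[left] - gap_extend; st = 2; }
      Y[cur] = best; tY[cur] = st;
    }
  }

  const int end = n * W + m;
  double best = M[end]; int state = 0;
  if (X[end] > best) { best = X[end]; state = 1; }
  if (Y[end] > best) { best = Y[end]; state = 2; }

  std::string ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      signed char prev = tM[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      --i; --j; state = prev;
    } else if (state == 1) {
      signed char prev = tX[i * W + j];
      ra.push_back(a[i - 1]); rb.push_back('-');
      --i; state = prev;
    } else {
      signed char prev = tY[i * W + j];
      ra.push_back('-'); rb.push_back(b[j - 1]);
      --j; state = prev;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int match = 0, gapcol = 0;
  for (size_t k = 0; k < ra.size(); ++k) {
    const char ca = ra[k], cb = rb[k];
    if (ca == '-' || cb == '-') { ++gapcol; continue; }
    if (ca == cb && ca != 'X' && code[(unsigned char)ca] >= 0) ++match;
  }

  return List::create(
    _["aligned_a"] = ra, _["aligned_b"] = rb, _["score"] = best,
    _["alignment_length"] = (int)ra.size(), _["match_count"] = match,
    _["gap_columns"] = gapcol);
}
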