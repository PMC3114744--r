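#include <Rcpp.h>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

// Global pairwise alignment with affine gaps (Gotoh), maximization.
// Gap run of length L costs open + (L-1) * extend (open charged on the
// first gapped residue only).  Deterministic traceback: on score ties the
// preference is diagonal (match state), then up (gap in b), then left
// (gap in a), and gap states prefer to stay open rather than re-open.
// [[Rcpp::export(name = ".pair_align_cpp")]]
List pair_align_cpp(std::string a, std::string b,
                    double match, double mismatch,
                    double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e30;
  if (n == 0 || m == 0) {
    std::string ga(m, '-'), gb(n, '-');
    return List::create(_["a"] = a + ga, _["b"] = gb + b,
                        _["score"] = (n == 0 && m == 0) ? 0.0
                          : gap_open + (std::max(n, m) - 1) * gap_extend);
  }
  // state 0 = M (a[i] ~ b[j]), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector<double> M(m + 1), X(m + 1), Y(m + 1), Mp(m + 1), Xp(m + 1), Yp(m + 1);
  // traceback: for each cell and state, the predecessor state
  std::vector<unsigned char> tb((size_t)(n + 1) * (m + 1) * 3);
  auto TB = [&](int i, int j, int s) -> unsigned char& {
    return tb[((size_t)i * (m + 1) + j) * 3 + s];
  };
  Mp[0] = 0.0; Xp[0] = NEG; Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = gap_open + (j - 1) * gap_extend;
    TB(0, j, 2) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    M[0] = NEG; Y[0] = NEG;
    X[0] = gap_open + (i - 1) * gap_extend;
    TB(i, 0, 1) = 1;
    for (int j = 1; j <= m; ++j) {
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M from best of previous diagonal states (prefer M, X, Y on ties)
      double bm = Mp[j - 1]; unsigned char ps = 0;
      if (Xp[j - 1] > bm) { bm = Xp[j - 1]; ps = 1; }
      if (Yp[j - 1] > bm) { bm = Yp[j - 1]; ps = 2; }
      M[j] = bm + s; TB(i, j, 0) = ps;
      // X: gap in b (move down); stay in X (extend) preferred over open on tie
      double x_open = std::max(Mp[j], Yp[j]) + gap_open;
      double x_ext = Xp[j] + gap_extend;
      if (x_ext >= x_open) { X[j] = x_ext; TB(i, j, 1) = 1; }
      else { X[j] = x_open; TB(i, j, 1) = (Mp[j] >= Yp[j]) ? 0 : 2; }
      // Y: gap in a (move right)
      double y_open = std::max(M[j - 1], X[j - 1]) + gap_open;
      double y_ext = Y[j - 1] + gap_extend;
      if (y_ext >= y_open) { Y[j] = y_ext; TB(i, j, 2) = 2; }
      else { Y[j] = y_open; TB(i, j, 2) = (M[j - 1] >= X[j - 1]) ? 0 : 1; }
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
  }
  double best = Mp[m]; int st = 0;
  if (Xp[m] > best) { best = Xp[m]; st = 1; }
  if (Yp[m] > best) { best = Yp[m]; st = 2; }
  std::string ga, gb;
  ga.reserve(n + m); gb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char prev = TB(i, j, st);
    if (st == 0) { ga.push_back(a[--i]); gb.push_back(b[--j]); }
    else if (st == 1) { ga.push_back(a[--i]); gb.push_back('-'); }
    else { ga.push_back('-'); gb.push_back(b[--j]); }
    st = prev;
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["a"] = ga, _["b"] = gb, _["score"] = best);
}
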