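#include <Rcpp.h>
using namespace Rcpp;

// Gotoh global alignment with affine gaps and a fixed deterministic
// traceback (diagonal preferred over up, up over left; within a state,
// predecessor preference M > X > Y). A gap of length L costs
// gap_open + L * gap_extend (both passed as positive penalties).
//
// a and b are 1-based indices into the square scoring matrix `score`.
// Returns 0-based traceback as two index vectors where 0 marks a gap.

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_align_idx(IntegerVector a, IntegerVector b, NumericMatrix score,
                  double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double gi = gap_open + gap_extend; // cost of opening (first residue)
  const double ge = gap_extend;

  // state matrices: M = a[i] aligned to b[j], X = gap in b (consume a),
  // Y = gap in a (consume b)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  // traceback: which predecessor state (0=M,1=X,2=Y), per state
  IntegerMatrix tM(n + 1, m + 1), tX(n + 1, m + 1), tY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG_INF; Y(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; Y(i, 0) = NEG_INF;
    X(i, 0) = -(gi + ge * (i - 1));
    tX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; X(0, j) = NEG_INF;
    Y(0, j) = -(gi + ge * (j - 1));
    tY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = score(a[i - 1] - 1, b[j - 1] - 1);
      // M: diagonal step; predecessor preference M > X > Y (>= keeps first)
      double best = M(i - 1, j - 1); int arg = 0;
      if (X(i - 1, j - 1) > best) { best = X(i - 1, j - 1); arg = 1; }
      if (Y(i - 1, j - 1) > best) { best = Y(i - 1, j - 1); arg = 2; }
      M(i, j) = best + s; tM(i, j) = arg;
      // X: vertical (consume a[i])
      best = M(i - 1, j) - gi; arg = 0;
      if (X(i - 1, j) - ge > best) { best = X(i - 1, j) - ge; arg = 1; }
      if (Y(i - 1, j) - gi > best) { best = Y(i - 1, j) - gi; arg = 2; }
      X(i, j) = best; tX(i, j) = arg;
      // Y: horizontal (consume b[j])
      best = M(i, j - 1) - gi; arg = 0;
      if (X(i, j - 1) - gi > best) { best = X(i, j - 1) - gi; arg = 1; }
      if (Y(i, j - 1) - ge > best) { best = Y(i, j - 1) - ge; arg = 2; }
      Y(i, j) = best; tY(i, j) = arg;
    }
  }

  // final state preference M > X > Y
  int state = 0; double sc = M(n, m);
  if (X(n, m) > sc) { sc = X(n, m); state = 1; }
  if (Y(n, m) > sc) { sc = Y(n, m); state = 2; }

  std::vector<int> ra, rb;
  ra.reserve(n + m); rb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    int prev;
    if (state == 0) {
      prev = tM(i, j);
      ra.push_back(i); rb.push_back(j); --i; --j;
    } else if (state == 1) {
      prev = tX(i, j);
      ra.push_back(i); rb.push_back(0); --i;
    } else {
      prev = tY(i, j);
      ra.push_back(0); rb.push_back(j); --j;
    }
    state = prev;
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["a_idx"] = wrap(ra), _["b_idx"] = wrap(rb),
                      _["score"] = sc);
}
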