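#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>

using namespace Rcpp;

// Pairwise score for one column. N is informationless base-caller output:
// it is never rewarded as a match nor penalized as a mismatch.
static inline int col_score(char x, char y, int match, int mismatch) {
  if (x == 'N' || y == 'N') return 0;
  return (x == y) ? match : -mismatch;
}

static const int NEG = INT_MIN / 4;

// Global affine-gap alignment (Gotoh). Penalties are magnitudes; a gap of
// length L costs open + L*extend. Three-state DP:
//   M  - column consumes one base of each sequence
//   X  - gap in the clone row (template base deleted in the clone)
//   Y  - gap in the template row (base inserted in the clone)
// Traceback ties resolve M > X > Y at every choice point, so the reported
// alignment is deterministic.
// [[Rcpp::export]]
List gotoh_align_cpp(std::string tmpl, std::string clone,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) tmpl.size();
  const int m = (int) clone.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  std::vector<int> M((n + 1) * (m + 1), NEG);
  std::vector<int> X((n + 1) * (m + 1), NEG);
  std::vector<int> Y((n + 1) * (m + 1), NEG);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0;
  for (int i = 1; i <= n; ++i) X[IDX(i, 0)] = -(gap_open + i * gap_extend);
  for (int j = 1; j <= m; ++j) Y[IDX(0, j)] = -(gap_open + j * gap_extend);

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int s = col_score(tmpl[i - 1], clone[j - 1], match, mismatch);
      int dM = M[IDX(i - 1, j - 1)], dX = X[IDX(i - 1, j - 1)], dY = Y[IDX(i - 1, j - 1)];
      int best = dM;
      if (dX > best) best = dX;
      if (dY > best) best = dY;
      M[IDX(i, j)] = (best <= NEG) ? NEG : best + s;

      int uM = M[IDX(i - 1, j)], uX = X[IDX(i - 1, j)], uY = Y[IDX(i - 1, j)];
      int xo = (uM <= NEG) ? NEG : uM - (gap_open + gap_extend);
      int xe = (uX <= NEG) ? NEG : uX - gap_extend;
      int xy = (uY <= NEG) ? NEG : uY - (gap_open + gap_extend);
      int xb = xo;
      if (xe > xb) xb = xe;
      if (xy > xb) xb = xy;
      X[IDX(i, j)] = xb;

      int lM = M[IDX(i, j - 1)], lX = X[IDX(i, j - 1)], lY = Y[IDX(i, j - 1)];
      int yo = (lM <= NEG) ? NEG : lM - (gap_open + gap_extend);
      int yx = (lX <= NEG) ? NEG : lX - (gap_open + gap_extend);
      int ye = (lY <= NEG) ? NEG : lY - gap_extend;
      int yb = yo;
      if (yx > yb) yb = yx;
      if (ye > yb) yb = ye;
      Y[IDX(i, j)] = yb;
    }
  }

  int fM = M[IDX(n, m)], fX = X[IDX(n, m)], fY = Y[IDX(n, m)];
  int score = fM, state = 0;          // 0 = M, 1 = X, 2 = Y; prefer M > X > Y
  if (fX > score) { score = fX; state = 1; }
  if (fY > score) { score = fY; state = 2; }

  std::string at, ac;
  at.reserve(n + m);
  ac.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      // column (tmpl[i-1], clone[j-1]); predecessor is the max at (i-1, j-1)
      int s = col_score(tmpl[i - 1], clone[j - 1], match, mismatch);
      at.push_back(tmpl[i - 1]);
      ac.push_back(clone[j - 1]);
      int cur = M[IDX(i, j)];
      --i; --j;
      if (i == 0 && j == 0) break;
      if (M[IDX(i, j)] + s == cur) state = 0;
      else if (X[IDX(i, j)] + s == cur) state = 1;
      else state = 2;
    } else if (state == 1) {
      at.push_back(tmpl[i - 1]);
      ac.push_back('-');
      int cur = X[IDX(i, j)];
      --i;
      if (i == 0 && j == 0) break;
      if (M[IDX(i, j)] - (gap_open + gap_extend) == cur) state = 0;
      else if (X[IDX(i, j)] - gap_extend == cur) state = 1;
      else state = 2;
    } else {
      at.push_back('-');
      ac.push_back(clone[j - 1]);
      int cur = Y[IDX(i, j)];
      --j;
      if (i == 0 && j == 0) break;
      if (M[IDX(i, j)] - (gap_open + gap_extend) == cur) state = 0;
      else if (Y[IDX(i, j)] - gap_extend == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(at.begin(), at.end());
  std::reverse(ac.begin(), ac.end());
#undef IDX

  return List::create(_["aligned_template"] = at,
                      _["aligned_clone"] = ac,
                      _["score"] = score);
}

// Exhaustive-enumeration optimum used as an independent oracle in tests.
// Recursively walks every monotone gapped pairing of the two sequences
// (no dynamic-programming state reuse) carrying only the previous move so
// affine gap runs are charged correctly.
static int brute_rec(const std::string& a, const std::string& b,
                     int i, int j, int last,
                     int match, int mismatch, int gap_open, int gap_extend) {
  const int n = (int) a.size(), m = (int) b.size();
  if (i == n && j == m) return 0;
  int best = NEG;
  if (i < n && j < m) {
    int v = col_score(a[i], b[j], match, mismatch) +
            brute_rec(a, b, i + 1, j + 1, 0, match, mismatch, gap_open, gap_extend);
    if (v > best) best = v;
  }
  if (i < n) {
    int cost = (last == 1) ? gap_extend : gap_open + gap_extend;
    int v = -cost + brute_rec(a, b, i + 1, j, 1, match, mismatch, gap_open, gap_extend);
    if (v > best) best = v;
  }
  if (j < m) {
    int cost = (last == 2) ? gap_extend : gap_open + gap_extend;
    int v = -cost + brute_rec(a, b, i, j + 1, 2, match, mismatch, gap_open, gap_extend);
    if (v > best) best = v;
  }
  return best;
}

// [[Rcpp::export]]
int brute_force_align_score_cpp(std::string a, std::string b,
                                int match, int mismatch,
                                int gap_open, int gap_extend) {
  if (a.empty() || b.empty()) stop("sequences must be non-empty");
  return brute_rec(a, b, 0, 0, 0, match, mismatch, gap_open, gap_extend);
}
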