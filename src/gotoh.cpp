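#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Three-state affine-gap global alignment (Gotoh). States:
//   M: a[i] aligned to b[j]
//   X: a[i] aligned to a gap (vertical / "up")
//   Y: b[j] aligned to a gap (horizontal / "left")
// A gap run of length k costs open + (k-1) * ext; terminal runs cost 0
// when end_free. Tie-breaking is fixed: diagonal (M) beats up (X)
// beats left (Y), making the traceback deterministic.

static const double NEG = -std::numeric_limits<double>::infinity();

static inline double subst(char x, char y, double match, double mismatch) {
  if (x == 'N' || y == 'N') return 0.0;  // N scores neutral
  return (x == y) ? match : mismatch;
}

// pick best of (m, x, y) with preference M > X > Y on ties
static inline int argmax3(double m, double x, double y) {
  if (m >= x && m >= y) return 0;
  if (x >= y) return 1;
  return 2;
}

// [[Rcpp::export(name = ".gotoh_align")]]
List gotoh_align(std::string a, std::string b,
                 double match, double mismatch,
                 double gap_open, double gap_ext,
                 bool end_free) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int W = m + 1;
  std::vector<double> M((n + 1) * W, NEG), X((n + 1) * W, NEG),
      Y((n + 1) * W, NEG);
  // pointer codes: previous state 0=M, 1=X, 2=Y
  std::vector<signed char> pM((n + 1) * W, -1), pX((n + 1) * W, -1),
      pY((n + 1) * W, -1);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = end_free ? 0.0 : -(gap_open + (i - 1) * gap_ext);
    pX[i * W] = 1;
  }
  pX[W] = 0;  // first vertical step opens from the origin
  for (int j = 1; j <= m; ++j) {
    Y[j] = end_free ? 0.0 : -(gap_open + (j - 1) * gap_ext);
    pY[j] = 2;
  }
  pY[1] = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1),
                u = (i - 1) * W + j, l = i * W + (j - 1);
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      int k = argmax3(M[d], X[d], Y[d]);
      M[c] = (k == 0 ? M[d] : (k == 1 ? X[d] : Y[d])) + s;
      pM[c] = k;

      double fm = M[u] - gap_open, fx = X[u] - gap_ext,
             fy = Y[u] - gap_open;
      k = argmax3(fm, fx, fy);
      X[c] = (k == 0 ? fm : (k == 1 ? fx : fy));
      pX[c] = k;

      fm = M[l] - gap_open; fx = X[l] - gap_open; fy = Y[l] - gap_ext;
      k = argmax3(fm, fx, fy);
      Y[c] = (k == 0 ? fm : (k == 1 ? fx : fy));
      pY[c] = k;
    }
  }

  // choose end cell; with free end gaps the unaligned tail of either
  // sequence is appended as a zero-cost terminal gap run
  int ei = n, ej = m;
  int estate = argmax3(M[n * W + m], X[n * W + m], Y[n * W + m]);
  double best = std::max(M[n * W + m],
                         std::max(X[n * W + m], Y[n * W + m]));
  if (end_free) {
    for (int i = n - 1; i >= 0; --i) {
      int c = i * W + m;
      int k = argmax3(M[c], X[c], Y[c]);
      double v = std::max(M[c], std::max(X[c], Y[c]));
      if (v > best) { best = v; ei = i; ej = m; estate = k; }
    }
    for (int j = m - 1; j >= 0; --j) {
      int c = n * W + j;
      int k = argmax3(M[c], X[c], Y[c]);
      double v = std::max(M[c], std::max(X[c], Y[c]));
      if (v > best) { best = v; ei = n; ej = j; estate = k; }
    }
  }

  std::string ra, rb;
  for (int i = n; i > ei; --i) { ra.push_back(a[i - 1]); rb.push_back('-'); }
  for (int j = m; j > ej; --j) { ra.push_back('-'); rb.push_back(b[j - 1]); }

  int i = ei, j = ej, st = estate;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (st == 0) {
      if (i == 0 && j == 0) break;
      ra.push_back(a[i - 1]); rb.push_back(b[j - 1]);
      st = pM[c]; --i; --j;
    } else if (st == 1) {
      ra.push_back(a[i - 1]); rb.push_back('-');
      st = pX[c]; --i;
    } else {
      ra.push_back('-'); rb.push_back(b[j - 1]);
      st = pY[c]; --j;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  return List::create(_["score"] = best,
                      _["aligned_a"] = ra,
                      _["aligned_b"] = rb);
}
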