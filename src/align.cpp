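#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Affine-gap Needleman-Wunsch (Gotoh three-state DP).
// A gap of length k costs gap_open + k * gap_extend (both penalties <= 0);
// setting gap_open = 0 recovers linear gap scoring.  End gaps are penalized
// (true global alignment).  Ties are broken deterministically by state
// preference M (diagonal) > X (gap in ref, consume query) > Y (gap in query).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".global_align_cpp")]]
List global_align_cpp(std::string query, std::string ref,
                      NumericMatrix sub, double gap_open, double gap_extend) {
  const int n = query.size(), m = ref.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");

  // residue -> row index of the substitution matrix
  std::vector<int> lut(256, -1);
  CharacterVector rn = rownames(sub);
  for (int i = 0; i < rn.size(); ++i) {
    std::string s = as<std::string>(rn[i]);
    if (s.size() == 1) lut[(unsigned char)s[0]] = i;
  }
  std::vector<int> qi(n), ri(m);
  for (int i = 0; i < n; ++i) {
    qi[i] = lut[(unsigned char)query[i]];
    if (qi[i] < 0) stop("query residue '%s' absent from substitution matrix",
                        std::string(1, query[i]));
  }
  for (int j = 0; j < m; ++j) {
    ri[j] = lut[(unsigned char)ref[j]];
    if (ri[j] < 0) stop("ref residue '%s' absent from substitution matrix",
                        std::string(1, ref[j]));
  }

  const size_t W = m + 1;
  std::vector<double> M((n + 1) * W, NEG_INF), X((n + 1) * W, NEG_INF),
      Y((n + 1) * W, NEG_INF);
  // traceback: which predecessor state fed each cell (0=M,1=X,2=Y)
  std::vector<unsigned char> pM((n + 1) * W), pX((n + 1) * W), pY((n + 1) * W);

  M[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[i * W] = gap_open + i * gap_extend;
    pX[i * W] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[j] = gap_open + j * gap_extend;
    pY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const size_t c = i * W + j, d = (i - 1) * W + (j - 1),
                   u = (i - 1) * W + j, l = i * W + (j - 1);
      // M: consume q[i-1] ~ r[j-1]
      double best = M[d];
      unsigned char bs = 0;
      if (X[d] > best) { best = X[d]; bs = 1; }
      if (Y[d] > best) { best = Y[d]; bs = 2; }
      M[c] = best + sub(qi[i - 1], ri[j - 1]);
      pM[c] = bs;
      // X: q[i-1] against a gap in ref
      double open = M[u] + gap_open + gap_extend, ext = X[u] + gap_extend;
      if (open >= ext) { X[c] = open; pX[c] = 0; }
      else             { X[c] = ext;  pX[c] = 1; }
      // Y: r[j-1] against a gap in query
      open = M[l] + gap_open + gap_extend; ext = Y[l] + gap_extend;
      if (open >= ext) { Y[c] = open; pY[c] = 0; }
      else             { Y[c] = ext;  pY[c] = 2; }
    }
  }

  const size_t end = n * W + m;
  double score = M[end];
  unsigned char state = 0;
  if (X[end] > score) { score = X[end]; state = 1; }
  if (Y[end] > score) { score = Y[end]; state = 2; }

  std::string aq, ar;
  aq.reserve(n + m); ar.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t c = i * W + j;
    if (state == 0) {
      aq.push_back(query[i - 1]); ar.push_back(ref[j - 1]);
      state = pM[c]; --i; --j;
    } else if (state == 1) {
      aq.push_back(query[i - 1]); ar.push_back('-');
      state = pX[c]; --i;
    } else {
      aq.push_back('-'); ar.push_back(ref[j - 1]);
      state = pY[c]; --j;
    }
  }
  std::reverse(aq.begin(), aq.end());
  std::reverse(ar.begin(), ar.end());

  return List::create(_["aligned_query"] = aq, _["aligned_ref"] = ar,
                      _["score"] = score);
}
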