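#include <Rcpp.h>
using namespace Rcpp;

// Global pairwise alignment with affine gap penalties (Gotoh three-state DP).
// States: M = a_i aligned to b_j, X = gap in `a` (consumes b), Y = gap in `b`
// (consumes a). Ties are broken M > X > Y everywhere, which realises the
// documented deterministic preference: match/mismatch over gap-in-a over
// gap-in-b. A gap run of length k costs open + k * extend (open and extend
// are supplied as non-positive numbers).

static inline int best3(double m, double x, double y, double &out) {
  // strict preference M > X > Y on ties
  int st = 0;
  out = m;
  if (x > out) { out = x; st = 1; }
  if (y > out) { out = y; st = 2; }
  return st;
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(std::string a, std::string b, NumericMatrix sub,
                  CharacterVector alphabet, double gap_open,
                  double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e30;

  // residue -> row index of the substitution matrix
  std::vector<int> lut(256, -1);
  for (int k = 0; k < alphabet.size(); ++k) {
    std::string s = as<std::string>(alphabet[k]);
    lut[(unsigned char)s[0]] = k;
  }
  std::vector<int> ai(m), bi(n);
  for (int i = 0; i < m; ++i) {
    ai[i] = lut[(unsigned char)a[i]];
    if (ai[i] < 0) stop("residue '%s' (sequence a, position %d) not in substitution matrix",
                        std::string(1, a[i]), i + 1);
  }
  for (int j = 0; j < n; ++j) {
    bi[j] = lut[(unsigned char)b[j]];
    if (bi[j] < 0) stop("residue '%s' (sequence b, position %d) not in substitution matrix",
                        std::string(1, b[j]), j + 1);
  }

  const int W = n + 1;
  std::vector<double> M((m + 1) * W, NEG), X((m + 1) * W, NEG), Y((m + 1) * W, NEG);
  // traceback: predecessor state for each cell of each layer
  std::vector<signed char> pM((m + 1) * W, -1), pX((m + 1) * W, -1), pY((m + 1) * W, -1);

  M[0] = 0.0;
  for (int j = 1; j <= n; ++j) {
    X[j] = gap_open + j * gap_extend;
    pX[j] = 1;
  }
  for (int i = 1; i <= m; ++i) {
    Y[i * W] = gap_open + i * gap_extend;
    pY[i * W] = 2;
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int c = i * W + j, d = (i - 1) * W + (j - 1), u = (i - 1) * W + j,
                l = i * W + (j - 1);
      double s = sub(ai[i - 1], bi[j - 1]), v;
      pM[c] = (signed char)best3(M[d], X[d], Y[d], v);
      M[c] = v + s;
      pX[c] = (signed char)best3(M[l] + gap_open + gap_extend,
                                 X[l] + gap_extend,
                                 Y[l] + gap_open + gap_extend, v);
      X[c] = v;
      pY[c] = (signed char)best3(M[u] + gap_open + gap_extend,
                                 X[u] + gap_open + gap_extend,
                                 Y[u] + gap_extend, v);
      Y[c] = v;
    }
  }

  double score;
  int state = best3(M[m * W + n], X[m * W + n], Y[m * W + n], score);

  std::string ra, rb;
  ra.reserve(m + n);
  rb.reserve(m + n);
  int i = m, j = n;
  while (i > 0 || j > 0) {
    const int c = i * W + j;
    if (state == 0) {
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      state = pM[c];
      --i; --j;
    } else if (state == 1) {
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      state = pX[c];
      --j;
    } else {
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      state = pY[c];
      --i;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());

  int matches = 0;
  for (size_t k = 0; k < ra.size(); ++k)
    if (ra[k] == rb[k] && ra[k] != '-') ++matches;

  return List::create(_["aligned_a"] = ra, _["aligned_b"] = rb,
                      _["score"] = score,
                      _["identity"] = ra.empty() ? 0.0 : (double)matches / ra.size());
}
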