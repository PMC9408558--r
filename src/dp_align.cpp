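#include <Rcpp.h>
using namespace Rcpp;

// Semi-global Needleman-Wunsch used by the TM-score-maximising aligner.
// The similarity S[i][j] = 1/(1+(d_ij/d0)^2) is computed on the fly from
// the superposed query coordinates P (n x 3) and reference Q (m x 3), so
// no n x m matrix crosses the R/C++ boundary per iteration. Affine gaps
// with an opening penalty only (extension free), terminal gaps free.
//
// Returns a 2-column 1-based matrix of matched (query, reference) indices.
// [[Rcpp::export(name = ".dp_align_cpp")]]
IntegerMatrix dp_align_cpp(NumericMatrix P, NumericMatrix Q, double d0,
                           double gap_open) {
  const int n = P.nrow(), m = Q.nrow();
  const double NEG = -1e30, inv_d02 = 1.0 / (d0 * d0);
  std::vector<double> S((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    const double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    for (int j = 0; j < m; ++j) {
      const double dx = px - Q(j, 0), dy = py - Q(j, 1), dz = pz - Q(j, 2);
      S[(size_t)i * m + j] =
          1.0 / (1.0 + (dx * dx + dy * dy + dz * dz) * inv_d02);
    }
  }
  // states: 0 = match (M), 1 = gap in reference (X, consumes query),
  //         2 = gap in query (Y, consumes reference)
  const size_t sz = (size_t)(n + 1) * (m + 1);
  std::vector<double> M(sz, NEG), X(sz, NEG), Y(sz, NEG);
  std::vector<unsigned char> ptrM(sz, 0), ptrX(sz, 0), ptrY(sz, 0);
  auto at = [m](int i, int j) { return (size_t)i * (m + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = 0.0;  // leading query gap free
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = 0.0;  // leading ref gap free
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double a = M[at(i - 1, j - 1)], b = X[at(i - 1, j - 1)],
             c = Y[at(i - 1, j - 1)];
      double best = a; unsigned char p = 0;
      if (b > best) { best = b; p = 1; }
      if (c > best) { best = c; p = 2; }
      M[at(i, j)] = best + S[(size_t)(i - 1) * m + (j - 1)];
      ptrM[at(i, j)] = p;
      double openx = M[at(i - 1, j)] + gap_open, extx = X[at(i - 1, j)];
      if (openx >= extx) { X[at(i, j)] = openx; ptrX[at(i, j)] = 0; }
      else              { X[at(i, j)] = extx;  ptrX[at(i, j)] = 1; }
      double openy = M[at(i, j - 1)] + gap_open, exty = Y[at(i, j - 1)];
      if (openy >= exty) { Y[at(i, j)] = openy; ptrY[at(i, j)] = 0; }
      else               { Y[at(i, j)] = exty;  ptrY[at(i, j)] = 2; }
    }
  }
  // free terminal gaps: best match cell on the last row/column
  double best = M[at(n, m)]; int bi = n, bj = m, bs = 0;
  if (X[at(n, m)] > best) { best = X[at(n, m)]; bs = 1; }
  if (Y[at(n, m)] > best) { best = Y[at(n, m)]; bs = 2; }
  for (int i = 1; i <= n; ++i)
    if (M[at(i, m)] > best) { best = M[at(i, m)]; bi = i; bj = m; bs = 0; }
  for (int j = 1; j <= m; ++j)
    if (M[at(n, j)] > best) { best = M[at(n, j)]; bi = n; bj = j; bs = 0; }
  // traceback (collected in reverse)
  std::vector<int> qi, rj;
  int i = bi, j = bj, s = bs;
  while (i > 0 || j > 0) {
    if (s == 0) {
      if (i == 0 || j == 0) break;
      qi.push_back(i); rj.push_back(j);
      s = ptrM[at(i, j)]; --i; --j;
    } else if (s == 1) {
      if (i == 0) { s = 0; continue; }
      s = ptrX[at(i, j)]; --i;
    } else {
      if (j == 0) { s = 0; continue; }
      s = ptrY[at(i, j)]; --j;
    }
  }
  const int k = (int)qi.size();
  IntegerMatrix out(k, 2);
  for (int r = 0; r < k; ++r) {
    out(r, 0) = qi[k - 1 - r];
    out(r, 1) = rj[k - 1 - r];
  }
  colnames(out) = CharacterVector::create("query", "reference");
  return out;
}
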