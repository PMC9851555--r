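#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment in the Gotoh three-state formulation.
// A gap of length k costs gap_open + k * gap_extend (BLAST convention,
// so defaults 11/1 price a length-1 gap at 12).
//
// Sequences arrive as 0-based integer codes into the substitution matrix;
// the wrapper on the R side owns the residue <-> code mapping.

static const double NEG_INF = -1e30;

// traceback codes
enum { FROM_NONE = 0, FROM_M = 1, FROM_IX = 2, FROM_IY = 3, FROM_ZERO = 4 };

// [[Rcpp::export]]
List align_pair_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                    double gap_open, double gap_extend, bool local) {
  const int n = a.size(), m = b.size();
  const double open_cost = gap_open + gap_extend;

  // DP matrices, (n+1) x (m+1), row-major
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF); // gap in b (consumes a)
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF); // gap in a (consumes b)
  std::vector<unsigned char> tM((n + 1) * (m + 1), FROM_NONE);
  std::vector<unsigned char> tIx((n + 1) * (m + 1), FROM_NONE);
  std::vector<unsigned char> tIy((n + 1) * (m + 1), FROM_NONE);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    if (local) {
      M[at(i, 0)] = 0.0;
      tM[at(i, 0)] = FROM_ZERO;
    } else {
      Ix[at(i, 0)] = -(gap_open + i * gap_extend);
      tIx[at(i, 0)] = (i == 1) ? FROM_M : FROM_IX;
    }
  }
  for (int j = 1; j <= m; ++j) {
    if (local) {
      M[at(0, j)] = 0.0;
      tM[at(0, j)] = FROM_ZERO;
    } else {
      Iy[at(0, j)] = -(gap_open + j * gap_extend);
      tIy[at(0, j)] = (j == 1) ? FROM_M : FROM_IY;
    }
  }

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = S(a[i - 1], b[j - 1]);
      // M
      double dM = M[at(i - 1, j - 1)], dIx = Ix[at(i - 1, j - 1)],
             dIy = Iy[at(i - 1, j - 1)];
      double mval;
      unsigned char mtr;
      if (dM >= dIx && dM >= dIy) { mval = dM; mtr = FROM_M; }
      else if (dIx >= dIy)        { mval = dIx; mtr = FROM_IX; }
      else                        { mval = dIy; mtr = FROM_IY; }
      mval += s;
      if (local && mval < 0.0) { mval = 0.0; mtr = FROM_ZERO; }
      M[at(i, j)] = mval;
      tM[at(i, j)] = mtr;
      // Ix: gap in b
      double oM = M[at(i - 1, j)] - open_cost;
      double oX = Ix[at(i - 1, j)] - gap_extend;
      if (oM >= oX) { Ix[at(i, j)] = oM; tIx[at(i, j)] = FROM_M; }
      else          { Ix[at(i, j)] = oX; tIx[at(i, j)] = FROM_IX; }
      // Iy: gap in a
      double pM = M[at(i, j - 1)] - open_cost;
      double pY = Iy[at(i, j - 1)] - gap_extend;
      if (pM >= pY) { Iy[at(i, j)] = pM; tIy[at(i, j)] = FROM_M; }
      else          { Iy[at(i, j)] = pY; tIy[at(i, j)] = FROM_IY; }

      if (local && M[at(i, j)] > best) {
        best = M[at(i, j)];
        best_i = i;
        best_j = j;
      }
    }
  }

  int i, j, state;
  double score;
  if (local) {
    score = best;
    i = best_i;
    j = best_j;
    state = FROM_M;
  } else {
    double eM = M[at(n, m)], eX = Ix[at(n, m)], eY = Iy[at(n, m)];
    if (eM >= eX && eM >= eY) { score = eM; state = FROM_M; }
    else if (eX >= eY)        { score = eX; state = FROM_IX; }
    else                      { score = eY; state = FROM_IY; }
    i = n;
    j = m;
  }

  std::vector<int> pa, pb; // 1-based positions, NA encoded as 0
  while (true) {
    if (local) {
      if (state == FROM_M && tM[at(i, j)] == FROM_ZERO) break;
      if (i == 0 && j == 0) break;
    } else {
      if (i == 0 && j == 0) break;
    }
    if (state == FROM_M) {
      unsigned char tr = tM[at(i, j)];
      pa.push_back(i);
      pb.push_back(j);
      --i; --j;
      state = (tr == FROM_ZERO) ? FROM_M : tr;
      if (local && tr == FROM_ZERO) break;
    } else if (state == FROM_IX) {
      unsigned char tr = tIx[at(i, j)];
      pa.push_back(i);
      pb.push_back(0);
      --i;
      state = tr;
    } else { // FROM_IY
      unsigned char tr = tIy[at(i, j)];
      pa.push_back(0);
      pb.push_back(j);
      --j;
      state = tr;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  IntegerVector ra(pa.size()), rb(pb.size());
  for (size_t k = 0; k < pa.size(); ++k) {
    ra[k] = pa[k] == 0 ? NA_INTEGER : pa[k];
    rb[k] = pb[k] == 0 ? NA_INTEGER : pb[k];
  }
  return List::create(_["score"] = score, _["a_pos"] = ra, _["b_pos"] = rb);
}

// Profile-profile global alignment for the progressive MSA.
// Profiles are nsym x L column-frequency matrices (frequencies over
// non-gap symbols, normalised by total row count so gappy columns carry
// less weight). Column-column score is the average-of-pairs score
// sum_ab f1[a] f2[b] S[a,b], computed via a precomputed S %*% P2.
// [[Rcpp::export]]
List align_profiles_cpp(NumericMatrix P1, NumericMatrix P2, NumericMatrix S,
                        double gap_open, double gap_extend) {
  const int n = P1.ncol(), m = P2.ncol(), nsym = P1.nrow();
  const double open_cost = gap_open + gap_extend;

  // SP2[a, j] = sum_b S[a,b] * P2[b,j]
  NumericMatrix SP2(nsym, m);
  for (int j = 0; j < m; ++j)
    for (int a = 0; a < nsym; ++a) {
      double acc = 0.0;
      for (int b = 0; b < nsym; ++b) acc += S(a, b) * P2(b, j);
      SP2(a, j) = acc;
    }
  auto colscore = [&](int i, int j) {
    double acc = 0.0;
    for (int a = 0; a < nsym; ++a)
      if (P1(a, i) != 0.0) acc += P1(a, i) * SP2(a, j);
    return acc;
  };

  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Ix((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Iy((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> tM((n + 1) * (m + 1), FROM_NONE);
  std::vector<unsigned char> tIx((n + 1) * (m + 1), FROM_NONE);
  std::vector<unsigned char> tIy((n + 1) * (m + 1), FROM_NONE);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    Ix[at(i, 0)] = -(gap_open + i * gap_extend);
    tIx[at(i, 0)] = (i == 1) ? FROM_M : FROM_IX;
  }
  for (int j = 1; j <= m; ++j) {
    Iy[at(0, j)] = -(gap_open + j * gap_extend);
    tIy[at(0, j)] = (j == 1) ? FROM_M : FROM_IY;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const double s = colscore(i - 1, j - 1);
      double dM = M[at(i - 1, j - 1)], dIx = Ix[at(i - 1, j - 1)],
             dIy = Iy[at(i - 1, j - 1)];
      if (dM >= dIx && dM >= dIy) { M[at(i, j)] = dM + s; tM[at(i, j)] = FROM_M; }
      else if (dIx >= dIy)        { M[at(i, j)] = dIx + s; tM[at(i, j)] = FROM_IX; }
      else                        { M[at(i, j)] = dIy + s; tM[at(i, j)] = FROM_IY; }
      double oM = M[at(i - 1, j)] - open_cost;
      double oX = Ix[at(i - 1, j)] - gap_extend;
      if (oM >= oX) { Ix[at(i, j)] = oM; tIx[at(i, j)] = FROM_M; }
      else          { Ix[at(i, j)] = oX; tIx[at(i, j)] = FROM_IX; }
      double pM = M[at(i, j - 1)] - open_cost;
      double pY = Iy[at(i, j - 1)] - gap_extend;
      if (pM >= pY) { Iy[at(i, j)] = pM; tIy[at(i, j)] = FROM_M; }
      else          { Iy[at(i, j)] = pY; tIy[at(i, j)] = FROM_IY; }
    }
  }

  double eM = M[at(n, m)], eX = Ix[at(n, m)], eY = Iy[at(n, m)];
  int state;
  double score;
  if (eM >= eX && eM >= eY) { score = eM; state = FROM_M; }
  else if (eX >= eY)        { score = eX; state = FROM_IX; }
  else                      { score = eY; state = FROM_IY; }

  int i = n, j = m;
  std::vector<int> pa, pb;
  while (i > 0 || j > 0) {
    if (state == FROM_M) {
      unsigned char tr = tM[at(i, j)];
      pa.push_back(i); pb.push_back(j);
      --i; --j;
      state = tr;
    } else if (state == FROM_IX) {
      unsigned char tr = tIx[at(i, j)];
      pa.push_back(i); pb.push_back(0);
      --i;
      state = tr;
    } else {
      unsigned char tr = tIy[at(i, j)];
      pa.push_back(0); pb.push_back(j);
      --j;
      state = tr;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  IntegerVector ra(pa.size()), rb(pb.size());
  for (size_t k = 0; k < pa.size(); ++k) {
    ra[k] = pa[k] == 0 ? NA_INTEGER : pa[k];
    rb[k] = pb[k] == 0 ? NA_INTEGER : pb[k];
  }
  return List::create(_["score"] = score, _["a_pos"] = ra, _["b_pos"] = rb);
}
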