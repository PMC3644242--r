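#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap alignment of a peptide against a position-specific scoring
// model. Columns carry their own deletion penalties so an optional
// insertion slot (zero-cost deletion column) can sit inside the model.
// mode: 0 = local (Smith-Waterman, used for domain scanning),
//       1 = global (Needleman-Wunsch over both),
//       2 = glocal (peptide fully aligned, model end columns free to
//           skip; used for anchoring and hit refinement).
//
// pep: 1-based residue codes into the score rows; 0 = masked/unknown
// (scores a fixed penalty so masked stretches cannot re-match).

static const double MASK_SCORE = -4.0;
static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List profile_align_cpp(IntegerVector pep, NumericMatrix scores,
                       NumericVector del_open, NumericVector del_ext,
                       double ins_open, double ins_ext, int mode) {
  const int n = pep.size();
  const int C = scores.ncol();

  NumericMatrix M(n + 1, C + 1), D(n + 1, C + 1), I(n + 1, C + 1);
  IntegerMatrix pM(n + 1, C + 1), pD(n + 1, C + 1), pI(n + 1, C + 1);
  const bool local = (mode == 0);
  const bool glocal = (mode == 2);

  for (int j = 0; j <= C; ++j) { M(0, j) = NEG_INF; I(0, j) = NEG_INF; }
  for (int i = 0; i <= n; ++i) {
    M(i, 0) = NEG_INF; D(i, 0) = NEG_INF;
    I(i, 0) = NEG_INF;
  }
  if (local || glocal) {
    // row-0 deletion states unused: alignments start inside the model
    for (int j = 0; j <= C; ++j) D(0, j) = NEG_INF;
    if (glocal) {
      for (int i = 1; i <= n; ++i) {
        double fromM = M(i - 1, 0) - ins_open;
        double fromI = I(i - 1, 0) - ins_ext;
        if (i == 1) { I(i, 0) = -ins_open; pI(i, 0) = 1; }
        else if (fromM >= fromI) { I(i, 0) = fromM; pI(i, 0) = 1; }
        else { I(i, 0) = fromI; pI(i, 0) = 3; }
      }
    }
  } else {
    M(0, 0) = 0.0;
    for (int j = 1; j <= C; ++j) {
      double fromM = M(0, j - 1) - del_open[j - 1];
      double fromD = D(0, j - 1) - del_ext[j - 1];
      if (j == 1) { D(0, j) = fromM; pD(0, j) = 1; }
      else if (fromM >= fromD) { D(0, j) = fromM; pD(0, j) = 1; }
      else { D(0, j) = fromD; pD(0, j) = 2; }
    }
    for (int i = 1; i <= n; ++i) {
      double fromM = M(i - 1, 0) - ins_open;
      double fromI = I(i - 1, 0) - ins_ext;
      if (i == 1) { I(i, 0) = fromM; pI(i, 0) = 1; }
      else if (fromM >= fromI) { I(i, 0) = fromM; pI(i, 0) = 1; }
      else { I(i, 0) = fromI; pI(i, 0) = 3; }
    }
  }

  double best = local ? 0.0 : NEG_INF;
  int bi = -1, bj = -1, bstate = 1;

  for (int i = 1; i <= n; ++i) {
    const int code = pep[i - 1];
    for (int j = 1; j <= C; ++j) {
      double s = (code > 0) ? scores(code - 1, j - 1) : MASK_SCORE;
      double dM = M(i - 1, j - 1), dD = D(i - 1, j - 1), dI = I(i - 1, j - 1);
      double m = dM; int pm = 1;
      if (dD > m) { m = dD; pm = 2; }
      if (dI > m) { m = dI; pm = 3; }
      if (local && 0.0 > m) { m = 0.0; pm = 0; }
      if (glocal && i == 1 && 0.0 > m) { m = 0.0; pm = 0; }
      M(i, j) = (m <= NEG_INF / 2) ? NEG_INF : m + s;
      pM(i, j) = pm;

      double fromM = M(i, j - 1) - del_open[j - 1];
      double fromD = D(i, j - 1) - del_ext[j - 1];
      if (fromM >= fromD) { D(i, j) = fromM; pD(i, j) = 1; }
      else { D(i, j) = fromD; pD(i, j) = 2; }

      double iM = M(i - 1, j) - ins_open;
      double iI = I(i - 1, j) - ins_ext;
      if (iM >= iI) { I(i, j) = iM; pI(i, j) = 1; }
      else { I(i, j) = iI; pI(i, j) = 3; }

      if (local && M(i, j) > best) {
        best = M(i, j); bi = i; bj = j; bstate = 1;
      }
    }
  }

  if (glocal) {
    best = NEG_INF; bi = n;
    for (int j = 1; j <= C; ++j) {
      if (M(n, j) > best) { best = M(n, j); bj = j; bstate = 1; }
      if (I(n, j) > best) { best = I(n, j); bj = j; bstate = 3; }
    }
  } else if (!local) {
    best = M(n, C); bstate = 1; bi = n; bj = C;
    if (D(n, C) > best) { best = D(n, C); bstate = 2; }
    if (I(n, C) > best) { best = I(n, C); bstate = 3; }
  }

  std::vector<int> path_i, path_j;
  if ((local && bi >= 0) || (!local && best > NEG_INF / 2)) {
    int i = local ? bi : n, j = (local || glocal) ? bj : C, st = bstate;
    while (!(i == 0 && j == 0)) {
      int prev;
      if (st == 1) {
        prev = pM(i, j);
        path_i.push_back(i); path_j.push_back(j);
        --i; --j;
        if ((local || glocal) && prev == 0) break;   // alignment start
      } else if (st == 2) {
        prev = pD(i, j);
        path_i.push_back(0); path_j.push_back(j);
        --j;
      } else {
        prev = pI(i, j);
        path_i.push_back(i); path_j.push_back(0);
        --i;
      }
      st = prev;
    }
    std::reverse(path_i.begin(), path_i.end());
    std::reverse(path_j.begin(), path_j.end());
  }

  return List::create(_["score"] = best,
                      _["path_i"] = wrap(path_i),
                      _["path_j"] = wrap(path_j));
}
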