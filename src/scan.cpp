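#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Glocal scan of an amino-acid sequence against a position-specific scoring
// model: global in the profile (every column matched or deleted), local in
// the sequence.  Emission scores are log-odds in bits; gaps are affine.
// seq holds 0-based indices into the emission columns' alphabet; the last
// alphabet slot is the neutral "other" class (X / *).  Returns all
// non-overlapping segments scoring >= threshold, best first, with the
// number of profile columns actually matched (for coverage).
//
// [[Rcpp::export(name = ".scan_pssm_cpp")]]
DataFrame scan_pssm_cpp(IntegerVector seq, NumericMatrix emis,
                        double gap_open, double gap_extend,
                        double threshold) {
  const int n = seq.size();
  const int m = emis.nrow();
  const int A = emis.ncol();
  const double NEG = -1e30;

  // flat column-major copy: E[a * m + (j-1)], unit stride over j
  std::vector<double> E(emis.begin(), emis.end());

  // previous row (i-1) and current row (i) buffers for states M, I, D,
  // plus parallel origin (segment start in seq) and match-count buffers
  std::vector<double> Mp(m + 1, NEG), Ip(m + 1, NEG), Dp(m + 1, NEG);
  std::vector<double> Mc(m + 1, NEG), Ic(m + 1, NEG), Dc(m + 1, NEG);
  std::vector<int> oMp(m + 1, -1), oIp(m + 1, -1), oDp(m + 1, -1);
  std::vector<int> oMc(m + 1, -1), oIc(m + 1, -1), oDc(m + 1, -1);
  std::vector<int> cMp(m + 1, 0), cIp(m + 1, 0), cDp(m + 1, 0);
  std::vector<int> cMc(m + 1, 0), cIc(m + 1, 0), cDc(m + 1, 0);

  std::vector<int> cand_start, cand_end, cand_cnt;
  std::vector<double> cand_score;

  for (int i = 1; i <= n; ++i) {
    const int a = seq[i - 1];
    if (a < 0 || a >= A) stop("residue index out of range");
    const double *Ea = &E[(size_t)a * m];
    for (int j = 1; j <= m; ++j) {
      // M(i,j): match column j to residue i-1; predecessors at (i-1, j-1),
      // or a fresh start when j == 1 (sequence-local)
      double best; int orig, cnt;
      if (j == 1) {
        best = 0.0; orig = i - 1; cnt = 0;
      } else {
        best = Mp[j - 1]; orig = oMp[j - 1]; cnt = cMp[j - 1];
        if (Ip[j - 1] > best) { best = Ip[j - 1]; orig = oIp[j - 1]; cnt = cIp[j - 1]; }
        if (Dp[j - 1] > best) { best = Dp[j - 1]; orig = oDp[j - 1]; cnt = cDp[j - 1]; }
      }
      Mc[j] = best + Ea[j - 1];
      oMc[j] = orig; cMc[j] = cnt + 1;

      // I(i,j): extra sequence residue sitting between columns j and j+1
      double iopen = Mp[j] - gap_open, iext = Ip[j] - gap_extend;
      if (iopen >= iext) { Ic[j] = iopen; oIc[j] = oMp[j]; cIc[j] = cMp[j]; }
      else { Ic[j] = iext; oIc[j] = oIp[j]; cIc[j] = cIp[j]; }

      // D(i,j): column j deleted; moves along the current row
      double dopen; int dorig, dcnt;
      if (j == 1) {
        dopen = -gap_open; dorig = i; dcnt = 0;  // leading deletion
      } else {
        dopen = Mc[j - 1] - gap_open; dorig = oMc[j - 1]; dcnt = cMc[j - 1];
      }
      if (j > 1 && Dc[j - 1] - gap_extend > dopen) {
        Dc[j] = Dc[j - 1] - gap_extend; oDc[j] = oDc[j - 1]; cDc[j] = cDc[j - 1];
      } else {
        Dc[j] = dopen; oDc[j] = dorig; cDc[j] = dcnt;
      }
    }
    // a segment can end wherever the last profile column is resolved
    double endscore = Mc[m]; int endo = oMc[m], endc = cMc[m];
    if (Dc[m] > endscore) { endscore = Dc[m]; endo = oDc[m]; endc = cDc[m]; }
    if (endscore >= threshold && endo >= 0 && i > endo) {
      cand_start.push_back(endo);
      cand_end.push_back(i);
      cand_score.push_back(endscore);
      cand_cnt.push_back(endc);
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
    std::swap(oMp, oMc); std::swap(oIp, oIc); std::swap(oDp, oDc);
    std::swap(cMp, cMc); std::swap(cIp, cIc); std::swap(cDp, cDc);
    std::fill(Mc.begin(), Mc.end(), NEG);
    std::fill(Ic.begin(), Ic.end(), NEG);
    std::fill(Dc.begin(), Dc.end(), NEG);
  }

  // greedy non-overlapping selection, best score first
  std::vector<int> idx(cand_start.size());
  for (size_t t = 0; t < idx.size(); ++t) idx[t] = (int)t;
  std::sort(idx.begin(), idx.end(), [&](int x, int y) {
    if (cand_score[x] != cand_score[y]) return cand_score[x] > cand_score[y];
    if (cand_start[x] != cand_start[y]) return cand_start[x] < cand_start[y];
    return cand_end[x] < cand_end[y];
  });
  std::vector<std::pair<int,int> > taken;
  std::vector<int> keep;
  for (size_t t = 0; t < idx.size(); ++t) {
    int c = idx[t];
    int s = cand_start[c], e = cand_end[c];
    bool free_ = true;
    for (size_t q = 0; q < taken.size(); ++q)
      if (s < taken[q].second && taken[q].first < e) { free_ = false; break; }
    if (free_) { taken.push_back(std::make_pair(s, e)); keep.push_back(c); }
  }
  IntegerVector rs(keep.size()), re(keep.size()), rc(keep.size());
  NumericVector rsc(keep.size());
  for (size_t t = 0; t < keep.size(); ++t) {
    rs[t] = cand_start[keep[t]];
    re[t] = cand_end[keep[t]];
    rsc[t] = cand_score[keep[t]];
    rc[t] = cand_cnt[keep[t]];
  }
  return DataFrame::create(_["aa_start"] = rs, _["aa_end"] = re,
                           _["score"] = rsc, _["matched"] = rc);
}

// Global (Gotoh) alignment of two sequence profiles for progressive
// multiple alignment.  Profiles are A x L column-frequency matrices over
// the residue alphabet (gap mass implicit).  The column score is the
// frequency-weighted expected substitution score; gap mass scores zero.
// Full traceback matrices are kept (profile lengths are modest), so the
// recovered path is exact.  Returns 1-based column indices with 0 = gap.
//
// [[Rcpp::export(name = ".align_profiles_cpp")]]
List align_profiles_cpp(NumericMatrix pa, NumericMatrix pb,
                        NumericMatrix submat, double gap_open,
                        double gap_extend) {
  const int A = pa.nrow();
  const int la = pa.ncol(), lb = pb.ncol();
  if (submat.nrow() != A || submat.ncol() != A)
    stop("substitution matrix does not match profile alphabet");
  const double NEG = -1e30;

  NumericMatrix S(la, lb);
  for (int i = 0; i < la; ++i)
    for (int j = 0; j < lb; ++j) {
      double s = 0.0;
      for (int a = 0; a < A; ++a) {
        double fa = pa(a, i);
        if (fa == 0.0) continue;
        for (int b = 0; b < A; ++b) {
          double fb = pb(b, j);
          if (fb != 0.0) s += fa * fb * submat(a, b);
        }
      }
      S(i, j) = s;
    }

  // state matrices and per-state traceback (predecessor state codes)
  std::vector<double> M((la + 1) * (lb + 1), NEG);
  std::vector<double> X((la + 1) * (lb + 1), NEG);  // gap in b (consume a)
  std::vector<double> Y((la + 1) * (lb + 1), NEG);  // gap in a (consume b)
  std::vector<signed char> tbM((la + 1) * (lb + 1), -1);
  std::vector<signed char> tbX((la + 1) * (lb + 1), -1);
  std::vector<signed char> tbY((la + 1) * (lb + 1), -1);
#define AT(i, j) ((i) * (lb + 1) + (j))

  M[AT(0, 0)] = 0.0;
  for (int i = 1; i <= la; ++i) {
    X[AT(i, 0)] = -gap_open - (i - 1) * gap_extend;
    tbX[AT(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= lb; ++j) {
    Y[AT(0, j)] = -gap_open - (j - 1) * gap_extend;
    tbY[AT(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= la; ++i) {
    for (int j = 1; j <= lb; ++j) {
      double m0 = M[AT(i - 1, j - 1)], x0 = X[AT(i - 1, j - 1)],
             y0 = Y[AT(i - 1, j - 1)];
      int st = 0; double best = m0;
      if (x0 > best) { best = x0; st = 1; }
      if (y0 > best) { best = y0; st = 2; }
      M[AT(i, j)] = best + S(i - 1, j - 1);
      tbM[AT(i, j)] = (signed char)st;

      double xo = std::max(M[AT(i - 1, j)], Y[AT(i - 1, j)]) - gap_open;
      double xe = X[AT(i - 1, j)] - gap_extend;
      if (xe > xo) { X[AT(i, j)] = xe; tbX[AT(i, j)] = 1; }
      else {
        X[AT(i, j)] = xo;
        tbX[AT(i, j)] = (M[AT(i - 1, j)] >= Y[AT(i - 1, j)]) ? 0 : 2;
      }
      double yo = std::max(M[AT(i, j - 1)], X[AT(i, j - 1)]) - gap_open;
      double ye = Y[AT(i, j - 1)] - gap_extend;
      if (ye > yo) { Y[AT(i, j)] = ye; tbY[AT(i, j)] = 2; }
      else {
        Y[AT(i, j)] = yo;
        tbY[AT(i, j)] = (M[AT(i, j - 1)] >= X[AT(i, j - 1)]) ? 0 : 1;
      }
    }
  }

  std::vector<int> ra, rb;
  int i = la, j = lb, state = 0;
  {
    double best = M[AT(i, j)];
    if (X[AT(i, j)] > best) { best = X[AT(i, j)]; state = 1; }
    if (Y[AT(i, j)] > best) { best = Y[AT(i, j)]; state = 2; }
  }
  while (i > 0 || j > 0) {
    if (state == 0) {
      ra.push_back(i); rb.push_back(j);
      state = tbM[AT(i, j)];
      --i; --j;
    } else if (state == 1) {
      ra.push_back(i); rb.push_back(0);
      state = tbX[AT(i, j)];
      --i;
    } else {
      ra.push_back(0); rb.push_back(j);
      state = tbY[AT(i, j)];
      --j;
    }
  }
#undef AT
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = wrap(ra), _["b"] = wrap(rb));
}
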