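#include <Rcpp.h>
#include <limits>
using namespace Rcpp;

// Affine gap model used throughout: a gap run of length k costs
// gap_open + (k - 1) * gap_extend (gap_open is the cost of the first
// gap character). Tie-breaking in traceback is fixed: diagonal, then
// up (gap in b), then left (gap in a), so results are reproducible.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double subst(char a, char b, double match, double mismatch) {
  return (a == b) ? match : mismatch;
}

// [[Rcpp::export(name = ".align_global_cpp")]]
List align_global_cpp(std::string a, std::string b,
                      double match, double mismatch,
                      double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  // M: both consumed; X: gap in b (consume a, "up"); Y: gap in a ("left")
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double dm = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = dm + s;
      X(i, j) = std::max(M(i - 1, j) + gap_open,
                std::max(X(i - 1, j) + gap_extend, Y(i - 1, j) + gap_open));
      Y(i, j) = std::max(M(i, j - 1) + gap_open,
                std::max(Y(i, j - 1) + gap_extend, X(i, j - 1) + gap_open));
    }
  }
  double best = std::max(M(n, m), std::max(X(n, m), Y(n, m)));
  // traceback; state 0 = M, 1 = X, 2 = Y; prefer diagonal > up > left
  std::string ga, gb;
  int i = n, j = m;
  int state = (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) ? 0 :
              (X(n, m) >= Y(n, m) ? 1 : 2);
  while (i > 0 || j > 0) {
    if (i == 0) { ga.push_back('-'); gb.push_back(b[--j]); continue; }
    if (j == 0) { ga.push_back(a[--i]); gb.push_back('-'); continue; }
    if (state == 0) {
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      double prev = M(i, j) - subst(a[i - 1], b[j - 1], match, mismatch);
      --i; --j;
      if (M(i, j) == prev) state = 0;
      else if (X(i, j) == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      ga.push_back(a[i - 1]); gb.push_back('-');
      double cur = X(i, j);
      --i;
      if (M(i, j) + gap_open == cur) state = 0;
      else if (X(i, j) + gap_extend == cur) state = 1;
      else state = 2;
    } else {
      ga.push_back('-'); gb.push_back(b[j - 1]);
      double cur = Y(i, j);
      --j;
      if (M(i, j) + gap_open == cur) state = 0;
      else if (Y(i, j) + gap_extend == cur) state = 2;
      else state = 1;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = best);
}

// [[Rcpp::export(name = ".align_local_cpp")]]
List align_local_cpp(std::string a, std::string b,
                     double match, double mismatch,
                     double gap_open, double gap_extend) {
  int n = a.size(), m = b.size();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = 0.0; X(i, j) = NEG_INF; Y(i, j) = NEG_INF; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = subst(a[i - 1], b[j - 1], match, mismatch);
      double dm = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = std::max(0.0, dm + s);
      X(i, j) = std::max(M(i - 1, j) + gap_open, X(i - 1, j) + gap_extend);
      Y(i, j) = std::max(M(i, j - 1) + gap_open, Y(i, j - 1) + gap_extend);
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  std::string ga, gb;
  int i = bi, j = bj, state = 0;
  int end_a = bi, end_b = bj;
  while (i > 0 && j > 0) {
    if (state == 0) {
      if (M(i, j) == 0.0) break;
      double prev = M(i, j) - subst(a[i - 1], b[j - 1], match, mismatch);
      ga.push_back(a[i - 1]); gb.push_back(b[j - 1]);
      --i; --j;
      if (M(i, j) == prev) state = 0;
      else if (X(i, j) == prev) state = 1;
      else state = 2;
    } else if (state == 1) {
      double cur = X(i, j);
      ga.push_back(a[i - 1]); gb.push_back('-');
      --i;
      if (M(i, j) + gap_open == cur) state = 0; else state = 1;
    } else {
      double cur = Y(i, j);
      ga.push_back('-'); gb.push_back(b[j - 1]);
      --j;
      if (M(i, j) + gap_open == cur) state = 0; else state = 2;
    }
  }
  std::reverse(ga.begin(), ga.end());
  std::reverse(gb.begin(), gb.end());
  return List::create(_["gapped_a"] = ga, _["gapped_b"] = gb,
                      _["score"] = best,
                      _["start_a"] = (best > 0.0) ? i + 1 : 0,
                      _["end_a"] = (best > 0.0) ? end_a : 0,
                      _["start_b"] = (best > 0.0) ? j + 1 : 0,
                      _["end_b"] = (best > 0.0) ? end_b : 0);
}

// Profile-profile global alignment for progressive MSA.
// Profiles are 4 x L matrices of A/C/G/T fractions per column (gaps and
// ambiguity codes contribute nothing). Column-pair score is the expected
// pairwise substitution score; gap penalties are plain affine on columns.
// Returns an op vector: 0 = consume both, 1 = consume A only (gap in B),
// 2 = consume B only (gap in A), in alignment order.
// [[Rcpp::export(name = ".align_profiles_cpp")]]
IntegerVector align_profiles_cpp(NumericMatrix pa, NumericMatrix pb,
                                 double match, double mismatch,
                                 double gap_open, double gap_extend) {
  int n = pa.ncol(), m = pb.ncol();
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { M(i, j) = NEG_INF; X(i, j) = NEG_INF; Y(i, j) = NEG_INF; }
  M(0, 0) = 0.0;
  for (int i = 1; i <= n; ++i) X(i, 0) = gap_open + (i - 1) * gap_extend;
  for (int j = 1; j <= m; ++j) Y(0, j) = gap_open + (j - 1) * gap_extend;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double same = 0.0, tota = 0.0, totb = 0.0;
      for (int k = 0; k < 4; ++k) {
        same += pa(k, i - 1) * pb(k, j - 1);
        tota += pa(k, i - 1);
        totb += pb(k, j - 1);
      }
      double s = same * match + (tota * totb - same) * mismatch;
      double dm = std::max(M(i - 1, j - 1), std::max(X(i - 1, j - 1), Y(i - 1, j - 1)));
      M(i, j) = dm + s;
      X(i, j) = std::max(M(i - 1, j) + gap_open,
                std::max(X(i - 1, j) + gap_extend, Y(i - 1, j) + gap_open));
      Y(i, j) = std::max(M(i, j - 1) + gap_open,
                std::max(Y(i, j - 1) + gap_extend, X(i, j - 1) + gap_open));
    }
  }
  std::vector<int> ops;
  int i = n, j = m;
  int state = (M(n, m) >= X(n, m) && M(n, m) >= Y(n, m)) ? 0 :
              (X(n, m) >= Y(n, m) ? 1 : 2);
  while (i > 0 || j > 0) {
    if (i == 0) { ops.push_back(2); --j; continue; }
    if (j == 0) { ops.push_back(1); --i; continue; }
    if (state == 0) {
      double same = 0.0, tota = 0.0, totb = 0.0;
      for (int k = 0; k < 4; ++k) {
        same += pa(k, i - 1) * pb(k, j - 1);
        tota += pa(k, i - 1);
        totb += pb(k, j - 1);
      }
      double s = same * match + (tota * totb - same) * mismatch;
      double prev = M(i, j) - s;
      ops.push_back(0); --i; --j;
      // tolerate fp noise in state recovery
      if (std::abs(M(i, j) - prev) < 1e-9) state = 0;
      else if (std::abs(X(i, j) - prev) < 1e-9) state = 1;
      else state = 2;
    } else if (state == 1) {
      double cur = X(i, j);
      ops.push_back(1); --i;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(X(i, j) + gap_extend - cur) < 1e-9) state = 1;
      else state = 2;
    } else {
      double cur = Y(i, j);
      ops.push_back(2); --j;
      if (std::abs(M(i, j) + gap_open - cur) < 1e-9) state = 0;
      else if (std::abs(Y(i, j) + gap_extend - cur) < 1e-9) state = 2;
      else state = 1;
    }
  }
  std::reverse(ops.begin(), ops.end());
  return wrap(ops);
}

// Pairwise transition/transversion counts over an integer-coded MSA.
// code: 1=A, 2=C, 3=G, 4=T, 0=gap/ambiguous. Returns three k x k
// matrices: P (transition proportion), Q (transversion proportion),
// L (effective sites); P/Q are NA when L = 0.
// [[Rcpp::export(name = ".pair_counts_cpp")]]
List pair_counts_cpp(IntegerMatrix msa) {
  int k = msa.nrow(), L = msa.ncol();
  NumericMatrix P(k, k), Q(k, k), eff(k, k);
  for (int i = 0; i < k; ++i) {
    for (int j = i + 1; j < k; ++j) {
      int l = 0, ts = 0, tv = 0;
      for (int c = 0; c < L; ++c) {
        int x = msa(i, c), y = msa(j, c);
        if (x == 0 || y == 0) continue;
        ++l;
        if (x == y) continue;
        // transitions: A<->G codes {1,3} sum 4; C<->T codes {2,4} sum 6;
        // no transversion pair shares these sums
        if (x + y == 4 || x + y == 6) ++ts; else ++tv;
      }
      eff(i, j) = eff(j, i) = l;
      if (l > 0) {
        P(i, j) = P(j, i) = (double)ts / l;
        Q(i, j) = Q(j, i) = (double)tv / l;
      } else {
        P(i, j) = P(j, i) = NA_REAL;
        Q(i, j) = Q(j, i) = NA_REAL;
      }
    }
  }
  return List::create(_["P"] = P, _["Q"] = Q, _["L"] = eff);
}

// ---- batch kernels ----------------------------------------------------
// Rolling-array DP over all sequence pairs, avoiding per-pair R overhead.

static std::vector<int> encode_acgt(const std::string &s) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': v[i] = 1; break;
      case 'C': v[i] = 2; break;
      case 'G': v[i] = 3; break;
      case 'T': v[i] = 4; break;
      default: v[i] = -(int)i - 10;  // unique negatives never match
    }
  }
  return v;
}

// Global affine alignment statistics for every pair: score, identity
// (matches / aligned columns on one optimal path, ties broken
// diagonal > up > left) and number of aligned (non-gap-pair) columns.
// [[Rcpp::export(name = ".global_stats_cpp")]]
List global_stats_cpp(std::vector<std::string> seqs, double match,
                      double mismatch, double gap_open,
                      double gap_extend) {
  int n = seqs.size();
  NumericMatrix score(n, n), ident(n, n), aligned(n, n);
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_acgt(seqs[i]);
  for (int i = 0; i < n; ++i) {
    ident(i, i) = 1.0;
    aligned(i, i) = seqs[i].size();
    score(i, i) = match * seqs[i].size();
  }
  for (int i = 0; i < n - 1; ++i) {
    const std::vector<int> &a = enc[i];
    for (int j = i + 1; j < n; ++j) {
      const std::vector<int> &b = enc[j];
      int la = a.size(), lb = b.size();
      // state arrays over columns of b for current/previous row of a
      std::vector<double> Ms(lb + 1), Xs(lb + 1), Ys(lb + 1);
      std::vector<double> pMs(lb + 1), pXs(lb + 1), pYs(lb + 1);
      std::vector<int> Mm(lb + 1), Xm(lb + 1), Ym(lb + 1);
      std::vector<int> pMm(lb + 1), pXm(lb + 1), pYm(lb + 1);
      std::vector<int> Ma(lb + 1), Xa(lb + 1), Ya(lb + 1);
      std::vector<int> pMa(lb + 1), pXa(lb + 1), pYa(lb + 1);
      for (int c = 0; c <= lb; ++c) {
        pMs[c] = (c == 0) ? 0.0 : NEG_INF;
        pXs[c] = NEG_INF;
        pYs[c] = (c == 0) ? NEG_INF : gap_open + (c - 1) * gap_extend;
        pMm[c] = pXm[c] = pYm[c] = 0;
        pMa[c] = pXa[c] = pYa[c] = 0;
      }
      for (int r = 1; r <= la; ++r) {
        Ms[0] = NEG_INF; Ys[0] = NEG_INF;
        Xs[0] = gap_open + (r - 1) * gap_extend;
        Mm[0] = Xm[0] = Ym[0] = 0;
        Ma[0] = Xa[0] = Ya[0] = 0;
        for (int c = 1; c <= lb; ++c) {
          bool eq = a[r - 1] == b[c - 1];
          double s = eq ? match : mismatch;
          // M from best of prev-diag states (pref M > X > Y)
          double bs = pMs[c - 1]; int bm = pMm[c - 1], ba = pMa[c - 1];
          if (pXs[c - 1] > bs) { bs = pXs[c - 1]; bm = pXm[c - 1]; ba = pXa[c - 1]; }
          if (pYs[c - 1] > bs) { bs = pYs[c - 1]; bm = pYm[c - 1]; ba = pYa[c - 1]; }
          Ms[c] = bs + s; Mm[c] = bm + (eq ? 1 : 0); Ma[c] = ba + 1;
          // X: gap in b (consume a): from previous row
          double xo = pMs[c] + gap_open, xe = pXs[c] + gap_extend,
                 xy = pYs[c] + gap_open;
          if (xo >= xe && xo >= xy) { Xs[c] = xo; Xm[c] = pMm[c]; Xa[c] = pMa[c]; }
          else if (xe >= xy) { Xs[c] = xe; Xm[c] = pXm[c]; Xa[c] = pXa[c]; }
          else { Xs[c] = xy; Xm[c] = pYm[c]; Xa[c] = pYa[c]; }
          // Y: gap in a (consume b): from current row, previous column
          double yo = Ms[c - 1] + gap_open, ye = Ys[c - 1] + gap_extend,
                 yx = Xs[c - 1] + gap_open;
          if (yo >= ye && yo >= yx) { Ys[c] = yo; Ym[c] = Mm[c - 1]; Ya[c] = Ma[c - 1]; }
          else if (ye >= yx) { Ys[c] = ye; Ym[c] = Xm[c - 1]; Ya[c] = Xa[c - 1]; }
          else { Ys[c] = yx; Ym[c] = Xm[c - 1]; Ya[c] = Xa[c - 1]; }
        }
        std::swap(Ms, pMs); std::swap(Xs, pXs); std::swap(Ys, pYs);
        std::swap(Mm, pMm); std::swap(Xm, pXm); std::swap(Ym, pYm);
        std::swap(Ma, pMa); std::swap(Xa, pXa); std::swap(Ya, pYa);
      }
      double bs = pMs[lb]; int bm = pMm[lb], ba = pMa[lb];
      if (pXs[lb] > bs) { bs = pXs[lb]; bm = pXm[lb]; ba = pXa[lb]; }
      if (pYs[lb] > bs) { bs = pYs[lb]; bm = pYm[lb]; ba = pYa[lb]; }
      score(i, j) = score(j, i) = bs;
      aligned(i, j) = aligned(j, i) = ba;
      double id = ba > 0 ? (double)bm / ba : NA_REAL;
      ident(i, j) = ident(j, i) = id;
    }
  }
  return List::create(_["score"] = score, _["identity"] = ident,
                      _["aligned"] = aligned);
}

// Smith-Waterman affine score (score only) for every sequence pair.
// [[Rcpp::export(name = ".local_scores_cpp")]]
NumericMatrix local_scores_cpp(std::vector<std::string> seqs, double match,
                               double mismatch, double gap_open,
                               double gap_extend) {
  int n = seqs.size();
  NumericMatrix score(n, n);
  std::vector<std::vector<int> > enc(n);
  for (int i = 0; i < n; ++i) enc[i] = encode_acgt(seqs[i]);
  for (int i = 0; i < n; ++i) score(i, i) = match * seqs[i].size();
  for (int i = 0; i < n - 1; ++i) {
    const std::vector<int> &a = enc[i];
    for (int j = i + 1; j < n; ++j) {
      const std::vector<int> &b = enc[j];
      int la = a.size(), lb = b.size();
      std::vector<double> Ms(lb + 1, 0.0), Xs(lb + 1, NEG_INF),
          Ys(lb + 1, NEG_INF);
      std::vector<double> pMs(lb + 1, 0.0), pXs(lb + 1, NEG_INF),
          pYs(lb + 1, NEG_INF);
      double best = 0.0;
      for (int r = 1; r <= la; ++r) {
        Ms[0] = 0.0; Xs[0] = NEG_INF; Ys[0] = NEG_INF;
        for (int c = 1; c <= lb; ++c) {
          double s = (a[r - 1] == b[c - 1]) ? match : mismatch;
          double dm = std::max(pMs[c - 1], std::max(pXs[c - 1], pYs[c - 1]));
          double m = dm + s;
          Ms[c] = m > 0.0 ? m : 0.0;
          Xs[c] = std::max(pMs[c] + gap_open, pXs[c] + gap_extend);
          Ys[c] = std::max(Ms[c - 1] + gap_open, Ys[c - 1] + gap_extend);
          if (Ms[c] > best) best = Ms[c];
        }
        std::swap(Ms, pMs); std::swap(Xs, pXs); std::swap(Ys, pYs);
      }
      score(i, j) = score(j, i) = best;
    }
  }
  return score;
}
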