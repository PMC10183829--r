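// Alignment kernels: affine-gap Smith-Waterman / Needleman-Wunsch,
// profile-profile alignment, PSSM local search, and a brute-force
// enumeration oracle used only for testing.
//
// Sequences arrive as 1-based integer codes into the 21-letter alphabet
// ACDEFGHIKLMNPQRSTVWYX; the scoring matrix is 21x21 with the X row/column
// zeroed. Gap convention throughout: a gap of length L costs
// gap_open + (L - 1) * gap_extend.

#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List sw_affine_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                   double gap_open, double gap_extend) {
  int n = q.size(), m = t.size();
  // M: alignment ends in match/mismatch; Iq: gap in target (consumes query);
  // It: gap in query (consumes target).
  NumericMatrix M(n + 1, m + 1), Iq(n + 1, m + 1), It(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbIq(n + 1, m + 1), tbIt(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { Iq(i, j) = NEG_INF; It(i, j) = NEG_INF; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(q[i - 1] - 1, t[j - 1] - 1);
      // tie-break order: diagonal (M) > up (Iq) > left (It); origin score 0
      // always means "start the alignment here" (restart, tb = 3).
      double dM = M(i - 1, j - 1), dIq = Iq(i - 1, j - 1), dIt = It(i - 1, j - 1);
      double from = dM; int tb = 0;
      if (dIq > from) { from = dIq; tb = 1; }
      if (dIt > from) { from = dIt; tb = 2; }
      if (from <= 0.0) { from = 0.0; tb = 3; }
      double v = from + s;
      if (v < 0.0) { v = 0.0; tb = 3; }
      M(i, j) = v; tbM(i, j) = tb;

      double openq = M(i - 1, j) - gap_open, extq = Iq(i - 1, j) - gap_extend;
      if (openq >= extq) { Iq(i, j) = openq; tbIq(i, j) = 0; }
      else               { Iq(i, j) = extq;  tbIq(i, j) = 1; }

      double opent = M(i, j - 1) - gap_open, extt = It(i, j - 1) - gap_extend;
      if (opent >= extt) { It(i, j) = opent; tbIt(i, j) = 0; }
      else               { It(i, j) = extt;  tbIt(i, j) = 2; }

      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> qa, ta;
  int i = bi, j = bj, state = 0; // 0 = M, 1 = Iq, 2 = It
  if (best > 0.0) {
    for (;;) {
      if (state == 0) {
        int tb = tbM(i, j);
        qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
        --i; --j;
        if (tb == 3) break;
        state = tb;
      } else if (state == 1) {
        int tb = tbIq(i, j);
        qa.push_back(q[i - 1]); ta.push_back(0);
        --i; state = tb;
      } else {
        int tb = tbIt(i, j);
        qa.push_back(0); ta.push_back(t[j - 1]);
        --j; state = tb;
      }
    }
    std::reverse(qa.begin(), qa.end());
    std::reverse(ta.begin(), ta.end());
  }
  int qstart = 0, qend = 0, tstart = 0, tend = 0;
  if (best > 0.0) {
    qend = bi; tend = bj;
    int nq = 0, nt = 0;
    for (size_t k = 0; k < qa.size(); ++k) { if (qa[k] > 0) ++nq; if (ta[k] > 0) ++nt; }
    qstart = bi - nq + 1; tstart = bj - nt + 1;
  }
  return List::create(_["score"] = best,
                      _["qstart"] = qstart, _["qend"] = qend,
                      _["tstart"] = tstart, _["tend"] = tend,
                      _["qaln"] = wrap(qa), _["taln"] = wrap(ta));
}

// Global affine alignment; returns aligned code vectors with 0 for gaps.
// [[Rcpp::export]]
List nw_affine_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                   double gap_open, double gap_extend) {
  int n = q.size(), m = t.size();
  NumericMatrix M(n + 1, m + 1), Iq(n + 1, m + 1), It(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbIq(n + 1, m + 1), tbIt(n + 1, m + 1);
  M(0, 0) = 0; Iq(0, 0) = NEG_INF; It(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; It(i, 0) = NEG_INF;
    Iq(i, 0) = -gap_open - (i - 1) * gap_extend; tbIq(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; Iq(0, j) = NEG_INF;
    It(0, j) = -gap_open - (j - 1) * gap_extend; tbIt(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = S(q[i - 1] - 1, t[j - 1] - 1);
      double dM = M(i - 1, j - 1), dIq = Iq(i - 1, j - 1), dIt = It(i - 1, j - 1);
      double from = dM; int tb = 0;
      if (dIq > from) { from = dIq; tb = 1; }
      if (dIt > from) { from = dIt; tb = 2; }
      M(i, j) = from + s; tbM(i, j) = tb;

      double openq = M(i - 1, j) - gap_open, extq = Iq(i - 1, j) - gap_extend;
      double altq = It(i - 1, j) - gap_open;
      if (altq > openq) openq = altq; // allow gap switch, still an opening
      if (openq >= extq) { Iq(i, j) = openq; tbIq(i, j) = 0; }
      else               { Iq(i, j) = extq;  tbIq(i, j) = 1; }

      double opent = M(i, j - 1) - gap_open, extt = It(i, j - 1) - gap_extend;
      double altt = Iq(i, j - 1) - gap_open;
      if (altt > opent) opent = altt;
      if (opent >= extt) { It(i, j) = opent; tbIt(i, j) = 0; }
      else               { It(i, j) = extt;  tbIt(i, j) = 2; }
    }
  }
  double sM = M(n, m), sIq = Iq(n, m), sIt = It(n, m);
  int state = 0; double score = sM;
  if (sIq > score) { score = sIq; state = 1; }
  if (sIt > score) { score = sIt; state = 2; }

  std::vector<int> qa, ta;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int tb = tbM(i, j);
      qa.push_back(q[i - 1]); ta.push_back(t[j - 1]);
      --i; --j; state = tb;
    } else if (state == 1) {
      int tb = tbIq(i, j);
      qa.push_back(q[i - 1]); ta.push_back(0);
      --i;
      // tb 0: opened from max(M, It); 1: extended within Iq
      state = (tb == 1) ? 1 : ((M(i, j) >= It(i, j)) ? 0 : 2);
    } else {
      int tb = tbIt(i, j);
      qa.push_back(0); ta.push_back(t[j - 1]);
      --j;
      if (tb == 0) state = (M(i, j) >= Iq(i, j)) ? 0 : 1;
      else state = 2;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(ta.begin(), ta.end());
  return List::create(_["score"] = score, _["qaln"] = wrap(qa), _["taln"] = wrap(ta));
}

// Profile-profile global alignment for progressive MSA construction.
// cs: La x Lb matrix of precomputed column cross scores
// sum_a sum_b fa(i,a) fb(j,b) S(a,b) (computed with BLAS on the R side).
// Returns the merge path as two integer vectors of column indices (0 = gap).
// [[Rcpp::export]]
List profile_nw_cpp(NumericMatrix cs, double gap_open, double gap_extend) {
  int n = cs.nrow(), m = cs.ncol();
  NumericMatrix M(n + 1, m + 1), Iq(n + 1, m + 1), It(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbIq(n + 1, m + 1), tbIt(n + 1, m + 1);
  M(0, 0) = 0; Iq(0, 0) = NEG_INF; It(0, 0) = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG_INF; It(i, 0) = NEG_INF;
    Iq(i, 0) = -gap_open - (i - 1) * gap_extend; tbIq(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG_INF; Iq(0, j) = NEG_INF;
    It(0, j) = -gap_open - (j - 1) * gap_extend; tbIt(0, j) = 2;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double dM = M(i - 1, j - 1), dIq = Iq(i - 1, j - 1), dIt = It(i - 1, j - 1);
      double from = dM; int tb = 0;
      if (dIq > from) { from = dIq; tb = 1; }
      if (dIt > from) { from = dIt; tb = 2; }
      M(i, j) = from + cs(i - 1, j - 1); tbM(i, j) = tb;

      double openq = std::max(M(i - 1, j), It(i - 1, j)) - gap_open;
      double extq = Iq(i - 1, j) - gap_extend;
      if (openq >= extq) { Iq(i, j) = openq; tbIq(i, j) = 0; }
      else               { Iq(i, j) = extq;  tbIq(i, j) = 1; }

      double opent = std::max(M(i, j - 1), Iq(i, j - 1)) - gap_open;
      double extt = It(i, j - 1) - gap_extend;
      if (opent >= extt) { It(i, j) = opent; tbIt(i, j) = 0; }
      else               { It(i, j) = extt;  tbIt(i, j) = 2; }
    }
  }
  double sM = M(n, m), sIq = Iq(n, m), sIt = It(n, m);
  int state = 0; double score = sM;
  if (sIq > score) { score = sIq; state = 1; }
  if (sIt > score) { score = sIt; state = 2; }
  std::vector<int> pa, pb;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int tb = tbM(i, j);
      pa.push_back(i); pb.push_back(j);
      --i; --j; state = tb;
    } else if (state == 1) {
      int tb = tbIq(i, j);
      pa.push_back(i); pb.push_back(0);
      --i;
      state = (tb == 1) ? 1 : ((M(i, j) >= It(i, j)) ? 0 : 2);
    } else {
      int tb = tbIt(i, j);
      pa.push_back(0); pb.push_back(j);
      --j;
      state = (tb == 2) ? 2 : ((M(i, j) >= Iq(i, j)) ? 0 : 1);
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());
  return List::create(_["score"] = score, _["pa"] = wrap(pa), _["pb"] = wrap(pb));
}

// Local alignment of a PSSM against a sequence with affine gaps.
// pssm: L x 21 per-column scores; t: sequence codes.
// [[Rcpp::export]]
List pssm_local_cpp(NumericMatrix pssm, IntegerVector t,
                    double gap_open, double gap_extend) {
  int n = pssm.nrow(), m = t.size();
  NumericMatrix M(n + 1, m + 1), Iq(n + 1, m + 1), It(n + 1, m + 1);
  for (int i = 0; i <= n; ++i)
    for (int j = 0; j <= m; ++j) { Iq(i, j) = NEG_INF; It(i, j) = NEG_INF; }
  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = pssm(i - 1, t[j - 1] - 1);
      double from = std::max(M(i - 1, j - 1),
                             std::max(Iq(i - 1, j - 1), It(i - 1, j - 1)));
      double v = from + s;
      if (v < 0.0) v = 0.0;
      M(i, j) = v;
      Iq(i, j) = std::max(M(i - 1, j) - gap_open, Iq(i - 1, j) - gap_extend);
      It(i, j) = std::max(M(i, j - 1) - gap_open, It(i, j - 1) - gap_extend);
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }
  return List::create(_["score"] = best, _["pend"] = bi, _["tend"] = bj);
}

// ---- testing oracle: exhaustive enumeration of local alignments ----------
// Recursively enumerates every gapped local alignment (starting and ending
// on an aligned residue pair) and reports the best score. Exponential; only
// for short sequences in tests. Kept free of DP tables so it is an
// independent check on sw_affine_cpp.

struct EnumCtx {
  const int *q, *t; int n, m;
  const double *S; int A;
  double go, ge;
  double best;
};

static void enum_rec(EnumCtx &C, int i, int j, double score, int state) {
  // state 0: last column was a pair; 1: gap consuming query; 2: gap consuming target
  if (state == 0 && score > C.best) C.best = score;
  if (i < C.n && j < C.m)
    enum_rec(C, i + 1, j + 1, score + C.S[(C.q[i] - 1) + C.A * (C.t[j] - 1)], 0);
  if (i < C.n)
    enum_rec(C, i + 1, j, score - (state == 1 ? C.ge : C.go), 1);
  if (j < C.m)
    enum_rec(C, i, j + 1, score - (state == 2 ? C.ge : C.go), 2);
}

// [[Rcpp::export]]
double sw_enumerate_cpp(IntegerVector q, IntegerVector t, NumericMatrix S,
                        double gap_open, double gap_extend) {
  EnumCtx C;
  std::vector<int> qv(q.begin(), q.end()), tv(t.begin(), t.end());
  C.q = qv.data(); C.t = tv.data(); C.n = q.size(); C.m = t.size();
  C.S = S.begin(); C.A = S.nrow(); C.go = gap_open; C.ge = gap_extend;
  C.best = 0.0;
  for (int i = 0; i < C.n; ++i)
    for (int j = 0; j < C.m; ++j)
      enum_rec(C, i + 1, j + 1, C.S[(C.q[i] - 1) + C.A * (C.t[j] - 1)], 0);
  return C.best;
}
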