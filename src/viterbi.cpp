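#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Glocal Viterbi: the whole profile (match/insert/delete states) must be
// traversed, the sequence is local (flanking residues are free, emitted by the
// null model on both sides). Scores are log2-odds; insert emissions equal the
// background so inserts cost transitions only. Ties prefer M over D over I.
//
// lodds: L x A matrix of per-match-state log2(emission/background); the query
// is passed as 0-based column indices. Transition vectors are log2
// probabilities; tmm..tdd have length L-1.
// [[Rcpp::export]]
List viterbi_glocal_cpp(NumericMatrix lodds, IntegerVector seq,
                        double tBM, double tBD,
                        NumericVector tmm, NumericVector tmi, NumericVector tmd,
                        NumericVector tim, NumericVector tii,
                        NumericVector tdm, NumericVector tdd) {
  const int L = lodds.nrow();
  const int n = seq.size();
  const double NEG = -1e30;
  const int W = n + 1;
  const double* LO = &lodds(0, 0);      // column-major: LO[(k-1) + L*s]
  const int* SQ = &seq[0];

  std::vector<double> M((size_t)(L + 1) * W, NEG), D((size_t)(L + 1) * W, NEG),
      I((size_t)(L + 1) * W, NEG);
  std::vector<uint8_t> pM((size_t)(L + 1) * W, 255), pD((size_t)(L + 1) * W, 255),
      pI((size_t)(L + 1) * W, 255);
  // pointer codes: M: 0 from M, 1 from I, 2 from D, 3 from begin
  //               I: 0 from M, 1 from I;  D: 0 from M, 1 from D, 2 begin

  #define IX(k, i) ((size_t)(k) * W + (i))

  for (int i = 1; i <= n; ++i) {
    M[IX(1, i)] = tBM + LO[(size_t)L * SQ[i - 1]];
    pM[IX(1, i)] = 3;
  }
  for (int i = 0; i <= n; ++i) { D[IX(1, i)] = tBD; pD[IX(1, i)] = 2; }

  for (int k = 1; k <= L; ++k) {
    if (k >= 2) {
      const double vmm = tmm[k - 2], vim = tim[k - 2], vdm = tdm[k - 2];
      const double vmd = tmd[k - 2], vdd = tdd[k - 2];
      for (int i = 0; i <= n; ++i) {
        // D(k,i)
        double best = M[IX(k - 1, i)] + vmd; uint8_t ptr = 0;
        double cand = D[IX(k - 1, i)] + vdd;
        if (cand > best) { best = cand; ptr = 1; }
        D[IX(k, i)] = best; pD[IX(k, i)] = ptr;
        // M(k,i)
        if (i >= 1) {
          double e = LO[(k - 1) + (size_t)L * SQ[i - 1]];
          double bm = M[IX(k - 1, i - 1)] + vmm; uint8_t pm = 0;
          double cd = D[IX(k - 1, i - 1)] + vdm;
          if (cd > bm) { bm = cd; pm = 2; }
          double ci = I[IX(k - 1, i - 1)] + vim;
          if (ci > bm) { bm = ci; pm = 1; }
          M[IX(k, i)] = bm + e; pM[IX(k, i)] = pm;
        }
      }
    }
    if (k <= L - 1) {
      const double vmi = tmi[k - 1], vii = tii[k - 1];
      for (int i = 1; i <= n; ++i) {
        double best = M[IX(k, i - 1)] + vmi; uint8_t ptr = 0;
        double cand = I[IX(k, i - 1)] + vii;
        if (cand > best) { best = cand; ptr = 1; }
        I[IX(k, i)] = best; pI[IX(k, i)] = ptr;
      }
    }
  }

  // end state: exit from M_L or D_L at any i (remaining residues free)
  double score = NEG; int end_i = 0; int end_state = 0; // 0 = M, 2 = D
  for (int i = 0; i <= n; ++i) {
    if (M[IX(L, i)] > score) { score = M[IX(L, i)]; end_i = i; end_state = 0; }
  }
  for (int i = 0; i <= n; ++i) {
    if (D[IX(L, i)] > score) { score = D[IX(L, i)]; end_i = i; end_state = 2; }
  }

  // traceback
  IntegerVector emit(L, 0); // 1-based seq position emitted by M_k, 0 if delete
  int n_insert = 0;
  int k = L, i = end_i, st = end_state; // st: 0 M, 1 I, 2 D
  while (k >= 1) {
    if (st == 0) {
      emit[k - 1] = i;
      uint8_t p = pM[IX(k, i)];
      --i; --k;
      if (p == 3) break;
      st = (p == 0) ? 0 : (p == 1 ? 1 : 2);
    } else if (st == 2) {
      uint8_t p = pD[IX(k, i)];
      --k;
      if (p == 2) break;
      st = (p == 0) ? 0 : 2;
    } else { // insert at position k (between k and k+1)
      ++n_insert;
      uint8_t p = pI[IX(k, i)];
      --i;
      st = (p == 0) ? 0 : 1;
    }
  }

  int first_emit = 0, last_emit = 0;
  for (int j = 0; j < L; ++j) {
    if (emit[j] > 0) { if (first_emit == 0) first_emit = emit[j]; last_emit = emit[j]; }
  }

  return List::create(_["score"] = score, _["emit"] = emit,
                      _["n_insert"] = n_insert,
                      _["first_emit"] = first_emit, _["last_emit"] = last_emit);
}
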