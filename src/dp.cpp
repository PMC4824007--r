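// Dynamic-programming kernels for the profile hidden Markov model.
//
// Model layout (simplified Plan7, single-hit):
//   match states M_1..M_M, insert states I_0..I_M, delete states D_1..D_M.
//   Glocal mode: begin -> {M_1, I_0, D_1}; end reached from {M_M, I_M, D_M}.
//   Local mode: uniform entry (1/M) into any match state, free exit from any
//   match state; flanking residues are emitted by the background and carry
//   neither emission nor transition cost in the log-odds score.
// All scores are log-odds against the background in natural log; emission
// ratios for insert states are 0 (inserts emit the background), 'X' emits the
// background in every state (log-odds 0).
//
// Argument conventions (0-based C++ indexing):
//   lem  : M x 21 matrix, lem(j, a) = log(e_M[j+1][a] / q[a]); column 20 is X (= 0).
//   ltMM : length M; ltMM[M-1] = log P(M_M -> end).
//   ltMI : length M; ltMI[M-1] = log P(M_M -> I_M).
//   ltMD : length M; ltMD[M-1] unused (= -Inf).
//   ltIM : length M+1 (I_0..I_M); ltIM[M] = log P(I_M -> end).
//   ltII : length M+1.
//   ltDM : length M (D_1..D_M); ltDM[M-1] = log P(D_M -> end).
//   ltDD : length M.
//   seq  : integer vector, residues 0..19, X = 20.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  if (a < b) { double t = a; a = b; b = t; }
  double d = b - a;
  return (d < -37.0) ? a : a + log1p(exp(d));
}
static inline double lse3(double a, double b, double c) { return lse2(lse2(a, b), c); }

// Shared forward recursion. Returns log-odds (nats). Linear-probability
// space with per-row rescaling (classic scaled forward), which keeps the
// inner loop free of exp/log.
static double forward_core(const NumericMatrix& lem,
                           const NumericVector& ltMM, const NumericVector& ltMI,
                           const NumericVector& ltMD, const NumericVector& ltIM,
                           const NumericVector& ltII, const NumericVector& ltDM,
                           const NumericVector& ltDD,
                           double ltBM, double ltBI, double ltBD,
                           const IntegerVector& seq, bool local) {
  const int M = lem.nrow();
  const int L = seq.size();
  const double ent = local ? 1.0 / M : 0.0;

  // linear-space transition tables
  std::vector<double> tMM(M), tMI(M), tMD(M), tIM(M + 1), tII(M + 1),
      tDM(M), tDD(M);
  for (int j = 0; j < M; ++j) {
    tMM[j] = exp(ltMM[j]); tMI[j] = exp(ltMI[j]); tMD[j] = exp(ltMD[j]);
    tDM[j] = exp(ltDM[j]); tDD[j] = exp(ltDD[j]);
  }
  for (int j = 0; j <= M; ++j) { tIM[j] = exp(ltIM[j]); tII[j] = exp(ltII[j]); }
  const double tBM = exp(ltBM), tBI = exp(ltBI), tBD = exp(ltBD);

  std::vector<double> pM(M + 1, 0.0), pD(M + 1, 0.0), pI(M + 1, 0.0);
  std::vector<double> cM(M + 1, 0.0), cD(M + 1, 0.0), cI(M + 1, 0.0);
  // linear emission-ratio table, residue-major for cache-friendly rows
  const int A = lem.ncol();
  std::vector<double> eer((size_t)A * M);
  for (int a = 0; a < A; ++a)
    for (int j = 0; j < M; ++j)
      eer[(size_t)a * M + j] = exp(lem(j, a));

  double logscale = 0.0;      // cumulated log of applied scale factors
  double total = R_NegInf;    // local-mode accumulator (nats)

  if (!local && M >= 1) {     // i = 0: pure-delete prefix
    pD[1] = tBD;
    for (int j = 2; j <= M; ++j) pD[j] = pD[j - 1] * tDD[j - 2];
  }

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    const double* er = &eer[(size_t)a * M];

    // entry terms are unscaled constants; bring them into the current scale
    const double entS = (logscale < 700.0) ? ent * exp(-logscale) : 0.0;
    if (!local) {
      cI[0] = (i == 1) ? tBI * exp(-logscale) : pI[0] * tII[0];
      const double fromB = (i == 1) ? tBM * exp(-logscale) : 0.0;
      cM[1] = er[0] * (fromB + pI[0] * tIM[0]);
    } else {
      cM[1] = er[0] * entS;
    }
    for (int j = 2; j <= M; ++j) {
      double s = pM[j - 1] * tMM[j - 2] + pI[j - 1] * tIM[j - 1] +
                 pD[j - 1] * tDM[j - 2];
      if (local) s += entS;
      cM[j] = er[j - 1] * s;
    }
    const int jmaxI = local ? (M - 1) : M;  // I_M is a dead end in local mode
    for (int j = 1; j <= jmaxI; ++j)
      cI[j] = pM[j] * tMI[j - 1] + pI[j] * tII[j];
    if (local) cI[0] = 0.0;
    // delete states consume no residue: ascending j at this i
    cD[1] = 0.0;
    for (int j = 2; j <= M; ++j)
      cD[j] = cM[j - 1] * tMD[j - 2] + cD[j - 1] * tDD[j - 2];

    if (local) {
      double rowSum = 0.0;
      for (int j = 1; j <= M; ++j) rowSum += cM[j];
      if (rowSum > 0.0) total = lse2(total, log(rowSum) + logscale);
    }

    // rescale so the row maximum is 1
    double mx = 0.0;
    for (int j = 0; j <= M; ++j) {
      if (cM[j] > mx) mx = cM[j];
      if (cI[j] > mx) mx = cI[j];
      if (cD[j] > mx) mx = cD[j];
    }
    if (mx > 0.0 && (mx > 1e100 || mx < 1e-100)) {
      const double inv = 1.0 / mx;
      for (int j = 0; j <= M; ++j) { cM[j] *= inv; cI[j] *= inv; cD[j] *= inv; }
      logscale += log(mx);
    }
    std::swap(pM, cM); std::swap(pD, cD); std::swap(pI, cI);
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  if (local) return total;
  if (L == 0) {  // pure-delete path only
    double end = tBD;
    for (int j = 2; j <= M; ++j) end *= tDD[j - 2];
    end *= tDM[M - 1];
    return end > 0.0 ? log(end) : R_NegInf;
  }
  double end = pM[M] * tMM[M - 1] + pI[M] * tIM[M] + pD[M] * tDM[M - 1];
  return end > 0.0 ? log(end) + logscale : R_NegInf;
}

// [[Rcpp::export(name = ".phmmForward")]]
double phmm_forward(NumericMatrix lem, NumericVector ltMM, NumericVector ltMI,
                    NumericVector ltMD, NumericVector ltIM, NumericVector ltII,
                    NumericVector ltDM, NumericVector ltDD,
                    double ltBM, double ltBI, double ltBD,
                    IntegerVector seq, bool local) {
  double nats = forward_core(lem, ltMM, ltMI, ltMD, ltIM, ltII, ltDM, ltDD,
                             ltBM, ltBI, ltBD, seq, local);
  return nats / M_LN2;  // bits
}

// [[Rcpp::export(name = ".phmmForwardBatch")]]
NumericVector phmm_forward_batch(NumericMatrix lem, NumericVector ltMM,
                                 NumericVector ltMI, NumericVector ltMD,
                                 NumericVector ltIM, NumericVector ltII,
                                 NumericVector ltDM, NumericVector ltDD,
                                 double ltBM, double ltBI, double ltBD,
                                 List seqs, bool local) {
  const int n = seqs.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    IntegerVector s = seqs[k];
    out[k] = forward_core(lem, ltMM, ltMI, ltMD, ltIM, ltII, ltDM, ltDD,
                          ltBM, ltBI, ltBD, s, local) / M_LN2;
    if (k % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Viterbi with traceback. States coded 0 = M, 1 = I, 2 = D.
// [[Rcpp::export(name = ".phmmViterbi")]]
List phmm_viterbi(NumericMatrix lem, NumericVector ltMM, NumericVector ltMI,
                  NumericVector ltMD, NumericVector ltIM, NumericVector ltII,
                  NumericVector ltDM, NumericVector ltDD,
                  double ltBM, double ltBI, double ltBD,
                  IntegerVector seq, bool local) {
  const int M = lem.nrow();
  const int L = seq.size();
  const double NEG = R_NegInf;
  const double lent = local ? -log((double)M) : NEG;

  // full matrices, (L+1) x (M+1); insert has column 0..M
  auto idx = [&](int i, int j) { return i * (M + 1) + j; };
  std::vector<double> VM((L + 1) * (M + 1), NEG), VI((L + 1) * (M + 1), NEG),
      VD((L + 1) * (M + 1), NEG);
  // backpointer: previous state code (0 M,1 I,2 D, 3 = begin/entry), -1 unset
  std::vector<signed char> BM(VM.size(), -1), BI(VM.size(), -1), BD(VM.size(), -1);

  if (!local) {
    VD[idx(0, 1)] = ltBD; BD[idx(0, 1)] = 3;
    for (int j = 2; j <= M; ++j) {
      VD[idx(0, j)] = VD[idx(0, j - 1)] + ltDD[j - 2];
      BD[idx(0, j)] = 2;
    }
  }

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    // M states
    for (int j = 1; j <= M; ++j) {
      double best = NEG; signed char who = -1;
      if (j == 1) {
        if (!local) {
          if (i == 1 && ltBM > best) { best = ltBM; who = 3; }
          double v = VI[idx(i - 1, 0)] + ltIM[0];
          if (v > best) { best = v; who = 1; }
        } else {
          best = lent; who = 3;
        }
      } else {
        double v;
        v = VM[idx(i - 1, j - 1)] + ltMM[j - 2]; if (v > best) { best = v; who = 0; }
        v = VI[idx(i - 1, j - 1)] + ltIM[j - 1]; if (v > best) { best = v; who = 1; }
        v = VD[idx(i - 1, j - 1)] + ltDM[j - 2]; if (v > best) { best = v; who = 2; }
        if (local && lent > best) { best = lent; who = 3; }
      }
      if (who >= 0) { VM[idx(i, j)] = lem(j - 1, a) + best; BM[idx(i, j)] = who; }
    }
    // I states
    int jmaxI = local ? (M - 1) : M;
    if (!local) {
      double v = (i == 1) ? ltBI : VI[idx(i - 1, 0)] + ltII[0];
      VI[idx(i, 0)] = v; BI[idx(i, 0)] = (i == 1) ? 3 : 1;
    }
    for (int j = 1; j <= jmaxI; ++j) {
      double vm = VM[idx(i - 1, j)] + ltMI[j - 1];
      double vi = VI[idx(i - 1, j)] + ltII[j];
      if (vm >= vi) { VI[idx(i, j)] = vm; BI[idx(i, j)] = 0; }
      else          { VI[idx(i, j)] = vi; BI[idx(i, j)] = 1; }
    }
    // D states
    for (int j = 2; j <= M; ++j) {
      double vm = VM[idx(i, j - 1)] + ltMD[j - 2];
      double vd = VD[idx(i, j - 1)] + ltDD[j - 2];
      if (vm >= vd) { VD[idx(i, j)] = vm; BD[idx(i, j)] = 0; }
      else          { VD[idx(i, j)] = vd; BD[idx(i, j)] = 2; }
    }
  }

  // termination
  double best = NEG; int endState = -1, endJ = -1, endI = -1;
  if (local) {
    for (int i = 1; i <= L; ++i)
      for (int j = 1; j <= M; ++j)
        if (VM[idx(i, j)] > best) { best = VM[idx(i, j)]; endState = 0; endJ = j; endI = i; }
  } else {
    double v;
    v = VM[idx(L, M)] + ltMM[M - 1]; if (v > best) { best = v; endState = 0; endJ = M; endI = L; }
    v = VI[idx(L, M)] + ltIM[M];     if (v > best) { best = v; endState = 1; endJ = M; endI = L; }
    v = VD[idx(L, M)] + ltDM[M - 1]; if (v > best) { best = v; endState = 2; endJ = M; endI = L; }
  }
  if (endState < 0)
    return List::create(_["bits"] = R_NegInf, _["states"] = IntegerVector(0),
                        _["positions"] = IntegerVector(0), _["residues"] = IntegerVector(0),
                        _["envStart"] = NA_INTEGER, _["envEnd"] = NA_INTEGER);

  // traceback
  std::vector<int> st, pj, ri;
  int s = endState, j = endJ, i = endI;
  while (true) {
    st.push_back(s); pj.push_back(j); ri.push_back(s == 2 ? NA_INTEGER : i);
    signed char who;
    if (s == 0) who = BM[idx(i, j)];
    else if (s == 1) who = BI[idx(i, j)];
    else who = BD[idx(i, j)];
    if (who == 3) break;  // reached entry
    if (s == 0) { --i; --j; s = who; }          // into M: prev emitted at i-1, pos j-1 (or I at j-1)
    else if (s == 1) { --i; s = who; }          // insert: same j, prev residue
    else { --j; s = who; }                      // delete: same i, prev position
  }
  std::reverse(st.begin(), st.end());
  std::reverse(pj.begin(), pj.end());
  std::reverse(ri.begin(), ri.end());

  int envS = NA_INTEGER, envE = NA_INTEGER;
  for (size_t k = 0; k < st.size(); ++k)
    if (st[k] != 2) { if (envS == NA_INTEGER) envS = ri[k]; envE = ri[k]; }

  return List::create(_["bits"] = best / M_LN2,
                      _["states"] = IntegerVector(st.begin(), st.end()),
                      _["positions"] = IntegerVector(pj.begin(), pj.end()),
                      _["residues"] = IntegerVector(ri.begin(), ri.end()),
                      _["envStart"] = envS, _["envEnd"] = envE);
}
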