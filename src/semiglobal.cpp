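#include <Rcpp.h>
#include <vector>
#include <climits>
using namespace Rcpp;

// Semi-global affine-gap alignment: the read must be fully consumed, gaps at
// the reference ends are free. Three-state DP (M: diagonal, D: gap in read
// consuming reference, I: gap in reference consuming read) with full
// traceback. Tie order at every choice point: diagonal > deletion >
// insertion. A gap of length L scores gap_open + (L - 1) * gap_extend.
//
// Op codes returned: 0 '=', 1 'X', 2 'I', 3 'D'.

static const int NEG = INT_MIN / 4;

// [[Rcpp::export(name = ".cpp_semiglobal")]]
List cpp_semiglobal(std::string read, std::string ref, int match,
                    int mismatch, int gap_open, int gap_extend) {
  const int n = (int)read.size();
  const int m = (int)ref.size();
  const int W = m + 1;
  // score matrices, row-major (i * W + j)
  std::vector<int> M((n + 1) * W, NEG), D((n + 1) * W, NEG),
      I((n + 1) * W, NEG);
  // traceback: predecessor state for each cell/state (0=M,1=D,2=I,3=start)
  std::vector<unsigned char> tM((n + 1) * W, 255), tD((n + 1) * W, 255),
      tI((n + 1) * W, 255);

  for (int j = 0; j <= m; ++j) {           // free reference prefix
    M[j] = 0;
    tM[j] = 3;
  }
  I[0] = NEG;
  for (int i = 1; i <= n; ++i) {           // leading insertions at ref start
    I[i * W] = gap_open + (i - 1) * gap_extend;
    tI[i * W] = (i == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    const char rc = read[i - 1];
    const int row = i * W, prow = (i - 1) * W;
    for (int j = 1; j <= m; ++j) {
      const char fc = ref[j - 1];
      const int s = (rc == fc && rc != 'N') ? match : mismatch;
      // M: diagonal move, predecessor any state at (i-1, j-1)
      int best = M[prow + j - 1];
      unsigned char bt = 0;
      if (D[prow + j - 1] > best) { best = D[prow + j - 1]; bt = 1; }
      if (I[prow + j - 1] > best) { best = I[prow + j - 1]; bt = 2; }
      M[row + j] = (best <= NEG) ? NEG : best + s;
      tM[row + j] = bt;
      // D: consume ref[j-1], predecessor at (i, j-1)
      int dM = M[row + j - 1] + gap_open;
      int dD = D[row + j - 1] + gap_extend;
      int dI = I[row + j - 1] + gap_open;
      best = dM; bt = 0;
      if (dD > best) { best = dD; bt = 1; }
      if (dI > best) { best = dI; bt = 2; }
      D[row + j] = best;
      tD[row + j] = bt;
      // I: consume read[i-1], predecessor at (i-1, j)
      int iM = M[prow + j] + gap_open;
      int iD = D[prow + j] + gap_open;
      int iI = I[prow + j] + gap_extend;
      best = iM; bt = 0;
      if (iD > best) { best = iD; bt = 1; }
      if (iI > best) { best = iI; bt = 2; }
      I[row + j] = best;
      tI[row + j] = bt;
    }
  }

  // endpoint: read fully consumed, free reference suffix. D excluded so a
  // trailing deletion is impossible; smallest j wins ties (leftmost end).
  int bestScore = NEG, bestJ = 0;
  unsigned char bestState = 0;
  const int lrow = n * W;
  for (int j = 0; j <= m; ++j) {
    if (M[lrow + j] > bestScore) { bestScore = M[lrow + j]; bestJ = j;
                                   bestState = 0; }
    if (I[lrow + j] > bestScore) { bestScore = I[lrow + j]; bestJ = j;
                                   bestState = 2; }
  }

  // traceback
  std::vector<int> opsRev;       // op codes, reversed
  std::vector<int> lensRev;
  int i = n, j = bestJ;
  unsigned char st = bestState;
  auto push = [&](int op) {
    if (!opsRev.empty() && opsRev.back() == op) {
      ++lensRev.back();
    } else {
      opsRev.push_back(op);
      lensRev.push_back(1);
    }
  };
  while (!(st == 0 && i == 0)) {  // M state in row 0 is the free start
    unsigned char prev;
    if (st == 0) {                 // M: emitted read[i-1] vs ref[j-1]
      prev = tM[i * W + j];
      push((read[i - 1] == ref[j - 1] && read[i - 1] != 'N') ? 0 : 1);
      --i; --j;
    } else if (st == 1) {          // D: ref[j-1] deleted
      prev = tD[i * W + j];
      push(3);
      --j;
    } else {                       // I: read[i-1] inserted
      prev = tI[i * W + j];
      push(2);
      --i;
    }
    st = prev;
  }
  const int refStart = j;

  const int k = (int)opsRev.size();
  IntegerVector ops(k), lens(k);
  for (int t = 0; t < k; ++t) {
    ops[t] = opsRev[k - 1 - t];
    lens[t] = lensRev[k - 1 - t];
  }
  return List::create(_["score"] = bestScore, _["ref_start"] = refStart,
                      _["ref_end"] = bestJ, _["ops"] = ops,
                      _["lens"] = lens);
}
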