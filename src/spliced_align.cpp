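// Splice-aware semi-global alignment of a coding sequence against genomic
// DNA. Affine-gap dynamic programming with an additional intron move that
// may open only at GT and close only at AG, charged a fixed opening penalty
// and no per-base cost. The CDS is aligned end-to-end; genomic flanks are
// free. Deterministic tie-break: for equal scores the leftmost intron start
// is preferred (earlier openers win ties in the lagged prefix max).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG = -1e18;

// [[Rcpp::export(name = ".spliced_align_cpp")]]
List spliced_align_cpp(std::string genomic, std::string cds,
                       double match, double mismatch,
                       double gap_open, double gap_ext,
                       double intron_open, int min_intron) {
  int n = genomic.size(), m = cds.size();
  if (n == 0 || m == 0) stop("empty sequence");

  // GT opener after consuming i genomic bases: genomic[i] == 'G', [i+1] == 'T'
  std::vector<char> gt(n + 1, 0), ag(n + 1, 0);
  for (int i = 0; i <= n - 2; ++i)
    if (genomic[i] == 'G' && genomic[i + 1] == 'T') gt[i] = 1;
  // AG closer at i: last two consumed bases genomic[i-2], genomic[i-1]
  for (int i = 2; i <= n; ++i)
    if (genomic[i - 2] == 'A' && genomic[i - 1] == 'G') ag[i] = 1;

  int W = m + 1;
  // G matrix (best of all states) kept in full for the intron lookback.
  std::vector<double> Gm((size_t)(n + 1) * W, NEG);
  std::vector<double> Mrow(W, NEG), Xrow(W, NEG), Yrow(W, NEG);
  std::vector<double> Mprev(W, NEG), Xprev(W, NEG), Yprev(W, NEG);
  std::vector<double> P(W, NEG);      // lagged prefix max of opener G values
  std::vector<int> Parg(W, -1);       // opener row attaining P

  // traceback: state of G at each cell: 0=M 1=X 2=Y 3=intron 4=start(free)
  std::vector<signed char> tbG((size_t)(n + 1) * W, -1);
  std::vector<signed char> tbX((size_t)(n + 1) * W, -1);
  std::vector<signed char> tbY((size_t)(n + 1) * W, -1);
  std::vector<int> isrc((size_t)(n + 1) * W, -1);        // intron start row

  // row 0: free genomic prefix handled by G[i][0] = 0 below; CDS prefix gaps
  Gm[0] = 0; tbG[0] = 4;
  for (int j = 1; j <= m; ++j) {
    Yprev[j] = (j == 1 ? gap_open : Yprev[j - 1] + gap_ext);
    Gm[j] = Yprev[j];
    tbG[j] = 2; tbY[j] = (j == 1 ? 0 : 2);
  }

  for (int i = 1; i <= n; ++i) {
    size_t row = (size_t)i * W, prow = row - W;
    // admit opener row i - min_intron into the lagged prefix max
    int iadm = i - min_intron;
    if (iadm >= 0 && gt[iadm]) {
      size_t arow = (size_t)iadm * W;
      for (int j = 0; j <= m; ++j) {
        if (Gm[arow + j] > P[j]) { P[j] = Gm[arow + j]; Parg[j] = iadm; }
      }
    }
    // j = 0: free genomic prefix
    Mrow[0] = NEG; Yrow[0] = NEG;
    if (Gm[prow] + gap_open >= Xprev[0] + gap_ext) {
      Xrow[0] = Gm[prow] + gap_open; tbX[row] = 5;  // 5: from G at (i-1, j)
    } else {
      Xrow[0] = Xprev[0] + gap_ext; tbX[row] = 1;
    }
    Gm[row] = 0; tbG[row] = 4;
    for (int j = 1; j <= m; ++j) {
      double s = (genomic[i - 1] == cds[j - 1]) ? match : mismatch;
      // M: diagonal from G (predecessor state re-read from tbG in traceback)
      Mrow[j] = Gm[prow + j - 1] + s;
      // X: consume genomic (gap in CDS)
      double xo = NEG; signed char xs = -1;
      double cand;
      cand = Mprev[j] + gap_open; if (cand > xo) { xo = cand; xs = 0; }
      cand = Xprev[j] + gap_ext;  if (cand > xo) { xo = cand; xs = 1; }
      cand = Yprev[j] + gap_open; if (cand > xo) { xo = cand; xs = 2; }
      Xrow[j] = xo; tbX[row + j] = xs;
      // Y: consume CDS (gap in genomic)
      double yo = NEG; signed char ys = -1;
      cand = Mrow[j - 1] + gap_open; if (cand > yo) { yo = cand; ys = 0; }
      cand = Xrow[j - 1] + gap_open; if (cand > yo) { yo = cand; ys = 1; }
      cand = Yrow[j - 1] + gap_ext;  if (cand > yo) { yo = cand; ys = 2; }
      Yrow[j] = yo; tbY[row + j] = ys;
      // E: intron ending exactly at i
      double e = NEG;
      if (ag[i] && P[j] > NEG / 2) e = P[j] + intron_open;
      // G = max state; ties: M > intron > X > Y (leftmost-intron comes from
      // the prefix-max keeping the earliest argmax on ties)
      double g = Mrow[j]; signed char st = 0;
      if (e > g) { g = e; st = 3; }
      if (Xrow[j] > g) { g = Xrow[j]; st = 1; }
      if (Yrow[j] > g) { g = Yrow[j]; st = 2; }
      Gm[row + j] = g; tbG[row + j] = st;
      if (st == 3) isrc[row + j] = Parg[j];
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }

  // best end: G[i][m], free genomic suffix
  int best_i = -1; double best = NEG;
  for (int i = 0; i <= n; ++i) {
    double v = Gm[(size_t)i * W + m];
    if (v > best) { best = v; best_i = i; }
  }

  // traceback: explicit state machine (gap states chain through their own
  // recorded predecessors, not through the cell's overall best state)
  std::vector<int> intron_s, intron_e; // 0-based half-open genomic
  int i = best_i, j = m;
  int align_end = best_i;  // genomic consumed at alignment end
  int align_start = -1;
  signed char st = tbG[(size_t)i * W + j];
  while (true) {
    if (st == 4 || (i == 0 && j == 0)) { align_start = i; break; }
    if (st == 3) {                       // intron ending at i, from G[i0][j]
      int i0 = isrc[(size_t)i * W + j];
      intron_s.push_back(i0); intron_e.push_back(i);
      i = i0;
      st = tbG[(size_t)i * W + j];
    } else if (st == 0) {                // M: from G[i-1][j-1]
      i -= 1; j -= 1;
      st = tbG[(size_t)i * W + j];
    } else if (st == 1) {                // X: from recorded state at (i-1,j)
      signed char p = tbX[(size_t)i * W + j];
      i -= 1;
      st = (p == 5) ? tbG[(size_t)i * W + j] : p;
    } else {                             // Y: from recorded state at (i,j-1)
      signed char p = tbY[(size_t)i * W + j];
      j -= 1;
      st = p;
    }
  }
  if (align_start < 0) align_start = 0;

  // exon intervals: [align_start, align_end) minus introns
  std::vector<int> ex_s, ex_e;
  int cur = align_start;
  for (int k = (int)intron_s.size() - 1; k >= 0; --k) {
    if (intron_s[k] > cur) { ex_s.push_back(cur); ex_e.push_back(intron_s[k]); }
    cur = intron_e[k];
  }
  if (align_end > cur) { ex_s.push_back(cur); ex_e.push_back(align_end); }

  return List::create(
    _["score"] = best,
    _["exon_start"] = wrap(ex_s),
    _["exon_end"] = wrap(ex_e),
    _["align_start"] = align_start,
    _["align_end"] = align_end);
}
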