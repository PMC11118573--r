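#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Global affine-gap alignment (Gotoh). A gap of length L costs
// open + (L-1) * extend, i.e. the opening penalty is charged on the first
// gap residue. Traceback tie-break: diagonal > up (gap in query row) > left
// (gap in reference row), applied both to the final state and to every
// predecessor choice, so the alignment is deterministic.
//
// ref/qry: 0-based indices into the scoring matrix. Returns the score and
// the operation string 5'->3': 1 = M (diagonal), 2 = D (ref consumed, gap in
// qry row), 3 = I (qry consumed, gap in ref row).

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// [[Rcpp::export(name = ".align_affine_cpp")]]
List align_affine_cpp(IntegerVector ref, IntegerVector qry, NumericMatrix smat,
                      double gap_open, double gap_extend) {
  const int n = ref.size();   // rows: reference
  const int m = qry.size();   // cols: query

  // rolling score rows
  std::vector<double> Mprev(m + 1), Dprev(m + 1), Iprev(m + 1);
  std::vector<double> Mcur(m + 1), Dcur(m + 1), Icur(m + 1);

  // traceback: predecessor state for each cell/state.
  // states: 0 = M, 1 = D, 2 = I; 255 = invalid
  std::vector<unsigned char> ptrM((size_t)(n + 1) * (m + 1), 255);
  std::vector<unsigned char> ptrD((size_t)(n + 1) * (m + 1), 255);
  std::vector<unsigned char> ptrI((size_t)(n + 1) * (m + 1), 255);
  const size_t W = (size_t)m + 1;

  Mprev[0] = 0.0;
  Dprev[0] = NEG_INF;
  Iprev[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mprev[j] = NEG_INF;
    Dprev[j] = NEG_INF;
    Iprev[j] = -(gap_open + (j - 1) * gap_extend);
    ptrI[0 * W + j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mcur[0] = NEG_INF;
    Icur[0] = NEG_INF;
    Dcur[0] = -(gap_open + (i - 1) * gap_extend);
    ptrD[(size_t)i * W + 0] = (i == 1) ? 0 : 1;

    for (int j = 1; j <= m; ++j) {
      const size_t at = (size_t)i * W + j;
      // M: diagonal step; predecessor preference M > D > I
      double s = smat(ref[i - 1], qry[j - 1]);
      double best = Mprev[j - 1];
      unsigned char p = 0;
      if (Dprev[j - 1] > best) { best = Dprev[j - 1]; p = 1; }
      if (Iprev[j - 1] > best) { best = Iprev[j - 1]; p = 2; }
      Mcur[j] = best + s;
      ptrM[at] = p;

      // D: consume ref[i], gap in qry row. From M (open) or D (extend);
      // on tie prefer opening from M.
      double fromM = Mprev[j] - gap_open;
      double fromD = Dprev[j] - gap_extend;
      if (fromM >= fromD) { Dcur[j] = fromM; ptrD[at] = 0; }
      else                { Dcur[j] = fromD; ptrD[at] = 1; }

      // I: consume qry[j], gap in ref row.
      double gM = Mcur[j - 1] - gap_open;
      double gI = Icur[j - 1] - gap_extend;
      if (gM >= gI) { Icur[j] = gM; ptrI[at] = 0; }
      else          { Icur[j] = gI; ptrI[at] = 2; }
    }
    std::swap(Mprev, Mcur);
    std::swap(Dprev, Dcur);
    std::swap(Iprev, Icur);
  }

  // final state preference M > D > I
  double score = Mprev[m];
  unsigned char state = 0;
  if (Dprev[m] > score) { score = Dprev[m]; state = 1; }
  if (Iprev[m] > score) { score = Iprev[m]; state = 2; }

  // traceback
  std::vector<unsigned char> ops;
  ops.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t at = (size_t)i * W + j;
    if (state == 0) {
      ops.push_back(1);
      state = ptrM[at];
      --i; --j;
    } else if (state == 1) {
      ops.push_back(2);
      state = ptrD[at];
      --i;
    } else {
      ops.push_back(3);
      state = ptrI[at];
      --j;
    }
  }
  IntegerVector out(ops.size());
  for (size_t k = 0; k < ops.size(); ++k) out[k] = ops[ops.size() - 1 - k];
  return List::create(_["score"] = score, _["ops"] = out);
}
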