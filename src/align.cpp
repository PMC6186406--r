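#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global (end-to-end) alignment of two integer-coded sequences.
//
// Scoring: substitution score from `submat` (indexed by the integer codes);
// a gap of length k costs gap_open + k * gap_ext (both are <= 0 here).
// Three-state DP (M = match/mismatch, X = gap in b i.e. consuming a,
// Y = gap in a i.e. consuming b) with a fixed deterministic tie-break:
// on equal scores prefer M over X over Y, which makes the traceback
// prefer diagonal > up > left.
//
// Scores are kept in two rolling rows; the full traceback is stored packed
// (2 bits per state per cell) so memory stays ~1 byte per DP cell.
//
// Returns the optimal score, the number of identical aligned columns, the
// total number of alignment columns, and the two gapped index vectors
// (0-based positions into a and b, -1 for a gap).

static const double NEG_INF = -1e30;

// [[Rcpp::export]]
List nw_affine(IntegerVector a, IntegerVector b, NumericMatrix submat,
               double gap_open, double gap_ext) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int nr = submat.nrow();
  std::vector<double> sm(submat.begin(), submat.end());  // column-major
  std::vector<int> av(a.begin(), a.end()), bv(b.begin(), b.end());
  const int W = m + 1;

  // Rolling rows.
  std::vector<double> Mp(W), Xp(W), Yp(W), Mc(W), Xc(W), Yc(W);
  // Packed traceback: bits 0-1 = tM, 2-3 = tX, 4-5 = tY (values 0/1/2).
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0);

  Mp[0] = 0.0; Xp[0] = NEG_INF; Yp[0] = NEG_INF;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG_INF; Xp[j] = NEG_INF;
    Yp[j] = gap_open + j * gap_ext;
    tb[j] = (unsigned char)((j == 1 ? 0 : 2) << 4);
  }

  for (int i = 1; i <= n; ++i) {
    unsigned char *trow = &tb[(size_t)i * W];
    Mc[0] = NEG_INF; Yc[0] = NEG_INF;
    Xc[0] = gap_open + i * gap_ext;
    trow[0] = (unsigned char)((i == 1 ? 0 : 1) << 2);
    const double *scol = &sm[av[i - 1]];     // row av[i-1], stride nr
    for (int j = 1; j <= m; ++j) {
      const double s = scol[(size_t)nr * bv[j - 1]];
      // M: from previous row/col diagonal; prefer M > X > Y on ties.
      double bm = Mp[j - 1]; unsigned char tm = 0;
      if (Xp[j - 1] > bm) { bm = Xp[j - 1]; tm = 1; }
      if (Yp[j - 1] > bm) { bm = Yp[j - 1]; tm = 2; }
      const double Mv = bm + s;
      // X (gap in b, consume a[i-1]): from row above.
      const double openx = Mp[j] + gap_open + gap_ext;
      const double extx = Xp[j] + gap_ext;
      double Xv; unsigned char tx;
      if (openx >= extx) { Xv = openx; tx = 0; } else { Xv = extx; tx = 1; }
      // Y (gap in a, consume b[j-1]): from current row, left.
      const double openy = Mc[j - 1] + gap_open + gap_ext;
      const double exty = Yc[j - 1] + gap_ext;
      double Yv; unsigned char ty;
      if (openy >= exty) { Yv = openy; ty = 0; } else { Yv = exty; ty = 2; }
      Mc[j] = Mv; Xc[j] = Xv; Yc[j] = Yv;
      trow[j] = (unsigned char)(tm | (tx << 2) | (ty << 4));
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  double score = Mp[m]; unsigned char state = 0;
  if (Xp[m] > score) { score = Xp[m]; state = 1; }
  if (Yp[m] > score) { score = Yp[m]; state = 2; }

  // Traceback over the packed pointers.
  std::vector<int> pa, pb;
  pa.reserve(n + m); pb.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const unsigned char cell = tb[(size_t)i * W + j];
    if (state == 0 && i > 0 && j > 0) {
      unsigned char prev = cell & 3;
      pa.push_back(i - 1); pb.push_back(j - 1);
      --i; --j; state = prev;
    } else if (state == 1 || (state == 0 && j == 0)) {
      unsigned char prev = (cell >> 2) & 3;
      pa.push_back(i - 1); pb.push_back(-1);
      --i; state = prev;
    } else {
      unsigned char prev = (cell >> 4) & 3;
      pa.push_back(-1); pb.push_back(j - 1);
      --j; state = prev;
    }
  }
  std::reverse(pa.begin(), pa.end());
  std::reverse(pb.begin(), pb.end());

  int ident = 0;
  const int ncol = pa.size();
  for (int k = 0; k < ncol; ++k) {
    if (pa[k] >= 0 && pb[k] >= 0 && av[pa[k]] == bv[pb[k]]) ++ident;
  }

  return List::create(_["score"] = score,
                      _["n_identical"] = ident,
                      _["n_columns"] = ncol,
                      _["a_idx"] = IntegerVector(pa.begin(), pa.end()),
                      _["b_idx"] = IntegerVector(pb.begin(), pb.end()));
}
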