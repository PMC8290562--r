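#include <Rcpp.h>
using namespace Rcpp;

// Local (Smith-Waterman) alignment of a protein sequence against a
// position-specific score matrix with affine gap penalties (Gotoh).
//
// pssm: L x 20 matrix of match scores (half-bit units), rows = profile
//       positions, columns = amino acids in the package's fixed order.
// seq:  integer codes, 1..20 = amino acid index, 0 = unknown (X, scores 0),
//       -1 = masked (effectively unalignable).
// ref_codes: length-L integer vector of "reference" residues used only to
//       count identities along the traceback (0 = never identical).
// A gap of length k costs gap_open + k * gap_extend (both negative).
//
// Returns the single best local alignment: raw score, 1-based inclusive
// coordinates on the sequence and the profile, identity count and aligned
// column count.

static const double MASK_SCORE = -1e9;

// [[Rcpp::export]]
List cpp_pssm_local(NumericMatrix pssm, IntegerVector seq,
                    IntegerVector ref_codes,
                    double gap_open, double gap_extend) {
  const int L = pssm.nrow();
  const int n = seq.size();
  if (pssm.ncol() != 20) stop("pssm must have 20 columns");
  if (ref_codes.size() != L) stop("ref_codes must match profile length");

  // transpose the score matrix to row-major so the inner loop over the
  // sequence touches one contiguous 20-entry row per profile position
  std::vector<double> S((size_t)L * 20);
  for (int i = 0; i < L; ++i)
    for (int a = 0; a < 20; ++a) S[(size_t)i * 20 + a] = pssm(i, a);
  std::vector<int> scode(n);
  for (int j = 0; j < n; ++j) scode[j] = seq[j];

  // DP matrices over (profile i = 1..L, seq j = 1..n); row 0 / col 0 = 0.
  // M = match state, X = gap in sequence (profile consumed), Y = gap in
  // profile (sequence consumed).
  std::vector<double> Mprev(n + 1, 0.0), Mcur(n + 1, 0.0);
  std::vector<double> Xprev(n + 1, MASK_SCORE), Xcur(n + 1, MASK_SCORE);
  std::vector<double> Yprev(n + 1, MASK_SCORE), Ycur(n + 1, MASK_SCORE);

  // traceback pointers: 0 = restart, 1 = from M, 2 = from X, 3 = from Y
  // stored per state in byte matrices of (L+1) x (n+1)
  std::vector<unsigned char> ptrM((L + 1) * (n + 1), 0);
  std::vector<unsigned char> ptrX((L + 1) * (n + 1), 0);
  std::vector<unsigned char> ptrY((L + 1) * (n + 1), 0);
  #define IDX(i, j) ((size_t)(i) * (n + 1) + (j))

  double best = 0.0;
  int best_i = 0, best_j = 0;

  for (int i = 1; i <= L; ++i) {
    Mcur[0] = 0.0; Xcur[0] = MASK_SCORE; Ycur[0] = MASK_SCORE;
    const double *Srow = &S[(size_t)(i - 1) * 20];
    unsigned char *pM = &ptrM[IDX(i, 0)];
    unsigned char *pX = &ptrX[IDX(i, 0)];
    unsigned char *pY = &ptrY[IDX(i, 0)];
    for (int j = 1; j <= n; ++j) {
      const int code = scode[j - 1];
      double s;
      if (code < 0)       s = MASK_SCORE;   // masked residue
      else if (code == 0) s = 0.0;          // unknown residue, neutral
      else                s = Srow[code - 1];

      // M state: diagonal predecessor or local restart
      double dM = Mprev[j - 1], dX = Xprev[j - 1], dY = Yprev[j - 1];
      double pre = 0.0; unsigned char pm = 0;
      if (dM > pre) { pre = dM; pm = 1; }
      if (dX > pre) { pre = dX; pm = 2; }
      if (dY > pre) { pre = dY; pm = 3; }
      double m = pre + s;
      if (m < 0.0 || code < 0) { m = (code < 0) ? MASK_SCORE : 0.0; pm = 0; }
      Mcur[j] = m; pM[j] = pm;

      // X state: gap in sequence, consume profile row i
      double xo = Mprev[j] + gap_open + gap_extend;
      double xe = Xprev[j] + gap_extend;
      if (xo >= xe) { Xcur[j] = xo; pX[j] = 1; }
      else          { Xcur[j] = xe; pX[j] = 2; }

      // Y state: gap in profile, consume sequence residue j
      double yo = Mcur[j - 1] + gap_open + gap_extend;
      double ye = Ycur[j - 1] + gap_extend;
      if (yo >= ye) { Ycur[j] = yo; pY[j] = 1; }
      else          { Ycur[j] = ye; pY[j] = 3; }

      if (Mcur[j] > best) { best = Mcur[j]; best_i = i; best_j = j; }
    }
    std::swap(Mprev, Mcur); std::swap(Xprev, Xcur); std::swap(Yprev, Ycur);
  }

  if (best <= 0.0 || best_i == 0) {
    return List::create(_["score"] = 0.0, _["seq_start"] = NA_INTEGER,
                        _["seq_end"] = NA_INTEGER, _["prof_start"] = NA_INTEGER,
                        _["prof_end"] = NA_INTEGER, _["n_ident"] = 0,
                        _["n_cols"] = 0);
  }

  // traceback from (best_i, best_j) in state M
  int i = best_i, j = best_j, state = 1; // 1=M, 2=X, 3=Y
  int n_ident = 0, n_cols = 0;
  int seq_start = best_j, prof_start = best_i;
  while (i > 0 && j > 0) {
    if (state == 1) {
      unsigned char p = ptrM[IDX(i, j)];
      ++n_cols;
      if (seq[j - 1] > 0 && ref_codes[i - 1] == seq[j - 1]) ++n_ident;
      seq_start = j; prof_start = i;
      --i; --j;
      if (p == 0) break;
      state = p;
    } else if (state == 2) {
      unsigned char p = ptrX[IDX(i, j)];
      ++n_cols;
      --i;
      state = (p == 1) ? 1 : 2;
    } else {
      unsigned char p = ptrY[IDX(i, j)];
      ++n_cols;
      --j;
      state = (p == 1) ? 1 : 3;
    }
  }

  return List::create(_["score"] = best,
                      _["seq_start"] = seq_start, _["seq_end"] = best_j,
                      _["prof_start"] = prof_start, _["prof_end"] = best_i,
                      _["n_ident"] = n_ident, _["n_cols"] = n_cols);
}
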