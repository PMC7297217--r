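#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman of a sequence against a position-specific
// scoring profile (Gotoh three-state recursion). Profile scores are integer
// half-bits stored as doubles, so all DP cell values are exact and the
// traceback can test equality safely.
//
// prof: L x 20 score matrix (columns of the model x residue alphabet)
// seq:  1-based residue codes, 0 = unknown residue (scores 0 everywhere)
// gap of length k costs go + ge * k
//
// Returns score and the optimal local path: qstart/qend, cstart/cend and
// col_of_res (for each residue in [qstart,qend], its profile column, 0 if
// the residue is an insertion relative to the profile). Ties are resolved
// deterministically: best cell with smallest sequence end then column end,
// traceback preferring match over deletion over insertion.
// [[Rcpp::export]]
List align_local_cpp(const NumericMatrix& prof, const IntegerVector& seq,
                     double go, double ge) {
  const int L = prof.nrow();
  const int n = seq.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, L + 1), E(n + 1, L + 1), F(n + 1, L + 1);
  for (int j = 0; j <= L; ++j) { H(0, j) = 0; E(0, j) = NEG; F(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { H(i, 0) = 0; E(i, 0) = NEG; F(i, 0) = NEG; }
  double best = 0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= L; ++j) {
      double s = (seq[i - 1] > 0 && seq[i - 1] <= 20) ? prof(j - 1, seq[i - 1] - 1) : 0.0;
      double e = std::max(H(i - 1, j) - go - ge, E(i - 1, j) - ge);
      double f = std::max(H(i, j - 1) - go - ge, F(i, j - 1) - ge);
      double h = H(i - 1, j - 1) + s;
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      E(i, j) = e; F(i, j) = f; H(i, j) = h;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best <= 0) {
    return List::create(_["score"] = 0.0, _["qstart"] = 0, _["qend"] = -1,
                        _["cstart"] = 0, _["cend"] = -1,
                        _["col_of_res"] = IntegerVector(0));
  }
  // traceback: ops recorded backwards; 'M' residue i <-> col j, 'I' residue
  // insert, 'D' column deletion
  std::vector<char> ops;
  std::vector<int> op_i, op_j;
  int i = bi, j = bj;
  char state = 'H';
  while (true) {
    if (state == 'H') {
      if (H(i, j) == 0) break;
      double s = (seq[i - 1] > 0 && seq[i - 1] <= 20) ? prof(j - 1, seq[i - 1] - 1) : 0.0;
      if (i > 0 && j > 0 && H(i, j) == H(i - 1, j - 1) + s) {
        ops.push_back('M'); op_i.push_back(i); op_j.push_back(j);
        --i; --j;
      } else if (H(i, j) == F(i, j)) {
        state = 'F';
      } else if (H(i, j) == E(i, j)) {
        state = 'E';
      } else {
        stop("traceback inconsistency");
      }
    } else if (state == 'F') {
      ops.push_back('D'); op_i.push_back(i); op_j.push_back(j);
      if (F(i, j) == H(i, j - 1) - go - ge) { --j; state = 'H'; }
      else { --j; state = 'F'; }
    } else { // E
      ops.push_back('I'); op_i.push_back(i); op_j.push_back(j);
      if (E(i, j) == H(i - 1, j) - go - ge) { --i; state = 'H'; }
      else { --i; state = 'E'; }
    }
  }
  int qstart = i + 1, cstart = j + 1;
  // walk ops forward (they were recorded backwards)
  IntegerVector col_of_res(bi - qstart + 1);
  int ri = 0;
  for (int k = (int)ops.size() - 1; k >= 0; --k) {
    if (ops[k] == 'M') col_of_res[ri++] = op_j[k];
    else if (ops[k] == 'I') col_of_res[ri++] = 0;
  }
  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = bi,
                      _["cstart"] = cstart, _["cend"] = bj,
                      _["col_of_res"] = col_of_res);
}

// Pairwise percent identity over match columns. sm: n x L integer codes
// (0 = deletion, >0 = residue class). Identity = matches at co-occupied
// columns / min(total residues of the two rows); 0 when nothing co-occupied.
// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(const IntegerMatrix& sm) {
  const int n = sm.nrow(), L = sm.ncol();
  std::vector<int> nres(n, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < L; ++j)
      if (sm(i, j) > 0) ++nres[i];
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    out(a, a) = nres[a] > 0 ? 1.0 : 0.0;
    for (int b = a + 1; b < n; ++b) {
      int match = 0, denom = std::min(nres[a], nres[b]);
      if (denom > 0) {
        for (int j = 0; j < L; ++j)
          if (sm(a, j) > 0 && sm(a, j) == sm(b, j)) ++match;
      }
      double id = denom > 0 ? (double)match / denom : 0.0;
      out(a, b) = id; out(b, a) = id;
    }
  }
  return out;
}

// Sequence reweighting for coupling analysis: weight_i = 1 / |{j : fraction
// of positions with identical state (gap included as a state) >= thresh}|.
// [[Rcpp::export]]
NumericVector dca_weights_cpp(const IntegerMatrix& X, double thresh) {
  const int n = X.nrow(), L = X.ncol();
  std::vector<int> cnt(n, 1); // self
  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int same = 0;
      for (int j = 0; j < L; ++j) if (X(a, j) == X(b, j)) ++same;
      if ((double)same / L >= thresh) { ++cnt[a]; ++cnt[b]; }
    }
  }
  NumericVector w(n);
  for (int i = 0; i < n; ++i) w[i] = 1.0 / cnt[i];
  return w;
}

// Glocal alignment: global across the profile columns (every column is
// consumed by a residue or a deletion), local in the sequence (unaligned
// flanks are free). Used to derive the reported alignment path once a node
// has been chosen by local-alignment score: the projection into root
// coordinates then covers the full domain model, including weakly scoring
// terminal columns a purely local path would trim.
// [[Rcpp::export]]
List align_glocal_cpp(const NumericMatrix& prof, const IntegerVector& seq,
                      double go, double ge) {
  const int L = prof.nrow();
  const int n = seq.size();
  const double NEG = -1e30;
  NumericMatrix H(n + 1, L + 1), E(n + 1, L + 1), F(n + 1, L + 1);
  for (int i = 0; i <= n; ++i) { H(i, 0) = 0; E(i, 0) = NEG; F(i, 0) = NEG; }
  for (int j = 1; j <= L; ++j) {
    H(0, j) = NEG; E(0, j) = NEG;
    F(0, j) = std::max(H(0, j - 1) - go - ge, F(0, j - 1) - ge);
    H(0, j) = F(0, j);
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= L; ++j) {
      double s = (seq[i - 1] > 0 && seq[i - 1] <= 20) ? prof(j - 1, seq[i - 1] - 1) : 0.0;
      double e = std::max(H(i - 1, j) - go - ge, E(i - 1, j) - ge);
      double f = std::max(H(i, j - 1) - go - ge, F(i, j - 1) - ge);
      double h = H(i - 1, j - 1) + s;
      if (e > h) h = e;
      if (f > h) h = f;
      E(i, j) = e; F(i, j) = f; H(i, j) = h;
    }
  }
  int bi = 0; double best = H(0, L);
  for (int i = 1; i <= n; ++i) if (H(i, L) > best) { best = H(i, L); bi = i; }
  std::vector<char> ops;
  std::vector<int> op_i, op_j;
  int i = bi, j = L;
  char state = 'H';
  while (j > 0) {
    if (state == 'H') {
      double s = (i > 0 && seq[i - 1] > 0 && seq[i - 1] <= 20) ? prof(j - 1, seq[i - 1] - 1) : 0.0;
      if (i > 0 && H(i, j) == H(i - 1, j - 1) + s) {
        ops.push_back('M'); op_i.push_back(i); op_j.push_back(j);
        --i; --j;
      } else if (H(i, j) == F(i, j)) {
        state = 'F';
      } else if (H(i, j) == E(i, j)) {
        state = 'E';
      } else {
        stop("glocal traceback inconsistency");
      }
    } else if (state == 'F') {
      ops.push_back('D'); op_i.push_back(i); op_j.push_back(j);
      if (F(i, j) == H(i, j - 1) - go - ge) { --j; state = 'H'; }
      else { --j; state = 'F'; }
    } else { // E
      ops.push_back('I'); op_i.push_back(i); op_j.push_back(j);
      if (E(i, j) == H(i - 1, j) - go - ge) { --i; state = 'H'; }
      else { --i; state = 'E'; }
    }
  }
  // trim leading/trailing insert ops (they are flank, not path)
  int lo = 0, hi = (int)ops.size() - 1; // ops are reversed (end first)
  while (hi >= 0 && ops[hi] == 'I') --hi;   // leading in sequence order
  while (lo <= hi && ops[lo] == 'I') ++lo;  // trailing in sequence order
  int qstart = bi + 1, qend = 0, cstart = 0, cend = 0;
  std::vector<int> cov;
  bool any_res = false;
  for (int k = hi; k >= lo; --k) {
    if (ops[k] == 'M' || ops[k] == 'I') {
      if (!any_res) { qstart = op_i[k]; any_res = true; }
      qend = op_i[k];
      cov.push_back(ops[k] == 'M' ? op_j[k] : 0);
    }
    if (cstart == 0) cstart = op_j[k] > 0 ? op_j[k] : 1;
    cend = op_j[k];
  }
  if (!any_res) {
    return List::create(_["score"] = best, _["qstart"] = 0, _["qend"] = -1,
                        _["cstart"] = 1, _["cend"] = L,
                        _["col_of_res"] = IntegerVector(0));
  }
  IntegerVector col_of_res(cov.size());
  for (size_t k = 0; k < cov.size(); ++k) col_of_res[k] = cov[k];
  return List::create(_["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
                      _["cstart"] = 1, _["cend"] = L,
                      _["col_of_res"] = col_of_res);
}
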