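#include <Rcpp.h>
using namespace Rcpp;

static const double NEG_INF = -1e30;

// Viterbi score of a query against a profile, global in both profile and
// query: every match state is either matched or deleted, every query residue
// is either matched or inserted.  Emission matrix `m` is K x 20 (bits);
// query `q` is 0-based residue indices, -1 for X/unknown (emission 0 bits).
// Deletes cost `del` bits per skipped state (linear); an insert run costs
// `ins_open` for its first residue and `ins_ext` for each later one.
// [[Rcpp::export]]
double viterbi_raw_cpp(NumericMatrix m, IntegerVector q,
                       double del, double ins_open, double ins_ext) {
  const int K = m.nrow();
  const int L = q.size();
  if (K == 0 && L == 0) return 0.0;
  if (K == 0) return -ins_open - ins_ext * (L - 1);
  if (L == 0) return -del * K;
  // rolling rows over profile states: M/D/I best scores ending in a
  // match, delete, or insert, having consumed j query residues
  std::vector<double> pM(L + 1, NEG_INF), pD(L + 1, NEG_INF),
      pI(L + 1, NEG_INF);
  std::vector<double> cM(L + 1), cD(L + 1), cI(L + 1);
  // virtual row 0 (no states consumed): leading inserts only
  pM[0] = 0.0;
  for (int j = 1; j <= L; ++j)
    pI[j] = -ins_open - ins_ext * (j - 1);

  for (int k = 1; k <= K; ++k) {
    cD[0] = std::max(pM[0], std::max(pD[0], pI[0])) - del;
    cM[0] = NEG_INF;
    cI[0] = NEG_INF;
    for (int j = 1; j <= L; ++j) {
      int a = q[j - 1];
      double emit = (a < 0) ? 0.0 : m(k - 1, a);
      cM[j] = emit + std::max(pM[j - 1], std::max(pD[j - 1], pI[j - 1]));
      cD[j] = std::max(pM[j], std::max(pD[j], pI[j])) - del;
      cI[j] = std::max(std::max(cM[j - 1], cD[j - 1]) - ins_open,
                       cI[j - 1] - ins_ext);
    }
    std::swap(pM, cM); std::swap(pD, cD); std::swap(pI, cI);
  }
  return std::max(pM[L], std::max(pD[L], pI[L]));
}

// batch version: scores many integer-encoded queries against one profile
// [[Rcpp::export]]
NumericVector viterbi_raw_batch_cpp(NumericMatrix m, List queries,
                                    double del, double ins_open,
                                    double ins_ext) {
  const int n = queries.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector q = queries[i];
    out[i] = viterbi_raw_cpp(m, q, del, ins_open, ins_ext);
  }
  return out;
}

// Affine-gap global alignment (Gotoh) of a sequence against a fixed profile
// of column scores.  `colsc` is K x A: score of aligning residue a to column
// k; `q` is 0-based indices into the same A-letter alphabet.  Returns the
// operation string encoded as integers: 1 = align column+residue,
// 2 = column against gap (residue skipped in query), 3 = residue against gap
// (new all-gap column inserted into the profile).
// Tie-break order: match > column-gap > residue-gap, applied on traceback.
// [[Rcpp::export]]
List align_profile_seq_cpp(NumericMatrix colsc, IntegerVector q,
                           double gap_open, double gap_ext) {
  const int K = colsc.nrow();
  const int L = q.size();
  std::vector<double> M((K + 1) * (L + 1), NEG_INF);
  std::vector<double> X((K + 1) * (L + 1), NEG_INF);  // gap in query
  std::vector<double> Y((K + 1) * (L + 1), NEG_INF);  // gap in profile
  auto at = [L](int k, int j) { return k * (L + 1) + j; };
  M[at(0, 0)] = 0.0;
  for (int k = 1; k <= K; ++k)
    X[at(k, 0)] = -gap_open - gap_ext * (k - 1);
  for (int j = 1; j <= L; ++j)
    Y[at(0, j)] = -gap_open - gap_ext * (j - 1);

  for (int k = 1; k <= K; ++k) {
    for (int j = 1; j <= L; ++j) {
      double s = colsc(k - 1, q[j - 1]);
      M[at(k, j)] = s + std::max(M[at(k - 1, j - 1)],
                        std::max(X[at(k - 1, j - 1)], Y[at(k - 1, j - 1)]));
      X[at(k, j)] = std::max(M[at(k - 1, j)] - gap_open,
                    std::max(X[at(k - 1, j)] - gap_ext,
                             Y[at(k - 1, j)] - gap_open));
      Y[at(k, j)] = std::max(M[at(k, j - 1)] - gap_open,
                    std::max(Y[at(k, j - 1)] - gap_ext,
                             X[at(k, j - 1)] - gap_open));
    }
  }

  // traceback
  std::vector<int> ops;
  int k = K, j = L;
  double m0 = M[at(k, j)], x0 = X[at(k, j)], y0 = Y[at(k, j)];
  int state = (m0 >= x0 && m0 >= y0) ? 0 : (x0 >= y0 ? 1 : 2);
  double score = std::max(m0, std::max(x0, y0));
  const double eps = 1e-9;
  while (k > 0 || j > 0) {
    if (state == 0) {
      double s = colsc(k - 1, q[j - 1]);
      double need = M[at(k, j)] - s;
      ops.push_back(1);
      if (std::fabs(M[at(k - 1, j - 1)] - need) < eps) state = 0;
      else if (std::fabs(X[at(k - 1, j - 1)] - need) < eps) state = 1;
      else state = 2;
      --k; --j;
    } else if (state == 1) {
      ops.push_back(2);
      double cur = X[at(k, j)];
      if (std::fabs(M[at(k - 1, j)] - gap_open - cur) < eps) state = 0;
      else if (std::fabs(X[at(k - 1, j)] - gap_ext - cur) < eps) state = 1;
      else state = 2;
      --k;
    } else {
      ops.push_back(3);
      double cur = Y[at(k, j)];
      if (std::fabs(M[at(k, j - 1)] - gap_open - cur) < eps) state = 0;
      else if (std::fabs(Y[at(k, j - 1)] - gap_ext - cur) < eps) state = 2;
      else state = 1;
      --j;
    }
    if (k == 0 && j > 0) state = 2;
    if (j == 0 && k > 0) state = 1;
  }
  std::reverse(ops.begin(), ops.end());
  return List::create(_["ops"] = wrap(ops), _["score"] = score);
}
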