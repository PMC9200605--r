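#include <Rcpp.h>
using namespace Rcpp;

// Maximum information content over common ancestors for every pair of terms.
// anc: T x K logical incidence (term i has candidate ancestor k within the
// current search scope); ic_cand: IC of the K candidate ancestors.
// Returns T x T matrix of MICA IC; NA_REAL where no common ancestor exists.
// [[Rcpp::export]]
NumericMatrix mica_ic_matrix_cpp(LogicalMatrix anc, NumericVector ic_cand) {
  int T = anc.nrow(), K = anc.ncol();
  NumericMatrix out(T, T);
  for (int i = 0; i < T; ++i) {
    for (int j = i; j < T; ++j) {
      double best = NA_REAL;
      bool found = false;
      for (int k = 0; k < K; ++k) {
        if (anc(i, k) && anc(j, k)) {
          double v = ic_cand[k];
          if (!found || v > best) { best = v; found = true; }
        }
      }
      out(i, j) = best;
      out(j, i) = best;
    }
  }
  return out;
}

// order of candidate a vs b under (IC descending, index ascending);
// candidate indices are positions in a master list sorted by term id, so the
// index tie-break realises "lexicographically smallest id wins".
static inline bool before(int a, int b, const double *ic) {
  if (ic[a] != ic[b]) return ic[a] > ic[b];
  return a < b;
}

// Global MICA tables over a set of terms. anc_idx: per term, 0-based
// candidate indices of its (self-inclusive) ancestors, pre-sorted by
// (IC desc, index asc). Returns the MICA IC matrix and the matrix of the
// winning candidate index (-1 when no common ancestor).
// [[Rcpp::export]]
List lin_tables_cpp(List anc_idx, NumericVector ic_cand) {
  int T = anc_idx.size();
  const double *ic = ic_cand.begin();
  std::vector<IntegerVector> av(T);
  for (int i = 0; i < T; ++i) av[i] = as<IntegerVector>(anc_idx[i]);
  NumericMatrix M(T, T);
  IntegerMatrix W(T, T);
  for (int i = 0; i < T; ++i) {
    const IntegerVector &A = av[i];
    for (int j = i; j < T; ++j) {
      const IntegerVector &B = av[j];
      int a = 0, b = 0, la = A.size(), lb = B.size();
      int win = -1;
      while (a < la && b < lb) {
        if (A[a] == B[b]) { win = A[a]; break; }
        if (before(A[a], B[b], ic)) ++a; else ++b;
      }
      double v = win >= 0 ? ic[win] : NA_REAL;
      M(i, j) = v; M(j, i) = v;
      W(i, j) = win; W(j, i) = win;
    }
  }
  return List::create(_["M"] = M, _["W"] = W);
}

// Restricted MICA IC for selected term pairs: same merge walk but skipping
// candidates outside the restriction. pairs: 2-column 0-based index matrix
// into anc_idx.
// [[Rcpp::export]]
NumericVector mica_restricted_pairs_cpp(List anc_idx, NumericVector ic_cand,
                                        LogicalVector in_nodes,
                                        IntegerMatrix pairs) {
  const double *ic = ic_cand.begin();
  int T = anc_idx.size();
  std::vector<IntegerVector> av(T);
  for (int i = 0; i < T; ++i) av[i] = as<IntegerVector>(anc_idx[i]);
  int np = pairs.nrow();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const IntegerVector &A = av[pairs(p, 0)], &B = av[pairs(p, 1)];
    int a = 0, b = 0, la = A.size(), lb = B.size();
    double v = NA_REAL;
    while (a < la && b < lb) {
      if (A[a] == B[b]) {
        if (in_nodes[A[a]]) { v = ic[A[a]]; break; }
        ++a; ++b;
      } else if (before(A[a], B[b], ic)) ++a; else ++b;
    }
    out[p] = v;
  }
  return out;
}

// Column-wise best-match table: C[a, j] = max over b in set j of lin(a, b).
// lin: T x T; sets: list of 1-based index vectors into lin (may be empty).
// [[Rcpp::export]]
NumericMatrix set_rowmax_cpp(NumericMatrix lin, List sets) {
  int T = lin.nrow(), n = sets.size();
  NumericMatrix C(T, n);
  for (int j = 0; j < n; ++j) {
    IntegerVector s = as<IntegerVector>(sets[j]);
    for (int k = 0; k < s.size(); ++k) {
      int b = s[k] - 1;
      for (int a = 0; a < T; ++a) {
        double v = lin(a, b);
        if (v > C(a, j)) C(a, j) = v;
      }
    }
  }
  return C;
}

// Reference pairwise best-match-average kernel (kept as the slow oracle for
// the row-max formulation). lin: T x T; sets: 1-based index vectors.
// [[Rcpp::export]]
NumericMatrix bma_matrix_cpp(NumericMatrix lin, List sets) {
  int n = sets.size();
  NumericMatrix out(n, n);
  std::vector<IntegerVector> sv(n);
  for (int i = 0; i < n; ++i) sv[i] = as<IntegerVector>(sets[i]);
  for (int i = 0; i < n; ++i) {
    out(i, i) = sv[i].size() > 0 ? 1.0 : 0.0;
    for (int j = i + 1; j < n; ++j) {
      const IntegerVector &A = sv[i], &B = sv[j];
      int na = A.size(), nb = B.size();
      double s = 0.0;
      if (na > 0 && nb > 0) {
        double sum_a = 0.0;
        std::vector<double> best_b(nb, 0.0);
        for (int a = 0; a < na; ++a) {
          double best = 0.0;
          int ia = A[a] - 1;
          for (int b = 0; b < nb; ++b) {
            double v = lin(ia, B[b] - 1);
            if (v > best) best = v;
            if (v > best_b[b]) best_b[b] = v;
          }
          sum_a += best;
        }
        double sum_b = 0.0;
        for (int b = 0; b < nb; ++b) sum_b += best_b[b];
        s = 0.5 * (sum_a / na + sum_b / nb);
      }
      out(i, j) = s;
      out(j, i) = s;
    }
  }
  return out;
}
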