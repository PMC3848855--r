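#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Deterministic k-NN vote over a distance array. The k nearest neighbours
// are the k smallest (distance, training-row) pairs, kept in a small sorted
// insertion buffer with an early-bail scan: a candidate only enters when it
// is strictly closer than the current k-th neighbour, so distance ties at
// the k-th position resolve by training-row order. Among classes tied on
// vote count the smaller mean neighbour distance wins; remaining ties go to
// the lowest class index.
static int topk_classify(const double *dist, int ntr, const int *ytr, int k,
                         int C, double *bd, int *bi, int *votes,
                         double *dsum) {
  int filled = 0;
  for (int t = 0; t < ntr; ++t) {
    double d = dist[t];
    if (filled == k && d >= bd[k - 1]) continue;
    int pos = (filled < k) ? filled : k - 1;
    while (pos > 0 && d < bd[pos - 1]) {
      bd[pos] = bd[pos - 1];
      bi[pos] = bi[pos - 1];
      --pos;
    }
    bd[pos] = d;
    bi[pos] = t;
    if (filled < k) ++filled;
  }
  for (int c = 0; c < C; ++c) {
    votes[c] = 0;
    dsum[c] = 0.0;
  }
  for (int j = 0; j < k; ++j) {
    int c = ytr[bi[j]] - 1;
    votes[c] += 1;
    dsum[c] += bd[j];
  }
  int best = -1;
  for (int c = 0; c < C; ++c) {
    if (votes[c] == 0) continue;
    if (best < 0 || votes[c] > votes[best]) {
      best = c;
    } else if (votes[c] == votes[best]) {
      double mc = dsum[c] / votes[c], mb = dsum[best] / votes[best];
      if (mc < mb) best = c;  // equal mean distance: keep lower class index
    }
  }
  return best + 1;
}

// [[Rcpp::export]]
IntegerVector knn_predict_cpp(NumericMatrix Xtr, IntegerVector ytr,
                              NumericMatrix Xte, int k, int C) {
  const int ntr = Xtr.nrow(), nte = Xte.nrow(), p = Xtr.ncol();
  if (Xte.ncol() != p) stop("feature width mismatch between train and test");
  if (k < 1 || k > ntr) stop("k must be in 1..n_train");
  const double *xtr = REAL(Xtr), *xte = REAL(Xte);
  const int *ytr_ = INTEGER(ytr);
  IntegerVector out(nte);
  std::vector<double> dist(ntr), bd(k), dsum(C);
  std::vector<int> bi(k), votes(C);
  for (int i = 0; i < nte; ++i) {
    std::fill(dist.begin(), dist.end(), 0.0);
    for (int f = 0; f < p; ++f) {
      const double *col = xtr + (size_t)f * ntr;
      const double xi = xte[(size_t)f * nte + i];
      for (int t = 0; t < ntr; ++t) {
        double d = xi - col[t];
        dist[t] += d * d;
      }
    }
    out[i] = topk_classify(dist.data(), ntr, ytr_, k, C, bd.data(), bi.data(),
                           votes.data(), dsum.data());
  }
  return out;
}

// Test accuracy of every leave-one-feature-out candidate of the current
// subset in one pass: per test point the full-subset squared distances are
// computed once and each candidate's distances obtained by subtracting the
// removed feature's contribution.
// [[Rcpp::export]]
NumericVector knn_candidate_acc_cpp(NumericMatrix Xtr, IntegerVector ytr,
                                    NumericMatrix Xte, IntegerVector yte,
                                    int k, int C) {
  const int ntr = Xtr.nrow(), nte = Xte.nrow(), p = Xtr.ncol();
  if (Xte.ncol() != p) stop("feature width mismatch between train and test");
  if (k < 1 || k > ntr) stop("k must be in 1..n_train");
  if (nte < 1) stop("empty test part");
  const double *xtr = REAL(Xtr), *xte = REAL(Xte);
  const int *ytr_ = INTEGER(ytr);
  std::vector<double> base(ntr), dist(ntr), bd(k), dsum(C);
  std::vector<int> bi(k), votes(C), correct(p, 0);
  for (int i = 0; i < nte; ++i) {
    std::fill(base.begin(), base.end(), 0.0);
    for (int f = 0; f < p; ++f) {
      const double *col = xtr + (size_t)f * ntr;
      const double xi = xte[(size_t)f * nte + i];
      for (int t = 0; t < ntr; ++t) {
        double d = xi - col[t];
        base[t] += d * d;
      }
    }
    for (int f = 0; f < p; ++f) {
      const double *col = xtr + (size_t)f * ntr;
      const double xi = xte[(size_t)f * nte + i];
      for (int t = 0; t < ntr; ++t) {
        double d = xi - col[t];
        double v = base[t] - d * d;
        dist[t] = v > 0 ? v : 0.0;  // guard tiny negative rounding residue
      }
      int pred = topk_classify(dist.data(), ntr, ytr_, k, C, bd.data(),
                               bi.data(), votes.data(), dsum.data());
      if (pred == yte[i]) ++correct[f];
    }
  }
  NumericVector acc(p);
  for (int f = 0; f < p; ++f) acc[f] = (double)correct[f] / nte;
  return acc;
}
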