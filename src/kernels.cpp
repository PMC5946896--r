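#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Shared helpers for the k-nearest-neighbour cross-classification kernels.
//
// Patterns live in a matrix X (observations x voxels). A "fold" is a pair of
// 0-based row index vectors (train, test). A "center" is a 0-based column
// index vector: the in-mask voxels of one searchlight sphere or one ROI.
//
// Feature scaling (z-scoring per voxel) always uses training-fold statistics
// only, so no information leaks from test to train. metric: 0 = Euclidean,
// 1 = correlation distance (implemented by centering + unit-norm scaling of
// each local pattern, which preserves the neighbour ordering of 1 - r).

namespace {

struct FoldLocal {
  // voxel-major local copies: tr[v * ntr + i], te[v * nte + j]
  std::vector<double> tr, te;
  int ntr, nte, nvox;
};

// Gather (and optionally z-score / row-standardise) the local pattern block
// for one fold and one voxel set.
void gather_local(const NumericMatrix& X,
                  const IntegerVector& train, const IntegerVector& test,
                  const IntegerVector& vox,
                  bool scale, int metric, FoldLocal& out) {
  const int ntr = train.size(), nte = test.size(), nv = vox.size();
  out.ntr = ntr; out.nte = nte; out.nvox = nv;
  out.tr.assign((size_t)ntr * nv, 0.0);
  out.te.assign((size_t)nte * nv, 0.0);
  for (int v = 0; v < nv; ++v) {
    const int col = vox[v];
    double mu = 0.0, sd = 1.0;
    if (scale) {
      double s = 0.0, ss = 0.0;
      for (int i = 0; i < ntr; ++i) {
        const double x = X(train[i], col);
        s += x; ss += x * x;
      }
      mu = s / ntr;
      const double var = (ss - ntr * mu * mu) / std::max(1, ntr - 1);
      sd = var > 0 ? std::sqrt(var) : 1.0;
    }
    for (int i = 0; i < ntr; ++i)
      out.tr[(size_t)v * ntr + i] = (X(train[i], col) - mu) / sd;
    for (int j = 0; j < nte; ++j)
      out.te[(size_t)v * nte + j] = (X(test[j], col) - mu) / sd;
  }
  if (metric == 1) {
    // center + unit-norm each pattern across the local voxels
    auto standardise = [nv](std::vector<double>& m, int n) {
      for (int i = 0; i < n; ++i) {
        double s = 0.0;
        for (int v = 0; v < nv; ++v) s += m[(size_t)v * n + i];
        const double mu = s / nv;
        double ss = 0.0;
        for (int v = 0; v < nv; ++v) {
          const double c = m[(size_t)v * n + i] - mu;
          ss += c * c;
        }
        const double nrm = ss > 0 ? std::sqrt(ss) : 1.0;
        for (int v = 0; v < nv; ++v)
          m[(size_t)v * n + i] = (m[(size_t)v * n + i] - mu) / nrm;
      }
    };
    standardise(out.tr, ntr);
    standardise(out.te, nte);
  }
}

// squared Euclidean distances test j -> all train rows
void dist_row(const FoldLocal& L, int j, std::vector<double>& d) {
  const int ntr = L.ntr, nte = L.nte, nv = L.nvox;
  std::fill(d.begin(), d.end(), 0.0);
  for (int v = 0; v < nv; ++v) {
    const double tv = L.te[(size_t)v * nte + j];
    const double* trv = &L.tr[(size_t)v * ntr];
    for (int i = 0; i < ntr; ++i) {
      const double diff = trv[i] - tv;
      d[i] += diff * diff;
    }
  }
}

// neighbour order: ascending distance, ties by training order (stable)
void neighbour_order(const std::vector<double>& d, int ntr,
                     std::vector<int>& ord) {
  ord.resize(ntr);
  for (int i = 0; i < ntr; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&d](int a, int b) { return d[a] < d[b]; });
}

// majority vote among the k nearest; vote ties broken by smallest label
int vote(const std::vector<int>& ord, const IntegerVector& train,
         const int* labels, int k) {
  const int kk = std::min<int>(k, ord.size());
  std::vector<std::pair<int, int> > counts;  // (label, count)
  for (int m = 0; m < kk; ++m) {
    const int lab = labels[train[ord[m]]];
    bool found = false;
    for (auto& c : counts)
      if (c.first == lab) { ++c.second; found = true; break; }
    if (!found) counts.push_back(std::make_pair(lab, 1));
  }
  int best = counts[0].first, bestn = counts[0].second;
  for (auto& c : counts)
    if (c.second > bestn || (c.second == bestn && c.first < best)) {
      best = c.first; bestn = c.second;
    }
  return best;
}

}  // namespace

// Searchlight / ROI k-NN cross-classification.
// Returns correct counts and totals per (center, fold).
//
// For the Euclidean metric the z-scoring is per voxel (independent of the
// sphere), so the whole pattern matrix is scaled once per fold and sphere
// distances accumulate directly from the pre-scaled voxel-major copies.
// The correlation metric standardises each pattern across the sphere's
// voxels, which depends on the sphere, so it takes the per-center path.
// [[Rcpp::export]]
List cpp_knn_folds(NumericMatrix X, IntegerVector labels, List folds,
                   List centers, int k, bool scale, int metric) {
  const int nc = centers.size(), nf = folds.size();
  const int nvox = X.ncol();
  NumericMatrix correct(nc, nf);
  IntegerMatrix total(nc, nf);
  std::vector<double> d;
  std::vector<int> ord;
  FoldLocal L;
  std::vector<double> Tr, Te;  // voxel-major pre-scaled fold copies
  for (int f = 0; f < nf; ++f) {
    List fold = folds[f];
    IntegerVector train = fold["train"], test = fold["test"];
    const int ntr = train.size(), nte = test.size();
    if (ntr == 0) stop("fold %d has an empty training set", f + 1);
    d.assign((size_t)ntr * nte, 0.0);
    ord.reserve(ntr);
    if (metric == 0) {
      Tr.assign((size_t)ntr * nvox, 0.0);
      Te.assign((size_t)nte * nvox, 0.0);
      for (int v = 0; v < nvox; ++v) {
        double mu = 0.0, sd = 1.0;
        if (scale) {
          double s = 0.0, ss = 0.0;
          for (int i = 0; i < ntr; ++i) {
            const double x = X(train[i], v);
            s += x; ss += x * x;
          }
          mu = s / ntr;
          const double var = (ss - ntr * mu * mu) / std::max(1, ntr - 1);
          sd = var > 0 ? std::sqrt(var) : 1.0;
        }
        for (int i = 0; i < ntr; ++i)
          Tr[(size_t)v * ntr + i] = (X(train[i], v) - mu) / sd;
        for (int j = 0; j < nte; ++j)
          Te[(size_t)v * nte + j] = (X(test[j], v) - mu) / sd;
      }
    }
    for (int c = 0; c < nc; ++c) {
      IntegerVector vox = centers[c];
      int corr = 0;
      if (metric == 0) {
        std::fill(d.begin(), d.end(), 0.0);
        for (int vi = 0; vi < vox.size(); ++vi) {
          const double* trv = &Tr[(size_t)vox[vi] * ntr];
          const double* tev = &Te[(size_t)vox[vi] * nte];
          double* dp = &d[0];
          for (int j = 0; j < nte; ++j) {
            const double tv = tev[j];
            for (int i = 0; i < ntr; ++i) {
              const double diff = trv[i] - tv;
              dp[i] += diff * diff;
            }
            dp += ntr;
          }
        }
        for (int j = 0; j < nte; ++j) {
          ord.resize(ntr);
          for (int i = 0; i < ntr; ++i) ord[i] = i;
          const double* dj = &d[(size_t)j * ntr];
          std::stable_sort(ord.begin(), ord.end(),
                           [dj](int a, int b) { return dj[a] < dj[b]; });
          const int pred = vote(ord, train, INTEGER(labels), k);
          if (pred == labels[test[j]]) ++corr;
        }
      } else {
        gather_local(X, train, test, vox, scale, metric, L);
        std::vector<double> drow(ntr);
        for (int j = 0; j < nte; ++j) {
          dist_row(L, j, drow);
          neighbour_order(drow, ntr, ord);
          const int pred = vote(ord, train, INTEGER(labels), k);
          if (pred == labels[test[j]]) ++corr;
        }
      }
      correct(c, f) += corr;
      total(c, f) += nte;
    }
  }
  return List::create(_["correct"] = correct, _["total"] = total);
}

// ROI classification under many label assignments (columns of labels_mat).
// The neighbour ordering depends only on the patterns, so it is computed
// once per fold and reused across label permutations.
// [[Rcpp::export]]
List cpp_roi_perm(NumericMatrix X, IntegerMatrix labels_mat, List folds,
                  IntegerVector voxels, int k, bool scale, int metric) {
  const int nf = folds.size(), P = labels_mat.ncol();
  NumericMatrix correct(P, nf);
  IntegerVector total(nf);
  FoldLocal L;
  std::vector<double> d;
  std::vector<int> ord;
  for (int f = 0; f < nf; ++f) {
    List fold = folds[f];
    IntegerVector train = fold["train"], test = fold["test"];
    if (train.size() == 0) stop("fold %d has an empty training set", f + 1);
    gather_local(X, train, test, voxels, scale, metric, L);
    d.resize(train.size());
    total[f] = test.size();
    std::vector<std::vector<int> > orders(test.size());
    for (int j = 0; j < (int)test.size(); ++j) {
      dist_row(L, j, d);
      neighbour_order(d, L.ntr, ord);
      orders[j] = ord;
    }
    for (int p = 0; p < P; ++p) {
      const int* lab = &labels_mat(0, p);
      int corr = 0;
      for (int j = 0; j < (int)test.size(); ++j) {
        const int pred = vote(orders[j], train, lab, k);
        if (pred == lab[test[j]]) ++corr;
      }
      correct(p, f) = corr;
    }
  }
  return List::create(_["correct"] = correct, _["total"] = total);
}

// Connected components of a binary 3-D volume under 6/18/26-connectivity.
// Labels are 1..K in first-encounter (column-major scan) order; 0 elsewhere.
// [[Rcpp::export]]
IntegerVector cpp_label_clusters(IntegerVector supra, IntegerVector dim,
                                 int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (supra.size() != n) stop("volume length does not match dim");
  std::vector<std::array<int, 3> > offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        const int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        offs.push_back({{dx, dy, dz}});
      }
  IntegerVector labels(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!supra[s] || labels[s]) continue;
    labels[s] = ++next;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int x = cur % nx, y = (cur / nx) % ny, z = cur / ((R_xlen_t)nx * ny);
      for (const auto& o : offs) {
        const int xx = x + o[0], yy = y + o[1], zz = z + o[2];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        const R_xlen_t idx = xx + (R_xlen_t)nx * (yy + (R_xlen_t)ny * zz);
        if (supra[idx] && !labels[idx]) {
          labels[idx] = next;
          stack.push_back(idx);
        }
      }
    }
  }
  labels.attr("n_clusters") = next;
  return labels;
}
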