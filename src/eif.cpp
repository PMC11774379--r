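#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Average path length of an unsuccessful binary-search-tree lookup among n
// points; the normaliser c(n) of the isolation-forest anomaly score.
static double cfac(double n) {
  if (n <= 1.0) return 0.0;
  if (n == 2.0) return 1.0;
  const double gamma_e = 0.5772156649;
  return 2.0 * (std::log(n - 1.0) + gamma_e) - 2.0 * (n - 1.0) / n;
}

struct TreeAccum {
  std::vector<double> normal, pvec; // nnodes x d, row-major
  std::vector<int> left, right, size, leaf;
  int d;
  explicit TreeAccum(int d_) : d(d_) {}
  int add() {
    int id = (int)left.size();
    left.push_back(0);
    right.push_back(0);
    size.push_back(0);
    leaf.push_back(0);
    normal.insert(normal.end(), d, 0.0);
    pvec.insert(pvec.end(), d, 0.0);
    return id;
  }
};

// Grow one node over X[idx[lo..hi)]. Splits use a random hyperplane: a normal
// with N(0,1) entries (d - el - 1 coordinates zeroed at random) and an
// intercept drawn uniformly inside the node's bounding box.
static int build_node(const NumericMatrix& X, std::vector<int>& idx, int lo, int hi,
                      int depth, int depth_limit, int el, TreeAccum& T) {
  int node = T.add();
  int n = hi - lo, d = T.d;

  bool same = n > 1;
  for (int i = lo + 1; i < hi && same; ++i)
    for (int j = 0; j < d; ++j)
      if (X(idx[i], j) != X(idx[lo], j)) { same = false; break; }

  if (n <= 1 || depth >= depth_limit || same) {
    T.leaf[node] = 1;
    T.size[node] = n;
    return node;
  }

  std::vector<double> w(d), p(d);
  for (int j = 0; j < d; ++j) w[j] = norm_rand();
  int nzero = d - el - 1;
  if (nzero > 0) {
    std::vector<int> dims(d);
    for (int j = 0; j < d; ++j) dims[j] = j;
    for (int j = 0; j < nzero; ++j) {
      int pick = j + (int)std::floor(unif_rand() * (d - j));
      if (pick >= d) pick = d - 1;
      std::swap(dims[j], dims[pick]);
      w[dims[j]] = 0.0;
    }
  }
  for (int j = 0; j < d; ++j) {
    double mn = X(idx[lo], j), mx = mn;
    for (int i = lo + 1; i < hi; ++i) {
      double v = X(idx[i], j);
      if (v < mn) mn = v;
      if (v > mx) mx = v;
    }
    p[j] = mn + unif_rand() * (mx - mn);
  }

  int i = lo, k = hi - 1;
  while (i <= k) {
    double s = 0.0;
    for (int j = 0; j < d; ++j) s += (X(idx[i], j) - p[j]) * w[j];
    if (s <= 0.0) {
      ++i;
    } else {
      std::swap(idx[i], idx[k]);
      --k;
    }
  }
  int mid = i;

  for (int j = 0; j < d; ++j) {
    T.normal[(size_t)node * d + j] = w[j];
    T.pvec[(size_t)node * d + j] = p[j];
  }
  T.size[node] = n;
  int lc = build_node(X, idx, lo, mid, depth + 1, depth_limit, el, T);
  int rc = build_node(X, idx, mid, hi, depth + 1, depth_limit, el, T);
  T.left[node] = lc + 1;  // 1-based child ids, 0 = none
  T.right[node] = rc + 1;
  return node;
}

// [[Rcpp::export(name = ".eif_build")]]
List eif_build(NumericMatrix X, IntegerMatrix samp, int el, int depth_limit) {
  int d = X.ncol(), sub = samp.nrow(), ntrees = samp.ncol();
  List trees(ntrees);
  for (int t = 0; t < ntrees; ++t) {
    std::vector<int> idx(sub);
    for (int i = 0; i < sub; ++i) idx[i] = samp(i, t) - 1;
    TreeAccum acc(d);
    build_node(X, idx, 0, sub, 0, depth_limit, el, acc);
    int nn = (int)acc.left.size();
    NumericMatrix normal(nn, d), pvec(nn, d);
    for (int r = 0; r < nn; ++r)
      for (int j = 0; j < d; ++j) {
        normal(r, j) = acc.normal[(size_t)r * d + j];
        pvec(r, j) = acc.pvec[(size_t)r * d + j];
      }
    trees[t] = List::create(
        Named("normal") = normal, Named("pvec") = pvec,
        Named("left") = IntegerVector(acc.left.begin(), acc.left.end()),
        Named("right") = IntegerVector(acc.right.begin(), acc.right.end()),
        Named("size") = IntegerVector(acc.size.begin(), acc.size.end()),
        Named("leaf") = IntegerVector(acc.leaf.begin(), acc.leaf.end()));
  }
  return trees;
}

// Path length (edges traversed plus the leaf-size correction c(size)) of each
// row of Y in each tree.
// [[Rcpp::export(name = ".eif_paths")]]
NumericMatrix eif_paths(List trees, NumericMatrix Y) {
  int npts = Y.nrow(), d = Y.ncol(), ntrees = trees.size();
  NumericMatrix out(npts, ntrees);
  for (int t = 0; t < ntrees; ++t) {
    List tr = trees[t];
    NumericMatrix normal = tr["normal"], pvec = tr["pvec"];
    IntegerVector left = tr["left"], right = tr["right"];
    IntegerVector size = tr["size"], leaf = tr["leaf"];
    for (int i = 0; i < npts; ++i) {
      int node = 0, depth = 0;
      while (!leaf[node]) {
        double s = 0.0;
        for (int j = 0; j < d; ++j) s += (Y(i, j) - pvec(node, j)) * normal(node, j);
        node = (s <= 0.0 ? left[node] : right[node]) - 1;
        ++depth;
      }
      out(i, t) = depth + cfac((double)size[node]);
    }
  }
  return out;
}

// For each column of A (d x nA), the summed Euclidean distance to every
// column of B (d x nB). Used to maintain buffer distance sums incrementally.
// [[Rcpp::export(name = ".cross_distance_sums")]]
NumericVector cross_distance_sums(NumericMatrix A, NumericMatrix B) {
  int d = A.nrow(), nA = A.ncol(), nB = B.ncol();
  if (B.nrow() != d) stop("dimension mismatch");
  NumericVector sums(nA);
  const double* a = A.begin();
  const double* b = B.begin();
  for (int j = 0; j < nA; ++j) {
    const double* aj = a + (size_t)j * d;
    double acc = 0.0;
    for (int k = 0; k < nB; ++k) {
      const double* bk = b + (size_t)k * d;
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = aj[m] - bk[m];
        s += diff * diff;
      }
      acc += std::sqrt(s);
    }
    sums[j] = acc;
  }
  return sums;
}

// Sum of Euclidean distances from each column of X (d x N, vectors as
// columns) to every other column; the medoid is the column minimising it.
// [[Rcpp::export(name = ".medoid_distance_sums")]]
NumericVector medoid_distance_sums(NumericMatrix X) {
  int d = X.nrow(), N = X.ncol();
  NumericVector sums(N);
  const double* base = X.begin();
  for (int j = 0; j < N; ++j) {
    const double* xj = base + (size_t)j * d;
    for (int k = j + 1; k < N; ++k) {
      const double* xk = base + (size_t)k * d;
      double s = 0.0;
      for (int m = 0; m < d; ++m) {
        double diff = xj[m] - xk[m];
        s += diff * diff;
      }
      double dist = std::sqrt(s);
      sums[j] += dist;
      sums[k] += dist;
    }
  }
  return sums;
}
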