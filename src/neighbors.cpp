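#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>

// 3-d KD-tree used for all neighborhood queries (SOR denoising, DBSCAN,
// distance-to-part queries). Median split on the widest dimension,
// leaf buckets of 16 points.

namespace {

struct Node {
  int lo, hi;        // range in idx (leaf) or unused (internal)
  int left, right;   // child node ids, -1 for leaf
  int axis;
  double split;
};

class KDTree {
public:
  KDTree(const double* pts, int n) : pts_(pts), n_(n), idx_(n) {
    for (int i = 0; i < n; ++i) idx_[i] = i;
    if (n > 0) root_ = build(0, n);
  }

  // k nearest neighbours of an arbitrary point; optionally exclude one index.
  // Returns squared distances (sorted ascending) in out.
  void knn(const double* q, int k, int exclude, std::vector<double>& out) const {
    heap_ = std::priority_queue<std::pair<double, int> >();
    k_ = k; exclude_ = exclude;
    search_knn(root_, q);
    out.resize(heap_.size());
    for (int i = (int)heap_.size() - 1; i >= 0; --i) {
      out[i] = heap_.top().first;
      heap_.pop();
    }
  }

  // nearest neighbour: squared distance and index; cap2 > 0 bounds the search
  // (points farther than sqrt(cap2) report d2 = cap2, which = -1)
  void nn1(const double* q, double& d2, int& which, double cap2 = -1.0) const {
    best_d2_ = cap2 > 0 ? cap2 : R_PosInf; best_i_ = -1;
    search_nn1(root_, q);
    d2 = best_d2_; which = best_i_;
  }

  // all points within radius r (squared r2) of point q
  void radius(const double* q, double r2, std::vector<int>& out) const {
    out.clear();
    search_radius(root_, q, r2, out);
  }

private:
  const double* pts_;
  int n_;
  std::vector<int> idx_;
  std::vector<Node> nodes_;
  int root_ = -1;

  mutable std::priority_queue<std::pair<double, int> > heap_;
  mutable int k_ = 0, exclude_ = -1;
  mutable double best_d2_ = 0.0;
  mutable int best_i_ = -1;

  inline double coord(int i, int ax) const { return pts_[3 * i + ax]; }

  inline double dist2(const double* q, int i) const {
    double dx = q[0] - pts_[3 * i];
    double dy = q[1] - pts_[3 * i + 1];
    double dz = q[2] - pts_[3 * i + 2];
    return dx * dx + dy * dy + dz * dz;
  }

  int build(int lo, int hi) {
    Node nd;
    nd.lo = lo; nd.hi = hi; nd.left = nd.right = -1; nd.axis = 0; nd.split = 0.0;
    int id = (int)nodes_.size();
    nodes_.push_back(nd);
    if (hi - lo <= 16) return id;
    double mn[3], mx[3];
    for (int ax = 0; ax < 3; ++ax) { mn[ax] = R_PosInf; mx[ax] = R_NegInf; }
    for (int i = lo; i < hi; ++i)
      for (int ax = 0; ax < 3; ++ax) {
        double v = coord(idx_[i], ax);
        if (v < mn[ax]) mn[ax] = v;
        if (v > mx[ax]) mx[ax] = v;
      }
    int axis = 0;
    double wid = mx[0] - mn[0];
    for (int ax = 1; ax < 3; ++ax)
      if (mx[ax] - mn[ax] > wid) { wid = mx[ax] - mn[ax]; axis = ax; }
    if (wid <= 0.0) return id;  // all points identical: keep as leaf
    int mid = lo + (hi - lo) / 2;
    const double* pts = pts_;
    std::nth_element(idx_.begin() + lo, idx_.begin() + mid, idx_.begin() + hi,
                     [pts, axis](int a, int b) {
                       return pts[3 * a + axis] < pts[3 * b + axis];
                     });
    nodes_[id].axis = axis;
    nodes_[id].split = coord(idx_[mid], axis);
    int l = build(lo, mid);
    int r = build(mid, hi);
    nodes_[id].left = l;
    nodes_[id].right = r;
    return id;
  }

  void search_knn(int id, const double* q) const {
    const Node& nd = nodes_[id];
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx_[i];
        if (j == exclude_) continue;
        double d2 = dist2(q, j);
        if ((int)heap_.size() < k_) heap_.push(std::make_pair(d2, j));
        else if (d2 < heap_.top().first) { heap_.pop(); heap_.push(std::make_pair(d2, j)); }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search_knn(near, q);
    double worst = (int)heap_.size() < k_ ? R_PosInf : heap_.top().first;
    if (diff * diff <= worst) search_knn(far, q);
  }

  void search_nn1(int id, const double* q) const {
    const Node& nd = nodes_[id];
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx_[i];
        double d2 = dist2(q, j);
        if (d2 < best_d2_ || (d2 == best_d2_ && j < best_i_)) { best_d2_ = d2; best_i_ = j; }
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search_nn1(near, q);
    if (diff * diff <= best_d2_) search_nn1(far, q);
  }

  void search_radius(int id, const double* q, double r2, std::vector<int>& out) const {
    const Node& nd = nodes_[id];
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx_[i];
        if (dist2(q, j) <= r2) out.push_back(j);
      }
      return;
    }
    double diff = q[nd.axis] - nd.split;
    int near = diff <= 0 ? nd.left : nd.right;
    int far = diff <= 0 ? nd.right : nd.left;
    search_radius(near, q, r2, out);
    if (diff * diff <= r2) search_radius(far, q, r2, out);
  }
};

} // namespace

// [[Rcpp::export]]
Rcpp::NumericVector cpp_knn_mean_dist(Rcpp::NumericMatrix coords, int k) {
  int n = coords.nrow();
  if (k < 1) Rcpp::stop("k must be >= 1");
  if (n <= k) Rcpp::stop("need more points than k");
  // column-major R matrix -> packed row-major xyz
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0);
    pts[3 * i + 1] = coords(i, 1);
    pts[3 * i + 2] = coords(i, 2);
  }
  KDTree tree(pts.data(), n);
  Rcpp::NumericVector out(n);
  std::vector<double> d2;
  for (int i = 0; i < n; ++i) {
    tree.knn(&pts[3 * i], k, i, d2);
    double s = 0.0;
    for (size_t j = 0; j < d2.size(); ++j) s += std::sqrt(d2[j]);
    out[i] = s / (double)d2.size();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_nn_to_set(Rcpp::NumericMatrix query, Rcpp::NumericMatrix ref,
                         double cap = -1.0) {
  int nq = query.nrow(), nr = ref.nrow();
  if (nr < 1) Rcpp::stop("reference set is empty");
  std::vector<double> pts(3 * nr);
  for (int i = 0; i < nr; ++i) {
    pts[3 * i] = ref(i, 0);
    pts[3 * i + 1] = ref(i, 1);
    pts[3 * i + 2] = ref(i, 2);
  }
  KDTree tree(pts.data(), nr);
  Rcpp::NumericVector dist(nq);
  Rcpp::IntegerVector index(nq);
  double q[3];
  double cap2 = cap > 0 ? cap * cap : -1.0;
  for (int i = 0; i < nq; ++i) {
    q[0] = query(i, 0); q[1] = query(i, 1); q[2] = query(i, 2);
    double d2; int which;
    tree.nn1(q, d2, which, cap2);
    dist[i] = std::sqrt(d2);
    index[i] = which + 1;  // 1-based; 0 when no neighbour within cap
  }
  return Rcpp::List::create(Rcpp::Named("dist") = dist,
                            Rcpp::Named("index") = index);
}

// DBSCAN with Euclidean eps-neighbourhoods. minPts counts the point itself
// (the scikit-learn convention). Returns 0 for noise, clusters numbered 1..K
// in order of discovery (scan order = point order), so the labelling is
// deterministic for a given point order.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_dbscan(Rcpp::NumericMatrix coords, double eps, int min_pts) {
  int n = coords.nrow();
  if (eps <= 0) Rcpp::stop("eps must be > 0");
  if (min_pts < 1) Rcpp::stop("min_pts must be >= 1");
  std::vector<double> pts(3 * n);
  for (int i = 0; i < n; ++i) {
    pts[3 * i] = coords(i, 0);
    pts[3 * i + 1] = coords(i, 1);
    pts[3 * i + 2] = coords(i, 2);
  }
  KDTree tree(pts.data(), n);
  double r2 = eps * eps;
  const int UNVISITED = -1, NOISE = 0;
  std::vector<int> label(n, UNVISITED);
  std::vector<int> nbrs, nbrs2;
  std::vector<int> stack;
  int ncl = 0;
  for (int i = 0; i < n; ++i) {
    if (label[i] != UNVISITED) continue;
    tree.radius(&pts[3 * i], r2, nbrs);
    if ((int)nbrs.size() < min_pts) { label[i] = NOISE; continue; }
    ++ncl;
    label[i] = ncl;
    stack.clear();
    for (size_t q = 0; q < nbrs.size(); ++q) {
      int j = nbrs[q];
      if (label[j] == UNVISITED) { label[j] = ncl; stack.push_back(j); }
      else if (label[j] == NOISE) label[j] = ncl;   // border point
    }
    while (!stack.empty()) {
      int j = stack.back();
      stack.pop_back();
      tree.radius(&pts[3 * j], r2, nbrs2);
      if ((int)nbrs2.size() < min_pts) continue;    // border: no expansion
      for (size_t q = 0; q < nbrs2.size(); ++q) {
        int m = nbrs2[q];
        if (label[m] == UNVISITED) { label[m] = ncl; stack.push_back(m); }
        else if (label[m] == NOISE) label[m] = ncl;
      }
    }
  }
  return Rcpp::IntegerVector(label.begin(), label.end());
}
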