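#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Static kd-tree with Chebyshev (max-norm) metric, used by the
// Kraskov-style conditional mutual information estimator and by the
// Cao embedding statistics. Points are stored row-major; nodes keep
// axis-aligned bounding boxes for pruning.
//
// Temporal exclusion (Theiler window) is handled outside the tree:
// range counts are done over all points and the few excluded
// temporal neighbours (same trial, |dt| <= T) are subtracted by a
// direct scan, which keeps subtree count shortcuts valid. k-NN
// queries skip excluded points while scanning leaves.

namespace {

struct KDTree {
  int n = 0, D = 0, leaf = 24;
  std::vector<double> pts;            // row-major n x D
  std::vector<int> idx;               // permutation: tree order -> original
  struct Node { int lo, hi, left, right, axis; double split; };
  std::vector<Node> nodes;
  std::vector<double> bbmin, bbmax;   // per node, D values each

  void build(const double* data, int n_, int D_) {
    n = n_; D = D_;
    pts.assign(n * D, 0.0);
    idx.resize(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    // copy row-major
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < D; ++d) pts[i * D + d] = data[i + (size_t)n * d];
    nodes.clear(); bbmin.clear(); bbmax.clear();
    if (n > 0) build_rec(0, n);
  }

  int build_rec(int lo, int hi) {
    int id = (int)nodes.size();
    nodes.push_back(Node{lo, hi, -1, -1, -1, 0.0});
    bbmin.insert(bbmin.end(), D, R_PosInf);
    bbmax.insert(bbmax.end(), D, R_NegInf);
    for (int i = lo; i < hi; ++i) {
      const double* p = &pts[(size_t)idx[i] * D];
      for (int d = 0; d < D; ++d) {
        if (p[d] < bbmin[(size_t)id * D + d]) bbmin[(size_t)id * D + d] = p[d];
        if (p[d] > bbmax[(size_t)id * D + d]) bbmax[(size_t)id * D + d] = p[d];
      }
    }
    if (hi - lo <= leaf) return id;
    // widest dimension
    int ax = 0; double w = -1.0;
    for (int d = 0; d < D; ++d) {
      double wd = bbmax[(size_t)id * D + d] - bbmin[(size_t)id * D + d];
      if (wd > w) { w = wd; ax = d; }
    }
    if (w <= 0.0) return id;  // all points identical: keep as leaf
    int mid = (lo + hi) / 2;
    const std::vector<double>& P = pts; const int DD = D;
    std::nth_element(idx.begin() + lo, idx.begin() + mid, idx.begin() + hi,
                     [&P, DD, ax](int a, int b) {
                       return P[(size_t)a * DD + ax] < P[(size_t)b * DD + ax];
                     });
    nodes[id].axis = ax;
    nodes[id].split = pts[(size_t)idx[mid] * D + ax];
    int l = build_rec(lo, mid);
    int r = build_rec(mid, hi);
    nodes[id].left = l; nodes[id].right = r;
    return id;
  }

  inline double dist_cheb(const double* q, int j) const {
    const double* p = &pts[(size_t)j * D];
    double m = 0.0;
    for (int d = 0; d < D; ++d) {
      double a = std::fabs(q[d] - p[d]);
      if (a > m) m = a;
    }
    return m;
  }

  // Chebyshev distance with early exit once `cap` is reached/passed;
  // returns a value >= cap when the true distance is >= cap.
  inline double dist_cheb_capped(const double* q, int j, double cap) const {
    const double* p = &pts[(size_t)j * D];
    double m = 0.0;
    for (int d = 0; d < D; ++d) {
      double a = std::fabs(q[d] - p[d]);
      if (a > m) {
        if (a >= cap) return a;
        m = a;
      }
    }
    return m;
  }

  inline double mindist_box(const double* q, int id) const {
    double m = 0.0;
    for (int d = 0; d < D; ++d) {
      double lo = bbmin[(size_t)id * D + d], hi = bbmax[(size_t)id * D + d];
      double a = 0.0;
      if (q[d] < lo) a = lo - q[d]; else if (q[d] > hi) a = q[d] - hi;
      if (a > m) m = a;
    }
    return m;
  }

  inline double maxdist_box(const double* q, int id) const {
    double m = 0.0;
    for (int d = 0; d < D; ++d) {
      double a = std::max(std::fabs(q[d] - bbmin[(size_t)id * D + d]),
                          std::fabs(q[d] - bbmax[(size_t)id * D + d]));
      if (a > m) m = a;
    }
    return m;
  }

  // distance to the k-th closest allowed point; `excluded(j)` marks
  // temporal neighbours to skip. Max-heap of current k best.
  template <typename Excl>
  double kth_dist(const double* q, int k, const Excl& excluded) const {
    std::vector<double> heap;
    heap.reserve(k + 1);
    kth_rec(0, q, k, excluded, heap);
    if ((int)heap.size() < k) return R_PosInf;
    return heap.front();
  }

  template <typename Excl>
  void kth_rec(int id, const double* q, int k, const Excl& excluded,
               std::vector<double>& heap) const {
    const Node& nd = nodes[id];
    if ((int)heap.size() == k && mindist_box(q, id) >= heap.front()) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx[i];
        if (excluded(j)) continue;
        if ((int)heap.size() < k) {
          double d = dist_cheb(q, j);
          heap.push_back(d); std::push_heap(heap.begin(), heap.end());
        } else {
          double d = dist_cheb_capped(q, j, heap.front());
          if (d < heap.front()) {
            std::pop_heap(heap.begin(), heap.end());
            heap.back() = d; std::push_heap(heap.begin(), heap.end());
          }
        }
      }
      return;
    }
    int ax = nd.axis;
    int first = (q[ax] <= nd.split) ? nd.left : nd.right;
    int second = (first == nd.left) ? nd.right : nd.left;
    kth_rec(first, q, k, excluded, heap);
    kth_rec(second, q, k, excluded, heap);
  }

  // count of ALL points with distance strictly < r (no exclusion)
  int count_within(const double* q, double r) const {
    if (n == 0 || !(r > 0)) return 0;
    return count_rec(0, q, r);
  }

  int count_rec(int id, const double* q, double r) const {
    const Node& nd = nodes[id];
    if (mindist_box(q, id) >= r) return 0;
    if (maxdist_box(q, id) < r) return nd.hi - nd.lo;
    if (nd.left < 0) {
      int c = 0;
      for (int i = nd.lo; i < nd.hi; ++i)
        if (dist_cheb_capped(q, idx[i], r) < r) ++c;
      return c;
    }
    return count_rec(nd.left, q, r) + count_rec(nd.right, q, r);
  }

  // nearest allowed neighbour with strictly positive distance
  template <typename Excl>
  void nn1_pos(const double* q, const Excl& excluded, int self,
               int& best_j, double& best_d) const {
    best_j = -1; best_d = R_PosInf;
    nn1_rec(0, q, excluded, self, best_j, best_d);
  }

  template <typename Excl>
  void nn1_rec(int id, const double* q, const Excl& excluded, int self,
               int& best_j, double& best_d) const {
    const Node& nd = nodes[id];
    if (mindist_box(q, id) >= best_d) return;
    if (nd.left < 0) {
      for (int i = nd.lo; i < nd.hi; ++i) {
        int j = idx[i];
        if (j == self || excluded(j)) continue;
        double d = dist_cheb(q, j);
        if (d > 0.0 && d < best_d) { best_d = d; best_j = j; }
      }
      return;
    }
    int ax = nd.axis;
    int first = (q[ax] <= nd.split) ? nd.left : nd.right;
    int second = (first == nd.left) ? nd.right : nd.left;
    nn1_rec(first, q, excluded, self, best_j, best_d);
    nn1_rec(second, q, excluded, self, best_j, best_d);
  }
};

// Temporal exclusion: point j is excluded for query point i when it
// lies in the same trial within the Theiler window (|t_i - t_j| <= T).
// The self point always satisfies this (dt = 0, T >= 0).
struct TheilerExcl {
  const int* trial; const int* tm; int i; int T;
  inline bool operator()(int j) const {
    return trial[j] == trial[i] && std::abs(tm[j] - tm[i]) <= T;
  }
};

// number of excluded points (other than in counts over all points)
// within strict radius r of query i, found by direct scan over the
// temporal neighbourhood. Points of one trial are stored contiguously
// and in time order, so candidates live in positions [i - span, i + span].
inline int excluded_within(int i, double r,
                           const int* trial, const int* tm, int T, int n,
                           int Dq, const double* allpts) {
  int c = 0;
  // span: time indices step by 1 within a trial
  for (int j = std::max(0, i - T); j <= std::min(n - 1, i + T); ++j) {
    if (trial[j] != trial[i] || std::abs(tm[j] - tm[i]) > T) continue;
    double m = 0.0;
    for (int d = 0; d < Dq; ++d) {
      double a = std::fabs(allpts[i + (size_t)n * d] - allpts[j + (size_t)n * d]);
      if (a > m) m = a;
    }
    if (m < r) ++c;
  }
  return c;
}

}  // namespace

// Kraskov/Frenzel-Pompe conditional mutual information
// I(xf ; yp | xp) in nats, the transfer-entropy core. Inputs are the
// future sink samples (xf, n x 1), the sink past states (xp, n x dx)
// and the source past states (yp, n x dy), plus per-point trial ids
// and within-trial time indices for Theiler exclusion. Points of a
// trial must be contiguous and in time order.
// [[Rcpp::export]]
List ksg_cmi_cpp(NumericVector xf, NumericMatrix xp, NumericMatrix yp,
                 IntegerVector trial, IntegerVector tm, int k, int theiler) {
  const int n = xf.size();
  const int dx = xp.ncol(), dy = yp.ncol();
  if (xp.nrow() != n || yp.nrow() != n)
    stop("state matrices must have one row per future sample");
  if (k < 1) stop("k must be >= 1");
  const int Dj = 1 + dx + dy;

  // column-major blocks: joint = [xf | xp | yp], m1 = [xf | xp],
  // m2 = [xp | yp], m3 = [xp]
  std::vector<double> joint((size_t)n * Dj), m1((size_t)n * (1 + dx)),
      m2((size_t)n * (dx + dy));
  for (int i = 0; i < n; ++i) joint[i] = xf[i];
  for (int d = 0; d < dx; ++d)
    for (int i = 0; i < n; ++i) joint[(size_t)(1 + d) * n + i] = xp(i, d);
  for (int d = 0; d < dy; ++d)
    for (int i = 0; i < n; ++i) joint[(size_t)(1 + dx + d) * n + i] = yp(i, d);
  std::copy(joint.begin(), joint.begin() + (size_t)n * (1 + dx), m1.begin());
  std::copy(joint.begin() + n, joint.begin() + (size_t)n * (1 + dx + dy),
            m2.begin());

  KDTree t_joint, t_m1, t_m2;
  t_joint.build(joint.data(), n, Dj);
  t_m1.build(m1.data(), n, 1 + dx);
  t_m2.build(m2.data(), n, dx + dy);

  // sink-past subspace: sorted-array fast path when 1-D
  KDTree t_m3;
  std::vector<double> m3sorted;
  if (dx == 1) {
    m3sorted.assign(joint.begin() + n, joint.begin() + 2 * (size_t)n);
    std::sort(m3sorted.begin(), m3sorted.end());
  } else {
    t_m3.build(joint.data() + n, n, dx);
  }

  const int* ptrial = INTEGER(trial);
  const int* ptm = INTEGER(tm);

  double acc = 0.0;
  int used = 0;
  std::vector<double> q(Dj);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < Dj; ++d) q[d] = joint[(size_t)d * n + i];
    TheilerExcl ex{ptrial, ptm, i, theiler};
    double eps = t_joint.kth_dist(q.data(), k, ex);
    if (!R_FINITE(eps) || eps <= 0.0) continue;  // degenerate (ties); caller jitters
    // counts strictly within eps, Theiler-excluded
    int n1 = t_m1.count_within(q.data(), eps) -
             excluded_within(i, eps, ptrial, ptm, theiler, n, 1 + dx, m1.data());
    int n2 = t_m2.count_within(&q[1], eps) -
             excluded_within(i, eps, ptrial, ptm, theiler, n, dx + dy, m2.data());
    int n3;
    if (dx == 1) {
      n3 = (int)(std::lower_bound(m3sorted.begin(), m3sorted.end(), q[1] + eps) -
                 std::upper_bound(m3sorted.begin(), m3sorted.end(), q[1] - eps)) -
           excluded_within(i, eps, ptrial, ptm, theiler, n, dx, joint.data() + n);
    } else {
      n3 = t_m3.count_within(&q[1], eps) -
           excluded_within(i, eps, ptrial, ptm, theiler, n, dx, joint.data() + n);
    }
    acc += R::digamma((double)n3 + 1.0) - R::digamma((double)n1 + 1.0) -
           R::digamma((double)n2 + 1.0);
    ++used;
  }
  if (used == 0) stop("no usable state vectors (degenerate input?)");
  double cmi = R::digamma((double)k) + acc / used;
  return List::create(_["cmi_nats"] = cmi, _["n_used"] = used, _["n"] = n);
}

// Nearest neighbour (strictly positive Chebyshev distance) for each
// row of `pts`, with Theiler exclusion; returns 1-based indices and
// distances. Used by the Cao embedding statistics.
// [[Rcpp::export]]
List nn1_cpp(NumericMatrix pts, IntegerVector trial, IntegerVector tm,
             int theiler) {
  const int n = pts.nrow(), D = pts.ncol();
  KDTree tr;
  tr.build(REAL(pts), n, D);
  IntegerVector out_idx(n);
  NumericVector out_dist(n);
  const int* ptrial = INTEGER(trial);
  const int* ptm = INTEGER(tm);
  std::vector<double> q(D);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < D; ++d) q[d] = pts(i, d);
    TheilerExcl ex{ptrial, ptm, i, theiler};
    int bj; double bd;
    tr.nn1_pos(q.data(), ex, i, bj, bd);
    out_idx[i] = (bj < 0) ? NA_INTEGER : bj + 1;
    out_dist[i] = (bj < 0) ? NA_REAL : bd;
  }
  return List::create(_["index"] = out_idx, _["dist"] = out_dist);
}
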