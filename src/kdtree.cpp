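#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Static 3-d k-d tree over a point set, used for nearest-neighbour segment
// matching. Ties in distance are always broken towards the lowest point
// index so results are independent of build/traversal order.

namespace {

struct KdNode {
  int left = -1, right = -1;  // child node ids; -1 = leaf
  int begin = 0, end = 0;     // index range into `order` (leaves only)
  int dim = 0;                // split dimension
  double split = 0.0;         // split coordinate
};

const int LEAF_SIZE = 8;

struct KdTree {
  const double* x;  // column-major n x 3
  int n;
  std::vector<int> order;
  std::vector<KdNode> nodes;

  double coord(int i, int d) const { return x[i + d * (size_t)n]; }

  int build(int begin, int end) {
    int id = (int)nodes.size();
    nodes.push_back(KdNode());
    if (end - begin <= LEAF_SIZE) {
      nodes[id].begin = begin;
      nodes[id].end = end;
      return id;
    }
    // split on the dimension with the widest extent
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int k = begin; k < end; ++k)
      for (int d = 0; d < 3; ++d) {
        double v = coord(order[k], d);
        if (v < lo[d]) lo[d] = v;
        if (v > hi[d]) hi[d] = v;
      }
    int dim = 0;
    for (int d = 1; d < 3; ++d)
      if (hi[d] - lo[d] > hi[dim] - lo[dim]) dim = d;
    int mid = begin + (end - begin) / 2;
    std::nth_element(order.begin() + begin, order.begin() + mid,
                     order.begin() + end, [&](int a, int b) {
                       double ca = coord(a, dim), cb = coord(b, dim);
                       if (ca != cb) return ca < cb;
                       return a < b;
                     });
    nodes[id].dim = dim;
    nodes[id].split = coord(order[mid], dim);
    int l = build(begin, mid);
    int r = build(mid, end);
    nodes[id].left = l;
    nodes[id].right = r;
    return id;
  }

  double dist2(int i, const double* q) const {
    double s = 0.0;
    for (int d = 0; d < 3; ++d) {
      double t = coord(i, d) - q[d];
      s += t * t;
    }
    return s;
  }

  void nn1(int node, const double* q, double& bestd2, int& besti) const {
    const KdNode& nd = nodes[node];
    if (nd.left < 0) {
      for (int k = nd.begin; k < nd.end; ++k) {
        int i = order[k];
        double d2 = dist2(i, q);
        if (d2 < bestd2 || (d2 == bestd2 && i < besti)) {
          bestd2 = d2;
          besti = i;
        }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    nn1(near, q, bestd2, besti);
    if (diff * diff <= bestd2) nn1(far, q, bestd2, besti);
  }

  // k smallest (dist2, index) pairs in lexicographic order
  void knn(int node, const double* q, int k,
           std::vector<std::pair<double, int> >& heap) const {
    const KdNode& nd = nodes[node];
    if (nd.left < 0) {
      for (int kk = nd.begin; kk < nd.end; ++kk) {
        int i = order[kk];
        std::pair<double, int> cand(dist2(i, q), i);
        if ((int)heap.size() < k) {
          heap.push_back(cand);
          std::push_heap(heap.begin(), heap.end());
        } else if (cand < heap.front()) {
          std::pop_heap(heap.begin(), heap.end());
          heap.back() = cand;
          std::push_heap(heap.begin(), heap.end());
        }
      }
      return;
    }
    double diff = q[nd.dim] - nd.split;
    int near = diff < 0 ? nd.left : nd.right;
    int far = diff < 0 ? nd.right : nd.left;
    knn(near, q, k, heap);
    if ((int)heap.size() < k || diff * diff <= heap.front().first)
      knn(far, q, k, heap);
  }
};

KdTree make_tree(const NumericMatrix& pts) {
  KdTree tree;
  tree.x = REAL(pts);
  tree.n = pts.nrow();
  tree.order.resize(tree.n);
  for (int i = 0; i < tree.n; ++i) tree.order[i] = i;
  tree.nodes.reserve(2 * tree.n / LEAF_SIZE + 2);
  tree.build(0, tree.n);
  return tree;
}

}  // namespace

// [[Rcpp::export]]
List kd_nn1(NumericMatrix target, NumericMatrix query) {
  if (target.ncol() != 3 || query.ncol() != 3)
    stop("point matrices must have 3 columns");
  if (target.nrow() < 1) stop("empty target point set");
  KdTree tree = make_tree(target);
  int nq = query.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  double q[3];
  for (int i = 0; i < nq; ++i) {
    for (int d = 0; d < 3; ++d) q[d] = query(i, d);
    double bestd2 = R_PosInf;
    int besti = tree.n;
    tree.nn1(0, q, bestd2, besti);
    idx[i] = besti + 1;
    dist[i] = std::sqrt(bestd2);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export]]
IntegerMatrix kd_knn(NumericMatrix pts, int k) {
  if (pts.ncol() != 3) stop("point matrix must have 3 columns");
  int n = pts.nrow();
  if (k < 1 || k > n) stop("k out of range");
  KdTree tree = make_tree(pts);
  IntegerMatrix out(n, k);
  double q[3];
  std::vector<std::pair<double, int> > heap;
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) q[d] = pts(i, d);
    heap.clear();
    tree.knn(0, q, k, heap);
    std::sort_heap(heap.begin(), heap.end());
    for (int j = 0; j < k; ++j) out(i, j) = heap[j].second + 1;
  }
  return out;
}
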