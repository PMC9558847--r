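// JC69 pruning likelihood and per-topology branch-length optimization
// for small trees. Site patterns are pre-compressed in R; states are
// coded 0..3 (A,C,G,T), -1 for anything else (treated as missing).
//
// Under JC69 the transition kernel applied to a conditional-likelihood
// vector v is (P_d v)[y] = (1-e)/4 * sum(v) + e * v[y] with
// e = exp(-4d/3), which keeps every pass O(npat * 4).

#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Tree {
  int nnode, ntip, root, nedge, npat;
  std::vector<int> parent_of;            // node -> parent (0 if root)
  std::vector<int> edge_of;              // node -> incoming edge index
  std::vector<std::vector<int>> kids;    // node -> children
  std::vector<int> postorder_nodes;      // internal nodes, children first
};

Tree build_tree(const IntegerMatrix& edge, int ntip, int npat) {
  Tree t;
  t.nedge = edge.nrow();
  t.ntip = ntip;
  t.npat = npat;
  int maxn = 0;
  for (int i = 0; i < t.nedge; ++i)
    maxn = std::max(maxn, std::max(edge(i, 0), edge(i, 1)));
  t.nnode = maxn;
  t.parent_of.assign(maxn + 1, 0);
  t.edge_of.assign(maxn + 1, -1);
  t.kids.assign(maxn + 1, {});
  for (int i = 0; i < t.nedge; ++i) {
    t.parent_of[edge(i, 1)] = edge(i, 0);
    t.edge_of[edge(i, 1)] = i;
    t.kids[edge(i, 0)].push_back(edge(i, 1));
  }
  t.root = 0;
  for (int v = ntip + 1; v <= maxn; ++v)
    if (t.parent_of[v] == 0) t.root = v;
  // internal nodes in postorder (children before parents) by explicit DFS
  std::vector<int> stack = {t.root}, order;
  while (!stack.empty()) {
    int v = stack.back(); stack.pop_back();
    order.push_back(v);
    for (int ch : t.kids[v])
      if (ch > ntip) stack.push_back(ch);
  }
  t.postorder_nodes.assign(order.rbegin(), order.rend());
  return t;
}

// apply JC transition: out[y] = (1-e)/4 * S + e * v[y], per pattern
inline void jc_apply(const double* v, double e, double* out, int npat) {
  for (int p = 0; p < npat; ++p) {
    const double* vp = v + 4 * p;
    double S = vp[0] + vp[1] + vp[2] + vp[3];
    double base = (1.0 - e) * 0.25 * S;
    double* op = out + 4 * p;
    for (int s = 0; s < 4; ++s) op[s] = base + e * vp[s];
  }
}

void tip_cond(const IntegerMatrix& tips, int tip, double* out, int npat) {
  for (int p = 0; p < npat; ++p) {
    int s = tips(p, tip - 1);
    double* op = out + 4 * p;
    if (s < 0) { op[0] = op[1] = op[2] = op[3] = 1.0; }
    else { op[0] = op[1] = op[2] = op[3] = 0.0; op[s] = 1.0; }
  }
}

// internal-node part of the down pass; tip conditionals in cond[1..ntip]
// must already be filled (they never change)
void down_pass(const Tree& t, const std::vector<double>& elen,
               std::vector<std::vector<double>>& cond,
               std::vector<double>& buf) {
  int npat = t.npat;
  for (int v : t.postorder_nodes) {
    std::fill(cond[v].begin(), cond[v].end(), 1.0);
    for (int ch : t.kids[v]) {
      double e = std::exp(-4.0 * elen[t.edge_of[ch]] / 3.0);
      jc_apply(cond[ch].data(), e, buf.data(), npat);
      for (int i = 0; i < 4 * npat; ++i) cond[v][i] *= buf[i];
    }
  }
}

double root_loglik(const Tree& t, const std::vector<std::vector<double>>& cond,
                   const NumericVector& w) {
  double ll = 0.0;
  const std::vector<double>& r = cond[t.root];
  for (int p = 0; p < t.npat; ++p) {
    const double* rp = r.data() + 4 * p;
    ll += w[p] * std::log(0.25 * (rp[0] + rp[1] + rp[2] + rp[3]));
  }
  return ll;
}

// outside-vector G for the edge above node v: likelihood of all data
// outside subtree(v), as a function of the state at parent(v)
void outside_vec(const Tree& t, const std::vector<double>& elen,
                 const std::vector<std::vector<double>>& cond, int v,
                 std::vector<double>& G, std::vector<double>& W,
                 std::vector<double>& buf) {
  int npat = t.npat;
  // path root -> parent(v)
  std::vector<int> path;
  for (int u = t.parent_of[v]; u != 0; u = t.parent_of[u]) path.push_back(u);
  std::reverse(path.begin(), path.end());
  std::fill(W.begin(), W.end(), 1.0);
  for (size_t k = 0; k < path.size(); ++k) {
    int u = path[k];
    int nxt = (k + 1 < path.size()) ? path[k + 1] : v;
    for (int ch : t.kids[u]) {
      if (ch == nxt) continue;
      double e = std::exp(-4.0 * elen[t.edge_of[ch]] / 3.0);
      jc_apply(cond[ch].data(), e, buf.data(), npat);
      for (int i = 0; i < 4 * npat; ++i) W[i] *= buf[i];
    }
    if (nxt != v) {
      double e = std::exp(-4.0 * elen[t.edge_of[nxt]] / 3.0);
      jc_apply(W.data(), e, buf.data(), npat);
      W.swap(buf);
    }
  }
  G = W;
}

} // namespace

// [[Rcpp::export]]
double jc69_loglik_cpp(IntegerMatrix edge, NumericVector lengths,
                       IntegerMatrix tips, NumericVector weights) {
  int npat = tips.nrow(), ntip = tips.ncol();
  Tree t = build_tree(edge, ntip, npat);
  std::vector<double> elen(lengths.begin(), lengths.end());
  std::vector<std::vector<double>> cond(t.nnode + 1,
                                        std::vector<double>(4 * npat));
  std::vector<double> buf(4 * npat);
  for (int v = 1; v <= ntip; ++v) tip_cond(tips, v, cond[v].data(), npat);
  down_pass(t, elen, cond, buf);
  return root_loglik(t, cond, weights);
}

// [[Rcpp::export]]
List jc69_optimize_cpp(IntegerMatrix edge, NumericVector lengths,
                       IntegerMatrix tips, NumericVector weights,
                       double tol = 1e-6, int max_sweeps = 20,
                       double min_len = 1e-9, double max_len = 10.0) {
  int npat = tips.nrow(), ntip = tips.ncol();
  Tree t = build_tree(edge, ntip, npat);
  std::vector<double> elen(lengths.begin(), lengths.end());
  std::vector<std::vector<double>> cond(t.nnode + 1,
                                        std::vector<double>(4 * npat));
  std::vector<double> G(4 * npat), W(4 * npat), buf(4 * npat);
  std::vector<double> a(npat), b(npat);
  for (int v = 1; v <= ntip; ++v) tip_cond(tips, v, cond[v].data(), npat);
  down_pass(t, elen, cond, buf);
  double ll = root_loglik(t, cond, weights);
  double zmin = std::exp(-4.0 * max_len / 3.0);
  double zmax = std::exp(-4.0 * min_len / 3.0);

  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    for (int i = 0; i < t.nedge; ++i) {
      int v = edge(i, 1);
      down_pass(t, elen, cond, buf);
      outside_vec(t, elen, cond, v, G, W, buf);
      const std::vector<double>& B = cond[v];
      // per-pattern likelihood is a + z (b - a), z = exp(-4d/3)
      for (int p = 0; p < npat; ++p) {
        const double* gp = G.data() + 4 * p;
        const double* bp = B.data() + 4 * p;
        double SG = gp[0] + gp[1] + gp[2] + gp[3];
        double SB = bp[0] + bp[1] + bp[2] + bp[3];
        double dot = gp[0] * bp[0] + gp[1] * bp[1] + gp[2] * bp[2] +
                     gp[3] * bp[3];
        a[p] = SG * SB / 16.0;
        b[p] = dot / 4.0;
      }
      // the per-site log-likelihood is concave in z; find the root of
      // the monotone derivative by bisection
      auto deriv = [&](double z) {
        double d = 0.0;
        for (int p = 0; p < npat; ++p) {
          double diff = b[p] - a[p];
          d += weights[p] * diff / (a[p] + z * diff);
        }
        return d;
      };
      double z;
      if (deriv(zmax) >= 0.0) z = zmax;
      else if (deriv(zmin) <= 0.0) z = zmin;
      else {
        double lo = zmin, hi = zmax;
        for (int it = 0; it < 60; ++it) {
          double mid = 0.5 * (lo + hi);
          if (deriv(mid) > 0.0) lo = mid; else hi = mid;
        }
        z = 0.5 * (lo + hi);
      }
      elen[i] = -0.75 * std::log(z);
    }
    down_pass(t, elen, cond, buf);
    double ll_new = root_loglik(t, cond, weights);
    if (sweep > 0 && ll_new - ll < tol) { ll = ll_new; break; }
    ll = ll_new;
  }
  return List::create(_["loglik"] = ll,
                      _["lengths"] = NumericVector(elen.begin(), elen.end()));
}
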