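// Core counting loop: subtree-intersection DP plus the O(1)-per-edge-pair
// shared/different directed-butterfly counts, accumulated over all pairs of
// directed inner edges.  All quantities are exact integers held in doubles
// (guaranteed below 2^53 for n <= 10,000 leaves); accumulators are long
// double.  Matrix products go through Armadillo (BLAS).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Rooted {
  int N;
  std::vector<std::vector<int> > adj;   // 0-based
  std::vector<int> parent;              // -1 at root
  std::vector<int> post;                // postorder node sequence
  std::vector<double> size;             // leaves below
  std::vector<int> leafidx;             // -1 internal, else 0..n-1
  std::vector<int> internal;            // internal node ids
};

Rooted build_rooted(const List& adj_r, const IntegerVector& leafidx_r,
                    int root1based) {
  Rooted t;
  t.N = adj_r.size();
  t.adj.resize(t.N);
  t.leafidx.resize(t.N);
  for (int v = 0; v < t.N; ++v) {
    IntegerVector nb = adj_r[v];
    t.adj[v].reserve(nb.size());
    for (int k = 0; k < nb.size(); ++k) t.adj[v].push_back(nb[k] - 1);
    t.leafidx[v] = leafidx_r[v] - 1;  // 0 in R (internal) -> -1
    if (t.leafidx[v] < 0 && (int)t.adj[v].size() > 0) t.internal.push_back(v);
  }
  int root = root1based - 1;
  t.parent.assign(t.N, -1);
  t.post.reserve(t.N);
  std::vector<int> stack;
  std::vector<int> order;
  order.reserve(t.N);
  stack.push_back(root);
  std::vector<bool> seen(t.N, false);
  seen[root] = true;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    order.push_back(v);
    for (size_t k = 0; k < t.adj[v].size(); ++k) {
      int u = t.adj[v][k];
      if (!seen[u]) {
        seen[u] = true;
        t.parent[u] = v;
        stack.push_back(u);
      }
    }
  }
  t.post.assign(order.rbegin(), order.rend());
  t.size.assign(t.N, 0.0);
  for (size_t idx = 0; idx < t.post.size(); ++idx) {
    int v = t.post[idx];
    if (t.leafidx[v] >= 0) t.size[v] = 1.0;
    for (size_t k = 0; k < t.adj[v].size(); ++k) {
      int u = t.adj[v][k];
      if (u != t.parent[v]) t.size[v] += t.size[u];
    }
  }
  return t;
}

}  // namespace

// [[Rcpp::export]]
NumericVector qd_core_cpp(List adj1, IntegerVector leafidx1, int root1,
                          List adj2, IntegerVector leafidx2, int root2,
                          int n) {
  Rooted T1 = build_rooted(adj1, leafidx1, root1);
  Rooted T2 = build_rooted(adj2, leafidx2, root2);

  // node of T2 carrying each common leaf index
  std::vector<int> leaf2node(n, -1);
  for (int v = 0; v < T2.N; ++v)
    if (T2.leafidx[v] >= 0) leaf2node[T2.leafidx[v]] = v;

  // C(u, u') = |L(u) \cap L(u')| over rooted subtrees
  arma::mat C(T1.N, T2.N, arma::fill::zeros);
  arma::rowvec row(T2.N);
  for (size_t idx = 0; idx < T1.post.size(); ++idx) {
    int u = T1.post[idx];
    if (T1.leafidx[u] >= 0) {
      row.zeros();
      row(leaf2node[T1.leafidx[u]]) = 1.0;
      for (size_t j = 0; j < T2.post.size(); ++j) {
        int u2 = T2.post[j];
        if (T2.leafidx[u2] >= 0) continue;
        double s = 0.0;
        for (size_t k = 0; k < T2.adj[u2].size(); ++k) {
          int c2 = T2.adj[u2][k];
          if (c2 != T2.parent[u2]) s += row(c2);
        }
        row(u2) = s;
      }
      C.row(u) = row;
    } else {
      row.zeros();
      for (size_t k = 0; k < T1.adj[u].size(); ++k) {
        int c1 = T1.adj[u][k];
        if (c1 != T1.parent[u]) row += C.row(c1);
      }
      C.row(u) = row;
    }
  }

  long double shared2 = 0.0L;  // twice the directed shared total
  long double diff_raw = 0.0L;
  const double nn = (double)n;

  for (size_t a1 = 0; a1 < T1.internal.size(); ++a1) {
    int v = T1.internal[a1];
    const std::vector<int>& nb1 = T1.adj[v];
    int d1 = nb1.size();
    std::vector<int> in1;
    for (int i = 0; i < d1; ++i)
      if (T1.leafidx[nb1[i]] < 0) in1.push_back(i);
    if (in1.empty()) continue;

    for (size_t a2 = 0; a2 < T2.internal.size(); ++a2) {
      int vp = T2.internal[a2];
      const std::vector<int>& nb2 = T2.adj[vp];
      int d2 = nb2.size();
      std::vector<int> in2;
      for (int j = 0; j < d2; ++j)
        if (T2.leafidx[nb2[j]] < 0) in2.push_back(j);
      if (in2.empty()) continue;

      // I[i, j] = |front(v -> nb1[i])  \cap  front(vp -> nb2[j])|
      arma::mat I(d1, d2);
      for (int i = 0; i < d1; ++i) {
        int a = nb1[i];
        bool up1 = (a == T1.parent[v]);
        for (int j = 0; j < d2; ++j) {
          int b = nb2[j];
          bool up2 = (b == T2.parent[vp]);
          double val;
          if (!up1 && !up2) val = C(a, b);
          else if (!up1 && up2) val = T1.size[a] - C(a, vp);
          else if (up1 && !up2) val = T2.size[b] - C(v, b);
          else val = nn - T1.size[v] - T2.size[vp] + C(v, vp);
          I(i, j) = val;
        }
      }

      arma::vec R = arma::sum(I, 1);       // row sums
      arma::rowvec Cs = arma::sum(I, 0);   // column sums
      double M = arma::accu(I);
      arma::mat Isq = I % I;
      arma::vec R2 = arma::sum(Isq, 1);
      arma::rowvec C2 = arma::sum(Isq, 0);
      double M2 = arma::accu(Isq);
      double SR2 = arma::dot(R, R);
      double SC2 = arma::dot(Cs, Cs);
      arma::rowvec W = R.t() * I;          // W[j] = sum_k R[k] I[k, j]
      arma::vec V = I * Cs.t();            // V[i] = sum_l C[l] I[i, l]

      bool left = (d1 <= d2);
      arma::mat P = left ? arma::mat(I * I.t()) : arma::mat(I.t() * I);

      for (size_t ii = 0; ii < in1.size(); ++ii) {
        int i = in1[ii];
        for (size_t jj = 0; jj < in2.size(); ++jj) {
          int j = in2[jj];
          double Iij = I(i, j);
          if (Iij < 1.0) continue;
          double Ri = R(i), Cj = Cs(j);
          double K = M - Ri - Cj + Iij;
          if (Iij >= 2.0) {
            double Tsum = K * K - SR2 - SC2 + M2 + Ri * Ri + Cj * Cj +
              2.0 * W(j) + 2.0 * V(i) - 2.0 * Ri * Iij - 2.0 * Cj * Iij -
              2.0 * R2(i) - 2.0 * C2(j) + 3.0 * Iij * Iij;
            shared2 += (long double)(Iij * (Iij - 1.0) / 2.0 * Tsum);
          }
          double g3 = left ? arma::dot(P.row(i), I.col(j).t())
                           : arma::dot(I.row(i), P.col(j).t());
          double aa = Ri - Iij;
          double bb = Cj - Iij;
          double vv = V(i) - Cj * Iij;
          double ww = W(j) - Ri * Iij;
          double a2 = R2(i) - Iij * Iij;
          double b2 = C2(j) - Iij * Iij;
          double cross = g3 - Iij * R2(i) - Iij * C2(j) + Iij * Iij * Iij;
          diff_raw += (long double)(Iij * (K * aa * bb - aa * ww - vv * bb +
                                           a2 * bb + aa * b2 + cross));
        }
      }
    }
  }

  NumericVector out(2);
  out[0] = (double)(shared2 / 2.0L);
  out[1] = (double)diff_raw;
  return out;
}
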