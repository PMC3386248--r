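#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Signed modularity Q* for fully connected weighted graphs:
//   Q* = Q+ - (v- / (v+ + v-)) * Q-,
//   Q+- = (1/v+-) sum_{ij} (w+-_ij - s+-_i s+-_j / v+-) delta(c_i, c_j),
// where w+ = max(w,0), w- = max(-w,0), v+- the total positive/negative
// weight over ordered pairs and s+-_i node strengths. The weight diagonal
// is zero while the strength-product null term runs over all pairs, so a
// single community scores exactly 0. If v- = 0 the negative term is
// dropped; v+ = 0 likewise.

static double part_modularity(const std::vector<double>& A, int N,
                              const std::vector<int>& lab, double v) {
  if (v <= 0.0) return 0.0;
  int K = 0;
  for (int i = 0; i < N; ++i) K = std::max(K, lab[i] + 1);
  // one community: total within-weight equals total strength product /v
  // identically, so the value is exactly 0
  if (K == 1) return 0.0;
  std::vector<double> S(K, 0.0), Win(K, 0.0), s(N, 0.0);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) s[i] += A[i + (size_t)j * N];
  for (int i = 0; i < N; ++i) S[lab[i]] += s[i];
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      if (lab[i] == lab[j]) Win[lab[i]] += A[i + (size_t)j * N];
  double q = 0.0;
  for (int c = 0; c < K; ++c) q += Win[c] / v - (S[c] / v) * (S[c] / v);
  return q;
}

static void split_parts(const NumericMatrix& W, int N,
                        std::vector<double>& Ap, std::vector<double>& An,
                        double& vp, double& vn) {
  Ap.assign((size_t)N * N, 0.0);
  An.assign((size_t)N * N, 0.0);
  vp = 0.0; vn = 0.0;
  for (int j = 0; j < N; ++j) {
    for (int i = 0; i < N; ++i) {
      if (i == j) continue;
      double w = W(i, j);
      if (w > 0) { Ap[i + (size_t)j * N] = w;  vp += w; }
      else if (w < 0) { An[i + (size_t)j * N] = -w; vn += -w; }
    }
  }
}

// [[Rcpp::export(name = ".qstar_cpp")]]
double qstar_cpp(NumericMatrix W, IntegerVector labels) {
  int N = W.nrow();
  std::vector<double> Ap, An;
  double vp, vn;
  split_parts(W, N, Ap, An, vp, vn);
  std::vector<int> lab(N);
  for (int i = 0; i < N; ++i) lab[i] = labels[i] - 1;
  double qp = part_modularity(Ap, N, lab, vp);
  double qn = part_modularity(An, N, lab, vn);
  double tot = vp + vn;
  if (tot <= 0.0) return 0.0;
  return qp - (vn / tot) * qn;
}

// One Louvain level: local moving on a (super)graph with self-loops.
// Ap/An are K x K dense part matrices (diagonal = internal weight of the
// supernode, counted over ordered pairs of original nodes). vp/vn are the
// fixed totals of the *original* graph. Returns community labels (0-based)
// and reports whether any node moved.
static bool local_moving(std::vector<double>& Ap, std::vector<double>& An,
                         int K, double vp, double vn, double lambda,
                         std::vector<int>& comm, std::mt19937& rng) {
  std::vector<double> sp(K, 0.0), sn(K, 0.0);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i) {
      sp[i] += Ap[i + (size_t)j * K];
      sn[i] += An[i + (size_t)j * K];
    }
  // community aggregate strengths and sizes
  std::vector<double> Sp(K, 0.0), Sn(K, 0.0);
  std::vector<int> csize(K, 0);
  for (int i = 0; i < K; ++i) {
    Sp[comm[i]] += sp[i]; Sn[comm[i]] += sn[i]; ++csize[comm[i]];
  }

  std::vector<int> order(K);
  for (int i = 0; i < K; ++i) order[i] = i;

  std::vector<double> kp(K), kn(K);
  bool any_move = false;
  const double tol = 1e-12;
  bool improved = true;
  int sweeps = 0;
  while (improved && sweeps < 100) {
    improved = false;
    ++sweeps;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < K; ++oi) {
      int u = order[oi];
      int cu = comm[u];
      // links from u to each community (excluding self-loop)
      std::fill(kp.begin(), kp.end(), 0.0);
      std::fill(kn.begin(), kn.end(), 0.0);
      for (int j = 0; j < K; ++j) {
        if (j == u) continue;
        kp[comm[j]] += Ap[u + (size_t)j * K];
        kn[comm[j]] += An[u + (size_t)j * K];
      }
      // remove u from its community
      Sp[cu] -= sp[u]; Sn[cu] -= sn[u]; --csize[cu];
      // score of joining a non-empty community c, relative to being alone (= 0)
      double best = 0.0;
      int best_c = -1;  // -1 means u stays alone
      for (int c = 0; c < K; ++c) {
        if (csize[c] == 0) continue;
        double g = 0.0;
        if (vp > 0) g += 2.0 * kp[c] / vp - 2.0 * sp[u] * Sp[c] / (vp * vp);
        if (vn > 0) g -= lambda * (2.0 * kn[c] / vn - 2.0 * sn[u] * Sn[c] / (vn * vn));
        if (g > best + tol) { best = g; best_c = c; }
      }
      int target;
      if (best_c >= 0) {
        target = best_c;
      } else if (csize[cu] == 0) {
        target = cu;  // old slot is now empty: u is alone there
      } else {
        // u is better off alone: claim an empty slot (one must exist)
        target = cu;
        for (int c = 0; c < K; ++c) if (csize[c] == 0) { target = c; break; }
      }
      Sp[target] += sp[u]; Sn[target] += sn[u]; ++csize[target];
      if (target != cu) { comm[u] = target; improved = true; any_move = true; }
    }
  }
  return any_move;
}

static void aggregate(const std::vector<double>& Ap, const std::vector<double>& An,
                      int K, const std::vector<int>& comm, int K2,
                      std::vector<double>& Ap2, std::vector<double>& An2) {
  Ap2.assign((size_t)K2 * K2, 0.0);
  An2.assign((size_t)K2 * K2, 0.0);
  for (int j = 0; j < K; ++j)
    for (int i = 0; i < K; ++i) {
      Ap2[comm[i] + (size_t)comm[j] * K2] += Ap[i + (size_t)j * K];
      An2[comm[i] + (size_t)comm[j] * K2] += An[i + (size_t)j * K];
    }
}

// [[Rcpp::export(name = ".louvain_signed_cpp")]]
List louvain_signed_cpp(NumericMatrix W, int n_restarts, int seed) {
  int N = W.nrow();
  std::vector<double> Ap0, An0;
  double vp, vn;
  split_parts(W, N, Ap0, An0, vp, vn);
  double tot = vp + vn;
  double lambda = (tot > 0) ? vn / tot : 0.0;

  std::vector<int> best_lab(N, 0);
  double best_q = R_NegInf;

  for (int r = 0; r < n_restarts; ++r) {
    std::mt19937 rng((unsigned)(seed) + 1000003u * (unsigned)r);
    // node -> community at finest level, refined through levels
    std::vector<int> assign(N);
    for (int i = 0; i < N; ++i) assign[i] = i;
    std::vector<double> Ap = Ap0, An = An0;
    int K = N;
    std::vector<int> comm(K);
    for (int i = 0; i < K; ++i) comm[i] = i;
    while (true) {
      bool moved = local_moving(Ap, An, K, vp, vn, lambda, comm, rng);
      // relabel communities consecutively
      std::vector<int> remap(K, -1);
      int K2 = 0;
      for (int i = 0; i < K; ++i)
        if (remap[comm[i]] < 0) remap[comm[i]] = K2++;
      for (int i = 0; i < K; ++i) comm[i] = remap[comm[i]];
      // push down to original nodes
      for (int i = 0; i < N; ++i) assign[i] = comm[assign[i]];
      if (!moved || K2 == K) break;
      std::vector<double> Ap2, An2;
      aggregate(Ap, An, K, comm, K2, Ap2, An2);
      Ap.swap(Ap2); An.swap(An2);
      K = K2;
      comm.assign(K, 0);
      for (int i = 0; i < K; ++i) comm[i] = i;
    }
    double qp = part_modularity(Ap0, N, assign, vp);
    double qn = part_modularity(An0, N, assign, vn);
    double q = (tot > 0) ? qp - lambda * qn : 0.0;
    if (q > best_q + 1e-15) { best_q = q; best_lab = assign; }
  }

  IntegerVector out(N);
  for (int i = 0; i < N; ++i) out[i] = best_lab[i] + 1;
  return List::create(_["labels"] = out, _["qstar"] = best_q);
}

// Signed discrepancy-reducing swaps: candidate swaps exchange the (signed)
// weights held by two edge slots — so the placement of positive versus
// negative weights can move too — and are accepted iff they reduce
//   sum_i |s+_i(cur) - s+_i(target)| + |s-_i(cur) - s-_i(target)|.
// [[Rcpp::export(name = ".strength_swap_signed_cpp")]]
NumericVector strength_swap_signed_cpp(IntegerVector ei, IntegerVector ej,
                                       NumericVector w,
                                       NumericVector sp_target,
                                       NumericVector sn_target,
                                       int n_nodes, double n_attempts,
                                       int seed) {
  int E = w.size();
  std::vector<double> wv(w.begin(), w.end());
  std::vector<double> cp(n_nodes, 0.0), cn(n_nodes, 0.0);
  for (int e = 0; e < E; ++e) {
    double x = wv[e];
    if (x > 0) { cp[ei[e]] += x; cp[ej[e]] += x; }
    else if (x < 0) { cn[ei[e]] += -x; cn[ej[e]] += -x; }
  }
  std::mt19937 rng((unsigned)seed);
  std::uniform_int_distribution<int> pick(0, E - 1);
  long long n_try = (long long)n_attempts;
  for (long long t = 0; t < n_try; ++t) {
    int e1 = pick(rng), e2 = pick(rng);
    if (e1 == e2) continue;
    double w1 = wv[e1], w2 = wv[e2];
    if (w1 == w2) continue;
    // per-node deltas on the positive and negative strength sequences
    double w1p = w1 > 0 ? w1 : 0.0, w1n = w1 < 0 ? -w1 : 0.0;
    double w2p = w2 > 0 ? w2 : 0.0, w2n = w2 < 0 ? -w2 : 0.0;
    int nodes[4] = { ei[e1], ej[e1], ei[e2], ej[e2] };
    double dp[4] = { w2p - w1p, w2p - w1p, w1p - w2p, w1p - w2p };
    double dn[4] = { w2n - w1n, w2n - w1n, w1n - w2n, w1n - w2n };
    double before = 0.0, after = 0.0;
    for (int a = 0; a < 4; ++a) {
      if (nodes[a] < 0) continue;
      double ddp = dp[a], ddn = dn[a];
      for (int b = a + 1; b < 4; ++b) {
        if (nodes[b] == nodes[a]) { ddp += dp[b]; ddn += dn[b]; nodes[b] = -1; }
      }
      int v = nodes[a];
      before += std::abs(cp[v] - sp_target[v]) + std::abs(cn[v] - sn_target[v]);
      after  += std::abs(cp[v] + ddp - sp_target[v]) +
                std::abs(cn[v] + ddn - sn_target[v]);
    }
    if (after < before - 1e-15) {
      cp[ei[e1]] += w2p - w1p; cp[ej[e1]] += w2p - w1p;
      cn[ei[e1]] += w2n - w1n; cn[ej[e1]] += w2n - w1n;
      cp[ei[e2]] += w1p - w2p; cp[ej[e2]] += w1p - w2p;
      cn[ei[e2]] += w1n - w2n; cn[ej[e2]] += w1n - w2n;
      std::swap(wv[e1], wv[e2]);
    }
  }
  return NumericVector(wv.begin(), wv.end());
}
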