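#include <Rcpp.h>
#include <vector>

using namespace Rcpp;

// Kernighan-Lin fine-tuning of a complete community division on the
// modularity matrix B (q tracked as sum over same-community pairs of B_ij,
// proportional to Q). Each round moves every node exactly once to its best
// target community -- an existing one or a fresh empty one -- allowing
// mid-round decreases, keeps the best configuration seen, and repeats while
// q improves. Deterministic: the best (gain, node, target) is chosen by
// strict comparison scanning nodes then targets in index order.
// mem0 is 1-based; the result keeps arbitrary labels (caller renumbers).
// [[Rcpp::export]]
IntegerVector kl_partition_refine_cpp(NumericMatrix B, IntegerVector mem0) {
  const int n = B.nrow();
  std::vector<int> mem(n);
  for (int i = 0; i < n; ++i) mem[i] = mem0[i] - 1;

  // community occupancy over ids 0..n-1 (labels are compacted lazily)
  std::vector<int> size(n + 1, 0);
  for (int i = 0; i < n; ++i) size[mem[i]]++;

  // S(i, c) = sum_{j in c, j != i} B_ij ; diagonal excluded throughout
  std::vector<double> S(static_cast<size_t>(n) * (n + 1));
  auto rebuild_S = [&](const std::vector<int>& m) {
    std::fill(S.begin(), S.end(), 0.0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (j != i) S[static_cast<size_t>(i) * (n + 1) + m[j]] += B(i, j);
  };

  auto score = [&](const std::vector<int>& m) {
    double q = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j)
        if (i != j && m[i] == m[j]) q += B(i, j);
    for (int i = 0; i < n; ++i) q += B(i, i);   // self-pairs always count
    return q;
  };

  double q = score(mem);
  const double tol = 1e-12;

  for (int round = 0; round < 4 * n + 16; ++round) {
    std::vector<int> mem_iter(mem), best_mem(mem);
    std::vector<int> size_iter(size);
    double best_q = q, q_iter = q;
    rebuild_S(mem_iter);
    std::vector<char> unmoved(n, 1);

    for (int step = 0; step < n; ++step) {
      // active communities plus the first empty id (the "new" target)
      std::vector<int> targets;
      int fresh = -1;
      for (int t = 0; t <= n; ++t) {
        if (size_iter[t] > 0) {
          targets.push_back(t);
        } else if (fresh < 0) {
          fresh = t;
        }
      }
      if (fresh >= 0) targets.push_back(fresh);

      double best_gain = -std::numeric_limits<double>::infinity();
      int bi = -1, bt = -1;
      for (int i = 0; i < n; ++i) {
        if (!unmoved[i]) continue;
        const int cur = mem_iter[i];
        const double s_cur = S[static_cast<size_t>(i) * (n + 1) + cur];
        for (int t : targets) {
          if (t == cur) continue;
          const double gain =
              2.0 * (S[static_cast<size_t>(i) * (n + 1) + t] - s_cur);
          if (gain > best_gain + tol) {
            best_gain = gain;
            bi = i;
            bt = t;
          }
        }
      }
      if (bi < 0) break;
      const int cur = mem_iter[bi];
      for (int j = 0; j < n; ++j) {
        if (j == bi) continue;
        S[static_cast<size_t>(j) * (n + 1) + cur] -= B(j, bi);
        S[static_cast<size_t>(j) * (n + 1) + bt] += B(j, bi);
      }
      mem_iter[bi] = bt;
      size_iter[cur]--;
      size_iter[bt]++;
      unmoved[bi] = 0;
      q_iter += best_gain;
      if (q_iter > best_q + 1e-12) {
        best_q = q_iter;
        best_mem = mem_iter;
      }
    }

    // re-evaluate exactly: accumulated gains carry float error that could
    // otherwise fake an improvement forever
    best_q = score(best_mem);
    if (best_q > q + 1e-10) {
      q = best_q;
      mem = best_mem;
      std::fill(size.begin(), size.end(), 0);
      for (int i = 0; i < n; ++i) size[mem[i]]++;
    } else {
      break;
    }
  }

  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = mem[i] + 1;
  return out;
}
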