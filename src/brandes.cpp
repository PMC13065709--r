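#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Brandes' algorithm on edge lengths L_ij = 1/A_ij, returning unnormalized
// betweenness over unordered pairs and the global-efficiency sum in one
// pass (both need the same single-source shortest paths; computing them
// together halves the path work of a threshold sweep).
// Ties in path length are detected with an absolute 1e-12 tolerance.
// [[Rcpp::export]]
List brandes_path_metrics(NumericMatrix A) {
  const int n = A.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  const double EPS = 1e-12;

  std::vector<std::vector<std::pair<int, double>>> adj(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (A(i, j) > 0) {
        const double len = 1.0 / A(i, j);
        adj[i].push_back({j, len});
        adj[j].push_back({i, len});
      }

  std::vector<double> bc(n, 0.0);
  double inv_sum = 0.0;

  std::vector<double> dist(n), sigma(n), delta(n);
  std::vector<std::vector<int>> pred(n);
  std::vector<int> order;
  std::vector<char> done(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(sigma.begin(), sigma.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    std::fill(done.begin(), done.end(), 0);
    for (auto& p : pred) p.clear();
    order.clear();

    typedef std::pair<double, int> DI;
    std::priority_queue<DI, std::vector<DI>, std::greater<DI>> pq;
    dist[s] = 0.0;
    sigma[s] = 1.0;
    pq.push({0.0, s});
    while (!pq.empty()) {
      const int u = pq.top().second;
      pq.pop();
      if (done[u]) continue;
      done[u] = 1;
      order.push_back(u);
      for (const auto& e : adj[u]) {
        const int v = e.first;
        const double nd = dist[u] + e.second;
        if (nd < dist[v] - EPS) {
          dist[v] = nd;
          sigma[v] = sigma[u];
          pred[v].assign(1, u);
          pq.push({nd, v});
        } else if (std::fabs(nd - dist[v]) <= EPS) {
          sigma[v] += sigma[u];
          pred[v].push_back(u);
        }
      }
    }

    for (int v = 0; v < n; ++v)
      if (v != s && dist[v] < INF) inv_sum += 1.0 / dist[v];

    for (auto it = order.rbegin(); it != order.rend(); ++it) {
      const int w = *it;
      for (int u : pred[w])
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      if (w != s) bc[w] += delta[w];
    }
  }

  for (int i = 0; i < n; ++i) bc[i] /= 2.0;  // each unordered pair once
  const double eff = (n > 1) ? inv_sum / (static_cast<double>(n) * (n - 1))
                             : 0.0;
  return List::create(_["bc"] = NumericVector(bc.begin(), bc.end()),
                      _["efficiency"] = eff);
}
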