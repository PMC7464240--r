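#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Single-source shortest-path accumulation (Brandes) over all sources of an
// undirected unweighted graph in CSR form (0-based), with a parallel
// counter for stress (number of shortest paths through a node) and the sum
// of geodesic distances used for closeness. Betweenness and stress are
// returned for unordered pairs (ordered totals halved). Path counts are
// kept as doubles (exact up to 2^53).
// [[Rcpp::export(name = ".brandesAll")]]
List brandesAll(IntegerVector ptr, IntegerVector adj) {
  const int n = ptr.size() - 1;
  std::vector<double> bet(n, 0.0), stress(n, 0.0), distsum(n, 0.0);
  std::vector<int> dist(n), bfs(n), order(n);
  std::vector<double> sigma(n), delta(n), phi(n);

  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int qh = 0, qt = 0, no = 0;
    dist[s] = 0; sigma[s] = 1.0; bfs[qt++] = s;
    while (qh < qt) {
      int v = bfs[qh++];
      order[no++] = v;
      for (int k = ptr[v]; k < ptr[v + 1]; ++k) {
        int w = adj[k];
        if (dist[w] < 0) { dist[w] = dist[v] + 1; sigma[w] = 0.0; bfs[qt++] = w; }
        if (dist[w] == dist[v] + 1) sigma[w] += sigma[v];
      }
    }
    for (int i = 0; i < no; ++i) { delta[order[i]] = 0.0; phi[order[i]] = 0.0; }
    double ds = 0.0;
    for (int i = no - 1; i >= 1; --i) {
      int w = order[i];
      ds += dist[w];
      for (int k = ptr[w]; k < ptr[w + 1]; ++k) {
        int v = adj[k];
        if (dist[v] == dist[w] - 1) {            // v is a predecessor of w
          delta[v] += sigma[v] / sigma[w] * (1.0 + delta[w]);
          phi[v] += 1.0 + phi[w];                // geodesics v->... via w
        }
      }
      bet[w] += delta[w];
      stress[w] += sigma[w] * phi[w];
    }
    distsum[s] = ds;
  }
  NumericVector b(n), st(n), dsum(n);
  for (int i = 0; i < n; ++i) {
    b[i] = bet[i] / 2.0;
    st[i] = stress[i] / 2.0;
    dsum[i] = distsum[i];
  }
  return List::create(_["betweenness_raw"] = b, _["stress"] = st,
                      _["distsum"] = dsum);
}
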