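#include <Rcpp.h>
using namespace Rcpp;

// One discrete-time synchronous SIR realization on an adjacency list
// (0-based integer neighbor vectors). Seeds start Infected, everyone else
// Susceptible. Each step, every currently infected node tries to infect each
// susceptible neighbor independently with probability lambda; afterwards it
// recovers with probability gamma. Nodes infected in a step only transmit
// from the next step on. Uses R's RNG, so results are reproducible from
// set.seed(). Returns c(final_recovered, steps).
// [[Rcpp::export]]
IntegerVector sir_run_cpp(const List& adj, const IntegerVector& seeds,
                          double lambda, double gamma) {
  const int n = adj.size();
  std::vector<char> status(n, 0);  // 0 = S, 1 = I, 2 = R
  std::vector<int> cur(seeds.begin(), seeds.end());
  for (size_t i = 0; i < cur.size(); ++i) {
    if (cur[i] < 0 || cur[i] >= n) stop("seed index out of range");
    status[cur[i]] = 1;
  }
  int steps = 0, recovered = 0;
  std::vector<int> nxt, newly;
  while (!cur.empty()) {
    newly.clear();
    for (size_t i = 0; i < cur.size(); ++i) {
      const IntegerVector nb = adj[cur[i]];
      for (int j = 0; j < nb.size(); ++j) {
        const int u = nb[j];
        if (status[u] == 0 && unif_rand() < lambda) {
          status[u] = 1;
          newly.push_back(u);
        }
      }
    }
    nxt.clear();
    for (size_t i = 0; i < cur.size(); ++i) {
      if (unif_rand() < gamma) {
        status[cur[i]] = 2;
        ++recovered;
      } else {
        nxt.push_back(cur[i]);
      }
    }
    nxt.insert(nxt.end(), newly.begin(), newly.end());
    cur.swap(nxt);
    ++steps;
  }
  return IntegerVector::create(recovered, steps);
}
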