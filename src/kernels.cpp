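#include <Rcpp.h>
using namespace Rcpp;

// Hot-loop kernels for the per-period network operations. Both use R's own
// RNG stream (RNGScope via Rcpp attributes), so set.seed() fully determines
// every run.

static inline int unif_index(int n) {
  // uniform index in [0, n); n >= 1
  int k = (int)(unif_rand() * n);
  return k == n ? n - 1 : k;
}

// Fresh Erdos-Renyi adjacency: each unordered pair linked with probability p.
// [[Rcpp::export(name = ".er_adj_cpp")]]
NumericMatrix er_adj_cpp(int N, double p) {
  NumericMatrix A(N, N);
  for (int j = 1; j < N; ++j)
    for (int i = 0; i < j; ++i)
      if (unif_rand() < p) { A(i, j) = 1.0; A(j, i) = 1.0; }
  return A;
}

// One strategic network update.
//   A         numeric 0/1 adjacency (modified copy returned)
//   coop_last logical: last-period executed action was C
//   repok     logical eligibility-by-reputation, or NULL when r = 0
//   two_m     degree cap
//   gamma     per-agent probability of skipping the whole update
// Order of events: per-agent skip draw; each non-skipping agent with a
// defecting neighbour drops exactly one such neighbour (uniform); drops are
// simultaneous; each non-skipping agent nominates up to two_m - degree
// eligible non-neighbours (uniform, without replacement, excluding self and
// its just-dropped partner); mutual nominations form links in random order
// unless a formation would breach the cap.
// [[Rcpp::export(name = ".strategic_update_cpp")]]
NumericMatrix strategic_update_cpp(NumericMatrix A, LogicalVector coop_last,
                                   Nullable<LogicalVector> repok,
                                   int two_m, double gamma) {
  int N = A.nrow();
  NumericMatrix B = clone(A);
  std::vector<bool> skip(N);
  for (int i = 0; i < N; ++i) skip[i] = unif_rand() < gamma;

  // (1) drops, computed from the pre-update network, applied simultaneously
  std::vector<int> dropped(N, -1);
  std::vector<int> cand;
  cand.reserve(N);
  for (int i = 0; i < N; ++i) {
    if (skip[i]) continue;
    cand.clear();
    for (int j = 0; j < N; ++j)
      if (B(i, j) > 0 && !coop_last[j]) cand.push_back(j);
    if (!cand.empty()) dropped[i] = cand[unif_index(cand.size())];
  }
  for (int i = 0; i < N; ++i) {
    if (dropped[i] >= 0) { B(i, dropped[i]) = 0.0; B(dropped[i], i) = 0.0; }
  }

  // (2) nominations from the post-drop network
  std::vector<int> deg(N, 0);
  for (int i = 0; i < N; ++i) {
    int d = 0;
    for (int j = 0; j < N; ++j) d += B(i, j) > 0;
    deg[i] = d;
  }
  bool use_rep = repok.isNotNull();
  LogicalVector rok;
  if (use_rep) rok = repok.get();
  std::vector<unsigned char> nom(N * (size_t)N, 0);
  for (int i = 0; i < N; ++i) {
    if (skip[i]) continue;
    int budget = two_m - deg[i];
    if (budget <= 0) continue;
    cand.clear();
    for (int j = 0; j < N; ++j) {
      if (j == i || B(i, j) > 0 || j == dropped[i]) continue;
      if (use_rep && !rok[j]) continue;
      cand.push_back(j);
    }
    int k = std::min((int)cand.size(), budget);
    // partial Fisher-Yates: first k entries are a uniform sample
    for (int s = 0; s < k; ++s) {
      int pick = s + unif_index(cand.size() - s);
      std::swap(cand[s], cand[pick]);
      nom[(size_t)i * N + cand[s]] = 1;
    }
  }

  // (3) mutual consent in random order, under the degree cap
  std::vector<std::pair<int, int> > pairs;
  for (int i = 0; i < N; ++i)
    for (int j = i + 1; j < N; ++j)
      if (nom[(size_t)i * N + j] && nom[(size_t)j * N + i])
        pairs.push_back(std::make_pair(i, j));
  int np = pairs.size();
  for (int s = 0; s < np - 1; ++s)
    std::swap(pairs[s], pairs[s + unif_index(np - s)]);
  for (int s = 0; s < np; ++s) {
    int i = pairs[s].first, j = pairs[s].second;
    if (deg[i] < two_m && deg[j] < two_m) {
      B(i, j) = 1.0; B(j, i) = 1.0;
      ++deg[i]; ++deg[j];
    }
  }
  return B;
}
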