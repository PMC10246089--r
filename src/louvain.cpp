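#include <Rcpp.h>
using namespace Rcpp;

// Local-moving phase of generalized Louvain on a (supra-)modularity matrix.
//
// Quality of a partition is the sum of B entries over co-assigned node pairs
// (both orders, plus the diagonal), so the gain of moving node v into
// community c is 2 * sum_{u in c, u != v} B(v, u) relative to being a
// singleton; the diagonal B(v, v) contributes identically everywhere.
//
// Tie-breaks: a node stays in its community when that ties the best gain;
// otherwise the lowest community label among the tied best is chosen. The
// node visiting order is reshuffled each sweep with R's RNG, so results are
// reproducible under set.seed().
//
// labels are 1-based on the R side; moves are accepted only for gains above
// a small absolute tolerance to avoid cycling on numerically tied states.
//
// prob_move = false: deterministic maximal-gain moves. prob_move = true:
// the move target is drawn among all strictly improving communities with
// probability proportional to the gain (the randomized move selection used
// by multilayer Louvain implementations to diversify runs feeding a
// consensus; best-move dynamics are near-deterministic on small systems).
// [[Rcpp::export]]
IntegerVector louvain_local_move(NumericMatrix B, IntegerVector init,
                                 bool prob_move = false) {
  const int n = B.nrow();
  if (B.ncol() != n) stop("B must be square");
  if (init.size() != n) stop("init labels must match B");
  std::vector<int> labels(n);
  for (int i = 0; i < n; ++i) {
    labels[i] = init[i] - 1;
    if (labels[i] < 0 || labels[i] >= n) stop("labels must lie in 1..n");
  }
  const double tol = 1e-12;
  std::vector<double> s(n);
  bool improved = true;
  int sweeps = 0;
  while (improved && sweeps++ < 10000) {
    improved = false;
    IntegerVector ord = sample(n, n, false); // 1-based, uses R RNG
    for (int t = 0; t < n; ++t) {
      int v = ord[t] - 1;
      int cur = labels[v];
      std::fill(s.begin(), s.end(), 0.0);
      std::vector<bool> used(n, false);
      for (int u = 0; u < n; ++u)
        if (u != v) { s[labels[u]] += B(v, u); used[labels[u]] = true; }
      int empty_c = -1; // lowest-label empty community = singleton option
      for (int c = 0; c < n; ++c) if (!used[c]) { empty_c = c; break; }
      int target = -1;
      if (!prob_move) {
        // an empty community (gain 0, becoming a singleton) always exists
        double best = s[0];
        for (int c = 1; c < n; ++c) if (s[c] > best) best = s[c];
        if (best < 0.0) best = 0.0;
        if (s[cur] >= best - tol) continue; // stay on ties
        for (int c = 0; c < n; ++c) {
          if (used[c] && s[c] >= best - tol) { target = c; break; }
        }
        if (target < 0) target = empty_c;
      } else {
        // draw among strictly improving targets, probability ~ gain
        std::vector<int> cand;
        std::vector<double> gain;
        double tot = 0.0;
        for (int c = 0; c < n; ++c) {
          if (c == cur) continue;
          double gc = (used[c] ? s[c] : (c == empty_c ? 0.0 : NA_REAL));
          if (c != empty_c && !used[c]) continue;
          double g = gc - s[cur];
          if (g > tol) { cand.push_back(c); gain.push_back(g); tot += g; }
        }
        if (cand.empty()) continue;
        double u = R::unif_rand() * tot;
        double acc = 0.0;
        target = cand.back();
        for (size_t q = 0; q < cand.size(); ++q) {
          acc += gain[q];
          if (u <= acc) { target = cand[q]; break; }
        }
      }
      if (target >= 0 && target != cur) {
        labels[v] = target;
        improved = true;
      }
    }
  }
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = labels[i] + 1;
  return out;
}
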