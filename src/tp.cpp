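#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n) from R's RNG (keeps set.seed() reproducibility).
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// One curveball trade between two distinct random rows: the taxa exclusive
// to either row are pooled, shuffled, and dealt back in the original
// exclusive-set sizes. Both marginal vectors are invariant.
static void curveball_trade_inplace(IntegerMatrix &m, std::vector<int> &pool) {
  const int R = m.nrow(), S = m.ncol();
  int r1 = runif_int(R);
  int r2 = runif_int(R - 1);
  if (r2 >= r1) ++r2;
  pool.clear();
  int n1 = 0;
  for (int c = 0; c < S; ++c) {
    const int x1 = m(r1, c), x2 = m(r2, c);
    if (x1 == 1 && x2 == 0) { pool.push_back(c); ++n1; }
    else if (x1 == 0 && x2 == 1) pool.push_back(c);
  }
  const int n = (int)pool.size();
  if (n1 == 0 || n1 == n) return;  // nothing exchangeable
  for (int i = n - 1; i > 0; --i) {  // Fisher-Yates
    int j = runif_int(i + 1);
    std::swap(pool[i], pool[j]);
  }
  for (int i = 0; i < n; ++i) {
    const int c = pool[i];
    const int to_r1 = (i < n1);
    m(r1, c) = to_r1 ? 1 : 0;
    m(r2, c) = to_r1 ? 0 : 1;
  }
}

// [[Rcpp::export]]
IntegerMatrix cpp_curveball(IntegerMatrix m, int n_trades) {
  IntegerMatrix out = clone(m);
  if (out.nrow() < 2) return out;
  std::vector<int> pool;
  pool.reserve(out.ncol());
  for (int t = 0; t < n_trades; ++t) curveball_trade_inplace(out, pool);
  return out;
}

// Steer one axis of the marginal-discrepancy space by relocating single
// occurrences. steer_rows = true uses within-column moves (row totals move,
// column totals fixed); false uses within-row moves (the converse). A move
// is accepted only if it takes the normalized discrepancy strictly closer
// to `target` without exceeding target + eps.
// [[Rcpp::export]]
List cpp_steer(IntegerMatrix m, NumericVector orig_totals, double d_ref,
               double target, double eps, int budget, bool steer_rows) {
  IntegerMatrix out = clone(m);
  const int R = out.nrow(), S = out.ncol();
  const int axis_n = steer_rows ? R : S;
  const double F = (double)sum(out);
  std::vector<double> cur(axis_n, 0.0);
  for (int r = 0; r < R; ++r)
    for (int c = 0; c < S; ++c)
      if (out(r, c)) cur[steer_rows ? r : c] += 1.0;
  double raw = 0.0;
  for (int i = 0; i < axis_n; ++i) raw += std::fabs(cur[i] - orig_totals[i]);
  auto norm = [&](double rawv) {
    double v = rawv / (2.0 * F) / d_ref;
    return v > 1.0 ? 1.0 : v;
  };
  // a single relocation moves the raw discrepancy by at most 2, i.e. the
  // normalized value by 1/(F * d_ref): the tolerance cannot be finer than
  // half that lattice spacing
  double eps_eff = std::max(eps, 0.5 / (F * d_ref) + 1e-12);
  double cur_norm = norm(raw);
  int attempts = 0;
  while (std::fabs(cur_norm - target) > eps_eff && attempts < budget) {
    ++attempts;
    // random occupied cell (rejection; fill is bounded away from 0 by caller)
    int r = -1, c = -1;
    for (int tries = 0; tries < 64; ++tries) {
      int rr = runif_int(R), cc = runif_int(S);
      if (out(rr, cc) == 1) { r = rr; c = cc; break; }
    }
    if (r < 0) continue;
    // random empty cell in the same column (steer_rows) or row
    int dest = -1;
    const int dn = steer_rows ? R : S;
    for (int tries = 0; tries < 64; ++tries) {
      int dd = runif_int(dn);
      int v = steer_rows ? out(dd, c) : out(r, dd);
      if (v == 0) { dest = dd; break; }
    }
    if (dest < 0) continue;
    const int from_i = steer_rows ? r : c;
    const int to_i = dest;
    double d_from = std::fabs(cur[from_i] - 1.0 - orig_totals[from_i]) -
                    std::fabs(cur[from_i] - orig_totals[from_i]);
    double d_to = std::fabs(cur[to_i] + 1.0 - orig_totals[to_i]) -
                  std::fabs(cur[to_i] - orig_totals[to_i]);
    double new_raw = raw + d_from + d_to;
    double new_norm = norm(new_raw);
    if (new_norm <= target + eps_eff &&
        std::fabs(new_norm - target) < std::fabs(cur_norm - target)) {
      if (steer_rows) { out(r, c) = 0; out(dest, c) = 1; }
      else            { out(r, c) = 0; out(r, dest) = 1; }
      cur[from_i] -= 1.0;
      cur[to_i] += 1.0;
      raw = new_raw;
      cur_norm = new_norm;
    }
  }
  return List::create(
    _["matrix"] = out,
    _["achieved"] = cur_norm,
    _["raw"] = raw,
    _["converged"] = std::fabs(cur_norm - target) <= eps_eff,
    _["eps_eff"] = eps_eff,
    _["attempts"] = attempts
  );
}

// Mean Bray-Curtis discrepancy between the original marginal totals of one
// axis and those of `n_ref` equiprobable refills (F occurrences placed
// uniformly without collision).
// [[Rcpp::export]]
double cpp_discrepancy_reference(IntegerMatrix m, bool rows_axis, int n_ref) {
  const int R = m.nrow(), S = m.ncol();
  const int ncell = R * S;
  const int F = sum(m);
  const int axis_n = rows_axis ? R : S;
  std::vector<double> orig(axis_n, 0.0);
  for (int r = 0; r < R; ++r)
    for (int c = 0; c < S; ++c)
      if (m(r, c)) orig[rows_axis ? r : c] += 1.0;
  std::vector<int> cells(ncell);
  std::vector<double> tot(axis_n);
  double acc = 0.0;
  for (int k = 0; k < n_ref; ++k) {
    for (int i = 0; i < ncell; ++i) cells[i] = i;
    std::fill(tot.begin(), tot.end(), 0.0);
    for (int i = 0; i < F; ++i) {  // partial Fisher-Yates draw of F cells
      int j = i + runif_int(ncell - i);
      std::swap(cells[i], cells[j]);
      int cell = cells[i];
      int idx = rows_axis ? (cell % R) : (cell / R);
      tot[idx] += 1.0;
    }
    double raw = 0.0;
    for (int i = 0; i < axis_n; ++i) raw += std::fabs(tot[i] - orig[i]);
    acc += raw / (2.0 * F);
  }
  return acc / n_ref;
}
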