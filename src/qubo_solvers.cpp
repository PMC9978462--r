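#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// Objective: E(x) = sum_{i<j} d_ij [x_i != x_j] + alpha * (sum_i x_i - c)^2
// d is symmetric, non-negative, zero diagonal.
//
// Besides minimizing E, both solvers post-process every cardinality-feasible
// labeling they encounter (sum x_i == c) into its normalized cut
//   Ncut = cut/assoc(A,V) + cut/assoc(B,V),
// with assoc(A,V) = sum of degrees over A plus optional per-node self
// weights, and keep the feasible labeling with the smallest Ncut. The Ncut
// criterion itself is never part of the annealed objective.

static double cut_energy(const NumericMatrix& d, const std::vector<int>& x) {
  const int n = x.size();
  double e = 0.0;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j)
      if (x[i] != x[j]) e += d(i, j);
  return e;
}

static bool lex_less(const std::vector<int>& a, const std::vector<int>& b) {
  for (size_t i = 0; i < a.size(); ++i) {
    if (a[i] != b[i]) return a[i] < b[i];
  }
  return false;
}

struct NcutTracker {
  double best = R_PosInf;
  double best_cut = 0.0;
  std::vector<int> labels;
  double total_assoc = 0.0;

  void consider(double cut, double assoc_a, const std::vector<int>& x) {
    double assoc_b = total_assoc - assoc_a;
    if (assoc_a <= 0.0 || assoc_b <= 0.0) return;
    double nc = cut / assoc_a + cut / assoc_b;
    if (nc < best - 1e-12 ||
        (std::abs(nc - best) <= 1e-12 &&
         (labels.empty() || lex_less(x, labels)))) {
      best = nc;
      best_cut = cut;
      labels = x;
    }
  }
};

// Exhaustive minimization over all 2^n labelings, Gray-code order with O(n)
// incremental updates. Ties resolved to the lexicographically smallest
// label vector. n is capped by the caller.
// [[Rcpp::export]]
List qubo_exhaustive(NumericMatrix d, int c, double alpha, NumericVector selfw) {
  const int n = d.nrow();
  if (n > 30) stop("exhaustive enumeration limited to n <= 30");
  std::vector<double> wdeg(n, 0.0);  // assoc contribution per node
  double total_assoc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) if (j != i) wdeg[i] += d(i, j);
    wdeg[i] += selfw[i];
    total_assoc += wdeg[i];
  }
  NcutTracker trk;
  trk.total_assoc = total_assoc;

  std::vector<int> x(n, 0);
  double cut = 0.0, assoc_a = 0.0;
  int ones = 0;
  double energy = alpha * (double)(ones - c) * (ones - c);
  std::vector<int> best = x;
  double best_energy = energy, best_cut = cut;
  int best_ones = ones;
  const std::uint64_t total = (std::uint64_t)1 << n;
  std::uint64_t gray_prev = 0;
  for (std::uint64_t s = 1; s < total; ++s) {
    std::uint64_t gray = s ^ (s >> 1);
    std::uint64_t diff = gray ^ gray_prev;
    gray_prev = gray;
    int i = 0;
    while (!(diff & 1)) { diff >>= 1; ++i; }
    double dcut = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      dcut += (x[j] == x[i]) ? d(i, j) : -d(i, j);
    }
    cut += dcut;
    if (x[i]) { ones -= 1; assoc_a -= wdeg[i]; }
    else      { ones += 1; assoc_a += wdeg[i]; }
    x[i] = 1 - x[i];
    double e = cut + alpha * (double)(ones - c) * (ones - c);
    if (e < best_energy - 1e-12 ||
        (std::abs(e - best_energy) <= 1e-12 && lex_less(x, best))) {
      best = x;
      best_energy = e;
      best_cut = cut;
      best_ones = ones;
    }
    if (ones == c) trk.consider(cut, assoc_a, x);
  }
  return List::create(
    _["labels"] = IntegerVector(best.begin(), best.end()),
    _["mincut_energy"] = best_cut,
    _["penalty_energy"] = alpha * (double)(best_ones - c) * (best_ones - c),
    _["energy"] = best_energy,
    _["ncut_best"] = trk.best,
    _["ncut_labels"] = IntegerVector(trk.labels.begin(), trk.labels.end()),
    _["ncut_cut"] = trk.best_cut);
}

// Simulated annealing: independent Metropolis chains (one per seed) with
// single-bit-flip moves and geometric cooling from t0 to tf over `sweeps`
// sweeps of n proposed flips each. Chains start from a random labeling with
// exactly c ones. Returns the best state over all chains plus per-chain
// best energies (used to verify convergence across replicas).
// [[Rcpp::export]]
List qubo_sa(NumericMatrix d, int c, double alpha, int sweeps,
             double t0, double tf, IntegerVector seeds, NumericVector selfw) {
  const int n = d.nrow();
  const int R = seeds.size();
  if (t0 <= 0 || tf <= 0 || tf > t0) stop("temperatures must satisfy 0 < tf <= t0");

  std::vector<double> wdeg(n, 0.0);
  double total_assoc = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) if (j != i) wdeg[i] += d(i, j);
    wdeg[i] += selfw[i];
    total_assoc += wdeg[i];
  }
  NcutTracker trk;
  trk.total_assoc = total_assoc;

  std::vector<int> best_all;
  double best_all_energy = R_PosInf, best_all_cut = 0.0;
  int best_all_ones = 0, best_replica = -1;
  NumericVector replica_energy(R);

  const double cool = (sweeps > 1) ? std::pow(tf / t0, 1.0 / (sweeps - 1)) : 1.0;

  for (int r = 0; r < R; ++r) {
    std::mt19937 rng((std::uint32_t)seeds[r]);
    std::uniform_int_distribution<int> pick(0, n - 1);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    // random start with exactly c ones (Fisher-Yates prefix)
    std::vector<int> idx(n);
    for (int i = 0; i < n; ++i) idx[i] = i;
    for (int i = 0; i < c; ++i) {
      std::uniform_int_distribution<int> u(i, n - 1);
      std::swap(idx[i], idx[u(rng)]);
    }
    std::vector<int> x(n, 0);
    double assoc_a = 0.0;
    for (int i = 0; i < c; ++i) { x[idx[i]] = 1; assoc_a += wdeg[idx[i]]; }

    double cut = cut_energy(d, x);
    int ones = c;
    double energy = cut;  // penalty 0 at start
    std::vector<int> best = x;
    double best_energy = energy, best_cut = cut;
    int best_ones = ones;
    trk.consider(cut, assoc_a, x);

    double T = t0;
    for (int s = 0; s < sweeps; ++s) {
      for (int m = 0; m < n; ++m) {
        int i = pick(rng);
        double dcut = 0.0;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          dcut += (x[j] == x[i]) ? d(i, j) : -d(i, j);
        }
        int new_ones = ones + (x[i] ? -1 : 1);
        double dpen = alpha * ((double)(new_ones - c) * (new_ones - c) -
                               (double)(ones - c) * (ones - c));
        double dE = dcut + dpen;
        if (dE <= 0.0 || unif(rng) < std::exp(-dE / T)) {
          if (x[i]) assoc_a -= wdeg[i]; else assoc_a += wdeg[i];
          x[i] = 1 - x[i];
          cut += dcut;
          ones = new_ones;
          energy += dE;
          if (energy < best_energy - 1e-12 ||
              (std::abs(energy - best_energy) <= 1e-12 && lex_less(x, best))) {
            best = x;
            best_energy = energy;
            best_cut = cut;
            best_ones = ones;
          }
          if (ones == c) trk.consider(cut, assoc_a, x);
        }
      }
      T *= cool;
    }
    replica_energy[r] = best_energy;
    if (best_energy < best_all_energy - 1e-12 ||
        (std::abs(best_energy - best_all_energy) <= 1e-12 &&
         (best_all.empty() || lex_less(best, best_all)))) {
      best_all = best;
      best_all_energy = best_energy;
      best_all_cut = best_cut;
      best_all_ones = best_ones;
      best_replica = r;
    }
  }
  return List::create(
    _["labels"] = IntegerVector(best_all.begin(), best_all.end()),
    _["mincut_energy"] = best_all_cut,
    _["penalty_energy"] = alpha * (double)(best_all_ones - c) * (best_all_ones - c),
    _["energy"] = best_all_energy,
    _["replica_energies"] = replica_energy,
    _["best_replica"] = best_replica + 1,
    _["ncut_best"] = trk.best,
    _["ncut_labels"] = IntegerVector(trk.labels.begin(), trk.labels.end()),
    _["ncut_cut"] = trk.best_cut);
}

// Initial-temperature heuristic: max |dE| over random single-bit flips from
// random states.
// [[Rcpp::export]]
double sa_initial_temperature(NumericMatrix d, int c, double alpha, int seed,
                              int samples = 200) {
  const int n = d.nrow();
  std::mt19937 rng((std::uint32_t)seed);
  std::uniform_int_distribution<int> pick(0, n - 1);
  std::bernoulli_distribution coin(0.5);
  double mx = 1.0;
  for (int s = 0; s < samples; ++s) {
    std::vector<int> x(n);
    int ones = 0;
    for (int i = 0; i < n; ++i) { x[i] = coin(rng) ? 1 : 0; ones += x[i]; }
    int i = pick(rng);
    double dcut = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      dcut += (x[j] == x[i]) ? d(i, j) : -d(i, j);
    }
    int new_ones = ones + (x[i] ? -1 : 1);
    double dpen = alpha * ((double)(new_ones - c) * (new_ones - c) -
                           (double)(ones - c) * (ones - c));
    double dE = std::abs(dcut + dpen);
    if (dE > mx) mx = dE;
  }
  return mx;
}
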