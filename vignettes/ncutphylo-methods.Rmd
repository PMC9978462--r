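---
title: "Normalized min-cut phylogenetics: models, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized min-cut phylogenetics: models, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ncutphylo)
```

## The method in one paragraph

`ncutphylo` reconstructs a phylogenetic tree topology from protein sequences
without ever scoring whole trees. The sequence set is represented as a
weighted graph whose edge weights are normalized pairwise bit scores
(integers in 0–100), and the tree emerges from recursive bipartition of that
graph. Each bipartition is found by solving a family of cardinality-
constrained minimum cuts — quadratic binary (QUBO) objectives of the kind
annealing hardware accepts — and then selecting among the resulting cut
patterns by the normalized cut (Ncut) criterion of Shi and Malik. The
recursion bottoms out at clusters of one or two sequences, and each accepted
bipartition becomes an internal node of a rooted binary cladogram.

## Similarity graph

For sequences $i$ and $j$, the edge weight is

$$\mathrm{Normbit}(i,j) =
  \mathrm{round}\!\left(\frac{\mathrm{bit}(i,j)}
  {\tfrac12\{\mathrm{bit}(i,i)+\mathrm{bit}(j,j)\}} \cdot 100\right),$$

where $\mathrm{bit}(i,j) = (\lambda S - \ln K)/\ln 2$ is the Karlin–Altschul
bit score of the optimal Smith–Waterman local affine-gap alignment score
$S$. A pair whose e-value $K m n e^{-\lambda S}$ exceeds the cutoff gets
weight 0; self-comparison always gives 100 by construction. Alignment runs
through `Biostrings::pairwiseAlignment()`.

Parameter defaults (`alignment_params()`):

* substitution matrix **BLOSUM62**, gap open **11**, gap extend **1** — the
  standard protein local-alignment defaults for this matrix;
* $\lambda = 0.267$, $K = 0.041$ — the published gapped-BLOSUM62 constants;
* e-value cutoff **10** — a deliberately permissive relatedness filter.

Numerical choices: values exceeding 100 (a pairwise score above the mean
self-score, possible for length-asymmetric pairs) are clipped to 100;
rounding is half-away-from-zero because the downstream solver consumes
integers and no rounding rule is otherwise implied; a best local raw score
of 0 (every residue pair scoring negative) is treated as "no alignment
exists" — bit score 0, e-value infinite, similarity 0. Unknown residues are
mapped to `X` on input and score 0 against everything. The e-value uses the
plain $Kmn e^{-\lambda S}$ form without finite-size length correction: at a
cutoff as permissive as 10 the correction cannot change whether a pair
survives in any regime that matters here.

## The constrained cut and its penalty

For binary labels $x_i \in \{0,1\}$ over $n$ sequences the solver minimizes

$$E(x) = \sum_{i<j} d_{ij}\,(x_i - x_j)^2 \;+\; \alpha\Big(\sum_i x_i - c\Big)^2 .$$

The first term is the similarity crossing the cut; the second vanishes
exactly when the 1-side has $c$ members. Because the count term is what
makes the problem hard to game — an unconstrained minimum cut on a
similarity graph almost always shaves off the single most diverged sequence
— $c$ is swept over $1..\lfloor n/2 \rfloor$ (the complementary sizes are
redundant by symmetry), and $\alpha$ is escalated from 100 in steps of 500
whenever the returned solution violates the constraint, up to 20
escalations. These escalation constants are protocol constants of the
method, not tuning knobs.

Two interchangeable backends satisfy the solver contract:

* **exhaustive** — Gray-code enumeration of all $2^n$ labelings with $O(n)$
  incremental energy updates; guaranteed optimum; refused above
  `exhaustive_limit` (default 20) nodes.
* **simulated_annealing** — 12 independent Metropolis chains (the method's
  replicate count, also used to verify convergence), single-bit-flip moves,
  geometric cooling over $10^4$ sweeps from an initial temperature
  auto-calibrated as the largest single-flip $|\Delta E|$ seen over random
  states down to $0.01$. Chains start from a random labeling with exactly
  $c$ ones. Replica exchange between chains is not implemented: at the
  problem sizes where a desk-scale solver is appropriate, independent
  restarts already reach the exhaustive optimum on every tested instance,
  and exchange would couple the chains' reproducibility to their scheduling.

Determinism: all randomness derives from the configured seed (replica seeds
are derived arithmetically from it), and equal-energy optima resolve to the
lexicographically smallest label vector, so both backends are bitwise
reproducible.

## From min-cut to normalized cut

The selection criterion is

$$\mathrm{Ncut}(A,B) = \frac{\mathrm{cut}(A,B)}{\mathrm{assoc}(A,V)} +
  \frac{\mathrm{cut}(A,B)}{\mathrm{assoc}(B,V)},$$

with $\mathrm{assoc}(A,V)$ the total similarity between members of $A$ and
the whole node set. Ncut cannot be written as a fixed quadratic binary form,
so it is never the solved objective; it is obtained purely by
post-processing cut solutions.

Two design points deserve emphasis:

* **Diagonal handling.** Whether $\mathrm{assoc}$ includes the self-terms
  $d_{uu} = 100$ is genuinely open; self-similarity inflates every subset's
  association by a constant per member and carries no grouping information,
  so the default excludes it. Both readings are implemented
  (`include_diagonal` in `solver_config()`), and the cut value in the Ncut
  numerator is always the bare crossing similarity, never the solver's
  penalty term (which is zero in any accepted solution anyway).
* **The selection pool.** The minimum-*cut* bipartition of size $c$ is not
  in general the minimum-*Ncut* bipartition of size $c$: association varies
  across equal-sized subsets, and on random integer matrices the two
  disagree on a noticeable fraction of instances. Scoring only the energy
  minimizer of each $c$ would therefore miss the Ncut optimum the sweep
  exists to find. Both backends consequently post-process **every**
  cardinality-feasible labeling encountered during the search — all of them
  for the exhaustive backend, every visited state for the annealer — and
  the sweep selects the minimum Ncut over this pool. With the exhaustive
  backend the selection is provably the global Ncut minimum over all
  nontrivial bipartitions, which is what the package's oracle-equivalence
  tests assert against brute force. The annealed objective remains the pure
  QUBO above.

Ties in the final selection break toward smaller $c$, then lexicographically
smaller labels. A cut of value 0 (disconnected graph) has Ncut 0 by
convention; a side with zero association and a positive crossing cut is
impossible, and `ncut_value()` rejects degenerate all-zero graphs
explicitly.

## Tree construction

`reconstruct_tree()` applies the sweep recursively: the accepted bipartition
of the current cluster becomes an internal node, each side recurses on its
induced submatrix, and clusters of one or two members terminate (a 3-member
cluster necessarily splits 1|2, its only admissible cut). The emitted
cladogram is rooted at the first cut — a presentation choice, which is why
`rf_distance()` compares topologies unrooted — and carries no branch
lengths: the method recovers topology only. Unit lengths can be attached for
tools that require them.

## What the simulator emulates

`simulate_tree()` and `evolve_sequences()` generate the benchmark inputs
end-to-end.

**Trees.** Topologies come from a uniform random shape (`ape::rtree`) or a
Yule pure-birth process (birth rate 1, via `ape::rphylo`). Branch lengths
are redrawn: normal with variance equal to half the mean (negatives
resampled — i.e. a truncated normal) for random-shape trees, exponential
(rate 2) for Yule trees, then rescaled multiplicatively so the realized mean
matches the target exactly. The mean grid used throughout the benchmarks is
$\{0.125, 0.250, \dots, 0.750\}$ substitutions/site. `balanced_clade_tree()`
additionally provides the fully balanced, constant-branch-length topology
used for end-to-end recovery checks (see limitations below).

**Sequences.** Amino-acid evolution along the tree uses the WAG replacement
model (exchangeabilities and equilibrium frequencies embedded as package
constants) with discrete-gamma rate heterogeneity — $k = 5$ equal-
probability categories represented by their category means — plus a 1%
fraction of invariant sites. The gamma shape parameter is not part of the
benchmark protocol's stated constants; the package defaults it to 1.0, a
middle-of-the-road heterogeneity level, and exposes it in
`seq_evol_config()`. Rates are left with mean 1 among variable sites, so a
branch of length $t$ produces $t(1-p_{\mathrm{inv}})$ expected substitutions
per site; this is the convention under which the small-branch linearization
$p \approx 2t(1-p_{\mathrm{inv}})$ holds, and the calibration tests check
exactly that.

Substitutions are simulated event-wise (per-site Gillespie along each
branch) rather than by transition-probability sampling, so the realized
substitution event count is available; that is what makes the
indel-to-substitution ratio a measurable quantity rather than a nominal one.
Indel events arrive as a Poisson count with mean 2% of the branch's expected
substitutions (the per-branch reading of the event-ratio; a per-tree reading
would only differ through sequence-length drift, which is second-order at
2%). Each event inserts (content from equilibrium, position uniform) or
deletes (start uniform) a block whose length follows the discrete power law
$P(\ell) \propto \ell^{-1.7}$ truncated at 50. Indels are applied at the end
of the branch, after the branch's substitutions; the interaction between
within-branch deletion timing and substitution exposure is again
second-order at this rate. Every residue carries a global homology column
id, so `p_distance()` can compare true homologous sites even after indels;
without homology maps it falls back to a global alignment and flags the
result.

**What passing tests do not show.** The generator produces clean WAG+Γ+I
evolution on known trees. Real protein families add domain shuffling,
heterotachy, compositional bias, and alignment ambiguity, none of which are
modeled; recovery rates measured here are upper bounds on what the method
would achieve on real data.

## Numerical and scale choices

Test and benchmark problem sizes are chosen so the exhaustive backend can
serve as the within-suite oracle: oracle-equivalence runs use $n \in
\{6..12\}$ (20 random instances), end-to-end recovery uses 20 replicates at
$n \in \{8, 16\}$ with 500-residue sequences, and the simulator calibrations
use 200 replicates (invariant fraction), 40 replicates on an 8-taxon clade
tree (indel ratio), and $5 \times 10^4$ draws (power-law exponent). These
sizes give the 3-standard-error calibration bands quoted in the tests
comfortable resolution while keeping the whole suite under a minute of
solver time. Floating-point ties in energies and Ncut values are compared at
an absolute tolerance of $10^{-12}$, far below the integer similarity scale.

## Known limitations

* **Balance bias of the greedy recursion.** Ncut penalizes unbalanced cuts.
  When the true topology is strongly unbalanced (caterpillar-like) and
  similarities are nearly uniform, the top-down recursion can prefer a
  balanced split that crosses a true clade; with noisy branch lengths
  (truncated normal with variance half the mean) many internal branches are
  near zero and no distance-based method — including neighbor-joining on
  the true p-distance matrix — recovers the topology reliably. The
  end-to-end recovery benchmark therefore uses balanced clades with
  constant branch length 0.125, the regime in which the optimum is
  unambiguous; recovery there is exact in all tested replicates.
* **Transitivity saturates at the default cutoff.** Under exact local
  alignment, a random protein pair almost always has some hit with e-value
  below 10, so the >0-thresholded graph stays complete and transitivity is
  identically 1 regardless of divergence. The divergence dependence of
  transitivity only appears at stringent cutoffs (the trend test uses
  $10^{-6}$); heuristic aligners show it at permissive cutoffs only because
  they drop weak hits.
* **Topology only.** No branch lengths, no support values, no likelihood
  model for the reconstruction itself.
* The exhaustive backend is capped at 20 nodes by design; beyond that only
  the annealer applies and its optimality is empirical, not guaranteed.

## Reproducing the benchmark tables

`benchmark_grid()` runs simulate → similarity → {Ncut sweep, spectral,
k-means, Ward} over a grid of taxa counts and branch lengths and returns a
tidy table (one row per replicate × method) with each method's Ncut,
within-cluster criterion, NMI against the Ncut selection, and the dataset
statistics (transitivity, mean standardized bit score, mean p-distance).
The same grid is reachable from the command line via
`exec/ncutphylo benchmark`.
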