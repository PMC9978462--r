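#' Cardinality-constrained min-cut as a QUBO problem
#'
#' Bundles the quadratic binary objective
#' `E(x) = sum_{i<j} d_ij (x_i - x_j)^2 + alpha (sum_i x_i - c)^2`
#' over binary labels `x_i` in `{0, 1}`. The first term is the weight of the
#' cut induced by the labeling; the second is a penalty that vanishes exactly
#' when the 1-labeled side has `c` members, so `c` indirectly fixes the cut
#' size and `alpha` sets how expensive a violation is.
#'
#' @param d symmetric non-negative numeric matrix of pairwise similarities
#'   (a [similarity_matrix()] or plain matrix).
#' @param c target number of 1-labeled nodes, `1 <= c <= floor(n/2)`.
#' @param alpha positive integer penalty weight.
#' @return an object of class `qubo_problem`.
#' @export
qubo_problem <- function(d, c, alpha = 100L) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(n == ncol(d), n >= 2)
  if (!isTRUE(all.equal(unname(d), unname(t(d))))) stop("d must be symmetric")
  if (any(d < 0)) stop("d must be non-negative")
  if (c < 1 || c > floor(n / 2)) stop("c must lie in 1..floor(n/2)")
  if (alpha < 1) stop("alpha must be >= 1")
  structure(list(n = n, d = d, c = as.integer(c), alpha = as.numeric(alpha)),
            class = "qubo_problem")
}

#' Solver configuration
#'
#' Backends: `"exhaustive"` enumerates all labelings (guaranteed optimum,
#' refused above `exhaustive_limit` nodes); `"simulated_annealing"` runs
#' `replicas` independent Metropolis chains with single-bit-flip moves and
#' geometric cooling. The initial temperature defaults to the maximum
#' absolute single-flip energy change observed over random states; the final
#' temperature is 0.01. The penalty weight `alpha` starts at `alpha_init`
#' and is raised by `alpha_step` whenever the returned solution violates the
#' cardinality constraint (non-zero penalty energy), up to
#' `alpha_max_retries` escalations.
#'
#' @param backend `"exhaustive"` or `"simulated_annealing"`.
#' @param replicas number of independent annealing chains (default 12).
#' @param sweeps sweeps per chain (each sweep proposes n flips).
#' @param t_initial initial temperature; `NULL` means auto-calibrated.
#' @param t_final final temperature.
#' @param seed integer seed; every stochastic choice derives from it.
#' @param alpha_init initial penalty weight (default 100).
#' @param alpha_step penalty escalation step (default 500).
#' @param alpha_max_retries maximum escalations before giving up.
#' @param exhaustive_limit largest n the exhaustive backend accepts.
#' @param include_diagonal logical; whether assoc sums include d_uu terms
#'   (default `FALSE`, see [assoc()]).
#' @return an object of class `solver_config`.
#' @export
solver_config <- function(backend = c("exhaustive", "simulated_annealing"),
                          replicas = 12L, sweeps = 10000L,
                          t_initial = NULL, t_final = 0.01,
                          seed = 1L,
                          alpha_init = 100L, alpha_step = 500L,
                          alpha_max_retries = 20L,
                          exhaustive_limit = 20L,
                          include_diagonal = FALSE) {
  backend <- match.arg(backend)
  stopifnot(replicas >= 1, sweeps >= 1, t_final > 0,
            is.null(t_initial) || t_initial >= t_final,
            alpha_init >= 1, alpha_step >= 1, alpha_max_retries >= 0)
  structure(list(backend = backend, replicas = as.integer(replicas),
                 sweeps = as.integer(sweeps), t_initial = t_initial,
                 t_final = t_final, seed = as.integer(seed),
                 alpha_init = as.integer(alpha_init),
                 alpha_step = as.integer(alpha_step),
                 alpha_max_retries = as.integer(alpha_max_retries),
                 exhaustive_limit = as.integer(exhaustive_limit),
                 include_diagonal = isTRUE(include_diagonal)),
            class = "solver_config")
}

#' Cut energy of a labeling
#'
#' Total similarity across the cut: `sum_{i<j} d_ij (x_i - x_j)^2`, i.e. the
#' sum of `d_ij` over pairs assigned to different sides. Invariant under
#' complementing all labels.
#'
#' @param labels binary vector (0/1) of length n.
#' @param d symmetric similarity matrix.
#' @return non-negative number.
#' @export
mincut_energy <- function(labels, d) {
  d <- as.matrix(d)
  if (length(labels) != nrow(d)) stop("labels length must match matrix size")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  a <- labels == 1
  sum(d[a, !a, drop = FALSE])
}

#' Cardinality penalty energy of a labeling
#'
#' `alpha * (sum_i x_i - c)^2`: zero exactly when the 1-side has `c`
#' members, positive otherwise.
#'
#' @param labels binary vector (0/1).
#' @param c target count of 1-labels, >= 1.
#' @param alpha penalty weight.
#' @return non-negative number.
#' @export
penalty_energy <- function(labels, c, alpha) {
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  if (c < 1) stop("c must be >= 1")
  alpha * (sum(labels) - c)^2
}

# replica seeds derived deterministically from the base seed; call_index
# distinguishes successive solver calls inside one pipeline run
.derive_seeds <- function(seed, replicas, call_index = 0L) {
  as.integer((as.double(seed) + 104729 * as.double(call_index) +
                9973 * seq_len(replicas)) %% 2147483647) + 1L
}

#' Solve the constrained min-cut at fixed c
#'
#' Minimizes the full quadratic objective (cut + cardinality penalty) with
#' the configured backend. The exhaustive backend returns the true optimum;
#' the annealing backend returns the best labeling over all replicas.
#' Equal-energy optima resolve to the lexicographically smallest label
#' vector, making both backends deterministic for a fixed seed.
#'
#' @param problem a [qubo_problem()].
#' @param cfg a [solver_config()].
#' @param call_index internal offset for deriving per-call replica seeds.
#' @return an object of class `cut_solution`: `labels`, `mincut_energy`,
#'   `penalty_energy`, `alpha_used`, `replica_count`, `seed`, and (for the
#'   annealing backend) `replica_energies`. The solver additionally
#'   post-processes every cardinality-feasible labeling it encounters into
#'   its normalized cut and reports the best as `ncut_candidate` (list:
#'   `ncut`, `labels`, `cut`); the annealed objective itself is never the
#'   normalized cut.
#' @export
solve_fixed_c <- function(problem, cfg = solver_config(), call_index = 0L) {
  stopifnot(inherits(problem, "qubo_problem"), inherits(cfg, "solver_config"))
  d <- problem$d
  selfw <- if (cfg$include_diagonal) diag(d) else rep(0, problem$n)
  diag(d) <- 0
  if (cfg$backend == "exhaustive") {
    if (problem$n > cfg$exhaustive_limit)
      stop("exhaustive backend refuses n = ", problem$n,
           " > limit ", cfg$exhaustive_limit)
    res <- qubo_exhaustive(d, problem$c, problem$alpha, selfw)
    replica_energies <- NULL
    replicas <- 1L
  } else {
    seeds <- .derive_seeds(cfg$seed, cfg$replicas, call_index)
    t0 <- cfg$t_initial
    if (is.null(t0))
      t0 <- max(sa_initial_temperature(d, problem$c, problem$alpha, seeds[1]),
                cfg$t_final)
    res <- qubo_sa(d, problem$c, problem$alpha, cfg$sweeps,
                   t0, cfg$t_final, seeds, selfw)
    replica_energies <- res$replica_energies
    replicas <- cfg$replicas
  }
  structure(list(labels = res$labels,
                 ncut_candidate = list(ncut = res$ncut_best,
                                       labels = res$ncut_labels,
                                       cut = res$ncut_cut),
                 mincut_energy = res$mincut_energy,
                 penalty_energy = res$penalty_energy,
                 energy = res$energy,
                 alpha_used = problem$alpha,
                 c = problem$c,
                 replica_count = replicas,
                 replica_energies = replica_energies,
                 seed = cfg$seed,
                 backend = cfg$backend),
            class = "cut_solution")
}

#' Solve with penalty-weight escalation
#'
#' Runs [solve_fixed_c()] and, whenever the returned solution has non-zero
#' penalty energy (the 1-side does not have exactly `c` members), raises
#' `alpha` by `alpha_step` and re-solves, starting from `alpha_init`. The
#' accepted solution always satisfies the cardinality constraint exactly.
#'
#' @inheritParams solve_fixed_c
#' @return a `cut_solution` with `penalty_energy == 0` and
#'   `sum(labels) == c`.
#' @export
solve_with_alpha_adaptation <- function(problem, cfg = solver_config(),
                                        call_index = 0L) {
  alpha <- cfg$alpha_init
  for (k in 0:cfg$alpha_max_retries) {
    p <- qubo_problem(problem$d, problem$c, alpha)
    sol <- solve_fixed_c(p, cfg, call_index = call_index + k)
    if (sol$penalty_energy == 0) return(sol)
    alpha <- alpha + cfg$alpha_step
  }
  stop("no zero-penalty solution within ", cfg$alpha_max_retries,
       " escalations (last alpha tried: ", alpha - cfg$alpha_step, ")")
}

#' Serialize a cut solution to JSON
#'
#' Writes the labeling, energies, penalty weight, and seed of a
#' `cut_solution` as a JSON record for audit trails.
#'
#' @param sol a `cut_solution`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cut_json <- function(sol, path) {
  stopifnot(inherits(sol, "cut_solution"))
  rec <- sol[c("labels", "mincut_energy", "penalty_energy", "alpha_used",
               "c", "replica_count", "seed", "backend")]
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @export
print.cut_solution <- function(x, ...) {
  cat("Constrained min-cut solution (", x$backend, ")\n", sep = "")
  cat("  c =", x$c, " alpha =", x$alpha_used,
      " cut =", x$mincut_energy, " penalty =", x$penalty_energy, "\n")
  cat("  labels:", paste(x$labels, collapse = ""), "\n")
  invisible(x)
}
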