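#' Spectral bipartition of a similarity graph
#'
#' Shi–Malik spectral relaxation of the normalized cut: the similarity
#' matrix (diagonal zeroed) is taken as the affinity matrix, the second
#' eigenvector of the symmetric normalized Laplacian is computed, and the
#' embedding is split at whichever of the two standard thresholds (sign, or
#' median) yields the smaller Ncut. On a disconnected graph a warning is
#' issued and the split separates one connected component from the rest
#' (a zero-cut partition).
#'
#' @param matrix a [similarity_matrix()] or symmetric non-negative matrix.
#' @param seed unused by the deterministic eigen solver, kept for interface
#'   stability with stochastic baselines.
#' @return binary integer labels (1 = side A).
#' @export
spectral_bipartition <- function(matrix, seed = 1L) {
  w <- as.matrix(matrix)
  storage.mode(w) <- "double"
  diag(w) <- 0
  n <- nrow(w)
  if (all(w == 0)) stop("degenerate graph: all similarities are zero")
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  comp <- igraph::components(g)
  if (comp$no > 1) {
    warning("graph is disconnected; splitting off one component")
    return(as.integer(comp$membership == comp$membership[1]))
  }
  deg <- rowSums(w)
  dinv <- 1 / sqrt(deg)
  lsym <- diag(n) - (dinv * w) * rep(dinv, each = n)
  ev <- eigen((lsym + t(lsym)) / 2, symmetric = TRUE)
  # Fiedler vector of L_sym, mapped back through D^{-1/2}
  f <- dinv * ev$vectors[, n - 1]
  cand <- list(as.integer(f > 0), as.integer(f > stats::median(f)))
  cand <- Filter(function(l) any(l == 1) && any(l == 0), cand)
  if (length(cand) == 0) cand <- list(as.integer(f >= stats::median(f)))
  scores <- vapply(cand, .ncut_safe, numeric(1), d = w)
  cand[[which.min(scores)]]
}

#' Normalized mutual information of two clusterings
#'
#' Mutual information normalized by the arithmetic mean of the two label
#' entropies, in `[0, 1]`; invariant to label permutation. When the mean
#' entropy is zero (e.g. one clustering puts everything in one cluster) the
#' score is 0.
#'
#' @param labels_a,labels_b clustering label vectors of equal length.
#' @return value in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop("clusterings must have equal length")
  n <- length(labels_a)
  tab <- table(labels_a, labels_b)
  pij <- tab / n
  pi_ <- rowSums(pij)
  pj_ <- colSums(pij)
  nz <- pij > 0
  mi <- sum(pij[nz] * log(pij[nz] / outer(pi_, pj_)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi_) + h(pj_)) / 2
  if (denom <= 0) return(0)
  max(0, min(1, mi / denom))
}

#' Graph transitivity of a similarity matrix
#'
#' Global clustering coefficient — the ratio of closed triads (3 x
#' triangles) to connected triples — of the graph obtained by thresholding
#' off-diagonal similarities at > 0. Returns 0 when the graph has no
#' connected triples.
#'
#' @param matrix a [similarity_matrix()] or symmetric non-negative matrix.
#' @return value in `[0, 1]`.
#' @export
graph_transitivity <- function(matrix) {
  w <- as.matrix(matrix)
  if (nrow(w) < 3) stop("transitivity needs at least 3 nodes")
  diag(w) <- 0
  g <- igraph::graph_from_adjacency_matrix(w > 0, mode = "undirected")
  tr <- igraph::transitivity(g, type = "global")
  if (is.nan(tr)) 0 else tr
}

#' Within-cluster sum of squared pairwise distances
#'
#' The k-means objective evaluated on the similarity graph with the
#' distance transform `distance = 100 - similarity`: the sum over all
#' within-cluster pairs of squared distances.
#'
#' @param labels clustering label vector.
#' @param matrix a [similarity_matrix()].
#' @return non-negative value; attribute `distance_transform` records the
#'   transform used.
#' @export
kmeans_criterion <- function(labels, matrix) {
  d <- as.matrix(matrix)
  if (length(labels) != nrow(d)) stop("labels length must match matrix size")
  dist2 <- (100 - d)^2
  tot <- 0
  for (g in unique(labels)) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      sub <- dist2[idx, idx]
      tot <- tot + sum(sub[upper.tri(sub)])
    }
  }
  structure(tot, distance_transform = "100 - similarity")
}

#' Mean standardized bit score of a similarity matrix
#'
#' Mean of the off-diagonal entries; summarizes overall sequence similarity
#' of a dataset.
#'
#' @param matrix a [similarity_matrix()].
#' @return value in `[0, 100]`.
#' @export
mean_standardized_bitscore <- function(matrix) {
  m <- as.matrix(matrix)
  if (nrow(m) < 2) stop("need at least 2 sequences")
  mean(m[row(m) != col(m)])
}

#' Baseline bipartitioners
#'
#' Thin adapters around established clustering implementations, operated on
#' the similarity matrix with the `100 - similarity` distance transform
#' where a distance is required: `baseline_kmeans()` runs
#' [stats::kmeans()] (`centers = 2`, `nstart = 100`) on the matrix rows;
#' `baseline_ward()` cuts a Ward hierarchy ([stats::hclust()],
#' `method = "ward.D2"`) into two groups.
#'
#' @param matrix a [similarity_matrix()].
#' @param seed integer seed for the k-means restarts.
#' @return binary integer labels.
#' @export
baseline_kmeans <- function(matrix, seed = 1L) {
  set.seed(seed)
  km <- kmeans(as.matrix(matrix), centers = 2, nstart = 100)
  as.integer(km$cluster == 1)
}

#' @rdname baseline_kmeans
#' @export
baseline_ward <- function(matrix) {
  hc <- hclust(as.dist(100 - as.matrix(matrix)), method = "ward.D2")
  as.integer(cutree(hc, k = 2) == 1)
}

#' Benchmark cut methods over a simulation grid
#'
#' For each (taxa count, mean branch length, replicate) cell: simulates a
#' tree, evolves sequences, builds the similarity matrix, bipartitions it
#' with the Ncut sweep, the spectral baseline, k-means, and Ward, and
#' records per-method Ncut, k-means criterion, and NMI against the Ncut
#' selection, together with dataset statistics (transitivity, mean
#' standardized bit score, mean p-distance).
#'
#' @param n_taxa integer vector of taxa counts.
#' @param branch_lengths numeric vector of mean branch lengths.
#' @param replicates replicates per cell.
#' @param cfg a [solver_config()] for the Ncut sweep.
#' @param tree_shape passed to [sim_tree_config()].
#' @param seq_cfg_args list of overrides for [seq_evol_config()].
#' @param seed base seed; each cell derives its own.
#' @return tidy data frame, one row per replicate x method.
#' @export
benchmark_grid <- function(n_taxa = 8L, branch_lengths = 0.5,
                           replicates = 3L, cfg = solver_config(),
                           tree_shape = "uniform_random",
                           seq_cfg_args = list(), seed = 1L) {
  out <- list()
  cell <- 0L
  for (nt in n_taxa) for (bl in branch_lengths) for (r in seq_len(replicates)) {
    cell <- cell + 1L
    s <- as.integer((as.double(seed) + 7919 * cell) %% 2147483647)
    tcfg <- sim_tree_config(nt, shape = tree_shape, mean_branch_length = bl,
                            seed = s)
    tree <- simulate_tree(tcfg)
    scfg <- do.call(seq_evol_config, c(list(seed = s + 1L), seq_cfg_args))
    seqs <- evolve_sequences(tree, scfg)
    m <- build_similarity_matrix(seqs)
    ref <- sweep_and_select(m, cfg)
    methods <- list(
      ncut_sweep = ref$labels,
      spectral = tryCatch(spectral_bipartition(m, seed = s),
                          error = function(e) NULL, warning = function(w) NULL),
      kmeans = baseline_kmeans(m, seed = s),
      ward = baseline_ward(m))
    tr <- graph_transitivity(m)
    msb <- mean_standardized_bitscore(m)
    mpd <- mean(p_distance_matrix(seqs)[upper.tri(diag(nt))])
    for (meth in names(methods)) {
      lab <- methods[[meth]]
      if (is.null(lab)) next
      out[[length(out) + 1L]] <- data.frame(
        n_taxa = nt, branch_length = bl, replicate = r, method = meth,
        ncut = .ncut_safe(lab, as.matrix(m)),
        kmeans_criterion = as.numeric(kmeans_criterion(lab, m)),
        nmi_vs_ncut = nmi(lab, ref$labels),
        transitivity = tr, mean_bitscore = msb, mean_p_distance = mpd)
    }
  }
  do.call(rbind, out)
}
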