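# Fixtures and independent oracles used across the suite. The oracles are
# deliberately naive (double loops, full enumeration, textbook DP) so they
# share no code path with the implementation they check.

# random integer similarity matrix: symmetric, diagonal 100, entries 0..100
random_sim_matrix <- function(n, seed) {
  set.seed(seed)
  m <- matrix(0L, n, n)
  v <- sample.int(101, n * (n - 1) / 2, replace = TRUE) - 1L
  m[upper.tri(m)] <- v
  m <- m + t(m)
  diag(m) <- 100L
  similarity_matrix(m)
}

# two k-cliques (intra-clique weight `intra`) with uniform between-clique
# weight `cross`
two_clique_matrix <- function(k, intra = 100L, cross = 1L) {
  n <- 2L * k
  m <- matrix(cross, n, n)
  m[1:k, 1:k] <- intra
  m[(k + 1):n, (k + 1):n] <- intra
  diag(m) <- 100L
  similarity_matrix(m)
}

# the min-cut-pathology fixture: two 5-cliques joined by one bridge edge,
# plus a diverged member whose intra-clique similarity is below the bridge
# weight, so its degree undercuts the clique split
contrast_fixture <- function() {
  k <- 5L; n <- 2L * k
  m <- matrix(0L, n, n)
  m[1:k, 1:k] <- 100L
  m[(k + 1):n, (k + 1):n] <- 100L
  m[1, k + 1] <- m[k + 1, 1] <- 40L
  m[n, (k + 1):(n - 1)] <- m[(k + 1):(n - 1), n] <- 5L
  diag(m) <- 100L
  list(matrix = similarity_matrix(m), planted = rep(c(0L, 1L), each = k))
}

# cut energy by independent double loop
brute_cut_energy <- function(labels, d) {
  d <- as.matrix(d)
  tot <- 0
  n <- length(labels)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n))
    if (labels[i] != labels[j]) tot <- tot + d[i, j]
  tot
}

# assoc by double loop, diagonal excluded
brute_assoc <- function(group, d) {
  d <- as.matrix(d)
  tot <- 0
  for (u in group) for (t in seq_len(nrow(d))) if (u != t) tot <- tot + d[u, t]
  tot
}

# all nontrivial bipartitions of n nodes as 0/1 rows (complements included)
all_bipartitions <- function(n) {
  g <- as.matrix(expand.grid(rep(list(0:1), n)))[, n:1, drop = FALSE]
  g[rowSums(g) > 0 & rowSums(g) < n, , drop = FALSE]
}

# global minimum of the normalized cut over all nontrivial bipartitions
brute_min_ncut <- function(d) {
  d <- as.matrix(d)
  bp <- all_bipartitions(nrow(d))
  best <- Inf
  best_labels <- NULL
  for (r in seq_len(nrow(bp))) {
    lab <- bp[r, ]
    cut <- brute_cut_energy(lab, d)
    aa <- brute_assoc(which(lab == 1), d)
    ab <- brute_assoc(which(lab == 0), d)
    nc <- if (cut == 0) 0 else cut / aa + cut / ab
    if (nc < best) { best <- nc; best_labels <- lab }
  }
  list(ncut = best, labels = best_labels)
}

# global minimum cut weight over all nontrivial bipartitions
brute_min_cut <- function(d) {
  bp <- all_bipartitions(nrow(as.matrix(d)))
  min(apply(bp, 1, brute_cut_energy, d = d))
}

# textbook affine-gap Smith-Waterman (gap of length L costs open + L * ext),
# scores from a residue-pair matrix; O(mn) with three DP layers
sw_oracle <- function(a, b, mat, open = 11, ext = 1) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  m <- length(x); n <- length(y)
  M <- Ix <- Iy <- matrix(-Inf, m + 1, n + 1)
  M[1, ] <- M[, 1] <- 0
  best <- 0
  for (i in 2:(m + 1)) for (j in 2:(n + 1)) {
    Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
    Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) +
                     mat[x[i - 1], y[j - 1]])
    best <- max(best, M[i, j])
  }
  best
}

blosum62 <- local({
  e <- new.env()
  utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

random_protein <- function(len, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  paste(sample(aa, len, replace = TRUE), collapse = "")
}

fast_sa_config <- function(seed = 1L, sweeps = 2000L)
  solver_config("simulated_annealing", sweeps = sweeps, seed = seed)
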