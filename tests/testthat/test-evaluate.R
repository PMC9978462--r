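test_that("spectral bipartition splits bridged cliques along the planted cut", {
  m <- two_clique_matrix(4, intra = 100L, cross = 0L)
  mm <- unclass(m)
  mm[4, 5] <- mm[5, 4] <- 1L
  lab <- spectral_bipartition(similarity_matrix(mm))
  expect_equal(nmi(lab, rep(c(0, 1), each = 4)), 1)
})

test_that("spectral bipartition always returns two non-empty sides", {
  k4 <- similarity_matrix({m <- matrix(1L, 4, 4); diag(m) <- 100L; m})
  lab <- spectral_bipartition(k4)
  expect_true(any(lab == 1) && any(lab == 0))
  z <- matrix(0L, 4, 4); diag(z) <- 100L
  expect_error(spectral_bipartition(similarity_matrix(z)), "degenerate")
})

test_that("spectral and ncut sweeps agree on easy planted fixtures", {
  m <- two_clique_matrix(4, intra = 100L, cross = 3L)
  sp <- spectral_bipartition(m)
  nc <- sweep_and_select(m, solver_config("exhaustive"))
  expect_equal(nmi(sp, nc$labels), 1)
  expect_equal(nmi(sp, rep(c(0, 1), each = 4)), 1)
})

test_that("disconnected graphs are split at a component with a warning", {
  d <- matrix(0L, 6, 6)
  d[1:3, 1:3] <- 50L; d[4:6, 4:6] <- 50L; diag(d) <- 100L
  expect_warning(lab <- spectral_bipartition(similarity_matrix(d)),
                 "disconnected")
  expect_equal(nmi(lab, c(0, 0, 0, 1, 1, 1)), 1)
})

test_that("NMI matches the reference implementation on frozen cases", {
  # values frozen from scikit-learn normalized_mutual_info_score
  # (average_method = 'arithmetic')
  expect_equal(nmi(c(0, 0, 1, 1, 1, 0), c(0, 0, 1, 1, 0, 1)),
               0.08170416594551037, tolerance = 1e-12)
  expect_equal(nmi(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  expect_equal(nmi(c(0, 0, 0, 1, 1, 1, 1, 1), c(0, 0, 1, 1, 1, 1, 0, 1)),
               0.16645258379632516, tolerance = 1e-12)
})

test_that("NMI is 1 on identical or complemented clusterings, 0 on constants", {
  lab <- c(0, 1, 1, 0, 1)
  expect_equal(nmi(lab, lab), 1)
  expect_equal(nmi(lab, 1 - lab), 1)
  expect_equal(nmi(lab, rep(0, 5)), 0)
  expect_error(nmi(lab, c(0, 1)), "equal length")
})

test_that("transitivity: complete 1, star 0, triangle-plus-pendant 3/5", {
  cm <- matrix(50L, 5, 5); diag(cm) <- 100L
  expect_equal(graph_transitivity(similarity_matrix(cm)), 1)
  star <- matrix(0L, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 10L; diag(star) <- 100L
  expect_equal(graph_transitivity(similarity_matrix(star)), 0)
  tp <- matrix(0L, 4, 4)
  tp[1:3, 1:3] <- 30L
  tp[3, 4] <- tp[4, 3] <- 30L
  diag(tp) <- 100L
  expect_equal(graph_transitivity(similarity_matrix(tp)), 0.6)
  expect_error(graph_transitivity(matrix(1, 2, 2)), "3 nodes")
})

test_that("k-means criterion equals the brute-force within-cluster sum", {
  m <- similarity_matrix({x <- matrix(100L, 3, 3); x})
  expect_equal(as.numeric(kmeans_criterion(c(0, 0, 1), m)), 0)
  pairm <- similarity_matrix(matrix(c(100L, 90L, 90L, 100L), 2, 2))
  expect_equal(as.numeric(kmeans_criterion(c(0, 0), pairm)), 100)
  for (s in 1:4) {
    d <- unclass(random_sim_matrix(7, seed = 900 + s))
    lab <- sample(0:1, 7, replace = TRUE)
    brute <- 0
    for (i in 1:6) for (j in (i + 1):7)
      if (lab[i] == lab[j]) brute <- brute + (100 - d[i, j])^2
    expect_equal(as.numeric(kmeans_criterion(lab, d)), brute)
  }
})

test_that("mean standardized bit score averages the off-diagonal entries", {
  hi <- matrix(100L, 4, 4)
  expect_equal(mean_standardized_bitscore(similarity_matrix(hi)), 100)
  lo <- matrix(0L, 4, 4); diag(lo) <- 100L
  expect_equal(mean_standardized_bitscore(similarity_matrix(lo)), 0)
  cb <- matrix(0L, 4, 4); cb[1:2, 3:4] <- 100L; cb[3:4, 1:2] <- 100L
  diag(cb) <- 100L
  expect_equal(mean_standardized_bitscore(similarity_matrix(cb)),
               mean(cb[row(cb) != col(cb)]))
})

test_that("all methods recover an easy planted split; the criterion is minimal there", {
  m <- two_clique_matrix(4, intra = 95L, cross = 5L)
  planted <- rep(c(0, 1), each = 4)
  nc <- sweep_and_select(m, solver_config("exhaustive"))
  expect_equal(nmi(nc$labels, planted), 1)
  expect_equal(nmi(spectral_bipartition(m), planted), 1)
  expect_equal(nmi(baseline_kmeans(m, seed = 1), planted), 1)
  expect_equal(nmi(baseline_ward(m), planted), 1)
  crit <- apply(all_bipartitions(8), 1, function(l)
    as.numeric(kmeans_criterion(l, m)))
  planted_crit <- as.numeric(kmeans_criterion(planted, m))
  expect_equal(min(crit), planted_crit)
})

test_that("transitivity declines as divergence grows (rank trend)", {
  # exact local alignment at the permissive default threshold (e-value 10)
  # links essentially every pair, so the thresholded graph stays complete;
  # a stringent threshold is needed for edges to vanish with divergence
  p <- alignment_params(evalue_cutoff = 1e-6)
  levels <- c(0.125, 0.5, 1.2)
  tr_means <- vapply(seq_along(levels), function(i) {
    vals <- vapply(1:5, function(s) {
      tr <- simulate_tree(sim_tree_config(8, mean_branch_length = levels[i],
                                          seed = 1100 + 10 * i + s))
      seqs <- evolve_sequences(tr, seq_evol_config(root_length = 150,
                                                   seed = 1200 + 10 * i + s))
      graph_transitivity(build_similarity_matrix(seqs, p))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(tr_means[1] >= tr_means[2] && tr_means[2] >= tr_means[3])
  expect_lt(tr_means[3], tr_means[1])
})

test_that("the benchmark grid emits one tidy row per method and replicate", {
  tab <- benchmark_grid(n_taxa = 6L, branch_lengths = 0.3, replicates = 2L,
                        cfg = solver_config("exhaustive"),
                        seq_cfg_args = list(root_length = 120), seed = 4)
  expect_true(all(c("ncut_sweep", "kmeans", "ward") %in% tab$method))
  expect_true(all(tab$ncut >= 0))
  expect_true(all(tab$nmi_vs_ncut >= 0 & tab$nmi_vs_ncut <= 1))
  expect_equal(unique(tab$n_taxa), 6)
  ref_rows <- tab[tab$method == "ncut_sweep", ]
  expect_true(all(ref_rows$nmi_vs_ncut == 1))
})
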