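test_that("simulated trees have the requested size and exact mean branch length", {
  cfg <- sim_tree_config(32, mean_branch_length = 0.5, seed = 1)
  phy <- simulate_tree(cfg)
  expect_equal(length(phy$tip.label), 32)
  expect_equal(nrow(phy$edge), 2 * 32 - 2)
  expect_equal(mean(phy$edge.length), 0.5)
  expect_true(all(phy$edge.length > 0))
  y <- simulate_tree(sim_tree_config(16, shape = "yule",
                                     mean_branch_length = 0.25, seed = 2))
  expect_equal(length(y$tip.label), 16)
  expect_equal(mean(y$edge.length), 0.25)
})

test_that("normal-mode branch draws match the truncated-normal expectation", {
  # draws are N(mu, mu/2) resampled at <= 0, i.e. truncated normal; its mean
  # is mu + sd * dnorm(a)/ (1 - pnorm(a)) with a = -mu/sd (closed form)
  mu <- 0.5; sd <- sqrt(mu / 2)
  a <- -mu / sd
  trunc_mean <- mu + sd * dnorm(a) / (1 - pnorm(a))
  trunc_var <- sd^2 * (1 + a * dnorm(a) / (1 - pnorm(a)) -
                         (dnorm(a) / (1 - pnorm(a)))^2)
  pre <- vapply(1:200, function(s)
    attr(simulate_tree(sim_tree_config(16, mean_branch_length = mu, seed = s)),
         "pre_rescale_mean"), numeric(1))
  nb <- 2 * 16 - 2
  se <- sqrt(trunc_var / (nb * 200))
  expect_lt(abs(mean(pre) - trunc_mean), 3 * se)
})

test_that("exponential-mode branch lengths have unit coefficient of variation", {
  bl <- unlist(lapply(1:50, function(s)
    simulate_tree(sim_tree_config(16, shape = "yule",
                                  mean_branch_length = 0.5,
                                  seed = 1000 + s))$edge.length))
  cv2 <- var(bl) / mean(bl)^2
  expect_lt(abs(cv2 - 1), 0.15)
})

test_that("zero-length branches transmit the root unchanged", {
  tree <- balanced_clade_tree(4, branch_length = 0)
  seqs <- evolve_sequences(tree, seq_evol_config(root_length = 80, seed = 3))
  expect_equal(length(unique(unname(seqs))), 1)
  pd <- p_distance_matrix(seqs)
  expect_true(all(pd == 0))
})

test_that("tiny-branch p-distance matches the CTMC linearization", {
  # two taxa at branch t each: expected p-distance ~= 2 t (1 - p_inv)
  t_br <- 0.001
  p_inv <- 0.01
  tree <- ape::read.tree(text = sprintf("(t1:%g,t2:%g);", t_br, t_br))
  nrep <- 30; L <- 10000
  hits <- 0; sites <- 0
  for (s in seq_len(nrep)) {
    seqs <- evolve_sequences(tree, seq_evol_config(
      root_length = L, indel_rate_ratio = 0, invariant_fraction = p_inv,
      seed = 2000 + s))
    hits <- hits + as.numeric(p_distance_matrix(seqs)[1, 2]) * L
    sites <- sites + L
  }
  p_exp <- 2 * t_br * (1 - p_inv)
  se <- sqrt(p_exp * (1 - p_exp) / sites)
  expect_lt(abs(hits / sites - p_exp), 3 * se)
})

test_that("the invariant-site fraction calibrates to its configured 1%", {
  tree <- ape::read.tree(text = "(t1:0.01,t2:0.01);")
  n_inv <- vapply(1:200, function(s) {
    seqs <- evolve_sequences(tree, seq_evol_config(root_length = 500,
                                                   seed = 3000 + s))
    attr(seqs, "events")$n_invariant_root
  }, numeric(1))
  n_sites <- 200 * 500
  p_hat <- sum(n_inv) / n_sites
  se <- sqrt(0.01 * 0.99 / n_sites)
  expect_lt(abs(p_hat - 0.01), 3 * se)
})

test_that("the substitution process preserves the WAG equilibrium", {
  # root drawn from equilibrium => leaf states remain equilibrium-distributed
  tree <- ape::read.tree(text = "(t1:1.0,t2:1.0);")
  seqs <- evolve_sequences(tree, seq_evol_config(
    root_length = 30000, indel_rate_ratio = 0, invariant_fraction = 0,
    seed = 11))
  freqs <- table(factor(strsplit(seqs[["t1"]], "")[[1]],
                        levels = ncutphylo:::.wag_order)) / 30000
  pi0 <- ncutphylo:::.wag_freq
  se <- sqrt(pi0 * (1 - pi0) / 30000)
  expect_true(all(abs(as.numeric(freqs) - pi0) < 3.5 * se))
})

test_that("embedded WAG constants match phangorn's copy of the model", {
  w <- get(".WAG", asNamespace("phangorn"))
  expect_equal(ncutphylo:::.wag_exch, w$Q)
  expect_equal(ncutphylo:::.wag_freq, unname(w$bf))
  expect_identical(ncutphylo:::.wag_order, toupper(names(w$bf)))
})

test_that("indel events arrive at the configured fraction of substitutions", {
  tree <- balanced_clade_tree(8, branch_length = 0.5)
  n_ind <- 0; expected_sub <- 0
  for (s in 1:40) {
    seqs <- evolve_sequences(tree, seq_evol_config(seed = 4000 + s))
    ev <- attr(seqs, "events")
    n_ind <- n_ind + ev$n_insertions + ev$n_deletions
    expected_sub <- expected_sub + ev$expected_substitutions
  }
  lambda <- 0.02 * expected_sub
  se <- sqrt(lambda)  # Poisson
  expect_lt(abs(n_ind - lambda), 3 * se)
})

test_that("the indel-length sampler recovers its power-law exponent", {
  set.seed(9)
  x <- rindel_length(50000, a = 1.7, max_len = 50)
  fit <- fit_indel_power(x, max_len = 50)
  expect_lt(abs(fit$a_hat - 1.7), 3 * fit$se)
  expect_lt(fit$se, 0.05)
})

test_that("p-distance handles the textbook cases", {
  expect_equal(p_distance("AAAA", "AAAA"), 0)
  expect_equal(p_distance("AAAA", "AAAT"), 0.25)
  expect_equal(p_distance("AAAA", "TTTT"), 1)
  expect_equal(p_distance("AA-A", "AATA"), 0)  # gapped column excluded
  expect_error(p_distance("--", "AA"), "comparable")
  # true-homology comparison after an indel
  expect_equal(p_distance("ACD", "AD", hom_a = c(1, 2, 3), hom_b = c(1, 3)),
               0)
  expect_equal(p_distance("ACD", "AW", hom_a = c(1, 2, 3), hom_b = c(1, 3)),
               0.5)
})

test_that("unequal-length sequences fall back to alignment, flagged", {
  d <- p_distance("MKVLITAAAG", "MKVLITAAG")
  expect_true(isTRUE(attr(d, "aligned")))
  expect_lt(as.numeric(d), 0.2)
})

test_that("mean p-distance rises with mean branch length", {
  levels <- c(0.125, 0.375, 0.750)
  means <- vapply(seq_along(levels), function(i) {
    pd <- vapply(1:12, function(s) {
      tr <- simulate_tree(sim_tree_config(4, mean_branch_length = levels[i],
                                          seed = 5000 + 100 * i + s))
      seqs <- evolve_sequences(tr, seq_evol_config(root_length = 150,
                                                   seed = 6000 + 100 * i + s))
      mean(p_distance_matrix(seqs)[upper.tri(diag(4))])
    }, numeric(1))
    mean(pd)
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("simulation replicates write a complete file set", {
  dir <- tempfile()
  tcfg <- sim_tree_config(5, mean_branch_length = 0.2, seed = 7)
  tree <- simulate_tree(tcfg)
  scfg <- seq_evol_config(root_length = 100, seed = 8)
  seqs <- evolve_sequences(tree, scfg)
  write_simulation(dir, tree, seqs, tcfg, scfg)
  expect_true(all(file.exists(file.path(dir,
    c("true_tree.nwk", "sequences.fasta", "p_distance.tsv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(man$tree_config$seed, 7)
  expect_equal(man$events$root_length, 100)
  back <- ape::read.tree(file.path(dir, "true_tree.nwk"))
  expect_equal(rf_distance(back, tree), 0)
})

test_that("balanced clade trees are binary with constant branch lengths", {
  phy <- balanced_clade_tree(16, branch_length = 0.125)
  expect_equal(length(phy$tip.label), 16)
  expect_true(all(phy$edge.length == 0.125))
  expect_error(balanced_clade_tree(6), "power of 2")
})
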