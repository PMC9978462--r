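#' Configuration for simulated phylogenetic trees
#'
#' Tree topologies come either from a uniform random shape (`ape::rtree`)
#' or from a Yule pure-birth process (birth rate 1). Branch lengths are
#' redrawn from the configured distribution and rescaled multiplicatively so
#' the realized mean equals `mean_branch_length` exactly:
#' `"normal"` draws have variance equal to half the mean (negatives
#' resampled); `"exponential"` draws use rate 2 before rescaling.
#'
#' @param n_taxa number of leaves, >= 3.
#' @param shape `"uniform_random"` or `"yule"`.
#' @param mean_branch_length target mean branch length, substitutions/site.
#' @param branch_distribution `"normal"` or `"exponential"`; defaults to
#'   normal for random-shape trees and exponential for Yule trees.
#' @param seed integer seed or `NULL`.
#' @return an object of class `sim_tree_config`.
#' @export
sim_tree_config <- function(n_taxa, shape = c("uniform_random", "yule"),
                            mean_branch_length = 0.5,
                            branch_distribution = NULL, seed = NULL) {
  shape <- match.arg(shape)
  if (is.null(branch_distribution))
    branch_distribution <- if (shape == "yule") "exponential" else "normal"
  branch_distribution <- match.arg(branch_distribution,
                                   c("normal", "exponential"))
  stopifnot(n_taxa >= 3, mean_branch_length > 0)
  structure(list(n_taxa = as.integer(n_taxa), shape = shape,
                 mean_branch_length = mean_branch_length,
                 branch_distribution = branch_distribution, seed = seed),
            class = "sim_tree_config")
}

#' Simulate a phylogenetic tree
#'
#' Generates a binary tree with `n_taxa` leaves labeled `t1..tn` and branch
#' lengths drawn per the configured distribution, then rescaled so their
#' realized mean equals the target exactly. The pre-rescaling sample mean is
#' kept in attribute `pre_rescale_mean` for calibration checks.
#'
#' @param cfg a [sim_tree_config()].
#' @return an [ape::phylo] tree.
#' @export
simulate_tree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_tree_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  phy <- switch(cfg$shape,
    uniform_random = ape::rtree(cfg$n_taxa, rooted = TRUE),
    yule = ape::rphylo(cfg$n_taxa, birth = 1, death = 0))
  phy$tip.label <- paste0("t", seq_len(cfg$n_taxa))
  nb <- nrow(phy$edge)
  mu <- cfg$mean_branch_length
  bl <- switch(cfg$branch_distribution,
    normal = {
      x <- rnorm(nb, mean = mu, sd = sqrt(mu / 2))
      while (any(x <= 0)) x[x <= 0] <- rnorm(sum(x <= 0), mu, sqrt(mu / 2))
      x
    },
    exponential = rexp(nb, rate = 2))
  phy$edge.length <- bl * (mu / mean(bl))
  attr(phy, "pre_rescale_mean") <- mean(bl)
  phy
}

#' Fully balanced clade tree with constant branch lengths
#'
#' A perfectly balanced rooted binary tree over `n` leaves (`n` a power of
#' two), every branch of length `branch_length`. This is the low-divergence
#' benchmark topology for end-to-end recovery: with equal, short branches
#' every clade is tight and well separated, so the correct bipartition is
#' unambiguous at each level of the recursion.
#'
#' @param n number of leaves (power of 2, >= 4).
#' @param branch_length constant branch length, substitutions/site.
#' @return an [ape::phylo] tree with tips `t1..tn`.
#' @export
balanced_clade_tree <- function(n, branch_length = 0.125) {
  if (n < 4 || bitwAnd(n, n - 1L) != 0)
    stop("n must be a power of 2, >= 4")
  rec <- function(labs) {
    if (length(labs) == 1) return(labs)
    h <- length(labs) / 2
    sprintf("(%s:%g,%s:%g)", rec(labs[seq_len(h)]), branch_length,
            rec(labs[-seq_len(h)]), branch_length)
  }
  ape::read.tree(text = paste0(rec(paste0("t", seq_len(n))), ";"))
}

#' Configuration for protein sequence evolution
#'
#' Continuous-time Markov substitution under the WAG replacement model with
#' discrete-gamma rate heterogeneity (`gamma_categories` equal-probability
#' categories represented by their means) plus a proportion of invariant
#' sites; rates are normalized so the expected number of substitutions per
#' site per unit branch length is 1. Insertion/deletion events occur at
#' `indel_rate_ratio` times the substitution rate, with lengths from a
#' discrete power law `P(l) ~ l^-a` truncated at `max_indel_length`.
#'
#' @param root_length root sequence length in residues (default 500).
#' @param substitution_model `"WAG"` or `"poisson"` (equal rates and
#'   frequencies; a fast surrogate for tests).
#' @param gamma_categories number of discrete gamma categories (default 5).
#' @param gamma_shape gamma shape parameter (default 1).
#' @param invariant_fraction proportion of invariant sites (default 0.01).
#' @param indel_power_a power-law exponent for indel lengths (default 1.7).
#' @param indel_rate_ratio indel events per substitution event (default
#'   0.02; 0 disables indels).
#' @param max_indel_length truncation of the indel length law (default 50).
#' @param seed integer seed or `NULL`.
#' @return an object of class `seq_evol_config`.
#' @export
seq_evol_config <- function(root_length = 500L,
                            substitution_model = c("WAG", "poisson"),
                            gamma_categories = 5L, gamma_shape = 1,
                            invariant_fraction = 0.01,
                            indel_power_a = 1.7, indel_rate_ratio = 0.02,
                            max_indel_length = 50L, seed = NULL) {
  substitution_model <- match.arg(substitution_model)
  stopifnot(root_length >= 1, gamma_categories >= 1, gamma_shape > 0,
            invariant_fraction >= 0, invariant_fraction < 1,
            indel_power_a > 1, indel_rate_ratio >= 0, max_indel_length >= 1)
  structure(list(root_length = as.integer(root_length),
                 substitution_model = substitution_model,
                 gamma_categories = as.integer(gamma_categories),
                 gamma_shape = gamma_shape,
                 invariant_fraction = invariant_fraction,
                 indel_power_a = indel_power_a,
                 indel_rate_ratio = indel_rate_ratio,
                 max_indel_length = as.integer(max_indel_length),
                 seed = seed),
            class = "seq_evol_config")
}

# Rate matrix machinery: Q with q_ij = s_ij * pi_j, diagonal -rowsum,
# normalized to one expected substitution per site per unit time at
# equilibrium; cumJ holds cumulative jump probabilities per row.
.aa_model <- function(name = "WAG") {
  n <- 20L
  if (name == "WAG") {
    S <- matrix(0, n, n, dimnames = list(.wag_order, .wag_order))
    S[lower.tri(S)] <- .wag_exch
    S <- S + t(S)
    freq <- .wag_freq
  } else {
    S <- matrix(1, n, n, dimnames = list(.aa_canonical, .aa_canonical))
    diag(S) <- 0
    freq <- rep(1 / n, n)
  }
  Q <- sweep(S, 2, freq, "*")
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(freq * diag(Q)))
  J <- -Q / diag(Q)
  diag(J) <- 0
  list(Q = Q, freq = freq, cumJ = t(apply(J, 1, cumsum)),
       alphabet = rownames(S))
}

# Event-wise (Gillespie) substitution simulation of one branch for all
# sites at once. `rates` are per-site rate multipliers (0 = invariant).
.evolve_branch_states <- function(states, rates, b, model) {
  tsite <- numeric(length(states))
  active <- which(rates > 0)
  nev <- 0L
  qdiag <- -diag(model$Q)
  while (length(active)) {
    lam <- qdiag[states[active]] * rates[active]
    tsite[active] <- tsite[active] + rexp(length(active), lam)
    active <- active[tsite[active] <= b]
    if (!length(active)) break
    u <- runif(length(active))
    rows <- model$cumJ[states[active], , drop = FALSE]
    states[active] <- rowSums(rows < u) + 1L
    nev <- nev + length(active)
  }
  list(states = states, n_events = nev)
}

# draw a site rate vector for `n` new sites (invariant with prob p, else a
# gamma category mean scaled so the overall expectation is 1)
.draw_site_rates <- function(n, cat_rates, p_inv) {
  inv <- runif(n) < p_inv
  r <- cat_rates[sample.int(length(cat_rates), n, replace = TRUE)]
  r[inv] <- 0
  list(rates = r, invariant = inv)
}

#' Sample indel lengths from the truncated discrete power law
#'
#' `P(l) proportional to l^-a` for `l = 1..max_len`.
#'
#' @param n number of draws.
#' @param a exponent, > 1.
#' @param max_len truncation bound.
#' @return integer vector of lengths.
#' @export
rindel_length <- function(n, a = 1.7, max_len = 50L) {
  stopifnot(a > 1, max_len >= 1)
  p <- (1:max_len)^(-a)
  sample.int(max_len, n, replace = TRUE, prob = p)
}

#' Maximum-likelihood exponent of the truncated discrete power law
#'
#' Fits `P(l) ~ l^-a` on `1..max_len` by direct likelihood maximization;
#' the standard error comes from the observed Fisher information.
#'
#' @param lengths integer sample of indel lengths.
#' @param max_len truncation bound used when sampling.
#' @return list with `a_hat` and `se`.
#' @export
fit_indel_power <- function(lengths, max_len = 50L) {
  stopifnot(length(lengths) > 1, all(lengths >= 1), all(lengths <= max_len))
  sl <- sum(log(lengths))
  n <- length(lengths)
  nll <- function(a) a * sl + n * log(sum((1:max_len)^(-a)))
  opt <- optimize(nll, c(1.0001, 10))
  a_hat <- opt$minimum
  h <- 1e-4
  fisher <- (nll(a_hat + h) - 2 * nll(a_hat) + nll(a_hat - h)) / h^2
  list(a_hat = a_hat, se = 1 / sqrt(max(fisher, .Machine$double.eps)))
}

#' Evolve protein sequences along a tree
#'
#' Simulates one amino-acid sequence per leaf. The root is drawn from the
#' model's equilibrium frequencies; each site carries a rate multiplier
#' (invariant with probability `invariant_fraction`, otherwise a discrete
#' gamma category mean). Substitutions are simulated event-wise along every
#' branch; indel events arrive as a Poisson count with mean
#' `indel_rate_ratio` times the branch's expected substitution count
#' (`branch_length * sum(site rates)`), each inserting
#' (from equilibrium, at a uniform position) or deleting (uniform start) a
#' power-law-distributed number of residues. Every residue carries a global
#' homology column id, so true site homology survives indels.
#'
#' @param tree an [ape::phylo] tree with branch lengths.
#' @param cfg a [seq_evol_config()].
#' @return named character vector of leaf sequences with attributes
#'   `homology` (per-leaf integer column ids) and `events` (realized event
#'   counts: substitutions, insertions, deletions, indel lengths, invariant
#'   sites at the root, and the total expected substitution count summed
#'   over branches).
#' @export
evolve_sequences <- function(tree, cfg = seq_evol_config()) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  model <- .aa_model(cfg$substitution_model)
  # equal-probability discrete gamma, category means, mean rate 1 among
  # variable sites; invariant sites have rate 0
  cat_rates <- phangorn::discrete.gamma(cfg$gamma_shape, cfg$gamma_categories)

  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  L0 <- cfg$root_length
  site <- .draw_site_rates(L0, cat_rates, cfg$invariant_fraction)
  tally <- new.env(parent = emptyenv())
  tally$n_sub <- 0L; tally$n_ins <- 0L; tally$n_del <- 0L
  tally$exposure <- 0; tally$indel_lengths <- integer(0)
  tally$next_col <- L0 + 1L

  node_seq <- vector("list", max(tree$edge))
  node_seq[[root]] <- list(
    states = sample.int(20L, L0, replace = TRUE, prob = model$freq),
    rates = site$rates, cols = seq_len(L0))

  # preorder: parents appear before children in ape's cladewise edge matrix
  eo <- ape::reorder.phylo(tree, "cladewise")
  for (k in seq_len(nrow(eo$edge))) {
    par <- eo$edge[k, 1]; child <- eo$edge[k, 2]
    b <- eo$edge.length[k]
    s <- node_seq[[par]]
    # expected substitution events on this branch, given the realized site
    # rates; indel events arrive at indel_rate_ratio times this rate
    exp_sub <- b * sum(s$rates)
    tally$exposure <- tally$exposure + exp_sub
    ev <- .evolve_branch_states(s$states, s$rates, b, model)
    tally$n_sub <- tally$n_sub + ev$n_events
    s$states <- ev$states
    if (cfg$indel_rate_ratio > 0) {
      n_events <- rpois(1, cfg$indel_rate_ratio * exp_sub)
      for (e in seq_len(n_events)) {
        len <- rindel_length(1, cfg$indel_power_a, cfg$max_indel_length)
        Lc <- length(s$states)
        if (runif(1) < 0.5) {  # insertion
          pos <- sample.int(Lc + 1L, 1) - 1L
          new_site <- .draw_site_rates(len, cat_rates, cfg$invariant_fraction)
          ins <- list(states = sample.int(20L, len, TRUE, prob = model$freq),
                      rates = new_site$rates,
                      cols = seq.int(tally$next_col, length.out = len))
          tally$next_col <- tally$next_col + len
          pre <- seq_len(pos)
          post <- if (pos < Lc) (pos + 1L):Lc else integer(0)
          s <- list(states = c(s$states[pre], ins$states, s$states[post]),
                    rates = c(s$rates[pre], ins$rates, s$rates[post]),
                    cols = c(s$cols[pre], ins$cols, s$cols[post]))
          tally$n_ins <- tally$n_ins + 1L
        } else {               # deletion
          if (Lc <= 1) next    # never delete the whole sequence
          start <- sample.int(Lc, 1)
          drop <- start:min(Lc, start + len - 1L)
          if (length(drop) >= Lc) drop <- drop[-length(drop)]
          s <- list(states = s$states[-drop], rates = s$rates[-drop],
                    cols = s$cols[-drop])
          tally$n_del <- tally$n_del + 1L
        }
        tally$indel_lengths <- c(tally$indel_lengths, len)
      }
    }
    node_seq[[child]] <- s
  }

  seqs <- vapply(seq_len(n_tip), function(i)
    paste(model$alphabet[node_seq[[i]]$states], collapse = ""), character(1))
  names(seqs) <- tree$tip.label
  hom <- lapply(seq_len(n_tip), function(i) node_seq[[i]]$cols)
  names(hom) <- tree$tip.label
  attr(seqs, "homology") <- hom
  attr(seqs, "events") <- list(
    n_substitutions = tally$n_sub, n_insertions = tally$n_ins,
    n_deletions = tally$n_del, indel_lengths = tally$indel_lengths,
    n_invariant_root = sum(site$invariant), root_length = L0,
    expected_substitutions = tally$exposure)
  seqs
}

#' Proportion of differing homologous sites (p-distance)
#'
#' With homology maps (as produced by [evolve_sequences()]), the comparison
#' runs over columns present in both sequences; columns lost to deletion on
#' either side are excluded. Without maps, equal-length sequences are
#' compared positionally (columns containing `-` excluded); unequal-length
#' sequences are first globally aligned and gapped columns excluded, and the
#' result is flagged with attribute `aligned = TRUE`.
#'
#' @param a,b amino-acid sequence strings.
#' @param hom_a,hom_b optional integer homology column ids per residue.
#' @return proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b, hom_a = NULL, hom_b = NULL) {
  if (!is.null(hom_a) && !is.null(hom_b)) {
    ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
    stopifnot(length(ra) == length(hom_a), length(rb) == length(hom_b))
    shared <- intersect(hom_a, hom_b)
    if (length(shared) == 0) stop("no comparable homologous sites")
    xa <- ra[match(shared, hom_a)]
    xb <- rb[match(shared, hom_b)]
    return(mean(xa != xb))
  }
  if (nchar(a) != nchar(b)) {
    e <- new.env()
    utils::data(list = "BLOSUM62", package = "Biostrings", envir = e)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = get("BLOSUM62", envir = e),
      gapOpening = 11, gapExtension = 1)
    a <- as.character(Biostrings::alignedPattern(al))
    b <- as.character(Biostrings::alignedSubject(al))
    aligned <- TRUE
  } else aligned <- FALSE
  ra <- strsplit(a, "")[[1]]; rb <- strsplit(b, "")[[1]]
  keep <- ra != "-" & rb != "-"
  if (!any(keep)) stop("no comparable sites")
  out <- mean(ra[keep] != rb[keep])
  if (aligned) attr(out, "aligned") <- TRUE
  out
}

#' Mean pairwise p-distance of a sequence set
#'
#' Uses true homology maps when the set carries them (see
#' [evolve_sequences()]).
#'
#' @param seqs named character vector, optionally with a `homology`
#'   attribute.
#' @return symmetric matrix of pairwise p-distances.
#' @export
p_distance_matrix <- function(seqs) {
  hom <- attr(seqs, "homology")
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    m[i, j] <- m[j, i] <- as.numeric(p_distance(
      seqs[[i]], seqs[[j]], hom[[i]], hom[[j]]))
  }
  m
}

#' Write a simulation replicate to disk
#'
#' Emits the true tree (newick), leaf sequences (FASTA), true p-distance
#' matrix (TSV), and a run manifest (JSON: seeds, configs, realized event
#' counts).
#'
#' @param dir output directory (created if needed).
#' @param tree the simulated [ape::phylo] tree.
#' @param seqs sequences from [evolve_sequences()].
#' @param tree_cfg,seq_cfg the configurations used.
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(dir, tree, seqs, tree_cfg = NULL, seq_cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ape::write.tree(tree, file.path(dir, "true_tree.nwk"))
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs),
                              file.path(dir, "sequences.fasta"))
  pd <- p_distance_matrix(seqs)
  utils::write.table(data.frame(id = rownames(pd), pd, check.names = FALSE),
                     file.path(dir, "p_distance.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  manifest <- list(tree_config = tree_cfg[!vapply(tree_cfg, is.null, TRUE)],
                   seq_config = seq_cfg[!vapply(seq_cfg, is.null, TRUE)],
                   events = attr(seqs, "events")[c("n_substitutions",
                     "n_insertions", "n_deletions", "n_invariant_root",
                     "root_length", "expected_substitutions")])
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
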