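#' Reconstruct a tree by recursive normalized min-cut
#'
#' Recursively bipartitions the similarity graph: the full node set is split
#' by [sweep_and_select()], then each side is split again on its induced
#' submatrix, until every cluster has at most two members. Each accepted
#' bipartition becomes an internal node of a rooted binary cladogram (a
#' 3-member cluster is necessarily cut 1|2). Reconstructed trees carry no
#' branch lengths — the method recovers topology only; unit branch lengths
#' can be attached on request.
#'
#' @param matrix a [similarity_matrix()].
#' @param cfg a [solver_config()]; with the annealing backend the result is
#'   deterministic for a fixed `cfg$seed`.
#' @param unit_branch_lengths logical; attach branch length 1 to every edge.
#' @return an [ape::phylo] rooted binary tree whose tip labels are the
#'   matrix ids.
#' @export
reconstruct_tree <- function(matrix, cfg = solver_config(),
                             unit_branch_lengths = FALSE) {
  d <- as.matrix(matrix)
  n <- nrow(d)
  if (n < 2) stop("need at least 2 sequences")
  ids <- rownames(d)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  counter <- new.env(parent = emptyenv())
  counter$k <- 0L
  recurse <- function(idx) {
    if (length(idx) == 1) return(.newick_label(ids[idx]))
    if (length(idx) == 2)
      return(sprintf("(%s,%s)", .newick_label(ids[idx[1]]),
                     .newick_label(ids[idx[2]])))
    counter$k <- counter$k + 1L
    res <- tryCatch(
      sweep_and_select(d[idx, idx, drop = FALSE], cfg,
                       call_index = 10000L * counter$k),
      error = function(e) stop("bipartition failed for cluster {",
                               paste(ids[idx], collapse = ", "), "}: ",
                               conditionMessage(e)))
    a <- idx[res$labels == 1]
    b <- idx[res$labels == 0]
    sprintf("(%s,%s)", recurse(a), recurse(b))
  }
  nwk <- paste0(recurse(seq_len(n)), ";")
  phy <- ape::read.tree(text = nwk)
  if (unit_branch_lengths) phy$edge.length <- rep(1, nrow(phy$edge))
  phy
}

.newick_label <- function(x) {
  if (grepl("[ \t(),:;'\\[\\]]", x)) paste0("'", gsub("'", "''", x), "'") else x
}

#' Robinson–Foulds distance between two trees
#'
#' Symmetric-difference count of nontrivial bipartitions, compared unrooted
#' (so the arbitrary root placed by [reconstruct_tree()] does not count as a
#' topological difference). Both trees must share the same leaf set; zero
#' means identical topologies.
#'
#' @param t1,t2 [ape::phylo] trees with identical tip label sets.
#' @return non-negative integer.
#' @export
rf_distance <- function(t1, t2) {
  stopifnot(inherits(t1, "phylo"), inherits(t2, "phylo"))
  if (!setequal(t1$tip.label, t2$tip.label) ||
      length(t1$tip.label) != length(t2$tip.label))
    stop("trees must share an identical leaf set")
  u1 <- ape::unroot(t1)
  u2 <- ape::unroot(t2)
  as.integer(phangorn::RF.dist(u1, u2, check.labels = TRUE))
}
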