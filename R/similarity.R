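#' Alignment and bit-score parameters
#'
#' Parameters controlling pairwise local alignment and the Karlin–Altschul
#' conversion of raw alignment scores to bit scores. Defaults are the
#' standard gapped-BLOSUM62 settings: gap open 11, gap extend 1, and the
#' gapped constants lambda = 0.267, K = 0.041. The e-value cutoff (default
#' 10) is the permissive significance threshold below which a pair is kept;
#' pairs whose best local alignment exceeds it get similarity 0.
#'
#' @param substitution_matrix name of a scoring matrix shipped with
#'   Biostrings (default `"BLOSUM62"`), or a numeric residue-pair matrix.
#' @param gap_open positive integer gap opening penalty.
#' @param gap_extend positive integer gap extension penalty.
#' @param lambda Karlin–Altschul scale (bits conversion), > 0.
#' @param k_const Karlin–Altschul constant K, > 0.
#' @param evalue_cutoff e-value above which a pair is treated as unrelated.
#' @return an object of class `alignment_params`.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_open = 11L, gap_extend = 1L,
                             lambda = 0.267, k_const = 0.041,
                             evalue_cutoff = 10) {
  if (is.character(substitution_matrix)) {
    e <- new.env()
    utils::data(list = substitution_matrix, package = "Biostrings", envir = e)
    substitution_matrix <- get(substitution_matrix, envir = e)
  }
  stopifnot(is.matrix(substitution_matrix),
            gap_open > 0, gap_extend > 0,
            lambda > 0, k_const > 0, evalue_cutoff > 0)
  # unknown residues score 0 against everything
  if ("X" %in% rownames(substitution_matrix)) {
    substitution_matrix["X", ] <- 0
    substitution_matrix[, "X"] <- 0
  }
  structure(list(substitution_matrix = substitution_matrix,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 lambda = lambda, k_const = k_const,
                 evalue_cutoff = evalue_cutoff),
            class = "alignment_params")
}

.aa_canonical <- c("A","R","N","D","C","Q","E","G","H","I",
                   "L","K","M","F","P","S","T","W","Y","V")

#' Read protein sequences from a FASTA file
#'
#' Loads a multi-record protein FASTA, strips gap characters, upper-cases
#' residues, and maps any non-canonical residue to `X` with a warning.
#'
#' @param path path to a FASTA file.
#' @return named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  seqs <- toupper(gsub("[-.]", "", as.character(ss)))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  validate_sequences(seqs)
}

#' @keywords internal
validate_sequences <- function(seqs) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must carry non-empty ids")
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence ids: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence(s): ",
                               paste(names(seqs)[!nzchar(seqs)], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(.aa_canonical, collapse = "")), seqs)
  if (any(bad)) {
    warning("non-canonical residues mapped to X in: ",
            paste(names(seqs)[bad], collapse = ", "))
    seqs[bad] <- gsub(sprintf("[^%s]", paste(.aa_canonical, collapse = "")),
                      "X", seqs[bad])
  }
  seqs
}

#' Pairwise local-alignment bit score
#'
#' Computes the optimal Smith–Waterman local affine-gap alignment score
#' between two protein sequences and converts it to a bit score via the
#' Karlin–Altschul relation `bit = (lambda * S - ln K) / ln 2`, with e-value
#' `K * m * n * exp(-lambda * S)`. A best local raw score of 0 (no
#' positive-scoring local alignment exists) is reported as no hit:
#' bit score 0 and e-value `Inf`.
#'
#' @param a,b amino-acid sequence strings (non-empty).
#' @param params an [alignment_params()] object.
#' @return list with elements `bit_score`, `evalue`, and `raw_score`.
#' @export
pairwise_bitscore <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  s <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE)
  if (s <= 0) {
    return(list(bit_score = 0, evalue = Inf, raw_score = 0))
  }
  bit <- (params$lambda * s - log(params$k_const)) / log(2)
  ev <- params$k_const * nchar(a) * nchar(b) * exp(-params$lambda * s)
  list(bit_score = bit, evalue = ev, raw_score = s)
}

#' Normalized bit score
#'
#' Normalizes a pairwise bit score by the mean of the two self-alignment
#' bit scores and scales to an integer similarity in 0..100:
#' `round(bit_ij / mean(bit_ii, bit_jj) * 100)`. Identical sequences score
#' 100; pairs whose e-value exceeds the cutoff score 0. Values are rounded
#' half-away-from-zero (the downstream solver takes integers only) and
#' clipped to `[0, 100]`.
#'
#' @param bit_ij pairwise bit score.
#' @param bit_ii,bit_jj self-alignment bit scores (must be > 0).
#' @param evalue e-value of the pairwise alignment.
#' @param cutoff e-value cutoff (default 10).
#' @return integer in 0..100.
#' @export
normbit <- function(bit_ij, bit_ii, bit_jj, evalue, cutoff = 10) {
  if (bit_ii <= 0 || bit_jj <= 0)
    stop("non-positive self bit score: degenerate sequence")
  if (evalue > cutoff) return(0L)
  v <- bit_ij / mean(c(bit_ii, bit_jj)) * 100
  v <- sign(v) * floor(abs(v) + 0.5)  # round half away from zero
  as.integer(min(100, max(0, v)))
}

#' Construct (and validate) a similarity matrix
#'
#' A similarity matrix is a symmetric integer matrix with entries in 0..100,
#' diagonal 100, and row/column names giving the sequence ids in order. It
#' is the weighted adjacency matrix of the similarity graph that all
#' downstream cut operations consume.
#'
#' @param values square numeric matrix of integer values in 0..100.
#' @param ids character vector of unique ids (defaults to existing dimnames).
#' @return an integer matrix of class `similarity_matrix`.
#' @export
similarity_matrix <- function(values, ids = rownames(values)) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (is.null(ids)) ids <- paste0("s", seq_len(n))
  if (n != ncol(values)) stop("similarity matrix must be square")
  if (length(ids) != n || anyDuplicated(ids)) stop("ids must be unique, one per row")
  if (any(values != round(values))) stop("similarity values must be integers")
  if (any(values < 0 | values > 100)) stop("similarity values must lie in [0, 100]")
  if (!isTRUE(all.equal(unname(values), unname(t(values)))))
    stop("similarity matrix must be symmetric")
  if (any(diag(values) != 100)) stop("diagonal must be 100 (self-similarity)")
  m <- matrix(as.integer(values), n, n, dimnames = list(ids, ids))
  class(m) <- c("similarity_matrix", class(m))
  m
}

#' Build the normalized bit-score similarity matrix
#'
#' All-to-all pairwise local alignment of a protein sequence set, bit-score
#' conversion, and normalization to integer similarities in 0..100 (see
#' [normbit()]). The result is the input graph for the cut-based tree
#' reconstruction.
#'
#' @param seqs named character vector of >= 2 protein sequences with unique
#'   ids.
#' @param params an [alignment_params()] object.
#' @return a [similarity_matrix()] in input id order.
#' @export
build_similarity_matrix <- function(seqs, params = alignment_params()) {
  seqs <- validate_sequences(seqs)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  self_bits <- vapply(seqs, function(s)
    pairwise_bitscore(s, s, params)$bit_score, numeric(1))
  if (any(self_bits <= 0))
    stop("non-positive self bit score for: ",
         paste(names(seqs)[self_bits <= 0], collapse = ", "))
  m <- diag(100L, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      hit <- pairwise_bitscore(seqs[[i]], seqs[[j]], params)
      v <- normbit(hit$bit_score, self_bits[i], self_bits[j],
                   hit$evalue, params$evalue_cutoff)
      m[i, j] <- m[j, i] <- v
    }
  }
  similarity_matrix(m, names(seqs))
}

#' Write / read a similarity matrix as TSV
#'
#' TSV layout: header row of ids, first column of ids, integer entries.
#' `read_similarity_tsv()` validates all similarity-matrix invariants on
#' load, so the file can be used to feed the solver directly.
#'
#' @param m a [similarity_matrix()].
#' @param path file path.
#' @return `write_similarity_tsv()` returns `path` invisibly;
#'   `read_similarity_tsv()` returns a [similarity_matrix()].
#' @export
write_similarity_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  similarity_matrix(m, ids)
}
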