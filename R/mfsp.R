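#' Build the binary miRNA-disease association matrix
#'
#' Rows are miRNAs (union of miRNAs observed in \code{pairs}), columns are
#' the diseases of the ontology. Duplicate pairs collapse to a single 1.
#' Associations naming diseases absent from the DAG are dropped with a
#' message listing them; the affected miRNAs are retained (possibly with
#' an all-zero row).
#'
#' @param pairs data.frame with columns \code{mirna}, \code{disease}, one
#'   association per row.
#' @param dag a \code{disease_dag} providing the disease universe.
#' @return binary integer matrix |M| x |D| with dimnames
#'   (miRNAs, diseases); diseases ordered as in
#'   [disease_similarity_matrix()].
#' @export
association_matrix <- function(pairs, dag) {
  stopifnot(inherits(dag, "disease_dag"))
  if (is.list(pairs) && !is.data.frame(pairs)) {
    pairs <- data.frame(
      mirna = vapply(pairs, function(p) as.character(p[[1]]), character(1)),
      disease = vapply(pairs, function(p) as.character(p[[2]]), character(1)),
      stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(pairs), all(c("mirna", "disease") %in% names(pairs)))
  if (nrow(pairs) == 0L) stop("empty association list")
  diseases <- sort(names(dag$diseases))
  known <- pairs$disease %in% diseases
  if (any(!known)) {
    orphans <- sort(unique(pairs$disease[!known]))
    message(sprintf(
      "dropping %d association(s) to %d disease(s) absent from the ontology: %s",
      sum(!known), length(orphans),
      paste(utils::head(orphans, 5), collapse = ", ")))
    pairs <- pairs[known, , drop = FALSE]
  }
  mirnas <- sort(unique(as.character(pairs$mirna)))
  if (length(mirnas) == 0L) {
    stop("no associations left after dropping ontology-orphaned diseases")
  }
  R <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  R[cbind(match(pairs$mirna, mirnas), match(pairs$disease, diseases))] <- 1L
  R
}

#' Read an association TSV (HMDD dialect)
#'
#' Two tab-separated columns \code{mirna_name<TAB>disease_name}, one pair
#' per row, \code{#} comments allowed; extra columns are ignored with a
#' warning.
#'
#' @param path TSV file path.
#' @return data.frame with columns \code{mirna}, \code{disease}.
#' @export
read_associations <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "",
                          strip.white = TRUE)
  if (ncol(df) > 2L) {
    warning(sprintf("association file %s has %d columns; using the first two",
                    path, ncol(df)))
  }
  stats::setNames(df[, 1:2], c("mirna", "disease"))
}

#' Transferring matrices of the disease similarity network
#'
#' The i-th transferring matrix holds, for each disease pair (p, q), the
#' summed weight of all length-i walks from p to q in the disease
#' similarity network, where the weight of a walk is the product of its
#' edge weights. That sum is exactly the i-th matrix power of S, so
#' M_i = S^i; M_1 = S. Each power is symmetrized on output to absorb
#' floating-point drift.
#'
#' @param S symmetric disease similarity matrix.
#' @param b maximum transferring times (walk-length cap), integer >= 1.
#' @return list of b symmetric matrices \code{M[[i]] == S^i}.
#' @export
transfer_matrices <- function(S, b) {
  stopifnot(is.matrix(S), nrow(S) == ncol(S))
  if (!is.numeric(b) || length(b) != 1L || b < 1) {
    stop("maximum transferring times b must be a single integer >= 1")
  }
  b <- as.integer(b)
  if (max(abs(S - t(S))) > 1e-9 * max(1, max(abs(S)))) {
    stop("disease similarity matrix is not symmetric")
  }
  M <- vector("list", b)
  M[[1]] <- (S + t(S)) / 2
  if (b > 1L) {
    for (i in 2:b) {
      Mi <- M[[i - 1]] %*% S
      M[[i]] <- (Mi + t(Mi)) / 2
    }
  }
  M
}

#' miRNA-miRNA path matrix
#'
#' Damped sum of walk weights between the disease sets of each miRNA pair:
#' P = sum over t = 1..b of a^t * (R M_t R^T). The weight ratio a in
#' (0, 1] down-weights longer walks (Katz-style damping), so remote
#' relationships contribute less; the entry P(i, j) is the total damped
#' weight of all walks of length at most b running from any disease of
#' miRNA i to any disease of miRNA j.
#'
#' @param R binary association matrix (miRNAs x diseases).
#' @param M list of transferring matrices from [transfer_matrices()],
#'   aligned with the columns of \code{R}.
#' @param a weight ratio in (0, 1].
#' @return symmetric nonnegative |M| x |M| matrix with attributes
#'   \code{a} and \code{b}.
#' @export
path_matrix <- function(R, M, a) {
  stopifnot(is.matrix(R), is.list(M), length(M) >= 1L)
  if (!is.numeric(a) || length(a) != 1L || a <= 0 || a > 1) {
    stop("weight ratio a must be a single number in (0, 1]")
  }
  for (Mt in M) {
    if (!identical(dim(Mt), c(ncol(R), ncol(R)))) {
      stop("association and transferring matrices have misaligned ",
           "disease orders")
    }
    if (!is.null(colnames(Mt)) && !is.null(colnames(R)) &&
        !identical(colnames(Mt), colnames(R))) {
      stop("association and transferring matrices have misaligned ",
           "disease orders")
    }
  }
  P <- matrix(0, nrow(R), nrow(R), dimnames = list(rownames(R), rownames(R)))
  Rn <- R * 1.0
  for (t in seq_along(M)) {
    P <- P + a^t * (Rn %*% M[[t]] %*% t(Rn))
  }
  P <- (P + t(P)) / 2
  structure(P, a = a, b = length(M))
}

#' MFSP similarity from a path matrix
#'
#' Normalizes the path matrix into similarity scores:
#' MFSP(i, j) = 2 P(i, j) / (P(i, i) + P(j, j)). The numerator measures
#' the connectivity of the two disease sets through the disease network;
#' the denominator suppresses miRNAs associated with many diseases.
#' Self-similarity is exactly 1 whenever P(i, i) > 0. Pairs whose two
#' diagonal entries are both 0 (miRNAs without usable associations) score
#' 0, with a warning.
#'
#' @param P symmetric nonnegative path matrix from [path_matrix()].
#' @return symmetric similarity matrix; for positive semidefinite P all
#'   entries lie in [0, 1].
#' @export
mfsp <- function(P) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (min(P) < -1e-9 * max(1, max(abs(P)))) {
    stop("path matrix has negative entries; upstream matrices are corrupted")
  }
  d <- diag(P)
  denom <- outer(d, d, "+")
  sim <- matrix(0, nrow(P), ncol(P), dimnames = dimnames(P))
  ok <- denom > 0
  sim[ok] <- 2 * P[ok] / denom[ok]
  if (any(!ok)) {
    warning(sprintf("%d miRNA(s) have zero path weight to themselves; ",
                    sum(d == 0)),
            "their similarities are reported as 0")
  }
  diag(sim)[d > 0] <- 1
  sim <- (sim + t(sim)) / 2
  sim
}

#' End-to-end MFSP pipeline
#'
#' Composes the full method: parse the ontology, build the CSD disease
#' similarity matrix, the binary association matrix, the transferring and
#' path matrices, and normalize to MFSP scores. Deterministic for fixed
#' inputs.
#'
#' @param tree_records name/code records accepted by
#'   [parse_tree_code_records()] (or an already-built \code{disease_dag}).
#' @param association_pairs data.frame of (mirna, disease) pairs.
#' @param a weight ratio in (0, 1]; default 0.6.
#' @param b maximum transferring times; default 5.
#' @return the MFSP similarity matrix, with the path matrix attached as
#'   attribute \code{path_matrix}.
#' @export
mfsp_pipeline <- function(tree_records, association_pairs, a = 0.6, b = 5) {
  dag <- if (inherits(tree_records, "disease_dag")) tree_records
         else parse_tree_code_records(tree_records)
  S <- disease_similarity_matrix(dag)
  R <- association_matrix(association_pairs, dag)
  M <- transfer_matrices(S, b)
  P <- path_matrix(R, M, a)
  sim <- mfsp(P)
  attr(sim, "path_matrix") <- P
  sim
}

#' Write miRNA pairs above a similarity cutoff in long format
#'
#' Emits \code{mirna_a<TAB>mirna_b<TAB>score} for every unordered pair
#' with score strictly above \code{cutoff}.
#'
#' @param sim symmetric similarity matrix.
#' @param path output TSV path.
#' @param cutoff minimum score (exclusive); default 0.
#' @return invisibly, the number of pairs written.
#' @export
write_pairs_tsv <- function(sim, path, cutoff = 0) {
  stopifnot(is.matrix(sim))
  idx <- which(upper.tri(sim) & sim > cutoff, arr.ind = TRUE)
  df <- data.frame(mirna_a = rownames(sim)[idx[, 1]],
                   mirna_b = colnames(sim)[idx[, 2]],
                   score = sim[idx])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(df))
}
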