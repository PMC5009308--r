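#' Cosine similarity of two disease feature vectors (CSD)
#'
#' Standard cosine: dot product over the product of Euclidean norms,
#' computed on the sparse ancestor-weight vectors. Identical diseases
#' score 1; diseases with disjoint ancestor sets score 0.
#'
#' @param v1,v2 \code{feature_vector} objects from the same DAG.
#' @return similarity in [0, 1].
#' @export
csd <- function(v1, v2) {
  stopifnot(inherits(v1, "feature_vector"), inherits(v2, "feature_vector"))
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    stop("cosine similarity undefined for a zero feature vector ",
         "(disease with no codes)")
  }
  shared <- intersect(names(v1), names(v2))
  if (length(shared) == 0L) return(0)
  sum(unclass(v1)[shared] * unclass(v2)[shared]) / (n1 * n2)
}

#' Disease-by-disease CSD similarity matrix
#'
#' Assembles the symmetric matrix S of pairwise cosine similarities of
#' ancestor-distance feature vectors, the weighted adjacency of the
#' disease similarity network. Computed as a Gram matrix of the
#' row-normalized feature matrix, so it is positive semidefinite by
#' construction.
#'
#' @param dag a \code{disease_dag}.
#' @return symmetric numeric matrix with unit diagonal, dimnames set to
#'   the sorted disease names.
#' @export
disease_similarity_matrix <- function(dag) {
  stopifnot(inherits(dag, "disease_dag"))
  nms <- sort(names(dag$diseases))
  n <- length(nms)
  if (n == 0L) stop("empty DAG")
  FM <- matrix(0, n, n, dimnames = list(nms, nms))
  for (d in nms) {
    v <- feature_vector(dag, d)
    FM[d, names(v)] <- unclass(v)
  }
  FM <- FM / sqrt(rowSums(FM^2))
  S <- tcrossprod(FM)
  S <- (S + t(S)) / 2          # absorb floating-point asymmetry
  diag(S) <- 1
  S
}

#' Best-match-average miRNA similarity from a disease similarity matrix
#'
#' For each miRNA pair with associated disease sets D1 and D2, pairs every
#' disease with its most similar counterpart in the other set and averages:
#' (sum over D1 of max similarity to D2 + sum over D2 of max similarity to
#' D1) / (|D1| + |D2|). This is the comparator aggregation used with CSD
#' in place of a path-based score.
#'
#' @param S disease similarity matrix (as from
#'   [disease_similarity_matrix()]).
#' @param R binary association matrix (as from [association_matrix()]);
#'   its disease order must be a subset of \code{colnames(S)}.
#' @return symmetric miRNA-by-miRNA matrix in [0, 1] with unit diagonal
#'   (0 on the diagonal for miRNAs without associations, with a warning).
#' @export
bma_similarity <- function(S, R) {
  stopifnot(is.matrix(S), is.matrix(R))
  if (!all(colnames(R) %in% colnames(S))) {
    stop("association matrix refers to diseases absent from the ",
         "similarity matrix")
  }
  S <- S[colnames(R), colnames(R), drop = FALSE]
  m <- nrow(R)
  mirnas <- rownames(R)
  sets <- lapply(seq_len(m), function(i) which(R[i, ] == 1))
  nz <- lengths(sets) > 0L
  if (any(!nz)) {
    warning(sprintf("%d miRNA(s) have no associated diseases; their BMA ",
                    sum(!nz)), "scores are set to 0")
  }
  out <- matrix(0, m, m, dimnames = list(mirnas, mirnas))
  for (i in seq_len(m)) {
    if (!nz[i]) next
    D1 <- sets[[i]]
    for (j in i:m) {
      if (!nz[j]) next
      D2 <- sets[[j]]
      blk <- S[D1, D2, drop = FALSE]
      v <- (sum(apply(blk, 1, max)) + sum(apply(blk, 2, max))) /
        (length(D1) + length(D2))
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  diag(out)[nz] <- 1
  out
}

#' Write / read a named symmetric similarity matrix as TSV
#'
#' The TSV carries the entity names as both header row and first column.
#' \code{read_similarity_tsv} checks symmetry on load.
#'
#' @param S numeric matrix with identical row and column names.
#' @param path file path.
#' @return \code{write_similarity_tsv}: the path, invisibly;
#'   \code{read_similarity_tsv}: the matrix.
#' @export
write_similarity_tsv <- function(S, path) {
  stopifnot(is.matrix(S), identical(rownames(S), colnames(S)))
  df <- data.frame(name = rownames(S), S, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "")
  S <- as.matrix(df[, -1, drop = FALSE])
  rownames(S) <- df[[1]]
  if (!isTRUE(all.equal(S, t(S), tolerance = 1e-8))) {
    stop("matrix read from ", path, " is not symmetric")
  }
  S
}
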