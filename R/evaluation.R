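#' Intra-family / inter-family / random miRNA pair groups
#'
#' Restricts attention to miRNAs that carry a family annotation and are
#' present in the similarity matrix, enumerates all unordered pairs, and
#' splits them into intra-family (same family) and inter-family
#' (different family) groups, plus a seeded uniform random sample drawn
#' from their union. These are the positive-control groupings under which
#' functionally similar miRNAs (same sequence family) are expected to
#' score higher.
#'
#' @param families named character vector, miRNA name -> family id.
#' @param sim symmetric miRNA similarity matrix.
#' @param n_random size of the random group; default
#'   \code{min(n_intra, 10000)}.
#' @param seed RNG seed for the random sample (mandatory).
#' @return list of three \code{pair_group} data.frames (\code{intra},
#'   \code{inter}, \code{random}), each with columns \code{mirna_a},
#'   \code{mirna_b}, \code{score}, \code{label}.
#' @export
family_pair_groups <- function(families, sim, n_random = NULL, seed) {
  stopifnot(length(families) > 0L, !is.null(names(families)),
            is.matrix(sim))
  if (missing(seed)) stop("a seed for the random pair group is required")
  annotated <- intersect(names(families), rownames(sim))
  if (length(annotated) < 2L) {
    stop("fewer than 2 family-annotated miRNAs present in the ",
         "similarity matrix")
  }
  annotated <- sort(annotated)
  pairs <- t(utils::combn(annotated, 2))
  fam_a <- families[pairs[, 1]]
  fam_b <- families[pairs[, 2]]
  scores <- sim[cbind(pairs[, 1], pairs[, 2])]
  intra <- fam_a == fam_b
  if (!any(intra)) stop("no intra-family pairs among annotated miRNAs")
  mk <- function(sel, label) {
    data.frame(mirna_a = pairs[sel, 1], mirna_b = pairs[sel, 2],
               score = scores[sel], label = label,
               stringsAsFactors = FALSE)
  }
  if (is.null(n_random)) n_random <- min(sum(intra), 10000L)
  ridx <- withr::with_seed(seed,
    sample.int(nrow(pairs), size = min(n_random, nrow(pairs))))
  list(intra = mk(which(intra), "intra"),
       inter = mk(which(!intra), "inter"),
       random = mk(ridx, "random"))
}

#' Group miRNA loci into genomic clusters by distance cutoff
#'
#' Single-linkage chaining: two loci on the same chromosome (and, by
#' default, the same strand) whose gap is at most \code{cutoff_bp} base
#' pairs are linked; clusters are the connected components of those
#' links. The gap between two intervals is the number of bases strictly
#' between them (0 for overlapping or adjacent intervals). Membership is
#' independent of input order.
#'
#' @param loci data.frame with columns \code{mirna}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand} (1-based inclusive
#'   coordinates), or a \code{GRanges} whose names are miRNA names.
#' @param cutoff_bp linkage distance in base pairs, > 0.
#' @param same_strand require co-linked loci to share the strand
#'   (polycistronic clusters are co-transcribed); default TRUE.
#' @return named integer vector, miRNA name -> cluster id.
#' @export
cluster_by_distance <- function(loci, cutoff_bp, same_strand = TRUE) {
  if (!is.numeric(cutoff_bp) || length(cutoff_bp) != 1L || cutoff_bp <= 0) {
    stop("cutoff_bp must be a single positive number")
  }
  if (!methods::is(loci, "GRanges")) {
    req <- c("mirna", "chrom", "start", "end", "strand")
    if (!is.data.frame(loci) || !all(req %in% names(loci))) {
      stop("loci must be a GRanges or a data.frame with columns ",
           paste(req, collapse = ", "))
    }
    if (any(loci$start > loci$end)) stop("malformed locus: start > end")
    if (!all(loci$strand %in% c("+", "-"))) {
      stop("malformed locus: strand must be '+' or '-'")
    }
    gr <- GenomicRanges::GRanges(
      seqnames = loci$chrom,
      ranges = IRanges::IRanges(start = loci$start, end = loci$end),
      strand = loci$strand)
    names(gr) <- loci$mirna
  } else {
    gr <- loci
    if (is.null(names(gr))) stop("GRanges loci must carry miRNA names")
  }
  red <- GenomicRanges::reduce(gr, min.gapwidth = cutoff_bp + 1,
                               ignore.strand = !same_strand)
  hits <- GenomicRanges::findOverlaps(gr, red,
                                      ignore.strand = !same_strand,
                                      select = "first")
  stats::setNames(as.integer(hits), names(gr))
}

#' Read miRNA loci from a miRBase-style GFF3 file
#'
#' Keeps one record per miRNA name (attribute \code{Name}, falling back
#' to \code{ID}) and returns the plain data.frame layout used by
#' [cluster_by_distance()].
#'
#' @param path GFF3 file path.
#' @return data.frame with columns \code{mirna}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}.
#' @export
read_loci_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  nm <- gr$Name
  if (is.null(nm)) nm <- gr$ID
  data.frame(mirna = as.character(nm),
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Rank-based significance tests on similarity score groups
#'
#' \code{rank_sum_test} runs the two-sided Wilcoxon rank-sum test
#' (exact enumeration for small tie-free samples, normal approximation
#' with tie correction otherwise); \code{kruskal_wallis} runs the
#' Kruskal-Wallis test across two or more groups. Both return a uniform
#' report structure; p-values below double precision are flagged as
#' underflow rather than printed as zero.
#'
#' @param x,y numeric score vectors (each with >= 2 observations).
#' @return list of class \code{test_report} with \code{test},
#'   \code{comparison}, \code{statistic}, \code{p_value},
#'   \code{underflow}.
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 observations")
  }
  exact <- max(length(x), length(y)) <= 20 &&
    !anyDuplicated(c(x, y))
  ht <- stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                           correct = TRUE)
  structure(list(test = "wilcoxon_rank_sum",
                 comparison = c(deparse(substitute(x)),
                                deparse(substitute(y))),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 underflow = ht$p.value < .Machine$double.xmin),
            class = "test_report")
}

#' @rdname rank_sum_test
#' @param groups named list of >= 2 numeric score vectors.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) {
    stop("each group needs at least 2 observations")
  }
  ht <- stats::kruskal.test(groups)
  structure(list(test = "kruskal_wallis",
                 comparison = names(groups),
                 statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 underflow = ht$p.value < .Machine$double.xmin),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  p <- if (x$underflow) "< double precision (underflow)"
       else format(x$p_value, digits = 4)
  cat(sprintf("%s [%s]: statistic %.4g, p-value %s\n",
              x$test, paste(x$comparison, collapse = " vs "),
              x$statistic, p))
  invisible(x)
}

#' Benchmark report over intra/inter/random pair groups
#'
#' Runs the three pairwise rank-sum comparisons and the three-group
#' Kruskal-Wallis test on the pair groups from [family_pair_groups()]
#' (or the analogous cluster-based grouping), mirroring the usual
#' benchmark table layout (test x comparison -> p-value).
#'
#' @param groups list with elements \code{intra}, \code{inter},
#'   \code{random}, each a pair-group data.frame with a \code{score}
#'   column.
#' @return data.frame with columns \code{test}, \code{comparison},
#'   \code{p_value}, \code{underflow}, plus group means as attribute
#'   \code{group_means}.
#' @export
benchmark_report <- function(groups) {
  stopifnot(all(c("intra", "inter", "random") %in% names(groups)))
  sc <- lapply(groups, `[[`, "score")
  rows <- list(
    c(test = "wilcoxon_rank_sum", comparison = "intra-inter",
      p = rank_sum_test(sc$intra, sc$inter)$p_value),
    c(test = "wilcoxon_rank_sum", comparison = "intra-random",
      p = rank_sum_test(sc$intra, sc$random)$p_value),
    c(test = "wilcoxon_rank_sum", comparison = "inter-random",
      p = rank_sum_test(sc$inter, sc$random)$p_value),
    c(test = "kruskal_wallis", comparison = "intra-inter-random",
      p = kruskal_wallis(sc[c("intra", "inter", "random")])$p_value))
  out <- data.frame(
    test = vapply(rows, `[[`, character(1), "test"),
    comparison = vapply(rows, `[[`, character(1), "comparison"),
    p_value = as.numeric(vapply(rows, `[[`, character(1), "p")),
    stringsAsFactors = FALSE)
  out$underflow <- out$p_value < .Machine$double.xmin
  attr(out, "group_means") <- vapply(sc, mean, numeric(1))
  out
}

#' Expression-similarity curve over MFSP thresholds
#'
#' For each threshold t on a grid, computes the mean pairwise Pearson
#' correlation of expression profiles over miRNA pairs whose functional
#' similarity exceeds t. A rising curve indicates that functionally
#' similar miRNAs share expression patterns. Pairs with a miRNA missing
#' from the expression matrix, or with a constant profile (undefined
#' correlation), are skipped and counted.
#'
#' @param sim symmetric miRNA similarity matrix.
#' @param expr numeric matrix, miRNAs as rows, tissues as columns
#'   (>= 2 tissues).
#' @param thresholds threshold grid; default \code{seq(0, 1, by = 0.05)}.
#' @return data.frame with columns \code{threshold}, \code{mean_pcc},
#'   \code{n_pairs}, \code{n_skipped}; the Pearson correlation between
#'   the curve and the thresholds is attached as attribute
#'   \code{curve_threshold_pcc}.
#' @export
expression_correlation_curve <- function(sim, expr,
                                         thresholds = seq(0, 1, by = 0.05)) {
  stopifnot(is.matrix(sim), is.matrix(expr))
  if (ncol(expr) < 2L) stop("expression matrix needs at least 2 tissues")
  common <- intersect(rownames(sim), rownames(expr))
  if (length(common) < 2L) {
    stop("no usable miRNA overlap between similarity and expression data")
  }
  constant <- apply(expr[common, , drop = FALSE], 1,
                    function(v) stats::sd(v) == 0 || anyNA(v))
  if (any(constant)) {
    warning(sprintf("%d miRNA(s) with constant or missing expression ",
                    sum(constant)), "profiles skipped")
  }
  usable <- common[!constant]
  pcc <- stats::cor(t(expr[usable, , drop = FALSE]))
  missing_n <- nrow(sim) - length(common)
  subsim <- sim[usable, usable, drop = FALSE]
  up <- upper.tri(subsim)
  res <- lapply(thresholds, function(t) {
    sel <- up & subsim > t
    data.frame(threshold = t,
               mean_pcc = if (any(sel)) mean(pcc[sel]) else NA_real_,
               n_pairs = sum(sel),
               n_skipped = missing_n + sum(constant))
  })
  out <- do.call(rbind, res)
  ok <- !is.na(out$mean_pcc)
  attr(out, "curve_threshold_pcc") <-
    if (sum(ok) >= 3 && stats::sd(out$mean_pcc[ok]) > 0) {
      stats::cor(out$threshold[ok], out$mean_pcc[ok])
    } else NA_real_   # flat curve: correlation with t undefined
  out
}

#' Sweep MFSP parameters and summarize group similarity
#'
#' Recomputes the full MFSP pipeline for every (a, b) grid point and
#' reports the mean similarity of each supplied pair group, in long
#' format. Used to study damping (growth with the weight ratio a) and
#' convergence (stabilization as the walk-length cap b grows).
#'
#' @param tree_records ontology records or a \code{disease_dag}.
#' @param pairs association data.frame (mirna, disease).
#' @param a_grid,b_grid numeric grids of weight ratios / transfer caps.
#' @param groups named list of pair-group data.frames (columns
#'   \code{mirna_a}, \code{mirna_b}).
#' @return data.frame with columns \code{a}, \code{b}, \code{group},
#'   \code{mean_similarity}, \code{n_pairs}.
#' @export
parameter_sweep <- function(tree_records, pairs, a_grid, b_grid, groups) {
  stopifnot(length(a_grid) > 0L, length(b_grid) > 0L,
            is.list(groups), length(groups) > 0L, !is.null(names(groups)))
  dag <- if (inherits(tree_records, "disease_dag")) tree_records
         else parse_tree_code_records(tree_records)
  S <- disease_similarity_matrix(dag)
  R <- association_matrix(pairs, dag)
  M_all <- transfer_matrices(S, max(b_grid))
  rows <- list()
  for (a in a_grid) {
    for (b in b_grid) {
      sim <- mfsp(path_matrix(R, M_all[seq_len(b)], a))
      for (g in names(groups)) {
        gp <- groups[[g]]
        keep <- gp$mirna_a %in% rownames(sim) & gp$mirna_b %in% rownames(sim)
        sc <- sim[cbind(gp$mirna_a[keep], gp$mirna_b[keep])]
        rows[[length(rows) + 1L]] <- data.frame(
          a = a, b = b, group = g,
          mean_similarity = mean(sc), n_pairs = length(sc),
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}
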