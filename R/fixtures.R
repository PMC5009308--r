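#' Specification for the synthetic fixture generators
#'
#' Bundles the knobs shared by all generators: ontology shape, number of
#' miRNAs, association density, family structure and the planted effect
#' sizes that give the benchmark protocols a recoverable ground truth.
#' All generators are fully deterministic for a given seed.
#'
#' @param seed integer RNG seed.
#' @param n_diseases number of diseases in the ontology.
#' @param depth maximum depth of the code hierarchy (number of segments).
#' @param branching children per node (and number of roots).
#' @param n_mirnas number of miRNAs.
#' @param assoc_density fraction of the ontology each miRNA is associated
#'   with, in (0, 1].
#' @param n_families number of miRNA families.
#' @param planted_effect excess tendency of same-family miRNAs to share a
#'   disease neighborhood; 0 = no family signal (null), larger values
#'   concentrate each family on a common subtree anchor.
#' @param expression_coupling target correlation scale tying expression
#'   profiles to functional similarity, in [0, 1]; 0 = independent
#'   profiles.
#' @param second_code_fraction fraction of non-root diseases that receive
#'   a second tree code in another subtree.
#' @param n_tissues number of expression columns.
#' @return list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1L, n_diseases = 100L, depth = 4L,
                         branching = 4L, n_mirnas = 50L,
                         assoc_density = 0.05, n_families = 10L,
                         planted_effect = 4, expression_coupling = 0.6,
                         second_code_fraction = 0.1, n_tissues = 40L) {
  spec <- list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
               depth = as.integer(depth), branching = as.integer(branching),
               n_mirnas = as.integer(n_mirnas),
               assoc_density = assoc_density,
               n_families = as.integer(n_families),
               planted_effect = planted_effect,
               expression_coupling = expression_coupling,
               second_code_fraction = second_code_fraction,
               n_tissues = as.integer(n_tissues))
  with(spec, {
    stopifnot(n_diseases > 0, depth >= 1, branching > 0, n_mirnas > 0,
              n_families > 0, n_tissues > 0,
              assoc_density > 0, assoc_density <= 1,
              planted_effect >= 0,
              expression_coupling >= 0, expression_coupling <= 1,
              second_code_fraction >= 0, second_code_fraction <= 1)
  })
  structure(spec, class = "fixture_spec")
}

#' Generate a toy disease ontology as tree-code records
#'
#' Builds a rooted multi-tree of dotted codes breadth-first:
#' \code{branching} root codes, each node receiving up to
#' \code{branching} children, down to \code{depth} segments, until
#' \code{n_diseases} diseases exist. A fraction of non-root diseases get
#' a second code grafted under a random other node, emulating the
#' multi-position diseases of real ontologies.
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with columns \code{name}, \code{code}, one row per
#'   code, ready for [parse_tree_code_records()]; the number of two-code
#'   diseases is attached as attribute \code{n_second_codes}.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (spec$branching^spec$depth < spec$n_diseases) {
    stop(sprintf("infeasible ontology shape: branching^depth = %d < %d diseases",
                 spec$branching^spec$depth, spec$n_diseases))
  }
  withr::with_seed(spec$seed, {
    codes <- character(0)
    frontier <- sprintf("C%02d", seq_len(min(spec$branching, spec$n_diseases)))
    codes <- frontier
    level <- 1L
    while (length(codes) < spec$n_diseases && level < spec$depth) {
      kids <- unlist(lapply(frontier, function(p) {
        paste0(p, ".", sprintf("%03d", seq_len(spec$branching)))
      }))
      need <- spec$n_diseases - length(codes)
      kids <- kids[seq_len(min(length(kids), need))]
      codes <- c(codes, kids)
      frontier <- kids
      level <- level + 1L
    }
    if (length(codes) < spec$n_diseases) {
      stop("infeasible ontology shape: hierarchy exhausted before ",
           spec$n_diseases, " diseases were placed")
    }
    names_ <- sprintf("disease_%03d", seq_along(codes))
    rec <- data.frame(name = names_, code = codes, stringsAsFactors = FALSE)
    deep <- which(code_depth(codes) > 1L)
    n_second <- round(spec$second_code_fraction * length(deep))
    if (n_second > 0L) {
      chosen <- sample(deep, n_second)
      hosts <- sample(seq_along(codes), n_second, replace = TRUE)
      extra <- data.frame(
        name = names_[chosen],
        code = paste0(codes[hosts], ".", sprintf("X%03d", seq_len(n_second))),
        stringsAsFactors = FALSE)
      rec <- rbind(rec, extra)
    }
    structure(rec, n_second_codes = n_second)
  })
}

#' Generate miRNA-disease associations with a planted family effect
#'
#' Each miRNA is assigned a disease "neighborhood": the subtree (by code
#' prefix) around an anchor disease. miRNAs of the same family share the
#' family's anchor with probability \code{planted_effect /
#' (1 + planted_effect)}, so intra-family pairs have overlapping disease
#' sets - and hence higher path-based similarity - in expectation. With
#' \code{planted_effect = 0} anchors are drawn independently and the
#' family labels carry no signal (the null of the benchmark tests).
#' Associations are the anchor's subtree members topped up with uniform
#' noise diseases.
#'
#' @param spec a [fixture_spec()].
#' @param ontology tree-code records from [generate_ontology()] (or a
#'   \code{disease_dag}).
#' @return list with \code{pairs} (data.frame mirna/disease),
#'   \code{families} (named character vector mirna -> family id) and
#'   \code{n_per_mirna} (named integer vector of association counts).
#' @export
generate_associations <- function(spec, ontology) {
  stopifnot(inherits(spec, "fixture_spec"))
  dag <- if (inherits(ontology, "disease_dag")) ontology
         else parse_tree_code_records(ontology)
  diseases <- sort(names(dag$diseases))
  if (length(diseases) == 0L) stop("empty ontology")
  k <- max(2L, round(spec$assoc_density * length(diseases)))
  all_codes <- names(dag$code_index)

  subtree_members <- function(anchor) {
    hits <- unlist(lapply(dag$diseases[[anchor]], function(code) {
      m <- all_codes == code |
        startsWith(all_codes, paste0(code, "."))
      dag$code_index[m]
    }))
    sort(unique(unname(hits)))
  }

  withr::with_seed(spec$seed + 1L, {
    mirnas <- sprintf("mir-%03d", seq_len(spec$n_mirnas))
    fam <- sprintf("fam%02d", sample(rep_len(seq_len(spec$n_families),
                                             spec$n_mirnas)))
    names(fam) <- mirnas
    fam_anchor <- stats::setNames(
      sample(diseases, spec$n_families, replace = TRUE),
      sprintf("fam%02d", seq_len(spec$n_families)))
    p_share <- spec$planted_effect / (1 + spec$planted_effect)
    pairs <- lapply(mirnas, function(m) {
      anchor <- if (stats::runif(1) < p_share) fam_anchor[[fam[[m]]]]
                else sample(diseases, 1)
      nb <- subtree_members(anchor)
      chosen <- if (length(nb) <= k) nb else sample(nb, k)
      if (length(chosen) < k) {
        extra <- sample(setdiff(diseases, chosen), k - length(chosen))
        chosen <- c(chosen, extra)
      }
      data.frame(mirna = m, disease = chosen, stringsAsFactors = FALSE)
    })
    pairs <- do.call(rbind, pairs)
    counts <- table(pairs$mirna)
    if (any(counts == 0L)) {
      warning("some miRNAs received no associations at this density")
    }
    list(pairs = pairs, families = fam,
         n_per_mirna = stats::setNames(as.integer(counts), names(counts)))
  })
}

#' Generate miRNA genomic loci with planted clusters
#'
#' Partitions the miRNAs into genomic clusters of 1-3 loci, places each
#' cluster on a chromosome with within-cluster gaps under 10 kb and
#' between-cluster gaps above 100 kb, so a distance-cutoff sweep from
#' 10 kb to 100 kb recovers exactly the planted clusters. Hairpin loci
#' are ~80 bp; all loci of a cluster share a strand (co-transcription).
#'
#' @param spec a [fixture_spec()].
#' @return data.frame with columns \code{mirna}, \code{chrom},
#'   \code{start}, \code{end}, \code{strand}; the planted cluster ids
#'   are attached as attribute \code{planted_clusters} (named integer
#'   vector).
#' @export
generate_loci <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(spec$seed + 2L, {
    mirnas <- sprintf("mir-%03d", seq_len(spec$n_mirnas))
    sizes <- integer(0)
    while (sum(sizes) < spec$n_mirnas) {
      sizes <- c(sizes, sample(1:3, 1))
    }
    sizes[length(sizes)] <- sizes[length(sizes)] -
      (sum(sizes) - spec$n_mirnas)
    sizes <- sizes[sizes > 0L]
    cluster_id <- rep(seq_along(sizes), sizes)
    chroms <- paste0("chr", 1:5)
    rows <- list()
    pos <- stats::setNames(rep(1e6, length(chroms)), chroms)
    i <- 0L
    for (cl in seq_along(sizes)) {
      chrom <- sample(chroms, 1)
      strand <- sample(c("+", "-"), 1)
      pos[chrom] <- pos[chrom] + round(stats::runif(1, 1.5e5, 5e5))
      for (j in seq_len(sizes[cl])) {
        i <- i + 1L
        start <- pos[chrom]
        end <- start + 79
        rows[[i]] <- data.frame(mirna = mirnas[i], chrom = chrom,
                                start = start, end = end, strand = strand,
                                stringsAsFactors = FALSE)
        pos[chrom] <- end + round(stats::runif(1, 1000, 9000))
      }
      pos[chrom] <- pos[chrom] + 1.2e5   # keep clusters > 100 kb apart
    }
    loci <- do.call(rbind, rows)
    rownames(loci) <- NULL
    structure(loci,
              planted_clusters = stats::setNames(cluster_id, loci$mirna))
  })
}

#' Write miRNA loci as a miRBase-style GFF3 file
#'
#' @param loci data.frame as returned by [generate_loci()].
#' @param path output GFF3 path.
#' @return invisibly, the path.
#' @export
write_loci_gff3 <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    strand = loci$strand,
    type = "miRNA_primary_transcript",
    ID = loci$mirna, Name = loci$mirna)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Generate an expression matrix coupled to a similarity matrix
#'
#' Draws Gaussian tissue profiles whose target pairwise correlation is
#' \code{expression_coupling * sim}, via the Cholesky/eigen factor of
#' the (PSD-clipped) target correlation matrix. With coupling 0 the
#' profiles are independent of the similarity structure.
#'
#' @param spec a [fixture_spec()].
#' @param sim symmetric miRNA similarity matrix with dimnames.
#' @return numeric matrix, miRNAs as rows and tissues as columns.
#' @export
generate_expression <- function(spec, sim) {
  stopifnot(inherits(spec, "fixture_spec"), is.matrix(sim))
  n <- nrow(sim)
  C <- spec$expression_coupling * sim
  diag(C) <- 1
  eig <- eigen((C + t(C)) / 2, symmetric = TRUE)
  vals <- pmax(eig$values, 0)
  L <- eig$vectors %*% diag(sqrt(vals), n)
  withr::with_seed(spec$seed + 3L, {
    Z <- matrix(stats::rnorm(n * spec$n_tissues), n, spec$n_tissues)
    X <- L %*% Z
    dimnames(X) <- list(rownames(sim),
                        sprintf("tissue_%02d", seq_len(spec$n_tissues)))
    X
  })
}

#' Write / read a miRNA-by-tissue expression TSV
#'
#' Plain TSV matrix: miRNAs as rows (first column \code{mirna}), tissues
#' as columns.
#'
#' @param expr numeric matrix with miRNA rownames.
#' @param path file path.
#' @return \code{write_expression_tsv}: the path, invisibly;
#'   \code{read_expression_tsv}: the matrix.
#' @export
write_expression_tsv <- function(expr, path) {
  df <- data.frame(mirna = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          quote = "", comment.char = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Write / read a miRNA family annotation TSV
#'
#' Two columns: \code{mirna<TAB>family_id}.
#'
#' @param families named character vector, miRNA -> family id.
#' @param path file path.
#' @return \code{write_families_tsv}: the path, invisibly;
#'   \code{read_families_tsv}: the named vector.
#' @export
write_families_tsv <- function(families, path) {
  utils::write.table(
    data.frame(mirna = names(families), family = unname(families)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_families_tsv
#' @export
read_families_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = "character", comment.char = "#")
  stats::setNames(df[[2]], df[[1]])
}

#' Write the complete fixture file set
#'
#' Emits all five input dialects into a directory: tree-code TSV,
#' association TSV, family TSV, loci GFF3 and expression TSV (the
#' expression matrix is coupled to the MFSP similarity computed from the
#' generated ontology and associations).
#'
#' @param spec a [fixture_spec()].
#' @param dir output directory (created if absent).
#' @return named character vector of the five file paths, invisibly.
#' @export
write_fixtures <- function(spec, dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ont <- generate_ontology(spec)
  assoc <- generate_associations(spec, ont)
  loci <- generate_loci(spec)
  sim <- mfsp_pipeline(ont, assoc$pairs)
  expr <- generate_expression(spec, sim)
  paths <- c(
    tree_codes = file.path(dir, "tree_codes.tsv"),
    associations = file.path(dir, "associations.tsv"),
    families = file.path(dir, "families.tsv"),
    loci = file.path(dir, "loci.gff3"),
    expression = file.path(dir, "expression.tsv"))
  write_tree_codes(parse_tree_code_records(ont), paths["tree_codes"])
  utils::write.table(assoc$pairs, paths["associations"], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_families_tsv(assoc$families, paths["families"])
  write_loci_gff3(loci, paths["loci"])
  write_expression_tsv(expr, paths["expression"])
  invisible(paths)
}
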