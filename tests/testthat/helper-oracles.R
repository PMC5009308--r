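# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and, where possible, the
# libraries) used by the package functions.

# Shortest ancestor distance by explicit breadth-first search over the
# materialized child -> parent code edges (one edge per dropped segment).
oracle_ancestor_distance <- function(dag, ancestor, descendant) {
  codes <- names(dag$code_index)
  parent_of <- function(code) {
    segs <- strsplit(code, ".", fixed = TRUE)[[1]]
    if (length(segs) == 1L) return(NA_character_)
    paste(segs[-length(segs)], collapse = ".")
  }
  anc_codes <- dag$diseases[[ancestor]]
  best <- Inf
  for (start in dag$diseases[[descendant]]) {
    # BFS upward (each code has a unique parent chain, walked explicitly)
    frontier <- start
    dist <- 0L
    repeat {
      if (any(frontier %in% anc_codes)) {
        best <- min(best, dist)
        break
      }
      nxt <- parent_of(frontier)
      if (is.na(nxt)) break
      # skip positions not owned by any disease: they are not graph nodes,
      # but the depth difference still counts the dropped segments
      frontier <- nxt
      dist <- dist + 1L
    }
  }
  if (is.infinite(best)) NA_integer_ else as.integer(best)
}

# Sum of the weights of all length-len walks p -> q, by recursive
# enumeration (weight of a walk = product of edge weights).
oracle_walk_sum <- function(S, p, q, len) {
  n <- nrow(S)
  if (len == 1L) return(S[p, q])
  total <- 0
  for (r in seq_len(n)) {
    total <- total + S[p, r] * oracle_walk_sum(S, r, q, len - 1L)
  }
  total
}

# Path matrix entry by exhaustive walk enumeration between disease sets.
oracle_path_entry <- function(S, D1, D2, a, b) {
  total <- 0
  for (t in seq_len(b)) {
    for (p in D1) for (q in D2) {
      total <- total + a^t * oracle_walk_sum(S, p, q, t)
    }
  }
  total
}

# Connected components over the pairwise genomic-gap matrix (union-find).
oracle_clusters <- function(loci, cutoff_bp, same_strand = TRUE) {
  n <- nrow(loci)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  gap <- function(i, j) {
    if (loci$chrom[i] != loci$chrom[j]) return(Inf)
    if (same_strand && loci$strand[i] != loci$strand[j]) return(Inf)
    lo <- min(loci$end[i], loci$end[j])
    hi <- max(loci$start[i], loci$start[j])
    max(0, hi - lo - 1)
  }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (gap(i, j) <= cutoff_bp) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  stats::setNames(match(roots, unique(roots)), loci$mirna)
}

# All-pairs unweighted shortest paths by hand-rolled BFS over an
# adjacency list; returns the mean over connected pairs.
oracle_path_length <- function(adj) {
  nodes <- names(adj)
  dists <- c()
  for (s in nodes) {
    d <- stats::setNames(rep(Inf, length(nodes)), nodes)
    d[s] <- 0
    queue <- s
    while (length(queue) > 0L) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(d[v])) { d[v] <- d[u] + 1; queue <- c(queue, v) }
      }
    }
    dists <- c(dists, d[nodes > s & is.finite(d)])
  }
  mean(dists)
}

# Mean local clustering coefficient by direct triangle counting.
oracle_clustering <- function(adj) {
  vals <- vapply(names(adj), function(u) {
    nb <- adj[[u]]
    k <- length(nb)
    if (k < 2) return(0)
    links <- 0
    for (i in seq_len(k - 1)) for (j in (i + 1):k) {
      if (nb[j] %in% adj[[nb[i]]]) links <- links + 1
    }
    2 * links / (k * (k - 1))
  }, numeric(1))
  mean(vals)
}

# igraph -> named adjacency list (for the hand-rolled graph oracles)
graph_adj_list <- function(net) {
  nodes <- igraph::V(net)$name
  adj <- lapply(nodes, function(u) {
    setdiff(igraph::V(net)$name[
      as.integer(igraph::neighbors(net, u))], character(0))
  })
  stats::setNames(adj, nodes)
}

# The printed two-miRNA worked-example path matrix.
worked_example_P <- function() {
  matrix(c(9.3741, 7.377, 7.377, 7.5149), 2, 2,
         dimnames = list(c("m1", "m2"), c("m1", "m2")))
}

toy_dag <- function() {
  read_tree_codes(system.file("extdata", "toy_tree_codes.tsv",
                              package = "mirsimpath"))
}

toy_pairs <- function() {
  read_associations(system.file("extdata", "toy_associations.tsv",
                                package = "mirsimpath"))
}
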