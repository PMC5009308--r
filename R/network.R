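#' Threshold a similarity matrix into a miRNA functional network
#'
#' Adds an undirected weighted edge for every miRNA pair whose similarity
#' is strictly greater than the threshold (default 0.7). miRNAs left
#' without any qualifying edge are excluded from the network.
#'
#' @param sim symmetric similarity matrix with miRNA dimnames.
#' @param threshold edge cutoff in [0, 1]; strict inequality.
#' @return an \code{igraph} undirected graph with edge attribute
#'   \code{weight} and graph attribute \code{threshold}.
#' @export
build_network <- function(sim, threshold = 0.7) {
  stopifnot(is.matrix(sim), nrow(sim) == ncol(sim))
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single number in [0, 1]")
  }
  if (max(abs(sim - t(sim))) > 1e-9) stop("similarity matrix is not symmetric")
  idx <- which(upper.tri(sim) & sim > threshold, arr.ind = TRUE)
  nodes <- rownames(sim)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(sim)))
  edges <- data.frame(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                      weight = sim[idx])
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  g <- igraph::set_graph_attr(g, "threshold", threshold)
  g
}

#' Power-law fit to a degree histogram
#'
#' Ordinary least squares on (log10 degree, log10 count) over the degrees
#' with positive count, as used to diagnose scale-free degree
#' distributions. With \code{normalized = TRUE} the counts are first
#' converted to probabilities; the slope is unchanged, only the intercept
#' moves.
#'
#' @param degree_histogram named numeric vector (names = degree,
#'   values = count) or table, e.g. \code{table(igraph::degree(g))}.
#' @param normalized regress probabilities instead of raw counts.
#' @return list with \code{slope}, \code{r2}, \code{intercept},
#'   \code{n_points}.
#' @export
power_law_fit <- function(degree_histogram, normalized = FALSE) {
  h <- c(degree_histogram)
  deg <- as.numeric(names(h))
  cnt <- as.numeric(h)
  keep <- cnt > 0 & deg > 0
  deg <- deg[keep]
  cnt <- cnt[keep]
  if (length(deg) < 3L) {
    stop("power-law fit needs at least 3 distinct positive degrees")
  }
  if (normalized) cnt <- cnt / sum(cnt)
  fit <- stats::lm(log10(cnt) ~ log10(deg))
  # R^2 computed directly; summary.lm warns on exact power laws
  y <- log10(cnt)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = r2,
       n_points = length(deg))
}

#' Characteristic path length of a network
#'
#' Mean unweighted shortest-path length over connected node pairs;
#' disconnected pairs are excluded (their count is reported via a
#' message when present).
#'
#' @param net an \code{igraph} graph with at least 2 nodes.
#' @return mean shortest-path length.
#' @export
characteristic_path_length <- function(net) {
  stopifnot(igraph::is_igraph(net))
  n <- igraph::vcount(net)
  if (n < 2L) stop("characteristic path length needs at least 2 nodes")
  D <- igraph::distances(net, weights = NA)
  up <- D[upper.tri(D)]
  disconnected <- sum(is.infinite(up))
  if (disconnected > 0L) {
    message(sprintf("%d disconnected pair(s) excluded from path length",
                    disconnected))
  }
  mean(up[is.finite(up)])
}

#' Average local clustering coefficient
#'
#' Mean Watts-Strogatz local clustering coefficient over all nodes; nodes
#' of degree < 2 contribute 0.
#'
#' @param net an \code{igraph} graph.
#' @return mean local clustering coefficient in [0, 1].
#' @export
avg_clustering <- function(net) {
  stopifnot(igraph::is_igraph(net))
  if (igraph::vcount(net) == 0L) stop("empty network")
  mean(igraph::transitivity(net, type = "local", isolates = "zero"))
}

#' Topology report for a miRNA functional network
#'
#' Collects node/edge counts, the degree histogram, raw-count and
#' probability-normalized power-law fits, characteristic path length and
#' average clustering coefficient. Optionally adds an Erdos-Renyi
#' G(n, m) baseline with the same node and edge counts.
#'
#' @param net an \code{igraph} graph from [build_network()].
#' @param er_baseline add random-graph comparison statistics.
#' @param er_replicates number of random graphs for the baseline.
#' @param seed RNG seed for the baseline graphs.
#' @return a list of class \code{topology_report}.
#' @export
topology_report <- function(net, er_baseline = FALSE, er_replicates = 10,
                            seed = 1L) {
  stopifnot(igraph::is_igraph(net))
  deg <- igraph::degree(net)
  hist <- table(deg[deg > 0])
  rep <- list(
    n_nodes = igraph::vcount(net),
    n_edges = igraph::ecount(net),
    degree_histogram = stats::setNames(as.integer(hist), names(hist)),
    characteristic_path_length = characteristic_path_length(net),
    avg_clustering_coefficient = avg_clustering(net))
  pl <- tryCatch(power_law_fit(hist), error = function(e) NULL)
  if (!is.null(pl)) {
    rep$power_law_slope <- pl$slope
    rep$power_law_r2 <- pl$r2
    pln <- power_law_fit(hist, normalized = TRUE)
    rep$power_law_slope_normalized <- pln$slope
    rep$power_law_r2_normalized <- pln$r2
  }
  if (er_baseline) {
    stats_er <- withr::with_seed(seed, {
      vapply(seq_len(er_replicates), function(k) {
        g <- igraph::sample_gnm(rep$n_nodes, rep$n_edges)
        c(path = characteristic_path_length(g), clust = avg_clustering(g))
      }, numeric(2))
    })
    rep$er_baseline <- list(
      path_length_mean = mean(stats_er["path", ]),
      path_length_sd = stats::sd(stats_er["path", ]),
      clustering_mean = mean(stats_er["clust", ]),
      clustering_sd = stats::sd(stats_er["clust", ]))
  }
  class(rep) <- "topology_report"
  rep
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf("miRNA network: %d nodes, %d edges\n", x$n_nodes, x$n_edges))
  if (!is.null(x$power_law_slope)) {
    cat(sprintf("  power-law fit: slope %.3f, R^2 %.3f\n",
                x$power_law_slope, x$power_law_r2))
  }
  cat(sprintf("  characteristic path length: %.3f\n",
              x$characteristic_path_length))
  cat(sprintf("  average clustering coefficient: %.3f\n",
              x$avg_clustering_coefficient))
  invisible(x)
}

#' Write a network's edges / report to disk
#'
#' \code{write_edge_list} writes \code{a<TAB>b<TAB>weight} rows;
#' \code{write_graphml} delegates to igraph's GraphML writer;
#' \code{write_topology_json} serializes a [topology_report()] to JSON.
#'
#' @param net an \code{igraph} graph.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_edge_list <- function(net, path) {
  df <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' @rdname write_edge_list
#' @param report a \code{topology_report}.
#' @export
write_topology_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
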