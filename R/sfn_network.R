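# Splice-Function Networks: the TU x FL contingency matrix, its projection
# onto weighted FL-FL co-occurrence graphs, and network statistics.

#' Build the TU-by-FL contingency matrix
#'
#' `cell(t, f)` = number of annotated splice-variant proteins of TU `t`
#' whose functional label is `f`. Stored in triplet (long) form; use
#' [as_contingency_matrix()] for a dense matrix on small data.
#'
#' @param dataset an `organism_dataset` with catalogue built.
#' @return A `contingency_matrix`: list with `cells` (data frame `tu_id`,
#'   `fl_id`, `count`), `tu_ids`, `fl_ids`.
#' @export
build_contingency <- function(dataset) {
  stopifnot(inherits(dataset, "organism_dataset"))
  if (is.null(dataset$catalogue)) stop("catalogue not built")
  p <- dataset$proteins
  ann <- p[!is.na(p$fl_id), c("tu_id", "fl_id"), drop = FALSE]
  if (nrow(ann)) {
    agg <- stats::aggregate(list(count = rep(1L, nrow(ann))),
                            by = ann[c("tu_id", "fl_id")], FUN = sum)
    agg <- agg[order(agg$tu_id, agg$fl_id, method = "radix"), ,
               drop = FALSE]
    rownames(agg) <- NULL
  } else {
    agg <- data.frame(tu_id = character(0), fl_id = character(0),
                      count = integer(0))
  }
  structure(list(cells = agg,
                 tu_ids = dataset$tus$tu_id,
                 fl_ids = dataset$catalogue$table$fl_id),
            class = "contingency_matrix")
}

#' Densify a contingency matrix
#'
#' @param x a `contingency_matrix`.
#' @return Integer matrix, rows TUs, columns FLs.
#' @export
as_contingency_matrix <- function(x) {
  stopifnot(inherits(x, "contingency_matrix"))
  m <- matrix(0L, length(x$tu_ids), length(x$fl_ids),
              dimnames = list(x$tu_ids, x$fl_ids))
  if (nrow(x$cells))
    m[cbind(x$cells$tu_id, x$cells$fl_id)] <- x$cells$count
  m
}

#' @export
print.contingency_matrix <- function(x, ...) {
  cat("contingency_matrix:", length(x$tu_ids), "TUs x",
      length(x$fl_ids), "FLs,", nrow(x$cells), "nonzero cells\n")
  invisible(x)
}

#' Build the splice-function network
#'
#' Projects the polyform TU group onto the FL space: every unordered pair
#' of distinct FLs realized by the same polyform TU gains one unit of edge
#' weight, so an edge weight is the number of distinct polyform TUs shared
#' by the FL pair (regardless of how many isoform pairs realize it). Nodes
#' carry their `;`-joined keyword set as attribute `keywords`.
#'
#' @param dataset an `organism_dataset` with catalogue built.
#' @param include_isolated logical; also add catalogue FLs not incident to
#'   any edge as degree-0 nodes (the single-node aggregates surrounding the
#'   connected clusters).
#' @return An undirected weighted igraph object.
#' @export
build_sfn <- function(dataset, include_isolated = FALSE) {
  stopifnot(inherits(dataset, "organism_dataset"))
  if (is.null(dataset$catalogue)) stop("catalogue not built")
  tus <- dataset$tus
  poly <- tus$fls[tus$class == "polyform"]
  pair_keys <- unlist(lapply(poly, function(fls) {
    prs <- combn(fls, 2L)  # fls already sorted
    paste(prs[1L, ], prs[2L, ], sep = "\r")
  }))
  tab <- dataset$catalogue$table
  kw_of <- setNames(vapply(tab$keywords, paste, "", collapse = ";"),
                    tab$fl_id)
  g <- igraph::make_empty_graph(0, directed = FALSE)
  if (length(pair_keys)) {
    wt <- table(pair_keys)
    keys <- sort(names(wt), method = "radix")
    ends <- strsplit(keys, "\r", fixed = TRUE)
    nodes <- sort(unique(unlist(ends)), method = "radix")
    g <- igraph::add_vertices(g, length(nodes), name = nodes)
    g <- igraph::add_edges(g, unlist(ends))
    igraph::E(g)$weight <- as.integer(wt[keys])
  }
  if (include_isolated) {
    extra <- setdiff(tab$fl_id, igraph::V(g)$name)
    if (length(extra)) g <- igraph::add_vertices(g, length(extra),
                                                 name = extra)
  }
  if (igraph::vcount(g))
    igraph::V(g)$keywords <- unname(kw_of[igraph::V(g)$name])
  g
}

#' Network statistics of an SFN
#'
#' Summary used to compare organisms: node and edge counts, heterogeneity
#' (coefficient of variation of the degree sequence, population variance),
#' average number of neighbors (mean degree), the degree distribution over
#' connected nodes, and connected components.
#'
#' @param graph an igraph object (nonempty).
#' @return A `network_stats`: list with `n_nodes`, `n_edges`,
#'   `heterogeneity`, `avg_neighbors`, `degree_distribution` (`freq_dist`
#'   over degrees `>= 1`, or `NULL` if all nodes are isolated),
#'   `n_components`, `component_sizes`.
#' @export
network_stats <- function(graph) {
  stopifnot(inherits(graph, "igraph"))
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  deg <- igraph::degree(graph)
  mu <- mean(deg)
  het <- if (mu > 0) sqrt(mean(deg^2) - mu^2) / mu else 0
  comp <- igraph::components(graph)
  pos <- deg[deg >= 1L]
  structure(list(
    n_nodes = igraph::vcount(graph),
    n_edges = igraph::ecount(graph),
    heterogeneity = het,
    avg_neighbors = mu,
    degree_distribution = if (length(pos)) freq_distribution(pos) else NULL,
    n_components = comp$no,
    component_sizes = sort(as.integer(comp$csize), decreasing = TRUE)),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf("network_stats: %d nodes, %d edges, heterogeneity %.3f, avg neighbors %.3f, %d components\n",
              x$n_nodes, x$n_edges, x$heterogeneity, x$avg_neighbors,
              x$n_components))
  invisible(x)
}

#' Rank functional-label hubs of an SFN
#'
#' FLs sorted by degree (number of distinct neighbor FLs) descending, ties
#' broken by `fl_id`; the weighted degree (sum of shared-TU edge weights)
#' is reported alongside.
#'
#' @param graph an igraph object from [build_sfn()].
#' @param n maximum number of hubs to return (`>= 1`).
#' @return Data frame `fl_id`, `degree`, `weighted_degree`, `keywords`.
#' @export
rank_hubs <- function(graph, n) {
  stopifnot(inherits(graph, "igraph"), n >= 1)
  if (igraph::vcount(graph) == 0L)
    return(data.frame(fl_id = character(0), degree = integer(0),
                      weighted_degree = numeric(0),
                      keywords = character(0)))
  deg <- igraph::degree(graph)
  w <- if (igraph::ecount(graph) && !is.null(igraph::E(graph)$weight))
    igraph::strength(graph, weights = igraph::E(graph)$weight)
  else deg
  kw <- if (!is.null(igraph::V(graph)$keywords)) igraph::V(graph)$keywords
        else rep(NA_character_, length(deg))
  ord <- order(-deg, names(deg), method = "radix")
  k <- min(as.integer(n), length(deg))
  idx <- ord[seq_len(k)]
  data.frame(fl_id = names(deg)[idx], degree = as.integer(deg[idx]),
             weighted_degree = as.numeric(w[idx]), keywords = kw[idx],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write SFN statistics and hub tables as TSV
#'
#' @param stats a `network_stats`.
#' @param path output path.
#' @param organism organism name for the report row.
#' @export
write_network_stats <- function(stats, path, organism = "") {
  df <- data.frame(organism = organism, n_nodes = stats$n_nodes,
                   n_edges = stats$n_edges,
                   heterogeneity = stats$heterogeneity,
                   avg_neighbors = stats$avg_neighbors,
                   n_components = stats$n_components)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
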