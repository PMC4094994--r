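#' Newman modularity of a partition
#'
#' Computes \eqn{Q = \sum_k (e_{kk} - a_k^2)}, where \eqn{e_{kk}} is the
#' fraction of edges with both endpoints in module \eqn{C_k} and \eqn{a_k}
#' is the fraction of edge ends attached to nodes of \eqn{C_k}. The
#' one-module partition has \eqn{Q = 0} for every graph; \eqn{K} equal-sized
#' disjoint modules attain the maximum \eqn{1 - 1/K}.
#'
#' @param graph An igraph object, 2-column edge matrix, or from/to data
#'   frame. Must have at least one edge.
#' @param partition Integer membership vector (module of node `i` at position
#'   `i`, labels in `1..K`) or a tibble with `node` and `module` columns.
#' @return Modularity `Q` as a single number.
#' @examples
#' g <- igraph::make_full_graph(3) + igraph::make_full_graph(3)
#' modularity_q(g, c(1, 1, 1, 2, 2, 2)) # 1/2: two disjoint triangles
#' @export
modularity_q <- function(graph, partition) {
  gd <- as_graph_data(graph)
  m <- nrow(gd$edges)
  if (m == 0L) abort_input("Modularity is undefined for a graph with no edges.")
  mem <- as_membership(partition, gd$n)
  K <- max(mem)
  k1 <- mem[gd$edges[, 1L]]
  k2 <- mem[gd$edges[, 2L]]
  e_kk <- tabulate(k1[k1 == k2], nbins = K) / m
  deg <- degree_from_edges(gd$edges, gd$n)
  a_k <- as.numeric(rowsum(deg, mem, reorder = TRUE)) / (2 * m)
  sum(e_kk - a_k^2)
}

#' Structural metrics of a graph
#'
#' `degree_assortativity()` is the Pearson correlation of the degrees at the
#' two ends of each edge (each edge counted in both orientations); it is
#' undefined (NaN, with a warning) on regular graphs. `clustering_coefficient()`
#' defaults to the mean local clustering coefficient with nodes of degree < 2
#' contributing 0; `type = "global"` gives transitivity (triangle density).
#' `average_path_length()` is the mean shortest-path length over unordered
#' node pairs; on a disconnected graph it is computed on the largest
#' component with a warning. `graph_metrics()` bundles all three (plus `Q`
#' when a partition is given) into a one-row tibble.
#'
#' @inheritParams modularity_q
#' @param type `"local"` (mean local clustering, default) or `"global"`
#'   (transitivity).
#' @param partition Optional partition for the modularity column.
#' @return A single numeric value; `graph_metrics()` returns a one-row
#'   tibble with columns `n`, `m`, `q` (if a partition is given),
#'   `assortativity`, `clustering`, `path_length`.
#' @examples
#' g <- igraph::make_star(4, mode = "undirected")
#' degree_assortativity(g) # -1
#' clustering_coefficient(g) # 0
#' average_path_length(igraph::make_full_graph(4)) # 1
#' @name structural_metrics
NULL

as_igraph_obj <- function(graph, n = NULL) {
  if (igraph::is_igraph(graph)) return(graph)
  gd <- as_graph_data(graph, n)
  graph_from_edges(gd$edges, gd$n)
}

#' @rdname structural_metrics
#' @export
degree_assortativity <- function(graph) {
  g <- as_igraph_obj(graph)
  if (igraph::ecount(g) < 1L) abort_input("Assortativity needs at least one edge.")
  r <- suppressWarnings(igraph::assortativity_degree(g))
  if (is.nan(r) || is.na(r)) {
    warn("Degree assortativity is undefined (no degree variance at edge endpoints); returning NaN.")
    return(NaN)
  }
  r
}

#' @rdname structural_metrics
#' @export
clustering_coefficient <- function(graph, type = c("local", "global")) {
  type <- match.arg(type)
  g <- as_igraph_obj(graph)
  if (type == "local") {
    igraph::transitivity(g, type = "localaverage", isolates = "zero")
  } else {
    igraph::transitivity(g, type = "global")
  }
}

#' @rdname structural_metrics
#' @export
average_path_length <- function(graph) {
  g <- as_igraph_obj(graph)
  comps <- igraph::components(g)
  if (comps$no > 1L) {
    warn(sprintf(
      "Graph is disconnected (%d components); average path length computed on the largest component.",
      comps$no
    ))
    keep <- which(comps$membership == which.max(comps$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  igraph::mean_distance(g)
}

#' @rdname structural_metrics
#' @export
graph_metrics <- function(graph, partition = NULL, type = c("local", "global")) {
  g <- as_igraph_obj(graph)
  out <- tibble(
    n = igraph::vcount(g),
    m = igraph::ecount(g)
  )
  if (!is.null(partition)) out$q <- modularity_q(g, partition)
  out$assortativity <- suppressWarnings(degree_assortativity(g))
  out$clustering <- clustering_coefficient(g, type)
  out$path_length <- suppressWarnings(average_path_length(g))
  out
}
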