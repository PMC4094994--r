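# Internal helpers: edge storage, membership coercion, structured conditions.
#
# Edges are stored as a 2-column integer matrix of canonical unordered pairs
# (column 1 < column 2, 1-based node ids). Canonical storage makes multi-edge
# detection and file output deterministic.

abort_input <- function(msg, ...) abort(msg, class = "modgraph_input_error", ...)
abort_feasibility <- function(msg, ...) abort(msg, class = "modgraph_feasibility_error", ...)
abort_sampling <- function(msg, ...) abort(msg, class = "modgraph_sampling_error", ...)
abort_wiring <- function(msg, ...) abort(msg, class = "modgraph_wiring_error", ...)

canonical_edges <- function(from, to) {
  lo <- pmin(from, to)
  hi <- pmax(from, to)
  cbind(lo, hi, deparse.level = 0L)
}

# Sort canonical edge matrix lexicographically (for deterministic output).
sort_edges <- function(edges) {
  if (nrow(edges) == 0L) return(edges)
  edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
}

edge_key <- function(i, j, n) (pmin(i, j) - 1) * n + pmax(i, j)

# Mutable edge set with O(1) membership tests, backed by an environment.
new_edge_set <- function(edges, n) {
  env <- new.env(parent = emptyenv(), size = max(64L, 2L * nrow(edges)))
  if (nrow(edges) > 0L) {
    keys <- as.character(edge_key(edges[, 1L], edges[, 2L], n))
    for (k in keys) assign(k, TRUE, envir = env)
  }
  list(env = env, n = n)
}

es_has <- function(set, i, j) {
  exists(as.character(edge_key(i, j, set$n)), envir = set$env, inherits = FALSE)
}

es_add <- function(set, i, j) {
  assign(as.character(edge_key(i, j, set$n)), TRUE, envir = set$env)
}

es_remove <- function(set, i, j) {
  rm(list = as.character(edge_key(i, j, set$n)), envir = set$env)
}

# Accept an igraph, a 2-column matrix, or a data frame with from/to columns;
# return list(n = node count, edges = canonical integer matrix).
as_graph_data <- function(graph, n = NULL) {
  if (igraph::is_igraph(graph)) {
    el <- igraph::as_edgelist(graph, names = FALSE)
    storage.mode(el) <- "integer"
    return(list(n = igraph::vcount(graph), edges = canonical_edges(el[, 1L], el[, 2L])))
  }
  if (is.data.frame(graph)) {
    if (!all(c("from", "to") %in% names(graph))) {
      abort_input("Edge data frames need `from` and `to` columns.")
    }
    el <- cbind(as.integer(graph$from), as.integer(graph$to))
  } else if (is.matrix(graph) && ncol(graph) == 2L) {
    el <- graph
    storage.mode(el) <- "integer"
  } else {
    abort_input("`graph` must be an igraph object, a 2-column edge matrix, or a from/to data frame.")
  }
  if (nrow(el) > 0L && any(el[, 1L] == el[, 2L])) abort_input("Self loops are not allowed.")
  edges <- canonical_edges(el[, 1L], el[, 2L])
  n <- n %||% if (nrow(edges) > 0L) max(edges) else 0L
  if (nrow(edges) > 0L && (min(edges) < 1L || max(edges) > n)) {
    abort_input("Edge endpoints must be node ids in [1, n].")
  }
  list(n = as.integer(n), edges = edges)
}

edges_to_igraph <- function(edges, n) {
  igraph::graph_from_edgelist(edges, directed = FALSE) |>
    igraph::add_vertices(max(0L, n - max(edges, 0L)))
}

graph_from_edges <- function(edges, n) {
  if (nrow(edges) == 0L) {
    return(igraph::make_empty_graph(n = n, directed = FALSE))
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  g
}

# Accept a membership integer vector or a tibble(node, module); return an
# integer vector indexed by node id 1..n with values 1..K.
as_membership <- function(partition, n = NULL) {
  if (is.data.frame(partition)) {
    if (!all(c("node", "module") %in% names(partition))) {
      abort_input("Partition data frames need `node` and `module` columns.")
    }
    n <- n %||% max(partition$node)
    if (anyDuplicated(partition$node) > 0L) abort_input("Each node must have exactly one module label.")
    if (nrow(partition) < n || any(partition$node < 1L) || any(partition$node > n)) {
      abort_input("Partition must cover node ids 1..n exactly once.")
    }
    mem <- integer(n)
    mem[partition$node] <- as.integer(partition$module)
    return(mem)
  }
  mem <- as.integer(partition)
  if (!is.null(n) && length(mem) != n) {
    abort_input(sprintf("Partition covers %d nodes but the graph has %d.", length(mem), n))
  }
  if (anyNA(mem) || any(mem < 1L)) abort_input("Module labels must be positive integers.")
  mem
}

partition_tbl <- function(membership) {
  tibble(node = seq_along(membership), module = as.integer(membership))
}

degree_from_edges <- function(edges, n) {
  tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
}
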