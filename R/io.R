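# Readers and writers: edge lists (0-based, whitespace-separated), partition
# TSVs (node TAB module, modules 1-based), GML/GraphML via igraph, and the
# three-file output bundle of a generation run.

#' Read and write graphs and partitions
#'
#' Edge-list files contain one edge per line as two whitespace-separated
#' 0-based node indices; comment lines start with `#` and the writer records
#' the node count as `# n=<n>` so isolated trailing nodes survive a round
#' trip. Duplicate edges and self loops found on input are dropped with a
#' warning. Partition files are TSVs with one line per node: 0-based node
#' index, TAB, 1-based module index. GML and GraphML are read and written
#' through igraph (nodes and edges only).
#'
#' @param path File path.
#' @param graph An igraph object, edge matrix or from/to data frame.
#' @param format One of `"edgelist"`, `"gml"`, `"graphml"`; default guessed
#'   from the file extension.
#' @param partition Membership vector or `node`/`module` tibble.
#' @return `read_graph_file()` returns an igraph object; `read_partition()`
#'   a tibble with `node` (1-based) and `module` columns; writers return the
#'   path invisibly.
#' @name graph_io
NULL

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
    gml = "gml",
    graphml = "graphml",
    "edgelist"
  )
}

#' @rdname graph_io
#' @export
read_graph_file <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format %in% c("gml", "graphml")) {
    g <- igraph::read_graph(path, format = format)
    g <- igraph::as_undirected(g, mode = "collapse")
    before <- igraph::ecount(g)
    g <- igraph::simplify(g)
    dropped <- before - igraph::ecount(g)
    if (dropped > 0L) {
      warn(sprintf("Dropped %d duplicate/self-loop edge(s) while reading %s.", dropped, path))
    }
    return(g)
  }
  lines <- readLines(path)
  n_declared <- NA_integer_
  header <- grep("^#", lines, value = TRUE)
  n_line <- grep("^#\\s*n\\s*=", header, value = TRUE)
  if (length(n_line) > 0L) {
    n_declared <- as.integer(sub("^#\\s*n\\s*=\\s*", "", n_line[1L]))
  }
  body <- grep("^\\s*(#|$)", lines, invert = TRUE)
  if (length(body) == 0L) {
    if (is.na(n_declared)) abort_input(sprintf("%s has no edges and no '# n=' header.", path))
    return(igraph::make_empty_graph(n = n_declared, directed = FALSE))
  }
  parts <- strsplit(trimws(lines[body]), "\\s+")
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    abort_input(sprintf("Parse error in %s at line %d: expected two node indices.", path, body[bad[1L]]))
  }
  el <- matrix(as.integer(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(el)) {
    abort_input(sprintf("Parse error in %s: non-integer node index.", path))
  }
  el <- el + 1L # file is 0-based
  n <- max(el, n_declared, na.rm = TRUE)
  loops <- el[, 1L] == el[, 2L]
  if (any(loops)) {
    warn(sprintf("Dropped %d self loop(s) while reading %s.", sum(loops), path))
    el <- el[!loops, , drop = FALSE]
  }
  edges <- canonical_edges(el[, 1L], el[, 2L])
  dup <- duplicated(edge_key(edges[, 1L], edges[, 2L], n))
  if (any(dup)) {
    warn(sprintf("Dropped %d duplicate edge(s) while reading %s.", sum(dup), path))
    edges <- edges[!dup, , drop = FALSE]
  }
  graph_from_edges(edges, n)
}

#' @rdname graph_io
#' @export
write_graph_file <- function(graph, path, format = NULL) {
  format <- format %||% guess_format(path)
  if (format %in% c("gml", "graphml")) {
    g <- as_igraph_obj(graph)
    igraph::write_graph(g, path, format = format)
    return(invisible(path))
  }
  gd <- as_graph_data(graph)
  edges <- sort_edges(gd$edges) - 1L # 0-based on disk
  lines <- c(
    "# modgraph edge list (0-based node indices)",
    sprintf("# n=%d", gd$n),
    sprintf("%d %d", edges[, 1L], edges[, 2L])
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname graph_io
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", comment.char = "#",
    col.names = c("node", "module"), colClasses = "integer"
  )
  tibble(node = df$node + 1L, module = df$module) |>
    dplyr::arrange(.data$node)
}

#' @rdname graph_io
#' @export
write_partition <- function(partition, path) {
  mem <- as_membership(partition)
  lines <- c(
    "# modgraph partition (0-based node index TAB 1-based module index)",
    sprintf("%d\t%d", seq_along(mem) - 1L, mem)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write a generation result as a file bundle
#'
#' Writes `<prefix>.edgelist` (sorted canonical edges),
#' `<prefix>.partition.tsv`, and `<prefix>.meta` (target and achieved
#' modularity, seed, attempts, and a spec echo, in YAML). Output is
#' deterministic: the same result writes byte-identical files.
#'
#' @param result A `modular_graph` from [generate_modular_graph()].
#' @param out_prefix Path prefix for the three files.
#' @return Character vector of the written paths, invisibly.
#' @export
write_result <- function(result, out_prefix) {
  if (!inherits(result, "modular_graph")) abort_input("`result` must be a modular_graph.")
  paths <- paste0(out_prefix, c(".edgelist", ".partition.tsv", ".meta"))
  write_graph_file(as.matrix(result$edges[, c("from", "to")]), paths[1L])
  write_partition(result$partition, paths[2L])
  spec <- result$spec
  meta <- list(
    n = spec$n,
    modules = spec$modules,
    degree_family = spec$degree$family,
    degree_mean = spec$degree$mean,
    target_q = result$target_q,
    achieved_q = result$achieved_q,
    epsilon = spec$epsilon,
    swaps_per_edge = spec$swaps_per_edge,
    attempts = result$attempts,
    seed = result$seed %||% "none",
    edges = nrow(result$edges),
    within_edge_fraction = mean(result$edges$class == "within")
  )
  writeLines(yaml::as.yaml(meta, precision = 15L), paths[3L])
  invisible(paths)
}
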