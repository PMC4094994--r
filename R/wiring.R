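# Edge realization from degree triples: modified Havel-Hakimi for
# between-edges, standard Havel-Hakimi per module for within-edges,
# constrained double-edge swaps, and degree-preserving connectivity repair.

#' Wire between-edges from a between-degree sequence
#'
#' Realizes the between-edge set of a planted partition with a modified
#' Havel–Hakimi construction: nodes are sorted primarily by their module's
#' total residual between-degree (descending) and secondarily by their own
#' residual between-degree (descending); the top node is connected to
#' uniformly random eligible partners until its residual is exhausted, the
#' list is re-sorted, and the process repeats. A partner is eligible if it
#' has positive residual, lives in a different module, is not already a
#' neighbor, and the two nodes do not both have within-degree zero (a guard
#' against disconnected components). On a stall the construction restarts
#' with fresh randomness.
#'
#' @param triples Degree-triple tibble from [sample_within_degrees()]
#'   (columns `node`, `module`, `degree`, `within_degree`, `between_degree`).
#' @param max_restarts Construction restarts before giving up.
#' @return Integer edge matrix (2 columns, canonical node pairs).
#' @export
connect_between_edges <- function(triples, max_restarts = 50) {
  n <- nrow(triples)
  membership <- triples$module
  d_b <- as.integer(triples$between_degree)
  d_w <- as.integer(triples$within_degree)
  if (sum(d_b) == 0L) return(matrix(integer(0), ncol = 2L))
  for (restart in seq_len(max_restarts)) {
    res <- attempt_between_wiring(d_b, d_w, membership, n)
    if (!is.null(res)) return(res)
  }
  abort_wiring(sprintf("Between-edge wiring stalled %d times; within-degrees must be re-sampled.", max_restarts))
}

attempt_between_wiring <- function(d_b, d_w, membership, n) {
  res <- d_b
  edges_from <- integer(sum(d_b) / 2L)
  edges_to <- integer(length(edges_from))
  n_edges <- 0L
  neigh <- vector("list", n) # adjacency restricted to this construction

  add_edge <- function(a, b) {
    n_edges <<- n_edges + 1L
    edges_from[n_edges] <<- a
    edges_to[n_edges] <<- b
    neigh[[a]] <<- c(neigh[[a]], b)
    neigh[[b]] <<- c(neigh[[b]], a)
    res[a] <<- res[a] - 1L
    res[b] <<- res[b] - 1L
  }

  # End-game jam repair: absorb one stub each of u and w (w may equal u when
  # res[u] >= 2) by splitting an existing between-edge (x, y) into (u, x)
  # and (w, y). Degrees of x and y are unchanged; u and w each lose a stub.
  # Valid (edge, orientation) pairs are enumerated vectorially, so a repair
  # is found whenever one exists.
  repair_with <- function(u, w) {
    idx <- seq_len(n_edges)
    ef <- edges_from[idx]
    et <- edges_to[idx]
    nu <- logical(n); nu[neigh[[u]]] <- TRUE
    nw <- logical(n); nw[neigh[[w]]] <- TRUE
    base <- ef != u & et != u & ef != w & et != w
    ok_x <- function(x) membership[x] != membership[u] & !nu[x] & !(d_w[x] == 0L & d_w[u] == 0L)
    ok_y <- function(y) membership[y] != membership[w] & !nw[y] & !(d_w[y] == 0L & d_w[w] == 0L)
    cand1 <- which(base & ok_x(ef) & ok_y(et))
    cand2 <- which(base & ok_x(et) & ok_y(ef))
    total <- length(cand1) + length(cand2)
    if (total == 0L) return(FALSE)
    pick <- sample.int(total, 1L)
    if (pick <= length(cand1)) {
      e <- cand1[pick]; x <- edges_from[e]; y <- edges_to[e]
    } else {
      e <- cand2[pick - length(cand1)]; x <- edges_to[e]; y <- edges_from[e]
    }
    # drop (x, y); slot e becomes (u, x), (w, y) is appended
    neigh[[x]] <<- neigh[[x]][neigh[[x]] != y]
    neigh[[y]] <<- neigh[[y]][neigh[[y]] != x]
    edges_from[e] <<- u
    edges_to[e] <<- x
    neigh[[u]] <<- c(neigh[[u]], x)
    neigh[[x]] <<- c(neigh[[x]], u)
    res[u] <<- res[u] - 1L
    n_edges <<- n_edges + 1L
    edges_from[n_edges] <<- w
    edges_to[n_edges] <<- y
    neigh[[w]] <<- c(neigh[[w]], y)
    neigh[[y]] <<- c(neigh[[y]], w)
    res[w] <<- res[w] - 1L
    TRUE
  }

  repair_jam <- function(u) {
    if (res[u] >= 2L && repair_with(u, u)) return(TRUE)
    others <- which(res > 0L)
    others <- others[others != u]
    if (length(others) == 0L) return(res[u] >= 2L && FALSE)
    for (w in others[sample.int(length(others), min(length(others), 5L))]) {
      if (repair_with(u, w)) return(TRUE)
    }
    FALSE
  }

  while (any(res > 0L)) {
    mod_tot <- as.numeric(rowsum(res, membership, reorder = TRUE))
    node_rank <- order(-mod_tot[membership], -res)
    u <- node_rank[which(res[node_rank] > 0L)[1L]]
    while (res[u] > 0L) {
      elig <- which(
        res > 0L &
          membership != membership[u] &
          !(d_w == 0L & d_w[u] == 0L)
      )
      elig <- elig[elig != u]
      if (length(neigh[[u]]) > 0L) elig <- elig[!(elig %in% neigh[[u]])]
      if (length(elig) == 0L && d_w[u] == 0L) {
        # the within-degree guard exists to discourage disconnected
        # components; when it leaves no partner at all (e.g. singleton
        # modules) it is relaxed and connectivity is repaired afterwards
        elig <- which(res > 0L & membership != membership[u])
        elig <- setdiff(elig, c(u, neigh[[u]]))
      }
      if (length(elig) == 0L) {
        if (n_edges == 0L || !repair_jam(u)) return(NULL) # stall
        next
      }
      # random eligible partner, chosen stub-wise (probability proportional
      # to residual between-degree, as in configuration-model matching)
      v <- if (length(elig) == 1L) {
        elig
      } else {
        elig[sample.int(length(elig), 1L, prob = res[elig])]
      }
      add_edge(u, v)
    }
  }
  canonical_edges(edges_from[seq_len(n_edges)], edges_to[seq_len(n_edges)])
}

#' Wire within-edges module by module
#'
#' Realizes each module's within-edge set independently with the standard
#' Havel–Hakimi construction: repeatedly take the node of highest residual
#' within-degree and connect it to the nodes of next-highest residual.
#' Partners where both nodes have between-degree zero are avoided while
#' possible (the same disconnectedness guard as in the between stage); if
#' the guarded construction stalls, it is retried with random tie-breaking
#' and finally without the guard (global connectivity is restored
#' afterwards by [ensure_global_connectivity()]). For a single-module graph
#' the guard does not apply.
#'
#' @inheritParams connect_between_edges
#' @return Integer edge matrix (2 columns, canonical node pairs).
#' @export
connect_within_edges <- function(triples, max_restarts = 50) {
  membership <- triples$module
  K <- max(membership)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    idx <- which(membership == k)
    d_w <- as.integer(triples$within_degree[idx])
    d_b <- as.integer(triples$between_degree[idx])
    if (sum(d_w) == 0L) {
      out[[k]] <- matrix(integer(0), ncol = 2L)
      next
    }
    guard <- K > 1L
    edges <- NULL
    for (restart in seq_len(max_restarts)) {
      edges <- hh_module(d_w, d_b, guard = guard && restart <= max_restarts / 2)
      if (!is.null(edges)) break
    }
    if (is.null(edges)) {
      abort_wiring(sprintf("Within-edge wiring stalled in module %d.", k))
    }
    out[[k]] <- cbind(idx[edges[, 1L]], idx[edges[, 2L]], deparse.level = 0L)
  }
  edges <- do.call(rbind, out)
  if (nrow(edges) == 0L) return(matrix(integer(0), ncol = 2L))
  canonical_edges(edges[, 1L], edges[, 2L])
}

# Standard Havel-Hakimi on one module (local indices); returns NULL on stall.
hh_module <- function(d_w, d_b, guard = FALSE) {
  s <- length(d_w)
  res <- d_w
  neigh <- vector("list", s)
  edges_from <- integer(sum(d_w) / 2L)
  edges_to <- integer(length(edges_from))
  n_edges <- 0L
  while (any(res > 0L)) {
    # node of highest residual, random among ties
    mx <- max(res)
    top <- which(res == mx)
    u <- if (length(top) == 1L) top else top[sample.int(length(top), 1L)]
    cand <- setdiff(which(res > 0L), c(u, neigh[[u]]))
    if (guard && d_b[u] == 0L) cand <- cand[d_b[cand] > 0L]
    if (length(cand) < res[u]) return(NULL)
    # next-highest residuals first, ties broken at random
    cand <- cand[order(-res[cand], runif(length(cand)))]
    targets <- cand[seq_len(res[u])]
    for (v in targets) {
      n_edges <- n_edges + 1L
      edges_from[n_edges] <- u
      edges_to[n_edges] <- v
      neigh[[u]] <- c(neigh[[u]], v)
      neigh[[v]] <- c(neigh[[v]], u)
      res[v] <- res[v] - 1L
    }
    res[u] <- 0L
  }
  canonical_edges(edges_from, edges_to)
}

#' Randomize an edge set by degree-preserving double-edge swaps
#'
#' Repeatedly picks two random edges `(u,v)` and `(x,y)` and replaces them
#' with `(u,x)` and `(v,y)`. A proposal is rejected (and retried) if it
#' would create a self loop or a multi-edge, or — when `membership` is
#' given and the edges are between-class — if either new edge would fall
#' inside one module. Swaps preserve every node's degree and, for
#' class-pure input, the planted partition's within/between edge counts and
#' hence its modularity.
#'
#' @param edges Integer edge matrix (2 columns) of a single class: all
#'   between-edges, or the within-edges of one module.
#' @param n Number of nodes in the graph (for edge hashing).
#' @param n_swaps Number of accepted swaps to perform.
#' @param membership Optional module membership vector; supply it when
#'   `edges` are between-class so the class constraint is enforced.
#' @param attempt_factor Attempt budget as a multiple of `n_swaps`; if the
#'   budget is exhausted first, a warning is raised and the current state
#'   returned.
#' @return The randomized edge matrix (canonical pairs).
#' @export
double_edge_swap <- function(edges, n, n_swaps, membership = NULL, attempt_factor = 100) {
  m <- nrow(edges)
  if (m < 2L || n_swaps <= 0L) return(edges)
  between <- !is.null(membership)
  n_swaps <- as.integer(n_swaps)
  budget <- as.integer(attempt_factor) * n_swaps

  # Adjacency as a flat logical vector for O(1) scalar lookups; fall back to
  # an environment hash when n^2 would be too large to allocate.
  nn <- as.double(n) * n
  use_vec <- nn <= 16e6
  if (use_vec) {
    adj <- logical(nn)
    adj[(edges[, 1L] - 1) * n + edges[, 2L]] <- TRUE
  } else {
    set <- new_edge_set(edges, n)
  }
  has <- function(a, b) {
    k <- if (a < b) (a - 1) * n + b else (b - 1) * n + a
    if (use_vec) adj[k] else exists(as.character(k), envir = set$env, inherits = FALSE)
  }
  put <- function(a, b, val) {
    k <- if (a < b) (a - 1) * n + b else (b - 1) * n + a
    if (use_vec) {
      adj[k] <<- val
    } else if (val) {
      assign(as.character(k), TRUE, envir = set$env)
    } else {
      rm(list = as.character(k), envir = set$env)
    }
  }

  accepted <- 0L
  attempts <- 0L
  while (accepted < n_swaps && attempts < budget) {
    chunk <- min(4096L, budget - attempts)
    i1 <- sample.int(m, chunk, replace = TRUE)
    i2 <- sample.int(m, chunk, replace = TRUE)
    flip <- runif(chunk) < 0.5
    for (t in seq_len(chunk)) {
      attempts <- attempts + 1L
      i <- i1[t]; j <- i2[t]
      if (i == j) next
      u <- edges[i, 1L]; v <- edges[i, 2L]
      if (flip[t]) { x <- edges[j, 2L]; y <- edges[j, 1L] } else { x <- edges[j, 1L]; y <- edges[j, 2L] }
      if (u == x || u == y || v == x || v == y) next
      if (between && (membership[u] == membership[x] || membership[v] == membership[y])) next
      if (has(u, x) || has(v, y)) next
      put(u, v, FALSE)
      put(x, y, FALSE)
      put(u, x, TRUE)
      put(v, y, TRUE)
      edges[i, 1L] <- if (u < x) u else x
      edges[i, 2L] <- if (u < x) x else u
      edges[j, 1L] <- if (v < y) v else y
      edges[j, 2L] <- if (v < y) y else v
      accepted <- accepted + 1L
      if (accepted >= n_swaps) break
    }
  }
  if (accepted < n_swaps) {
    warn(sprintf(
      "Only %d of %d requested double-edge swaps accepted within the attempt budget.",
      accepted, n_swaps
    ))
  }
  edges
}

#' Make one module's within-edge subgraph connected (Taylor rewiring)
#'
#' Degree-preserving connectivity repair within a module: while the
#' module's within-edge subgraph is disconnected, pick edges `(u,v)` and
#' `(x,y)` in two different components and replace them with `(u,x)` and
#' `(v,y)` (always simple across components). Each rewire merges two
#' components, so the subgraph becomes connected in at most
#' `#components - 1` steps whenever the within-degree sequence admits a
#' connected realization (at least `s_k - 1` within-edges and no
#' within-isolated node).
#'
#' @param edges Integer edge matrix of one module's within-edges (global
#'   node ids).
#' @param nodes Integer vector of the module's node ids.
#' @param n Number of nodes in the full graph (for hashing).
#' @return Rewired edge matrix with the same degree sequence, connected on
#'   `nodes`.
#' @export
connect_module_taylor <- function(edges, nodes, n) {
  s <- length(nodes)
  if (s <= 1L) return(edges)
  if (nrow(edges) < s - 1L) {
    abort_wiring(sprintf(
      "Module has %d within-edges but needs at least %d for connectivity.", nrow(edges), s - 1L
    ))
  }
  touched <- unique(as.integer(edges))
  if (length(setdiff(nodes, touched)) > 0L) {
    abort_wiring("Module has within-isolated nodes; a connected realization is impossible.")
  }
  guard <- 0L
  repeat {
    comp <- component_labels(edges, nodes)
    if (max(comp) == 1L) return(edges)
    guard <- guard + 1L
    if (guard > 20L * nrow(edges)) {
      abort_wiring("Module connectivity rewiring budget exhausted.")
    }
    comp_of_edge <- comp[match(edges[, 1L], nodes)]
    # One random edge from the smallest component, one from any other.
    c_src <- which.min(tabulate(comp))
    own <- which(comp_of_edge == c_src)
    other <- which(comp_of_edge != c_src)
    i <- own[sample.int(length(own), 1L)]
    j <- other[sample.int(length(other), 1L)]
    u <- edges[i, 1L]; v <- edges[i, 2L]
    x <- edges[j, 1L]; y <- edges[j, 2L]
    # Cross-component pairs can never pre-exist, so the rewire stays simple.
    edges[i, ] <- c(min(u, x), max(u, x))
    edges[j, ] <- c(min(v, y), max(v, y))
  }
}

# Connected-component labels (1-based) of the subgraph induced on `nodes`
# by `edges`; thin wrapper over igraph's component finder.
component_labels <- function(edges, nodes) {
  a <- match(edges[, 1L], nodes)
  b <- match(edges[, 2L], nodes)
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  if (igraph::vcount(g) < length(nodes)) {
    g <- igraph::add_vertices(g, length(nodes) - igraph::vcount(g))
  }
  as.integer(igraph::components(g)$membership)
}

#' Repair global connectivity by cross-component same-class swaps
#'
#' If the wired graph is disconnected, merges components with
#' degree-preserving double-edge swaps that keep every edge's class: two
#' between-edges in different components are swapped when both replacement
#' edges still cross modules; two within-edges of the same module in
#' different components are swapped likewise. Per-node within- and
#' between-degree counts are unchanged. If no class-compatible swap exists
#' the caller must regenerate.
#'
#' @param edges Full edge matrix (canonical pairs).
#' @param triples Degree-triple tibble (for module labels).
#' @param max_iter Swap attempts before signalling failure.
#' @return Edge matrix of a connected graph with identical degree triples.
#' @export
ensure_global_connectivity <- function(edges, triples, max_iter = 500) {
  n <- nrow(triples)
  membership <- triples$module
  comp <- component_labels(edges, seq_len(n))
  C <- max(comp)
  if (C == 1L) return(edges)
  is_between <- membership[edges[, 1L]] != membership[edges[, 2L]]

  # Propose a class-compatible swap between an edge of the smallest
  # component and one outside it; NULL if none exists after a few draws.
  propose <- function(own, other, between) {
    if (length(own) == 0L || length(other) == 0L) return(NULL)
    for (t in seq_len(20L)) {
      i <- own[sample.int(length(own), 1L)]
      j <- other[sample.int(length(other), 1L)]
      u <- edges[i, 1L]; v <- edges[i, 2L]
      for (orient in sample.int(2L)) {
        x <- edges[j, orient]; y <- edges[j, 3L - orient]
        if (between) {
          if (membership[u] == membership[x] || membership[v] == membership[y]) next
        } else {
          if (membership[u] != membership[x]) next # within-swaps stay in one module
        }
        return(c(i, j, x, y))
      }
    }
    NULL
  }

  stale <- 0L
  for (iter in seq_len(max_iter)) {
    ecomp <- comp[edges[, 1L]]
    c_src <- which.min(tabulate(comp))
    cand <- propose(
      which(ecomp == c_src & is_between),
      which(ecomp != c_src & is_between),
      between = TRUE
    )
    if (is.null(cand)) {
      cand <- propose(
        which(ecomp == c_src & !is_between),
        which(ecomp != c_src & !is_between),
        between = FALSE
      )
    }
    if (is.null(cand)) {
      abort_wiring("No class-compatible cross-component swap exists; regenerate from fresh within-degrees.")
    }
    i <- cand[1L]; j <- cand[2L]; x <- cand[3L]; y <- cand[4L]
    u <- edges[i, 1L]; v <- edges[i, 2L]
    new_edges <- edges
    new_edges[i, ] <- c(min(u, x), max(u, x))
    new_edges[j, ] <- c(min(v, y), max(v, y))
    new_comp <- component_labels(new_edges, seq_len(n))
    # Swapping across components usually merges them, but breaking a
    # bridge can split one again; accept only improvements, with an
    # occasional neutral move to escape bridge-locked states.
    if (max(new_comp) < C || (stale >= 20L && max(new_comp) == C)) {
      edges <- new_edges
      comp <- new_comp
      C <- max(new_comp)
      stale <- 0L
      if (C == 1L) return(edges)
    } else {
      stale <- stale + 1L
    }
  }
  abort_wiring("Connectivity repair budget exhausted; regenerate from fresh within-degrees.")
}
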