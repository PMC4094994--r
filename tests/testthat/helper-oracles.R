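# Independent reference implementations used as oracles. These deliberately
# avoid the package's own code paths: plain loops, exhaustive search, and
# first-principles formulas.

# Modularity by explicit edge loop: e_kk and a_k accumulated edge by edge.
brute_modularity <- function(edges, membership) {
  m <- nrow(edges)
  K <- max(membership)
  e_kk <- numeric(K)
  ends <- numeric(K)
  for (i in seq_len(m)) {
    k1 <- membership[edges[i, 1]]
    k2 <- membership[edges[i, 2]]
    if (k1 == k2) e_kk[k1] <- e_kk[k1] + 1
    ends[k1] <- ends[k1] + 1
    ends[k2] <- ends[k2] + 1
  }
  sum(e_kk / m - (ends / (2 * m))^2)
}

# Exhaustive simple-graph realizability: a sequence is realizable iff some
# neighbor set of the highest-degree node leaves a realizable remainder.
# Every subset is tried (no Havel-Hakimi/Erdos-Gallai theory involved);
# memoized on the sorted residual sequence.
.brute_graphical_memo <- new.env(parent = emptyenv())
brute_graphical <- function(degs) {
  degs <- sort(as.integer(degs), decreasing = TRUE)
  degs <- degs[degs > 0]
  n <- length(degs)
  if (n == 0) return(TRUE)
  if (degs[1] > n - 1) return(FALSE)
  key <- paste(degs, collapse = ",")
  hit <- .brute_graphical_memo[[key]]
  if (!is.null(hit)) return(hit)
  d1 <- degs[1]
  rest <- degs[-1]
  ok <- FALSE
  for (nb in utils::combn(length(rest), d1, simplify = FALSE)) {
    reduced <- rest
    reduced[nb] <- reduced[nb] - 1L
    if (any(reduced < 0L)) next
    if (brute_graphical(reduced)) {
      ok <- TRUE
      break
    }
  }
  .brute_graphical_memo[[key]] <- ok
  ok
}

# Exhaustive capped-multigraph realizability: assign a multiplicity
# 0..b to every node pair and test whether some assignment realizes the
# degree sequence; recursive with row-sum pruning.
brute_multigraph_realizable <- function(degs, b) {
  degs <- as.integer(degs)
  K <- length(degs)
  if (sum(degs) %% 2 != 0) return(FALSE)
  if (K <= 1) return(all(degs == 0L))
  pairs <- utils::combn(K, 2)
  recurse <- function(p, res) {
    if (all(res == 0L)) return(TRUE)
    if (p > ncol(pairs)) return(FALSE)
    i <- pairs[1, p]
    j <- pairs[2, p]
    # capacity pruning: remaining pairs must be able to absorb residuals
    for (mult in 0:min(b, res[i], res[j])) {
      res2 <- res
      res2[i] <- res2[i] - mult
      res2[j] <- res2[j] - mult
      # each node's residual must fit in its remaining incident pairs
      rem_cap <- vapply(seq_len(K), function(v) {
        if (p >= ncol(pairs)) 0L else {
          later <- pairs[, (p + 1):ncol(pairs), drop = FALSE]
          b * sum(later[1, ] == v | later[2, ] == v)
        }
      }, numeric(1))
      if (all(res2 <= rem_cap)) {
        if (recurse(p + 1L, res2)) return(TRUE)
      }
    }
    FALSE
  }
  recurse(1L, degs)
}

# First-principles structural metrics on an edge matrix (1-based ids).
brute_assortativity <- function(edges, n) {
  deg <- tabulate(c(edges[, 1], edges[, 2]), n)
  x <- c(deg[edges[, 1]], deg[edges[, 2]])
  y <- c(deg[edges[, 2]], deg[edges[, 1]])
  suppressWarnings(stats::cor(x, y))
}

brute_mean_local_clustering <- function(edges, n) {
  adj <- matrix(FALSE, n, n)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  local <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ])
    k <- length(nb)
    if (k < 2) return(0)
    links <- sum(adj[nb, nb]) / 2
    links / (k * (k - 1) / 2)
  }, numeric(1))
  mean(local)
}

brute_avg_path_length <- function(edges, n) {
  # BFS from every node over the adjacency list
  nb <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    nb[[a]] <- c(nb[[a]], b)
    nb[[b]] <- c(nb[[b]], a)
  }
  total <- 0
  count <- 0
  for (s in seq_len(n)) {
    dist <- rep(NA_integer_, n)
    dist[s] <- 0L
    queue <- s
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      for (w in nb[[v]]) {
        if (is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          queue <- c(queue, w)
        }
      }
    }
    reach <- which(!is.na(dist) & seq_len(n) > s)
    total <- total + sum(dist[reach])
    count <- count + length(reach)
  }
  total / count
}

# A random connected-ish simple graph as an edge matrix.
random_edge_graph <- function(n, p = 0.3) {
  g <- igraph::sample_gnp(n, p)
  el <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(el) <- "integer"
  cbind(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
}

# Fixtures -------------------------------------------------------------

# Two triangles joined by one bridge edge (6 nodes, 7 edges).
bridged_triangles <- function() {
  list(
    edges = cbind(
      c(1L, 1L, 2L, 4L, 4L, 5L, 3L),
      c(2L, 3L, 3L, 5L, 6L, 6L, 4L)
    ),
    membership = c(1L, 1L, 1L, 2L, 2L, 2L)
  )
}

# K disjoint complete graphs of size s each.
disjoint_cliques <- function(K, s) {
  edges <- do.call(rbind, lapply(seq_len(K), function(k) {
    nodes <- (k - 1L) * s + seq_len(s)
    t(utils::combn(nodes, 2))
  }))
  list(edges = edges, membership = rep(seq_len(K), each = s))
}

# Enumerate all set partitions of 1..n (restricted growth strings).
all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxk) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_len(maxk + 1L)) {
      rec(c(prefix, k), max(maxk, k))
    }
  }
  rec(integer(0), 0L)
  out
}
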