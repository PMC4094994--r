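# Havel-Hakimi wiring, constrained swaps, and connectivity repair.

triples_fixture <- function(d, d_w, sizes) {
  tibble::tibble(
    node = seq_along(d),
    module = rep(seq_along(sizes), sizes),
    degree = as.integer(d),
    within_degree = as.integer(d_w),
    between_degree = as.integer(d - d_w)
  )
}

test_that("between-edge wiring realizes the between-degrees exactly", {
  # all between-degrees zero
  tri0 <- triples_fixture(c(2, 2, 2, 2), c(2, 2, 2, 2), c(2, 2))
  expect_identical(nrow(connect_between_edges(tri0)), 0L)

  # two singleton modules, one forced cross edge
  tri1 <- triples_fixture(c(1, 1), c(0, 0), c(1, 1))
  e1 <- connect_between_edges(tri1)
  expect_identical(e1, cbind(1L, 2L, deparse.level = 0L))

  # K = 3 modules of 2, everyone with between-degree 2
  set.seed(4)
  tri2 <- triples_fixture(rep(3, 6), rep(1, 6), rep(2, 3))
  e2 <- connect_between_edges(tri2)
  expect_identical(nrow(e2), 6L)
  expect_true(all(tabulate(c(e2), 6) == 2L))
  mem <- tri2$module
  expect_true(all(mem[e2[, 1]] != mem[e2[, 2]]))
  expect_false(any(duplicated(paste(e2[, 1], e2[, 2]))))
})

test_that("within-edge wiring is a per-module Havel-Hakimi", {
  set.seed(4)
  tri <- triples_fixture(c(1, 1, 2, 2, 2, 1, 1), c(1, 1, 2, 2, 2, 0, 0), c(2, 3, 2))
  e <- connect_within_edges(tri)
  mem <- tri$module
  expect_true(all(mem[e[, 1]] == mem[e[, 2]]))
  w_deg <- tabulate(c(e), 7)
  expect_identical(w_deg, tri$within_degree)
  # module 2 with d_w = (2,2,2) can only be the triangle
  sub <- e[mem[e[, 1]] == 2, , drop = FALSE]
  expect_identical(nrow(sub), 3L)
})

test_that("plain Havel-Hakimi never stalls on graphical sequences", {
  set.seed(12)
  for (i in 1:1000) {
    n <- sample(4:20, 1)
    repeat {
      d <- sample(1:(n - 1), n, replace = TRUE, prob = (1:(n - 1))^-1.5)
      if (handshake_check(d) && erdos_gallai_check(d)) break
    }
    tri <- triples_fixture(d, d, n)
    e <- connect_within_edges(tri)
    expect_identical(tabulate(c(e), n), as.integer(d))
    expect_false(any(duplicated(paste(e[, 1], e[, 2]))))
  }
})

test_that("double-edge swaps preserve degrees, class, and planted modularity", {
  set.seed(9)
  spec <- graph_spec(n = 120, degree = deg_poisson(8), target_q = 0.35, modules = 3)
  res <- generate_modular_graph(spec, seed = 21)
  mem <- res$partition$module
  edges <- as.matrix(res$edges[, c("from", "to")])
  is_between <- mem[edges[, 1]] != mem[edges[, 2]]
  q0 <- modularity_q(edges, mem)
  deg0 <- tabulate(c(edges), 120)

  bet <- double_edge_swap(edges[is_between, , drop = FALSE], 120,
    n_swaps = 200, membership = mem
  )
  expect_identical(tabulate(c(bet), 120), tabulate(c(edges[is_between, ]), 120))
  expect_true(all(mem[bet[, 1]] != mem[bet[, 2]]))

  wit1 <- edges[!is_between & mem[edges[, 1]] == 1, , drop = FALSE]
  wit1s <- double_edge_swap(wit1, 120, n_swaps = 100)
  expect_identical(tabulate(c(wit1s), 120), tabulate(c(wit1), 120))

  rewired <- rbind(bet, wit1s, edges[!is_between & mem[edges[, 1]] != 1, , drop = FALSE])
  expect_identical(tabulate(c(rewired), 120), deg0)
  expect_equal(modularity_q(rewired, mem), q0, tolerance = 1e-12)
})

test_that("swaps on a 4-cycle keep the graph simple and 2-regular", {
  cyc <- cbind(c(1L, 2L, 3L, 1L), c(2L, 3L, 4L, 4L))
  set.seed(2)
  for (i in 1:20) {
    out <- suppressWarnings(double_edge_swap(cyc, 4, n_swaps = 3))
    expect_identical(tabulate(c(out), 4), rep(2L, 4))
    expect_false(any(out[, 1] == out[, 2]))
    expect_false(any(duplicated(paste(out[, 1], out[, 2]))))
  }
})

test_that("Taylor rewiring connects a module without touching degrees", {
  # two disjoint triangles inside one 6-node module (6 edges >= 5 needed)
  edges <- cbind(c(1L, 1L, 2L, 4L, 4L, 5L), c(2L, 3L, 3L, 5L, 6L, 6L))
  set.seed(1)
  out <- connect_module_taylor(edges, nodes = 1:6, n = 6)
  expect_identical(tabulate(c(out), 6), rep(2L, 6))
  comp <- igraph::components(igraph::graph_from_edgelist(out, directed = FALSE))
  expect_equal(comp$no, 1L)
  expect_false(any(duplicated(paste(out[, 1], out[, 2]))))

  # already connected: unchanged
  tri <- cbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
  expect_identical(connect_module_taylor(tri, 1:3, 3), tri)

  # fewer edges than a spanning tree: impossible
  expect_error(
    connect_module_taylor(cbind(1L, 2L), 1:4, 4),
    class = "modgraph_wiring_error"
  )
})

test_that("global connectivity repair preserves the degree triples", {
  # two components, each containing within- and between-edges: component A
  # holds nodes 1,2 (module 1) and 4,5 (module 2) with within-edges 1-2 and
  # 4-5 plus between-edges 1-4 and 2-5; component B is the lone
  # between-edge 3-6; 5 edges suffice for a spanning structure on 6 nodes
  edges <- cbind(
    c(1L, 4L, 1L, 2L, 3L),
    c(2L, 5L, 4L, 5L, 6L)
  )
  tri <- triples_fixture(
    d = c(2, 2, 1, 2, 2, 1),
    d_w = c(1, 1, 0, 1, 1, 0),
    sizes = c(3, 3)
  )
  set.seed(6)
  out <- ensure_global_connectivity(edges, tri)
  g <- igraph::graph_from_edgelist(out, directed = FALSE)
  expect_equal(igraph::components(g)$no, 1L)
  expect_identical(tabulate(c(out), 6), tri$degree)
  mem <- tri$module
  w <- out[mem[out[, 1]] == mem[out[, 2]], , drop = FALSE]
  expect_identical(tabulate(c(w), 6), tri$within_degree)

  # connected input is returned unchanged
  tri3 <- triples_fixture(c(2, 2, 2), c(2, 2, 2), 3)
  ring <- cbind(c(1L, 1L, 2L), c(2L, 3L, 3L))
  expect_identical(ensure_global_connectivity(ring, tri3), ring)
})

test_that("swap randomization decorrelates endpoint degrees", {
  set.seed(31)
  spec <- graph_spec(n = 500, degree = deg_poisson(10), target_q = 0.4, modules = 5)
  res <- generate_modular_graph(spec, seed = 77)
  mem <- res$partition$module
  edges <- as.matrix(res$edges[, c("from", "to")])
  bet <- edges[mem[edges[, 1]] != mem[edges[, 2]], , drop = FALSE]
  deg <- tabulate(c(edges), 500)
  cors <- replicate(10, {
    sw <- double_edge_swap(bet, 500, n_swaps = 10 * nrow(bet), membership = mem)
    x <- c(deg[sw[, 1]], deg[sw[, 2]])
    y <- c(deg[sw[, 2]], deg[sw[, 1]])
    suppressWarnings(cor(x, y))
  })
  expect_lt(abs(mean(cors)), 0.05)
})
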