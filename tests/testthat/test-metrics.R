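# Modularity and structural metrics against brute-force references.

test_that("modularity matches hand-computed cases", {
  bt <- bridged_triangles()
  # 6/7 within-edges, each block holding half the degree: 6/7 - 2*(1/2)^2
  expect_equal(modularity_q(bt$edges, bt$membership), 5 / 14)

  dc <- disjoint_cliques(2, 3)
  expect_equal(modularity_q(dc$edges, dc$membership), 1 / 2)
  for (K in c(2, 4, 5)) {
    dck <- disjoint_cliques(K, 4)
    expect_equal(modularity_q(dck$edges, dck$membership), 1 - 1 / K)
  }

  # one-module partition is exactly 0 for any graph
  g <- random_edge_graph(30, 0.2)
  expect_identical(modularity_q(g, rep(1L, 30)), 0)

  expect_error(
    modularity_q(matrix(integer(0), ncol = 2), c(1, 1)),
    class = "modgraph_input_error"
  )
})

test_that("modularity agrees with brute force and igraph on random graphs", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(8:50, 1)
    edges <- random_edge_graph(n, runif(1, 0.1, 0.5))
    if (nrow(edges) == 0) next
    mem <- sample(1:sample(2:5, 1), n, replace = TRUE)
    mem <- match(mem, sort(unique(mem))) # contiguous labels
    g <- igraph::graph_from_edgelist(edges, directed = FALSE)
    if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
    q <- modularity_q(g, mem)
    expect_equal(q, brute_modularity(edges, mem), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, mem), tolerance = 1e-12)
  }
})

test_that("degree assortativity handles stars, paths and regular graphs", {
  star <- cbind(1L, 2:4)
  expect_equal(degree_assortativity(star), -1)
  path3 <- cbind(c(1L, 2L), c(2L, 3L))
  expect_equal(degree_assortativity(path3), -1)
  ring <- igraph::make_ring(6)
  expect_warning(r <- degree_assortativity(ring), "undefined")
  expect_true(is.nan(r))
})

test_that("clustering coefficient is mean-local with zero for low degree", {
  expect_equal(clustering_coefficient(igraph::make_full_graph(3)), 1)
  expect_equal(clustering_coefficient(igraph::make_star(5, mode = "undirected")), 0)
  # 4-cycle plus one diagonal: the degree-2 nodes see their two neighbors
  # joined by the diagonal (local 1); each diagonal endpoint sees 2 of its
  # 3 neighbor pairs joined (local 2/3); mean (1 + 2/3 + 1 + 2/3)/4 = 5/6
  g <- igraph::graph_from_edgelist(
    cbind(c(1, 2, 3, 4, 1), c(2, 3, 4, 1, 3)),
    directed = FALSE
  )
  expect_equal(clustering_coefficient(g), 5 / 6)
  expect_equal(clustering_coefficient(g), brute_mean_local_clustering(igraph::as_edgelist(g), 4))
  expect_equal(
    clustering_coefficient(g, type = "global"),
    igraph::transitivity(g, type = "global")
  )
})

test_that("average path length falls back to the largest component", {
  expect_equal(average_path_length(igraph::make_full_graph(4)), 1)
  path3 <- cbind(c(1L, 2L), c(2L, 3L))
  expect_equal(average_path_length(path3), 4 / 3)
  two_edges <- cbind(c(1L, 3L), c(2L, 4L))
  expect_warning(l <- average_path_length(two_edges), "disconnected")
  expect_equal(l, 1)
})

test_that("structural metrics agree with first-principles implementations", {
  set.seed(23)
  for (i in 1:20) {
    n <- sample(10:40, 1)
    edges <- random_edge_graph(n, runif(1, 0.15, 0.5))
    if (nrow(edges) < 3) next
    expect_equal(
      suppressWarnings(degree_assortativity(edges)),
      brute_assortativity(edges, n),
      tolerance = 1e-10
    )
    expect_equal(
      clustering_coefficient(edges),
      brute_mean_local_clustering(edges, n),
      tolerance = 1e-10
    )
    expect_equal(
      suppressWarnings(average_path_length(edges)),
      brute_avg_path_length(edges, n),
      tolerance = 1e-10
    )
  }
})

test_that("graph_metrics bundles the report as a one-row tibble", {
  bt <- bridged_triangles()
  rep <- graph_metrics(bt$edges, partition = bt$membership)
  expect_s3_class(rep, "tbl_df")
  expect_identical(nrow(rep), 1L)
  expect_equal(rep$q, 5 / 14)
  expect_named(rep, c("n", "m", "q", "assortativity", "clustering", "path_length"))
})
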