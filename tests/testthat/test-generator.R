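# End-to-end generation contracts.

expect_valid_result <- function(res, spec) {
  edges <- as.matrix(res$edges[, c("from", "to")])
  n <- spec$n
  # simple
  expect_false(any(edges[, 1] == edges[, 2]))
  expect_false(any(duplicated(paste(edges[, 1], edges[, 2]))))
  # connected
  expect_true(igraph::is_connected(res$graph))
  # realized degrees equal the assigned triples exactly
  expect_identical(tabulate(c(edges), n), res$triples$degree)
  mem <- res$partition$module
  w <- edges[mem[edges[, 1]] == mem[edges[, 2]], , drop = FALSE]
  expect_identical(tabulate(c(w), n), res$triples$within_degree)
  # achieved modularity within tolerance of the target
  expect_lte(abs(res$achieved_q - spec$target_q), spec$epsilon)
  expect_equal(res$achieved_q, modularity_q(edges, mem), tolerance = 1e-12)
}

test_that("generation hits the target modularity with valid structure", {
  spec <- graph_spec(n = 250, degree = deg_poisson(8), target_q = 0.45, modules = 5)
  res <- generate_modular_graph(spec, seed = 42)
  expect_valid_result(res, spec)
  g <- glance(res)
  expect_identical(g$n, 250L)
  expect_true(g$connected)
  td <- tidy(res)
  expect_true(all(td$class[td$module_from == td$module_to] == "within"))
})

test_that("single-module generation gives exactly Q = 0 and no between-edges", {
  spec <- graph_spec(n = 100, degree = deg_poisson(6))
  res <- generate_modular_graph(spec, seed = 7)
  expect_identical(res$achieved_q, 0)
  expect_true(all(res$triples$between_degree == 0L))
  expect_valid_result(res, spec)
})

test_that("identical spec and seed reproduce the graph bit for bit", {
  spec <- graph_spec(n = 150, degree = deg_geometric(mean = 6), target_q = 0.3, modules = 3)
  r1 <- generate_modular_graph(spec, seed = 99)
  r2 <- generate_modular_graph(spec, seed = 99)
  expect_identical(r1$edges, r2$edges)
  expect_identical(r1$partition, r2$partition)
  r3 <- generate_modular_graph(spec, seed = 100)
  expect_false(identical(r1$edges, r3$edges))
})

test_that("within-module edge fraction increases with the target modularity", {
  spec <- graph_spec(n = 200, degree = deg_poisson(8), target_q = 0.1, modules = 4)
  wf <- vapply(c(0.1, 0.3, 0.6), function(q) {
    spec$target_q <- q
    res <- generate_modular_graph(spec, seed = 11)
    mean(res$edges$class == "within")
  }, numeric(1))
  expect_true(all(diff(wf) > 0))
})

test_that("configuration counterparts realize the degree sequence with Q = 0", {
  res <- configuration_counterpart(c(2, 2, 2), seed = 1)
  expect_identical(nrow(res$edges), 3L) # the triangle
  expect_identical(res$achieved_q, 0)
  expect_error(configuration_counterpart(c(1, 1, 1)), class = "modgraph_input_error")

  spec <- graph_spec(n = 200, degree = deg_poisson(8), target_q = 0.4, modules = 4)
  mod <- generate_modular_graph(spec, seed = 3)
  cfg <- configuration_counterpart(mod$triples$degree, seed = 4)
  expect_identical(
    sort(tabulate(c(as.matrix(cfg$edges[, 1:2])), 200)),
    sort(mod$triples$degree)
  )
  expect_identical(max(cfg$partition$module), 1L)
})

test_that("spec extraction from a network inverts the generator", {
  dc <- disjoint_cliques(2, 3)
  sp <- spec_from_network(dc$edges, dc$membership)
  expect_equal(sp$target_q, 1 / 2)
  expect_identical(sp$modules, 2L)

  # single-module partition
  sp1 <- spec_from_network(dc$edges, rep(1L, 6))
  expect_identical(sp1$modules, 1L)
  expect_equal(sp1$target_q, 0)

  # round trip: generate, extract, regenerate, recover Q and degrees
  spec <- graph_spec(n = 200, degree = deg_poisson(8), target_q = 0.4, modules = 4)
  res <- generate_modular_graph(spec, seed = 13)
  sp2 <- spec_from_network(res$graph, res$partition)
  expect_equal(sp2$target_q, res$achieved_q, tolerance = 1e-12)
  expect_identical(
    sort(sp2$degree$degrees),
    sort(res$triples$degree)
  )
  res2 <- generate_modular_graph(sp2, seed = 14)
  expect_lte(abs(res2$achieved_q - res$achieved_q), sp2$epsilon)
  expect_identical(sort(res2$triples$degree), sort(res$triples$degree))

  # preserving observed sizes and within-degrees (second null-model class)
  sp3 <- spec_from_network(res$graph, res$partition, preserve_within = TRUE)
  expect_identical(sum(sp3$module_sizes), 200L)
  res3 <- generate_modular_graph(sp3, seed = 15)
  expect_lte(abs(res3$achieved_q - res$achieved_q), sp3$epsilon)
})

test_that("infeasible targets fail before any sampling", {
  expect_error(
    graph_spec(n = 90, degree = deg_poisson(6), target_q = 0.7, modules = 3),
    "2/3|0.667|0.6667"
  )
})

test_that("structural sweep reports per-replicate metrics and summaries", {
  spec <- graph_spec(n = 150, degree = deg_poisson(8), target_q = 0, modules = 3)
  sw <- structural_sweep(spec, q_values = c(0.1, 0.4), replicates = 2, seed = 5)
  expect_s3_class(sw, "modular_sweep")
  expect_identical(nrow(sw), 4L)
  expect_true(all(abs(sw$achieved_q - sw$target_q) <= 0.01))
  summ <- sweep_summary(sw)
  expect_identical(nrow(summ), 2L)
  expect_named(
    summ,
    c(
      "target_q", "replicates", "achieved_q_mean",
      "assortativity_mean", "assortativity_sd",
      "clustering_mean", "clustering_sd",
      "path_length_mean", "path_length_sd"
    )
  )
  p <- autoplot(sw)
  expect_s3_class(p, "ggplot")
})

test_that("result autoplot returns a ggplot", {
  spec <- graph_spec(n = 60, degree = deg_poisson(5), target_q = 0.3, modules = 3)
  res <- generate_modular_graph(spec, seed = 2)
  expect_s3_class(autoplot(res), "ggplot")
})
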