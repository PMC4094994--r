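# Closed-form modularity relations and spec validation.

test_that("q_max follows 1 - 1/K and rejects bad input", {
  expect_equal(q_max(3), 2 / 3)
  expect_identical(q_max(1), 0)
  expect_equal(q_max(10), 0.9)
  expect_true(all(diff(vapply(1:50, q_max, numeric(1))) > 0))
  expect_lt(1 - q_max(10000), 1e-3)
  expect_error(q_max(0), class = "modgraph_input_error")
})

test_that("expected_q reduces correctly for equal module sizes", {
  # d_w_mean = d_mean with equal sizes gives the maximum 1 - 1/K
  expect_equal(expected_q(10, rep(100, 4), 10), 1 - 1 / 4)
  # equal sizes: E[Q] = d_w_mean/d_mean - 1/K
  expect_equal(expected_q(7, rep(200, 10), 10), 7 / 10 - 1 / 10)
  # single module at full within-degree
  expect_equal(expected_q(6, 100, 6), 0)
})

test_that("solve_mean_within_degree inverts expected_q", {
  # value frozen from a bisection inversion of expected_q
  expect_equal(solve_mean_within_degree(0.6, 10, rep(200, 10)), 7, tolerance = 1e-12)
  bisect <- function(target, d_mean, sizes) {
    f <- function(x) expected_q(x, sizes, d_mean) - target
    uniroot(f, c(0, d_mean), tol = 1e-13)$root
  }
  set.seed(1)
  for (i in 1:20) {
    K <- sample(2:8, 1)
    sizes <- sample(20:60, K, replace = TRUE)
    d_mean <- runif(1, 3, 12)
    target <- runif(1, -sum((sizes / sum(sizes))^2) + 0.01, 1 - sum((sizes / sum(sizes))^2) - 0.01)
    dw <- solve_mean_within_degree(target, d_mean, sizes)
    expect_equal(dw, bisect(target, d_mean, sizes), tolerance = 1e-9)
    # round trip through expected_q
    expect_equal(expected_q(dw, sizes, d_mean), target, tolerance = 1e-12)
  }
  # boundary: all edges within
  sizes <- rep(50, 4)
  expect_equal(
    solve_mean_within_degree(1 - sum((sizes / 200)^2), 8, sizes), 8,
    tolerance = 1e-12
  )
  # equal sizes at Q = 0 gives d_mean / K
  expect_equal(solve_mean_within_degree(0, 12, rep(30, 6)), 2, tolerance = 1e-12)
  expect_error(
    solve_mean_within_degree(0.95, 10, rep(50, 3)),
    class = "modgraph_feasibility_error"
  )
})

test_that("block densities recover the planted-partition probabilities", {
  bd <- block_densities(d_mean = 10, d_w_mean = 7, s_mean = 200, K = 10)
  expect_equal(bd$p_in, 7 / 199)
  expect_equal(bd$p_out, 3 / 1800)
  expect_equal(block_densities(10, 10, 50, 4)$p_out, 0)
  expect_equal(block_densities(10, 0, 50, 4)$p_in, 0)
})

test_that("graph_spec validates feasibility up front", {
  expect_error(
    graph_spec(n = 100, degree = deg_poisson(8), target_q = 0.9, modules = 3),
    class = "modgraph_feasibility_error"
  )
  expect_error(
    graph_spec(n = 100, degree = deg_poisson(8), target_q = 0.5, modules = 1),
    class = "modgraph_feasibility_error"
  )
  # K = 1 with Q = 0 is the one attainable boundary case
  expect_s3_class(graph_spec(n = 100, degree = deg_poisson(8)), "graph_spec")
  # the m = |E| parameterization converts to mean degree 2m/n
  sp <- graph_spec(n = 150, edges = 375, family = "powerlaw", target_q = 0.1, modules = 3)
  expect_equal(sp$degree$mean, 5)
  expect_error(
    graph_spec(n = 10, degree = deg_sequence(rep(2, 9))),
    class = "modgraph_input_error"
  )
})

test_that("degree distribution constructors keep their parameter relations", {
  expect_equal(deg_geometric(mean = 10)$p, 0.1)
  expect_equal(deg_geometric(p = 0.25)$mean, 4)
  expect_error(deg_powerlaw(alpha = 0.5), class = "modgraph_input_error")
  expect_error(deg_sequence(c(1, -2)), class = "modgraph_input_error")
})
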