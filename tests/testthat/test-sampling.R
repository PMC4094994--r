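# Module sizes, degree sequences, and within-/between-degree triples.

test_that("module sizes follow the equal-with-remainder rule", {
  expect_identical(sample_module_sizes(150, 3), rep(50L, 3))
  expect_identical(sample_module_sizes(10, 3), c(4L, 3L, 3L))
  expect_identical(sample_module_sizes(7, 1), 7L)
  expect_identical(sample_module_sizes(12, 4, c(3, 3, 3, 3)), rep(3L, 4))
  expect_error(sample_module_sizes(10, 3, c(5, 5)), class = "modgraph_input_error")
  set.seed(1)
  s <- sample_module_sizes(60, 4, deg_poisson(15))
  expect_identical(sum(s), 60L)
  expect_true(all(s >= 1L))
})

test_that("sampled degree sequences satisfy all realizability conditions", {
  set.seed(5)
  for (dist in list(deg_poisson(10), deg_geometric(mean = 8), deg_powerlaw(mean = 4))) {
    d <- sample_degree_sequence(dist, 300)
    expect_true(all(d >= 1L))
    expect_true(all(d <= 299L))
    expect_lt(abs(mean(d) - dist$mean), 0.05 * dist$mean + 1e-9)
    expect_true(handshake_check(d))
    expect_true(erdos_gallai_check(d))
  }
  # explicit sequences pass through unchanged after validation
  expect_identical(sample_degree_sequence(deg_sequence(c(2, 2, 2)), 3), c(2L, 2L, 2L))
  expect_error(
    sample_degree_sequence(deg_sequence(c(3, 3, 1, 1)), 4),
    class = "modgraph_input_error"
  )
  expect_error(
    sample_degree_sequence(deg_sequence(c(1, 1, 1)), 3),
    class = "modgraph_input_error"
  )
})

test_that("within-degree triples satisfy every structural identity", {
  set.seed(8)
  d <- sample_degree_sequence(deg_poisson(10), 400)
  sizes <- rep(100L, 4)
  tri <- sample_within_degrees(d, sizes, d_w_mean = 7, dist = deg_poisson(10), eps_dw = 0.1)
  expect_identical(tri$degree, as.integer(d))
  expect_identical(tri$degree, tri$within_degree + tri$between_degree)
  expect_true(all(tri$within_degree >= 0L))
  expect_true(all(tri$between_degree >= 0L))
  expect_true(all(tri$within_degree <= pmin(tri$degree, 99L)))
  expect_lt(abs(mean(tri$within_degree) - 7), 0.1 + 1e-9)
  for (k in 1:4) {
    dw_k <- tri$within_degree[tri$module == k]
    expect_identical(sum(dw_k) %% 2L, 0L)
    expect_true(erdos_gallai_check(dw_k))
  }
  expect_identical(sum(tri$between_degree) %% 2L, 0L)
})

test_that("single module with full within-degree mean returns d_w = d", {
  d <- c(3L, 3L, 2L, 2L, 2L)
  tri <- sample_within_degrees(d, 5L, d_w_mean = mean(d), dist = deg_poisson(2.4))
  expect_identical(tri$within_degree, d)
  expect_true(all(tri$between_degree == 0L))
})

test_that("tiny split example respects the module-size cap", {
  # D = (3,2 | 3,2) over two modules of two: the cap forces d_w <= 1, so
  # each module carries exactly one within-edge and the hubs export the
  # surplus as between-degree (coarse totals 3 and 3, realizable)
  set.seed(2)
  tri <- sample_within_degrees(
    c(3L, 2L, 3L, 2L), c(2L, 2L),
    d_w_mean = 1, dist = deg_poisson(2.5), eps_dw = 0.3
  )
  expect_identical(tri$within_degree, rep(1L, 4))
  expect_identical(tri$between_degree, c(2L, 1L, 2L, 1L))
})

test_that("explicit within-degree sequences are validated", {
  d <- c(3L, 2L, 3L, 2L)
  tri <- sample_within_degrees(
    d, c(2L, 2L),
    d_w_mean = 1,
    dist = deg_sequence(c(1L, 1L, 1L, 1L))
  )
  expect_identical(tri$within_degree, rep(1L, 4))
  expect_error(
    sample_within_degrees(d, c(2L, 2L), 1, dist = deg_sequence(c(2L, 2L, 0L, 0L))),
    class = "modgraph_input_error"
  )
})
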