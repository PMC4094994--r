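#' Closed-form modularity relations
#'
#' `expected_q()` gives the expected modularity of a modular random graph in
#' terms of the mean within-degree \eqn{\bar d_w}, the mean degree
#' \eqn{\bar d}, and the module sizes \eqn{s_k}:
#' \deqn{E[Q] = \sum_k \left[\bar d_w s_k / M - (\bar d s_k / M)^2\right],
#'   \quad M = n \bar d,}
#' where \eqn{M} is the total degree sum. With equal module sizes this
#' reduces to \eqn{\bar d_w/\bar d - 1/K}. `solve_mean_within_degree()`
#' inverts the relation: \eqn{\bar d_w = \bar d (Q + \sum_k (s_k/n)^2)},
#' which is how a target modularity is translated into a within-degree
#' specification. `q_max()` is the supremum of modularity attainable with
#' `K` modules, \eqn{1 - 1/K}.
#'
#' @param d_w_mean Mean within-degree \eqn{\bar d_w}.
#' @param sizes Integer vector of module sizes \eqn{s_k} summing to `n`.
#' @param d_mean Mean degree \eqn{\bar d}.
#' @param n Number of nodes; defaults to `sum(sizes)`.
#' @param target_q Desired modularity.
#' @param K Number of modules.
#' @return A single numeric value.
#' @examples
#' q_max(3) # 2/3
#' solve_mean_within_degree(0.6, d_mean = 10, sizes = rep(200, 10)) # 7
#' expected_q(7, rep(200, 10), d_mean = 10) # 0.6
#' @name modularity_relations
NULL

#' @rdname modularity_relations
#' @export
expected_q <- function(d_w_mean, sizes, d_mean, n = sum(sizes)) {
  if (d_w_mean > d_mean + 1e-12) abort_input("Mean within-degree cannot exceed the mean degree.")
  if (abs(sum(sizes) - n) > 1e-9) abort_input("Module sizes must sum to n.")
  M <- n * d_mean
  sum(d_w_mean * sizes / M - (d_mean * sizes / M)^2)
}

#' @rdname modularity_relations
#' @export
solve_mean_within_degree <- function(target_q, d_mean, sizes) {
  n <- sum(sizes)
  ssq <- sum((sizes / n)^2)
  if (target_q >= 1 - ssq + 1e-12 || target_q < -ssq - 1e-12) {
    abort_feasibility(sprintf(
      "Target modularity %.4g is infeasible for these module sizes; admissible range is [%.4g, %.4g].",
      target_q, -ssq, 1 - ssq
    ))
  }
  d_mean * (target_q + ssq)
}

#' @rdname modularity_relations
#' @export
q_max <- function(K) {
  if (length(K) != 1L || is.na(K) || K < 1 || K != floor(K)) {
    abort_input("`K` must be a positive integer.")
  }
  (K - 1) / K # exact at the representable fractions, e.g. 2/3 for K = 3
}

#' Girvan-Newman block densities implied by a modular graph specification
#'
#' For a modular random graph with Poisson-like degrees, the within-module
#' linking probability and cross-module linking probability of the equivalent
#' planted-partition (Girvan-Newman) model are
#' \eqn{p_{in} = \bar d_w / (\bar s - 1)} and
#' \eqn{p_{out} = (\bar d - \bar d_w) / (\bar s (K - 1))}.
#'
#' @inheritParams modularity_relations
#' @param s_mean Mean module size \eqn{\bar s}.
#' @return A one-row tibble with columns `p_in` and `p_out`.
#' @examples
#' block_densities(d_mean = 10, d_w_mean = 7, s_mean = 200, K = 10)
#' @export
block_densities <- function(d_mean, d_w_mean, s_mean, K) {
  if (s_mean <= 1) abort_input("Mean module size must exceed 1.")
  if (K <= 1) abort_input("Block densities need at least two modules.")
  if (d_w_mean < 0 || d_w_mean > d_mean) abort_input("Need 0 <= d_w_mean <= d_mean.")
  tibble(
    p_in = d_w_mean / (s_mean - 1),
    p_out = (d_mean - d_w_mean) / (s_mean * (K - 1))
  )
}

#' Specify a modular random graph
#'
#' Bundles every knob of the generative model into a validated recipe:
#' network size, degree distribution (or explicit degree sequence), target
#' modularity of the planted partition, number of modules, module sizes,
#' optional within-degree specification, tolerances, and retry budgets.
#'
#' @param n Number of nodes.
#' @param degree A [degree_dist] object (`deg_poisson()`, `deg_geometric()`,
#'   `deg_powerlaw()`, `deg_sequence()`). May be omitted when `edges` plus a
#'   `family` name is given.
#' @param target_q Target modularity `E[Q]` of the planted partition. Must be
#'   below `q_max(modules)`; negative (disassortative) targets are accepted
#'   down to the feasibility bound at which the mean within-degree reaches 0.
#' @param modules Number of modules `K`.
#' @param module_sizes `"equal"` (default; sizes `floor(n/K)` with the
#'   remainder spread one per module), an explicit integer vector summing to
#'   `n`, or a [degree_dist] object to sample sizes from.
#' @param within_degree Optional within-degree specification: `NULL`
#'   (default: same family as `degree` with mean solved from the target
#'   modularity) or a `deg_sequence()` of per-node within-degrees.
#' @param edges Optional total edge count `m`; convenience alternative to a
#'   mean degree, converted via \eqn{\bar d = 2m/n} (requires `degree` to be
#'   a family constructor result whose mean may be overridden, or a `family`
#'   string).
#' @param family Optional family name (`"poisson"`, `"geometric"`,
#'   `"powerlaw"`) used with `edges` when `degree` is not supplied.
#' @param epsilon Tolerance on the achieved modularity; the generator retries
#'   until `|Q - target_q| <= epsilon`. Default 0.01.
#' @param epsilon_dw Tolerance on the realized mean within-degree; default
#'   `epsilon * d_mean`.
#' @param degree_mean_tol Tolerance on the realized mean degree of a sampled
#'   degree sequence; default `0.05 * d_mean`.
#' @param swaps_per_edge Accepted double-edge swaps per edge of each class
#'   during randomization. Default 10.
#' @param connect_modules If `TRUE`, every module's internal subgraph is made
#'   connected (Taylor rewiring). Default `FALSE`: only the full graph is
#'   required to be connected.
#' @param max_attempts Rejection-sampling budget per stochastic stage.
#' @return A `graph_spec` object.
#' @examples
#' graph_spec(n = 150, edges = 375, family = "powerlaw", target_q = 0.6, modules = 3)
#' graph_spec(n = 2000, degree = deg_poisson(10), target_q = 0.4, modules = 10)
#' @export
graph_spec <- function(n, degree = NULL, target_q = 0, modules = 1,
                       module_sizes = "equal", within_degree = NULL,
                       edges = NULL, family = NULL,
                       epsilon = 0.01, epsilon_dw = NULL,
                       degree_mean_tol = NULL, swaps_per_edge = 10,
                       connect_modules = FALSE, max_attempts = 1000) {
  n <- as.integer(n)
  modules <- as.integer(modules)
  if (n < 1L) abort_input("`n` must be at least 1.")
  if (modules < 1L || modules > n) abort_input("Need 1 <= modules <= n.")
  if (epsilon <= 0) abort_input("`epsilon` must be positive.")

  if (!is.null(edges)) {
    mean_degree <- 2 * edges / n
    if (is.null(degree)) {
      if (is.null(family)) abort_input("With `edges`, give either `degree` or a `family` name.")
      degree <- switch(family,
        poisson = deg_poisson(mean_degree),
        geometric = deg_geometric(mean = mean_degree),
        powerlaw = deg_powerlaw(mean = mean_degree),
        abort_input(sprintf("Unknown degree family '%s'.", family))
      )
    } else if (degree$family != "explicit") {
      degree$mean <- mean_degree
      if (degree$family == "geometric") degree$p <- 1 / mean_degree
      if (degree$family == "powerlaw") degree$alpha <- NULL
    }
  }
  if (is.null(degree)) abort_input("A degree specification is required.")
  if (!inherits(degree, "degree_dist")) abort_input("`degree` must be a degree_dist object.")
  if (degree$family == "explicit" && length(degree$degrees) != n) {
    abort_input("Explicit degree sequence length must equal `n`.")
  }

  # Q_max = 1 - 1/K; equality corresponds to fully within-wired equal
  # modules (e.g. disjoint cliques) and is accepted — the generator's
  # epsilon tolerance absorbs the few between-edges connectivity needs.
  if (target_q > q_max(modules) + 1e-12 || (modules == 1L && target_q != 0)) {
    abort_feasibility(sprintf(
      "Target modularity %.4g is not attainable with K = %d modules (Q_max = 1 - 1/K = %.4g).",
      target_q, modules, q_max(modules)
    ))
  }
  sizes_known <- if (is.numeric(module_sizes)) {
    as.integer(module_sizes)
  } else if (identical(module_sizes, "equal")) {
    equal_sizes(n, modules)
  } else {
    NULL
  }
  if (!is.null(sizes_known)) {
    if (length(sizes_known) != modules || sum(sizes_known) != n || any(sizes_known < 1L)) {
      abort_input("Explicit module sizes must be `modules` positive integers summing to `n`.")
    }
    # Fail fast on targets outside the admissible modularity interval.
    solve_mean_within_degree(target_q, degree$mean, sizes_known)
  }
  if (!is.null(within_degree)) {
    if (!inherits(within_degree, "degree_dist") || within_degree$family != "explicit") {
      abort_input("`within_degree` must be NULL or a deg_sequence() of per-node within-degrees.")
    }
    if (length(within_degree$degrees) != n) {
      abort_input("Explicit within-degree sequence length must equal `n`.")
    }
  }

  structure(
    list(
      n = n, degree = degree, target_q = target_q, modules = modules,
      module_sizes = module_sizes, within_degree = within_degree,
      epsilon = epsilon,
      epsilon_dw = epsilon_dw %||% (epsilon * degree$mean),
      degree_mean_tol = degree_mean_tol %||% (0.05 * degree$mean),
      swaps_per_edge = swaps_per_edge,
      connect_modules = isTRUE(connect_modules),
      max_attempts = as.integer(max_attempts)
    ),
    class = "graph_spec"
  )
}

#' @export
print.graph_spec <- function(x, ...) {
  cat("<graph_spec>\n")
  cat(sprintf("  n = %d nodes, K = %d modules, target Q = %.4g (epsilon %.3g)\n",
    x$n, x$modules, x$target_q, x$epsilon))
  cat("  degree: ")
  print(x$degree)
  sizes <- if (is.numeric(x$module_sizes)) {
    paste(x$module_sizes, collapse = ", ")
  } else if (identical(x$module_sizes, "equal")) {
    "equal"
  } else {
    "sampled"
  }
  cat(sprintf("  module sizes: %s\n", sizes))
  if (!is.null(x$within_degree)) cat("  within-degree: explicit sequence\n")
  invisible(x)
}

equal_sizes <- function(n, K) {
  base <- n %/% K
  rem <- n %% K
  as.integer(base + (seq_len(K) <= rem))
}
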