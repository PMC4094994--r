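#' Compare two partitions of the same node set
#'
#' `partition_jaccard()` is the pair-counting Jaccard similarity: over all
#' unordered node pairs, with \eqn{n_{11}} pairs co-clustered in both
#' partitions and \eqn{n_{10}}, \eqn{n_{01}} co-clustered in exactly one,
#' \eqn{J = n_{11} / (n_{11} + n_{10} + n_{01})}. When no pair is
#' co-clustered in either partition (both all-singletons) the ratio is
#' degenerate and 1 is returned with a warning.
#'
#' `variation_of_information()` is the information-theoretic distance
#' \eqn{VI = H(X) + H(Y) - 2 I(X;Y)} computed from the \eqn{K_1 \times K_2}
#' confusion matrix of co-membership counts; it is a metric on partitions.
#' Natural logarithm by default.
#'
#' `compare_partitions()` returns both in a one-row tibble.
#'
#' @param p1,p2 Partitions of the same `n` nodes: integer membership vectors
#'   or tibbles with `node` and `module` columns.
#' @param base Logarithm base for VI (default `exp(1)`).
#' @return A single numeric value; `compare_partitions()` returns a one-row
#'   tibble with columns `jaccard` and `vi`.
#' @examples
#' p1 <- c(1, 1, 2, 2)
#' p2 <- c(1, 1, 1, 2)
#' partition_jaccard(p1, p2) # 1/4
#' variation_of_information(p1, p1) # 0
#' @name partition_comparison
NULL

aligned_memberships <- function(p1, p2) {
  m1 <- as_membership(p1)
  m2 <- as_membership(p2)
  if (length(m1) != length(m2)) {
    abort_input("Partitions must cover the same node set.")
  }
  list(m1 = m1, m2 = m2)
}

#' @rdname partition_comparison
#' @export
partition_jaccard <- function(p1, p2) {
  ms <- aligned_memberships(p1, p2)
  conf <- table(ms$m1, ms$m2)
  pairs2 <- function(x) sum(x * (x - 1) / 2)
  n11 <- pairs2(conf)
  a <- pairs2(table(ms$m1)) # co-clustered in p1
  b <- pairs2(table(ms$m2)) # co-clustered in p2
  denom <- a + b - n11 # n11 + n10 + n01
  if (denom == 0) {
    warn("Neither partition co-clusters any pair (all singletons); Jaccard similarity returned as 1 by convention.")
    return(1)
  }
  n11 / denom
}

#' @rdname partition_comparison
#' @export
variation_of_information <- function(p1, p2, base = exp(1)) {
  ms <- aligned_memberships(p1, p2)
  n <- length(ms$m1)
  conf <- table(ms$m1, ms$m2) / n
  plogp <- function(p) {
    p <- p[p > 0]
    -sum(p * log(p, base = base))
  }
  h1 <- plogp(rowSums(conf))
  h2 <- plogp(colSums(conf))
  h12 <- plogp(as.numeric(conf))
  mi <- h1 + h2 - h12
  vi <- h1 + h2 - 2 * mi
  max(vi, 0) # clamp tiny negative rounding noise
}

#' @rdname partition_comparison
#' @export
compare_partitions <- function(p1, p2, base = exp(1)) {
  tibble(
    jaccard = partition_jaccard(p1, p2),
    vi = variation_of_information(p1, p2, base = base)
  )
}
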