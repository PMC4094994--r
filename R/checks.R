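#' Realizability tests for degree sequences
#'
#' `handshake_check()` tests the Handshake Theorem (even degree sum).
#' `erdos_gallai_check()` tests whether an integer sequence is graphical,
#' i.e. realizable as the degree sequence of a simple undirected graph:
#' the sum must be even and, with degrees sorted non-increasingly, every
#' prefix must satisfy
#' \eqn{\sum_{i \le j} d_i \le j(j-1) + \sum_{i > j} \min(j, d_i)}.
#' `chungphaisan_check()` tests realizability as a multigraph whose edge
#' multiplicities are capped at `b`; the generator applies it to the coarse
#' module-level graph of between-edge stubs, with `b` equal to the maximum
#' between-degree of any node.
#'
#' @param degrees Integer vector of (multi)graph degrees; sorted internally.
#' @param b Maximum allowed number of parallel edges between a node pair.
#' @return `TRUE` if the sequence is realizable, else `FALSE`.
#' @examples
#' erdos_gallai_check(c(2, 2, 2)) # triangle
#' erdos_gallai_check(c(3, 3, 1, 1)) # not graphical
#' chungphaisan_check(c(4, 4), b = 4) # four parallel edges
#' @name realizability
NULL

#' @rdname realizability
#' @export
handshake_check <- function(degrees) {
  sum(degrees) %% 2 == 0
}

#' @rdname realizability
#' @export
erdos_gallai_check <- function(degrees) {
  if (anyNA(degrees) || any(degrees < 0) || any(degrees != floor(degrees))) {
    abort_input("Degrees must be non-negative integers.")
  }
  d <- sort(as.integer(degrees), decreasing = TRUE)
  n <- length(d)
  if (n == 0L || d[1L] == 0L) return(TRUE)
  if (sum(d) %% 2 != 0) return(FALSE)
  if (d[1L] > n - 1L) return(FALSE)
  lhs <- cumsum(d)
  # Prefixes beyond the Durfee square (d_j < j) are implied by earlier ones.
  for (j in seq_len(n)) {
    if (j > 1L && d[j] < j) break
    tail_sum <- if (j < n) sum(pmin.int(j, d[(j + 1L):n])) else 0L
    if (lhs[j] > j * (j - 1L) + tail_sum) return(FALSE)
  }
  TRUE
}

#' @rdname realizability
#' @export
chungphaisan_check <- function(degrees, b) {
  if (anyNA(degrees) || any(degrees < 0) || any(degrees != floor(degrees))) {
    abort_input("Degrees must be non-negative integers.")
  }
  if (b < 0) abort_input("Multiplicity cap `b` must be non-negative.")
  d <- sort(as.integer(degrees), decreasing = TRUE)
  K <- length(d)
  if (K == 0L || d[1L] == 0L) return(TRUE)
  if (sum(d) %% 2 != 0) return(FALSE)
  if (b == 0) return(FALSE)
  lhs <- cumsum(d)
  for (j in seq_len(max(K - 1L, 1L))) {
    tail_sum <- if (j < K) sum(pmin.int(j * b, d[(j + 1L):K])) else 0L
    if (lhs[j] - b * j * (j - 1L) > tail_sum) return(FALSE)
  }
  TRUE
}
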