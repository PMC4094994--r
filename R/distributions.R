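#' Degree distribution specifications
#'
#' Constructors for the degree (and within-degree) distribution families the
#' generator supports: zero-truncated Poisson, geometric
#' \eqn{p(1-p)^{k-1}} on \eqn{k \ge 1}, discrete power law
#' \eqn{k^{-\alpha}/\zeta(\alpha)} on \eqn{k \ge 1}, and an explicit integer
#' sequence. Each family is parameterised either by its natural parameter or
#' by the target mean degree; the free parameter is then solved numerically on
#' the truncated support at sampling time.
#'
#' Sampled node degrees are always at least 1 (no isolate nodes) and at most
#' `n - 1`. Within-degree distributions reuse the same families with the mean
#' solved from the target modularity; Poisson within-degrees may be 0 while
#' the geometric and power-law families keep their natural support
#' \eqn{k \ge 1} (so they require a mean within-degree of at least 1).
#'
#' @param mean Target mean of the distribution (on the truncated support).
#' @param p Geometric success probability; `mean = 1/p`.
#' @param alpha Power-law exponent \eqn{\alpha > 1}.
#' @param degrees Integer vector: an explicit degree sequence used as-is
#'   (validated, not resampled).
#' @return A `degree_dist` specification object.
#' @examples
#' deg_poisson(10)
#' deg_powerlaw(mean = 5)
#' deg_sequence(c(2, 2, 2))
#' @name degree_dist
NULL

new_degree_dist <- function(family, mean = NULL, p = NULL, alpha = NULL, degrees = NULL) {
  structure(
    list(family = family, mean = mean, p = p, alpha = alpha, degrees = degrees),
    class = "degree_dist"
  )
}

#' @rdname degree_dist
#' @export
deg_poisson <- function(mean) {
  if (!is.numeric(mean) || mean <= 0) abort_input("Poisson mean must be positive.")
  new_degree_dist("poisson", mean = mean)
}

#' @rdname degree_dist
#' @export
deg_geometric <- function(p = NULL, mean = NULL) {
  if (is.null(p) && is.null(mean)) abort_input("Supply `p` or `mean` for the geometric family.")
  if (is.null(p)) p <- 1 / mean
  if (p <= 0 || p > 1) abort_input("Geometric `p` must be in (0, 1].")
  new_degree_dist("geometric", mean = mean %||% (1 / p), p = p)
}

#' @rdname degree_dist
#' @export
deg_powerlaw <- function(alpha = NULL, mean = NULL) {
  if (is.null(alpha) && is.null(mean)) abort_input("Supply `alpha` or `mean` for the power-law family.")
  if (!is.null(alpha) && alpha <= 1) abort_input("Power-law alpha must exceed 1.")
  new_degree_dist("powerlaw", mean = mean, alpha = alpha)
}

#' @rdname degree_dist
#' @export
deg_sequence <- function(degrees) {
  degrees <- as.integer(degrees)
  if (length(degrees) == 0L || anyNA(degrees) || any(degrees < 0L)) {
    abort_input("An explicit degree sequence must be non-negative integers.")
  }
  new_degree_dist("explicit", mean = mean(degrees), degrees = degrees)
}

#' @export
print.degree_dist <- function(x, ...) {
  lab <- switch(x$family,
    poisson = sprintf("Poisson(lambda for mean %.4g)", x$mean),
    geometric = sprintf("geometric(p = %.4g, mean %.4g)", x$p, x$mean),
    powerlaw = if (is.null(x$alpha)) {
      sprintf("power law(mean %.4g, alpha solved on support)", x$mean)
    } else {
      sprintf("power law(alpha = %.4g)", x$alpha)
    },
    explicit = sprintf("explicit sequence (n = %d, mean %.4g)", length(x$degrees), x$mean)
  )
  cat("<degree_dist>", lab, "\n")
  invisible(x)
}

# Mean of the discrete power law k^-alpha restricted to lo..hi.
powerlaw_mean <- function(alpha, lo, hi) {
  k <- lo:hi
  w <- k^(-alpha)
  sum(k * w) / sum(w)
}

solve_powerlaw_alpha <- function(mean, lo, hi) {
  lo_a <- 1.0001
  hi_a <- 12
  m_lo <- powerlaw_mean(lo_a, lo, hi) # heaviest tail -> largest mean
  m_hi <- powerlaw_mean(hi_a, lo, hi)
  if (mean > m_lo || mean < m_hi) {
    abort_feasibility(sprintf(
      "Power-law mean %.4g not attainable on support [%d, %d] (attainable range [%.4g, %.4g]).",
      mean, lo, hi, m_hi, m_lo
    ))
  }
  uniroot(function(a) powerlaw_mean(a, lo, hi) - mean, c(lo_a, hi_a), tol = 1e-10)$root
}

# lambda of a zero-truncated Poisson with the requested truncated mean.
solve_ztpois_lambda <- function(mean) {
  if (mean <= 1) abort_feasibility("Zero-truncated Poisson mean must exceed 1.")
  f <- function(l) l / (1 - exp(-l)) - mean
  uniroot(f, c(1e-9, mean), extendInt = "upX", tol = 1e-10)$root
}

# Sample n integers from `dist` truncated to [lo, hi]; out-of-range draws are
# rejected and redrawn. `lo` is 1 for node degrees and for the geometric /
# power-law families; Poisson within-degrees use lo = 0.
dist_sample <- function(dist, n, lo, hi, mean = NULL) {
  mean <- mean %||% dist$mean
  if (hi < lo) abort_input("Empty support for degree sampling.")
  out <- switch(dist$family,
    poisson = {
      lambda <- if (lo >= 1L) solve_ztpois_lambda(mean) else mean
      x <- rpois(n, lambda)
      bad <- which(x < lo | x > hi)
      guard <- 0L
      while (length(bad) > 0L && guard < 1000L) {
        x[bad] <- rpois(length(bad), lambda)
        bad <- bad[x[bad] < lo | x[bad] > hi]
        guard <- guard + 1L
      }
      if (length(bad) > 0L) abort_sampling("Poisson truncation rejected too many draws.")
      x
    },
    geometric = {
      p <- dist$p %||% (1 / mean)
      x <- 1L + stats::rgeom(n, p)
      bad <- which(x > hi)
      guard <- 0L
      while (length(bad) > 0L && guard < 1000L) {
        x[bad] <- 1L + stats::rgeom(length(bad), p)
        bad <- bad[x[bad] > hi]
        guard <- guard + 1L
      }
      if (length(bad) > 0L) abort_sampling("Geometric truncation rejected too many draws.")
      x
    },
    powerlaw = {
      support_lo <- max(lo, 1L)
      alpha <- dist$alpha %||% solve_powerlaw_alpha(mean, support_lo, hi)
      k <- support_lo:hi
      sample(k, n, replace = TRUE, prob = k^(-alpha))
    },
    explicit = abort_input("Explicit sequences are not resampled."),
    abort_input(sprintf("Unknown degree family '%s'.", dist$family))
  )
  as.integer(out)
}

# Same family as `dist` but with a new target mean (for within-degrees).
dist_with_mean <- function(dist, mean) {
  switch(dist$family,
    poisson = deg_poisson(mean),
    geometric = deg_geometric(mean = mean),
    powerlaw = deg_powerlaw(mean = mean),
    explicit = deg_poisson(mean), # within-degrees of an explicit-sequence spec
    abort_input(sprintf("Unknown degree family '%s'.", dist$family))
  )
}
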