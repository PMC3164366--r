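#' Hypergeometric probability of a gene-list overlap
#'
#' Probability mass function of the overlap count between two gene sets drawn
#' at random from a common universe. Drawing `m` genes into each of two lists
#' from a universe of `N` genes, the number `k` of genes common to both lists
#' follows the hypergeometric distribution
#' \deqn{P(X = k) = \frac{\binom{m}{k}\binom{N-m}{m-k}}{\binom{N}{m}}.}
#' The generalized form with unequal selections `m` and `m_b` replaces the
#' second list's draw size; the default `m_b = m` is the symmetric case used
#' by the marching comparison algorithm.
#'
#' All binomial coefficients are evaluated in log space (via log-gamma) so
#' that universes of tens of thousands of genes do not overflow.
#'
#' @param N Universe size: number of genes both lists are drawn from.
#' @param m Number of genes selected in the first list.
#' @param k Overlap count(s); vectorized.
#' @param m_b Number of genes selected in the second list (default `m`).
#' @return Numeric vector of probabilities, `0` for `k` outside the support.
#' @examples
#' hypergeom_pmf(10, 5, 5) # 1 / choose(10, 5)
#' sum(hypergeom_pmf(40, 10, 0:10)) # 1
#' @seealso [overlap_pvalue()] for the upper-tail probability.
#' @export
hypergeom_pmf <- function(N, m, k, m_b = m) {
  stopifnot(length(N) == 1, length(m) == 1, length(m_b) == 1)
  check_count(N, "N")
  check_count(m, "m")
  check_count(m_b, "m_b")
  if (m > N || m_b > N) {
    rlang::abort("`m` and `m_b` must not exceed the universe size `N`.")
  }
  lp <- lchoose(m, k) + lchoose(N - m, m_b - k) - lchoose(N, m_b)
  out <- exp(lp)
  # outside the combinatorial support the log terms are -Inf already, but be
  # explicit for negative or non-integer k
  out[k < 0 | k > pmin(m, m_b) | k < m + m_b - N | k != round(k)] <- 0
  out
}

#' Upper-tail overlap significance
#'
#' Probability of observing at least `k_star` genes in the intersection of two
#' lists formed by randomly choosing `m` genes (and `m_b` genes) out of `N`:
#' \deqn{P(X \ge k^*) = \sum_{k = k^*}^{m} P(X = k).}
#' This is the first stopping criterion of the marching list-comparison
#' algorithm: a step is retained only while this tail probability stays below
#' the significance level.
#'
#' Tail terms are accumulated from the smallest to the largest magnitude to
#' limit floating-point cancellation; the result is exact to summation
#' precision.
#'
#' @inheritParams hypergeom_pmf
#' @param k_star Observed overlap count; vectorized. `k_star` at or below the
#'   support minimum gives exactly 1.
#' @return Numeric vector of tail probabilities in `(0, 1]`.
#' @examples
#' overlap_pvalue(10, 5, 5) # 1 / 252
#' overlap_pvalue(20, 5, 0) # 1
#' @export
overlap_pvalue <- function(N, m, k_star, m_b = m) {
  stopifnot(length(N) == 1, length(m) == 1, length(m_b) == 1)
  vapply(k_star, function(ks) {
    hi <- min(m, m_b)
    lo <- max(ks, 0)
    if (lo > hi) {
      return(0)
    }
    terms <- hypergeom_pmf(N, m, lo:hi, m_b = m_b)
    min(1, sum(sort(terms)))
  }, numeric(1))
}

#' Significance of the overlap increase between consecutive steps
#'
#' The second stopping criterion of the marching algorithm asks whether the
#' growth of the overlap between one rank depth and the next could be
#' explained by chance alone. Conditional on the previous step's configuration
#' (`m_prev` genes selected from each list with `k_prev` in common), the next
#' `m_new - m_prev` ranks of each list are modelled as exchangeable random
#' draws from that list's remaining genes. The overlap gain then decomposes as
#' \eqn{\Delta k = X + Y + Z}, where
#' * `X` = new genes of list A that were already selected in list B,
#'   hypergeometric over A's remaining pool;
#' * `Y` = the mirror count for list B, independent of `X`;
#' * `Z` = genes newly selected by both lists, hypergeometric over the pool
#'   selected in neither list, conditional on `X` and `Y`.
#'
#' The full distribution of \eqn{\Delta k} is assembled by exact convolution
#' of this decomposition (terms below `1e-16` relative mass are dropped), and
#' the returned value is the upper tail
#' \eqn{P(\Delta K \ge k_{new} - k_{prev})}, summed smallest-terms-first.
#'
#' @param N Universe size shared by both lists.
#' @param m_prev,k_prev Previous step: genes selected per list and overlap.
#' @param m_new,k_new Current step: genes selected per list and overlap.
#' @return A single probability in `(0, 1]`; exactly 1 when the overlap did
#'   not increase.
#' @examples
#' increment_pvalue(1000, m_prev = 100, k_prev = 50, m_new = 200, k_new = 50) # 1
#' increment_pvalue(200, m_prev = 20, k_prev = 10, m_new = 40, k_new = 30)
#' @export
increment_pvalue <- function(N, m_prev, k_prev, m_new, k_new) {
  for (v in c("N", "m_prev", "k_prev", "m_new", "k_new")) {
    check_count(get(v), v)
  }
  if (m_new <= m_prev) {
    rlang::abort("`m_new` must exceed `m_prev`: the increment test needs a step.")
  }
  if (k_new < k_prev) {
    rlang::abort("`k_new` cannot be smaller than `k_prev`: overlaps only grow.")
  }
  if (k_prev > m_prev || k_new > m_new || m_new > N) {
    rlang::abort("Inconsistent configuration: need k <= m <= N at both steps.")
  }
  dm <- m_new - m_prev
  dk <- k_new - k_prev
  if (dk == 0) {
    return(1)
  }
  pmf <- increment_pmf(N, m_prev, k_prev, dm)
  tail_idx <- seq.int(dk + 1L, length(pmf)) # pmf[d + 1] = P(Delta k = d)
  min(1, max(sum(sort(pmf[tail_idx])), 0))
}

# Exact pmf of the overlap gain Delta k over a step of dm genes per list,
# conditional on (m_prev, k_prev). Returns a vector p with p[d + 1] = P(d).
increment_pmf <- function(N, m_prev, k_prev, dm) {
  b <- m_prev - k_prev # genes selected in exactly the other list (per side)
  w <- N - 2L * m_prev + k_prev # genes selected in neither list
  pool <- b + w # remaining genes per list
  if (w < 0) {
    rlang::abort("Configuration impossible: k_prev below the hypergeometric support.")
  }
  if (dm > pool) {
    rlang::abort("Step overruns the lists: m_new exceeds the remaining genes.")
  }
  xs <- max(0L, dm - w):min(dm, b)
  px <- hypergeom_pmf(pool, b, xs, m_b = dm)
  acc <- numeric(2L * dm + 1L)
  keep <- px > 1e-16
  for (ix in which(keep)) {
    x <- xs[ix]
    nx <- dm - x # new list-A genes landing in the "neither" pool
    for (iy in which(keep)) {
      y <- xs[iy]
      pxy <- px[ix] * px[iy]
      if (pxy <= 1e-18) next
      ny <- dm - y
      zs <- max(0L, nx + ny - w):min(nx, ny)
      pz <- hypergeom_pmf(w, nx, zs, m_b = ny)
      d <- x + y + zs
      acc[d + 1L] <- acc[d + 1L] + pxy * pz
    }
  }
  acc
}

check_count <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x != round(x)) {
    rlang::abort(sprintf("`%s` must be a single non-negative integer.", name))
  }
  invisible(x)
}
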