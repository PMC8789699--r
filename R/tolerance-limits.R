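#' Exact safety level of an outer tolerance-limit candidate rank
#'
#' For the r-th ascending order statistic of a sample of size `n`, the
#' population CDF value at that observation follows a Beta(r, n - r + 1)
#' distribution. The *safety level* of a candidate outer tolerance limit is
#' the probability that no more than a proportion `q` of the population
#' scores below the observation, i.e. \eqn{P[F(X_{(r)}) \le q]}, the
#' regularized incomplete Beta function at `q` with shape parameters
#' `(r, n - r + 1)`. It equals the upper binomial tail
#' \eqn{P[\mathrm{Bin}(n, q) \ge r]}.
#'
#' @param r Integer rank(s), 1-based ascending (worst score = rank 1).
#' @param n Sample size.
#' @param q Tail proportion defining the population quantile of interest
#'   (default 0.05, the conventional 5% "pathological" tail).
#' @return Probability (vectorized over `r`): strictly decreasing in `r`.
#' @seealso [safety_level_inner()], [find_outer_tl()]
#' @examples
#' safety_level_outer(9, 300)   # 0.966
#' @export
safety_level_outer <- function(r, n, q = 0.05) {
  check_rank_args(r, n, q)
  stats::pbeta(q, r, n - r + 1)
}

#' Exact safety level of an inner tolerance-limit candidate rank
#'
#' Complementary condition to [safety_level_outer()]: the probability that at
#' least a proportion `q` of the population scores below the r-th ascending
#' order statistic, \eqn{P[F(X_{(r)}) \ge q]} — equivalently the confidence
#' that at most `1 - q` of the population performs above it. Strictly
#' increasing in `r`.
#'
#' @inheritParams safety_level_outer
#' @return Probability (vectorized over `r`).
#' @examples
#' safety_level_inner(22, 300)  # 0.951
#' @export
safety_level_inner <- function(r, n, q = 0.05) {
  check_rank_args(r, n, q)
  1 - stats::pbeta(q, r, n - r + 1)
}

check_rank_args <- function(r, n, q) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != floor(n))
    stop("`n` must be a single positive integer", call. = FALSE)
  if (any(!is.finite(r)) || any(r < 1) || any(r > n) || any(r != floor(r)))
    stop("`r` must be integer rank(s) in 1..n", call. = FALSE)
  if (length(q) != 1L || !is.finite(q) || q <= 0 || q >= 1)
    stop("`q` must be a probability strictly inside (0, 1)", call. = FALSE)
  invisible(TRUE)
}

new_tol_limit <- function(kind, rank, safety_level, n, q, confidence) {
  structure(
    list(kind = kind, rank = as.integer(rank), safety_level = safety_level,
         n = as.integer(n), tail_proportion = q, confidence = confidence),
    class = "tol_limit"
  )
}

#' Outer one-sided lower non-parametric tolerance limit
#'
#' Finds the largest ascending rank `r` whose exact safety level
#' ([safety_level_outer()]) reaches the requested confidence: with
#' probability at least `confidence`, no more than a proportion `q` of the
#' population scores below the observation holding that rank. The adjusted
#' score at this rank defines the clinical cut-off of the Equivalent Score
#' scale (scores at or below it are ES = 0).
#'
#' The search scans every rank 1..n, the exhaustive counterpart of the
#' iterative trial-and-error procedure traditionally used in norming studies.
#'
#' @param n Normative sample size.
#' @param q Tail proportion (default 0.05).
#' @param confidence Required safety level (default 0.95).
#' @return A `tol_limit` object: `kind`, `rank`, full-precision
#'   `safety_level`, `n`, `tail_proportion`, `confidence`.
#' @examples
#' find_outer_tl(300)  # rank 9
#' @export
find_outer_tl <- function(n, q = 0.05, confidence = 0.95) {
  check_conf(confidence)
  check_rank_args(1L, n, q)
  ranks <- seq_len(n)
  p <- stats::pbeta(q, ranks, n - ranks + 1)
  ok <- p >= confidence
  if (!any(ok)) {
    # even rank 1 fails: P[F(X_(1)) <= q] = 1 - (1-q)^n < confidence
    min_n <- ceiling(log(1 - confidence) / log(1 - q))
    stop(sprintf(
      "sample too small: n = %d admits no outer tolerance limit at q = %g, confidence = %g (minimum qualifying n is %d)",
      n, q, confidence, min_n), call. = FALSE)
  }
  r <- max(ranks[ok])
  new_tol_limit("outer", r, p[r], n, q, confidence)
}

#' Inner one-sided lower non-parametric tolerance limit
#'
#' Finds the smallest ascending rank `r` whose inner safety level
#' ([safety_level_inner()]) reaches the requested confidence: with
#' probability at least `confidence`, at most `1 - q` of the population
#' performs above the observation holding that rank. Adjusted scores between
#' the outer and inner limits form the *gray area*, where the inferential
#' error risk of a "defective" judgment is not controlled at `q`.
#'
#' @inheritParams find_outer_tl
#' @return A `tol_limit` object. When both limits exist,
#'   `find_inner_tl(n)$rank > find_outer_tl(n)$rank`.
#' @examples
#' find_inner_tl(300)  # rank 22
#' @export
find_inner_tl <- function(n, q = 0.05, confidence = 0.95) {
  check_conf(confidence)
  check_rank_args(1L, n, q)
  ranks <- seq_len(n)
  p <- 1 - stats::pbeta(q, ranks, n - ranks + 1)
  ok <- p >= confidence
  if (!any(ok))
    stop(sprintf(
      "sample too small: n = %d admits no inner tolerance limit at q = %g, confidence = %g",
      n, q, confidence), call. = FALSE)
  r <- min(ranks[ok])
  new_tol_limit("inner", r, p[r], n, q, confidence)
}

check_conf <- function(confidence) {
  if (length(confidence) != 1L || !is.finite(confidence) ||
      confidence <= 0 || confidence >= 1)
    stop("`confidence` must be a probability strictly inside (0, 1)",
         call. = FALSE)
  invisible(TRUE)
}

#' Both tolerance limits for a normative sample size
#'
#' Convenience wrapper returning the outer and inner one-sided lower
#' tolerance limits together.
#'
#' @inheritParams find_outer_tl
#' @return A `tol_limits` object: list with elements `outer` and `inner`,
#'   each a `tol_limit`.
#' @examples
#' tol_limits(300)
#' @export
tol_limits <- function(n, q = 0.05, confidence = 0.95) {
  structure(
    list(outer = find_outer_tl(n, q, confidence),
         inner = find_inner_tl(n, q, confidence)),
    class = "tol_limits"
  )
}

#' @export
print.tol_limit <- function(x, ...) {
  cat(sprintf("%s tolerance limit: rank %d of n = %d (safety level %.3f; q = %g, confidence = %g)\n",
              if (x$kind == "outer") "Outer" else "Inner",
              x$rank, x$n, x$safety_level, x$tail_proportion, x$confidence))
  invisible(x)
}

#' @export
print.tol_limits <- function(x, ...) {
  print(x$outer); print(x$inner)
  invisible(x)
}
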