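#' Round half away from zero
#'
#' Deterministic half-up rounding to the nearest integer (0.5 always rounds
#' away from zero), independent of the platform's banker's rounding in
#' [base::round()].
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

round_half_down <- function(x) sign(x) * ceiling(abs(x) - 0.5)

#' z-deviate boundaries of the Equivalent Score partition
#'
#' The rank range between the outer tolerance limit and the median is split
#' into the ES = 1, 2, 3 segments by dividing the standard-normal interval
#' between the cut-off's deviate and zero into three equal parts. With
#' `cd1 = otl_rank / n` the cumulative density at the cut-off, the deviate
#' `z1 = qnorm(cd1)` is divided by three: the segment boundaries are
#' `2*z1/3` (last ES = 1), `z1/3` (last ES = 2) and `0` (last ES = 3, the
#' median).
#'
#' @param otl_rank Outer tolerance-limit rank (1-based ascending).
#' @param n Normative sample size; `otl_rank` must be below `n/2`.
#' @return List with `cd1`, `z1`, `z_two_thirds` (= 2·z1/3, boundary of
#'   ES 1) and `z_one_third` (= z1/3, boundary of ES 2); all negative while
#'   `cd1 < 0.5`.
#' @examples
#' z_boundaries(9, 300)  # z1 = -1.880794
#' @export
z_boundaries <- function(otl_rank, n) {
  check_partition_args(otl_rank, n)
  cd1 <- otl_rank / n
  z1 <- stats::qnorm(cd1)
  list(cd1 = cd1, z1 = z1, z_two_thirds = 2 * z1 / 3, z_one_third = z1 / 3)
}

check_partition_args <- function(otl_rank, n) {
  if (length(n) != 1L || !is.finite(n) || n < 2 || n != floor(n))
    stop("`n` must be a single integer >= 2", call. = FALSE)
  if (length(otl_rank) != 1L || !is.finite(otl_rank) ||
      otl_rank < 1 || otl_rank != floor(otl_rank))
    stop("`otl_rank` must be a single positive integer", call. = FALSE)
  if (otl_rank >= n / 2)
    stop(sprintf(
      "partition undefined: outer tolerance-limit rank %d is at or above the median of n = %d",
      otl_rank, n), call. = FALSE)
  invisible(TRUE)
}

#' Partition ranks between the outer tolerance limit and the median into ES 1-3
#'
#' Computes the expected number of observations in each of the three
#' z-deviate segments (`n` times the normal-density mass between successive
#' boundaries), rounds them to integer counts, and accumulates them on top of
#' the outer tolerance-limit rank to give the ranks of the last observation
#' holding ES = 1, 2 and 3. Observations above the last ES = 3 rank — the
#' median included — receive ES = 4; observations at or below the outer
#' tolerance limit receive ES = 0.
#'
#' Because a rounded count sitting near the .5 threshold is a judgment call
#' in the traditional manual procedure, each category carries a *near-half
#' flag* (fractional part within `near_half_tol` of .5) and an explicit
#' per-category `adjust` of +1/-1 can override the rounding; any override
#' propagates to every downstream cumulative rank.
#'
#' @inheritParams z_boundaries
#' @param rounding `"half_up"` (default; .5 rounds up, the convention of the
#'   reference procedure) or `"half_down"`.
#' @param adjust Integer vector of length 3 (ES 1, 2, 3): manual override
#'   added to the rounded counts.
#' @param near_half_tol Distance of the fractional part from .5 below which
#'   the near-half flag is raised (default 0.05).
#' @return An `es_partition` object: boundaries (`cd1`, `z1`,
#'   `z_two_thirds`, `z_one_third`), `raw_counts` and integer `counts`
#'   (named es1/es2/es3), `last_ranks` (last_es1/last_es2/last_es3),
#'   `near_half` flags, `otl_rank`, `n`, `rounding`, `adjust`.
#' @examples
#' es_partition(9, 300)  # counts 22, 48, 70; last ranks 31, 79, 149
#' @export
es_partition <- function(otl_rank, n, rounding = c("half_up", "half_down"),
                         adjust = c(0L, 0L, 0L), near_half_tol = 0.05) {
  rounding <- match.arg(rounding)
  if (length(adjust) != 3L || any(adjust != floor(adjust)))
    stop("`adjust` must be three integers (ES 1, 2, 3)", call. = FALSE)
  if (!is.finite(near_half_tol) || near_half_tol < 0 || near_half_tol >= 0.5)
    stop("`near_half_tol` must be in [0, 0.5)", call. = FALSE)
  zb <- z_boundaries(otl_rank, n)

  cd2 <- stats::pnorm(zb$z_two_thirds)
  cd3 <- stats::pnorm(zb$z_one_third)
  raw <- c(es1 = n * (cd2 - zb$cd1),
           es2 = n * (cd3 - cd2),
           es3 = n * (0.5 - cd3))
  rounder <- if (rounding == "half_up") round_half_up else round_half_down
  counts <- as.integer(rounder(raw) + adjust)
  if (any(counts < 0))
    stop("manual `adjust` produced a negative category count", call. = FALSE)
  frac <- raw - floor(raw)
  near_half <- abs(frac - 0.5) < near_half_tol
  names(near_half) <- names(raw)

  last <- as.integer(otl_rank) + cumsum(counts)
  structure(
    list(n = as.integer(n), otl_rank = as.integer(otl_rank),
         cd1 = zb$cd1, z1 = zb$z1,
         z_two_thirds = zb$z_two_thirds, z_one_third = zb$z_one_third,
         raw_counts = raw, counts = stats::setNames(counts, names(raw)),
         last_ranks = c(last_es1 = last[1], last_es2 = last[2],
                        last_es3 = last[3]),
         near_half = near_half, rounding = rounding,
         adjust = stats::setNames(as.integer(adjust), names(raw))),
    class = "es_partition"
  )
}

#' Cumulative "last ES = k" ranks
#'
#' Shorthand for the `last_ranks` element of [es_partition()].
#'
#' @inheritParams es_partition
#' @return Named integer vector `last_es1`, `last_es2`, `last_es3`.
#' @examples
#' es_rank_boundaries(9, 300)  # 31, 79, 149
#' @export
es_rank_boundaries <- function(otl_rank, n, rounding = c("half_up", "half_down"),
                               adjust = c(0L, 0L, 0L)) {
  es_partition(otl_rank, n, rounding, adjust)$last_ranks
}

#' @export
print.es_partition <- function(x, ...) {
  cat(sprintf("Equivalent Score partition (n = %d, outer TL rank = %d)\n",
              x$n, x$otl_rank))
  cat(sprintf("  cd1 = %g; z1 = %.6f; boundaries 2z1/3 = %.6f, z1/3 = %.6f\n",
              x$cd1, x$z1, x$z_two_thirds, x$z_one_third))
  for (i in 1:3) {
    cat(sprintf("  ES %d: raw count %.4f -> %d%s; last rank %d\n",
                i, x$raw_counts[i], x$counts[i],
                if (x$near_half[i]) " [near .5 - inspect]" else "",
                x$last_ranks[i]))
  }
  invisible(x)
}
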