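#' Conservative tied-rank correction for tolerance limits and ES thresholds
#'
#' When a formal tolerance-limit or threshold rank falls inside a run of
#' equal adjusted scores, the score-based classification can no longer honor
#' the rank-based guarantee. The conservative correction shifts the effective
#' rank to the safe side of the run: the *outer* tolerance limit moves down
#' to the highest rank below the run (keeping the error risk of a
#' "defective" call under the nominal level), while the *inner* limit and
#' the ES thresholds move up to the lowest rank above the run (widening the
#' stricter category). A formal rank already sitting at the safe edge of its
#' run is returned unchanged.
#'
#' @param scores Numeric vector of adjusted scores sorted ascending.
#' @param formal_rank Rank to correct (1-based).
#' @param kind `"otl"`, `"itl"` or `"es_threshold"`.
#' @return Integer effective rank.
#' @export
resolve_ties <- function(scores, formal_rank,
                         kind = c("otl", "itl", "es_threshold")) {
  kind <- match.arg(kind)
  n <- length(scores)
  if (formal_rank < 1 || formal_rank > n || formal_rank != floor(formal_rank))
    stop("`formal_rank` must be an integer in 1..n", call. = FALSE)
  if (is.unsorted(scores)) stop("`scores` must be sorted ascending", call. = FALSE)
  val <- scores[formal_rank]
  run <- range(which(scores == val))
  if (kind == "otl") {
    if (run[2] == formal_rank) return(as.integer(formal_rank))  # safe edge
    if (run[1] == 1L)
      stop("tie run at the outer tolerance limit extends to rank 1: correction impossible, manual review required",
           call. = FALSE)
    as.integer(run[1] - 1L)
  } else {
    if (run[1] == formal_rank) return(as.integer(formal_rank))  # safe edge
    if (run[2] == n)
      stop(sprintf("tie run at the %s extends to rank n: correction impossible, manual review required",
                   if (kind == "itl") "inner tolerance limit" else "ES threshold"),
           call. = FALSE)
    as.integer(run[2] + 1L)
  }
}

#' Assemble the clinical Equivalent Score norm table
#'
#' Maps the (tie-corrected) tolerance-limit and last-ES ranks to their
#' adjusted scores and lays out the deliverable clinicians use: the cut-off
#' (one reporting-precision unit above the outer tolerance-limit score), the
#' gray area (scores between the two limits, where the nominal error risk is
#' not guaranteed), and five contiguous ES score ranges covering the real
#' line. Band intervals are closed at their printed upper bounds; the next
#' band starts one precision unit above.
#'
#' @param scores Adjusted scores sorted ascending (the normative sample);
#'   rounded to `score_precision` before tie detection.
#' @param otl,itl `tol_limit` objects (or plain ranks) for the outer and
#'   inner limits.
#' @param partition An `es_partition` for the same `n` and outer rank.
#' @param score_precision Decimal places of the instrument's reporting scale
#'   (default 3); the cut-off is one unit at this precision above the outer
#'   tolerance-limit score.
#' @return An `es_norm_table` object: `otl_score`, `itl_score`, `cutoff`,
#'   `gray_area` (c(lower, upper], on the cut-off scale), `es_ranges`
#'   (5 x 2 matrix of \[lower, upper\] closed bounds at the reporting
#'   precision, rows ES0..ES4), `score_precision`, `n`, effective ranks, and
#'   `tie_corrections` (log of any rank shifts).
#' @export
build_norm_table <- function(scores, otl, itl, partition,
                             score_precision = 3) {
  otl_rank <- if (inherits(otl, "tol_limit")) otl$rank else as.integer(otl)
  itl_rank <- if (inherits(itl, "tol_limit")) itl$rank else as.integer(itl)
  if (itl_rank <= otl_rank)
    stop("inner tolerance-limit rank must exceed the outer rank", call. = FALSE)
  n <- length(scores)
  if (partition$n != n || partition$otl_rank != otl_rank)
    stop("partition does not match the sample size / outer rank", call. = FALSE)
  scores <- round(sort(scores), score_precision)
  unit <- 10^(-score_precision)

  ranks <- c(otl = otl_rank, itl = itl_rank, partition$last_ranks)
  kinds <- c("otl", "itl", "es_threshold", "es_threshold", "es_threshold")
  eff <- mapply(function(r, k) resolve_ties(scores, r, k), ranks, kinds)
  log_idx <- eff != ranks
  tie_log <- data.frame(boundary = names(ranks)[log_idx],
                        formal_rank = unname(ranks[log_idx]),
                        effective_rank = unname(eff[log_idx]))

  s <- scores[eff]
  names(s) <- names(ranks)
  cutoff <- s[["otl"]] + unit
  es_ranges <- rbind(
    ES0 = c(-Inf, s[["otl"]]),
    ES1 = c(cutoff, s[["last_es1"]]),
    ES2 = c(s[["last_es1"]] + unit, s[["last_es2"]]),
    ES3 = c(s[["last_es2"]] + unit, s[["last_es3"]]),
    ES4 = c(s[["last_es3"]] + unit, Inf)
  )
  colnames(es_ranges) <- c("lower", "upper")
  if (any(diff(es_ranges[, "upper"][1:4]) < 0))
    stop("inconsistent inputs: band upper bounds are not non-decreasing",
         call. = FALSE)
  structure(
    list(otl_score = s[["otl"]], itl_score = s[["itl"]], cutoff = cutoff,
         gray_area = c(lower = cutoff, upper = s[["itl"]]),
         es_ranges = es_ranges, score_precision = score_precision,
         n = n, effective_ranks = eff, formal_ranks = ranks,
         tie_corrections = tie_log),
    class = "es_norm_table"
  )
}

#' Classify adjusted scores against a norm table
#'
#' Returns the Equivalent Score band containing each score and whether it
#' falls inside the gray area. Gray-area membership is an annotation on
#' ES = 1 results (the error risk there is not controlled at the nominal
#' level), not a sixth category. Classification is monotone non-decreasing
#' in the score; every real number is classifiable.
#'
#' @param score Numeric vector of adjusted scores.
#' @param table An `es_norm_table`.
#' @return Data frame: `score`, `es` (integer 0..4), `in_gray_area`.
#' @export
classify_scores <- function(score, table) {
  if (!inherits(table, "es_norm_table")) stop("`table` must be an es_norm_table",
                                              call. = FALSE)
  uppers <- table$es_ranges[1:4, "upper"]
  es <- vapply(score, function(s) sum(s > uppers), numeric(1))
  data.frame(score = score, es = as.integer(es),
             in_gray_area = score > table$otl_score & score <= table$itl_score)
}

#' @export
print.es_norm_table <- function(x, ...) {
  p <- x$score_precision
  f <- function(v) formatC(v, format = "f", digits = p)
  cat(sprintf("Equivalent Score norm table (n = %d, reporting precision %d d.p.)\n",
              x$n, p))
  cat(sprintf("  Outer TL %s | Inner TL %s | cut-off %s | gray area %s-%s\n",
              f(x$otl_score), f(x$itl_score), f(x$cutoff),
              f(x$gray_area[["lower"]]), f(x$gray_area[["upper"]])))
  r <- x$es_ranges
  cat(sprintf("  ES 0: <= %s\n", f(r["ES0", "upper"])))
  for (i in 1:3)
    cat(sprintf("  ES %d: %s-%s\n", i, f(r[i + 1, "lower"]), f(r[i + 1, "upper"])))
  cat(sprintf("  ES 4: >= %s\n", f(r["ES4", "lower"])))
  if (nrow(x$tie_corrections)) {
    cat("  Tied-rank corrections applied:\n")
    for (i in seq_len(nrow(x$tie_corrections)))
      cat(sprintf("    %s: formal rank %d -> effective rank %d\n",
                  x$tie_corrections$boundary[i], x$tie_corrections$formal_rank[i],
                  x$tie_corrections$effective_rank[i]))
  }
  invisible(x)
}

#' Write / read a norm table as JSON
#'
#' Round-trip safe: a table written with [write_norm_table()] and re-read
#' with [read_norm_table()] classifies identically.
#'
#' @param table An `es_norm_table`.
#' @param path File path.
#' @return `write_norm_table` returns `path` invisibly; `read_norm_table`
#'   returns an `es_norm_table`.
#' @export
write_norm_table <- function(table, path) {
  x <- unclass(table)
  x$es_ranges <- as.data.frame(x$es_ranges)
  x$es_ranges$band <- rownames(table$es_ranges)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "string",
                       force = TRUE)
  invisible(path)
}

#' @rdname write_norm_table
#' @export
read_norm_table <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  er <- as.matrix(x$es_ranges[, c("lower", "upper")])
  er <- apply(er, 2, as.numeric)  # "-Inf"/"Inf" strings back to numeric
  rownames(er) <- x$es_ranges$band
  structure(
    list(otl_score = x$otl_score, itl_score = x$itl_score, cutoff = x$cutoff,
         gray_area = unlist(x$gray_area),
         es_ranges = er, score_precision = x$score_precision,
         n = x$n, effective_ranks = unlist(x$effective_ranks),
         formal_ranks = unlist(x$formal_ranks),
         tie_corrections = as.data.frame(x$tie_corrections)),
    class = "es_norm_table"
  )
}
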