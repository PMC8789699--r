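#' Fit Equivalent Score norms for a neuropsychological test
#'
#' One call runs the full norming pipeline on a healthy normative sample:
#' (1) screen each demographic predictor against the raw score with a simple
#' linear model; (2) for each continuous predictor, pick the transform that
#' best fits the shape of its relationship with the score; (3) select the
#' adjustment model by forward stepwise regression with Bonferroni-corrected
#' entry/removal (`alpha / k`); (4) adjust raw scores by the regression
#' equation (floor/ceiling scores are exempt from adjustment but kept in the
#' ranking) and rank them ascending; (5) compute the outer and inner
#' one-sided lower non-parametric tolerance limits from the Beta
#' distribution of order statistics; (6) partition the ranks between the
#' outer limit and the median into ES 1-3 via the z-deviate procedure; and
#' (7) assemble the norm table (cut-off, gray area, ES 0-4 adjusted-score
#' ranges) with conservative tied-rank corrections.
#'
#' @param formula Model formula, e.g. `raw_score ~ age + education + sex`.
#'   The predictor named `sex` (or any factor/character column) is treated
#'   as the binary male = 0 / female = 1 dummy and is never transformed.
#' @param data Data frame with one row per healthy participant.
#' @param test_min,test_max Instrument floor and ceiling (raw-score units).
#'   Rows at either bound keep their raw score (adjustment exemption).
#' @param q Population tail proportion defining "defective" (default 0.05).
#' @param confidence Required tolerance-limit safety level (default 0.95).
#' @param alpha Family-wise significance level for model selection
#'   (default 0.05; entry threshold is `alpha / k`).
#' @param transforms Candidate transform catalogue, see [es_transforms()].
#' @param score_precision Decimal places of the instrument's reporting scale
#'   (default 3).
#' @param rounding Rounding convention for the ES category counts
#'   (`"half_up"` or `"half_down"`).
#' @param id Subject-id column name (default `"subject_id"`; row order is
#'   used if absent).
#' @return An object of class `es_norm`: a list with `call`, `screening`,
#'   `transform_search`, `model` (`es_adjustment`), `scores` (ranked
#'   adjusted scores with tie groups and exemption flags), `tl`
#'   (`tol_limits`), `partition` (`es_partition`), `table`
#'   (`es_norm_table`), `test_range`, `n`.
#' @examples
#' set.seed(7)
#' d <- simulate_norm_sample(n = 300)
#' fit <- es_norm(raw_score ~ age + education + sex, d,
#'                test_min = 0, test_max = 15)
#' fit
#' predict(fit, newdata = data.frame(raw_score = 6, age = 74,
#'                                   education = 8, sex = "F"))
#' @export
es_norm <- function(formula, data, test_min, test_max,
                    q = 0.05, confidence = 0.95, alpha = 0.05,
                    transforms = es_transforms(), score_precision = 3,
                    rounding = c("half_up", "half_down"),
                    id = "subject_id") {
  rounding <- match.arg(rounding)
  if (missing(test_min) || missing(test_max) || test_min >= test_max)
    stop("`test_min` and `test_max` must be given, with test_min < test_max",
         call. = FALSE)
  vars <- all.vars(formula)
  outcome <- vars[1]
  predictors <- vars[-1]
  if (length(predictors) < 1L)
    stop("formula must name at least one demographic predictor", call. = FALSE)
  rs <- data[[outcome]]
  if (is.null(rs)) stop(sprintf("no column '%s' in data", outcome), call. = FALSE)
  if (anyNA(rs)) stop("missing raw scores are not allowed", call. = FALSE)
  if (any(rs < test_min | rs > test_max))
    stop("raw scores outside [test_min, test_max]", call. = FALSE)

  # model fitting and centering use the non-exempt rows only: exempt rows
  # are not adjusted, so the zero-gradient / mean-preservation identities of
  # the adjustment hold on the sample the model actually acts on
  fit_rows <- !(rs <= test_min | rs >= test_max)
  fit_data <- data[fit_rows, , drop = FALSE]

  screening <- screen_predictors(fit_data, outcome, predictors)
  usable <- screening$predictor[!screening$constant]
  is_binary <- function(p) p == "sex" || !is.numeric(data[[p]])
  tsearch <- lapply(usable, function(p) {
    if (is_binary(p))
      list(predictor = p, transform = "identity", r_squared = NA_real_)
    else search_transform(fit_data, outcome, p, transforms)
  })
  names(tsearch) <- usable
  candidates <- vapply(tsearch, `[[`, character(1), "transform")

  model <- if (length(candidates))
    select_model(fit_data, outcome, candidates, alpha, transforms)
  else structure(list(predictors = character(0), coefficients = numeric(0),
                      means = numeric(0), p_values = numeric(0),
                      alpha_adjusted = alpha, k = 0L, n = sum(fit_rows),
                      fit = NULL), class = "es_adjustment")

  scores <- adjust_scores(data, model, outcome, test_min, test_max, id)
  n <- nrow(scores)
  tl <- tol_limits(n, q, confidence)
  part <- es_partition(tl$outer$rank, n, rounding)
  tab <- build_norm_table(scores$adjusted_score, tl$outer, tl$inner, part,
                          score_precision)

  structure(
    list(call = match.call(), outcome = outcome, predictors = predictors,
         screening = screening, transform_search = tsearch, model = model,
         scores = scores, tl = tl, partition = part, table = tab,
         test_range = c(min = test_min, max = test_max),
         score_precision = score_precision, n = n),
    class = "es_norm"
  )
}

#' @export
print.es_norm <- function(x, ...) {
  cat("Equivalent Score norms\n")
  cat("Call: "); print(x$call)
  cat(sprintf("Normative sample: n = %d (%d floor/ceiling rows exempt from adjustment)\n",
              x$n, sum(x$scores$exempt)))
  print(x$model)
  print(x$tl)
  print(x$table)
  invisible(x)
}

#' @export
summary.es_norm <- function(object, ...) {
  structure(list(fit = object), class = "summary.es_norm")
}

#' @export
print.summary.es_norm <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPredictor screening (simple linear models on the fitting rows):\n")
  print(f$screening, row.names = FALSE)
  cat("\n")
  print(f$partition)
  invisible(x)
}

#' @export
coef.es_norm <- function(object, ...) object$model$coefficients

#' @export
residuals.es_norm <- function(object, ...) {
  if (is.null(object$model$fit)) return(numeric(0))
  stats::residuals(object$model$fit)
}

#' Classify new observations against fitted Equivalent Score norms
#'
#' Adjusts each new raw score with the fitted model (floor/ceiling raw
#' scores are exempt, as in fitting) and classifies the adjusted score
#' against the norm table.
#'
#' @param object An `es_norm` fit.
#' @param newdata Data frame with the raw-score column and every covariate
#'   retained by the model; alternatively supply `adjusted` directly.
#' @param adjusted Optional numeric vector of already-adjusted scores,
#'   bypassing the adjustment step.
#' @param ... Unused.
#' @return Data frame: `adjusted_score`, `es` (0-4), `in_gray_area`.
#' @export
predict.es_norm <- function(object, newdata = NULL, adjusted = NULL, ...) {
  if (is.null(adjusted)) {
    if (is.null(newdata)) stop("supply `newdata` or `adjusted`", call. = FALSE)
    sc <- adjust_scores(newdata, object$model, object$outcome,
                        object$test_range[["min"]], object$test_range[["max"]],
                        id = NULL)
    # restore input order
    adjusted <- sc$adjusted_score[order(sc$subject_id)]
  }
  cl <- classify_scores(round(adjusted, object$score_precision), object$table)
  data.frame(adjusted_score = adjusted, es = cl$es,
             in_gray_area = cl$in_gray_area)
}

#' Plot fitted Equivalent Score norms
#'
#' Histogram of the ranked adjusted scores with the ES band boundaries, the
#' cut-off and the gray area marked.
#'
#' @param x An `es_norm` fit.
#' @param ... Passed to [graphics::hist()].
#' @export
plot.es_norm <- function(x, ...) {
  s <- x$scores$adjusted_score
  graphics::hist(s, breaks = "FD", col = "grey85", border = "white",
                 main = "Adjusted scores and ES bands",
                 xlab = sprintf("Adjusted score (n = %d)", x$n), ...)
  b <- x$table$es_ranges[1:4, "upper"]
  graphics::abline(v = b, lty = 2, col = "grey40")
  graphics::abline(v = x$table$cutoff, col = "firebrick")
  graphics::rect(x$table$gray_area[["lower"]], 0, x$table$gray_area[["upper"]],
                 graphics::par("usr")[4], col = grDevices::adjustcolor("orange", 0.15),
                 border = NA)
  mids <- c(mean(c(min(s), b[1])), (b[-4] + b[-1]) / 2,
            mean(c(b[4], max(s))))
  graphics::mtext(paste0("ES", 0:4), side = 3, at = mids, line = 0, cex = 0.8)
  invisible(x)
}
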