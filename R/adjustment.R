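#' Candidate predictor transforms
#'
#' The transform catalogue searched by [search_transform()]: identity,
#' `ln(100 - x)` (the customary age transform, defined for x < 100),
#' `sqrt(x)` (the customary education transform, x >= 0), `ln(x)` (x > 0)
#' and `x^2`. Each entry carries an applicability guard over the observed
#' range.
#'
#' @return Named list of transforms; each has `fn` (the map) and `guard`
#'   (predicate on the observed values).
#' @export
es_transforms <- function() {
  list(
    identity     = list(fn = function(x) x,            guard = function(x) TRUE),
    log100minus  = list(fn = function(x) log(100 - x), guard = function(x) all(x < 100)),
    sqrt         = list(fn = function(x) sqrt(x),      guard = function(x) all(x >= 0)),
    log          = list(fn = function(x) log(x),       guard = function(x) all(x > 0)),
    square       = list(fn = function(x) x^2,          guard = function(x) TRUE)
  )
}

#' Apply a named transform from the catalogue
#'
#' @param x Numeric vector.
#' @param name Transform name, see [es_transforms()].
#' @param transforms Transform catalogue.
#' @return Transformed vector.
#' @export
apply_transform <- function(x, name, transforms = es_transforms()) {
  tr <- transforms[[name]]
  if (is.null(tr)) stop(sprintf("unknown transform '%s'", name), call. = FALSE)
  tr$fn(x)
}

# sex accepts factor/character {M, F} or numeric {0, 1}; male = 0, female = 1
sex_to_numeric <- function(x) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("numeric sex must be 0 (male) / 1 (female)",
                                   call. = FALSE)
    return(as.numeric(x))
  }
  x <- toupper(as.character(x))
  if (!all(x %in% c("M", "F", "0", "1")))
    stop("sex must be coded M/F or 0/1", call. = FALSE)
  as.numeric(x %in% c("F", "1"))
}

#' Screen candidate demographic predictors one at a time
#'
#' Fits a simple linear model of the raw score on each candidate predictor
#' (for a binary predictor such as sex this is the two-group mean comparison,
#' i.e. regression on the 0/1 dummy) and reports coefficient, R-squared and
#' p-value. Constant predictors are flagged and excluded from downstream
#' candidacy.
#'
#' @param data Data frame of the normative sample.
#' @param outcome Name of the raw-score column.
#' @param predictors Character vector of predictor column names.
#' @return Data frame: `predictor`, `estimate`, `r_squared`, `p_value`,
#'   `constant` (logical).
#' @export
screen_predictors <- function(data, outcome = "raw_score",
                              predictors = c("age", "education", "sex")) {
  y <- data[[outcome]]
  if (is.null(y)) stop(sprintf("no column '%s' in data", outcome), call. = FALSE)
  rows <- lapply(predictors, function(p) {
    x <- data[[p]]
    if (is.null(x)) stop(sprintf("no column '%s' in data", p), call. = FALSE)
    if (p == "sex" || !is.numeric(x)) x <- sex_to_numeric(x)
    if (length(unique(x)) < 2L)
      return(data.frame(predictor = p, estimate = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        constant = TRUE))
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    data.frame(predictor = p, estimate = stats::coef(fit)[["x"]],
               r_squared = sm$r.squared,
               p_value = sm$coefficients["x", "Pr(>|t|)"],
               constant = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pick the transform that best fits a predictor's relationship with the score
#'
#' Fits a simple linear model of the raw score on each applicable transform
#' of the predictor and returns the one maximizing R-squared. Ties are broken
#' toward identity, then by catalogue order. Transforms whose guard fails on
#' the observed range are skipped with a warning.
#'
#' @inheritParams screen_predictors
#' @param predictor Single predictor column name.
#' @param transforms Transform catalogue, see [es_transforms()].
#' @return List: `predictor`, `transform` (name), `r_squared`, `estimate`
#'   (slope on the transformed scale), and `fits` (R-squared of every
#'   candidate tried).
#' @export
search_transform <- function(data, outcome = "raw_score", predictor,
                             transforms = es_transforms()) {
  y <- data[[outcome]]
  x <- data[[predictor]]
  if (is.null(y) || is.null(x))
    stop("outcome or predictor column missing", call. = FALSE)
  # identity first so the R^2 tie-break resolves toward it
  nm <- union(intersect("identity", names(transforms)), names(transforms))
  r2 <- stats::setNames(rep(NA_real_, length(nm)), nm)
  beta <- r2
  for (t in nm) {
    if (!transforms[[t]]$guard(x)) {
      warning(sprintf("transform '%s' undefined on the observed range of '%s'; skipped",
                      t, predictor), call. = FALSE)
      next
    }
    tx <- transforms[[t]]$fn(x)
    if (stats::sd(tx) == 0) next
    fit <- stats::lm(y ~ tx)
    r2[t] <- summary(fit)$r.squared
    beta[t] <- stats::coef(fit)[["tx"]]
  }
  if (all(is.na(r2)))
    stop(sprintf("no applicable transform for '%s'", predictor), call. = FALSE)
  best <- nm[which.max(round(r2, 12))]  # first max in catalogue order
  list(predictor = predictor, transform = best, r_squared = r2[[best]],
       estimate = beta[[best]], fits = r2[!is.na(r2)])
}

#' Bonferroni-corrected forward stepwise selection of the adjustment model
#'
#' Forward stepwise multiple regression of the raw score on the (transformed)
#' candidate predictors. A predictor enters only if its coefficient p-value
#' in the enlarged model is below `alpha / k` (k = number of candidates
#' entering selection); after each entry, any included predictor whose
#' p-value has risen to or above that threshold is removed. The procedure is
#' deterministic given the input and can return an empty model (adjusted
#' score = raw score) when nothing survives.
#'
#' @inheritParams screen_predictors
#' @param candidates Named character vector: names are predictor columns,
#'   values are transform names from [es_transforms()] (use `"identity"` for
#'   sex and untransformed predictors).
#' @param alpha Family-wise significance level before correction
#'   (default 0.05).
#' @param transforms Transform catalogue.
#' @return An `es_adjustment` object: `predictors` (named transform vector of
#'   the retained predictors), `coefficients` (slopes on the transformed
#'   scale), `means` (sample means of the transformed covariates; 0.5 for
#'   sex), `p_values`, `alpha_adjusted`, `k`, `n`, and the final `fit`
#'   (`lm` object, `NULL` if empty).
#' @export
select_model <- function(data, outcome = "raw_score", candidates,
                         alpha = 0.05, transforms = es_transforms()) {
  if (length(candidates) < 1L) stop("at least one candidate required", call. = FALSE)
  if (is.null(names(candidates)))
    stop("`candidates` must be named: predictor -> transform", call. = FALSE)
  y <- data[[outcome]]
  k <- length(candidates)
  alpha_adj <- alpha / k

  # design columns on the transformed scale
  X <- lapply(names(candidates), function(p) {
    x <- data[[p]]
    if (is.null(x)) stop(sprintf("no column '%s' in data", p), call. = FALSE)
    if (p == "sex" || !is.numeric(x)) x <- sex_to_numeric(x)
    apply_transform(x, candidates[[p]], transforms)
  })
  names(X) <- names(candidates)
  X <- as.data.frame(X)

  included <- character(0)
  remaining <- names(candidates)
  repeat {
    changed <- FALSE
    if (length(remaining)) {
      pvals <- vapply(remaining, function(p) {
        d <- cbind(y = y, X[c(included, p)])
        fit <- stats::lm(y ~ ., data = d)
        summary(fit)$coefficients[p, "Pr(>|t|)"]
      }, numeric(1))
      if (min(pvals) < alpha_adj) {
        entrant <- remaining[which.min(pvals)]
        included <- c(included, entrant)
        remaining <- setdiff(remaining, entrant)
        changed <- TRUE
      }
    }
    if (length(included)) {
      fit <- stats::lm(y ~ ., data = cbind(y = y, X[included]))
      pv <- summary(fit)$coefficients[included, "Pr(>|t|)", drop = TRUE]
      drop <- included[pv >= alpha_adj]
      if (length(drop)) {
        included <- setdiff(included, drop)
        remaining <- c(remaining, drop)
        changed <- TRUE
      }
    }
    if (!changed) break
  }

  if (length(included) == 0L) {
    return(structure(
      list(predictors = stats::setNames(character(0), character(0)),
           coefficients = numeric(0), means = numeric(0),
           p_values = numeric(0), alpha_adjusted = alpha_adj, k = k,
           n = length(y), fit = NULL),
      class = "es_adjustment"))
  }
  fit <- stats::lm(y ~ ., data = cbind(y = y, X[included]))
  b <- stats::coef(fit)[included]
  pv <- summary(fit)$coefficients[included, "Pr(>|t|)", drop = TRUE]
  # sex is centered at the constant 0.5, continuous covariates at their means
  means <- vapply(included, function(p)
    if (p == "sex") 0.5 else mean(X[[p]]), numeric(1))
  structure(
    list(predictors = candidates[included], coefficients = b, means = means,
         p_values = stats::setNames(pv, included),
         alpha_adjusted = alpha_adj, k = k, n = length(y), fit = fit),
    class = "es_adjustment")
}

#' @export
print.es_adjustment <- function(x, ...) {
  if (length(x$coefficients) == 0L) {
    cat("Empty adjustment model: no predictor significant at alpha =",
        format(x$alpha_adjusted), "(adjusted score = raw score)\n")
    return(invisible(x))
  }
  cat(sprintf("Adjustment model (n = %d, Bonferroni alpha = %.4g, k = %d)\n",
              x$n, x$alpha_adjusted, x$k))
  for (p in names(x$coefficients)) {
    cat(sprintf("  %s [%s]: b = %.5f, mean = %.5f, p = %.3g\n",
                p, x$predictors[[p]], x$coefficients[[p]], x$means[[p]],
                x$p_values[[p]]))
  }
  invisible(x)
}

#' Adjust raw scores for demographic effects and rank them
#'
#' Applies the adjustment equation
#' \deqn{AS = RS + \sum_i [-b_i (x_i - M_{x_i})]}
#' with each covariate on its selected transformed scale; sex (male = 0,
#' female = 1) contributes \eqn{-b_{sex}(sex - 0.5)}. Rows whose raw score
#' sits at the instrument floor (`test_min`) or ceiling (`test_max`) are
#' *exempt*: they keep their raw score but still participate in the ranking
#' (they are real normative observations and count toward n).
#'
#' @inheritParams screen_predictors
#' @param model An `es_adjustment` from [select_model()].
#' @param test_min,test_max Instrument floor and ceiling.
#' @param id Name of the subject-id column (`NULL` to use row order).
#' @return Data frame sorted ascending by adjusted score (stable on subject
#'   id within ties): `subject_id`, `raw_score`, `adjusted_score`, `exempt`,
#'   `rank` (1..n), `tie_group` (integer id shared by equal adjusted scores).
#' @export
adjust_scores <- function(data, model, outcome = "raw_score",
                          test_min = -Inf, test_max = Inf, id = "subject_id") {
  rs <- data[[outcome]]
  if (is.null(rs)) stop(sprintf("no column '%s' in data", outcome), call. = FALSE)
  if (anyNA(rs)) stop("missing raw scores are not allowed", call. = FALSE)
  n <- length(rs)
  ids <- if (!is.null(id) && !is.null(data[[id]])) as.character(data[[id]])
         else sprintf("row%04d", seq_len(n))

  delta <- numeric(n)
  for (p in names(model$coefficients)) {
    x <- data[[p]]
    if (is.null(x)) stop(sprintf("no column '%s' in data", p), call. = FALSE)
    if (anyNA(x))
      stop(sprintf("missing covariate '%s' for row(s): %s", p,
                   paste(ids[is.na(x)], collapse = ", ")), call. = FALSE)
    if (p == "sex" || !is.numeric(x)) x <- sex_to_numeric(x)
    tx <- apply_transform(x, model$predictors[[p]])
    delta <- delta - model$coefficients[[p]] * (tx - model$means[[p]])
  }
  exempt <- rs <= test_min | rs >= test_max
  as_ <- ifelse(exempt, rs, rs + delta)

  ord <- order(as_, ids, method = "radix")
  out <- data.frame(subject_id = ids[ord], raw_score = rs[ord],
                    adjusted_score = as_[ord], exempt = exempt[ord],
                    rank = seq_len(n), stringsAsFactors = FALSE)
  out$tie_group <- cumsum(c(TRUE, diff(out$adjusted_score) != 0))
  out
}
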