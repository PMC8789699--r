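sample_with <- function(n = 300, seed = 1, ...) {
  simulate_norm_sample(n = n, seed = seed, ...)
}

test_that("screening recovers exact and near-exact marginal effects", {
  d <- data.frame(subject_id = sprintf("S%03d", 1:100),
                  education = rep(5:14, each = 10),
                  age = runif(100, 30, 80),
                  sex = rep(c("M", "F"), 50))
  d$raw_score <- 2 * d$education
  # the exact fit makes summary.lm warn about perfect fits; that is the point
  sc <- suppressWarnings(
    screen_predictors(d, "raw_score", c("age", "education", "sex")))
  expect_equal(sc$r_squared[sc$predictor == "education"], 1)
  expect_equal(sc$estimate[sc$predictor == "education"], 2)

  # known +3-point sex effect recovered within Monte-Carlo error
  set.seed(21)
  d2 <- sample_with(n = 2000, seed = 21, b_sex = 3, b_age = 0, b_edu = 0,
                    intercept = 7, noise_sd = 1)
  sc2 <- screen_predictors(d2, "raw_score", "sex")
  expect_equal(sc2$estimate, 3, tolerance = 0.15)
})

test_that("null predictors are rejected at about the nominal rate", {
  set.seed(99)
  reps <- 300
  p <- replicate(reps, {
    d <- simulate_norm_sample(n = 60, b_age = 0, b_edu = 0, b_sex = 0,
                              intercept = 7, noise_sd = 1.5)
    screen_predictors(d, "raw_score", "age")$p_value
  })
  rate <- mean(p < 0.05)
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / reps) + 0.01)
})

test_that("constant predictors are flagged and excluded", {
  d <- data.frame(raw_score = rnorm(20, 10), age = 50, sex = rep("M", 20))
  sc <- screen_predictors(d, "raw_score", c("age", "sex"))
  expect_true(all(sc$constant))
  expect_true(all(is.na(sc$p_value)))
})

test_that("transform search picks the generating shape", {
  set.seed(5)
  n <- 300
  age <- runif(n, 20, 90)
  edu <- runif(n, 5, 18)
  d_lin <- data.frame(raw_score = 3 + 0.1 * age + rnorm(n, 0, 0.01), age = age)
  expect_identical(search_transform(d_lin, "raw_score", "age")$transform,
                   "identity")
  d_ln <- data.frame(raw_score = 1 + 2 * log(100 - age) + rnorm(n, 0, 0.1),
                     age = age)
  expect_identical(search_transform(d_ln, "raw_score", "age")$transform,
                   "log100minus")
  d_sq <- data.frame(raw_score = 1 + 2 * sqrt(edu) + rnorm(n, 0, 0.05),
                     education = edu)
  expect_identical(search_transform(d_sq, "raw_score", "education")$transform,
                   "sqrt")
})

test_that("transforms undefined on the observed range are skipped with warning", {
  d <- data.frame(raw_score = rnorm(50, 10), age = runif(50, 90, 110))
  expect_warning(res <- search_transform(d, "raw_score", "age"),
                 "log100minus.*undefined")
  expect_false(res$transform %in% c("log100minus"))
})

test_that("stepwise keeps a dominant predictor and can return an empty model", {
  set.seed(8)
  d <- sample_with(n = 300, seed = 8, b_age = 2, b_edu = 0, b_sex = 0,
                   noise_sd = 0.5)
  m <- select_model(d, "raw_score",
                    c(age = "log100minus", education = "sqrt", sex = "identity"))
  expect_true("age" %in% names(m$coefficients))
  expect_false("education" %in% names(m$coefficients))
  expect_equal(m$alpha_adjusted, 0.05 / 3)

  d0 <- simulate_norm_sample(n = 80, seed = 123, b_age = 0, b_edu = 0,
                             b_sex = 0, intercept = 7, noise_sd = 1.5)
  m0 <- select_model(d0, "raw_score",
                     c(age = "identity", education = "identity",
                       sex = "identity"))
  # an empty model is a valid outcome, not an error
  expect_s3_class(m0, "es_adjustment")
  a <- adjust_scores(d0, m0, test_min = 0, test_max = 15)
  non_ex <- !a$exempt
  expect_equal(a$adjusted_score[non_ex], a$raw_score[non_ex])
})

test_that("adjustment follows the printed centering equation", {
  # hand arithmetic: b_edu = 0.5, M_edu = 10, education = 8, RS = 20
  # AS = 20 + (-0.5 * (8 - 10)) = 21
  model <- structure(list(predictors = c(education = "identity"),
                          coefficients = c(education = 0.5),
                          means = c(education = 10),
                          p_values = c(education = 0.001),
                          alpha_adjusted = 0.05, k = 1L, n = 3L, fit = NULL),
                     class = "es_adjustment")
  d <- data.frame(subject_id = c("a", "b", "c"),
                  raw_score = c(20, 20, 30),
                  education = c(8, 10, 12))
  a <- adjust_scores(d, model, test_min = 0, test_max = 30)
  expect_equal(a$adjusted_score[a$subject_id == "a"], 21)
  # covariate at the sample mean leaves the score untouched
  expect_equal(a$adjusted_score[a$subject_id == "b"], 20)
  # ceiling row keeps its raw score and is flagged exempt
  expect_true(a$exempt[a$subject_id == "c"])
  expect_equal(a$adjusted_score[a$subject_id == "c"], 30)
})

test_that("sex is centered at 0.5, with male = 0 and female = 1", {
  model <- structure(list(predictors = c(sex = "identity"),
                          coefficients = c(sex = 2),
                          means = c(sex = 0.5),
                          p_values = c(sex = 0.001),
                          alpha_adjusted = 0.05, k = 1L, n = 2L, fit = NULL),
                     class = "es_adjustment")
  d <- data.frame(subject_id = c("m", "f"), raw_score = c(10, 10),
                  sex = c("M", "F"))
  a <- adjust_scores(d, model, test_min = 0, test_max = 20)
  expect_equal(a$adjusted_score[a$subject_id == "m"], 10 - 2 * (0 - 0.5))
  expect_equal(a$adjusted_score[a$subject_id == "f"], 10 - 2 * (1 - 0.5))
})

test_that("missing covariates are rejected with an identifiable error", {
  model <- structure(list(predictors = c(age = "identity"),
                          coefficients = c(age = 0.1),
                          means = c(age = 50),
                          p_values = c(age = 0.001),
                          alpha_adjusted = 0.05, k = 1L, n = 2L, fit = NULL),
                     class = "es_adjustment")
  d <- data.frame(subject_id = c("ok", "bad"), raw_score = c(5, 6),
                  age = c(40, NA))
  expect_error(adjust_scores(d, model, test_min = 0, test_max = 15),
               "missing covariate 'age'.*bad")
})

test_that("adjustment removes the modeled gradient and preserves the mean", {
  set.seed(31)
  d <- sample_with(n = 400, seed = 31, b_sex = 0)
  fit <- es_norm(raw_score ~ age + education, d, test_min = 0, test_max = 15)
  a <- fit$scores
  non_ex <- !a$exempt
  expect_equal(mean(a$adjusted_score[non_ex]), mean(a$raw_score[non_ex]),
               tolerance = 1e-8)
  # re-merge covariates and regress adjusted scores on retained transforms
  dd <- d[match(a$subject_id, d$subject_id), ]
  for (p in names(coef(fit))) {
    tx <- apply_transform(dd[[p]][non_ex], fit$model$predictors[[p]])
    b <- coef(lm(a$adjusted_score[non_ex] ~ tx))[["tx"]]
    expect_lt(abs(b), 1e-8)
  }
})

test_that("ties in adjusted scores share a tie group under a stable order", {
  d <- data.frame(subject_id = c("d", "c", "b", "a"),
                  raw_score = c(5, 5, 4, 6))
  model <- structure(list(predictors = character(0),
                          coefficients = numeric(0), means = numeric(0),
                          p_values = numeric(0), alpha_adjusted = 0.05,
                          k = 0L, n = 4L, fit = NULL),
                     class = "es_adjustment")
  a <- adjust_scores(d, model, test_min = 0, test_max = 10)
  expect_identical(a$rank, 1:4)
  expect_identical(a$subject_id[2:3], c("c", "d"))  # stable on id within tie
  expect_identical(a$tie_group, c(1L, 2L, 2L, 3L))
})
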