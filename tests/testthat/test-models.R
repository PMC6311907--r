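make_two_cohorts <- function(seed = 51, n = 50, p = 6) {
  set.seed(seed)
  beta <- c(1, -0.8, 0.6, rep(0, p - 3))
  mk <- function(b0) {
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("g", seq_len(p))))
    y <- rbinom(n, 1, plogis(b0 + X %*% beta))
    if (length(unique(y)) == 1L) y[1:2] <- 0:1
    list(X = X, y = y)
  }
  list(mk(-1), mk(1))
}

test_that("integrated fit with one dataset equals the single-dataset fit", {
  d <- make_two_cohorts()[[1]]
  opts <- solver_options(tol_outer = 1e-10, tol_inner = 1e-9)
  cfg <- penalty_config("enet", alpha = 0.5, lambda = 0.05, mu = 1e7)
  fi <- fit_integrated(list(d), cfg, options = opts)
  fs <- fit_single(d, cfg, options = opts)
  expect_equal(unname(fi$beta), unname(fs$beta), tolerance = 1e-5)
  expect_equal(fi$dataset_intercepts[1], fs$dataset_intercepts[1],
               tolerance = 1e-4)
})

test_that("two identical copies of a dataset reproduce the single fit", {
  d <- make_two_cohorts()[[1]]
  opts <- solver_options(tol_outer = 1e-10, tol_inner = 1e-9)
  cfg <- penalty_config("lasso", lambda = 0.05, mu = 1e7)
  fdup <- fit_integrated(list(d, d), cfg, options = opts)
  fs <- fit_single(d, cfg, options = opts)
  expect_equal(unname(fdup$beta), unname(fs$beta), tolerance = 1e-5)
  expect_equal(fdup$dataset_intercepts[1], fdup$dataset_intercepts[2],
               tolerance = 1e-8)
})

test_that("merged fit under a huge penalty returns the pooled null model", {
  cohorts <- make_two_cohorts()
  fit <- fit_merged(cohorts, penalty_config("lasso", lambda = 1e6))
  expect_equal(unname(fit$beta), rep(0, 6))
  ybar <- mean(unlist(lapply(cohorts, `[[`, "y")))
  expect_equal(fit$dataset_intercepts[1], qlogis(ybar), tolerance = 1e-6)
})

test_that("merged elastic-net fit matches the reference penalized GLM", {
  skip_if_not_installed("glmnet")
  cohorts <- make_two_cohorts()
  X <- rbind(cohorts[[1]]$X, cohorts[[2]]$X)
  y <- c(cohorts[[1]]$y, cohorts[[2]]$y)
  fit <- fit_merged(cohorts, penalty_config("enet", alpha = 0.5,
                                            lambda = 0.05),
                    options = solver_options(tol_outer = 1e-10,
                                             tol_inner = 1e-9))
  ref <- glmnet::glmnet(X, y, family = "binomial", alpha = 0.5,
                        lambda = 0.05, standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(fit$beta - as.numeric(ref$beta))), 1e-3)
})

test_that("datasets disagreeing on features are rejected with the offenders named", {
  cohorts <- make_two_cohorts()
  colnames(cohorts[[2]]$X)[2] <- "weird_gene"
  expect_error(fit_integrated(cohorts, penalty_config("lasso")),
               "weird_gene")
})

test_that("prediction is the logistic evaluation with dataset-specific intercepts", {
  fit <- structure(
    list(beta = c(a = 0.5, b = -1), dataset_intercepts = c(-1, 2),
         intercept = "per_sample", feature_names = c("a", "b")),
    class = "intlognet_fit")
  Xn <- rbind(c(1, 0), c(0, 1), c(2, -1))
  expect_equal(predict(fit, Xn, dataset = c(1, 2, 1)),
               plogis(c(-1 + 0.5, 2 - 1, -1 + 2)), tolerance = 1e-12)
  expect_equal(predict(fit, Xn, dataset = 1, type = "link"),
               c(-0.5, -2, 1), tolerance = 1e-12)
  # beta = 0, intercept 0: coin-flip probabilities
  fit0 <- structure(
    list(beta = c(a = 0, b = 0), dataset_intercepts = 0,
         intercept = "scalar", feature_names = c("a", "b")),
    class = "intlognet_fit")
  expect_equal(predict(fit0, Xn), rep(0.5, 3))
  # monotonicity in a positive-coefficient feature
  X1 <- rbind(c(1, 1)); X2 <- rbind(c(2, 1))
  expect_gte(predict(fit, X2, dataset = 1), predict(fit, X1, dataset = 1))
  # unseen sources are a stated model limitation: explicit error, opt-in mean
  expect_error(predict(fit, Xn, dataset = c(1, 3, 1)), "not in the training")
  pm <- predict(fit, Xn, dataset = c(1, 3, 1), unknown_dataset = "mean")
  expect_equal(pm[2], plogis(mean(c(-1, 2)) + 0 * 0.5 + 1 * -1),
               tolerance = 1e-12)
})

test_that("cross-validation selects lambda on stratified within-dataset folds", {
  cohorts <- make_two_cohorts(seed = 61, n = 60)
  cv <- cv_lambda(cohorts, penalty_config("lasso", mu = 1),
                  fit_kind = "integrated",
                  lambda_grid = c(0.2, 0.05, 0.01), n_folds = 3, seed = 2)
  expect_true(cv$best_lambda %in% c(0.2, 0.05, 0.01))
  expect_equal(nrow(cv$cv_table), 3)
  expect_equal(cv$fit$n_training_samples, 120)
  # single grid value is returned untouched
  cv1 <- cv_lambda(cohorts, penalty_config("lasso", mu = 1),
                   fit_kind = "merged", lambda_grid = 0.07, n_folds = 3,
                   seed = 2)
  expect_equal(cv1$best_lambda, 0.07)
  # fold assignment partitions samples and respects dataset strata
  y <- unlist(lapply(cohorts, `[[`, "y"))
  ids <- rep(1:2, each = 60)
  fold <- intlognet:::make_cv_folds(y, ids, 3, seed = 4)
  expect_equal(length(fold), 120)
  expect_true(all(fold %in% 1:3))
  for (f in 1:3) {
    expect_true(all(table(ids[fold == f]) >= 1))
    expect_equal(length(unique(y[fold == f])), 2)
  }
})

test_that("cross-validated AUC on pure noise stays near chance", {
  set.seed(71)
  mk <- function() {
    X <- matrix(rnorm(60 * 5), 60, 5,
                dimnames = list(NULL, paste0("g", 1:5)))
    list(X = X, y = rep(0:1, 30))
  }
  cv <- cv_lambda(list(mk(), mk()), penalty_config("lasso", mu = 1),
                  fit_kind = "integrated",
                  lambda_grid = c(0.3, 0.1), n_folds = 3, seed = 5)
  expect_lt(abs(max(cv$cv_table$mean_auc) - 0.5), 0.15)
})

test_that("fitted models round-trip through the TSV serialization", {
  cohorts <- make_two_cohorts()
  fit <- fit_integrated(cohorts, penalty_config("lasso", lambda = 0.05))
  prefix <- file.path(withr::local_tempdir(), "model")
  write_fit(fit, prefix)
  back <- read_fit(prefix)
  Xn <- cohorts[[1]]$X[1:5, ]
  expect_equal(predict(back, Xn, dataset = 2),
               predict(fit, Xn, dataset = 2), tolerance = 1e-10)
})
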