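check_dataset_list <- function(datasets) {
  if (!length(datasets)) stop("need at least one dataset")
  get_names <- function(d) {
    nm <- colnames(d$X)
    if (is.null(nm)) paste0("V", seq_len(ncol(d$X))) else nm
  }
  ref <- get_names(datasets[[1]])
  for (m in seq_along(datasets)) {
    d <- datasets[[m]]
    if (is.null(d$X) || is.null(d$y)) {
      stop("each dataset must be a list with elements X and y")
    }
    nm <- get_names(d)
    if (length(nm) != length(ref) || any(nm != ref)) {
      bad <- union(setdiff(nm, ref), setdiff(ref, nm))
      stop("datasets disagree on features; offending columns: ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  ref
}

stack_datasets <- function(datasets) {
  feats <- check_dataset_list(datasets)
  X <- do.call(rbind, lapply(datasets, function(d) as.matrix(d$X)))
  y <- unlist(lapply(datasets, function(d) d$y), use.names = FALSE)
  ids <- rep(seq_along(datasets), vapply(datasets, function(d) nrow(d$X), 1L))
  stacked_design(X, y, ids, feats)
}

#' Integrative fit across multiple datasets
#'
#' Stacks the datasets into one design, keeps a shared coefficient vector
#' `beta`, and gives every sample its own intercept shrunk toward a common
#' within-dataset value by the sample-relation Laplacian penalty (weight
#' `mu` from the penalty configuration). Per-dataset intercepts for
#' prediction are the within-dataset averages of the fitted per-sample
#' intercepts.
#'
#' @param datasets List of datasets, each a list with numeric matrix `X`
#'   (samples x features, identical columns across datasets) and 0/1 vector `y`.
#' @param config A [penalty_config()].
#' @param network A [feature_network()] for the network penalty kinds.
#' @param options A [solver_options()].
#' @return An `intlognet_fit` with `method = "integrated"` and one averaged
#'   intercept per dataset.
#' @export
fit_integrated <- function(datasets, config, network = NULL,
                           options = solver_options()) {
  design <- stack_datasets(datasets)
  fit <- fit_penalized_logistic(design, config, network, options,
                                intercept = "per_sample")
  fit$method <- "integrated"
  fit
}

#' Direct-merging fit
#'
#' Concatenates all datasets and fits a single-intercept penalized logistic
#' regression, ignoring dataset heterogeneity (the "Merge-" baseline).
#'
#' @inheritParams fit_integrated
#' @return An `intlognet_fit` with `method = "merged"` and one intercept.
#' @export
fit_merged <- function(datasets, config, network = NULL,
                       options = solver_options()) {
  design <- stack_datasets(datasets)
  # one pseudo-dataset: heterogeneity collapsed into a common intercept
  design_one <- stacked_design(design$X, design$y,
                               rep(1L, nrow(design$X)), design$feature_names)
  fit <- fit_penalized_logistic(design_one, config, network, options,
                                intercept = "scalar")
  fit$method <- "merged"
  fit
}

#' Single-dataset fit
#'
#' Penalized logistic regression on one dataset with an unpenalized scalar
#' intercept (the "no integration" baseline).
#'
#' @param dataset A list with `X` and `y`.
#' @inheritParams fit_integrated
#' @return An `intlognet_fit` with `method = "single"`.
#' @export
fit_single <- function(dataset, config, network = NULL,
                       options = solver_options()) {
  fit <- fit_merged(list(dataset), config, network, options)
  fit$method <- "single"
  fit
}

#' Predicted class-1 probabilities
#'
#' Evaluates `plogis(intercept[dataset] + X beta)`. Integrated fits keep one
#' averaged intercept per training dataset, so new samples must declare which
#' training dataset they originate from; the model does not define an
#' intercept for unseen sources. Setting `unknown_dataset = "mean"` opts in
#' to using the mean of all dataset intercepts instead.
#'
#' @param object An `intlognet_fit`.
#' @param newdata Numeric matrix of samples x features (training feature
#'   order).
#' @param dataset Integer vector (length 1 or `nrow(newdata)`) of originating
#'   training datasets; ignored by scalar-intercept fits.
#' @param type `"response"` for probabilities, `"link"` for the linear
#'   predictor.
#' @param unknown_dataset `"error"` (default) or `"mean"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.intlognet_fit <- function(object, newdata, dataset = NULL,
                                  type = c("response", "link"),
                                  unknown_dataset = c("error", "mean"), ...) {
  type <- match.arg(type)
  unknown_dataset <- match.arg(unknown_dataset)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != length(object$beta)) {
    stop("newdata must have ", length(object$beta), " columns")
  }
  if (object$intercept == "scalar" || length(object$dataset_intercepts) == 1L) {
    b0 <- rep(object$dataset_intercepts[1], nrow(newdata))
  } else {
    if (is.null(dataset)) {
      stop("integrated fits need `dataset`: the training dataset each new ",
           "sample originates from")
    }
    dataset <- as.integer(rep(dataset, length.out = nrow(newdata)))
    seen <- seq_along(object$dataset_intercepts)
    bad <- !(dataset %in% seen)
    if (any(bad)) {
      if (unknown_dataset == "error") {
        stop("dataset id(s) ", paste(unique(dataset[bad]), collapse = ", "),
             " were not in the training data; the model only defines ",
             "intercepts for known sources (use unknown_dataset = \"mean\" ",
             "to fall back to the average intercept)")
      }
      dataset[bad] <- NA_integer_
    }
    b0 <- object$dataset_intercepts[dataset]
    b0[is.na(b0)] <- mean(object$dataset_intercepts)
  }
  eta <- b0 + as.numeric(newdata %*% object$beta)
  if (type == "link") eta else stats::plogis(eta)
}

# --- cross-validation -------------------------------------------------------

#' Default lambda grid
#'
#' Ten logarithmically spaced values spanning the sparse and dense regimes.
#' @param n_lambda Number of grid points.
#' @param min,max Grid endpoints.
#' @return Decreasing numeric vector.
#' @export
default_lambda_grid <- function(n_lambda = 10, min = 1e-3, max = 1) {
  sort(exp(seq(log(min), log(max), length.out = n_lambda)), decreasing = TRUE)
}

# Stratified fold assignment: within each dataset and outcome class, samples
# are shuffled and dealt round-robin, so every fold preserves the dataset
# composition and class balance as far as counts allow.
make_cv_folds <- function(y, dataset_ids, n_folds, seed) {
  n <- length(y)
  for (attempt in 0:9) {
    set.seed(seed + attempt)
    fold <- integer(n)
    for (m in unique(dataset_ids)) {
      for (cls in unique(y)) {
        idx <- which(dataset_ids == m & y == cls)
        idx <- sample(idx)
        fold[idx] <- rep_len(sample(n_folds), length(idx))
      }
    }
    ok <- all(vapply(seq_len(n_folds), function(f) {
      yv <- y[fold == f]
      length(unique(yv)) == 2L && sum(fold != f) > 0
    }, logical(1)))
    if (ok) return(fold)
  }
  stop("could not build ", n_folds,
       "-fold partition with both classes in every fold after 10 attempts")
}

subset_datasets <- function(datasets, fold, keep_fold, train = TRUE) {
  offs <- c(0L, cumsum(vapply(datasets, function(d) nrow(d$X), 1L)))
  out <- vector("list", length(datasets))
  for (m in seq_along(datasets)) {
    local_fold <- fold[(offs[m] + 1L):offs[m + 1L]]
    take <- if (train) local_fold != keep_fold else local_fold == keep_fold
    out[[m]] <- list(X = datasets[[m]]$X[take, , drop = FALSE],
                     y = datasets[[m]]$y[take])
  }
  out
}

fit_kind_dispatch <- function(kind, datasets, config, network, options,
                              init = NULL) {
  if (kind == "integrated") {
    design <- stack_datasets(datasets)
    fit <- fit_penalized_logistic(design, config, network, options,
                                  intercept = "per_sample", init = init)
    fit$method <- "integrated"
  } else {
    design <- stack_datasets(datasets)
    design <- stacked_design(design$X, design$y, rep(1L, nrow(design$X)),
                             design$feature_names)
    fit <- fit_penalized_logistic(design, config, network, options,
                                  intercept = "scalar", init = init)
    fit$method <- if (kind == "merged") "merged" else "single"
  }
  fit
}

#' Cross-validated selection of lambda
#'
#' Stratified folds are drawn within every dataset (each fold preserves the
#' dataset composition and, as far as counts allow, the class balance). For
#' every grid value the model is fit on the training folds — warm-started
#' along the decreasing lambda path — and scored by AUC on the pooled held-out
#' fold. The grid value with the best mean validation AUC wins; ties go to
#' the larger (sparser) lambda. The returned fit is refit on all data at the
#' winning lambda.
#'
#' @param datasets List of datasets (`X`, `y`); a single dataset may be given
#'   as `list(X=, y=)` or `list(list(X=, y=))` when `fit_kind = "single"`.
#' @param config A [penalty_config()]; its `lambda` is ignored in favor of
#'   the grid.
#' @param network Optional [feature_network()].
#' @param fit_kind `"integrated"`, `"merged"` or `"single"`.
#' @param lambda_grid Positive grid of penalty weights.
#' @param n_folds Number of folds (>= 2).
#' @param seed Integer seed for the fold draw.
#' @param options A [solver_options()].
#' @return List with `best_lambda`, `cv_table` (data.frame of lambda,
#'   mean/sd validation AUC and per-fold AUCs) and `fit` (refit on all data
#'   at `best_lambda`).
#' @export
cv_lambda <- function(datasets, config, network = NULL,
                      fit_kind = c("integrated", "merged", "single"),
                      lambda_grid = default_lambda_grid(), n_folds = 5,
                      seed = 1, options = solver_options()) {
  fit_kind <- match.arg(fit_kind)
  if (!is.null(datasets$X)) datasets <- list(datasets)
  stopifnot(n_folds >= 2, length(lambda_grid) >= 1, all(lambda_grid > 0))
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  y_all <- unlist(lapply(datasets, function(d) d$y), use.names = FALSE)
  ids_all <- rep(seq_along(datasets),
                 vapply(datasets, function(d) nrow(d$X), 1L))
  fold <- make_cv_folds(y_all, ids_all, n_folds, seed)
  auc_mat <- matrix(NA_real_, length(lambda_grid), n_folds,
                    dimnames = list(NULL, paste0("fold", seq_len(n_folds))))
  for (f in seq_len(n_folds)) {
    train <- subset_datasets(datasets, fold, f, train = TRUE)
    valid <- subset_datasets(datasets, fold, f, train = FALSE)
    Xv <- do.call(rbind, lapply(valid, function(d) as.matrix(d$X)))
    yv <- unlist(lapply(valid, function(d) d$y), use.names = FALSE)
    dv <- rep(seq_along(valid), vapply(valid, function(d) nrow(d$X), 1L))
    init <- NULL
    for (li in seq_along(lambda_grid)) {
      cfg <- config
      cfg$lambda <- lambda_grid[li]
      fit <- fit_kind_dispatch(fit_kind, train, cfg, network, options, init)
      init <- list(beta = fit$beta, beta0 = NULL)
      ph <- predict(fit, Xv, dataset = dv)
      auc_mat[li, f] <- auc_rank(yv, ph)
    }
  }
  mean_auc <- rowMeans(auc_mat)
  # ties broken toward the larger lambda; grid is stored decreasing
  best_i <- which(mean_auc >= max(mean_auc) - 1e-12)[1]
  best_lambda <- lambda_grid[best_i]
  cfg <- config
  cfg$lambda <- best_lambda
  final <- fit_kind_dispatch(fit_kind, datasets, cfg, network, options)
  final$n_training_samples <- length(y_all)
  cv_table <- data.frame(lambda = lambda_grid, mean_auc = mean_auc,
                         sd_auc = apply(auc_mat, 1, stats::sd))
  cv_table <- cbind(cv_table, auc_mat)
  list(best_lambda = best_lambda, cv_table = cv_table, fit = final)
}

# --- serialization ----------------------------------------------------------

#' Write a fitted model as a two-file TSV pair
#'
#' `<prefix>_features.tsv` holds feature names and coefficients;
#' `<prefix>_datasets.tsv` holds dataset ids and averaged intercepts.
#'
#' @param fit An `intlognet_fit`.
#' @param prefix Output path prefix.
#' @return Invisibly, the two file paths.
#' @export
write_fit <- function(fit, prefix) {
  fp <- paste0(prefix, "_features.tsv")
  dp <- paste0(prefix, "_datasets.tsv")
  utils::write.table(
    data.frame(feature = names(fit$beta), beta = unname(fit$beta)),
    fp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(dataset = seq_along(fit$dataset_intercepts),
               intercept = fit$dataset_intercepts),
    dp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(features = fp, datasets = dp))
}

#' Read a model written by [write_fit()]
#'
#' @param prefix Path prefix used when writing.
#' @return A minimal `intlognet_fit` usable for prediction.
#' @export
read_fit <- function(prefix) {
  feats <- utils::read.table(paste0(prefix, "_features.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  dsets <- utils::read.table(paste0(prefix, "_datasets.tsv"), sep = "\t",
                             header = TRUE)
  beta <- feats$beta
  names(beta) <- feats$feature
  structure(
    list(beta = beta, beta0 = NULL,
         dataset_intercepts = dsets$intercept,
         objective_trace = NULL, converged = NA, n_outer_iter = NA_integer_,
         config = NULL,
         intercept = if (nrow(dsets) == 1L) "scalar" else "per_sample",
         feature_names = feats$feature, method = "deserialized"),
    class = "intlognet_fit")
}
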