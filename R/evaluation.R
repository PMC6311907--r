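#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney statistic
#' with ties counted one half: the probability that a random case outranks a
#' random control.
#'
#' @param y_true Binary 0/1 vector with both classes present.
#' @param p_hat Numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc_rank <- function(y_true, p_hat) {
  y_true <- as.integer(y_true)
  n1 <- sum(y_true == 1L)
  n0 <- sum(y_true == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: y_true must contain both classes")
  }
  r <- rank(p_hat)  # average ranks handle ties as 1/2
  (sum(r[y_true == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Prediction metrics
#'
#' Sensitivity, specificity and accuracy at the given probability threshold,
#' plus the rank-statistic AUC.
#'
#' @param y_true Binary 0/1 vector.
#' @param p_hat Predicted probabilities.
#' @param threshold Classification cut on `p_hat` (default 0.5).
#' @return Named list: `sensitivity`, `specificity`, `accuracy`, `auc`.
#' @export
prediction_metrics <- function(y_true, p_hat, threshold = 0.5) {
  stopifnot(length(y_true) == length(p_hat))
  y_true <- as.integer(y_true)
  yhat <- as.integer(p_hat > threshold)
  tp <- sum(yhat == 1L & y_true == 1L)
  tn <- sum(yhat == 0L & y_true == 0L)
  fp <- sum(yhat == 1L & y_true == 0L)
  fn <- sum(yhat == 0L & y_true == 1L)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    accuracy = (tp + tn) / length(y_true),
    auc = auc_rank(y_true, p_hat)
  )
}

#' Variable-selection metrics
#'
#' Precision, recall and F1 of the estimated support (coefficients exceeding
#' `zero_tol` in absolute value) against the true support. An empty estimated
#' support yields precision 0 with `empty_support = TRUE`.
#'
#' @param beta_hat Estimated coefficients.
#' @param beta_true True coefficients (same length).
#' @param zero_tol Support threshold.
#' @return Named list: `precision`, `recall`, `f1`, `n_selected`,
#'   `empty_support`.
#' @export
selection_metrics <- function(beta_hat, beta_true, zero_tol = 1e-8) {
  stopifnot(length(beta_hat) == length(beta_true))
  shat <- abs(beta_hat) > zero_tol
  strue <- abs(beta_true) > zero_tol
  tp <- sum(shat & strue)
  precision <- if (sum(shat) > 0) tp / sum(shat) else 0
  recall <- if (sum(strue) > 0) tp / sum(strue) else NA_real_
  f1 <- if (!is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       n_selected = sum(shat), empty_support = sum(shat) == 0)
}

parse_method <- function(method) {
  parts <- strsplit(method, "-", fixed = TRUE)[[1]]
  kind <- parts[1]
  penalty <- paste(parts[-1], collapse = "-")
  penalty <- sub("-", "_", penalty, fixed = TRUE)
  if (penalty == "abs-network") penalty <- "abs_network"
  if (!kind %in% c("single", "merge", "int")) {
    stop("method must look like 'int-lasso', 'merge-network', ",
         "'single-abs_network', ...; got ", method)
  }
  if (!penalty %in% c("lasso", "enet", "network", "abs_network")) {
    stop("unknown penalty in method ", method)
  }
  list(kind = kind, penalty = penalty)
}

evaluate_method <- function(method, sim, lambda_grid, n_folds, seed,
                            alpha = 0.5, mu = 1, options = solver_options(),
                            zero_tol = 1e-8) {
  ms <- parse_method(method)
  config <- penalty_config(ms$penalty, alpha = alpha, lambda = 1, mu = mu)
  net <- if (needs_network(config)) sim$network else NULL
  Xte <- do.call(rbind, lapply(sim$test, function(d) as.matrix(d$X)))
  yte <- unlist(lapply(sim$test, function(d) d$y), use.names = FALSE)
  dte <- rep(seq_along(sim$test),
             vapply(sim$test, function(d) nrow(d$X), 1L))
  run_one <- function(datasets, fit_kind, ds_pred) {
    cv <- cv_lambda(datasets, config, net, fit_kind, lambda_grid, n_folds,
                    seed = seed, options = options)
    ph <- predict(cv$fit, Xte, dataset = ds_pred)
    list(fit = cv$fit, p_hat = ph, best_lambda = cv$best_lambda,
         auc = auc_rank(yte, ph))
  }
  if (ms$kind == "int") {
    res <- run_one(sim$train, "integrated", dte)
  } else if (ms$kind == "merge") {
    res <- run_one(sim$train, "merged", NULL)
  } else {
    # no-integration baseline: fit each training dataset separately,
    # predict all pooled test sets, keep the best AUC of the four
    runs <- lapply(sim$train, function(d) run_one(list(d), "single", NULL))
    res <- runs[[which.max(vapply(runs, `[[`, 0, "auc"))]]
  }
  pm <- prediction_metrics(yte, res$p_hat)
  sm <- selection_metrics(res$fit$beta, sim$beta_true, zero_tol)
  c(list(method = method, best_lambda = res$best_lambda), pm,
    sm[c("precision", "recall", "f1", "n_selected")])
}

#' Replicated simulation experiment
#'
#' For every replicate: draw a synthetic study, then for every method select
#' lambda by cross-validation, refit on the full training data, predict the
#' pooled test sets, and record the seven prediction/selection metrics. The
#' `single-*` baselines fit each training dataset separately and report the
#' model with the best pooled-test AUC. A failed replicate is retried with a
#' perturbed seed (at most twice) and logged, never dropped silently.
#'
#' @param methods Character vector like `c("int-lasso", "merge-enet",
#'   "single-abs_network")`.
#' @param n_replicates Number of simulation replicates.
#' @param config A [simulation_config()]; its seed is advanced per replicate.
#' @param lambda_grid Penalty grid for [cv_lambda()].
#' @param n_folds Cross-validation folds.
#' @param alpha,mu Penalty hyperparameters (alpha is forced to 1 for lasso).
#' @param options A [solver_options()].
#' @return Object of class `intlognet_experiment`: list with `results` (one
#'   row per replicate x method) and `summary` (per-method mean and sd of
#'   every metric).
#' @export
run_experiment <- function(methods, n_replicates = 30,
                           config = simulation_config(),
                           lambda_grid = default_lambda_grid(), n_folds = 5,
                           alpha = 0.5, mu = 1, options = solver_options()) {
  rows <- list()
  for (r in seq_len(n_replicates)) {
    base_seed <- config$seed + (r - 1L)
    done <- FALSE
    for (retry in 0:2) {
      seed_r <- base_seed + retry * 1000003L
      res <- tryCatch({
        cfg <- config
        cfg$seed <- seed_r
        sim <- simulate_datasets(cfg)
        lapply(methods, function(m) {
          evaluate_method(m, sim, lambda_grid, n_folds, seed = seed_r,
                          alpha = alpha, mu = mu, options = options)
        })
      }, error = function(e) e)
      if (!inherits(res, "error")) {
        for (one in res) {
          rows[[length(rows) + 1L]] <- c(list(replicate = r, seed = seed_r),
                                         one)
        }
        done <- TRUE
        break
      }
      message("replicate ", r, " failed (", conditionMessage(res),
              "); retrying with a new seed")
    }
    if (!done) stop("replicate ", r, " failed after 3 attempts")
  }
  results <- do.call(rbind, lapply(rows, function(x) {
    as.data.frame(x, stringsAsFactors = FALSE)
  }))
  metrics <- c("sensitivity", "specificity", "accuracy", "auc",
               "precision", "recall", "f1")
  summ <- do.call(rbind, lapply(split(results, results$method), function(d) {
    out <- data.frame(method = d$method[1], n_replicates = nrow(d))
    for (mt in metrics) {
      out[[paste0(mt, "_mean")]] <- mean(d[[mt]])
      out[[paste0(mt, "_sd")]] <- stats::sd(d[[mt]])
    }
    out
  }))
  summ <- summ[match(unique(results$method), summ$method), ]
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ),
            class = "intlognet_experiment")
}

#' @export
#' @method print intlognet_experiment
print.intlognet_experiment <- function(x, ...) {
  cat("Simulation experiment:", max(x$results$replicate), "replicate(s),",
      length(unique(x$results$method)), "method(s)\n\n")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-20s AUC %.2f(%.2f)  precision %.2f(%.2f)  recall %.2f(%.2f)\n",
                s$method[i], s$auc_mean[i], s$auc_sd[i],
                s$precision_mean[i], s$precision_sd[i],
                s$recall_mean[i], s$recall_sd[i]))
  }
  invisible(x)
}

#' Write experiment tables as TSV and Markdown
#'
#' @param experiment An `intlognet_experiment`.
#' @param prefix Output path prefix; writes `<prefix>_summary.tsv`,
#'   `<prefix>_replicates.tsv` and `<prefix>_summary.md`.
#' @return Invisibly, the written paths.
#' @export
write_experiment <- function(experiment, prefix) {
  sp <- paste0(prefix, "_summary.tsv")
  rp <- paste0(prefix, "_replicates.tsv")
  mp <- paste0(prefix, "_summary.md")
  utils::write.table(experiment$summary, sp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(experiment$results, rp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  s <- experiment$summary
  fmt <- function(m, sd) sprintf("%.2f(%.2f)", m, sd)
  md <- c("| Method | Sensitivity | Specificity | Accuracy | AUC | Precision | Recall | F1 |",
          "|---|---|---|---|---|---|---|---|",
          vapply(seq_len(nrow(s)), function(i) {
            paste0("| ", s$method[i], " | ",
                   fmt(s$sensitivity_mean[i], s$sensitivity_sd[i]), " | ",
                   fmt(s$specificity_mean[i], s$specificity_sd[i]), " | ",
                   fmt(s$accuracy_mean[i], s$accuracy_sd[i]), " | ",
                   fmt(s$auc_mean[i], s$auc_sd[i]), " | ",
                   fmt(s$precision_mean[i], s$precision_sd[i]), " | ",
                   fmt(s$recall_mean[i], s$recall_sd[i]), " | ",
                   fmt(s$f1_mean[i], s$f1_sd[i]), " |")
          }, character(1)))
  writeLines(md, mp)
  invisible(c(summary = sp, replicates = rp, markdown = mp))
}

#' Connected subnetworks of the selected features
#'
#' Induces the feature network on the selected support and returns its
#' connected components (including singletons), largest first — the
#' "subnetwork biomarkers" of a network-penalized fit.
#'
#' @param fit An `intlognet_fit` (or a named coefficient vector).
#' @param network A [feature_network()] covering the fitted features.
#' @param zero_tol Support threshold on `|beta|`.
#' @return List of components, each a list with `nodes` (character vector)
#'   and `edges` (two-column data.frame, zero rows for singletons).
#' @export
selected_subnetworks <- function(fit, network, zero_tol = 1e-8) {
  beta <- if (inherits(fit, "intlognet_fit")) fit$beta else fit
  if (length(beta) != network$n_features) {
    stop("network does not cover the fitted features")
  }
  sel <- which(abs(beta) > zero_tol)
  if (!length(sel)) return(list())
  g <- igraph::graph_from_adjacency_matrix(
    network$adjacency[sel, sel, drop = FALSE],
    mode = "undirected", weighted = TRUE)
  igraph::V(g)$name <- network$feature_names[sel]
  comp <- igraph::components(g)
  ord <- order(comp$csize, decreasing = TRUE)
  lapply(ord, function(ci) {
    nodes <- names(which(comp$membership == ci))
    sub <- igraph::induced_subgraph(g, nodes)
    el <- igraph::as_edgelist(sub)
    list(nodes = nodes,
         edges = data.frame(from = el[, 1], to = el[, 2],
                            stringsAsFactors = FALSE))
  })
}

#' Write selected subnetworks to disk
#'
#' One edge-list TSV per component plus a summary TSV (component id, size,
#' members).
#'
#' @param components Result of [selected_subnetworks()].
#' @param dir Output directory.
#' @return Invisibly, the summary path.
#' @export
write_subnetworks <- function(components, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- data.frame(component = seq_along(components),
                     size = vapply(components, function(c) length(c$nodes), 1L),
                     members = vapply(components, function(c) {
                       paste(c$nodes, collapse = ",")
                     }, character(1)))
  for (i in seq_along(components)) {
    utils::write.table(components[[i]]$edges,
                       file.path(dir, sprintf("component%03d_edges.tsv", i)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sp <- file.path(dir, "subnetworks_summary.tsv")
  utils::write.table(summ, sp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sp)
}
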