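#' Configuration of the synthetic multi-cohort generator
#'
#' The generator emulates expression data driven by transcription-factor (TF)
#' regulatory modules: `n_tf` TFs each regulate `n_rg` genes, a TF and each of
#' its targets are bivariate normal with correlation `rho`, and the features
#' related to the outcome are the first four TF modules. Dataset heterogeneity
#' enters through per-sample intercepts drawn around dataset-specific means.
#'
#' @param n_tf Number of transcription factors (default 200, giving
#'   `p = n_tf * (1 + n_rg) = 2200` features).
#' @param n_rg Regulated genes per TF (default 10; the fixed-coefficient
#'   setting requires 10).
#' @param rho TF-target correlation (default 0.7; target noise variance is
#'   `1 - rho^2 = 0.51`, so targets have unit marginal variance).
#' @param setting `1` for the fixed block coefficient vector, `2` for
#'   signed-uniform coefficients (magnitudes `U[0, 3]` redrawn per replicate,
#'   signs fixed).
#' @param intercept_means Per-dataset intercept means; the default
#'   `c(-3, -1, 1, 3)` gives four heterogeneous cohorts.
#' @param intercept_spread Dispersion of per-sample intercepts around their
#'   dataset mean.
#' @param spread_is Whether `intercept_spread` is a `"variance"` (default) or
#'   an `"sd"`.
#' @param n_train,n_test Samples per dataset in the training and test splits.
#' @param seed Integer seed; the whole draw is a deterministic function of the
#'   configuration.
#' @return Object of class `simulation_config`.
#' @export
simulation_config <- function(n_tf = 200, n_rg = 10, rho = 0.7, setting = 1,
                              intercept_means = c(-3, -1, 1, 3),
                              intercept_spread = 0.5,
                              spread_is = c("variance", "sd"),
                              n_train = 100, n_test = 100, seed = 1) {
  spread_is <- match.arg(spread_is)
  setting <- as.integer(setting)
  stopifnot(n_tf >= 1, n_rg >= 1, abs(rho) < 1, setting %in% c(1L, 2L),
            length(intercept_means) >= 1, intercept_spread >= 0,
            n_train >= 1, n_test >= 0)
  structure(list(n_tf = as.integer(n_tf), n_rg = as.integer(n_rg), rho = rho,
                 setting = setting, intercept_means = intercept_means,
                 intercept_spread = intercept_spread, spread_is = spread_is,
                 n_train = as.integer(n_train), n_test = as.integer(n_test),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' TF-module regulatory network (star forest)
#'
#' Features are ordered TF1, its `n_rg` targets, TF2, its targets, and so on;
#' the only edges join each TF to its own targets, so every TF has degree
#' `n_rg` and every target degree 1.
#'
#' @param n_tf,n_rg Module counts as in [simulation_config()].
#' @return A [feature_network()] with `n_tf * (1 + n_rg)` nodes.
#' @export
build_tf_network <- function(n_tf, n_rg) {
  p <- n_tf * (1L + n_rg)
  tf_idx <- ((seq_len(n_tf) - 1L) * (1L + n_rg)) + 1L
  from <- rep(tf_idx, each = n_rg)
  to <- from + sequence(rep(n_rg, n_tf))
  names <- character(p)
  names[tf_idx] <- sprintf("TF%04d", seq_len(n_tf))
  names[-tf_idx] <- sprintf("TF%04d_g%02d", rep(seq_len(n_tf), each = n_rg),
                            rep(seq_len(n_rg), n_tf))
  A <- Matrix::sparseMatrix(i = c(from, to), j = c(to, from),
                            x = 1, dims = c(p, p))
  dimnames(A) <- list(names, names)
  feature_network(A, names)
}

#' Draw expression values from the TF-module model
#'
#' TF expression is i.i.d. standard normal; each regulated gene equals
#' `rho * TF + noise` with noise variance `1 - rho^2`, so TF-target pairs are
#' bivariate normal with correlation `rho` and unit marginal variances.
#'
#' @param n Number of samples.
#' @param n_tf,n_rg,rho As in [simulation_config()].
#' @return Numeric matrix `n x (n_tf * (1 + n_rg))` in TF-module feature
#'   order.
#' @export
draw_expression <- function(n, n_tf, n_rg, rho = 0.7) {
  p <- n_tf * (1L + n_rg)
  X <- matrix(0, n, p)
  sd_noise <- sqrt(1 - rho^2)
  col <- 1L
  for (j in seq_len(n_tf)) {
    tf <- stats::rnorm(n)
    X[, col] <- tf
    for (g in seq_len(n_rg)) {
      X[, col + g] <- rho * tf + stats::rnorm(n, sd = sd_noise)
    }
    col <- col + 1L + n_rg
  }
  X
}

#' Fixed block coefficients (setting 1)
#'
#' The first four TF modules carry the signal: module TF weights are
#' `sqrt(5), -sqrt(5), sqrt(3), -sqrt(3)`; within each module seven targets
#' share the TF's sign at magnitude `5/sqrt(10)` (or `3/sqrt(10)`) and the
#' remaining three targets take the opposite sign. All other coefficients are
#' zero, for 44 nonzero entries in total.
#'
#' @param p Total feature count (`>= 44`).
#' @return Numeric vector of length `p`.
#' @export
coefficients_setting1 <- function(p) {
  if (p < 44) stop("setting-1 coefficients need at least 44 features")
  block <- function(s) {
    tf <- sign(s) * sqrt(abs(s))
    tgt <- s / sqrt(10)
    c(tf, rep(tgt, 7), rep(-tgt, 3))
  }
  beta <- numeric(p)
  beta[1:44] <- c(block(5), block(-5), block(3), block(-3))
  beta
}

#' Signed-uniform coefficients (setting 2)
#'
#' Magnitudes of the 44 signal coefficients are drawn `U[0, 3]` from the
#' current RNG stream; their signs follow the fixed pattern
#' (11 positive, 11 negative, 7 positive, 4 negative, 7 negative, 4 positive).
#'
#' @param p Total feature count (`>= 44`).
#' @return Numeric vector of length `p`.
#' @export
coefficients_setting2 <- function(p) {
  if (p < 44) stop("setting-2 coefficients need at least 44 features")
  signs <- c(rep(1, 11), rep(-1, 11), rep(1, 7), rep(-1, 4),
             rep(-1, 7), rep(1, 4))
  beta <- numeric(p)
  beta[1:44] <- signs * stats::runif(44, 0, 3)
  beta
}

draw_dataset <- function(n, cfg, beta, intercept_mean, sd0) {
  for (attempt in 1:10) {
    X <- draw_expression(n, cfg$n_tf, cfg$n_rg, cfg$rho)
    beta0 <- stats::rnorm(n, intercept_mean, sd0)
    pr <- stats::plogis(beta0 + as.numeric(X %*% beta))
    y <- stats::rbinom(n, 1, pr)
    if (length(unique(y)) == 2L) {
      return(list(X = X, y = y, beta0 = beta0))
    }
    message("degenerate one-class dataset drawn; redrawing (attempt ",
            attempt, ")")
  }
  stop("could not draw a two-class dataset in 10 attempts; ",
       "intercept mean ", intercept_mean, " is too extreme for n = ", n)
}

#' Simulate the multi-cohort study
#'
#' Draws, for each dataset, training and test samples from the TF-module
#' expression model with per-sample intercepts `N(mean_m, spread)` and
#' outcomes `Bernoulli(plogis(beta0_i + x_i' beta))`. Everything is a
#' deterministic function of the configuration (including its seed); a
#' dataset that comes out one-class is redrawn (at most 10 times, logged).
#'
#' @param config A [simulation_config()].
#' @return List with `train` and `test` (each a list of `M` datasets with
#'   `X`, `y`, `beta0`), `beta_true`, `network` (the TF star forest) and
#'   `config`.
#' @export
simulate_datasets <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  net <- build_tf_network(config$n_tf, config$n_rg)
  p <- net$n_features
  if (config$setting == 1L) {
    if (config$n_rg != 10L) {
      stop("the fixed-coefficient setting requires n_rg = 10")
    }
    beta <- coefficients_setting1(p)
  } else {
    beta <- coefficients_setting2(p)
  }
  sd0 <- if (config$spread_is == "variance") sqrt(config$intercept_spread) else
    config$intercept_spread
  train <- list()
  test <- list()
  for (m in seq_along(config$intercept_means)) {
    mu_m <- config$intercept_means[m]
    train[[m]] <- draw_dataset(config$n_train, config, beta, mu_m, sd0)
    if (config$n_test > 0) {
      test[[m]] <- draw_dataset(config$n_test, config, beta, mu_m, sd0)
    }
  }
  add_names <- function(d) {
    colnames(d$X) <- net$feature_names
    d
  }
  list(train = lapply(train, add_names), test = lapply(test, add_names),
       beta_true = stats::setNames(beta, net$feature_names),
       network = net, config = config)
}

#' Write a simulated study to disk
#'
#' Each dataset becomes an expression TSV (samples x features) plus one
#' combined labels TSV (`sample`, `split`, `dataset_id`, `y`); the network is
#' written as an edge-list TSV and the configuration (with seed) as a JSON
#' manifest.
#'
#' @param sim Result of [simulate_datasets()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  labels <- NULL
  for (split in c("train", "test")) {
    for (m in seq_along(sim[[split]])) {
      d <- sim[[split]][[m]]
      if (is.null(d)) next
      snames <- sprintf("%s_d%d_s%03d", split, m, seq_along(d$y))
      write_expression(d$X, file.path(dir, sprintf("%s_dataset%d.tsv",
                                                   split, m)),
                       sample_names = snames)
      labels <- rbind(labels, data.frame(sample = snames, split = split,
                                         dataset_id = m, y = d$y))
    }
  }
  utils::write.table(labels, file.path(dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_edgelist(sim$network, file.path(dir, "network.tsv"))
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(unclass(sim$config), manifest, auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
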