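#' Solver options for the proximal Newton fit
#'
#' @param max_outer Maximum proximal Newton (outer) iterations.
#' @param max_inner_sweeps Maximum coordinate-descent sweeps (counting
#'   active-set sweeps) per quadratic subproblem.
#' @param tol_outer Relative change of the penalized objective below which the
#'   outer loop stops.
#' @param tol_inner Maximum absolute coefficient change below which a
#'   quadratic subproblem is declared solved.
#' @param prob_clip Fitted probabilities are clamped into
#'   `[prob_clip, 1 - prob_clip]` before forming working weights, which keeps
#'   the Newton system nonsingular on separable data.
#' @param step_halving If `TRUE` (default), a Newton candidate that increases
#'   the objective is pulled back toward the previous iterate by successive
#'   halving (at most 20 times), so the objective trace is non-increasing.
#' @return Object of class `solver_options`.
#' @export
solver_options <- function(max_outer = 50, max_inner_sweeps = 200,
                           tol_outer = 1e-6, tol_inner = 1e-5,
                           prob_clip = 1e-5, step_halving = TRUE) {
  stopifnot(tol_outer > 0, tol_inner > 0, prob_clip > 0, prob_clip <= 0.01,
            max_outer >= 1, max_inner_sweeps >= 1)
  structure(list(max_outer = as.integer(max_outer),
                 max_inner_sweeps = as.integer(max_inner_sweeps),
                 tol_outer = tol_outer, tol_inner = tol_inner,
                 prob_clip = prob_clip, step_halving = isTRUE(step_halving)),
            class = "solver_options")
}

log1pexp <- function(x) {
  # overflow-safe log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

#' Penalized integrative logistic objective
#'
#' The negative average log-likelihood plus the variable penalty and the
#' sample-relation intercept penalty:
#' `(1/N) sum_i [-y_i eta_i + log(1 + exp(eta_i))] + lambda P_alpha(beta)
#'  + mu beta0' Ltilde beta0`, with `eta_i = beta0_i + x_i' beta`.
#'
#' @param beta0 Per-sample intercept vector (length N).
#' @param beta Coefficient vector (length p).
#' @param design A [stacked_design()].
#' @param config A [penalty_config()].
#' @param network Optional [feature_network()] (required for network kinds).
#' @param sample_lap Optional [sample_laplacian()]; when `NULL` the `mu` term
#'   is omitted (scalar-intercept models).
#' @return The objective value (finite, or an error if non-finite).
#' @export
objective_value <- function(beta0, beta, design, config, network = NULL,
                            sample_lap = NULL) {
  eta <- beta0 + as.numeric(design$X %*% beta)
  nll <- mean(-design$y * eta + log1pexp(eta))
  val <- nll + config$lambda * penalty_value(beta, config, network)
  if (!is.null(sample_lap) && config$mu > 0) {
    val <- val + config$mu * sample_laplacian_quadform(sample_lap, beta0)
  }
  if (!is.finite(val)) {
    stop("non-finite objective (nll = ", nll, "); check inputs and penalties")
  }
  val
}

#' Newton working response and weights
#'
#' Linearization of the logistic log-likelihood at the current iterate:
#' `z_i = eta_i + (y_i - p_i) / w_i` with `w_i = p_i (1 - p_i)` and
#' probabilities clamped away from 0 and 1.
#'
#' @inheritParams objective_value
#' @param prob_clip Clamping width for the fitted probabilities.
#' @return List with `z` (working response), `w` (working weights) and `p`
#'   (clamped probabilities).
#' @export
working_response <- function(beta0, beta, design, prob_clip = 1e-5) {
  eta <- beta0 + as.numeric(design$X %*% beta)
  p <- stats::plogis(eta)
  p <- pmin(pmax(p, prob_clip), 1 - prob_clip)
  w <- pmax(p * (1 - p), prob_clip * (1 - prob_clip))
  z <- eta + (design$y - p) / w
  list(z = z, w = w, p = p)
}

#' Exact intercept update of the quadratic subproblem
#'
#' Solves the stationarity system of the quadratic subproblem in the
#' per-sample intercepts, `((1/N) W + 2 mu Ltilde) beta0 = (1/N) W (z - X beta)`,
#' blockwise per dataset (the sample Laplacian is block-diagonal).
#' With `mu = 0` this reduces to `beta0 = z - X beta`.
#'
#' @param w Working weights (length N).
#' @param z Working response (length N).
#' @param Xbeta The vector `X %*% beta` (length N).
#' @param sample_lap A [sample_laplacian()].
#' @param mu Nonnegative intercept-penalty weight.
#' @return The minimizing intercept vector.
#' @export
solve_beta0 <- function(w, z, Xbeta, sample_lap, mu) {
  n <- length(w)
  stopifnot(length(z) == n, length(Xbeta) == n, sample_lap$n == n, mu >= 0)
  if (mu == 0) return(z - Xbeta)
  beta0 <- numeric(n)
  rhs_full <- w * (z - Xbeta) / n
  for (idx in sample_lap$blocks) {
    B <- 2 * mu * as.matrix(sample_lap$L[idx, idx, drop = FALSE])
    diag(B) <- diag(B) + w[idx] / n
    beta0[idx] <- solve(B, rhs_full[idx])
  }
  beta0
}

empty_adjacency <- function(p) {
  Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                       dims = c(p, p))
}

kind_code <- function(kind) {
  match(kind, c("lasso", "enet", "network", "abs_network")) - 1L
}

#' Solve one proximal Newton quadratic subproblem
#'
#' Alternates the exact blockwise intercept solve with cyclic coordinate
#' descent over the coefficients (active-set refinement between full sweeps)
#' until the largest coefficient change falls below `tol_inner`.
#'
#' @param design A [stacked_design()].
#' @param w,z Working weights and response from [working_response()].
#' @param beta,beta0 Starting values.
#' @param config A [penalty_config()].
#' @param network Optional [feature_network()].
#' @param sample_lap A [sample_laplacian()] (ignored for scalar intercepts).
#' @param scalar_intercept If `TRUE` a single common intercept is fit in
#'   closed form instead of per-sample intercepts.
#' @param options A [solver_options()].
#' @return List with `beta`, `beta0`, `sweeps`, `converged`.
#' @export
inner_quadratic_solve <- function(design, w, z, beta, beta0, config,
                                  network = NULL, sample_lap = NULL,
                                  scalar_intercept = FALSE,
                                  options = solver_options()) {
  p <- ncol(design$X)
  if (needs_network(config)) {
    if (is.null(network)) stop(config$kind, " penalty requires a feature_network")
    A <- network$adjacency
    deg <- network$degree
  } else {
    A <- empty_adjacency(p)
    deg <- numeric(p)
  }
  if (scalar_intercept || config$mu == 0) {
    blocks <- list()
    Lblocks <- list()
  } else {
    if (is.null(sample_lap)) stop("per-sample intercepts need a sample_laplacian")
    blocks <- sample_lap$blocks
    Lblocks <- lapply(blocks, function(idx) {
      as.matrix(sample_lap$L[idx, idx, drop = FALSE])
    })
  }
  inner_quadratic_cpp(design$X, w, z, beta, beta0, blocks, Lblocks,
                      config$mu, config$lambda, config$alpha,
                      kind_code(config$kind), A, deg,
                      scalar_intercept, options$max_inner_sweeps,
                      options$tol_inner)
}

init_intercepts <- function(design, scalar_intercept) {
  if (scalar_intercept) {
    pr <- min(max(mean(design$y), 0.01), 0.99)
    rep(stats::qlogis(pr), length(design$y))
  } else {
    pr <- tapply(design$y, design$dataset_ids, mean)
    pr <- pmin(pmax(pr, 0.01), 0.99)
    as.numeric(stats::qlogis(pr))[design$dataset_ids]
  }
}

#' Fit the penalized (integrative) logistic regression
#'
#' Proximal Newton iteration: at the current iterate the logistic
#' log-likelihood is replaced by its weighted least-squares approximation
#' (working response and weights), the resulting penalized quadratic
#' subproblem is solved by [inner_quadratic_solve()], and the candidate is
#' step-halved toward the previous iterate whenever it would increase the
#' penalized objective. Iterates until the relative objective change drops
#' below `tol_outer`.
#'
#' @param design A [stacked_design()].
#' @param config A [penalty_config()].
#' @param network A [feature_network()], required for the network penalties.
#' @param options A [solver_options()].
#' @param intercept `"per_sample"` (dataset-heterogeneous intercepts shrunk by
#'   the sample-relation Laplacian penalty) or `"scalar"` (one common
#'   unpenalized intercept, as in merged or single-dataset fits).
#' @param sample_lap Optional precomputed [sample_laplacian()]; built from the
#'   design's dataset ids when absent.
#' @param init Optional list with starting `beta` and/or `beta0` (warm start).
#' @return An object of class `intlognet_fit` with elements `beta` (named),
#'   `beta0` (per-sample), `dataset_intercepts` (per-dataset means of `beta0`),
#'   `objective_trace`, `converged`, `n_outer_iter`, plus the configuration
#'   and bookkeeping fields.
#' @export
fit_penalized_logistic <- function(design, config, network = NULL,
                                   options = solver_options(),
                                   intercept = c("per_sample", "scalar"),
                                   sample_lap = NULL, init = NULL) {
  stopifnot(inherits(design, "stacked_design"),
            inherits(config, "penalty_config"))
  intercept <- match.arg(intercept)
  scalar <- intercept == "scalar"
  if (needs_network(config)) {
    if (is.null(network)) stop(config$kind, " penalty requires a feature_network")
    if (network$n_features != ncol(design$X)) {
      stop("feature network size does not match the design")
    }
  }
  col_var <- matrixStats_colVars(design$X)
  if (any(col_var == 0)) {
    warning(sum(col_var == 0), " zero-variance feature column(s); ",
            "their coefficients stay at zero under any positive lambda")
  }
  if (!scalar && is.null(sample_lap)) {
    sample_lap <- sample_laplacian(design$dataset_ids)
  }
  p <- ncol(design$X)
  beta <- if (!is.null(init$beta)) as.numeric(init$beta) else numeric(p)
  beta0 <- if (!is.null(init$beta0)) as.numeric(init$beta0) else {
    init_intercepts(design, scalar)
  }
  sl_obj <- if (scalar) NULL else sample_lap
  f_old <- objective_value(beta0, beta, design, config, network, sl_obj)
  trace <- f_old
  converged <- FALSE
  iter <- 0L
  for (it in seq_len(options$max_outer)) {
    iter <- it
    wr <- working_response(beta0, beta, design, options$prob_clip)
    sol <- inner_quadratic_solve(design, wr$w, wr$z, beta, beta0, config,
                                 network, sample_lap, scalar, options)
    beta_new <- as.numeric(sol$beta)
    beta0_new <- as.numeric(sol$beta0)
    f_new <- objective_value(beta0_new, beta_new, design, config, network,
                             sl_obj)
    # accept up to round-off so the iteration can polish to the fixed point
    # instead of stalling one Newton step short of it
    slack <- 1e-14 * (abs(f_old) + 1)
    if (options$step_halving && f_new > f_old + slack) {
      ok <- FALSE
      for (h in seq_len(20)) {
        beta_new <- (beta_new + beta) / 2
        beta0_new <- (beta0_new + beta0) / 2
        f_new <- objective_value(beta0_new, beta_new, design, config, network,
                                 sl_obj)
        if (f_new <= f_old + slack) { ok <- TRUE; break }
      }
      if (!ok) {  # no descent direction left: keep previous iterate and stop
        trace <- c(trace, f_old)
        converged <- TRUE
        break
      }
    }
    beta <- beta_new
    beta0 <- beta0_new
    trace <- c(trace, f_new)
    if (abs(f_old - f_new) <= options$tol_outer * (abs(f_old) + 1e-12)) {
      converged <- TRUE
      break
    }
    f_old <- f_new
  }
  names(beta) <- design$feature_names
  d_int <- as.numeric(tapply(beta0, design$dataset_ids, mean))
  structure(
    list(beta = beta, beta0 = beta0,
         dataset_intercepts = d_int,
         objective_trace = trace, converged = converged,
         n_outer_iter = iter,
         config = config, intercept = intercept,
         feature_names = design$feature_names,
         n_per_dataset = design$n_per_dataset,
         dataset_ids_seen = sort(unique(design$dataset_ids))),
    class = "intlognet_fit"
  )
}

# column variances without extra dependencies
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  if (n < 2) return(rep(0, ncol(X)))
  mu <- colMeans(X)
  (colSums(X^2) - n * mu^2) / (n - 1)
}

#' @export
#' @method print intlognet_fit
print.intlognet_fit <- function(x, ...) {
  cat(sprintf(
    "Penalized logistic fit (%s, lambda = %g, alpha = %g, mu = %g)\n",
    x$config$kind, x$config$lambda, x$config$alpha, x$config$mu))
  cat(sprintf("  %d / %d nonzero coefficients; %d outer iteration(s); %s\n",
              sum(abs(x$beta) > 1e-8), length(x$beta), x$n_outer_iter,
              if (x$converged) "converged" else "not converged"))
  cat("  dataset intercepts:",
      paste(sprintf("%.3f", x$dataset_intercepts), collapse = ", "), "\n")
  invisible(x)
}

#' Selected features of a fit
#'
#' @param fit An `intlognet_fit`.
#' @param zero_tol Coefficients with `|beta| > zero_tol` count as selected.
#' @return Character vector of selected feature names.
#' @export
selected_features <- function(fit, zero_tol = 1e-8) {
  names(fit$beta)[abs(fit$beta) > zero_tol]
}

#' Write a convergence trace as TSV
#'
#' @param fit An `intlognet_fit`.
#' @param path Output file.
#' @export
write_convergence_trace <- function(fit, path) {
  utils::write.table(
    data.frame(iteration = seq_along(fit$objective_trace) - 1L,
               objective = fit$objective_trace),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
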