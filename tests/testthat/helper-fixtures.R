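# Small in-code fixtures shared across test files.

# a two-dataset toy design with weak signal on the first three features
make_toy_design <- function(n = 24, p = 5, seed = 42, m = 2) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p)
  beta <- c(1.2, -0.8, 0.5, rep(0, p - 3))
  ids <- rep(seq_len(m), length.out = n)
  b0 <- c(-0.5, 0.5)[ids %% 2 + 1]
  y <- rbinom(n, 1, plogis(b0 + X %*% beta))
  # guard against one-class draws at tiny n
  if (length(unique(y)) == 1L) y[1:2] <- c(0L, 1L)
  stacked_design(X, y, ids, paste0("g", seq_len(p)))
}

# path graph over p nodes as a feature network
make_path_network <- function(p, names = paste0("g", seq_len(p))) {
  A <- Matrix::sparseMatrix(i = c(seq_len(p - 1), 2:p),
                            j = c(2:p, seq_len(p - 1)),
                            x = 1, dims = c(p, p))
  dimnames(A) <- list(names, names)
  feature_network(A, names)
}

# literal term-by-term evaluation of the proximal quadratic objective
# (independent of the solver path)
quad_objective_literal <- function(beta0, beta, X, w, z, config, network,
                                   sample_lap) {
  n <- length(z)
  res <- z - beta0 - as.numeric(X %*% beta)
  val <- sum(w * res^2) / (2 * n) +
    config$lambda * penalty_value(beta, config, network)
  if (!is.null(sample_lap) && config$mu > 0) {
    val <- val + config$mu * sample_laplacian_quadform(sample_lap, beta0)
  }
  val
}

# independent 1-D minimizer over coordinate k of the quadratic subproblem:
# on each sign branch the objective is exactly quadratic, so three function
# evaluations recover it; candidates are the two clamped branch vertices and 0
coordinate_oracle <- function(k, X, w, z, beta, beta0, config, network,
                              sample_lap = NULL) {
  q <- function(bk) {
    b <- beta
    b[k] <- bk
    quad_objective_literal(beta0, b, X, w, z, config, network, sample_lap)
  }
  branch_vertex <- function(sgn) {
    xs <- sgn * c(1, 2, 3)
    ys <- vapply(xs, q, 0)
    # exact quadratic through three equally spaced points (|h| = 1):
    # second difference = 2 a2 h^2
    a2 <- (ys[3] - 2 * ys[2] + ys[1]) / 2
    a1 <- (ys[2] - ys[1]) / (xs[2] - xs[1]) - a2 * (xs[1] + xs[2])
    if (a2 <= 0) return(sgn * 1e6)  # degenerate; huge candidate gets clamped
    v <- -a1 / (2 * a2)
    if (sgn > 0) max(v, 0) else min(v, 0)
  }
  cand <- c(0, branch_vertex(1), branch_vertex(-1))
  cand[which.min(vapply(cand, q, 0))]
}

pooled_test <- function(sim) {
  list(X = do.call(rbind, lapply(sim$test, function(d) d$X)),
       y = unlist(lapply(sim$test, function(d) d$y), use.names = FALSE),
       dataset = rep(seq_along(sim$test),
                     vapply(sim$test, function(d) nrow(d$X), 1L)))
}
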