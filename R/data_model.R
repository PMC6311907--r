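#' Assemble a stacked multi-dataset design
#'
#' Concatenates samples from one or more case/control datasets into a single
#' design used by the integrative solver: a numeric feature matrix, a binary
#' outcome vector and the dataset membership of every sample.
#'
#' @param X Numeric matrix, samples in rows and features in columns.
#' @param y Binary outcome vector (0/1), one entry per row of `X`.
#' @param dataset_ids Integer vector giving, for every sample, the index of the
#'   dataset (cohort) it came from. Ids must cover `1..M` with every id
#'   occurring at least once.
#' @param feature_names Character vector of unique feature (gene) names;
#'   defaults to `colnames(X)`.
#'
#' @return An object of class `stacked_design`: a list with elements `X`, `y`,
#'   `dataset_ids`, `feature_names`, `n_per_dataset` (named integer vector of
#'   per-dataset sample counts) and `n_datasets`.
#' @export
stacked_design <- function(X, y, dataset_ids, feature_names = colnames(X)) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(feature_names)) {
    feature_names <- paste0("V", seq_len(ncol(X)))
  }
  feature_names <- as.character(feature_names)
  if (length(feature_names) != ncol(X)) {
    stop("feature_names must have one entry per column of X")
  }
  if (anyDuplicated(feature_names)) {
    stop("feature names must be unique")
  }
  y <- as.integer(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (!all(y %in% c(0L, 1L))) stop("y must contain only 0/1 values")
  dataset_ids <- as.integer(dataset_ids)
  if (length(dataset_ids) != nrow(X)) {
    stop("dataset_ids must have one entry per row of X")
  }
  if (length(dataset_ids) == 0L) stop("empty design")
  if (any(dataset_ids < 1L)) stop("dataset ids must be positive integers")
  m <- max(dataset_ids)
  if (!all(seq_len(m) %in% dataset_ids)) {
    stop("every dataset id in 1..M must occur at least once")
  }
  if (any(!is.finite(X))) {
    stop("X contains non-finite values; impute before building the design")
  }
  counts <- tabulate(dataset_ids, nbins = m)
  names(counts) <- as.character(seq_len(m))
  colnames(X) <- feature_names
  structure(
    list(
      X = X, y = y, dataset_ids = dataset_ids,
      feature_names = feature_names,
      n_per_dataset = counts, n_datasets = m
    ),
    class = "stacked_design"
  )
}

#' @export
#' @method print stacked_design
print.stacked_design <- function(x, ...) {
  cat(
    "Stacked design:", nrow(x$X), "samples,", ncol(x$X), "features,",
    x$n_datasets, "dataset(s)\n"
  )
  cat("  samples per dataset:", paste(x$n_per_dataset, collapse = ", "), "\n")
  cat("  outcome prevalence:", round(mean(x$y), 3), "\n")
  invisible(x)
}

#' Laplacian of the within-dataset sample-relation graph
#'
#' Builds the Laplacian of the graph that connects every pair of samples that
#' belong to the same dataset (a disjoint union of complete graphs, one per
#' dataset). Penalizing the quadratic form `beta0' L beta0` shrinks per-sample
#' intercepts toward a common value inside each dataset while leaving
#' between-dataset differences free.
#'
#' The default is the combinatorial (unnormalized) Laplacian, whose quadratic
#' form equals the sum of squared within-dataset intercept differences and
#' vanishes exactly when intercepts are constant within every dataset. A
#' degree-normalized variant is also available.
#'
#' @param dataset_ids Positive integer vector of dataset memberships.
#' @param normalized Logical; if `TRUE` return the symmetric degree-normalized
#'   Laplacian of the same graph instead of the combinatorial one.
#'
#' @return An object of class `sample_laplacian`: list with `L` (sparse
#'   symmetric `N x N` matrix), `blocks` (list of sample index vectors, one per
#'   dataset), `normalized`, and `n` (number of samples).
#' @export
#' @examples
#' sl <- sample_laplacian(c(1, 1, 2))
#' as.matrix(sl$L)
sample_laplacian <- function(dataset_ids, normalized = FALSE) {
  dataset_ids <- as.integer(dataset_ids)
  if (length(dataset_ids) == 0L) stop("dataset_ids must be non-empty")
  if (any(is.na(dataset_ids)) || any(dataset_ids < 1L)) {
    stop("dataset ids must be positive integers")
  }
  n <- length(dataset_ids)
  blocks <- split(seq_len(n), dataset_ids)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (idx in blocks) {
    nm <- length(idx)
    if (nm == 1L) next  # singleton: degree 0, Laplacian block is 0
    if (normalized) {
      # complete-graph normalized Laplacian: I - J/(nm-1) off the diagonal
      diag_val <- 1
      off_val <- -1 / (nm - 1)
    } else {
      diag_val <- nm - 1
      off_val <- -1
    }
    grid <- expand.grid(a = idx, b = idx)
    keep <- grid$a != grid$b
    ii <- c(ii, idx, grid$a[keep])
    jj <- c(jj, idx, grid$b[keep])
    xx <- c(xx, rep(diag_val, nm), rep(off_val, sum(keep)))
  }
  L <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
  structure(
    list(L = L, blocks = blocks, normalized = normalized, n = n),
    class = "sample_laplacian"
  )
}

#' Quadratic form of a sample-relation Laplacian
#'
#' Computes `b' L b` for the within-dataset sample graph. For the
#' combinatorial Laplacian this equals the sum over datasets of all pairwise
#' squared differences of `b` within the dataset.
#'
#' @param sl A `sample_laplacian`.
#' @param b Numeric vector of length `sl$n`.
#' @return A single number, always `>= 0` up to round-off.
#' @export
sample_laplacian_quadform <- function(sl, b) {
  stopifnot(inherits(sl, "sample_laplacian"), length(b) == sl$n)
  if (!sl$normalized) {
    # sum_{i<j in block} (b_i - b_j)^2 = nm * sum(b^2) - (sum b)^2 per block
    tot <- 0
    for (idx in sl$blocks) {
      bb <- b[idx]
      tot <- tot + length(bb) * sum(bb^2) - sum(bb)^2
    }
    return(tot)
  }
  as.numeric(b %*% (sl$L %*% b))
}

#' Build a feature network with its normalized Laplacian
#'
#' Wraps an undirected (optionally weighted) feature adjacency matrix together
#' with node degrees and the symmetric normalized Laplacian
#' `L = I - D^{-1/2} A D^{-1/2}` used by the network and absolute-value
#' network penalties. Rows/columns of isolated nodes (degree 0) are zero in
#' `L`, so such features carry only the L1 part of the penalty.
#'
#' @param adjacency Symmetric nonnegative matrix (dense or sparse) with zero
#'   diagonal; binary or weighted edges.
#' @param feature_names Optional character vector of node names; defaults to
#'   the adjacency dimnames.
#'
#' @return Object of class `feature_network`: list with sparse `adjacency`,
#'   `degree`, sparse normalized Laplacian `laplacian`, `feature_names` and
#'   `n_features`.
#' @export
feature_network <- function(adjacency, feature_names = NULL) {
  A <- methods::as(methods::as(Matrix::Matrix(adjacency, sparse = TRUE), "generalMatrix"), "CsparseMatrix")
  p <- nrow(A)
  if (ncol(A) != p) stop("adjacency must be square")
  if (any(A@x < 0)) stop("adjacency weights must be nonnegative")
  if (!Matrix::isSymmetric(A, tol = 1e-12)) stop("adjacency must be symmetric")
  if (any(Matrix::diag(A) != 0)) stop("adjacency diagonal must be zero")
  if (is.null(feature_names)) feature_names <- rownames(A)
  if (is.null(feature_names)) feature_names <- paste0("V", seq_len(p))
  d <- Matrix::rowSums(A)
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dhalf <- Matrix::Diagonal(p, inv_sqrt)
  L <- -(Dhalf %*% A %*% Dhalf)
  Matrix::diag(L) <- as.numeric(d > 0)
  L <- methods::as(methods::as(L, "generalMatrix"), "CsparseMatrix")
  dimnames(A) <- list(feature_names, feature_names)
  structure(
    list(
      adjacency = A, degree = as.numeric(d), laplacian = L,
      feature_names = as.character(feature_names), n_features = p
    ),
    class = "feature_network"
  )
}

#' @export
#' @method print feature_network
print.feature_network <- function(x, ...) {
  n_edges <- length(x$adjacency@x) / 2
  cat(
    "Feature network:", x$n_features, "nodes,", n_edges, "edges,",
    sum(x$degree == 0), "isolated\n"
  )
  invisible(x)
}

#' Read a feature network from an edge-list or SIF file
#'
#' Accepts a two-column edge list (`nodeA<TAB>nodeB`), a three-column weighted
#' edge list (`nodeA<TAB>nodeB<TAB>weight`), or the SIF dialect
#' (`nodeA<TAB>relation<TAB>nodeB`). The format is chosen by `format`, or
#' guessed from whether the third column is numeric. Edge endpoints are matched
#' against `feature_names`; edges touching unknown nodes are dropped with a
#' warning. Self-loops are ignored and duplicate edges collapsed (weights
#' take the maximum).
#'
#' @param path Path to a tab-separated file without header.
#' @param feature_names Character vector of features defining node order.
#' @param format One of `"auto"`, `"edgelist"`, `"sif"`.
#' @return A [feature_network()] over `feature_names`.
#' @export
read_feature_network <- function(path, feature_names,
                                 format = c("auto", "edgelist", "sif")) {
  format <- match.arg(format)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  if (ncol(tab) < 2) stop("network file must have at least two columns")
  if (format == "auto") {
    format <- if (ncol(tab) >= 3 &&
                  !all(!is.na(suppressWarnings(as.numeric(tab[[3]]))))) {
      "sif"
    } else {
      "edgelist"
    }
  }
  if (format == "sif") {
    if (ncol(tab) < 3) stop("SIF input needs three columns")
    from <- as.character(tab[[1]]); to <- as.character(tab[[3]])
    w <- rep(1, nrow(tab))
  } else {
    from <- as.character(tab[[1]]); to <- as.character(tab[[2]])
    w <- if (ncol(tab) >= 3) as.numeric(tab[[3]]) else rep(1, nrow(tab))
  }
  feature_names <- as.character(feature_names)
  i <- match(from, feature_names)
  j <- match(to, feature_names)
  known <- !is.na(i) & !is.na(j)
  if (any(!known)) {
    warning(sum(!known), " edge(s) with nodes absent from feature_names dropped")
  }
  keep <- known & (i != j)
  p <- length(feature_names)
  if (!any(keep)) {
    A <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(p, p))
  } else {
    ii <- pmin(i[keep], j[keep]); jj <- pmax(i[keep], j[keep])
    key <- paste(ii, jj)
    first <- !duplicated(key)
    wmax <- tapply(w[keep], key, max)[key[first]]
    A <- Matrix::sparseMatrix(i = c(ii[first], jj[first]),
                              j = c(jj[first], ii[first]),
                              x = rep(as.numeric(wmax), 2), dims = c(p, p))
  }
  dimnames(A) <- list(feature_names, feature_names)
  feature_network(A, feature_names)
}
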