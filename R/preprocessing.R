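#' Collapse probe columns to gene level by averaging
#'
#' Replaces the probe columns of an expression matrix by one column per gene,
#' equal to the mean of the probes mapping to that gene. Probes without a
#' mapping are dropped with a warning. Gene columns appear in order of first
#' probe occurrence.
#'
#' @param X Numeric matrix, samples x probes (column names = probe ids).
#' @param probe_gene_map Data frame or named vector mapping probe ids to gene
#'   symbols; as a data frame, the first column is the probe and the second
#'   the gene.
#' @return Numeric matrix, samples x genes.
#' @export
collapse_probes_mean <- function(X, probe_gene_map) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) stop("X needs probe ids as column names")
  if (is.data.frame(probe_gene_map)) {
    map <- stats::setNames(as.character(probe_gene_map[[2]]),
                           as.character(probe_gene_map[[1]]))
  } else {
    map <- probe_gene_map
  }
  genes <- unname(map[colnames(X)])
  unmapped <- is.na(genes) | genes == ""
  if (all(unmapped)) stop("no probe of X appears in the probe-gene map")
  if (any(unmapped)) {
    warning(sum(unmapped), " unmapped probe(s) dropped")
  }
  X <- X[, !unmapped, drop = FALSE]
  genes <- genes[!unmapped]
  ug <- unique(genes)
  out <- matrix(0, nrow(X), length(ug), dimnames = list(rownames(X), ug))
  for (g in ug) {
    out[, g] <- rowMeans(X[, genes == g, drop = FALSE])
  }
  out
}

#' Keep only features present in a network
#'
#' @param X Numeric matrix, samples x genes.
#' @param network A [feature_network()] (or character vector of node names).
#' @return `X` restricted to columns whose names are network nodes, original
#'   order preserved.
#' @export
filter_to_network_genes <- function(X, network) {
  nodes <- if (inherits(network, "feature_network")) {
    network$feature_names
  } else {
    as.character(network)
  }
  keep <- colnames(X) %in% nodes
  if (!any(keep)) stop("no gene of X appears in the network")
  X[, keep, drop = FALSE]
}

#' Top-variance genes per dataset, then intersection
#'
#' From each expression matrix takes the `k` columns with the largest sample
#' variance (unbiased, denominator n-1; ties broken by gene name) and returns
#' the intersection across datasets, sorted by name.
#'
#' @param tables List of at least two numeric matrices with column names.
#' @param k Number of genes to keep per dataset (default 2000).
#' @return Character vector of genes (possibly empty, with a warning).
#' @export
top_variance_then_intersect <- function(tables, k = 2000) {
  if (length(tables) < 2) stop("need at least two datasets to intersect")
  top_k <- lapply(tables, function(X) {
    X <- as.matrix(X)
    if (is.null(colnames(X))) stop("expression matrices need column names")
    kk <- k
    if (kk > ncol(X)) {
      warning("k exceeds the number of genes; using all ", ncol(X))
      kk <- ncol(X)
    }
    v <- apply(X, 2, stats::var)
    ord <- order(-v, colnames(X))
    colnames(X)[ord[seq_len(kk)]]
  })
  out <- Reduce(intersect, top_k)
  if (!length(out)) warning("top-variance gene sets have empty intersection")
  sort(out)
}

#' Mean-impute and standardize an expression matrix
#'
#' Missing values of each gene are replaced by the gene's observed mean, then
#' every gene is centered and scaled to unit standard deviation (denominator
#' n-1) within the dataset. Constant genes become all-zero columns with a
#' warning; an all-missing gene is an error.
#'
#' @param X Numeric matrix, samples x genes; `NA`s allowed.
#' @return Matrix of the same shape, no missing values, genes standardized.
#' @export
impute_and_normalize <- function(X) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    stop("gene(s) with all values missing: ",
         paste(utils::head(colnames(X)[all_na], 5), collapse = ", "))
  }
  mu <- colMeans(X, na.rm = TRUE)
  for (j in seq_len(ncol(X))) {
    miss <- is.na(X[, j])
    if (any(miss)) X[miss, j] <- mu[j]
  }
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  if (any(const)) {
    warning(sum(const), " constant gene(s) mapped to all-zero columns")
  }
  Xc <- sweep(X, 2, colMeans(X))
  Xc[, !const] <- sweep(Xc[, !const, drop = FALSE], 2, sds[!const], "/")
  Xc[, const] <- 0
  Xc
}
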