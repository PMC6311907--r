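#' Read an expression TSV
#'
#' Default dialect: samples as rows, first column the sample name, header row
#' the feature names. `transpose = TRUE` accepts the genes-as-rows dialect
#' common to expression matrices (first column = gene name, columns =
#' samples).
#'
#' @param path Tab-separated file.
#' @param transpose Set `TRUE` for genes-as-rows input.
#' @return Numeric matrix, samples x features, with dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, quote = "",
                           comment.char = "")
  X <- as.matrix(tab)
  storage.mode(X) <- "double"
  if (transpose) X <- t(X)
  X
}

#' Write an expression TSV (samples as rows)
#'
#' @param X Numeric matrix, samples x features.
#' @param path Output file.
#' @param sample_names Row names to use (defaults to existing or `s1, s2, ...`).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(X, path, sample_names = rownames(X)) {
  if (is.null(sample_names)) sample_names <- paste0("s", seq_len(nrow(X)))
  df <- data.frame(sample = sample_names, X, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a labels TSV
#'
#' Expected columns: `sample`, `dataset_id`, `y` (an optional `split` column
#' is preserved).
#'
#' @param path Tab-separated file with header.
#' @return A data.frame.
#' @export
read_labels <- function(path) {
  lab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("sample", "dataset_id", "y")
  if (!all(need %in% names(lab))) {
    stop("labels file must have columns: ", paste(need, collapse = ", "))
  }
  lab
}

#' Write a feature network as an edge-list TSV
#'
#' @param network A [feature_network()].
#' @param path Output file (two columns `from`, `to`, plus `weight` when the
#'   network is weighted).
#' @return Invisibly, `path`.
#' @export
write_edgelist <- function(network, path) {
  A <- network$adjacency
  tri <- Matrix::which(Matrix::triu(A, 1) != 0, arr.ind = TRUE)
  w <- A[tri]
  df <- data.frame(from = network$feature_names[tri[, 1]],
                   to = network$feature_names[tri[, 2]])
  if (any(w != 1)) df$weight <- w
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

# Assemble per-dataset (X, y) lists from an expression directory + labels,
# used by the command-line interface.
load_tsv_datasets <- function(expr_paths, labels_path, transpose = FALSE) {
  lab <- read_labels(labels_path)
  Xs <- lapply(expr_paths, read_expression, transpose = transpose)
  X <- do.call(rbind, Xs)
  idx <- match(rownames(X), lab$sample)
  if (any(is.na(idx))) {
    stop("samples missing from labels file: ",
         paste(utils::head(rownames(X)[is.na(idx)], 5), collapse = ", "))
  }
  lab <- lab[idx, ]
  ids <- sort(unique(lab$dataset_id))
  lapply(ids, function(m) {
    take <- lab$dataset_id == m
    list(X = X[take, , drop = FALSE], y = lab$y[take])
  })
}
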