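#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of
#' feature identifiers (features-in-rows, the genomics convention; set
#' `featuresInRows = FALSE` for the transpose).  Returns a samples x
#' features numeric matrix, ready for [gelnetFit()].  When a network is
#' supplied, features absent from it are dropped (with a message giving
#' the count) and the feature order follows the matrix.
#'
#' @param path file path.
#' @param featuresInRows orientation of the stored table.
#' @param net optional [FeatureNetwork-class] to align features against.
#' @param sep field separator (`"\t"` default; use `","` for CSV).
#' @return numeric matrix, samples in rows, features in columns.
#' @export
readExpressionMatrix <- function(path, featuresInRows = TRUE, net = NULL,
                                 sep = "\t") {
  df <- read.delim(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("non-numeric cells in ", path)
  rownames(M) <- ids
  X <- if (featuresInRows) t(M) else M
  if (!is.null(net)) {
    keep <- colnames(X) %in% nodeIds(net)
    if (any(!keep))
      message(sprintf("dropping %d feature(s) absent from the network",
                      sum(!keep)))
    X <- X[, keep, drop = FALSE]
  }
  X
}

#' Write an expression matrix as TSV (features in rows)
#'
#' @param X samples x features numeric matrix.
#' @param path output path.
#' @export
writeExpressionMatrix <- function(X, path) {
  M <- t(as.matrix(X))
  if (is.null(rownames(M))) rownames(M) <- paste0("g", seq_len(nrow(M)))
  if (is.null(colnames(M))) colnames(M) <- paste0("s", seq_len(ncol(M)))
  df <- data.frame(feature_id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
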