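#' Expression matrix with optional detection p-values
#'
#' Light container for a genes x samples matrix of log2 intensities, with an
#' optional same-shaped matrix of per-probe detection p-values as produced by
#' bead-array scanners. Gene and sample identifiers live in the dimnames and
#' must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns; rownames
#'   are gene ids, colnames sample ids.
#' @param detection_p optional numeric matrix in \[0, 1\] with the same
#'   dimensions and dimnames as `values`.
#' @return An object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, detection_p = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must carry gene ids (rownames) and sample ids (colnames)")
  if (anyDuplicated(rownames(values)))
    stop("gene ids must be unique")
  if (anyDuplicated(colnames(values)))
    stop("sample ids must be unique")
  if (!is.null(detection_p)) {
    detection_p <- as.matrix(detection_p)
    if (!identical(dim(detection_p), dim(values)))
      stop("detection_p must have the same shape as values")
    if (any(detection_p < 0 | detection_p > 1))
      stop("detection_p values must lie in [0, 1]")
    dimnames(detection_p) <- dimnames(values)
  }
  structure(list(values = values, detection_p = detection_p),
            class = "expression_matrix")
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$detection_p)) "" else " (with detection p-values)"))
  invisible(x)
}

#' Gene and sample identifiers
#' @param x an `expression_matrix`.
#' @return Character vector of ids.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' Read and write expression matrices as tab-separated text
#'
#' The on-disk layout is a header row of sample ids, a first column of gene
#' ids, and tab-separated values; detection p-values, when present, are a
#' sibling file with the identical layout and a `.detp.tsv` suffix.
#'
#' @param x an `expression_matrix`.
#' @param path file path for the value matrix.
#' @return `read_expression_matrix` returns an `expression_matrix`;
#'   `write_expression_matrix` returns `path` invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  df <- data.frame(gene_id = gene_ids(x), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$detection_p)) {
    dp <- data.frame(gene_id = gene_ids(x), x$detection_p,
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(dp, detp_path(path), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_expression_matrix
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  dp <- NULL
  if (file.exists(detp_path(path))) {
    dpf <- utils::read.delim(detp_path(path), check.names = FALSE,
                             stringsAsFactors = FALSE)
    dp <- as.matrix(dpf[, -1, drop = FALSE])
    rownames(dp) <- dpf[[1]]
  }
  expression_matrix(vals, dp)
}

detp_path <- function(path) sub("(\\.tsv)?$", ".detp.tsv", path, perl = TRUE)
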