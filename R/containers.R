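#' @importFrom stats quantile rbinom rpois dpois qpois runif rnorm sd
#'   setNames p.adjust rbeta
#' @importFrom utils combn
NULL

# Internal: unknown entries are NA throughout. Matrices are cells x features
# with unique dimnames; the classes below are thin validated wrappers.

new_scp_matrix <- function(values, class, extra = list()) {
  stopifnot(is.matrix(values))
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("matrix must have cell (row) and feature (column) names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate cell ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature ids")
  structure(c(list(values = values), extra), class = c(class, "scp_matrix"))
}

#' Cell-by-gene expression matrix with explicit unknowns
#'
#' Wraps a numeric cells x genes matrix in which `NA` marks an unknown
#' (unobserved) value, distinct from a numeric zero, together with a map
#' from cell id to the regional sample it was isolated from.
#'
#' @param values numeric matrix, cells in rows, genes in columns; dimnames
#'   required and unique. `NA` = unknown.
#' @param sample_of named character vector mapping every cell id to a
#'   sample label.
#' @return an `ExpressionMatrix` object.
#' @export
expression_matrix <- function(values, sample_of) {
  storage.mode(values) <- "double"
  if (!all(rownames(values) %in% names(sample_of)))
    stop("every cell needs a sample label")
  sample_of <- sample_of[rownames(values)]
  new_scp_matrix(values, "ExpressionMatrix", list(sample_of = sample_of))
}

#' Ordinal character matrix
#'
#' Cells x genes matrix of ordinal expression categories. In
#' `zero_mode = "unknown"` the category set is \{1..5\}; in
#' `zero_mode = "biological"` raw zeros form their own category 0 and the
#' set is \{0..5\}. `NA` marks unknown.
#'
#' @param values integer matrix with dimnames; `NA` = unknown.
#' @param zero_mode `"unknown"` or `"biological"`.
#' @return an `OrdinalMatrix` object.
#' @export
ordinal_matrix <- function(values, zero_mode = c("unknown", "biological")) {
  zero_mode <- match.arg(zero_mode)
  storage.mode(values) <- "integer"
  lo <- if (zero_mode == "biological") 0L else 1L
  known <- values[!is.na(values)]
  if (length(known) && (min(known) < lo || max(known) > 5L))
    stop("ordinal categories must lie in {", lo, "..5}")
  new_scp_matrix(values, "OrdinalMatrix", list(zero_mode = zero_mode))
}

#' SNV character matrix
#'
#' Cells x sites matrix of consensus bases in \{A,C,G,T\}; `NA` = unknown.
#'
#' @param values character matrix with dimnames.
#' @return an `SNVCharacterMatrix` object.
#' @export
snv_matrix <- function(values) {
  known <- values[!is.na(values)]
  if (length(known) && !all(known %in% c("A", "C", "G", "T")))
    stop("SNV characters must be A, C, G or T")
  new_scp_matrix(values, "SNVCharacterMatrix")
}

#' @export
print.scp_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("<%s> %d cells x %d features, data density %.3f\n",
              class(x)[1], nrow(v), ncol(v), mean(!is.na(v))))
  invisible(x)
}

#' @export
dim.scp_matrix <- function(x) dim(x$values)

# Accept either a bare matrix or one of the wrappers.
as_values <- function(x) {
  if (inherits(x, "scp_matrix")) x$values else as.matrix(x)
}

# Rebuild the same wrapper around a subsetted value matrix.
rewrap <- function(x, values) {
  if (!inherits(x, "scp_matrix")) return(values)
  out <- x
  out$values <- values
  if (!is.null(out$sample_of)) out$sample_of <- out$sample_of[rownames(values)]
  out
}

#' Read a cell-by-gene matrix from 10x-style MTX triplet files
#'
#' Reads `matrix.mtx` (genes x cells sparse triplet, as written by
#' Cellranger), a barcodes file (one cell id per line) and a features file
#' (one gene id per line, first column used), and returns the dense
#' cells x genes matrix.
#'
#' @param mtx,barcodes,features file paths.
#' @param sample_of optional named character vector of sample labels; if
#'   supplied an [expression_matrix()] is returned, otherwise a matrix.
#' @return numeric matrix or `ExpressionMatrix`.
#' @export
read_mtx_matrix <- function(mtx, barcodes, features, sample_of = NULL) {
  m <- as.matrix(Matrix::readMM(mtx))
  cells <- data.table::fread(barcodes, header = FALSE)[[1]]
  genes <- data.table::fread(features, header = FALSE)[[1]]
  if (nrow(m) != length(genes) || ncol(m) != length(cells))
    stop("MTX dimensions do not match feature/barcode files")
  m <- t(m)
  dimnames(m) <- list(cells, genes)
  if (is.null(sample_of)) m else expression_matrix(m, sample_of)
}

#' Read or write a delimited cells-x-features table
#'
#' Plain TSV with cell ids in the first column and one column per feature;
#' empty fields or `NA` are unknown values.
#'
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_table <- function(path) {
  dt <- data.table::fread(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' @rdname read_matrix_table
#' @param x matrix or `scp_matrix` to write.
#' @export
write_matrix_table <- function(x, path) {
  v <- as_values(x)
  dt <- data.table::data.table(cell_id = rownames(v))
  dt <- cbind(dt, data.table::as.data.table(v))
  data.table::fwrite(dt, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}
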