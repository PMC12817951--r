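#' Read and write dense expression matrices (CSV/TSV)
#'
#' Dense convention: cells in rows, genes in columns, header row of gene
#' ids, first column the cell ids.
#'
#' @param path file path.
#' @param sep field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return an [ExpressionMatrix].
#' @export
read_expression_dense <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE)
  ExpressionMatrix(as.matrix(df))
}

#' @rdname read_expression_dense
#' @param m an [ExpressionMatrix].
#' @export
write_expression_dense <- function(m, path, sep = ",") {
  stopifnot(inherits(m, "ExpressionMatrix"))
  df <- data.frame(cell_id = cell_ids(m), unclass(m), check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write 10X-style MatrixMarket matrices
#'
#' The on-disk convention stores the sparse matrix genes x cells
#' (`matrix.mtx`) with `genes.tsv` and `barcodes.tsv` sidecars; it is
#' transposed to cells x genes on load.
#'
#' @param dir directory containing `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv` (alternatively pass the three paths).
#' @param matrix_file,genes_file,barcodes_file explicit paths overriding
#'   `dir`.
#' @return an [ExpressionMatrix].
#' @export
read_expression_mtx <- function(dir = NULL, matrix_file = NULL,
                                genes_file = NULL, barcodes_file = NULL) {
  if (!is.null(dir)) {
    matrix_file <- matrix_file %||% file.path(dir, "matrix.mtx")
    genes_file <- genes_file %||% file.path(dir, "genes.tsv")
    barcodes_file <- barcodes_file %||% file.path(dir, "barcodes.tsv")
  }
  mm <- Matrix::readMM(matrix_file)
  genes <- utils::read.table(genes_file, sep = "\t",
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- utils::read.table(barcodes_file, sep = "\t",
                                stringsAsFactors = FALSE)[[1]]
  if (nrow(mm) != length(genes) || ncol(mm) != length(barcodes))
    stop("sidecar lengths do not match the matrix dimensions")
  ExpressionMatrix(t(as.matrix(mm)), cell_ids = barcodes, gene_ids = genes)
}

#' @rdname read_expression_mtx
#' @param m an [ExpressionMatrix].
#' @export
write_expression_mtx <- function(m, dir) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(t(unclass(m)), sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(gene_ids(m), file.path(dir, "genes.tsv"))
  writeLines(cell_ids(m), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read and write cell label files
#'
#' Two-column TSV mapping `cell_id` to `cell_type` (header optional on
#' read, written on write).
#'
#' @param path file path.
#' @param cell_ids optional: reorder/subset the result to these ids
#'   (error on missing cells).
#' @return named character vector of cell types, names = cell ids.
#' @export
read_labels_tsv <- function(path, cell_ids = NULL) {
  first <- readLines(path, n = 1)
  has_header <- grepl("cell_id", first, fixed = TRUE)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  out <- stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
  if (!is.null(cell_ids)) {
    if (!all(cell_ids %in% names(out)))
      stop("labels missing for some requested cells")
    out <- out[cell_ids]
  }
  out
}

#' @rdname read_labels_tsv
#' @param labels named character vector (names = cell ids) or a
#'   [labeled_set()].
#' @export
write_labels_tsv <- function(labels, path) {
  if (inherits(labels, "LabeledSet"))
    labels <- stats::setNames(labels$class_names[labels$labels],
                              cell_ids(labels$matrix))
  utils::write.table(data.frame(cell_id = names(labels),
                                cell_type = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
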