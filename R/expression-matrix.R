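#' Expression matrix container
#'
#' A cells x genes numeric matrix with mandatory unique cell and gene
#' identifiers. This is the input space of every operation in the package:
#' raw counts before preprocessing, normalized/log values afterwards.
#'
#' @param values numeric matrix, cells in rows, genes in columns. All values
#'   must be finite.
#' @param cell_ids character vector of unique cell identifiers
#'   (default: rownames of `values`).
#' @param gene_ids character vector of unique gene identifiers
#'   (default: colnames of `values`).
#' @return an `ExpressionMatrix`: a numeric matrix with the identifiers as
#'   dimnames and class `"ExpressionMatrix"`.
#' @examples
#' m <- ExpressionMatrix(matrix(0:5, 2, 3),
#'                       cell_ids = c("c1", "c2"),
#'                       gene_ids = c("g1", "g2", "g3"))
#' dim(m)
#' @export
ExpressionMatrix <- function(values, cell_ids = rownames(values),
                             gene_ids = colnames(values)) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(cell_ids) || is.null(gene_ids))
    stop("cell_ids and gene_ids are required (or set as dimnames)")
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("length(cell_ids) != number of rows")
  if (length(gene_ids) != ncol(values))
    stop("length(gene_ids) != number of columns")
  if (anyDuplicated(cell_ids)) stop("duplicate cell identifiers")
  if (anyDuplicated(gene_ids)) stop("duplicate gene identifiers")
  if (!all(is.finite(values))) stop("all values must be finite")
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("ExpressionMatrix", "matrix", "array")
  values
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d cells x %d genes\n", nrow(x), ncol(x)))
  cat(sprintf("  value range: [%.4g, %.4g], %.1f%% zeros\n",
              min(x), max(x), 100 * mean(x == 0)))
  invisible(x)
}

#' @rdname ExpressionMatrix
#' @param m an `ExpressionMatrix`
#' @export
cell_ids <- function(m) rownames(m)

#' @rdname ExpressionMatrix
#' @export
gene_ids <- function(m) colnames(m)

# Subset keeping class + dimnames; i/j as in `[`.
em_subset <- function(m, i = NULL, j = NULL) {
  v <- unclass(m)
  if (!is.null(i)) v <- v[i, , drop = FALSE]
  if (!is.null(j)) v <- v[, j, drop = FALSE]
  ExpressionMatrix(v)
}

#' Labeled and unlabeled cell sets
#'
#' `labeled_set()` pairs an [ExpressionMatrix] with integer class labels in
#' `1..C` and the class-name dictionary; `unlabeled_set()` wraps a matrix of
#' cells whose type is unknown to the learner. The two halves of a
#' semi-supervised problem must share an identical gene space (same ids, same
#' order).
#'
#' @param matrix an [ExpressionMatrix].
#' @param labels integer vector in `1..C` (or factor / character, converted
#'   against `class_names`), one per cell.
#' @param class_names character vector of the C class names. When omitted and
#'   `labels` is factor/character, levels are taken from the data.
#' @return a `LabeledSet` / `UnlabeledSet` list.
#' @export
labeled_set <- function(matrix, labels, class_names = NULL) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  if (is.character(labels)) labels <- factor(labels, levels = unique(labels))
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(factor(as.character(labels), levels = class_names))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(matrix))
    stop("label vector length != cell count")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(max(labels)))
  C <- length(class_names)
  if (anyNA(labels) || any(labels < 1L) || any(labels > C))
    stop("labels must lie in 1..C")
  missing <- setdiff(seq_len(C), unique(labels))
  if (length(missing))
    stop("every class must appear at least once; missing: ",
         paste(class_names[missing], collapse = ", "))
  structure(list(matrix = matrix, labels = labels, class_names = class_names),
            class = "LabeledSet")
}

#' @rdname labeled_set
#' @export
unlabeled_set <- function(matrix) {
  stopifnot(inherits(matrix, "ExpressionMatrix"))
  structure(list(matrix = matrix), class = "UnlabeledSet")
}

#' @export
print.LabeledSet <- function(x, ...) {
  cat(sprintf("LabeledSet: %d cells, %d genes, %d classes\n",
              nrow(x$matrix), ncol(x$matrix), length(x$class_names)))
  print(table(x$class_names[x$labels]))
  invisible(x)
}

#' @export
print.UnlabeledSet <- function(x, ...) {
  cat(sprintf("UnlabeledSet: %d cells, %d genes\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

check_same_genes <- function(labeled, unlabeled) {
  if (!identical(gene_ids(labeled$matrix), gene_ids(unlabeled$matrix)))
    stop("labeled and unlabeled sets must share an identical gene space")
  invisible(TRUE)
}
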