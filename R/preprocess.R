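#' Preprocessing configuration
#'
#' Bundles the thresholds and targets of the standard scRNA-seq cleaning
#' pipeline: cell/gene filtering, library-size normalization, log transform,
#' highly-variable-gene (HVG) selection and unit-variance scaling.
#'
#' @param min_genes_per_cell keep cells expressing at least this many genes
#'   (strictly positive values count as "expressed"). Default 200.
#' @param min_cells_per_gene keep genes expressed in at least this many cells.
#'   Default 3.
#' @param n_hvg number of highly variable genes retained (by per-gene
#'   standard deviation). Default 2000.
#' @param normalize_target per-cell total after library-size normalization.
#'   Default 1e4.
#' @param log_transform apply `log1p` after normalization. Default TRUE.
#' @return a `PreprocessConfig` list.
#' @export
preprocess_config <- function(min_genes_per_cell = 200L,
                              min_cells_per_gene = 3L,
                              n_hvg = 2000L,
                              normalize_target = 1e4,
                              log_transform = TRUE) {
  stopifnot(min_genes_per_cell >= 1, min_cells_per_gene >= 1,
            n_hvg >= 1, normalize_target > 0, is.logical(log_transform))
  structure(list(min_genes_per_cell = as.integer(min_genes_per_cell),
                 min_cells_per_gene = as.integer(min_cells_per_gene),
                 n_hvg = as.integer(n_hvg),
                 normalize_target = normalize_target,
                 log_transform = isTRUE(log_transform)),
            class = "PreprocessConfig")
}

#' Filter low-coverage cells and rarely expressed genes
#'
#' Removes cells with fewer than `min_genes_per_cell` expressed genes and
#' genes expressed (value > 0) in fewer than `min_cells_per_gene` cells. Both
#' counts are taken on the ORIGINAL matrix in a single pass, so removing a
#' cell never changes which genes survive and vice versa. Row/column order is
#' preserved.
#'
#' @param m an [ExpressionMatrix] of non-negative values (typically counts).
#' @param cfg a [preprocess_config()].
#' @return the filtered [ExpressionMatrix].
#' @export
filter_cells_and_genes <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  keep_cells <- rowSums(m > 0) >= cfg$min_genes_per_cell
  keep_genes <- colSums(m > 0) >= cfg$min_cells_per_gene
  if (!any(keep_cells))
    stop("all cells removed: no cell has >= ", cfg$min_genes_per_cell,
         " expressed genes (min_genes_per_cell)")
  if (!any(keep_genes))
    stop("all genes removed: no gene is expressed in >= ",
         cfg$min_cells_per_gene, " cells (min_cells_per_gene)")
  em_subset(m, which(keep_cells), which(keep_genes))
}

#' Library-size normalization and log transform
#'
#' Scales each cell so that its total expression equals
#' `cfg$normalize_target`, then applies `log1p` when `cfg$log_transform`.
#' This makes expression comparable across cells with different sequencing
#' depth.
#'
#' @inheritParams filter_cells_and_genes
#' @return the normalized [ExpressionMatrix].
#' @export
normalize_and_log <- function(m, cfg = preprocess_config()) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (min(m) < 0) stop("normalization expects non-negative values")
  totals <- rowSums(m)
  if (any(totals == 0))
    stop("cells with zero total expression present; filter them first")
  out <- unclass(m) * (cfg$normalize_target / totals)
  if (cfg$log_transform) out <- log1p(out)
  ExpressionMatrix(out)
}

#' Highly variable gene selection
#'
#' Keeps the `n_hvg` genes with the largest per-gene standard deviation
#' (sample sd across cells). Ties are broken in favor of the gene appearing
#' first in the matrix; the original gene order is preserved among survivors.
#'
#' @param m an [ExpressionMatrix] (conventionally log-normalized).
#' @param n_hvg number of genes to retain; must not exceed the gene count.
#' @return the reduced [ExpressionMatrix].
#' @export
select_hvg <- function(m, n_hvg) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  n_hvg <- as.integer(n_hvg)
  if (n_hvg > ncol(m))
    stop("n_hvg (", n_hvg, ") exceeds gene count (", ncol(m), ")")
  sds <- apply(unclass(m), 2, stats::sd)
  ord <- order(-sds, seq_along(sds))      # stable: ties to earlier genes
  keep <- sort(ord[seq_len(n_hvg)])
  em_subset(m, NULL, keep)
}

#' Scale genes to zero mean and unit variance
#'
#' Centers every gene column and divides by its population (ddof = 0)
#' standard deviation. Zero-variance columns become all-zero rather than NaN.
#'
#' @param m an [ExpressionMatrix] with at least 2 cells.
#' @return the scaled [ExpressionMatrix] (values may be negative).
#' @export
scale_unit_variance <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (nrow(m) < 2) stop("need >= 2 cells to scale")
  v <- unclass(m)
  mu <- colMeans(v)
  v <- sweep(v, 2, mu)
  sd0 <- sqrt(colSums(v^2) / nrow(v))
  nz <- sd0 > 0
  v[, nz] <- sweep(v[, nz, drop = FALSE], 2, sd0[nz], "/")
  v[, !nz] <- 0
  ExpressionMatrix(v)
}

#' Run the full preprocessing pipeline
#'
#' Applies, in this fixed order: [filter_cells_and_genes()] →
#' [normalize_and_log()] → [select_hvg()] → [scale_unit_variance()]. The
#' order matters (e.g. HVG standard deviations are computed on log-normalized
#' values) and is the one the pipeline guarantees.
#'
#' @inheritParams filter_cells_and_genes
#' @return the processed [ExpressionMatrix].
#' @export
preprocess_pipeline <- function(m, cfg = preprocess_config()) {
  m <- filter_cells_and_genes(m, cfg)
  m <- normalize_and_log(m, cfg)
  m <- select_hvg(m, min(cfg$n_hvg, ncol(m)))
  scale_unit_variance(m)
}

#' Stratified labeled/unlabeled split
#'
#' Draws a labeled subset of approximately a fraction `p` of the cells,
#' stratified per class: each class contributes `round_half_up(p * size)`
#' cells, with a floor of one labeled cell per class so that every class
#' center is computable. The complement forms the unlabeled set; its true
#' labels are returned separately for evaluation only.
#'
#' @param m an [ExpressionMatrix] (typically preprocessed).
#' @param labels full ground-truth label vector (factor, character, or
#'   integer codes), one per cell.
#' @param p labeled fraction in (0, 1).
#' @param seed integer seed making the draw deterministic.
#' @param class_names optional class dictionary (required when `labels` is
#'   already integer).
#' @return a list with elements `labeled` ([labeled_set()]), `unlabeled`
#'   ([unlabeled_set()]) and `truth` (integer labels of the unlabeled cells).
#' @export
split_by_label_fraction <- function(m, labels, p, seed, class_names = NULL) {
  stopifnot(inherits(m, "ExpressionMatrix"), p > 0, p < 1)
  if (is.character(labels)) labels <- factor(labels, levels = unique(labels))
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(factor(as.character(labels), levels = class_names))
  }
  labels <- as.integer(labels)
  if (length(labels) != nrow(m)) stop("label vector length != cell count")
  if (is.null(class_names)) class_names <- paste0("class", seq_len(max(labels)))
  C <- length(class_names)
  counts <- tabulate(labels, nbins = C)
  if (any(counts == 0))
    stop("class with 0 cells: ", paste(class_names[counts == 0], collapse = ", "))
  if (p * nrow(m) < C)
    warning("p * n_cells < number of classes; the per-class floor of 1 ",
            "labeled cell pushes the labeled fraction above p")
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_rng(old))
  lab_idx <- integer(0)
  for (c in seq_len(C)) {
    idx <- which(labels == c)
    k <- max(1L, floor(p * length(idx) + 0.5))   # half-up rounding
    k <- min(k, length(idx))
    lab_idx <- c(lab_idx, sort(sample(idx, k)))
  }
  lab_idx <- sort(lab_idx)
  unl_idx <- setdiff(seq_len(nrow(m)), lab_idx)
  if (!length(unl_idx)) stop("labeled fraction leaves no unlabeled cells")
  list(labeled = labeled_set(em_subset(m, lab_idx), labels[lab_idx], class_names),
       unlabeled = unlabeled_set(em_subset(m, unl_idx)),
       truth = labels[unl_idx])
}

restore_rng <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}
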