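#' Synthetic scRNA-seq dataset specification
#'
#' Parameters of the generative model used for offline benchmarking: C cell
#' types, each with a baseline mean profile plus a disjoint block of marker
#' genes upshifted by `2^marker_log_fold_change`; counts drawn
#' negative-binomial (size = `dispersion`) around per-cell means scaled by a
#' log-normal library-size factor; entries then zeroed independently with
#' `dropout_rate` (dropout-style zero inflation).
#'
#' @param n_cells,n_genes matrix dimensions.
#' @param n_types number of cell types C.
#' @param type_proportions probability vector of length C (default uniform).
#' @param n_marker_genes_per_type markers per type (disjoint blocks).
#'   Default 50 (10% of the default gene count per type, the order of
#'   magnitude of differentially expressed genes between real cell types).
#' @param marker_log_fold_change log2 fold change of markers in their own
#'   type. Default 2 (4x).
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed). Default 3.
#' @param dropout_rate probability an entry is zeroed after sampling.
#'   Default 0.2.
#' @param library_size_log_sd sd of the per-cell log-normal library-size
#'   factor. Default 0.35.
#' @param mean_counts_per_cell expected total counts per cell before
#'   dropout. Default 5000 (typical droplet-protocol depth).
#' @param seed RNG seed; generation is bitwise reproducible.
#' @return a `SyntheticSpec` list.
#' @export
synthetic_spec <- function(n_cells = 2000L, n_genes = 500L, n_types = 5L,
                           type_proportions = NULL,
                           n_marker_genes_per_type = 50L,
                           marker_log_fold_change = 2,
                           dispersion = 3,
                           dropout_rate = 0.2,
                           library_size_log_sd = 0.35,
                           mean_counts_per_cell = 5000,
                           seed = 1L) {
  if (is.null(type_proportions))
    type_proportions <- rep(1 / n_types, n_types)
  if (length(type_proportions) != n_types)
    stop("type_proportions length != n_types")
  if (abs(sum(type_proportions) - 1) > 1e-8)
    stop("type_proportions must sum to 1")
  if (n_types * n_marker_genes_per_type > n_genes)
    stop("marker blocks exceed the gene count")
  stopifnot(marker_log_fold_change > 0, dispersion > 0,
            dropout_rate >= 0, dropout_rate <= 1, library_size_log_sd >= 0)
  structure(list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
                 n_types = as.integer(n_types),
                 type_proportions = type_proportions,
                 n_marker_genes_per_type = as.integer(n_marker_genes_per_type),
                 marker_log_fold_change = marker_log_fold_change,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 library_size_log_sd = library_size_log_sd,
                 mean_counts_per_cell = mean_counts_per_cell,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic count matrix with known cell types
#'
#' @param spec a [synthetic_spec()].
#' @param marker_blocks optional C-row integer list overriding the default
#'   disjoint marker blocks, enabling shared-marker (near-duplicate) types.
#' @param marker_lfc optional per-type log2 fold change vector overriding
#'   the scalar in `spec`.
#' @return list with `matrix` (an [ExpressionMatrix] of counts), `labels`
#'   (integer types 1..C), `class_names`, and `marker_genes` (list of
#'   per-type marker column indices).
#' @export
generate_synthetic <- function(spec, marker_blocks = NULL, marker_lfc = NULL) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(spec$seed)
  on.exit(restore_rng(old))
  C <- spec$n_types; G <- spec$n_genes; N <- spec$n_cells
  if (is.null(marker_blocks)) {
    k <- spec$n_marker_genes_per_type
    marker_blocks <- lapply(seq_len(C), function(c)
      ((c - 1L) * k + 1L):(c * k))
  }
  if (is.null(marker_lfc)) marker_lfc <- rep(spec$marker_log_fold_change, C)
  # baseline relative expression, shared by all types
  base <- stats::rgamma(G, shape = 2, rate = 2) + 0.05
  mu_types <- do.call(rbind, lapply(seq_len(C), function(c) {
    m <- base
    m[marker_blocks[[c]]] <- m[marker_blocks[[c]]] * 2^marker_lfc[c]
    m / sum(m)                      # relative expression, sums to 1
  }))
  labels <- sample.int(C, N, replace = TRUE, prob = spec$type_proportions)
  lib <- spec$mean_counts_per_cell *
    exp(stats::rnorm(N, 0, spec$library_size_log_sd))
  counts <- matrix(0, N, G)
  for (c in seq_len(C)) {
    rows <- which(labels == c)
    if (!length(rows)) next
    mu <- outer(lib[rows], mu_types[c, ])
    counts[rows, ] <- stats::rnbinom(length(mu), size = spec$dispersion,
                                     mu = mu)
  }
  if (spec$dropout_rate > 0)
    counts[stats::runif(length(counts)) < spec$dropout_rate] <- 0
  m <- ExpressionMatrix(counts,
                        cell_ids = sprintf("cell%0*d", nchar(N), seq_len(N)),
                        gene_ids = sprintf("gene%0*d", nchar(G), seq_len(G)))
  list(matrix = m, labels = labels,
       class_names = paste0("type", seq_len(C)),
       marker_genes = marker_blocks)
}

#' Ready-made benchmark fixtures
#'
#' `easy`: 2,000 cells x 500 genes, 5 well-separated types (marker log2 fold
#' change 2). `hard`: 2,000 cells x 500 genes, 8 types of which two are
#' near-duplicates sharing the same marker block at log2 fold changes 2 and
#' 1.5 — emulating closely related cell subtypes, the discriminating
#' challenge for annotation. Both are run through the preprocessing pipeline
#' (filter at 50 expressed genes / 3 cells, normalize to 1e4, log1p, 250
#' HVGs, unit-variance scaling) and split with labeled fraction `p`.
#'
#' @param difficulty `"easy"` or `"hard"`.
#' @param seed RNG seed (generation and split).
#' @param p labeled fraction. Default 0.1.
#' @return list with `labeled`, `unlabeled`, `truth` (labels of the
#'   unlabeled cells), `class_names`, and `all` (the processed matrix with
#'   its full label vector, for CV designs).
#' @export
make_benchmark_fixture <- function(difficulty = c("easy", "hard"), seed = 1L,
                                   p = 0.1) {
  difficulty <- match.arg(difficulty)
  if (difficulty == "easy") {
    spec <- synthetic_spec(n_cells = 2000L, n_genes = 500L, n_types = 5L,
                           marker_log_fold_change = 2, seed = seed)
    sim <- generate_synthetic(spec)
  } else {
    spec <- synthetic_spec(n_cells = 2000L, n_genes = 500L, n_types = 8L,
                           marker_log_fold_change = 2, seed = seed)
    k <- spec$n_marker_genes_per_type
    blocks <- lapply(seq_len(8L), function(c) ((c - 1L) * k + 1L):(c * k))
    blocks[[8L]] <- blocks[[7L]]        # types 7 and 8 share their markers
    lfc <- c(rep(2, 7), 1.5)            # ...0.5 apart in log2 fold change
    sim <- generate_synthetic(spec, marker_blocks = blocks, marker_lfc = lfc)
  }
  cfg <- preprocess_config(min_genes_per_cell = 50L, min_cells_per_gene = 3L,
                           n_hvg = 250L)
  filt <- filter_cells_and_genes(sim$matrix, cfg)
  keep <- match(cell_ids(filt), cell_ids(sim$matrix))
  labels <- sim$labels[keep]
  proc <- scale_unit_variance(
    select_hvg(normalize_and_log(filt, cfg), min(cfg$n_hvg, ncol(filt))))
  sp <- split_by_label_fraction(proc, labels, p, seed = seed + 777L,
                                class_names = sim$class_names)
  c(sp, list(class_names = sim$class_names,
             all = list(matrix = proc, labels = labels)))
}
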