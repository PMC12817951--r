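#' Annotation scoring: accuracy, per-class and macro F1
#'
#' Accuracy is the fraction of correct predictions x 100. Per-class F1 is
#' `2PR/(P+R)` (0 when precision + recall is 0, including classes absent
#' from both truth and prediction, with a note); macro F1 is their
#' unweighted mean x 100, the imbalance-robust aggregate.
#'
#' @param truth,predicted aligned class vectors (integer in 1..C, factor or
#'   character).
#' @param class_names class dictionary; required when inputs are integer,
#'   otherwise inferred from the data.
#' @return an `EvaluationReport` list: `accuracy`, `macro_f1` (both
#'   percentages), `per_class_f1` (fractions), `confusion` (C x C counts,
#'   truth in rows) and `n_cells`.
#' @export
score_annotation <- function(truth, predicted, class_names = NULL) {
  if (length(truth) != length(predicted))
    stop("truth and predicted lengths differ")
  if (is.null(class_names)) {
    if (is.numeric(truth) && is.numeric(predicted)) {
      class_names <- paste0("class", seq_len(max(truth, predicted)))
    } else {
      class_names <- sort(unique(c(as.character(truth),
                                   as.character(predicted))))
    }
  }
  to_idx <- function(v) {
    if (is.numeric(v)) as.integer(v)
    else as.integer(factor(as.character(v), levels = class_names))
  }
  ti <- to_idx(truth); pi <- to_idx(predicted)
  C <- length(class_names)
  if (anyNA(ti) || anyNA(pi) || any(c(ti, pi) < 1L) || any(c(ti, pi) > C))
    stop("labels outside 1..C")
  n <- length(ti)
  confusion <- matrix(0L, C, C, dimnames = list(truth = class_names,
                                                predicted = class_names))
  for (k in seq_len(n))
    confusion[ti[k], pi[k]] <- confusion[ti[k], pi[k]] + 1L
  tp <- diag(confusion)
  prec_den <- colSums(confusion)
  rec_den <- rowSums(confusion)
  f1 <- numeric(C)
  for (c in seq_len(C)) {
    p <- if (prec_den[c] > 0) tp[c] / prec_den[c] else 0
    r <- if (rec_den[c] > 0) tp[c] / rec_den[c] else 0
    f1[c] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  absent <- rec_den == 0 & prec_den == 0
  if (any(absent))
    message("class(es) absent from truth and prediction scored F1 = 0: ",
            paste(class_names[absent], collapse = ", "))
  structure(list(accuracy = 100 * sum(tp) / n,
                 macro_f1 = 100 * mean(f1),
                 per_class_f1 = stats::setNames(f1, class_names),
                 confusion = confusion, n_cells = n),
            class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat(sprintf("EvaluationReport: %d cells, accuracy %.3f%%, macro-F1 %.3f%%\n",
              x$n_cells, x$accuracy, x$macro_f1))
  invisible(x)
}

# Stratified fold ids: per class, shuffled cells dealt into n_folds chunks.
stratified_folds <- function(labels, n_folds, seed) {
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_rng(old))
  fold <- integer(length(labels))
  for (c in unique(labels)) {
    idx <- sample(which(labels == c))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Stratified cross-validation with the small fold as labeled data
#'
#' Partitions the cells into `n_folds` folds preserving per-class
#' proportions. In each round ONE fold plays the labeled set and the
#' remaining folds form the unlabeled set, on which the predictions are
#' scored — the inversion of conventional CV that matches the
#' scarce-annotation setting (each round trains on ~1/n_folds of the data).
#'
#' @param m an [ExpressionMatrix].
#' @param labels full ground-truth labels.
#' @param runner closure `function(labeled, unlabeled) -> predicted labels`
#'   (class names or indices) for the unlabeled cells, e.g. wrapping
#'   [fit_semisup()] + [predict.scsemi_fit()].
#' @param n_folds number of folds (default 10); reduced with a warning when
#'   a class has fewer cells than folds.
#' @param seed RNG seed for fold assignment.
#' @param class_names class dictionary.
#' @return list with `fold_reports` (per-round `EvaluationReport`s) and
#'   `summary` (mean and standard error, sd/sqrt(folds), of accuracy and
#'   macro F1).
#' @export
stratified_cv <- function(m, labels, runner, n_folds = 10L, seed = 1L,
                          class_names = NULL) {
  if (is.character(labels)) labels <- factor(labels, levels = unique(labels))
  if (is.factor(labels)) {
    if (is.null(class_names)) class_names <- levels(labels)
    labels <- as.integer(factor(as.character(labels), levels = class_names))
  }
  if (is.null(class_names)) class_names <- paste0("class", seq_len(max(labels)))
  counts <- tabulate(labels, nbins = length(class_names))
  if (any(counts == 0)) stop("class with 0 cells")
  if (min(counts) < n_folds) {
    n_folds <- max(2L, min(counts))
    warning("smallest class has fewer cells than folds; reduced to ",
            n_folds, " folds")
  }
  fold <- stratified_folds(labels, n_folds, seed)
  reports <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    lab_idx <- which(fold == f)
    unl_idx <- which(fold != f)
    lab <- labeled_set(em_subset(m, lab_idx), labels[lab_idx], class_names)
    unl <- unlabeled_set(em_subset(m, unl_idx))
    pred <- runner(lab, unl)
    reports[[f]] <- score_annotation(labels[unl_idx], pred, class_names)
  }
  acc <- vapply(reports, `[[`, numeric(1), "accuracy")
  f1 <- vapply(reports, `[[`, numeric(1), "macro_f1")
  list(fold_reports = reports,
       summary = data.frame(
         metric = c("accuracy", "macro_f1"),
         mean = c(mean(acc), mean(f1)),
         se = c(stats::sd(acc), stats::sd(f1)) / sqrt(n_folds)))
}

#' Label-fraction sweep
#'
#' For each labeled fraction `p`, repeats `repeats` independent stratified
#' splits, trains via `runner`, scores on the unlabeled remainder and
#' averages.
#'
#' @inheritParams stratified_cv
#' @param p_values numeric vector of labeled fractions in (0, 1).
#' @param repeats independent splits per `p` (default 10).
#' @return data.frame with one row per `p`: mean/sd of accuracy and macro
#'   F1 over the repeats.
#' @export
label_fraction_sweep <- function(m, labels, p_values, runner, repeats = 10L,
                                 seed = 1L, class_names = NULL) {
  rows <- lapply(p_values, function(p) {
    accs <- f1s <- numeric(repeats)
    for (r in seq_len(repeats)) {
      sp <- split_by_label_fraction(m, labels, p,
                                    seed = seed + 1000L * r +
                                      round(1e5 * p),
                                    class_names = class_names)
      pred <- runner(sp$labeled, sp$unlabeled)
      rep_ <- score_annotation(sp$truth, pred, sp$labeled$class_names)
      accs[r] <- rep_$accuracy; f1s[r] <- rep_$macro_f1
    }
    data.frame(p = p, accuracy = mean(accs), accuracy_sd = stats::sd(accs),
               macro_f1 = mean(f1s), macro_f1_sd = stats::sd(f1s),
               repeats = repeats)
  })
  do.call(rbind, rows)
}

#' Write an evaluation report
#'
#' @param reports a list of `EvaluationReport`s (or a single one).
#' @param path_json,path_tsv output files (either may be NULL).
#' @param method,dataset annotation columns for the flat TSV.
#' @return invisibly, the flat data.frame.
#' @export
write_evaluation <- function(reports, path_json = NULL, path_tsv = NULL,
                             method = "scSemiLab", dataset = "fixture") {
  if (inherits(reports, "EvaluationReport")) reports <- list(reports)
  flat <- do.call(rbind, lapply(seq_along(reports), function(i)
    data.frame(method = method, dataset = dataset, fold = i,
               accuracy = reports[[i]]$accuracy,
               macro_f1 = reports[[i]]$macro_f1)))
  if (!is.null(path_json))
    jsonlite::write_json(lapply(reports, function(r)
      list(accuracy = r$accuracy, macro_f1 = r$macro_f1,
           per_class_f1 = as.list(r$per_class_f1), n_cells = r$n_cells)),
      path_json, auto_unbox = TRUE, digits = NA)
  if (!is.null(path_tsv))
    utils::write.table(flat, path_tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(flat)
}
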