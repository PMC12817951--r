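#' Training plan
#'
#' The full three-stage schedule: contrastive pretraining, supervised
#' warm-up, then alternating confidence-estimator / annotator training with
#' the consistency loss. Defaults follow the reference schedule: stage
#' epochs (100, 200, 150), annotator Adam learning rates (5e-4, 1e-4, 5e-5),
#' estimator learning rate 1e-4, and consistency weight lambda = 0.5.
#'
#' @param stage_epochs integer triple of epochs for stages 1-3.
#' @param stage_lrs annotator learning-rate triple for stages 1-3.
#' @param estimator_lr confidence-estimator learning rate.
#' @param lambda weight of the consistency loss in the stage-3 annotator
#'   objective `Ls + lambda * Lu`.
#' @param batch_size minibatch size for stages 2-3.
#' @param warmup_epochs_before_estimator stage-3 epochs run with confidence
#'   fixed at 1 before the estimator starts training. Default 0 (stage 2
#'   already provides the supervised warm-up).
#' @param conf_floor lower clip applied to confidences during estimator
#'   training, preventing the degenerate all-zero-confidence minimum of the
#'   estimator objective; set to 0 to disable. Default 0.01.
#' @param seed master RNG seed; makes `fit()` bitwise reproducible.
#' @param ablation character subset of `c("no_pretrain", "no_consistency",
#'   "no_confidence")`: skip stage 1 / run stage 3 supervised-only / fix
#'   confidence at 1.
#' @param hidden_dims annotator hidden widths. Default `c(100, 50, 25)`.
#' @return a `TrainingPlan` list.
#' @export
training_plan <- function(stage_epochs = c(100L, 200L, 150L),
                          stage_lrs = c(5e-4, 1e-4, 5e-5),
                          estimator_lr = 1e-4,
                          lambda = 0.5,
                          batch_size = 128L,
                          warmup_epochs_before_estimator = 0L,
                          conf_floor = 0.01,
                          seed = 1L,
                          ablation = character(0),
                          hidden_dims = c(100L, 50L, 25L)) {
  stopifnot(length(stage_epochs) == 3, all(stage_epochs >= 0),
            length(stage_lrs) == 3, all(stage_lrs > 0),
            estimator_lr > 0, lambda >= 0, batch_size >= 1,
            warmup_epochs_before_estimator >= 0, conf_floor >= 0)
  bad <- setdiff(ablation, c("no_pretrain", "no_consistency", "no_confidence"))
  if (length(bad)) stop("unknown ablation switch: ", paste(bad, collapse = ", "))
  structure(list(stage_epochs = as.integer(stage_epochs),
                 stage_lrs = stage_lrs, estimator_lr = estimator_lr,
                 lambda = lambda, batch_size = as.integer(batch_size),
                 warmup_epochs_before_estimator =
                   as.integer(warmup_epochs_before_estimator),
                 conf_floor = conf_floor, seed = as.integer(seed),
                 ablation = ablation,
                 hidden_dims = as.integer(hidden_dims)),
            class = "TrainingPlan")
}

#' Supervised cross-entropy loss
#'
#' Mean over cells of `-log p[i, y_i]` for probability rows `p` and integer
#' labels `y` in 1..C.
#'
#' @param probs N x C matrix of probabilities (rows sum to 1).
#' @param labels integer vector in 1..C.
#' @return non-negative scalar.
#' @export
supervised_loss <- function(probs, labels) {
  probs <- as.matrix(probs)
  labels <- as.integer(labels)
  if (length(labels) != nrow(probs)) stop("labels length != row count")
  if (any(labels < 1L) || any(labels > ncol(probs)))
    stop("label out of range 1..C")
  -mean(log(pmax(probs[cbind(seq_along(labels), labels)], 1e-12)))
}

#' Confidence-weighted consistency loss
#'
#' `Lu = mean_i conf_i * (H(y*_i, p_weak_i) + H(y*_i, p_strong_i))` where
#' `y*` are hard pseudo-labels and H is cross-entropy against them: the
#' predictions on both augmented views are pulled toward the pseudo-label,
#' each cell weighted by its estimated confidence.
#'
#' @param conf numeric vector of per-cell confidences in `[0, 1]`.
#' @param pseudo integer pseudo-labels in 1..C.
#' @param probs_weak,probs_strong N x C probability matrices for the weak
#'   and strong views.
#' @return non-negative scalar.
#' @export
consistency_loss <- function(conf, pseudo, probs_weak, probs_strong) {
  probs_weak <- as.matrix(probs_weak); probs_strong <- as.matrix(probs_strong)
  n <- length(conf)
  if (length(pseudo) != n || nrow(probs_weak) != n || nrow(probs_strong) != n)
    stop("conf, pseudo and probability matrices must align")
  if (any(conf < 0) || any(conf > 1)) stop("conf must lie in [0, 1]")
  i <- cbind(seq_len(n), as.integer(pseudo))
  hw <- -log(pmax(probs_weak[i], 1e-12))
  hs <- -log(pmax(probs_strong[i], 1e-12))
  mean(conf * (hw + hs))
}

# Gradient of mean CE w.r.t. logits for hard labels, optionally per-cell
# weighted: w_i * (p_i - onehot_i) / N.
ce_logit_grad <- function(probs, labels, weights = NULL) {
  n <- nrow(probs)
  g <- probs
  g[cbind(seq_len(n), labels)] <- g[cbind(seq_len(n), labels)] - 1
  if (!is.null(weights)) g <- g * weights
  g / n
}

# --- training log (JSON-lines friendly) -------------------------------------

#' Training log collector
#'
#' An environment accumulating one record per epoch; [write_training_log()]
#' dumps it as JSON-lines.
#' @return a `training_log` environment.
#' @export
training_log <- function() {
  e <- new.env(parent = emptyenv())
  e$records <- list()
  class(e) <- "training_log"
  e
}

log_event <- function(log, ...) {
  if (is.null(log)) return(invisible(NULL))
  log$records[[length(log$records) + 1L]] <- list(...)
  invisible(NULL)
}

#' @rdname training_log
#' @param log a `training_log`.
#' @param path output file; one JSON object per line.
#' @export
write_training_log <- function(log, path) {
  lines <- vapply(log$records, function(r)
    jsonlite::toJSON(r, auto_unbox = TRUE, digits = NA), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname training_log
#' @export
as.data.frame.training_log <- function(x, ...) {
  recs <- lapply(x$records, function(r) r[!vapply(r, is.null, logical(1))])
  cols <- unique(unlist(lapply(recs, names)))
  do.call(rbind, lapply(recs, function(r) {
    r[setdiff(cols, names(r))] <- NA
    as.data.frame(r[cols])
  }))
}

# --- stages ------------------------------------------------------------------

supervised_epoch <- function(net, state, x, y, bs, lr) {
  n <- nrow(x)
  ord <- sample.int(n)
  losses <- c()
  for (start in seq(1, n, by = bs)) {
    idx <- ord[start:min(start + bs - 1, n)]
    acts <- net_forward_acts(net, x[idx, , drop = FALSE])
    probs <- softmax(acts$A[[4]])
    losses <- c(losses, supervised_loss(probs, y[idx]))
    grads <- net_backprop(net, acts, ce_logit_grad(probs, y[idx]))
    upd <- adam_step(net, grads, state, lr)
    net <- upd$net; state <- upd$state
  }
  list(net = net, state = state, loss = mean(losses))
}

#' Stage 2: supervised warm-up on the labeled cells
#'
#' Adam on the supervised cross-entropy for `plan$stage_epochs[2]` epochs at
#' `plan$stage_lrs[2]`.
#'
#' @param net an [annotator_network()] (typically stage-1 output).
#' @param labeled a [labeled_set()].
#' @param plan a [training_plan()].
#' @param seed RNG seed for shuffling.
#' @param log optional [training_log()].
#' @return the trained network.
#' @export
run_stage2 <- function(net, labeled, plan = training_plan(), seed = 1L,
                       log = NULL) {
  stopifnot(inherits(labeled, "LabeledSet"))
  x <- as.matrix(labeled$matrix); y <- labeled$labels
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_rng(old))
  state <- adam_init(net)
  bs <- min(plan$batch_size, nrow(x))
  for (epoch in seq_len(plan$stage_epochs[2])) {
    r <- supervised_epoch(net, state, x, y, bs, plan$stage_lrs[2])
    net <- r$net; state <- r$state
    log_event(log, stage = 2L, epoch = epoch, loss_s = r$loss)
  }
  net
}

#' Stage 3: alternating confidence-estimator / annotator training
#'
#' Each epoch: (a) pseudo-labels are recomputed by class-seeded spherical
#' K-means on the current embeddings; (b) estimator phase — the annotator is
#' frozen and the estimator takes one pass over the unlabeled batches
#' minimizing the consistency loss Lu; (c) annotator phase — the estimator
#' is frozen and the annotator minimizes `Ls + lambda * Lu` over parallel
#' labeled/unlabeled batches (the labeled batch is resampled with
#' replacement once exhausted). Under `no_confidence` the confidence is
#' fixed at 1 and the estimator phase is skipped; under `no_consistency`
#' stage 3 degenerates to supervised-only epochs.
#'
#' @param net stage-2 annotator.
#' @param est a [confidence_estimator()] (ignored under ablations that
#'   disable it).
#' @param labeled,unlabeled the two cell sets.
#' @param plan a [training_plan()].
#' @param aug_cfg an [augmentation_config()].
#' @param seed RNG seed.
#' @param log optional [training_log()].
#' @return `list(net, est)`.
#' @export
run_stage3 <- function(net, est, labeled, unlabeled, plan = training_plan(),
                       aug_cfg = augmentation_config(), seed = 1L,
                       log = NULL) {
  stopifnot(inherits(labeled, "LabeledSet"), inherits(unlabeled, "UnlabeledSet"))
  check_same_genes(labeled, unlabeled)
  xl <- as.matrix(labeled$matrix); yl <- labeled$labels
  xu <- as.matrix(unlabeled$matrix)
  nl <- nrow(xl); nu <- nrow(xu)
  no_cons <- "no_consistency" %in% plan$ablation
  no_conf <- "no_confidence" %in% plan$ablation
  lr <- plan$stage_lrs[3]
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_rng(old))
  state_net <- adam_init(net)
  state_est <- adam_init(est)
  bs <- min(plan$batch_size, if (no_cons) nl else nu)
  for (epoch in seq_len(plan$stage_epochs[3])) {
    if (no_cons) {
      r <- supervised_epoch(net, state_net, xl, yl, min(bs, nl), lr)
      net <- r$net; state_net <- r$state
      log_event(log, stage = 3L, epoch = epoch, loss_s = r$loss)
      next
    }
    # (a) refresh pseudo-labels from current embeddings
    ps <- assign_pseudo_labels(net, labeled, unlabeled)
    pseudo <- ps$assignments
    in_warmup <- epoch <= plan$warmup_epochs_before_estimator
    # (b) estimator phase: annotator frozen
    lu_est <- NA_real_
    if (!no_conf && !in_warmup) {
      net <- freeze(net)
      est <- unfreeze(est)
      ord <- sample.int(nu)
      lus <- c()
      for (start in seq(1, nu, by = bs)) {
        idx <- ord[start:min(start + bs - 1, nu)]
        xb <- xu[idx, , drop = FALSE]
        fw <- net_forward(net, weak_augment(xb, aug_cfg))
        fs <- net_forward(net, strong_augment(xb, aug_cfg))
        i <- cbind(seq_along(idx), pseudo[idx])
        w <- -log(pmax(fw$probs[i], 1e-12)) - log(pmax(fs$probs[i], 1e-12))
        emb <- net_embed(net, xb)
        logits <- net_forward(net, xb)$logits
        ea <- est_forward_acts(est, emb, logits)
        lus <- c(lus, mean(pmax(ea$conf, plan$conf_floor) * w))
        eg <- est_backprop(est, ea, w, plan$conf_floor)
        upd <- adam_step(est, eg, state_est, plan$estimator_lr)
        est <- upd$net; state_est <- upd$state
      }
      lu_est <- mean(lus)
      net <- unfreeze(net)
    }
    # (c) annotator phase: estimator frozen
    est <- freeze(est)
    ord <- sample.int(nu)
    ls_ep <- lu_ep <- conf_ep <- c()
    for (start in seq(1, nu, by = bs)) {
      idx <- ord[start:min(start + bs - 1, nu)]
      xb <- xu[idx, , drop = FALSE]
      lidx <- sample.int(nl, min(bs, nl), replace = nl < bs)
      # confidence (detached)
      if (no_conf || in_warmup) {
        conf <- rep(1, length(idx))
      } else {
        conf <- estimate_confidence(est, net_embed(net, xb),
                                    net_forward(net, xb)$logits)
      }
      aw <- net_forward_acts(net, weak_augment(xb, aug_cfg))
      as_ <- net_forward_acts(net, strong_augment(xb, aug_cfg))
      pw <- softmax(aw$A[[4]]); pstr <- softmax(as_$A[[4]])
      al <- net_forward_acts(net, xl[lidx, , drop = FALSE])
      pl <- softmax(al$A[[4]])
      ls <- supervised_loss(pl, yl[lidx])
      lu <- consistency_loss(conf, pseudo[idx], pw, pstr)
      grads <- net_backprop(net, al, ce_logit_grad(pl, yl[lidx]))
      if (plan$lambda > 0) {
        gw <- net_backprop(net, aw,
                           plan$lambda * ce_logit_grad(pw, pseudo[idx], conf))
        gs <- net_backprop(net, as_,
                           plan$lambda * ce_logit_grad(pstr, pseudo[idx], conf))
        grads <- add_grads(grads, add_grads(gw, gs))
      }
      if (!all(vapply(grads, function(g) all(is.finite(g$W)) && all(is.finite(g$b)),
                      logical(1))))
        stop("non-finite gradient in stage 3 (epoch ", epoch, "): aborting")
      upd <- adam_step(net, grads, state_net, lr)
      net <- upd$net; state_net <- upd$state
      ls_ep <- c(ls_ep, ls); lu_ep <- c(lu_ep, lu); conf_ep <- c(conf_ep, conf)
    }
    est <- unfreeze(est)
    log_event(log, stage = 3L, epoch = epoch, loss_s = mean(ls_ep),
              loss_u = mean(lu_ep), loss_u_estimator = lu_est,
              mean_confidence = mean(conf_ep),
              kmeans_iterations = ps$n_iterations)
  }
  list(net = net, est = est)
}

#' Fit the full semi-supervised annotator
#'
#' Runs the three training stages: contrastive pretraining on the unlabeled
#' cells (skipped under the `no_pretrain` ablation), supervised warm-up on
#' the labeled cells, and alternating estimator/annotator training with
#' cluster pseudo-labels and the consistency loss. Fully deterministic given
#' `plan$seed`.
#'
#' @param labeled a [labeled_set()].
#' @param unlabeled an [unlabeled_set()] on the same gene space.
#' @param plan a [training_plan()].
#' @param aug_cfg an [augmentation_config()].
#' @param c_cfg a [contrastive_config()] (its `epochs`/`learning_rate` are
#'   overridden by stage 1 of the plan).
#' @return an object of class `scsemi_fit`: the trained annotator and
#'   estimator, the gene/class dictionaries, the plan and the training log.
#' @export
fit_semisup <- function(labeled, unlabeled, plan = training_plan(),
                        aug_cfg = augmentation_config(),
                        c_cfg = contrastive_config()) {
  stopifnot(inherits(labeled, "LabeledSet"), inherits(unlabeled, "UnlabeledSet"))
  check_same_genes(labeled, unlabeled)
  genes <- gene_ids(labeled$matrix)
  C <- length(labeled$class_names)
  log <- training_log()
  net <- annotator_network(length(genes), C, plan$hidden_dims,
                           seed = plan$seed)
  est <- confidence_estimator(plan$hidden_dims[2], C, seed = plan$seed + 1L)
  c_cfg$epochs <- plan$stage_epochs[1]
  c_cfg$learning_rate <- plan$stage_lrs[1]
  c_cfg$batch_size <- plan$batch_size
  if (!"no_pretrain" %in% plan$ablation && plan$stage_epochs[1] > 0)
    net <- pretrain_contrastive(net, unlabeled, aug_cfg, c_cfg,
                                seed = plan$seed + 11L, log = log)
  if (plan$stage_epochs[2] > 0)
    net <- run_stage2(net, labeled, plan, seed = plan$seed + 22L, log = log)
  if (plan$stage_epochs[3] > 0) {
    r <- run_stage3(net, est, labeled, unlabeled, plan, aug_cfg,
                    seed = plan$seed + 33L, log = log)
    net <- r$net; est <- r$est
  }
  structure(list(net = net, est = est, gene_ids = genes,
                 class_names = labeled$class_names, plan = plan,
                 aug_cfg = aug_cfg, c_cfg = c_cfg, log = log),
            class = "scsemi_fit")
}

#' @export
print.scsemi_fit <- function(x, ...) {
  cat(sprintf("scsemi_fit: %d genes, %d classes (%s)\n",
              length(x$gene_ids), length(x$class_names),
              paste(x$class_names, collapse = ", ")))
  cat(sprintf("  stages (epochs): %s; seed %d%s\n",
              paste(x$plan$stage_epochs, collapse = "/"), x$plan$seed,
              if (length(x$plan$ablation))
                paste0("; ablation: ", paste(x$plan$ablation, collapse = ","))
              else ""))
  invisible(x)
}

#' Predict cell types for a query matrix
#'
#' Aligns the query's genes to the training gene space by identifier
#' (reordering, and zero-filling genes missing from the query with a
#' warning), runs the annotator and returns the argmax class per cell (ties
#' to the lowest class index).
#'
#' @param object an `scsemi_fit`.
#' @param query an [ExpressionMatrix] (preprocessed like the training data)
#'   or bare matrix with gene column names.
#' @param ... unused.
#' @return list with `labels` (character class names), `labels_idx`
#'   (integer), and `probabilities` (N x C matrix).
#' @export
predict.scsemi_fit <- function(object, query, ...) {
  q <- as.matrix(query)
  if (is.null(colnames(q))) {
    if (ncol(q) != length(object$gene_ids))
      stop("unnamed query with wrong gene count")
    colnames(q) <- object$gene_ids
  }
  common <- intersect(object$gene_ids, colnames(q))
  if (!length(common)) stop("query shares no genes with the training data")
  if (length(common) < length(object$gene_ids)) {
    warning(length(object$gene_ids) - length(common),
            " training gene(s) absent from query; zero-filled")
  }
  x <- matrix(0, nrow(q), length(object$gene_ids),
              dimnames = list(rownames(q), object$gene_ids))
  x[, common] <- q[, common]
  fw <- net_forward(object$net, x)
  idx <- max.col(fw$probs, ties.method = "first")
  list(labels = object$class_names[idx], labels_idx = idx,
       probabilities = fw$probs)
}

#' Write a predictions table
#'
#' TSV with cell_id, predicted_type, max_probability and one column per
#' class probability.
#'
#' @param pred result of [predict.scsemi_fit()].
#' @param cell_ids character vector aligned to the predictions.
#' @param path output file.
#' @param class_names class dictionary (colnames for the probabilities).
#' @return the data.frame, invisibly.
#' @export
write_predictions <- function(pred, cell_ids, path, class_names = NULL) {
  probs <- pred$probabilities
  if (is.null(class_names))
    class_names <- if (!is.null(colnames(probs))) colnames(probs)
                   else paste0("class", seq_len(ncol(probs)))
  df <- data.frame(cell_id = cell_ids, predicted_type = pred$labels,
                   max_probability = probs[cbind(seq_len(nrow(probs)),
                                                 pred$labels_idx)])
  pm <- as.data.frame(probs)
  names(pm) <- paste0("prob_", class_names)
  df <- cbind(df, pm)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
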