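#' Save and load a fitted model
#'
#' Serializes the annotator, estimator, gene/class dictionaries and plan to
#' a single portable JSON archive. Architecture metadata travels with the
#' weights, so a reloaded model refuses query matrices on a mismatched gene
#' space (see [predict.scsemi_fit()]).
#'
#' @param fit an `scsemi_fit` from [fit_semisup()].
#' @param path output file (JSON).
#' @return `save_model()` the path, invisibly; `load_model()` the restored
#'   `scsemi_fit`.
#' @export
save_model <- function(fit, path) {
  stopifnot(inherits(fit, "scsemi_fit"))
  ser_net <- function(n) lapply(n$layers, function(ly)
    list(W = ly$W, b = ly$b))
  obj <- list(format = "scSemiLab-checkpoint-1",
              gene_ids = fit$gene_ids, class_names = fit$class_names,
              hidden_dims = fit$net$hidden_dims,
              est_hidden = fit$est$hidden_dims,
              est_use_probs = fit$est$use_probs,
              plan = unclass(fit$plan),
              net = ser_net(fit$net), est = ser_net(fit$est))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE)
  if (!identical(obj$format, "scSemiLab-checkpoint-1"))
    stop("not a scSemiLab checkpoint: ", path)
  C <- length(obj$class_names)
  net <- annotator_network(length(obj$gene_ids), C, obj$hidden_dims)
  for (l in 1:4) {
    net$layers[[l]]$W <- as.matrix(obj$net[[l]]$W)
    net$layers[[l]]$b <- as.numeric(obj$net[[l]]$b)
  }
  est <- confidence_estimator(obj$hidden_dims[2], C, obj$est_hidden,
                              use_probs = obj$est_use_probs)
  for (l in 1:2) {
    est$layers[[l]]$W <- as.matrix(obj$est[[l]]$W)
    est$layers[[l]]$b <- as.numeric(obj$est[[l]]$b)
  }
  plan <- do.call(training_plan, obj$plan[setdiff(names(obj$plan), NULL)])
  structure(list(net = net, est = est, gene_ids = obj$gene_ids,
                 class_names = obj$class_names, plan = plan,
                 aug_cfg = augmentation_config(),
                 c_cfg = contrastive_config(), log = NULL),
            class = "scsemi_fit")
}
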