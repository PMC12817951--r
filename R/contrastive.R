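#' Contrastive pretraining configuration
#'
#' @param temperature softmax temperature tau scaling the cosine
#'   similarities. Default 0.5.
#' @param batch_size cells per contrastive batch (N pairs -> 2N views).
#'   Default 128.
#' @param epochs pretraining epochs. Default 100.
#' @param learning_rate Adam learning rate. Default 5e-4.
#' @param embed_layer which annotator layer supplies the contrasted
#'   embedding z (2 = second hidden layer, default; 4 = output logits).
#' @return a `ContrastiveConfig` list.
#' @export
contrastive_config <- function(temperature = 0.5, batch_size = 128L,
                               epochs = 100L, learning_rate = 5e-4,
                               embed_layer = 2L) {
  stopifnot(temperature > 0, batch_size >= 2, epochs >= 0,
            learning_rate > 0, embed_layer %in% 1:4)
  structure(list(temperature = temperature,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 embed_layer = as.integer(embed_layer)),
            class = "ContrastiveConfig")
}

l2_normalize_rows <- function(z) {
  nrm <- sqrt(rowSums(z^2))
  if (any(nrm < 1e-12))
    stop("zero-norm embedding row: cosine similarity undefined")
  z / nrm
}

# Shared NT-Xent machinery. Views are stacked (weak first, strong second);
# row i's positive partner is row p(i). Returns loss and, if wanted, the
# gradient w.r.t. the raw (unnormalized) stacked embeddings. `dead_ok`
# (training path only) maps zero-norm rows to the zero vector with zero
# gradient instead of erroring: all-dead ReLU embeddings arise transiently
# during optimization and must not abort an epoch.
nt_xent_core <- function(z_weak, z_strong, tau, want_grad = FALSE,
                         dead_ok = FALSE) {
  z_weak <- as.matrix(z_weak); z_strong <- as.matrix(z_strong)
  if (!identical(dim(z_weak), dim(z_strong)))
    stop("view embeddings must have matching dimensions")
  n <- nrow(z_weak)
  Z <- rbind(z_weak, z_strong)
  nrm <- sqrt(rowSums(Z^2))
  dead <- nrm < 1e-12
  if (any(dead) && !dead_ok)
    stop("zero-norm embedding row: cosine similarity undefined")
  nrm[dead] <- 1
  U <- Z / nrm
  n2 <- 2L * n
  partner <- c(seq_len(n) + n, seq_len(n))
  S <- tcrossprod(U) / tau
  diag(S) <- -Inf                       # indicator 1(k != i)
  mx <- apply(S, 1, max)
  lse <- mx + log(rowSums(exp(S - mx)))
  loss <- mean(lse - S[cbind(seq_len(n2), partner)])
  if (!want_grad) return(list(loss = loss))
  W <- exp(S - lse)                     # row-softmax over negatives+positive
  gU <- ((W + t(W)) %*% U - 2 * U[partner, , drop = FALSE]) / (n2 * tau)
  # through row normalization u = z / ||z||
  gZ <- (gU - U * rowSums(U * gU)) / nrm
  gZ[dead, ] <- 0
  list(loss = loss, grad_weak = gZ[seq_len(n), , drop = FALSE],
       grad_strong = gZ[seq_len(n) + n, , drop = FALSE])
}

#' NT-Xent contrastive loss
#'
#' The normalized temperature-scaled cross-entropy loss over a batch of N
#' augmentation pairs (2N views). For each of the 2N anchors, the positive
#' is its augmentation partner and the remaining 2N - 2 views plus the
#' partner form the softmax denominator; similarity is cosine (embeddings
#' are L2-normalized internally). The loss is averaged over all 2N anchors
#' and is symmetric in the two views.
#'
#' @param z_weak,z_strong N x d embedding matrices of the weak and strong
#'   views, row i of each being the same cell.
#' @param temperature positive temperature tau.
#' @return scalar loss.
#' @export
nt_xent_loss <- function(z_weak, z_strong, temperature = 0.5) {
  stopifnot(temperature > 0)
  nt_xent_core(z_weak, z_strong, temperature)$loss
}

#' Stage 1: contrastive pretraining on unlabeled cells
#'
#' Trains the annotator by minimizing the NT-Xent loss between weakly and
#' strongly augmented views of randomly sampled unlabeled batches. The
#' contrasted embedding is the layer chosen in `c_cfg$embed_layer`
#' (second hidden layer by default). Batches of size < 2 at the tail of an
#' epoch are dropped (the loss needs at least one negative).
#'
#' @param net an [annotator_network()].
#' @param unlabeled an [unlabeled_set()] (or a bare matrix).
#' @param aug_cfg an [augmentation_config()].
#' @param c_cfg a [contrastive_config()].
#' @param seed integer seed (shuffling, augmentation).
#' @param log optional [training_log()] collector.
#' @return the pretrained `annotator_network`.
#' @export
pretrain_contrastive <- function(net, unlabeled,
                                 aug_cfg = augmentation_config(),
                                 c_cfg = contrastive_config(), seed = 1L,
                                 log = NULL) {
  x <- if (inherits(unlabeled, "UnlabeledSet")) unlabeled$matrix else unlabeled
  x <- as.matrix(x)
  nt <- nrow(x)
  if (nt < 1) stop("unlabeled set is empty")
  bs <- c_cfg$batch_size
  if (bs > nt) {
    warning("batch_size > number of unlabeled cells; reduced to ", nt)
    bs <- nt
  }
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(restore_rng(old))
  state <- adam_init(net)
  for (epoch in seq_len(c_cfg$epochs)) {
    ord <- sample.int(nt)
    losses <- c()
    for (start in seq(1, nt, by = bs)) {
      idx <- ord[start:min(start + bs - 1, nt)]
      if (length(idx) < 2) next
      xb <- x[idx, , drop = FALSE]
      xw <- weak_augment(xb, aug_cfg)
      xs <- strong_augment(xb, aug_cfg)
      L <- c_cfg$embed_layer
      aw <- net_forward_acts(net, xw)
      as_ <- net_forward_acts(net, xs)
      res <- nt_xent_core(aw$A[[L]], as_$A[[L]], c_cfg$temperature,
                          want_grad = TRUE, dead_ok = TRUE)
      gw <- net_backprop(net, aw, res$grad_weak, L)
      gs <- net_backprop(net, as_, res$grad_strong, L)
      grads <- add_grads(gw, gs)
      upd <- adam_step(net, grads, state, c_cfg$learning_rate)
      net <- upd$net; state <- upd$state
      losses <- c(losses, res$loss)
    }
    log_event(log, stage = 1L, epoch = epoch, loss_c = mean(losses))
  }
  net
}

add_grads <- function(a, b) {
  for (l in seq_along(a)) {
    a[[l]]$W <- a[[l]]$W + b[[l]]$W
    a[[l]]$b <- a[[l]]$b + b[[l]]$b
  }
  a
}

scale_grads <- function(a, s) {
  for (l in seq_along(a)) {
    a[[l]]$W <- a[[l]]$W * s
    a[[l]]$b <- a[[l]]$b * s
  }
  a
}
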