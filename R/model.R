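#' The annotation network
#'
#' A four-layer multi-layer perceptron (three ReLU hidden layers + linear
#' output, softmax applied by [net_forward()]): the compact architecture that
#' classic neural cell-type classifiers use for scRNA-seq. The
#' post-activation output of the second hidden layer serves as the embedding
#' used for contrastive pretraining and for pseudo-label clustering.
#'
#' @param input_dim number of genes D.
#' @param n_classes number of cell types C.
#' @param hidden_dims three hidden layer widths. Default `c(100, 50, 25)`.
#' @param seed integer seed for weight initialization (fan-in scaled
#'   uniform).
#' @return an object of class `annotator_network`.
#' @export
annotator_network <- function(input_dim, n_classes,
                              hidden_dims = c(100L, 50L, 25L), seed = 1L) {
  stopifnot(length(hidden_dims) == 3, all(hidden_dims >= 1),
            input_dim >= 1, n_classes >= 2)
  dims <- c(input_dim, as.integer(hidden_dims), n_classes)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  layers <- vector("list", 4L)
  for (l in 1:4) {
    fan_in <- dims[l]
    lim <- 1 / sqrt(fan_in)
    layers[[l]] <- list(
      W = matrix(stats::runif(fan_in * dims[l + 1], -lim, lim),
                 fan_in, dims[l + 1]),
      b = numeric(dims[l + 1]))
  }
  restore_rng(old)
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 n_classes = as.integer(n_classes),
                 layers = layers, activation = "relu", frozen = FALSE),
            class = "annotator_network")
}

#' @export
print.annotator_network <- function(x, ...) {
  cat(sprintf("annotator_network: %d -> %s -> %d (%s)%s\n",
              x$input_dim, paste(x$hidden_dims, collapse = "-"),
              x$n_classes, x$activation, if (x$frozen) " [frozen]" else ""))
  invisible(x)
}

relu <- function(x) (x > 0) * x

# Numerically stable row-wise softmax.
softmax <- function(logits) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  e / rowSums(e)
}

# Full forward pass keeping intermediate activations for backprop.
# Returns Z (pre-activation) and A (post-activation) per layer; A[[4]] are
# the raw logits (identity output layer).
net_forward_acts <- function(net, x) {
  x <- as.matrix(x)
  if (ncol(x) != net$input_dim)
    stop("input has ", ncol(x), " features; network expects ", net$input_dim)
  Z <- A <- vector("list", 4L)
  a <- x
  for (l in 1:4) {
    Z[[l]] <- sweep(a %*% net$layers[[l]]$W, 2, net$layers[[l]]$b, "+")
    A[[l]] <- if (l < 4) relu(Z[[l]]) else Z[[l]]
    a <- A[[l]]
  }
  list(input = x, Z = Z, A = A)
}

#' Forward pass of the annotator
#'
#' @param net an [annotator_network()].
#' @param x numeric matrix of cells x genes with `ncol(x) == input_dim`.
#' @return list with `logits` (N x C) and `probs` (row-wise softmax of the
#'   logits; rows sum to 1).
#' @export
net_forward <- function(net, x) {
  acts <- net_forward_acts(net, x)
  logits <- acts$A[[4]]
  list(logits = logits, probs = softmax(logits))
}

#' Embedding of a batch of cells
#'
#' Returns the post-activation output of the second hidden layer, the
#' representation clustered for pseudo-labels and contrasted during
#' pretraining.
#'
#' @inheritParams net_forward
#' @param layer which layer's post-activation output to return (1..3 hidden,
#'   4 = logits). Default 2.
#' @return numeric matrix N x `hidden_dims[layer]`.
#' @export
net_embed <- function(net, x, layer = 2L) {
  stopifnot(layer >= 1, layer <= 4)
  acts <- net_forward_acts(net, x)
  acts$A[[layer]]
}

# Backpropagate dL/dA[[L]] through layers L..1. Returns a grads list shaped
# like net$layers (layers > L get zero gradients).
net_backprop <- function(net, acts, dA, L = 4L) {
  grads <- lapply(net$layers, function(ly)
    list(W = ly$W * 0, b = ly$b * 0))
  for (l in seq(L, 1)) {
    dZ <- if (l < 4) dA * (acts$Z[[l]] > 0) else dA
    a_prev <- if (l == 1) acts$input else acts$A[[l - 1]]
    grads[[l]]$W <- crossprod(a_prev, dZ)
    grads[[l]]$b <- colSums(dZ)
    if (l > 1) dA <- tcrossprod(dZ, net$layers[[l]]$W)
  }
  grads
}

#' Pseudo-label confidence estimator
#'
#' A small auxiliary network that scores each cell's pseudo-label with a
#' weight in `[0, 1]`. It consumes the concatenation of the cell's
#' second-layer embedding and the annotator's output (softmax probabilities
#' by default, raw logits optionally), passes it through one ReLU hidden
#' layer, and squashes a scalar through a sigmoid.
#'
#' @param embed_dim dimension of the annotator embedding (its
#'   `hidden_dims[2]`).
#' @param n_classes number of classes C.
#' @param hidden_dims width(s) of the hidden layer. Default 64.
#' @param use_probs feed softmax probabilities (TRUE, default) or raw logits.
#' @param seed seed for weight initialization.
#' @return an object of class `confidence_estimator`.
#' @export
confidence_estimator <- function(embed_dim, n_classes, hidden_dims = 64L,
                                 use_probs = TRUE, seed = 1L) {
  stopifnot(embed_dim >= 1, n_classes >= 2, length(hidden_dims) == 1,
            hidden_dims >= 1)
  d_in <- embed_dim + n_classes
  h <- as.integer(hidden_dims)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  lim1 <- 1 / sqrt(d_in); lim2 <- 1 / sqrt(h)
  est <- structure(list(
    embed_dim = as.integer(embed_dim), n_classes = as.integer(n_classes),
    hidden_dims = h, use_probs = isTRUE(use_probs), frozen = FALSE,
    layers = list(
      list(W = matrix(stats::runif(d_in * h, -lim1, lim1), d_in, h),
           b = numeric(h)),
      list(W = matrix(stats::runif(h, -lim2, lim2), h, 1),
           b = numeric(1)))),
    class = "confidence_estimator")
  restore_rng(old)
  est
}

sigmoid <- function(x) 1 / (1 + exp(-x))

est_forward_acts <- function(est, embedding, logits) {
  embedding <- as.matrix(embedding); logits <- as.matrix(logits)
  if (nrow(embedding) != nrow(logits))
    stop("embedding and logits row counts differ")
  if (ncol(embedding) != est$embed_dim || ncol(logits) != est$n_classes)
    stop("confidence estimator dimension mismatch")
  feat <- if (est$use_probs) softmax(logits) else logits
  x <- cbind(embedding, feat)
  z1 <- sweep(x %*% est$layers[[1]]$W, 2, est$layers[[1]]$b, "+")
  a1 <- relu(z1)
  z2 <- drop(a1 %*% est$layers[[2]]$W) + est$layers[[2]]$b
  list(input = x, z1 = z1, a1 = a1, z2 = z2, conf = sigmoid(z2))
}

#' Estimate pseudo-label confidence
#'
#' @param est a [confidence_estimator()].
#' @param embedding N x embed_dim matrix, the annotator's second-layer output
#'   ([net_embed()]).
#' @param logits N x C matrix, the annotator's output logits.
#' @return numeric vector of per-cell confidences in `[0, 1]`.
#' @export
estimate_confidence <- function(est, embedding, logits) {
  est_forward_acts(est, embedding, logits)$conf
}

# Gradient of mean(weight * clip(conf)) w.r.t. estimator parameters, where
# `weight` is the (fixed) per-cell consistency cross-entropy and conf is
# clipped below at `floor` (gradient masked there to prevent collapse).
est_backprop <- function(est, acts, weight, floor = 0.01) {
  n <- length(acts$conf)
  dconf <- weight / n
  dconf[acts$conf < floor] <- 0
  dz2 <- dconf * acts$conf * (1 - acts$conf)
  g2 <- list(W = crossprod(acts$a1, matrix(dz2, ncol = 1)), b = sum(dz2))
  da1 <- matrix(dz2, ncol = 1) %*% t(est$layers[[2]]$W)
  dz1 <- da1 * (acts$z1 > 0)
  g1 <- list(W = crossprod(acts$input, dz1), b = colSums(dz1))
  list(g1, g2)
}

#' Freeze or unfreeze a network's parameters
#'
#' A frozen network is skipped by the optimizer: [adam_step()] returns its
#' parameters bit-identical. Used to alternate annotator and estimator
#' updates.
#'
#' @param net an [annotator_network()] or [confidence_estimator()].
#' @return the network with its `frozen` flag set/cleared.
#' @export
freeze <- function(net) { net$frozen <- TRUE; net }

#' @rdname freeze
#' @export
unfreeze <- function(net) { net$frozen <- FALSE; net }

#' Adam optimizer state
#'
#' Standard Adam (moment estimates with bias correction) over the list of
#' layer parameter matrices of either network.
#'
#' @param net network whose parameter shapes seed the moment buffers.
#' @param beta1,beta2,eps Adam constants. Defaults 0.9, 0.999, 1e-8.
#' @return an `adam_state` list.
#' @export
adam_init <- function(net, beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  zeros <- lapply(net$layers, function(ly)
    list(W = ly$W * 0, b = ly$b * 0))
  structure(list(t = 0L, m = zeros, v = zeros,
                 beta1 = beta1, beta2 = beta2, eps = eps),
            class = "adam_state")
}

#' @rdname adam_init
#' @param grads gradient list shaped like `net$layers`.
#' @param state an `adam_state` from `adam_init()`.
#' @param lr learning rate.
#' @return `adam_step()` returns `list(net, state)` after one update (or the
#'   inputs unchanged when the network is frozen).
#' @export
adam_step <- function(net, grads, state, lr) {
  if (isTRUE(net$frozen)) return(list(net = net, state = state))
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  c1 <- 1 - b1^state$t; c2 <- 1 - b2^state$t
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- b1 * state$m[[l]][[p]] + (1 - b1) * g
      state$v[[l]][[p]] <- b2 * state$v[[l]][[p]] + (1 - b2) * g^2
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] -
        lr * (state$m[[l]][[p]] / c1) /
          (sqrt(state$v[[l]][[p]] / c2) + state$eps)
    }
  }
  list(net = net, state = state)
}

# Flatten all parameters to one numeric vector (snapshot diffs in tests).
net_params <- function(net) {
  unlist(lapply(net$layers, function(ly) c(as.numeric(ly$W), ly$b)))
}
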