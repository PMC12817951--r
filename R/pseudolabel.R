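#' Cosine distance
#'
#' `dist(a, b) = (1 - cos(a, b)) / 2`, mapping parallel vectors to 0,
#' orthogonal ones to 0.5 and antipodal ones to 1.
#'
#' @param a,b nonzero numeric vectors of equal length.
#' @return scalar in `[0, 1]`.
#' @export
cosine_distance <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na < 1e-12 || nb < 1e-12)
    stop("cosine distance undefined for zero vectors")
  d <- 0.5 * (1 - sum(a * b) / (na * nb))
  min(max(d, 0), 1)
}

#' Class centers from labeled embeddings
#'
#' For each class c, sums the L2-normalized second-layer embeddings of its
#' labeled cells and renormalizes the sum to unit length. These centers seed
#' the spherical K-means clustering of the unlabeled cells, which is what
#' lets cluster index c be read directly as class label c.
#'
#' @param net an [annotator_network()].
#' @param labeled a [labeled_set()].
#' @param layer embedding layer (default 2).
#' @return a `ClusterCenters` object: C x d matrix of unit-norm rows plus a
#'   `class_names` attribute.
#' @export
init_centers_from_labeled <- function(net, labeled, layer = 2L) {
  stopifnot(inherits(labeled, "LabeledSet"))
  emb <- net_embed(net, labeled$matrix, layer)
  nrm <- sqrt(rowSums(emb^2))
  dead <- nrm < 1e-12
  if (any(dead))
    warning(sum(dead), " labeled cell(s) with zero-norm (all-dead ReLU) ",
            "embedding excluded from center initialization")
  nrm[dead] <- 1
  U <- emb / nrm
  C <- length(labeled$class_names)
  centers <- matrix(0, C, ncol(U))
  for (c in seq_len(C)) {
    rows <- which(labeled$labels == c & !dead)
    if (!length(rows)) stop("class without labeled cells (with usable ",
                            "embeddings): ", labeled$class_names[c])
    s <- colSums(U[rows, , drop = FALSE])
    ns <- sqrt(sum(s^2))
    if (ns < 1e-8)
      stop("degenerate (antipodal) embedding sum for class ",
           labeled$class_names[c])
    centers[c, ] <- s / ns
  }
  structure(centers, class_names = labeled$class_names,
            class = c("ClusterCenters", "matrix", "array"))
}

#' Spherical K-means with fixed class-seeded centers
#'
#' Alternates (i) assignment of every embedding to the center with smallest
#' [cosine_distance()] (ties to the lowest class index) and (ii) center
#' update to the renormalized sum of the normalized member embeddings, until
#' assignments stop changing, the maximum center movement falls below `tol`,
#' or `max_iter` is reached. Empty clusters keep their previous center so
#' the cluster-to-class mapping never degenerates. Zero-norm embedding rows
#' (all-dead ReLU cells) fall back to Euclidean nearest center with a
#' warning.
#'
#' @param embeddings Nt x d numeric matrix.
#' @param init a C x d matrix of unit-norm initial centers
#'   ([init_centers_from_labeled()]).
#' @param max_iter maximum iterations. Default 100.
#' @param tol center-movement convergence tolerance (max over centers of
#'   `1 - <old, new>`). Default 1e-6.
#' @return a `PseudoLabelState` list: `assignments` (integer in 1..C),
#'   `centers`, `n_iterations`, `converged`, and the per-iteration
#'   `objective` trace (mean cosine distance to the assigned center).
#' @export
spherical_kmeans <- function(embeddings, init, max_iter = 100L, tol = 1e-6) {
  embeddings <- as.matrix(embeddings)
  init <- as.matrix(init)
  if (ncol(embeddings) != ncol(init))
    stop("embedding dimension (", ncol(embeddings),
         ") != center dimension (", ncol(init), ")")
  C <- nrow(init)
  if (C < 2) stop("need at least 2 centers")
  nrm <- sqrt(rowSums(embeddings^2))
  dead <- nrm < 1e-12
  if (any(dead))
    warning(sum(dead), " zero-norm embedding row(s): assigned by Euclidean ",
            "fallback")
  U <- embeddings
  U[!dead, ] <- embeddings[!dead, , drop = FALSE] / nrm[!dead]
  centers <- init / sqrt(rowSums(init^2))
  assign_pass <- function(centers) {
    D <- 0.5 * (1 - tcrossprod(U, centers))       # cosine distance, unit rows
    if (any(dead)) {
      for (i in which(dead))
        D[i, ] <- rowSums(sweep(centers, 2, embeddings[i, ])^2)
    }
    list(a = max.col(-D, ties.method = "first"),
         obj = mean(D[cbind(seq_len(nrow(D)), max.col(-D, "first"))]))
  }
  assignments <- rep(0L, nrow(U))
  converged <- FALSE
  objective <- numeric(0)
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ap <- assign_pass(centers)
    objective <- c(objective, ap$obj)
    if (identical(ap$a, assignments)) { converged <- TRUE; break }
    assignments <- ap$a
    movement <- 0
    for (c in seq_len(C)) {
      rows <- which(assignments == c & !dead)
      if (!length(rows)) next                     # empty: keep old center
      s <- colSums(U[rows, , drop = FALSE])
      ns <- sqrt(sum(s^2))
      if (ns < 1e-12) next
      newc <- s / ns
      movement <- max(movement, 1 - sum(newc * centers[c, ]))
      centers[c, ] <- newc
    }
    if (movement < tol) { converged <- TRUE; break }
  }
  structure(list(assignments = assignments,
                 centers = structure(centers,
                                     class_names = attr(init, "class_names"),
                                     class = c("ClusterCenters", "matrix",
                                               "array")),
                 n_iterations = it, converged = converged,
                 objective = objective),
            class = "PseudoLabelState")
}

#' Pseudo-label the unlabeled cells
#'
#' Composes [net_embed()] on the unlabeled cells,
#' [init_centers_from_labeled()] on the labeled ones, and
#' [spherical_kmeans()]. Because every initial center is a class centroid,
#' the index of the cluster a cell lands in is its pseudo-label.
#'
#' @param net an [annotator_network()].
#' @param labeled a [labeled_set()].
#' @param unlabeled an [unlabeled_set()] sharing the labeled gene space.
#' @param max_iter,tol passed to [spherical_kmeans()].
#' @param layer embedding layer (default 2).
#' @return a `PseudoLabelState` (see [spherical_kmeans()]).
#' @export
assign_pseudo_labels <- function(net, labeled, unlabeled, max_iter = 100L,
                                 tol = 1e-6, layer = 2L) {
  stopifnot(inherits(unlabeled, "UnlabeledSet"))
  check_same_genes(labeled, unlabeled)
  centers <- init_centers_from_labeled(net, labeled, layer)
  emb <- net_embed(net, unlabeled$matrix, layer)
  spherical_kmeans(emb, centers, max_iter = max_iter, tol = tol)
}

#' @export
print.PseudoLabelState <- function(x, ...) {
  cat(sprintf("PseudoLabelState: %d cells -> %d clusters, %d iteration(s)%s\n",
              length(x$assignments), nrow(x$centers), x$n_iterations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}

#' Export a pseudo-label table
#'
#' Writes `cell_id`, `pseudo_label` and (optionally) `confidence` as TSV,
#' with the iteration count in a `#`-comment header line.
#'
#' @param state a `PseudoLabelState`.
#' @param cell_ids character vector aligned to the assignments.
#' @param path output file.
#' @param confidence optional numeric vector of per-cell confidences.
#' @param class_names class dictionary (defaults to the one carried by the
#'   centers).
#' @return the written data.frame, invisibly.
#' @export
write_pseudo_labels <- function(state, cell_ids, path, confidence = NULL,
                                class_names = NULL) {
  if (is.null(class_names)) class_names <- attr(state$centers, "class_names")
  if (is.null(class_names))
    class_names <- paste0("class", seq_len(nrow(state$centers)))
  df <- data.frame(cell_id = cell_ids,
                   pseudo_label = class_names[state$assignments])
  if (!is.null(confidence)) df$confidence <- confidence
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# spherical k-means iterations: %d (converged: %s)",
                     state$n_iterations, state$converged), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
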