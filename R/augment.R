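#' Augmentation configuration
#'
#' Parameters shared by the weak (additive Gaussian noise) and strong
#' (random masking) views. With probability `apply_prob` a cell is perturbed
#' at all; within a perturbed cell a uniformly random subset of
#' `floor(feature_fraction * D)` gene positions is touched. The weak view
#' adds `N(noise_mean, noise_sd^2)` noise at those positions, the strong
#' view zeroes them out.
#'
#' @param apply_prob probability that a given cell is perturbed. Default 0.8.
#' @param feature_fraction fraction of gene positions perturbed within a
#'   selected cell. Default 0.5.
#' @param noise_mean,noise_sd Gaussian noise parameters for the weak view.
#'   Defaults 0 and 0.5.
#' @param gate `"cell"` (default): one Bernoulli(`apply_prob`) gate per cell
#'   plus a fixed-size random subset; `"entry"`: each entry independently
#'   perturbed with probability `apply_prob * feature_fraction`.
#' @return an `AugmentationConfig` list.
#' @export
augmentation_config <- function(apply_prob = 0.8, feature_fraction = 0.5,
                                noise_mean = 0, noise_sd = 0.5,
                                gate = c("cell", "entry")) {
  gate <- match.arg(gate)
  stopifnot(apply_prob >= 0, apply_prob <= 1,
            feature_fraction > 0, feature_fraction <= 1, noise_sd > 0)
  structure(list(apply_prob = apply_prob, feature_fraction = feature_fraction,
                 noise_mean = noise_mean, noise_sd = noise_sd, gate = gate),
            class = "AugmentationConfig")
}

# Draw the perturbation mask common to both views: logical N x D matrix.
augment_mask <- function(n, d, cfg) {
  mask <- matrix(FALSE, n, d)
  if (cfg$gate == "entry") {
    mask[] <- stats::runif(n * d) < cfg$apply_prob * cfg$feature_fraction
    return(mask)
  }
  k <- floor(cfg$feature_fraction * d)
  if (k == 0) return(mask)
  gated <- stats::runif(n) < cfg$apply_prob
  for (i in which(gated)) mask[i, sample.int(d, k)] <- TRUE
  mask
}

#' Weak and strong augmentation of a batch of cells
#'
#' `weak_augment()` adds Gaussian noise to a random subset of gene positions
#' of randomly gated cells; `strong_augment()` zeroes the same kind of
#' subset (random masking / simulated dropout). Entries outside the selected
#' subset are returned bit-identical.
#'
#' @param batch numeric matrix, cells in rows (an [ExpressionMatrix] works).
#' @param cfg an [augmentation_config()].
#' @param stream optional [rng_stream()] making augmentation randomness
#'   reproducible independently of the session RNG.
#' @return a plain numeric matrix of the same shape.
#' @export
weak_augment <- function(batch, cfg = augmentation_config(), stream = NULL) {
  batch <- as.matrix(batch)
  stopifnot(all(is.finite(batch)))
  draw <- function() {
    mask <- augment_mask(nrow(batch), ncol(batch), cfg)
    nsel <- sum(mask)
    if (nsel)
      batch[mask] <- batch[mask] +
        stats::rnorm(nsel, cfg$noise_mean, cfg$noise_sd)
    batch
  }
  if (is.null(stream)) draw() else with_stream(stream, draw())
}

#' @rdname weak_augment
#' @export
strong_augment <- function(batch, cfg = augmentation_config(), stream = NULL) {
  batch <- as.matrix(batch)
  stopifnot(all(is.finite(batch)))
  draw <- function() {
    mask <- augment_mask(nrow(batch), ncol(batch), cfg)
    batch[mask] <- 0
    batch
  }
  if (is.null(stream)) draw() else with_stream(stream, draw())
}
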