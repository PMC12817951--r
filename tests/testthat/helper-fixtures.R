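# Small in-code fixtures shared across test files.

# Deterministic toy ExpressionMatrix with given dims.
toy_matrix <- function(n = 4, g = 5, seed = 1, max_count = 9) {
  set.seed(seed)
  ExpressionMatrix(matrix(sample(0:max_count, n * g, replace = TRUE), n, g),
                   cell_ids = paste0("c", seq_len(n)),
                   gene_ids = paste0("g", seq_len(g)))
}

# A small linearly separable 2-class dataset in `g` dims: class means at
# +mu/-mu on the first coordinate plus noise.
separable_data <- function(n_per_class = 40, g = 10, mu = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * g), n, g)
  y <- rep(1:2, each = n_per_class)
  x[, 1] <- x[, 1] + ifelse(y == 1, mu, -mu)
  m <- ExpressionMatrix(x, cell_ids = paste0("c", 1:n),
                        gene_ids = paste0("g", 1:g))
  list(m = m, y = y)
}

# Tiny labeled/unlabeled pair from separable data.
tiny_problem <- function(n_per_class = 40, g = 10, p = 0.2, seed = 1) {
  d <- separable_data(n_per_class, g, seed = seed)
  sp <- split_by_label_fraction(d$m, d$y, p, seed = seed,
                                class_names = c("A", "B"))
  sp
}

# A network with every weight and bias set to a constant.
constant_net <- function(input_dim, n_classes, hidden = c(4L, 3L, 2L),
                         value = 0) {
  net <- annotator_network(input_dim, n_classes, hidden, seed = 1)
  for (l in seq_along(net$layers)) {
    net$layers[[l]]$W[] <- value
    net$layers[[l]]$b[] <- value
  }
  net
}

# Points drawn tightly around C unit directions (von-Mises-Fischer-like):
# direction +- small tangent noise, then renormalized.
spherical_clusters <- function(n_per, dirs, kappa_sd = 0.05, seed = 1) {
  set.seed(seed)
  C <- nrow(dirs)
  d <- ncol(dirs)
  x <- do.call(rbind, lapply(seq_len(C), function(c) {
    pts <- matrix(rep(dirs[c, ], n_per), n_per, d, byrow = TRUE) +
      matrix(rnorm(n_per * d, 0, kappa_sd), n_per, d)
    pts / sqrt(rowSums(pts^2))
  }))
  list(x = x, y = rep(seq_len(C), each = n_per))
}

# Brute-force NT-Xent: explicit double loop over the 2N anchors.
brute_nt_xent <- function(zw, zs, tau) {
  Z <- rbind(zw, zs)
  n <- nrow(zw)
  U <- Z / sqrt(rowSums(Z^2))
  partner <- c(seq_len(n) + n, seq_len(n))
  total <- 0
  for (i in seq_len(2 * n)) {
    denom <- 0
    for (k in seq_len(2 * n)) {
      if (k != i) denom <- denom + exp(sum(U[i, ] * U[k, ]) / tau)
    }
    total <- total - log(exp(sum(U[i, ] * U[partner[i], ]) / tau) / denom)
  }
  total / (2 * n)
}

# Classed subsetting shorthand (keeps ExpressionMatrix class + ids).
em_subset_pub <- function(m, i = NULL, j = NULL) scSemiLab:::em_subset(m, i, j)
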