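test_that("cosine distance hits its landmark values and rejects zero vectors", {
  a <- c(1, 2, -1)
  expect_equal(cosine_distance(a, a), 0)
  expect_equal(cosine_distance(a, -a), 1)
  expect_equal(cosine_distance(c(1, 0), c(0, 3)), 0.5)
  expect_equal(cosine_distance(a, 7 * a), 0)          # scale invariance
  expect_error(cosine_distance(a, c(0, 0, 0)), "zero")
})

test_that("class centers are normalize-sum-renormalize of member embeddings", {
  net <- annotator_network(6, 3, c(10L, 8L, 3L), seed = 8)
  set.seed(7)
  x <- matrix(rnorm(36), 6, 6)
  m <- ExpressionMatrix(x, paste0("c", 1:6), paste0("g", 1:6))
  lab <- labeled_set(m, c(1, 1, 2, 2, 3, 3), paste0("t", 1:3))
  centers <- suppressWarnings(init_centers_from_labeled(net, lab))
  emb <- net_embed(net, m)
  nrm <- sqrt(rowSums(emb^2))
  live <- nrm >= 1e-12            # all-dead ReLU cells are excluded
  U <- emb / pmax(nrm, 1e-12)
  for (c in 1:3) {
    s <- colSums(U[lab$labels == c & live, , drop = FALSE])
    expect_equal(unname(centers[c, ]), unname(s / sqrt(sum(s^2))),
                 tolerance = 1e-6)
  }
  expect_equal(sqrt(rowSums(centers^2)), rep(1, 3), tolerance = 1e-6)
  # one cell per class -> its own normalized embedding
  lab1 <- labeled_set(em_subset_pub(m, 1:3), c(1, 2, 3), paste0("t", 1:3))
  c1 <- init_centers_from_labeled(net, lab1)
  expect_equal(unname(c1[2, ]), unname(U[2, ]), tolerance = 1e-6)
  # duplicating a cell leaves its class center unchanged
  m2 <- ExpressionMatrix(x[c(1, 1, 3, 5), ], paste0("c", 1:4), paste0("g", 1:6))
  lab2 <- labeled_set(m2, c(1, 1, 2, 3), paste0("t", 1:3))
  c2 <- init_centers_from_labeled(net, lab2)
  expect_equal(unname(c2[1, ]), unname(U[1, ]), tolerance = 1e-6)
})

test_that("k-means converges instantly at a fixed point with identity assignment", {
  dirs <- diag(3)
  st <- spherical_kmeans(dirs, dirs)
  expect_identical(st$assignments, 1:3)
  expect_identical(st$n_iterations, 1L)
  expect_true(st$converged)
})

test_that("k-means recovers antipodal clusters and concentrated spherical clusters", {
  sc <- spherical_clusters(30, rbind(c(1, 0, 0), c(-1, 0, 0)), 0.1, seed = 2)
  st <- spherical_kmeans(sc$x, rbind(c(1, 0.05, 0), c(-1, -0.05, 0)))
  expect_identical(st$assignments, sc$y)
  # >= 0.99 agreement on 4 concentrated clusters with class-center init
  set.seed(3)
  dirs <- matrix(rnorm(4 * 16), 4, 16)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  sc4 <- spherical_clusters(100, dirs, 0.15, seed = 4)
  init <- do.call(rbind, lapply(1:4, function(c) {
    s <- colSums(sc4$x[sc4$y == c, ][1:5, ])   # centers from a few members
    s / sqrt(sum(s^2))
  }))
  st4 <- spherical_kmeans(sc4$x, init)
  expect_gte(mean(st4$assignments == sc4$y), 0.99)
})

test_that("centers stay unit-norm, the objective is non-increasing, and the final assignment is self-consistent", {
  set.seed(9)
  for (rep in 1:3) {
    x <- matrix(rnorm(80 * 8), 80, 8)
    init <- matrix(rnorm(3 * 8), 3, 8)
    init <- init / sqrt(rowSums(init^2))
    st <- spherical_kmeans(x, init, max_iter = 50)
    expect_equal(sqrt(rowSums(st$centers^2)), rep(1, 3), tolerance = 1e-6)
    expect_true(all(diff(st$objective) <= 1e-12))
    # brute-force one-pass reassignment against the final centers
    U <- x / sqrt(rowSums(x^2))
    D <- 0.5 * (1 - tcrossprod(U, unclass(st$centers)))
    expect_identical(st$assignments, max.col(-D, ties.method = "first"))
    expect_lte(st$n_iterations, 50L)
  }
})

test_that("k-means validates dimensions and keeps empty clusters' centers", {
  init <- diag(3)
  expect_error(spherical_kmeans(matrix(1, 4, 2), init), "dimension")
  # all points near center 1: centers 2,3 never win, must stay unchanged
  x <- matrix(rep(c(1, 0.01, 0.01), 10), 10, 3, byrow = TRUE)
  st <- spherical_kmeans(x, init)
  expect_equal(unname(unclass(st$centers)[2, ]), c(0, 1, 0))
  expect_equal(unname(unclass(st$centers)[3, ]), c(0, 0, 1))
  expect_true(all(st$assignments == 1L))
})

test_that("assign_pseudo_labels is row-permutation equivariant and handles Nt = 1", {
  pr <- tiny_problem(25, 8, p = 0.2, seed = 19)
  net <- annotator_network(8, 2, c(6L, 5L, 3L), seed = 19)
  st <- assign_pseudo_labels(net, pr$labeled, pr$unlabeled)
  p <- sample(nrow(pr$unlabeled$matrix))
  unl_p <- unlabeled_set(em_subset_pub(pr$unlabeled$matrix, p))
  st_p <- assign_pseudo_labels(net, pr$labeled, unl_p)
  expect_identical(st_p$assignments, st$assignments[p])
  one <- unlabeled_set(em_subset_pub(pr$unlabeled$matrix, 1))
  st1 <- assign_pseudo_labels(net, pr$labeled, one)
  centers <- init_centers_from_labeled(net, pr$labeled)
  e1 <- net_embed(net, one$matrix)
  d1 <- apply(centers, 1, function(ctr) cosine_distance(e1[1, ], ctr))
  expect_identical(st1$assignments, which.min(d1))
})

test_that("closed loop: pseudo-labels reproduce true labels on a trained toy model", {
  pr <- tiny_problem(40, 10, p = 0.5, seed = 23)
  plan <- training_plan(stage_epochs = c(0L, 60L, 0L), stage_lrs = c(5e-4, 1e-3, 5e-5),
                        batch_size = 32L, seed = 23,
                        ablation = c("no_pretrain", "no_consistency"),
                        hidden_dims = c(16L, 8L, 4L))
  fit <- fit_semisup(pr$labeled, pr$unlabeled, plan)
  st <- assign_pseudo_labels(fit$net, pr$labeled,
                             unlabeled_set(pr$labeled$matrix))
  expect_gte(mean(st$assignments == pr$labeled$labels), 0.95)
})

test_that("pseudo-label tables round-trip through the TSV writer", {
  st <- spherical_kmeans(diag(3), diag(3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_pseudo_labels(st, c("a", "b", "c"), f, confidence = c(.9, .5, .1),
                      class_names = c("T", "B", "NK"))
  lines <- readLines(f)
  expect_match(lines[1], "^# spherical k-means iterations")
  df <- read.delim(f, comment.char = "#")
  expect_identical(df$pseudo_label, c("T", "B", "NK"))
})
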