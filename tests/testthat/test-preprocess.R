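test_that("filter keeps everything when nothing crosses a threshold", {
  m <- ExpressionMatrix(matrix(1, 3, 5), paste0("c", 1:3), paste0("g", 1:5))
  cfg <- preprocess_config(min_genes_per_cell = 2, min_cells_per_gene = 2)
  expect_identical(unclass(filter_cells_and_genes(m, cfg)), unclass(m))
})

test_that("filter boundary: 'fewer than' removes a cell at threshold - 1", {
  v <- matrix(1, 4, 6)
  v[1, 4:6] <- 0                      # cell 1 expresses 3 genes
  m <- ExpressionMatrix(v, paste0("c", 1:4), paste0("g", 1:6))
  out <- filter_cells_and_genes(m, preprocess_config(4, 1))
  expect_identical(cell_ids(out), paste0("c", 2:4))
  out2 <- filter_cells_and_genes(m, preprocess_config(3, 1))
  expect_identical(cell_ids(out2), paste0("c", 1:4))
})

test_that("filter matches a one-pass brute-force scan on random binary matrices", {
  for (seed in 1:5) {
    set.seed(seed)
    v <- matrix(rbinom(36, 1, 0.5), 6, 6)
    m <- ExpressionMatrix(v, paste0("c", 1:6), paste0("g", 1:6))
    keep_cells <- vapply(1:6, function(i) sum(v[i, ] > 0) >= 3, logical(1))
    keep_genes <- vapply(1:6, function(j) sum(v[, j] > 0) >= 3, logical(1))
    if (!any(keep_cells) || !any(keep_genes)) {
      expect_error(filter_cells_and_genes(m, preprocess_config(3, 3)),
                   "removed")
    } else {
      out <- filter_cells_and_genes(m, preprocess_config(3, 3))
      expect_identical(cell_ids(out), paste0("c", which(keep_cells)))
      expect_identical(gene_ids(out), paste0("g", which(keep_genes)))
    }
  }
})

test_that("filter errors name the offending threshold when everything dies", {
  m <- ExpressionMatrix(diag(3), paste0("c", 1:3), paste0("g", 1:3))
  expect_error(filter_cells_and_genes(m, preprocess_config(2, 1)),
               "min_genes_per_cell")
  expect_error(filter_cells_and_genes(m, preprocess_config(1, 2)),
               "min_cells_per_gene")
})

test_that("normalize_and_log scales rows to the target and applies log1p", {
  m <- ExpressionMatrix(rbind(c(2, 2, 0), c(1, 3, 4)), c("a", "b"),
                        paste0("g", 1:3))
  cfg <- preprocess_config(normalize_target = 4, log_transform = FALSE)
  out <- normalize_and_log(m, cfg)
  expect_equal(unname(unclass(out)[1, ]), c(2, 2, 0))
  expect_equal(unname(unclass(out)[2, ]), c(0.5, 1.5, 2))
  m2 <- ExpressionMatrix(rbind(c(1, 3)), "a", c("g1", "g2"))
  out2 <- normalize_and_log(m2, preprocess_config(normalize_target = 8,
                                                  log_transform = FALSE))
  expect_equal(unname(unclass(out2)[1, ]), c(2, 6))
})

test_that("normalize_and_log matches the per-row closed form under log", {
  m <- toy_matrix(5, 4, seed = 7, max_count = 20)
  m <- ExpressionMatrix(unclass(m) + 1)   # avoid zero rows
  cfg <- preprocess_config(normalize_target = 100, log_transform = TRUE)
  out <- normalize_and_log(m, cfg)
  for (i in 1:5) {
    row <- unclass(m)[i, ]
    expect_equal(unname(unclass(out)[i, ]), unname(log1p(row * 100 / sum(row))),
                 tolerance = 1e-12)
  }
})

test_that("normalize_and_log rejects zero-total cells", {
  v <- matrix(1, 3, 3); v[2, ] <- 0
  m <- ExpressionMatrix(v, paste0("c", 1:3), paste0("g", 1:3))
  expect_error(normalize_and_log(m), "zero total")
})

test_that("select_hvg drops constant genes and matches a brute-force sd sort", {
  set.seed(11)
  v <- matrix(rnorm(60), 10, 6)
  v[, 3] <- 5                               # constant gene
  m <- ExpressionMatrix(v, paste0("c", 1:10), paste0("g", 1:6))
  out <- select_hvg(m, 5)
  expect_false("g3" %in% gene_ids(out))
  expect_identical(gene_ids(select_hvg(m, 6)), gene_ids(m))  # n_hvg == D
  expect_error(select_hvg(m, 7), "exceeds")
  # brute-force oracle on 20 genes
  set.seed(12)
  v2 <- matrix(rnorm(200), 10, 20)
  m2 <- ExpressionMatrix(v2, paste0("c", 1:10), paste0("g", 1:20))
  sds <- vapply(1:20, function(j) sd(v2[, j]), numeric(1))
  expected <- sort(order(sds, decreasing = TRUE)[1:5])
  expect_identical(gene_ids(select_hvg(m2, 5)), paste0("g", expected))
})

test_that("select_hvg breaks sd ties toward the earlier gene", {
  v <- cbind(c(0, 2), c(0, 2), c(0, 1))    # g1 and g2 tie, g3 smaller
  m <- ExpressionMatrix(v, c("c1", "c2"), c("g1", "g2", "g3"))
  expect_identical(gene_ids(select_hvg(m, 1)), "g1")
  expect_identical(gene_ids(select_hvg(m, 2)), c("g1", "g2"))
})

test_that("scale_unit_variance centers, scales (population sd) and guards degeneracy", {
  m <- ExpressionMatrix(cbind(c(1, 3), c(7, 7)), c("a", "b"), c("g1", "g2"))
  out <- scale_unit_variance(m)
  expect_equal(unname(unclass(out)[, 1]), c(-1, 1))
  expect_equal(unname(unclass(out)[, 2]), c(0, 0))  # constant -> zeros, no NaN
  m2 <- toy_matrix(10, 6, seed = 3)
  out2 <- unclass(scale_unit_variance(m2))
  expect_true(all(abs(colMeans(out2)) < 1e-8))
  sds0 <- sqrt(colSums(sweep(out2, 2, colMeans(out2))^2) / nrow(out2))
  expect_true(all(abs(sds0 - 1) < 1e-6))
  expect_true(all(is.finite(out2)))
})

test_that("preprocess_pipeline equals the stepwise composition in the fixed order", {
  m <- toy_matrix(30, 25, seed = 5, max_count = 30)
  cfg <- preprocess_config(min_genes_per_cell = 10, min_cells_per_gene = 2,
                           n_hvg = 15, normalize_target = 1000)
  step <- filter_cells_and_genes(m, cfg)
  step <- normalize_and_log(step, cfg)
  step <- select_hvg(step, 15)
  step <- scale_unit_variance(step)
  expect_identical(unclass(preprocess_pipeline(m, cfg)), unclass(step))
})

test_that("stratified split applies the per-class half-up rounding with floor 1", {
  set.seed(2)
  n <- c(100, 50, 10)
  y <- rep(1:3, times = n)
  m <- ExpressionMatrix(matrix(rnorm(160 * 3), 160, 3),
                        paste0("c", 1:160), paste0("g", 1:3))
  sp <- split_by_label_fraction(m, y, 0.1, seed = 4,
                                class_names = c("A", "B", "C"))
  expect_identical(unname(tabulate(sp$labeled$labels, 3)), c(10L, 5L, 1L))
  # union/disjointness and truth alignment
  ids <- c(cell_ids(sp$labeled$matrix), cell_ids(sp$unlabeled$matrix))
  expect_setequal(ids, cell_ids(m))
  expect_length(intersect(cell_ids(sp$labeled$matrix),
                          cell_ids(sp$unlabeled$matrix)), 0)
  expect_identical(sp$truth,
                   y[match(cell_ids(sp$unlabeled$matrix), cell_ids(m))])
})

test_that("stratified split is deterministic and leaves C cells when p is near 1", {
  d <- separable_data(10, 4, seed = 9)
  a <- split_by_label_fraction(d$m, d$y, 0.3, seed = 42)
  b <- split_by_label_fraction(d$m, d$y, 0.3, seed = 42)
  expect_identical(cell_ids(a$labeled$matrix), cell_ids(b$labeled$matrix))
  # p = 0.94: per class of 10, floor(9.4 + .5) = 9 labeled -> 1 left per class
  sp <- split_by_label_fraction(d$m, d$y, 0.94, seed = 1)
  expect_identical(nrow(sp$unlabeled$matrix), 2L)
})

test_that("per-class labeled proportions stay within 1/class-size of p", {
  set.seed(33)
  y <- sample(1:4, 400, replace = TRUE, prob = c(.4, .3, .2, .1))
  m <- ExpressionMatrix(matrix(rnorm(400 * 2), 400, 2),
                        paste0("c", 1:400), c("g1", "g2"))
  for (p in c(0.05, 0.1, 0.3)) {
    sp <- split_by_label_fraction(m, y, p, seed = 7)
    lab_n <- tabulate(sp$labeled$labels, 4)
    tot_n <- tabulate(y, 4)
    expect_true(all(abs(lab_n / tot_n - p) <= 1 / tot_n + 1e-12))
  }
})
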