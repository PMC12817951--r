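test_that("supervised loss: one-hot zero, uniform log C, arithmetic oracle", {
  onehot <- diag(3)[c(1, 2, 3), ]
  expect_equal(supervised_loss(onehot, c(1, 2, 3)), 0, tolerance = 1e-9)
  unif <- matrix(1 / 4, 5, 4)
  expect_equal(supervised_loss(unif, c(1, 2, 3, 4, 1)), log(4),
               tolerance = 1e-12)
  p <- rbind(c(.7, .2, .1), c(.1, .8, .1), c(.3, .3, .4), c(.25, .5, .25))
  y <- c(1, 2, 3, 2)
  expect_equal(supervised_loss(p, y),
               -(log(.7) + log(.8) + log(.4) + log(.5)) / 4,
               tolerance = 1e-12)
  expect_error(supervised_loss(p, c(1, 2, 4, 1)), "range")
})

test_that("consistency loss: annihilated by zero confidence, 2 log C at uniform", {
  n <- 4; C <- 3
  unif <- matrix(1 / C, n, C)
  pseudo <- c(1, 2, 3, 1)
  expect_equal(consistency_loss(rep(0, n), pseudo, unif, unif), 0)
  onehot <- diag(C)[pseudo, ]
  expect_equal(consistency_loss(runif(n), pseudo, onehot, onehot), 0,
               tolerance = 1e-9)
  expect_equal(consistency_loss(rep(1, n), pseudo, unif, unif), 2 * log(C),
               tolerance = 1e-12)
  # half confidence halves the loss
  expect_equal(consistency_loss(rep(0.5, n), pseudo, unif, unif), log(C),
               tolerance = 1e-12)
  expect_error(consistency_loss(rep(1, 3), pseudo, unif, unif), "align")
})

test_that("zero confidence weights annihilate the consistency gradient", {
  probs <- matrix(c(.6, .3, .1, .2, .5, .3), 2, 3, byrow = TRUE)
  g <- scSemiLab:::ce_logit_grad(probs, c(1, 2), weights = c(0, 0))
  expect_true(all(g == 0))
})

test_that("stage 2 contract: no-op at 0 epochs, bitwise reproducible, learns", {
  pr <- tiny_problem(30, 8, seed = 3)
  net <- annotator_network(8, 2, c(8L, 6L, 4L), seed = 3)
  plan0 <- training_plan(stage_epochs = c(0L, 0L, 0L))
  expect_identical(
    scSemiLab:::net_params(run_stage2(net, pr$labeled, plan0)),
    scSemiLab:::net_params(net))
  plan <- training_plan(stage_epochs = c(0L, 30L, 0L),
                        stage_lrs = c(5e-4, 1e-3, 5e-5), batch_size = 16L)
  a <- run_stage2(net, pr$labeled, plan, seed = 9)
  b <- run_stage2(net, pr$labeled, plan, seed = 9)
  expect_identical(scSemiLab:::net_params(a), scSemiLab:::net_params(b))
  acc <- function(nn) mean(
    max.col(net_forward(nn, pr$labeled$matrix)$probs, "first") ==
      pr$labeled$labels)
  expect_gt(acc(a), acc(net))
})

test_that("stage 3 freeze contract: estimator untouched in warm-up, annotator decoupled", {
  pr <- tiny_problem(30, 8, seed = 13)
  net <- annotator_network(8, 2, c(8L, 6L, 4L), seed = 13)
  est <- confidence_estimator(6, 2, seed = 14)
  # warm-up epoch skips the estimator phase entirely
  plan_w <- training_plan(stage_epochs = c(0L, 0L, 1L), batch_size = 16L,
                          warmup_epochs_before_estimator = 5L)
  r <- run_stage3(net, est, pr$labeled, pr$unlabeled, plan_w, seed = 2)
  expect_identical(scSemiLab:::net_params(r$est), scSemiLab:::net_params(est))
  expect_false(identical(scSemiLab:::net_params(r$net),
                         scSemiLab:::net_params(net)))
  # with the estimator phase active both networks move
  plan_a <- training_plan(stage_epochs = c(0L, 0L, 2L), batch_size = 16L)
  r2 <- run_stage3(net, est, pr$labeled, pr$unlabeled, plan_a, seed = 2)
  expect_false(identical(scSemiLab:::net_params(r2$est),
                         scSemiLab:::net_params(est)))
})

test_that("lambda = 0 + no_confidence decouples the annotator from the unlabeled data", {
  pr <- tiny_problem(30, 8, seed = 17)
  net <- annotator_network(8, 2, c(8L, 6L, 4L), seed = 17)
  est <- confidence_estimator(6, 2, seed = 18)
  plan <- training_plan(stage_epochs = c(0L, 0L, 2L), batch_size = 16L,
                        lambda = 0, ablation = "no_confidence")
  r1 <- run_stage3(net, est, pr$labeled, pr$unlabeled, plan, seed = 4)
  # different unlabeled VALUES, same shape: Phi trajectory must be identical
  other <- unlabeled_set(ExpressionMatrix(
    matrix(rnorm(length(pr$unlabeled$matrix)), nrow(pr$unlabeled$matrix)),
    cell_ids(pr$unlabeled$matrix), gene_ids(pr$unlabeled$matrix)))
  r2 <- run_stage3(net, est, pr$labeled, other, plan, seed = 4)
  expect_identical(scSemiLab:::net_params(r1$net),
                   scSemiLab:::net_params(r2$net))
})

test_that("fit contract: zero epochs returns untrained nets; end-to-end bitwise seed reproducibility", {
  pr <- tiny_problem(20, 6, seed = 27)
  plan0 <- training_plan(stage_epochs = c(0L, 0L, 0L), seed = 7,
                         hidden_dims = c(6L, 4L, 3L))
  f0 <- fit_semisup(pr$labeled, pr$unlabeled, plan0)
  ref <- annotator_network(6, 2, c(6L, 4L, 3L), seed = 7)
  expect_identical(scSemiLab:::net_params(f0$net), scSemiLab:::net_params(ref))
  plan <- training_plan(stage_epochs = c(2L, 3L, 2L), batch_size = 16L,
                        seed = 7, hidden_dims = c(6L, 4L, 3L))
  f1 <- fit_semisup(pr$labeled, pr$unlabeled, plan)
  f2 <- fit_semisup(pr$labeled, pr$unlabeled, plan)
  expect_identical(scSemiLab:::net_params(f1$net), scSemiLab:::net_params(f2$net))
  expect_identical(scSemiLab:::net_params(f1$est), scSemiLab:::net_params(f2$est))
  expect_identical(predict(f1, pr$unlabeled$matrix)$labels,
                   predict(f2, pr$unlabeled$matrix)$labels)
})

test_that("predict aligns genes by id, handles single cells, rejects zero overlap", {
  pr <- tiny_problem(40, 10, p = 0.5, seed = 29)
  plan <- training_plan(stage_epochs = c(0L, 60L, 0L),
                        stage_lrs = c(5e-4, 1e-3, 5e-5), batch_size = 32L,
                        seed = 29, ablation = c("no_pretrain", "no_consistency"),
                        hidden_dims = c(16L, 8L, 4L))
  fit <- fit_semisup(pr$labeled, pr$unlabeled, plan)
  # self-accuracy on separable training cells
  expect_gte(mean(predict(fit, pr$labeled$matrix)$labels_idx ==
                    pr$labeled$labels), 0.99)
  # permuted gene columns give identical predictions
  q <- unclass(pr$unlabeled$matrix)
  perm <- sample(ncol(q))
  expect_identical(predict(fit, q[, perm])$labels,
                   predict(fit, q)$labels)
  # single-cell query
  p1 <- predict(fit, q[1, , drop = FALSE])
  expect_length(p1$labels, 1)
  # missing genes are zero-filled with a warning; zero overlap errors
  expect_warning(predict(fit, q[, 1:5]), "zero-filled")
  colnames(q) <- paste0("other", seq_len(ncol(q)))
  expect_error(predict(fit, q), "no genes")
})

test_that("training log captures per-stage records and writes JSON-lines", {
  pr <- tiny_problem(20, 6, seed = 37)
  plan <- training_plan(stage_epochs = c(1L, 1L, 1L), batch_size = 16L,
                        seed = 3, hidden_dims = c(12L, 8L, 4L))
  fit <- fit_semisup(pr$labeled, pr$unlabeled, plan)
  df <- as.data.frame(fit$log)
  expect_setequal(unique(df$stage), c(1L, 2L, 3L))
  expect_true(all(c("loss_c", "loss_s", "loss_u", "mean_confidence")
                  %in% names(df)))
  f <- withr::local_tempfile(fileext = ".jsonl")
  write_training_log(fit$log, f)
  rec <- jsonlite::fromJSON(readLines(f)[1])
  expect_identical(rec$stage, 1L)
})
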