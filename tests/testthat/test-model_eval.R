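test_that("75/25 split of 900 rows gives a 675/225 partition", {
  sp <- train_test_split(900, seed = 1)
  expect_length(sp$train, 675)
  expect_length(sp$test, 225)
  expect_setequal(c(sp$train, sp$test), 1:900)
  expect_identical(sp, train_test_split(900, seed = 1))
})

test_that("the RBF SVM fits a separable toy exactly and is deterministic", {
  X <- matrix(c(0, 0, 0, 1, 5, 5, 5, 6), 4, 2, byrow = TRUE,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c(0L, 0L, 1L, 1L)
  m <- train_svm(X, y, C = 10)
  expect_identical(predict(m, X), y)

  set.seed(40)
  Xn <- matrix(rnorm(120 * 3), 120, 3, dimnames = list(NULL, c("a", "b", "c")))
  yn <- as.integer(Xn[, 1] + 0.3 * rnorm(120) > 0)
  m1 <- train_svm(Xn, yn)
  m2 <- train_svm(Xn, yn)
  grid <- matrix(rnorm(600), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
  expect_identical(predict(m1, grid), predict(m2, grid))

  expect_error(train_svm(Xn, rep(0L, 120)), "2 classes")
  bad <- grid
  colnames(bad) <- c("a", "c", "b")
  expect_error(predict(m1, bad), "schema")
})

test_that("evaluation reports match hand-computed accuracy and sensitivity", {
  truth <- c(rep(0L, 10), rep(1L, 5), rep(2L, 5))
  pred <- c(rep(0L, 10), rep(2L, 5), rep(2L, 5))
  rep1 <- eval_report(truth, pred)
  expect_equal(rep1$confusion,
               matrix(c(10, 0, 0, 0, 0, 5, 0, 0, 5), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(rep1$accuracy, 0.75)
  expect_equal(rep1$sensitivity, 1.0)
  expect_equal(rep1$adjacent_misclass_rate, 0.25)
  expect_equal(rep1$nonadjacent_misclass_rate, 0)

  # order invariance and conservation
  perm <- sample(length(truth))
  rep2 <- eval_report(truth[perm], pred[perm])
  expect_equal(rep2$confusion, rep1$confusion)
  expect_equal(rowSums(rep1$confusion), c(10, 5, 5), ignore_attr = TRUE)
  expect_equal(sum(rep1$confusion), rep1$n)
  expect_equal(sum(diag(rep1$confusion)) / rep1$n, rep1$accuracy, tolerance = 1e-12)
  rs <- rowSums(rep1$confusion_normalized)
  expect_true(all(abs(rs[rowSums(rep1$confusion) > 0] - 1) < 1e-12))

  expect_identical(eval_report(c(0L, 1L), c(0L, 1L))$accuracy, 1)
  expect_error(eval_report(integer(0), integer(0)), "empty")
})

test_that("the discarded pool evaluates out-of-sample with absent classes flagged", {
  set.seed(41)
  n <- c(800, 400, 40)
  X <- rbind(matrix(rnorm(n[1] * 2), n[1], 2),
             matrix(rnorm(n[2] * 2, mean = 3), n[2], 2),
             matrix(rnorm(n[3] * 2, mean = 6), n[3], 2))
  colnames(X) <- c("f1", "f2")
  labels <- rep(0:2, times = n)
  ds <- rebalance_dataset(X, labels, target = 300, seed = 6)
  m <- train_svm(ds$matrix, ds$labels)
  repd <- evaluate_discarded(m, ds)
  expect_identical(repd$dataset_id, "discarded_pool")
  expect_identical(repd$n, (800L - 300L) + (400L - 300L))
  expect_identical(repd$absent_classes, 2L)
  expect_gt(repd$accuracy, 0.8) # well-separated Gaussians

  ds$discarded <- ds$discarded[integer(0), , drop = FALSE]
  expect_error(evaluate_discarded(m, ds), "empty")
})

test_that("PCA embedding is orthogonal, variance-bounded and reusable", {
  set.seed(42)
  X <- matrix(rnorm(500 * 10), 500, 10) %*% diag(sqrt(10:1))
  emb <- pca_embedding(X)
  expect_lt(abs(stats::cor(emb$coords[, 1], emb$coords[, 2])), 1e-8)
  tot_in <- sum(apply(scale(X), 2, stats::var))
  expect_lte(sum(apply(emb$coords, 2, stats::var)), tot_in + 1e-8)
  emb2 <- pca_embedding(X, transform_X = X)
  expect_identical(emb$coords, emb2$coords)
  expect_error(pca_embedding(X[, 1:2], n_components = 5), "exceeds")
})

test_that("the default synthetic benchmark clears chance level by a wide margin", {
  # full default benchmark: 24 sessions; chance level for three balanced
  # classes is 1/3
  res <- cached("default_run",
                run_pipeline(n_sessions = 24, config = session_config(), seed = 0))
  expect_gte(res$report_test$accuracy, 1 / 3 + 0.4)
  # PCA of the resampled set flags exactly the SMOTE rows as synthetic
  expect_identical(res$pca$synthetic, res$resampled$synthetic)
  expect_identical(nrow(res$pca$coords), nrow(res$resampled$matrix))
})
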