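# random feature matrix with the class geometry reported for the clinical
# dataset: 4437 / 366 / 47 rows for scores 0 / 1 / 2 (total 4850)
clinical_geometry <- function(d = 30, seed = 30) {
  set.seed(seed)
  n <- c(4437, 366, 47)
  X <- matrix(rnorm(sum(n) * d), sum(n), d,
              dimnames = list(NULL, paste0("f", seq_len(d))))
  list(X = X, labels = rep(0:2, times = n))
}

test_that("random undersampling keeps an exact uniform subset", {
  X <- matrix(rnorm(4437 * 5), 4437, 5)
  us <- random_undersample(X, 300, seed = 1)
  expect_length(us$kept, 300)
  expect_length(us$discarded, 4137)
  expect_setequal(c(us$kept, us$discarded), seq_len(4437))
  expect_identical(us, random_undersample(X, 300, seed = 1))

  Xs <- X[1:300, ]
  us2 <- random_undersample(Xs, 300, seed = 1)
  expect_identical(us2$kept, 1:300)
  expect_length(us2$discarded, 0)
  expect_error(random_undersample(X[1:10, ], 300), "not applicable")
})

test_that("SMOTE rows interpolate exactly between their two parents", {
  set.seed(31)
  X <- matrix(rnorm(47 * 30), 47, 30)
  sm <- smote_oversample(X, 300, k = 5, seed = 2)
  expect_identical(dim(sm$rows), c(300L, 30L))
  expect_identical(sum(sm$synthetic), 253L)
  expect_equal(sm$rows[1:47, ], X) # real rows retained untouched
  syn_idx <- which(sm$synthetic)
  for (i in syn_idx) {
    a <- X[sm$parents[i, 1], ]
    b <- X[sm$parents[i, 2], ]
    z <- sm$rows[i, ]
    # collinear betweenness: |z-a| + |z-b| == |a-b|
    expect_lt(abs(sqrt(sum((z - a)^2)) + sqrt(sum((z - b)^2)) -
                    sqrt(sum((a - b)^2))), 1e-9)
    # per-dimension convex-hull containment
    expect_true(all(z >= pmin(a, b) - 1e-12 & z <= pmax(a, b) + 1e-12))
  }

  # k capped at class size - 1
  X3 <- matrix(rnorm(9), 3, 3)
  sm3 <- smote_oversample(X3, 10, k = 5, seed = 3)
  expect_identical(sum(sm3$synthetic), 7L)
  expect_true(all(sm3$parents[sm3$synthetic, 2] %in% 1:3))
  expect_error(smote_oversample(X3[1, , drop = FALSE], 10), "at least 2")
  expect_error(smote_oversample(X3, 3), "already at or above")
})

test_that("rebalancing the printed class geometry gives 300/300/300 with 253 synthetic", {
  g <- clinical_geometry()
  ds <- rebalance_dataset(g$X, g$labels, target = 300, seed = 4)
  expect_identical(unname(table(ds$labels)), table(rep(0:2, each = 300)),
                   ignore_attr = TRUE)
  expect_identical(nrow(ds$matrix), 900L)
  expect_identical(sum(ds$synthetic), 253L)
  expect_equal(sum(ds$synthetic) / nrow(ds$matrix), 0.28, tolerance = 0.005)
  expect_identical(nrow(ds$discarded), 4137L + 66L)
  expect_identical(unname(tabulate(ds$discarded_labels + 1L, 3)), c(4137L, 66L, 0L))

  # conservation: balanced real rows and discarded rows partition the input
  real_ids <- ds$provenance[!ds$synthetic, "source_id"]
  expect_false(anyNA(real_ids))
  expect_identical(sort(c(real_ids, ds$discarded_ids)), seq_along(g$labels))
  expect_true(all(is.na(ds$provenance[ds$synthetic, "source_id"])))
  # synthetic provenance points at same-class parents
  syn_par <- ds$provenance[ds$synthetic, c("parent_i", "parent_nn")]
  expect_true(all(g$labels[syn_par] == 2L))
})

test_that("a minority class already at target is undersampled, not oversampled", {
  set.seed(32)
  X <- matrix(rnorm(1200 * 4), 1200, 4)
  labels <- rep(0:2, times = c(500, 400, 300))
  ds <- rebalance_dataset(X, labels, target = 300, seed = 5)
  expect_identical(sum(ds$synthetic), 0L)
  expect_identical(nrow(ds$discarded), 300L)
  expect_identical(unname(tabulate(ds$labels + 1L, 3)), rep(300L, 3))
})
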