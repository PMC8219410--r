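test_that("bootstrap sampling has classical coverage and is reproducible", {
  expect_identical(bootstrap_sample(1, 5), 1L)
  b <- bootstrap_sample(1000, 7)
  expect_length(b, 1000)
  expect_true(all(b >= 1 & b <= 1000))
  expect_lt(abs(length(unique(b)) / 1000 - (1 - exp(-1))), 0.03)
  expect_identical(bootstrap_sample(1000, 7), b)
  expect_false(identical(bootstrap_sample(1000, 8), b))
  expect_error(bootstrap_sample(0, 1), "positive integer")
})

test_that("single trees handle pure and separable data", {
  x <- matrix(rnorm(40), 20, 2)
  tr <- build_tree(x, rep(3L, 20), irf_hyperparams(1, 2, 1), seed = 1)
  expect_true(all(predict(tr, x) == 3L))

  # 1-D perfectly separable: one split suffices
  x1 <- matrix(c(1:10, 21:30), ncol = 1)
  y1 <- rep(c(0L, 4L), each = 10)
  tr1 <- build_tree(x1, y1, irf_hyperparams(1, 1, 1), seed = 2)
  expect_equal(length(tr1$feature), 3)  # root + two leaves
  expect_true(all(predict(tr1, x1) == y1))

  expect_error(build_tree(x[0, , drop = FALSE], integer(0)), "empty")
})

test_that("tree growing matches the brute-force CART oracle", {
  for (s in 1:5) {
    set.seed(400 + s)
    x <- matrix(rnorm(40), 20, 2)
    y <- sample(0:4, 20, replace = TRUE)
    for (msl in c(1L, 3L)) {
      tr <- build_tree(x, y, irf_hyperparams(1, 2, msl), seed = s)
      expect_identical(predict(tr, x), oracle_cart_predict(x, y, x, msl))
    }
  }
})

test_that("forest training is deterministic and learns separable blobs", {
  blobs <- make_blobs(100, sep = 3, seed = 31)
  hp <- irf_hyperparams(25, 1, 1)
  m1 <- train_forest(blobs$x, blobs$y, hp, seed = 11)
  m2 <- train_forest(blobs$x, blobs$y, hp, seed = 11)
  test <- make_blobs(20, sep = 3, seed = 32)
  expect_identical(predict(m1, test$x), predict(m2, test$x))
  expect_gte(mean(predict(m1, blobs$x) == blobs$y), 0.95)

  # k = 1 forest equals its single tree on out-of-sample points
  m3 <- train_forest(blobs$x, blobs$y, irf_hyperparams(1, 1, 1), seed = 3)
  expect_identical(predict(m3, test$x), predict(m3$trees[[1]], test$x))
  expect_length(m3$seeds, 1)
})

test_that("majority voting breaks ties toward the lower level", {
  blobs <- make_blobs(30, sep = 1, seed = 41)
  model <- train_forest(blobs$x, blobs$y, irf_hyperparams(10, 1, 1), seed = 6)
  test <- make_blobs(10, sep = 1, seed = 42)
  votes <- vapply(model$trees, function(tr) predict(tr, test$x),
                  integer(nrow(test$x)))
  manual <- apply(votes, 1, function(v) {
    tal <- tabulate(v + 1L, 5L)
    min(which(tal == max(tal))) - 1L   # argmax, ties -> lower ordinal
  })
  expect_identical(predict(model, test$x), manual)
  expect_error(predict(model, test$x[, 1, drop = FALSE]),
               "dimension mismatch")
})

test_that("cv plans partition the data into near-equal disjoint folds", {
  plan <- make_cv_plan(100, 10, seed = 1)
  expect_identical(vapply(plan$folds, length, 1L), rep(10L, 10))

  loo <- make_cv_plan(10, 10, seed = 1)
  expect_identical(sort(vapply(loo$folds, length, 1L)), rep(1L, 10))

  set.seed(99)
  for (i in 1:10) {
    n <- sample(10:500, 1)
    S <- sample(c(2, 5, 10), 1)
    p <- make_cv_plan(n, S, seed = i)
    all_idx <- sort(unlist(p$folds))
    expect_identical(all_idx, seq_len(n))          # coverage + disjointness
    sizes <- vapply(p$folds, length, 1L)
    expect_lte(max(sizes) - min(sizes), 1L)
  }
  expect_error(make_cv_plan(5, 10), "2 <= S <= n")
})

test_that("cross-validation returns S accuracies with a sane mean", {
  blobs <- make_blobs(20, sep = 8, seed = 51)
  plan <- make_cv_plan(100, 5, seed = 2)
  cv <- cross_validate(blobs$x, blobs$y, irf_hyperparams(15, 1, 1), plan,
                       seed = 3)
  expect_length(cv$accuracies, 5)
  expect_equal(cv$mean_accuracy, mean(cv$accuracies))
  expect_equal(cv$mean_accuracy, 1.0)  # perfectly separable

  expect_error(cross_validate(blobs$x, blobs$y, plan = make_cv_plan(50, 5),
                              seed = 1), "plan covers")
  broken <- plan; broken$folds[[1]] <- integer(0)
  expect_error(cross_validate(blobs$x, blobs$y, irf_hyperparams(5, 1, 1),
                              broken, 1), "empty")
})

test_that("grid search honors single points, ties, and determinism", {
  blobs <- make_blobs(12, sep = 8, seed = 61)
  plan <- make_cv_plan(60, 5, seed = 4)

  single <- grid_search(blobs$x, blobs$y,
                        coarse_grid = list(n_estimators = 7, max_features = 1,
                                           min_samples_leaf = 2),
                        plan = plan, seed = 5, phases = 1)
  expect_equal(single$best$n_estimators, 7L)
  expect_equal(nrow(single$trace), 1)
  expect_equal(single$best_score, single$trace$score[1])

  # both k=5 and k=10 reach accuracy 1 on separable data: smaller k wins
  tied <- grid_search(blobs$x, blobs$y,
                      coarse_grid = list(n_estimators = c(5, 10),
                                         max_features = 1,
                                         min_samples_leaf = 1),
                      plan = plan, seed = 6, phases = 1)
  expect_equal(max(tied$trace$score), 1)
  expect_equal(tied$best$n_estimators, 5L)

  g2 <- grid_search(blobs$x, blobs$y,
                    coarse_grid = list(n_estimators = c(5, 10),
                                       max_features = 1,
                                       min_samples_leaf = 1),
                    plan = plan, seed = 6, phases = 1)
  expect_identical(tied$trace, g2$trace)

  expect_error(grid_search(blobs$x, blobs$y,
                           coarse_grid = list(n_estimators = integer(0),
                                              max_features = 1,
                                              min_samples_leaf = 1),
                           plan = plan, seed = 1), "empty grid")
})

test_that("train_irf searches, refits, and never loses to a coarse point", {
  blobs <- make_blobs(16, sep = 2, seed = 71)
  grid <- list(n_estimators = c(5, 15), max_features = c(1, 2),
               min_samples_leaf = c(1, 5))
  fit <- train_irf(blobs$x, blobs$y, coarse_grid = grid, folds = 5, seed = 8)
  tr <- fit$search$trace
  expect_gte(fit$search$best_score, max(tr$score[tr$phase == 1]))
  in_trace <- any(tr$n_estimators == fit$search$best$n_estimators &
                  tr$max_features == fit$search$best$max_features &
                  tr$min_samples_leaf == fit$search$best$min_samples_leaf)
  expect_true(in_trace)
  expect_identical(fit$model$hyperparams, fit$search$best)

  fit2 <- train_irf(blobs$x, blobs$y, coarse_grid = grid, folds = 5, seed = 8)
  expect_identical(fit2$search$best, fit$search$best)

  expect_error(train_irf(blobs$x[1:5, ], blobs$y[1:5], folds = 10),
               "smaller S")
})

test_that("model JSON round trip preserves predictions exactly", {
  blobs <- make_blobs(20, sep = 2, seed = 81)
  model <- train_forest(blobs$x, blobs$y, irf_hyperparams(12, 2, 2), seed = 9)
  f <- withr::local_tempfile(fileext = ".json")
  write_model(model, f)
  back <- read_model(f)
  test <- make_blobs(30, sep = 2, seed = 82)
  expect_identical(predict(back, test$x), predict(model, test$x))
  expect_identical(back$hyperparams, model$hyperparams)
  expect_identical(back$seeds, model$seeds)
  expect_error(read_model(withr::local_tempfile()), "file not found")
})

test_that("forest accuracy rises with class separation", {
  seps <- c(0.5, 1.5, 3)
  mean_acc <- vapply(seps, function(sp) {
    mean(vapply(1:10, function(s) {
      tr <- make_blobs(20, sep = sp, seed = 900 + s)
      m <- train_forest(tr$x, tr$y, irf_hyperparams(15, 1, 1), seed = s)
      mean(predict(m, tr$x) == tr$y)
    }, 0))
  }, 0)
  expect_gte(suppressWarnings(cor(seps, mean_acc, method = "spearman")), 0.9)
})
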