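test_that("zero replacement matches the closed-form posterior expectation", {
  m <- matrix(c(0L, 9L, 1L), 3, 1, dimnames = list(c("z", "a", "b"), "s1"))
  out <- bm_replace(m, prior = "SQ")
  n <- 10
  s <- sqrt(n)
  r <- (1 / 3) * s / (n + s)
  expect_equal(out["z", 1], r)
  expect_equal(round(out["z", 1], 5), 0.08008)
  expect_equal(out["a", 1], 0.9 * (1 - r))
  expect_equal(out["a", 1], 0.82792, tolerance = 1e-5)
  expect_equal(round(out["b", 1], 5), 0.09199)
  expect_equal(sum(out[, 1]), 1, tolerance = 1e-12)
  # the 9:1 ratio between the non-zero parts is preserved exactly
  expect_equal(out["a", 1] / out["b", 1], 9, tolerance = 1e-12)
})

test_that("zero replacement preserves non-zero ratios and strict positivity", {
  set.seed(19)
  counts <- matrix(rpois(200, 2), 20,
                   dimnames = list(sprintf("f%02d", 1:20),
                                   sprintf("s%02d", 1:10)))
  counts[counts == 1] <- 0
  counts[1, ] <- counts[1, ] + 5L # keep totals positive
  for (prior in c("SQ", "Bayes-Laplace", "Perks", "Jeffreys")) {
    out <- bm_replace(counts, prior = prior)
    expect_true(all(out > 0))
    expect_true(all(abs(colSums(out) - 1) < 1e-12))
    for (j in 1:10) {
      nz <- counts[, j] > 0
      ratio <- out[nz, j] / counts[nz, j]
      expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
    }
  }

  # a sample with no zeros is returned as plain proportions
  full <- matrix(c(2L, 3L, 5L), 3, 1,
                 dimnames = list(c("a", "b", "c"), "s"))
  expect_equal(bm_replace(full)[, 1], c(a = 0.2, b = 0.3, c = 0.5))

  # all-zero samples are rejected by name
  bad <- cbind(full, none = c(0L, 0L, 0L))
  expect_error(bm_replace(bad), "none")
})

make_separable <- function(n_per_class = 10, m = 6, seed = 5) {
  set.seed(seed)
  x <- matrix(rnorm(2 * n_per_class * m), 2 * n_per_class, m,
              dimnames = list(sprintf("s%02d", 1:(2 * n_per_class)),
                              sprintf("f%d", 1:m)))
  # interleave the classes so any contiguous split stays balanced
  y <- factor(rep(c("student", "laborer"), n_per_class),
              levels = c("student", "laborer"))
  x[, 1] <- ifelse(y == "laborer", 1, 0) + rnorm(2 * n_per_class, 0, 0.01)
  list(x = x, y = y)
}

test_that("a perfectly separating feature yields perfect accuracy and top rank", {
  d <- make_separable()
  ens <- train_forest_ensemble(d$x[1:14, ], d$y[1:14], d$x[15:20, ],
                               d$y[15:20], n_forests = 20, n_trees = 25,
                               seed = 3)
  expect_equal(ens$train_accuracy, 1)
  expect_equal(ens$test_accuracy, 1)
  expect_identical(names(ens$importance)[1], "f1")

  expect_error(train_forest_ensemble(d$x, factor(rep("a", 20))), "single class")
})

test_that("forest ensembles are reproducible from the seed", {
  d <- make_separable(m = 4)
  a <- train_forest_ensemble(d$x, d$y, n_forests = 5, n_trees = 10, seed = 11)
  b <- train_forest_ensemble(d$x, d$y, n_forests = 5, n_trees = 10, seed = 11)
  expect_identical(a$importance, b$importance)
  expect_identical(a$train_accuracy, b$train_accuracy)
})

test_that("randomly labeled data gives chance-level test accuracy", {
  set.seed(23)
  accs <- replicate(10, {
    x <- matrix(rnorm(30 * 5), 30, 5,
                dimnames = list(NULL, sprintf("f%d", 1:5)))
    y <- factor(rep(c("a", "b"), 15))
    train_forest_ensemble(x[1:20, ], y[1:20], x[21:30, ], y[21:30],
                          n_forests = 10, n_trees = 25)$test_accuracy
  })
  expect_gt(mean(accs), 0.25)
  expect_lt(mean(accs), 0.75)
})

test_that("the elimination trace has the required structure", {
  d <- make_separable(n_per_class = 8, m = 5)
  tr <- rfe(d$x[1:12, ], d$y[1:12], d$x[13:16, ], d$y[13:16],
            n_forests = 10, n_trees = 25, seed = 2)
  expect_identical(nrow(tr$steps), 5L)
  expect_identical(tr$steps$n_features, 5:1)
  # step k holds exactly m - k + 1 features and eliminations never reappear
  for (k in 1:5) expect_identical(length(tr$feature_sets[[k]]), 6L - k)
  for (k in 2:5) {
    gone <- tr$steps$eliminated[k - 1]
    expect_false(gone %in% tr$feature_sets[[k]])
  }
  expect_true(is.na(tr$steps$eliminated[5]))

  # determinism end-to-end
  tr2 <- rfe(d$x[1:12, ], d$y[1:12], d$x[13:16, ], d$y[13:16],
             n_forests = 10, n_trees = 25, seed = 2)
  expect_identical(tr$steps, tr2$steps)

  # single-feature input produces a single-step trace
  tr1 <- rfe(d$x[1:12, 1, drop = FALSE], d$y[1:12],
             n_forests = 5, n_trees = 10, seed = 1)
  expect_identical(nrow(tr1$steps), 1L)
  expect_identical(tr1$feature_sets[[1]], "f1")
})

test_that("the informative feature survives elimination under strong signal", {
  survived <- vapply(1:5, function(s) {
    d <- make_separable(n_per_class = 10, m = 3, seed = 100 + s)
    tr <- rfe(d$x[1:14, ], d$y[1:14], d$x[15:20, ], d$y[15:20],
              n_forests = 20, n_trees = 25, seed = s)
    tr$feature_sets[[3]] == "f1"
  }, logical(1))
  expect_gte(mean(survived), 0.9)
})

fake_trace <- function(test_acc, train_acc, sets) {
  structure(list(
    steps = data.frame(step = seq_along(sets),
                       n_features = lengths(sets),
                       train_accuracy = train_acc,
                       test_accuracy = test_acc,
                       eliminated = NA_character_,
                       stringsAsFactors = FALSE),
    feature_sets = sets, n_forests = 5L, n_trees = 10L, seed = 1L),
    class = "rfe_trace")
}

test_that("best-model selection prefers accuracy, then fewer features", {
  d <- make_separable(n_per_class = 10, m = 6)
  xtr <- d$x[1:14, ]; ytr <- d$y[1:14]
  xte <- d$x[15:20, ]; yte <- d$y[15:20]
  feats <- colnames(d$x)

  # equal perfect accuracy at sizes 5 and 3: the size-3 step wins
  tr <- fake_trace(test_acc = c(1, 1, 0.8),
                   train_acc = c(1, 1, 1),
                   sets = list(feats[1:5], feats[1:3], feats[1:2]))
  sel <- occubiome:::best_trace_step(tr)
  expect_identical(sel$n_features, 3L)

  # strictly improving test accuracy: the smallest step wins
  tr2 <- fake_trace(test_acc = c(0.6, 0.8, 1),
                    train_acc = c(1, 1, 1),
                    sets = list(feats[1:3], feats[1:2], feats[1]))
  expect_identical(occubiome:::best_trace_step(tr2)$n_features, 1L)

  # all steps identical: the single-feature step wins
  tr3 <- fake_trace(test_acc = c(0.9, 0.9, 0.9),
                    train_acc = c(1, 1, 1),
                    sets = list(feats[1:3], feats[1:2], feats[1]))
  expect_identical(occubiome:::best_trace_step(tr3)$n_features, 1L)

  # ties on test accuracy fall back to training accuracy
  tr4 <- fake_trace(test_acc = c(0.9, 0.9),
                    train_acc = c(0.8, 1),
                    sets = list(feats[1:2], feats[1:4]))
  expect_identical(occubiome:::best_trace_step(tr4)$n_features, 4L)

  model <- select_best_model(tr, xtr, ytr, xte, yte)
  expect_identical(sort(model$features), sort(feats[1:3]))
  expect_true(model$train_accuracy >= 0 && model$train_accuracy <= 1)
})

test_that("prediction is deterministic, order-aware and checks features", {
  d <- make_separable(n_per_class = 10, m = 4)
  tr <- rfe(d$x[1:14, ], d$y[1:14], d$x[15:20, ], d$y[15:20],
            n_forests = 10, n_trees = 25, seed = 6)
  model <- select_best_model(tr, d$x[1:14, ], d$y[1:14],
                             d$x[15:20, ], d$y[15:20])
  pred <- predict(model, d$x[1:14, ])
  expect_equal(mean(pred == d$y[1:14]), model$train_accuracy)

  # permuting the samples permutes the labels
  perm <- c(3, 1, 2, 8, 5)
  expect_identical(as.character(predict(model, d$x[perm, ])),
                   as.character(predict(model, d$x[1:8, ])[perm]))

  # missing model features are named
  keep <- setdiff(colnames(d$x), model$features[1])
  expect_error(predict(model, d$x[, keep, drop = FALSE]),
               model$features[1], fixed = TRUE)
})

test_that("null studies give chance-level selected-model accuracy", {
  accs <- vapply(1:12, function(s) {
    cfg <- simulation_config(n_per_group = 10, n_features = 25,
                             n_informative = 5, effect_size = 1,
                             depth_mean = 2000, sparsity = 0.2,
                             seed = 3000 + s)
    sim <- simulate_study(cfg)
    fit <- build_occupation_model(sim$table, sim$metadata,
                                  sample_type = "saliva",
                                  min_prevalence = 5, n_forests = 15,
                                  n_trees = 25, seed = s)
    fit$model$test_accuracy
  }, numeric(1))
  expect_gte(mean(accs), 0.3)
  expect_lte(mean(accs), 0.7)
})

test_that("the full fit is reproducible from its master seed", {
  cfg <- simulation_config(n_per_group = 8, n_features = 15,
                           depth_mean = 2000, seed = 77)
  sim <- simulate_study(cfg)
  f1 <- build_occupation_model(sim$table, sim$metadata, min_prevalence = 4,
                               n_forests = 5, n_trees = 10, seed = 9)
  f2 <- build_occupation_model(sim$table, sim$metadata, min_prevalence = 4,
                               n_forests = 5, n_trees = 10, seed = 9)
  expect_identical(f1$trace$steps, f2$trace$steps)
  expect_identical(f1$model$features, f2$model$features)
  expect_identical(f1$split, f2$split)
})
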