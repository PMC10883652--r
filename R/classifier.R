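#' Bayesian-multiplicative zero replacement
#'
#' Transforms a count table into strictly positive compositions: within each
#' sample, zero counts are replaced by their posterior Dirichlet expectation
#' under the chosen prior and the non-zero parts are proportionally reduced
#' so the sample still sums to one. Ratios among non-zero parts are
#' preserved exactly.
#'
#' With a uniform base (`t = 1/m`) and prior strength `s`, a zero cell in a
#' sample of total `n` becomes `t * s / (n + s)`, and each non-zero count
#' `c` becomes `(c / n) * (1 - r)` where `r` is the total replaced mass.
#' Priors: `"SQ"` (square-root, `s = sqrt(n)`, the default), `"Bayes-Laplace"`
#' (`s = m`), `"Perks"` (`s = 1`), `"Jeffreys"` (`s = m/2`).
#'
#' @param x a [feature_table()] or non-negative count matrix
#'   (features x samples).
#' @param prior prior choice, see Details.
#' @param strength optional numeric overriding the prior's strength `s`.
#' @return A numeric matrix of strictly positive compositions (columns sum
#'   to 1).
#' @export
bm_replace <- function(x, prior = c("SQ", "Bayes-Laplace", "Perks", "Jeffreys"),
                       strength = NULL) {
  prior <- match.arg(prior)
  counts <- if (inherits(x, "feature_table")) x$counts else x
  if (!is.matrix(counts) || any(counts < 0) || !is_whole(counts))
    stop2("'x' must be a non-negative integer count matrix")
  m <- nrow(counts)
  totals <- colSums(counts)
  zero <- colnames(counts)[totals == 0]
  if (length(zero))
    stop2("sample(s) with all-zero counts: ", paste(zero, collapse = ", "))
  out <- matrix(0, m, ncol(counts), dimnames = dimnames(counts))
  t_i <- 1 / m
  for (j in seq_len(ncol(counts))) {
    n <- totals[j]
    s <- strength %||% switch(prior,
                              "SQ" = sqrt(n),
                              "Bayes-Laplace" = m,
                              "Perks" = 1,
                              "Jeffreys" = m / 2)
    cj <- counts[, j]
    is_zero <- cj == 0
    repl <- t_i * s / (n + s)
    r_total <- sum(is_zero) * repl
    out[is_zero, j] <- repl
    out[!is_zero, j] <- (cj[!is_zero] / n) * (1 - r_total)
  }
  out
}

majority_vote <- function(votes, levels) {
  # votes: character matrix, samples x voters; ties go to the first level
  n1 <- rowSums(votes == levels[1L])
  factor(ifelse(n1 * 2L >= ncol(votes), levels[1L], levels[2L]),
         levels = levels)
}

#' Train an ensemble of random forests with averaged permutation importance
#'
#' Grows `n_forests` random forests of `n_trees` trees each on the training
#' set (all from one seeded RNG stream, so the ensemble is reproducible),
#' ranks features by the average over forests of the unscaled
#' mean-decrease-accuracy importance, and evaluates the ensemble's
#' majority-vote accuracy (each forest votes with its own majority) on the
#' training set and, if given, a test set.
#'
#' @param x_train numeric matrix, samples x features, with feature column
#'   names.
#' @param y_train two-level factor of class labels.
#' @param x_test,y_test optional held-out set.
#' @param n_forests number of forests (>= 1).
#' @param n_trees trees per forest.
#' @param mtry variables tried at each split; default `floor(sqrt(m))`.
#' @param seed optional integer seed.
#' @param keep_forest retain the fitted forest object (needed for later
#'   prediction).
#' @return A list of class `forest_ensemble` with `importance` (named,
#'   decreasing), `train_accuracy`, `test_accuracy` (or `NA`), `levels`,
#'   and the call parameters; plus `forest` when `keep_forest = TRUE`.
#' @export
train_forest_ensemble <- function(x_train, y_train, x_test = NULL,
                                  y_test = NULL, n_forests = 100L,
                                  n_trees = 500L, mtry = NULL, seed = NULL,
                                  keep_forest = FALSE) {
  if (!is.matrix(x_train)) x_train <- as.matrix(x_train)
  if (is.null(colnames(x_train))) stop2("'x_train' needs feature names")
  y_train <- as.factor(y_train)
  if (nlevels(droplevels(y_train)) < 2L)
    stop2("training labels contain a single class")
  y_train <- droplevels(y_train)
  if (n_forests < 1L) stop2("'n_forests' must be >= 1")
  m <- ncol(x_train)
  mtry <- mtry %||% max(1L, floor(sqrt(m)))

  fit_and_score <- function() {
    rf <- randomForest::randomForest(
      x_train, y_train, ntree = n_forests * n_trees, mtry = mtry,
      importance = TRUE)
    # unscaled mean decrease accuracy = per-tree importance averaged over
    # the whole stream = average of the per-forest means
    imp <- randomForest::importance(rf, type = 1L, scale = FALSE)[, 1L]
    newdata <- if (is.null(x_test)) x_train else rbind(x_train, x_test)
    per_tree <- predict(rf, newdata, predict.all = TRUE)$individual
    # fold per-tree votes into per-forest majority votes
    forest_votes <- vapply(seq_len(n_forests), function(f) {
      cols <- ((f - 1L) * n_trees + 1L):(f * n_trees)
      as.character(majority_vote(per_tree[, cols, drop = FALSE],
                                 levels(y_train)))
    }, character(nrow(newdata)))
    forest_votes <- matrix(forest_votes, nrow = nrow(newdata))
    pred <- majority_vote(forest_votes, levels(y_train))
    ntr <- nrow(x_train)
    train_pred <- pred[seq_len(ntr)]
    test_pred <- if (!is.null(x_test)) pred[(ntr + 1L):length(pred)]
    list(rf = rf, imp = imp, train_pred = train_pred, test_pred = test_pred)
  }
  res <- if (is.null(seed)) fit_and_score() else with_seed(seed, fit_and_score())

  train_acc <- mean(res$train_pred == y_train)
  test_acc <- if (!is.null(y_test)) mean(res$test_pred == y_test) else NA_real_
  structure(list(importance = sort(res$imp, decreasing = TRUE),
                 train_accuracy = train_acc,
                 test_accuracy = test_acc,
                 levels = levels(y_train),
                 n_forests = n_forests, n_trees = n_trees, mtry = mtry,
                 seed = seed,
                 forest = if (keep_forest) res$rf),
            class = "forest_ensemble")
}

# Lowest-importance feature; ties broken by removing the lexicographically
# last id (radix order, locale-independent).
lowest_importance_feature <- function(importance) {
  low <- names(importance)[importance <= min(importance)]
  tail(sort(low, method = "radix"), 1L)
}

#' Recursive feature elimination with random-forest ensembles
#'
#' Starting from all features, repeatedly trains a [train_forest_ensemble()]
#' on the current feature set, records training and test accuracy, and
#' removes the single feature with the lowest average importance (ties:
#' the lexicographically last id), until one feature remains. The trace has
#' exactly `m` steps; eliminated features never reappear.
#'
#' @inheritParams train_forest_ensemble
#' @param seed master seed; per-step seeds are derived from it so the whole
#'   trace is reproducible.
#' @return A list of class `rfe_trace` with `steps` (data frame: `step`,
#'   `n_features`, `train_accuracy`, `test_accuracy`, `eliminated`),
#'   `feature_sets` (list of character vectors, one per step) and the call
#'   parameters.
#' @export
rfe <- function(x_train, y_train, x_test = NULL, y_test = NULL,
                n_forests = 100L, n_trees = 500L, seed = 1L) {
  if (!is.matrix(x_train)) x_train <- as.matrix(x_train)
  m <- ncol(x_train)
  if (m < 1L) stop2("need at least one feature")
  step_seeds <- derive_seeds(seed, m)
  current <- colnames(x_train)
  steps <- vector("list", m)
  sets <- vector("list", m)
  for (k in seq_len(m)) {
    ens <- train_forest_ensemble(
      x_train[, current, drop = FALSE], y_train,
      if (!is.null(x_test)) x_test[, current, drop = FALSE], y_test,
      n_forests = n_forests, n_trees = n_trees, seed = step_seeds[k])
    victim <- if (length(current) > 1L)
      lowest_importance_feature(ens$importance) else NA_character_
    steps[[k]] <- data.frame(step = k, n_features = length(current),
                             train_accuracy = ens$train_accuracy,
                             test_accuracy = ens$test_accuracy,
                             eliminated = victim, stringsAsFactors = FALSE)
    sets[[k]] <- current
    if (!is.na(victim)) current <- setdiff(current, victim)
  }
  structure(list(steps = do.call(rbind, steps), feature_sets = sets,
                 n_forests = n_forests, n_trees = n_trees, seed = seed),
            class = "rfe_trace")
}

#' @export
print.rfe_trace <- function(x, ...) {
  cat("<rfe_trace> ", nrow(x$steps), " steps (", x$steps$n_features[1L],
      " -> 1 features), ", x$n_forests, " forests x ", x$n_trees,
      " trees per step\n", sep = "")
  best <- best_trace_step(x)
  cat("  best step: ", best$n_features, " features, train ",
      round(100 * best$train_accuracy, 2), "%, test ",
      round(100 * best$test_accuracy, 2), "%\n", sep = "")
  invisible(x)
}

best_trace_step <- function(trace) {
  s <- trace$steps
  key_test <- ifelse(is.na(s$test_accuracy), -Inf, s$test_accuracy)
  ord <- order(-key_test, -s$train_accuracy, s$n_features)
  s[ord[1L], ]
}

#' Select and refit the best model from an elimination trace
#'
#' Steps are scored lexicographically by (test accuracy, training accuracy);
#' among the maximal steps the one with the fewest features wins. The
#' ensemble is then retrained on that feature subset (with a seed derived
#' from `seed`) and returned together with its accuracies.
#'
#' @param trace an [rfe()] trace.
#' @param x_train,y_train,x_test,y_test the data the trace was built from.
#' @param seed seed for the refit (defaults to the trace's master seed).
#' @return A list of class `occupation_model` with `features`, `ensemble`
#'   (a `forest_ensemble` carrying the fitted forest), `train_accuracy`,
#'   `test_accuracy`, `selection` (the chosen trace row) and `seed`.
#' @export
select_best_model <- function(trace, x_train, y_train, x_test = NULL,
                              y_test = NULL, seed = NULL) {
  stopifnot(inherits(trace, "rfe_trace"))
  best <- best_trace_step(trace)
  features <- trace$feature_sets[[best$step]]
  refit_seed <- derive_seeds(seed %||% trace$seed, nrow(trace$steps) + 1L)
  refit_seed <- refit_seed[length(refit_seed)]
  ens <- train_forest_ensemble(
    x_train[, features, drop = FALSE], y_train,
    if (!is.null(x_test)) x_test[, features, drop = FALSE], y_test,
    n_forests = trace$n_forests, n_trees = trace$n_trees,
    seed = refit_seed, keep_forest = TRUE)
  structure(list(features = features, ensemble = ens,
                 train_accuracy = ens$train_accuracy,
                 test_accuracy = ens$test_accuracy,
                 selection = best, seed = refit_seed),
            class = "occupation_model")
}

#' @export
print.occupation_model <- function(x, ...) {
  cat("<occupation_model> ", length(x$features), " feature(s): ",
      paste(utils::head(x$features, 5), collapse = ", "),
      if (length(x$features) > 5) ", ..." else "", "\n", sep = "")
  cat("  train accuracy ", round(100 * x$train_accuracy, 2), "%",
      if (!is.na(x$test_accuracy))
        paste0(", test accuracy ", round(100 * x$test_accuracy, 2), "%"),
      "\n", sep = "")
  invisible(x)
}

#' Predict occupation labels for new samples
#'
#' @param object an [select_best_model()] result.
#' @param newdata numeric matrix of compositions, either samples x features
#'   or features x samples (orientation is resolved from the feature names);
#'   must contain all of the model's features.
#' @param ... unused.
#' @return Factor of predicted labels, named by sample id.
#' @export
predict.occupation_model <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!all(object$features %in% colnames(newdata)) &&
      all(object$features %in% rownames(newdata)))
    newdata <- t(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop2("newdata lacks model feature(s): ", paste(missing, collapse = ", "))
  rf <- object$ensemble$forest
  if (is.null(rf)) stop2("model does not carry a fitted forest")
  x <- newdata[, object$features, drop = FALSE]
  per_tree <- predict(rf, x, predict.all = TRUE)$individual
  n_forests <- object$ensemble$n_forests
  n_trees <- object$ensemble$n_trees
  per_tree <- matrix(per_tree, nrow = nrow(x))
  forest_votes <- vapply(seq_len(n_forests), function(f) {
    cols <- ((f - 1L) * n_trees + 1L):(f * n_trees)
    as.character(majority_vote(per_tree[, cols, drop = FALSE],
                               object$ensemble$levels))
  }, character(nrow(x)))
  forest_votes <- matrix(forest_votes, nrow = nrow(x))
  out <- majority_vote(forest_votes, object$ensemble$levels)
  names(out) <- rownames(x)
  out
}

#' Build an occupation classifier from a feature table
#'
#' End-to-end model construction: female students are removed (occupation
#' and gender are confounded in the cohort design), samples are restricted
#' to one sample type, features are prevalence-filtered, counts undergo
#' Bayesian-multiplicative zero replacement, the samples are split into
#' stratified training and test sets, and the recursive elimination loop is
#' run and its best model selected.
#'
#' @param table a [feature_table()].
#' @param metadata sample metadata covering the table's samples.
#' @param sample_type restrict to `"saliva"` or `"feces"` samples (`NULL`
#'   keeps everything).
#' @param min_prevalence prevalence-filter threshold (default 10 samples).
#' @param prior zero-replacement prior, see [bm_replace()].
#' @param train_fraction fraction of each occupation assigned to the
#'   training set (default 0.7, i.e. a 28/12 split for 20 + 20 samples).
#' @param n_forests,n_trees forest ensemble size per elimination step.
#' @param seed master seed controlling the split and every forest.
#' @return A list of class `occupation_fit` with `model`
#'   (an `occupation_model`), `trace` (the [rfe()] trace), `split`
#'   (train/test sample ids), `features_used` and the preprocessing
#'   parameters.
#' @export
build_occupation_model <- function(table, metadata, sample_type = NULL,
                                   min_prevalence = 10L, prior = "SQ",
                                   train_fraction = 0.7, n_forests = 100L,
                                   n_trees = 500L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  metadata <- validate_metadata(metadata)
  meta <- metadata[match(sample_ids(table), metadata$sample_id), ,
                   drop = FALSE]
  if (anyNA(meta$sample_id)) stop2("metadata does not cover all samples")
  keep <- meta$gender == "M"
  if (!is.null(sample_type))
    keep <- keep & meta$sample_type == sample_type
  if (sum(keep) < 4L) stop2("fewer than 4 usable samples after filtering")
  meta <- meta[keep, , drop = FALSE]
  counts <- table$counts[, keep, drop = FALSE]
  filt <- prevalence_filter(feature_table(counts, kind = table$kind),
                            min_prevalence)
  comp <- bm_replace(filt, prior = prior)
  x <- t(comp)
  y <- factor(meta$occupation, levels = c("student", "laborer"))
  if (nlevels(droplevels(y)) < 2L)
    stop2("both occupations must be present")

  seeds <- derive_seeds(seed, 3L)
  split <- with_seed(seeds[1L], {
    train_idx <- unlist(lapply(split(seq_along(y), y), function(ii)
      sample(ii, round(train_fraction * length(ii)))))
    sort(train_idx)
  })
  test_idx <- setdiff(seq_along(y), split)
  trace <- rfe(x[split, , drop = FALSE], y[split],
               x[test_idx, , drop = FALSE], y[test_idx],
               n_forests = n_forests, n_trees = n_trees, seed = seeds[2L])
  model <- select_best_model(trace, x[split, , drop = FALSE], y[split],
                             x[test_idx, , drop = FALSE], y[test_idx],
                             seed = seeds[3L])
  structure(list(model = model, trace = trace,
                 split = list(train = rownames(x)[split],
                              test = rownames(x)[test_idx]),
                 features_used = feature_ids(filt),
                 min_prevalence = min_prevalence, prior = prior,
                 train_fraction = train_fraction, seed = seed),
            class = "occupation_fit")
}

#' @export
print.occupation_fit <- function(x, ...) {
  cat("<occupation_fit> ", length(x$features_used), " features after",
      " prevalence filter (>= ", x$min_prevalence, " samples), ",
      length(x$split$train), "/", length(x$split$test),
      " train/test split\n", sep = "")
  print(x$model)
  invisible(x)
}
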