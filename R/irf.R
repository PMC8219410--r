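# The improved random forest (IRF): a bootstrap ensemble of CART trees
# with majority voting, tuned by a coarse-to-fine grid search over
# (n_estimators, max_features, min_samples_leaf) under S-fold
# cross-validation. All randomness fans out from one master seed through
# named substreams, so every result is bit-reproducible.

as_feature_input <- function(features) {
  if (inherits(features, "feature_matrix")) return(features$x)
  if (is.data.frame(features)) return(as.matrix(features))
  if (is.matrix(features)) return(features)
  abort_fmt("features must be a feature_matrix, matrix or data.frame")
}

#' IRF hyperparameters
#'
#' @param n_estimators Number of trees k (positive integer).
#' @param max_features Features drawn (without replacement) at each split
#'   node; must not exceed the total feature count.
#' @param min_samples_leaf Minimum samples in each child of a split.
#' @return A `irf_hyperparams` list.
#' @export
irf_hyperparams <- function(n_estimators = 100, max_features = 4,
                            min_samples_leaf = 1) {
  for (v in list(n_estimators, max_features, min_samples_leaf)) {
    if (!is_count(v)) abort_fmt("hyperparameters must be positive integers")
  }
  structure(list(n_estimators = as.integer(n_estimators),
                 max_features = as.integer(max_features),
                 min_samples_leaf = as.integer(min_samples_leaf)),
            class = "irf_hyperparams")
}

#' @export
print.irf_hyperparams <- function(x, ...) {
  cat(sprintf("<irf_hyperparams> n_estimators=%d, max_features=%d, min_samples_leaf=%d\n",
              x$n_estimators, x$max_features, x$min_samples_leaf))
  invisible(x)
}

#' @export
print.grid_search_result <- function(x, ...) {
  cat(sprintf("<grid_search_result> %d evaluations, best mean CV accuracy %.4f\n",
              nrow(x$trace), x$best_score))
  print(x$best)
  invisible(x)
}

#' Bootstrap sample of indices
#'
#' Draws `n` indices uniformly with replacement from `1..n` (classical
#' bootstrap resampling of a training set of size `n`).
#'
#' @param n Dataset size (>= 1).
#' @param seed Integer seed; the draw is a pure function of `(n, seed)`.
#' @return Integer vector of length `n`.
#' @export
bootstrap_sample <- function(n, seed) {
  if (!is_count(n)) abort_fmt("bootstrap_sample: n must be a positive integer")
  set.seed(seed)
  sample.int(n, n, replace = TRUE)
}

#' Grow one CART tree
#'
#' At each node, `max_features` candidate features are drawn at random
#' without replacement and the (feature, threshold) pair minimizing the
#' Gini impurity of the children is chosen, with thresholds at midpoints
#' between sorted distinct values. Nodes are split until pure or until
#' `min_samples_leaf` forbids a split; there is no pruning. Ties resolve to
#' the lowest feature index, then the smallest threshold.
#'
#' @param features Feature matrix (rows = samples) or `feature_matrix`.
#' @param labels Attention labels (codes 0..4 or names), one per row.
#' @param hp An [irf_hyperparams()].
#' @param seed Integer seed for the per-node feature draws.
#' @param rows Optional training row indices (e.g. a bootstrap sample);
#'   default all rows.
#' @return An `irf_tree` (parallel node arrays).
#' @export
build_tree <- function(features, labels, hp = irf_hyperparams(), seed = 1,
                       rows = NULL) {
  x <- as_feature_input(features)
  y <- as_attention_level(labels)
  if (nrow(x) == 0) abort_fmt("build_tree: empty training data")
  if (length(y) != nrow(x)) abort_fmt("labels do not match feature rows")
  if (hp$max_features > ncol(x)) {
    abort_fmt("max_features (%d) exceeds feature count (%d)",
              hp$max_features, ncol(x))
  }
  if (is.null(rows)) rows <- seq_len(nrow(x))
  set.seed(seed)
  tree <- build_cart_cpp(x, y, 5L, hp$max_features, hp$min_samples_leaf,
                         as.integer(rows) - 1L)
  structure(tree, class = "irf_tree")
}

#' @export
predict.irf_tree <- function(object, newdata, ...) {
  x <- as_feature_input(newdata)
  predict_cart_cpp(object, x)
}

#' Train the bootstrap tree ensemble
#'
#' Fits `hp$n_estimators` CART trees, each on its own bootstrap sample of
#' the training rows and its own random feature-draw stream (the per-tree
#' random states phi_k are derived from `seed` and stored in the model).
#'
#' @inheritParams build_tree
#' @param seed Master seed; training is a pure function of
#'   `(features, labels, hp, seed)`.
#' @return An `irf_forest`.
#' @export
train_forest <- function(features, labels, hp = irf_hyperparams(), seed = 1) {
  x <- as_feature_input(features)
  y <- as_attention_level(labels)
  if (nrow(x) == 0) abort_fmt("train_forest: empty training data")
  if (length(y) != nrow(x)) abort_fmt("labels do not match feature rows")
  if (hp$n_estimators < 1) abort_fmt("n_estimators must be >= 1")
  seeds <- vapply(seq_len(hp$n_estimators),
                  function(i) derive_seed(seed, "tree", i), 1L)
  trees <- vector("list", hp$n_estimators)
  for (i in seq_len(hp$n_estimators)) {
    set.seed(seeds[i])
    rows <- sample.int(nrow(x), nrow(x), replace = TRUE)
    trees[[i]] <- structure(
      build_cart_cpp(x, y, 5L, hp$max_features, hp$min_samples_leaf,
                     as.integer(rows) - 1L),
      class = "irf_tree")
  }
  structure(list(trees = trees, seeds = seeds, classes = 0:4,
                 hyperparams = hp, n_features = ncol(x),
                 feature_names = colnames(x)),
            class = "irf_forest")
}

#' @export
print.irf_forest <- function(x, ...) {
  cat(sprintf("<irf_forest> %d trees, max_features=%d, min_samples_leaf=%d, %d features\n",
              x$hyperparams$n_estimators, x$hyperparams$max_features,
              x$hyperparams$min_samples_leaf, x$n_features))
  invisible(x)
}

forest_votes <- function(model, x) {
  votes <- vapply(model$trees, function(tr) predict_cart_cpp(tr, x),
                  integer(nrow(x)))
  if (nrow(x) == 1) votes <- matrix(votes, nrow = 1)
  votes
}

#' Predict attention levels by majority vote
#'
#' Each tree votes for a class; the ensemble prediction is the class with
#' the most votes, ties broken toward the lower ordinal attention level.
#'
#' @param object An `irf_forest`.
#' @param newdata Feature matrix or `feature_matrix` with the training
#'   feature count.
#' @param ... Unused.
#' @return Integer attention codes (0..4), one per row.
#' @export
predict.irf_forest <- function(object, newdata, ...) {
  x <- as_feature_input(newdata)
  if (ncol(x) != object$n_features) {
    abort_fmt("feature dimension mismatch: model has %d, data has %d",
              object$n_features, ncol(x))
  }
  votes <- forest_votes(object, x)
  apply(votes, 1, function(v) which.max(tabulate(v + 1L, 5L)) - 1L)
}

#' Cross-validation plan
#'
#' Randomly partitions `1..n` into `S` disjoint folds whose union covers
#' all indices and whose sizes differ by at most one.
#'
#' @param n Number of samples.
#' @param S Fold count, `2 <= S <= n`.
#' @param seed Integer seed for the shuffle.
#' @return A `cv_plan`: list with `S`, `n`, and `folds` (list of index
#'   vectors).
#' @export
make_cv_plan <- function(n, S = 10, seed = 1) {
  if (!is_count(n)) abort_fmt("n must be a positive integer")
  if (!is_count(S) || S < 2 || S > n) {
    abort_fmt("fold count S must satisfy 2 <= S <= n (n=%d, S=%s)", n,
              paste(S, collapse = ","))
  }
  set.seed(derive_seed(seed, "cvplan"))
  perm <- sample.int(n)
  sizes <- rep(n %/% S, S)
  if (n %% S > 0) sizes[seq_len(n %% S)] <- sizes[seq_len(n %% S)] + 1L
  ends <- cumsum(sizes)
  starts <- c(1L, head(ends, -1) + 1L)
  folds <- lapply(seq_len(S), function(i) sort(perm[starts[i]:ends[i]]))
  structure(list(S = S, n = n, folds = folds), class = "cv_plan")
}

#' S-fold cross-validation of the forest
#'
#' For each fold, trains on the remaining folds and scores accuracy on the
#' held-out fold.
#'
#' @inheritParams build_tree
#' @param plan A [make_cv_plan()] over the data rows.
#' @param seed Master seed; each fold trains with its own derived seed.
#' @return List with `accuracies` (length S) and `mean_accuracy`.
#' @export
cross_validate <- function(features, labels, hp = irf_hyperparams(),
                           plan, seed = 1) {
  x <- as_feature_input(features)
  y <- as_attention_level(labels)
  if (plan$n != nrow(x)) {
    abort_fmt("cv plan covers %d rows but data has %d", plan$n, nrow(x))
  }
  acc <- numeric(plan$S)
  for (i in seq_len(plan$S)) {
    test <- plan$folds[[i]]
    if (length(test) == 0) abort_fmt("fold %d is empty", i)
    train <- setdiff(seq_len(nrow(x)), test)
    model <- train_forest(x[train, , drop = FALSE], y[train], hp,
                          seed = derive_seed(seed, "fold", i))
    pred <- predict(model, x[test, , drop = FALSE])
    acc[i] <- mean(pred == y[test])
  }
  list(accuracies = acc, mean_accuracy = mean(acc))
}

#' Default coarse hyperparameter grid
#'
#' n_estimators 50..300 by 50, max_features 2..20 by 2 (capped at the
#' feature count), min_samples_leaf {1, 3, 5, 9}.
#'
#' @param n_features Total feature count X (caps max_features).
#' @return Named list of candidate vectors.
#' @export
default_irf_grid <- function(n_features = 20) {
  list(n_estimators = seq(50L, 300L, by = 50L),
       max_features = seq(2L, min(20L, n_features), by = 2L),
       min_samples_leaf = c(1L, 3L, 5L, 9L))
}

hp_key <- function(k, x, m) sprintf("%d_%d_%d", k, x, m)

grid_points <- function(grid) {
  expand.grid(n_estimators = grid$n_estimators,
              max_features = grid$max_features,
              min_samples_leaf = grid$min_samples_leaf,
              KEEP.OUT.ATTRS = FALSE)
}

# incumbent under the complexity tie-break: best score, then smallest
# n_estimators, max_features, min_samples_leaf
best_trace_row <- function(trace) {
  ord <- order(-trace$score, trace$n_estimators, trace$max_features,
               trace$min_samples_leaf)
  trace[ord[1], , drop = FALSE]
}

#' Coarse-to-fine grid search
#'
#' Phase 1 evaluates the mean cross-validated accuracy at every point of
#' the coarse grid. Each subsequent phase re-grids a +/- one-step
#' neighborhood of the incumbent with step `refine_step` (default 2) and
#' evaluates all of its points. Every hyperparameter point is scored with
#' a seed derived from the point itself, so scores do not depend on
#' evaluation order and repeated points score identically. Among equally
#' scoring points the one with the smallest complexity key
#' (n_estimators, then max_features, then min_samples_leaf) wins.
#'
#' @inheritParams cross_validate
#' @param coarse_grid Named list of candidate integer vectors
#'   (`n_estimators`, `max_features`, `min_samples_leaf`).
#' @param refine_step Step size of the refinement phases (default 2).
#' @param phases Total number of phases including the coarse pass
#'   (default 2).
#' @return A `grid_search_result`: list with `best` ([irf_hyperparams()]),
#'   `best_score`, and `trace` (data.frame of every evaluation in order,
#'   with its phase).
#' @export
grid_search <- function(features, labels, coarse_grid = NULL,
                        refine_step = 2, plan, seed = 1, phases = 2) {
  x <- as_feature_input(features)
  y <- as_attention_level(labels)
  if (is.null(coarse_grid)) coarse_grid <- default_irf_grid(ncol(x))
  for (nm in c("n_estimators", "max_features", "min_samples_leaf")) {
    if (length(coarse_grid[[nm]]) == 0) {
      abort_fmt("empty grid for %s", nm)
    }
  }
  if (!is_count(refine_step)) abort_fmt("refine_step must be >= 1")
  coarse_grid <- lapply(coarse_grid, function(v) sort(unique(as.integer(v))))
  cache <- new.env(parent = emptyenv())

  score_point <- function(k, xf, m) {
    key <- hp_key(k, xf, m)
    if (!is.null(cache[[key]])) return(cache[[key]])
    hp <- irf_hyperparams(k, xf, m)
    s <- cross_validate(x, y, hp, plan,
                        seed = derive_seed(seed, "grid", k, xf, m))$mean_accuracy
    cache[[key]] <- s
    s
  }

  eval_grid <- function(pts, phase, trace) {
    for (r in seq_len(nrow(pts))) {
      sc <- score_point(pts$n_estimators[r], pts$max_features[r],
                        pts$min_samples_leaf[r])
      trace <- rbind(trace, data.frame(
        n_estimators = pts$n_estimators[r],
        max_features = pts$max_features[r],
        min_samples_leaf = pts$min_samples_leaf[r],
        score = sc, phase = phase))
    }
    trace
  }

  trace <- data.frame()
  trace <- eval_grid(grid_points(coarse_grid), 1L, trace)

  grid_step <- vapply(coarse_grid,
                      function(v) if (length(v) > 1) min(diff(v)) else 0L, 1L)
  upper <- c(n_estimators = .Machine$integer.max,
             max_features = ncol(x), min_samples_leaf = .Machine$integer.max)
  win <- grid_step
  for (ph in seq_len(phases - 1)) {
    inc <- best_trace_row(trace)
    fine <- list()
    for (nm in names(coarse_grid)) {
      center <- inc[[nm]]
      if (win[[nm]] == 0) {
        fine[[nm]] <- center
      } else {
        cand <- seq(center - win[[nm]], center + win[[nm]], by = refine_step)
        cand <- unique(pmin(pmax(as.integer(cand), 1L), upper[[nm]]))
        fine[[nm]] <- sort(cand)
      }
    }
    trace <- eval_grid(grid_points(fine), ph + 1L, trace)
    win[] <- ifelse(win > 0, refine_step, 0L)  # shrink window if iterating
  }

  inc <- best_trace_row(trace)
  structure(list(
    best = irf_hyperparams(inc$n_estimators, inc$max_features,
                           inc$min_samples_leaf),
    best_score = inc$score,
    trace = trace), class = "grid_search_result")
}

#' Train the improved random forest end to end
#'
#' Runs the coarse-to-fine grid search under an S-fold cross-validation
#' plan (default 10-fold) and refits a final forest on the full training
#' set with the winning hyperparameters.
#'
#' @inheritParams grid_search
#' @param folds Fold count S (default 10).
#' @return List with `model` (`irf_forest`) and `search`
#'   (`grid_search_result`).
#' @export
train_irf <- function(features, labels, coarse_grid = NULL, folds = 10,
                      refine_step = 2, phases = 2, seed = 1) {
  x <- as_feature_input(features)
  if (nrow(x) < folds) {
    abort_fmt("only %d samples for %d-fold cross-validation; use a smaller S",
              nrow(x), folds)
  }
  plan <- make_cv_plan(nrow(x), folds, seed = derive_seed(seed, "cv"))
  search <- grid_search(features, labels, coarse_grid = coarse_grid,
                        refine_step = refine_step, plan = plan,
                        seed = derive_seed(seed, "search"), phases = phases)
  model <- train_forest(features, labels, search$best,
                        seed = derive_seed(seed, "final"))
  list(model = model, search = search)
}

#' Serialize a forest model to versioned JSON
#'
#' @param model An `irf_forest`.
#' @param path Output path.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "irf_forest"))
  payload <- list(
    format = "attneeg-irf",
    version = 1L,
    hyperparams = unclass(model$hyperparams),
    classes = model$classes,
    seeds = model$seeds,
    n_features = model$n_features,
    feature_names = model$feature_names,
    trees = lapply(model$trees, unclass))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a forest model written by [write_model()]
#' @param path JSON model path.
#' @return An `irf_forest` giving identical predictions to the original.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort_fmt("file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(p$format, "attneeg-irf")) {
    abort_fmt("not an attneeg IRF model file: %s", path)
  }
  trees <- lapply(p$trees, function(tr) {
    structure(list(feature = vapply(tr$feature, as.integer, 1L),
                   threshold = vapply(tr$threshold, as.numeric, 1),
                   left = vapply(tr$left, as.integer, 1L),
                   right = vapply(tr$right, as.integer, 1L),
                   klass = vapply(tr$klass, as.integer, 1L)),
              class = "irf_tree")
  })
  structure(list(trees = trees,
                 seeds = vapply(p$seeds, as.integer, 1L),
                 classes = vapply(p$classes, as.integer, 1L),
                 hyperparams = irf_hyperparams(p$hyperparams$n_estimators,
                                               p$hyperparams$max_features,
                                               p$hyperparams$min_samples_leaf),
                 n_features = as.integer(p$n_features),
                 feature_names = unlist(p$feature_names)),
            class = "irf_forest")
}
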