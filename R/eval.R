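# Evaluation: confusion matrices, accuracy / macro recall / macro
# precision, a classifier comparison harness on shared folds, and a paired
# t-test for per-fold accuracy differences.

#' Confusion matrix over the five attention classes
#'
#' @param true_labels,pred_labels Equal-length label vectors (codes 0..4 or
#'   names).
#' @return 5x5 integer matrix; entry (i, j) counts samples of true class i
#'   predicted as class j. Dimnames are the level names.
#' @export
confusion_matrix <- function(true_labels, pred_labels) {
  t_ <- as_attention_level(true_labels)
  p_ <- as_attention_level(pred_labels)
  if (length(t_) != length(p_)) {
    abort_fmt("label vectors differ in length (%d vs %d)", length(t_), length(p_))
  }
  if (length(t_) == 0) abort_fmt("empty label vectors")
  lv <- attention_levels()
  cm <- matrix(0L, 5, 5, dimnames = list(true = lv, predicted = lv))
  for (i in seq_along(t_)) {
    cm[t_[i] + 1L, p_[i] + 1L] <- cm[t_[i] + 1L, p_[i] + 1L] + 1L
  }
  cm
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is trace/total. Recall and precision are macro-averaged
#' (unweighted class means); classes whose denominator is zero contribute
#' zero and are reported in `undefined_classes`. `one_minus_accuracy` is
#' reported as a convenience error rate; it is not any published "loss".
#'
#' @param confusion Square count matrix (as from [confusion_matrix()]).
#' @return A `metric_report`: list with `accuracy`, `macro_recall`,
#'   `macro_precision`, `one_minus_accuracy`, `per_class` (data.frame),
#'   `undefined_classes`, `confusion`.
#' @export
metrics <- function(confusion) {
  cm <- as.matrix(confusion)
  if (nrow(cm) != ncol(cm)) abort_fmt("confusion matrix must be square")
  if (is.null(rownames(cm))) {
    rownames(cm) <- colnames(cm) <- paste0("class", seq_len(nrow(cm)) - 1)
  }
  total <- sum(cm)
  if (total == 0) abort_fmt("confusion matrix is empty (all zero)")
  tp <- diag(cm)
  row_tot <- rowSums(cm)   # true counts per class
  col_tot <- colSums(cm)   # predicted counts per class
  recall <- ifelse(row_tot > 0, tp / row_tot, 0)
  precision <- ifelse(col_tot > 0, tp / col_tot, 0)
  undefined <- union(rownames(cm)[row_tot == 0], colnames(cm)[col_tot == 0])
  structure(list(
    accuracy = sum(tp) / total,
    macro_recall = mean(recall),
    macro_precision = mean(precision),
    one_minus_accuracy = 1 - sum(tp) / total,
    per_class = data.frame(class = rownames(cm), recall = recall,
                           precision = precision, row.names = NULL),
    undefined_classes = undefined,
    confusion = cm), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("accuracy %.4f | macro recall %.4f | macro precision %.4f\n",
              x$accuracy, x$macro_recall, x$macro_precision))
  invisible(x)
}

#' Seeded 70/30 holdout split
#'
#' @param n Number of samples.
#' @param train_fraction Training share (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` index vectors.
#' @export
holdout_split <- function(n, train_fraction = 0.7, seed = 1) {
  if (!is_count(n) || n < 2) abort_fmt("need at least 2 samples to split")
  if (train_fraction <= 0 || train_fraction >= 1) {
    abort_fmt("train_fraction must be in (0, 1)")
  }
  set.seed(derive_seed(seed, "holdout"))
  train <- sort(sample.int(n, round(n * train_fraction)))
  list(train = train, test = setdiff(seq_len(n), train))
}

# --- baseline classifiers for the comparison harness -----------------------

# k-nearest-neighbour baseline (Euclidean, majority vote, ties -> lower class)
knn_predict <- function(x_train, y_train, x_test, k = 5) {
  k <- min(k, nrow(x_train))
  apply(x_test, 1, function(row) {
    d <- sqrt(colSums((t(x_train) - row)^2))
    nn <- order(d)[seq_len(k)]
    which.max(tabulate(y_train[nn] + 1L, 5L)) - 1L
  })
}

classifier_fun <- function(spec, seed) {
  name <- if (is.list(spec)) spec$type else spec
  params <- if (is.list(spec)) spec else list()
  switch(
    name,
    irf = function(x_tr, y_tr, x_te, fold) {
      hp <- if (!is.null(params$hp)) params$hp else
        irf_hyperparams(100, max(1L, min(4L, ncol(x_tr))), 1)
      m <- train_forest(x_tr, y_tr, hp, seed = derive_seed(seed, "irf", fold))
      predict(m, x_te)
    },
    knn = function(x_tr, y_tr, x_te, fold) {
      knn_predict(x_tr, y_tr, x_te,
                  k = if (!is.null(params$k)) params$k else 5)
    },
    lda = function(x_tr, y_tr, x_te, fold) {
      if (!requireNamespace("MASS", quietly = TRUE)) {
        abort_fmt("classifier 'lda' requires the MASS package")
      }
      keep <- apply(x_tr, 2, function(v) stats::sd(v) > 0)
      fit <- MASS::lda(x_tr[, keep, drop = FALSE], grouping = factor(y_tr, levels = 0:4))
      as.integer(as.character(predict(fit, x_te[, keep, drop = FALSE])$class))
    },
    dummy = function(x_tr, y_tr, x_te, fold) {
      maj <- which.max(tabulate(y_tr + 1L, 5L)) - 1L
      rep(maj, nrow(x_te))
    },
    abort_fmt("unknown classifier spec '%s' (known: irf, knn, lda, dummy)", name)
  )
}

#' Compare classifiers on identical cross-validation folds
#'
#' Every classifier sees byte-identical folds (the shared `plan`; its hash
#' is logged in the result) so per-fold accuracies are paired and can be
#' fed to [paired_ttest()]. Baselines: `knn` (built-in k-NN), `lda`
#' (MASS), `dummy` (majority class). `irf` is this package's own forest.
#'
#' @param features Feature matrix or `feature_matrix`.
#' @param labels Attention labels.
#' @param classifier_specs Character vector of spec names, or a named list
#'   of lists with a `type` field and parameters (e.g.
#'   `list(irf = list(type = "irf", hp = irf_hyperparams(50, 4, 1)))`).
#' @param plan A [make_cv_plan()].
#' @param seed Master seed for classifiers that train stochastically.
#' @return A `classifier_comparison`: data.frame with one row per
#'   classifier (mean and sd of fold accuracies), with the per-fold
#'   accuracy matrix in attribute `"fold_accuracies"` and the fold hash in
#'   attribute `"fold_hash"`.
#' @export
compare_classifiers <- function(features, labels, classifier_specs, plan,
                                seed = 1) {
  x <- as_feature_input(features)
  y <- as_attention_level(labels)
  if (length(classifier_specs) < 2) {
    abort_fmt("need at least two classifier specs to compare")
  }
  specs <- classifier_specs
  if (is.character(specs)) {
    specs <- stats::setNames(as.list(specs), specs)
  }
  # resolve every spec before any training so unknown names fail fast
  fns <- lapply(specs, classifier_fun, seed = seed)
  fold_acc <- matrix(NA_real_, nrow = length(specs), ncol = plan$S,
                     dimnames = list(names(specs), NULL))
  for (si in seq_along(specs)) {
    fn <- fns[[si]]
    for (fi in seq_len(plan$S)) {
      test <- plan$folds[[fi]]
      train <- setdiff(seq_len(nrow(x)), test)
      pred <- fn(x[train, , drop = FALSE], y[train],
                 x[test, , drop = FALSE], fi)
      fold_acc[si, fi] <- mean(pred == y[test])
    }
  }
  out <- data.frame(classifier = names(specs),
                    mean_accuracy = rowMeans(fold_acc),
                    sd_accuracy = apply(fold_acc, 1, stats::sd),
                    row.names = NULL)
  attr(out, "fold_accuracies") <- fold_acc
  attr(out, "fold_hash") <- fold_hash(plan$folds)
  class(out) <- c("classifier_comparison", "data.frame")
  out
}

#' Paired two-sided t-test on accuracy vectors
#'
#' Standard paired t on per-fold (or per-subject) accuracies. With all
#' differences equal to zero, t = 0 and p = 1; with a nonzero constant
#' difference (zero variance) the statistic diverges and p is reported as
#' the machine floor, flagged `degenerate`.
#'
#' @param acc_a,acc_b Equal-length numeric vectors, length >= 2.
#' @return List with `statistic`, `p_value`, `df`, `mean_diff`,
#'   `degenerate`.
#' @export
paired_ttest <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b)) {
    abort_fmt("accuracy vectors differ in length (%d vs %d)",
              length(acc_a), length(acc_b))
  }
  n <- length(acc_a)
  if (n < 2) abort_fmt("paired t-test needs at least 2 pairs")
  d <- acc_a - acc_b
  md <- mean(d)
  s <- sd(d)
  if (s == 0) {
    if (md == 0) {
      return(list(statistic = 0, p_value = 1, df = n - 1, mean_diff = 0,
                  degenerate = FALSE))
    }
    return(list(statistic = sign(md) * Inf,
                p_value = .Machine$double.xmin, df = n - 1, mean_diff = md,
                degenerate = TRUE))
  }
  t_stat <- md / (s / sqrt(n))
  list(statistic = t_stat, p_value = 2 * pt(-abs(t_stat), df = n - 1),
       df = n - 1, mean_diff = md, degenerate = FALSE)
}
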