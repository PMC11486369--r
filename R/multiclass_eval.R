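#' @title Multiclass evaluation harness
#'
#' @description
#' Hold-out plus stratified k-fold protocol for the three-class problem:
#' a seeded, class-proportional 30% hold-out reserved before any
#' training; stratified shuffled k-fold cross-validation with
#' standardization re-fitted inside every fold; exhaustive grid search
#' scored by mean CV accuracy; evaluation with per-class, micro- and
#' macro-averaged ROC AUC; and the robustness probes (recursive feature
#' elimination, learning curve, additive-noise sweep, k-sweep).
#'
#' @name multiclass_eval
NULL

#' Split/CV plan
#'
#' @param test_fraction hold-out fraction in (0, 1) (default 0.30).
#' @param k_folds folds for cross-validation (default 10).
#' @param seed shuffle seed.
#' @param stratified keep class proportions (default TRUE).
#' @return a `split_plan` list.
#' @export
split_plan <- function(test_fraction = 0.30, k_folds = 10L, seed = 1L,
                       stratified = TRUE) {
  if (test_fraction <= 0 || test_fraction >= 1)
    abort_input("test_fraction must be in (0, 1)")
  if (k_folds < 2) abort_input("k_folds must be >= 2")
  structure(list(test_fraction = test_fraction, k_folds = as.integer(k_folds),
                 seed = seed, stratified = stratified),
            class = "split_plan")
}

# Accept a feature_dataset, a list(features, labels), or a data.frame with
# a `label` column; return list(x = matrix, y = factor).
as_xy <- function(dataset) {
  if (inherits(dataset, "feature_dataset"))
    return(list(x = dataset$features, y = dataset$labels))
  if (is.data.frame(dataset)) {
    if (!"label" %in% names(dataset))
      abort_input("data.frame dataset needs a 'label' column")
    y <- factor(dataset$label)
    x <- as.matrix(dataset[setdiff(names(dataset), "label")])
    return(list(x = x, y = y))
  }
  if (is.list(dataset) && !is.null(dataset$features))
    return(list(x = as.matrix(dataset$features), y = factor(dataset$labels)))
  if (is.list(dataset) && !is.null(dataset$x))
    return(list(x = as.matrix(dataset$x), y = factor(dataset$y)))
  abort_input("unsupported dataset type")
}

#' Stratified hold-out split
#'
#' Reserves a class-proportional test set before any training. On a
#' balanced 600-row, 3-class set at fraction 0.30 this reserves exactly
#' 180 rows, 60 per class.
#'
#' @param dataset a `feature_dataset`, list with `features`/`labels`,
#'   or data.frame with a `label` column.
#' @param plan a [split_plan()].
#' @return list with `train` and `test`, each `list(x, y)`, plus the
#'   row indices used.
#' @export
holdout_split <- function(dataset, plan = split_plan()) {
  d <- as_xy(dataset)
  tab <- table(d$y)
  if (any(tab < 2)) abort_input("every class needs >= 2 instances")
  test_idx <- with_seed(plan$seed, {
    if (plan$stratified) {
      unlist(lapply(levels(d$y), function(cl) {
        rows <- which(d$y == cl)
        sample(rows, round(plan$test_fraction * length(rows)))
      }))
    } else {
      sample(seq_along(d$y), round(plan$test_fraction * length(d$y)))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(d$y), test_idx)
  list(train = list(x = d$x[train_idx, , drop = FALSE],
                    y = droplevels(d$y[train_idx])),
       test = list(x = d$x[test_idx, , drop = FALSE],
                   y = droplevels(d$y[test_idx])),
       train_idx = train_idx, test_idx = test_idx)
}

#' Standardize features (fit on train, apply to both)
#'
#' Rescales every feature to mean zero and standard deviation one using
#' the population (divide-by-n) convention, with parameters estimated on
#' the training set only. Zero-variance training features pass through
#' unscaled with a warning.
#'
#' @param train_x,test_x numeric matrices (test may be NULL).
#' @return list with `train`, `test`, and the fitted `center`/`scale`.
#' @export
standardize <- function(train_x, test_x = NULL) {
  if (nrow(train_x) == 0) abort_input("empty training set")
  center <- colMeans(train_x)
  scale_ <- sqrt(colMeans(sweep(train_x, 2, center)^2))
  zero <- scale_ == 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance feature(s) left unscaled")
    scale_[zero] <- 1
    center[zero] <- 0
  }
  app <- function(m) sweep(sweep(m, 2, center), 2, scale_, "/")
  list(train = app(train_x),
       test = if (!is.null(test_x)) app(test_x) else NULL,
       center = center, scale = scale_)
}

# Stratified shuffled fold assignment: vector of fold ids per row.
make_folds <- function(y, k, seed) {
  if (k > min(table(y)))
    abort_input("k = ", k, " exceeds the smallest class count (",
                min(table(y)), ")")
  folds <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      rows <- sample(which(y == cl))
      folds[rows] <- rep_len(seq_len(k), length(rows))
    }
  })
  folds
}

# Confusion-derived metrics. `conf` rows = truth, cols = predicted.
confusion_metrics <- function(conf) {
  n <- sum(conf)
  support <- rowSums(conf)
  tp <- diag(conf)
  prec_c <- ifelse(colSums(conf) > 0, tp / colSums(conf), 0)
  rec_c <- ifelse(support > 0, tp / support, 0)
  list(accuracy = sum(tp) / n,
       precision = sum(prec_c * support) / n, # weighted by true support
       recall = sum(rec_c * support) / n,
       per_class_precision = prec_c, per_class_recall = rec_c)
}

# One-vs-rest AUC of `score` for membership in `positive`.
binary_auc <- function(truth01, score) {
  r <- pROC::roc(truth01, score, levels = c(0, 1), direction = "<",
                 quiet = TRUE)
  as.numeric(pROC::auc(r))
}

# Per-class / micro / macro AUC from a score matrix.
multiclass_auc <- function(y, scores) {
  lev <- colnames(scores)
  per <- vapply(lev, function(cl)
    binary_auc(as.integer(y == cl), scores[, cl]), numeric(1))
  pooled_truth <- as.vector(vapply(lev, function(cl) as.integer(y == cl),
                                   integer(length(y))))
  micro <- binary_auc(pooled_truth, as.vector(scores))
  list(per_class = per, micro = micro, macro = mean(per))
}

#' Stratified k-fold cross-validation at fixed hyperparameters
#'
#' Folds are stratified and shuffled by the plan's seed; standardization
#' is re-fitted inside every fold (no leakage). Reports per-fold
#' accuracy, weighted precision/recall and macro AUC with mean and sd.
#'
#' @param spec a [model_spec()].
#' @param params hyperparameters as a named list (NULL for defaults/NB).
#' @param train `list(x, y)` as produced by [holdout_split()].
#' @param plan a [split_plan()].
#' @return list with `folds` (per-fold data.frame), `mean`, `sd`.
#' @export
cross_validate <- function(spec, params = NULL, train, plan = split_plan()) {
  y <- droplevels(as.factor(train$y))
  folds <- make_folds(y, plan$k_folds, plan$seed)
  rows <- lapply(seq_len(plan$k_folds), function(f) {
    tr <- folds != f
    st <- standardize(train$x[tr, , drop = FALSE],
                      train$x[!tr, , drop = FALSE])
    mod <- fit_classifier(spec, params, st$train, y[tr],
                          seed = derive_seed(plan$seed, f))
    sc <- predict_scores(mod, st$test)
    pred <- factor(mod$levels[max.col(sc, ties.method = "first")],
                   levels = levels(y))
    conf <- table(truth = y[!tr], pred = pred)
    met <- confusion_metrics(conf)
    auc <- multiclass_auc(y[!tr], sc)
    data.frame(fold = f, accuracy = met$accuracy, precision = met$precision,
               recall = met$recall, macro_auc = auc$macro)
  })
  tab <- do.call(rbind, rows)
  list(folds = tab,
       mean = colMeans(tab[, -1]),
       sd = apply(tab[, -1], 2, stats::sd))
}

#' Exhaustive grid search scored by mean CV accuracy
#'
#' Every grid point is scored with [cross_validate()]; ties are broken
#' by first-in-grid order. The winner is refit on the full training set
#' (standardized on all of train) and returned as a deployable bundle.
#'
#' @param spec a [model_spec()].
#' @param train `list(x, y)`.
#' @param plan a [split_plan()].
#' @return list with `best_params`, `cv_table`, `model`, `transform`
#'   (the fitted standardizer), `cv_best` (the winner's CV summary).
#' @export
grid_search <- function(spec, train, plan = split_plan()) {
  grid <- if (length(spec$grid) == 0) data.frame(.dummy = 1)
          else expand.grid(spec$grid, stringsAsFactors = FALSE)
  scores <- numeric(nrow(grid))
  cvs <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    params <- as.list(grid[i, , drop = FALSE])
    cvs[[i]] <- cross_validate(spec, params, train, plan)
    scores[i] <- cvs[[i]]$mean[["accuracy"]]
  }
  best <- which.max(scores) # which.max returns the first maximum
  best_params <- as.list(grid[best, , drop = FALSE])
  st <- standardize(train$x)
  model <- fit_classifier(spec, best_params, st$train,
                          droplevels(as.factor(train$y)),
                          seed = derive_seed(plan$seed, 0L))
  list(best_params = best_params,
       cv_table = cbind(grid, cv_accuracy = scores),
       cv_best = cvs[[best]],
       model = model,
       transform = st)
}

#' Evaluate a fitted bundle on a hold-out set
#'
#' Applies the already-fitted standardizer, scores the test set, and
#' reports accuracy, weighted precision/recall, the confusion matrix,
#' per-class one-vs-rest ROC AUC, the micro average (pooling all
#' class-instance decisions) and the macro average (unweighted mean of
#' per-class AUCs), plus per-class ROC curve points.
#'
#' @param bundle a [grid_search()] result (or any list with `model` and
#'   `transform`).
#' @param test `list(x, y)`.
#' @return an `evaluation_report` list.
#' @export
evaluate <- function(bundle, test) {
  st <- bundle$transform
  x <- sweep(sweep(test$x, 2, st$center), 2, st$scale, "/")
  y <- factor(test$y, levels = bundle$model$levels)
  scores <- predict_scores(bundle$model, x)
  pred <- factor(bundle$model$levels[max.col(scores, ties.method = "first")],
                 levels = bundle$model$levels)
  conf <- table(truth = y, pred = pred)
  met <- confusion_metrics(conf)
  auc <- multiclass_auc(y, scores)
  curves <- lapply(colnames(scores), function(cl) {
    r <- pROC::roc(as.integer(y == cl), scores[, cl], levels = c(0, 1),
                   direction = "<", quiet = TRUE)
    data.frame(fpr = rev(1 - r$specificities), tpr = rev(r$sensitivities))
  })
  names(curves) <- colnames(scores)
  structure(list(accuracy = met$accuracy, precision = met$precision,
                 recall = met$recall, per_class_auc = auc$per_class,
                 micro_auc = auc$micro, macro_auc = auc$macro,
                 confusion = conf, roc_curves = curves, scores = scores),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> accuracy %.3f, precision %.3f, recall %.3f\n",
    x$accuracy, x$precision, x$recall))
  cat(sprintf("  macro AUC %.3f, micro AUC %.3f; per class: %s\n",
              x$macro_auc, x$micro_auc,
              paste(sprintf("%s %.3f", names(x$per_class_auc),
                            x$per_class_auc), collapse = ", ")))
  invisible(x)
}

#' Recursive feature elimination with a linear SVM
#'
#' Repeatedly drops the `step` features with the smallest aggregated
#' absolute linear-SVM weight, recording the stratified-CV accuracy at
#' every feature count; the selected count maximizes accuracy, with ties
#' resolved toward fewer features.
#'
#' @param train `list(x, y)`.
#' @param plan a [split_plan()].
#' @param step features removed per iteration (default 10).
#' @param cost linear-SVM cost parameter.
#' @return list with `curve` (data.frame n_features/cv_accuracy),
#'   `selected` (feature names at the best count), `best_n`.
#' @export
recursive_feature_elimination <- function(train, plan = split_plan(),
                                          step = 10L, cost = 1) {
  p <- ncol(train$x)
  if (step >= p) abort_input("step must be smaller than the feature count")
  spec <- model_spec("SVM", grid = list(kernel = "linear", cost = cost))
  params <- list(kernel = "linear", cost = cost)
  y <- droplevels(as.factor(train$y))
  current <- colnames(train$x) %||% as.character(seq_len(p))
  colnames(train$x) <- current
  curve <- list()
  sets <- list()
  repeat {
    xs <- train$x[, current, drop = FALSE]
    cv <- cross_validate(spec, params, list(x = xs, y = y), plan)
    curve[[length(curve) + 1L]] <-
      data.frame(n_features = length(current),
                 cv_accuracy = cv$mean[["accuracy"]])
    sets[[length(sets) + 1L]] <- current
    if (length(current) <= step) break
    st <- standardize(xs)
    mod <- fit_classifier(spec, params, st$train, y,
                          seed = derive_seed(plan$seed, length(current)))
    w <- linear_svm_weights(mod)
    current <- current[order(w, decreasing = TRUE)][
      seq_len(length(current) - step)]
  }
  curve <- do.call(rbind, curve)
  best_acc <- max(curve$cv_accuracy)
  # ties -> fewest features (curve is ordered from most to fewest)
  cand <- which(curve$cv_accuracy >= best_acc - 1e-12)
  best_row <- cand[which.min(curve$n_features[cand])]
  list(curve = curve, selected = sets[[best_row]],
       best_n = curve$n_features[best_row])
}

#' Learning curve over stratified subsample sizes
#'
#' For each training fraction, fits the model on a seeded stratified
#' subsample of the training set and records accuracy on that subsample
#' and on the fixed hold-out test set. Duplicate sizes are dropped;
#' sizes leaving fewer than two instances in some class are skipped
#' with a warning.
#'
#' @param spec a [model_spec()].
#' @param params hyperparameters (named list).
#' @param train,test `list(x, y)`.
#' @param plan a [split_plan()].
#' @param sizes fractions of the training set in (0, 1].
#' @return data.frame with `size`, `n_train`, `train_accuracy`,
#'   `test_accuracy`.
#' @export
learning_curve <- function(spec, params = NULL, train, test,
                           plan = split_plan(),
                           sizes = seq(0.2, 1.0, by = 0.2)) {
  if (any(sizes <= 0 | sizes > 1)) abort_input("sizes must be in (0, 1]")
  sizes <- sort(unique(sizes))
  y <- droplevels(as.factor(train$y))
  rows <- list()
  for (s in sizes) {
    idx <- with_seed(derive_seed(plan$seed, round(1000 * s)), {
      unlist(lapply(levels(y), function(cl) {
        r <- which(y == cl)
        sample(r, max(1L, round(s * length(r))))
      }))
    })
    if (min(table(y[idx])) < 2) {
      warning("size ", s, " leaves a class with < 2 instances; skipped")
      next
    }
    st <- standardize(train$x[idx, , drop = FALSE], test$x)
    mod <- fit_classifier(spec, params, st$train, y[idx],
                          seed = derive_seed(plan$seed, round(1e6 * s)))
    tr_acc <- mean(predict_labels(mod, st$train) == y[idx])
    te_acc <- mean(predict_labels(mod, st$test) ==
                     factor(test$y, levels = mod$levels))
    rows[[length(rows) + 1L]] <-
      data.frame(size = s, n_train = length(idx),
                 train_accuracy = tr_acc, test_accuracy = te_acc)
  }
  do.call(rbind, rows)
}

#' Additive-noise robustness sweep
#'
#' Adds seeded Gaussian noise of increasing mean (fixed sd, default 0.1)
#' to the raw hold-out features, re-applies the already-fitted
#' standardizer, and re-evaluates. The default sweep runs the noise
#' mean from 0 to 1.5.
#'
#' @param bundle a [grid_search()] result.
#' @param test `list(x, y)` with raw (unstandardized) features.
#' @param means noise means to sweep.
#' @param sd noise standard deviation (default 0.1).
#' @param seed integer seed.
#' @return data.frame with `noise_mean`, `accuracy`, `macro_auc`.
#' @export
noise_robustness <- function(bundle, test, means = seq(0, 1.5, by = 0.25),
                             sd = 0.1, seed = 1L) {
  if (sd < 0) abort_input("sd must be >= 0")
  rows <- lapply(seq_along(means), function(k) {
    noisy <- test
    noisy$x <- test$x + with_seed(derive_seed(seed, k), {
      matrix(stats::rnorm(length(test$x), means[k], sd),
             nrow(test$x), ncol(test$x))
    })
    rep_ <- evaluate(bundle, noisy)
    data.frame(noise_mean = means[k], accuracy = rep_$accuracy,
               macro_auc = rep_$macro_auc)
  })
  do.call(rbind, rows)
}

#' Cross-validation stability across fold counts
#'
#' Re-runs stratified CV at each `k` and, alongside, reports fixed
#' hold-out metrics of the model refit on the full training set.
#' Infeasible fold counts (k exceeding the smallest class) are skipped
#' with a warning.
#'
#' @param spec a [model_spec()].
#' @param params hyperparameters.
#' @param train,test `list(x, y)`.
#' @param plan a [split_plan()] (its k is ignored in favor of `ks`).
#' @param ks fold counts to try (default 2, 3, 5, 10, 15).
#' @return data.frame with one row per feasible k.
#' @export
k_sweep <- function(spec, params = NULL, train, test, plan = split_plan(),
                    ks = c(2L, 3L, 5L, 10L, 15L)) {
  st <- standardize(train$x)
  mod <- fit_classifier(spec, params, st$train,
                        droplevels(as.factor(train$y)),
                        seed = derive_seed(plan$seed, 0L))
  bundle <- list(model = mod, transform = st)
  test_rep <- evaluate(bundle, test)
  rows <- list()
  for (k in ks) {
    if (k < 2 || k > min(table(train$y))) {
      warning("k = ", k, " infeasible; skipped")
      next
    }
    pk <- plan
    pk$k_folds <- as.integer(k)
    cv <- cross_validate(spec, params, train, pk)
    rows[[length(rows) + 1L]] <- data.frame(
      k = k,
      cv_accuracy = cv$mean[["accuracy"]], cv_accuracy_sd = cv$sd[["accuracy"]],
      cv_macro_auc = cv$mean[["macro_auc"]], cv_macro_auc_sd = cv$sd[["macro_auc"]],
      test_accuracy = test_rep$accuracy, test_macro_auc = test_rep$macro_auc)
  }
  do.call(rbind, rows)
}
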