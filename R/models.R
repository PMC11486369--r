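#' @title Classifier families and hyperparameter grids
#'
#' @description
#' Thin wrappers giving the four shallow classifier families (SVM,
#' logistic regression, multilayer perceptron, naive Bayes) a uniform
#' interface: `fit_classifier()` trains on a standardized feature matrix
#' and `predict_scores()` returns a per-class probability matrix, which
#' the evaluation harness needs for ROC/AUC.
#'
#' @name models
NULL

#' Model specification: family plus hyperparameter grid
#'
#' @param family one of `"SVM"`, `"LR"`, `"MLP"`, `"NB"`.
#' @param grid named list of candidate hyperparameter values; defaults to
#'   [default_grid()] for the family. Naive Bayes has no grid.
#' @return a `model_spec` list.
#' @export
model_spec <- function(family = c("SVM", "LR", "MLP", "NB"), grid = NULL) {
  family <- match.arg(family)
  grid <- grid %||% default_grid(family)
  if (family != "NB" && length(grid) == 0)
    abort_input("empty hyperparameter grid for ", family)
  structure(list(family = family, grid = grid), class = "model_spec")
}

#' Default hyperparameter grids per family
#'
#' Modest log-spaced grids: SVM over kernel, cost and RBF width; logistic
#' regression over the L2 penalty; MLP over hidden-layer size and weight
#' decay; naive Bayes has nothing to tune.
#'
#' @param family classifier family name.
#' @return named list of candidate values (possibly empty).
#' @export
default_grid <- function(family) {
  switch(family,
    SVM = list(kernel = c("linear", "radial"), cost = c(0.1, 1, 10, 100),
               gamma = c(0.01, 0.1)),
    LR  = list(decay = c(0.001, 0.01, 0.1, 1)),
    MLP = list(size = c(32, 64), decay = c(0.001, 0.1)),
    NB  = list(),
    abort_input("unknown family ", family))
}

#' Fit one classifier at fixed hyperparameters
#'
#' @param spec a [model_spec()].
#' @param params one row of the grid as a named list (ignored for NB).
#' @param x numeric feature matrix (rows = instances).
#' @param y factor of class labels.
#' @param seed integer seed (MLP weight initialization is stochastic).
#' @return a `classifier` object holding the fitted model.
#' @export
fit_classifier <- function(spec, params, x, y, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  y <- droplevels(as.factor(y))
  fit <- switch(spec$family,
    SVM = with_seed(seed, {
      # Platt probability calibration consumes the R RNG; seeding makes
      # refits bit-reproducible
      kern <- params$kernel %||% "radial"
      e1071::svm(x, y, kernel = kern, cost = params$cost %||% 1,
                 gamma = if (kern == "radial") params$gamma %||% (1 / ncol(x))
                         else 1 / ncol(x),
                 probability = TRUE, scale = FALSE)
    }),
    LR = with_seed(seed, {
      df <- data.frame(.y = y, x, check.names = FALSE)
      nnet::multinom(.y ~ ., data = df, decay = params$decay %||% 0,
                     maxit = 200, MaxNWts = 1e6, trace = FALSE)
    }),
    MLP = with_seed(seed, {
      nnet::nnet(x, nnet::class.ind(y), size = params$size %||% 32,
                 decay = params$decay %||% 0, softmax = TRUE,
                 maxit = 200, MaxNWts = 1e6, trace = FALSE)
    }),
    NB = e1071::naiveBayes(x, y)
  )
  structure(list(family = spec$family, fit = fit, levels = levels(y),
                 params = params, feature_names = colnames(x)),
            class = "classifier")
}

#' Per-class probability scores
#'
#' @param model a [fit_classifier()] result, or a hand-built
#'   `classifier` object with `family = "custom"` whose `fit` field is a
#'   function mapping a feature matrix to a score matrix (one column per
#'   level) -- useful for testing score-consuming code against models
#'   with analytically known behavior.
#' @param x feature matrix with the training columns.
#' @return matrix of class probabilities, columns ordered as
#'   `model$levels`.
#' @export
predict_scores <- function(model, x) {
  stopifnot(inherits(model, "classifier"))
  p <- switch(model$family,
    custom = {
      pr <- model$fit(x)
      colnames(pr) <- model$levels
      pr
    },
    SVM = {
      pr <- stats::predict(model$fit, x, probability = TRUE)
      attr(pr, "probabilities")
    },
    LR = {
      df <- data.frame(x, check.names = FALSE)
      pr <- stats::predict(model$fit, newdata = df, type = "probs")
      if (is.null(dim(pr))) { # two-class multinom returns P(second level)
        pr <- cbind(1 - pr, pr)
        colnames(pr) <- model$levels
      }
      pr
    },
    MLP = {
      pr <- stats::predict(model$fit, x)
      colnames(pr) <- model$levels
      pr
    },
    NB = stats::predict(model$fit, x, type = "raw")
  )
  p <- as.matrix(p)[, model$levels, drop = FALSE]
  rownames(p) <- NULL
  p
}

#' Predicted class labels from scores
#'
#' @inheritParams predict_scores
#' @return factor of predicted labels with the model's levels.
#' @export
predict_labels <- function(model, x) {
  p <- predict_scores(model, x)
  factor(model$levels[max.col(p, ties.method = "first")],
         levels = model$levels)
}

# Per-feature importance of a linear SVM: the one-vs-one weight vectors
# are reconstructed from the dual coefficients (libsvm stores the
# coefficients of each support vector for its class's k - 1 pairings),
# and features are ranked by the weight sum of squares over all pairs.
linear_svm_weights <- function(model) {
  stopifnot(model$family == "SVM")
  f <- model$fit
  k <- length(f$nSV)
  start <- c(1L, cumsum(f$nSV) + 1L)[seq_len(k)]
  imp <- numeric(ncol(f$SV))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      ri <- start[i]:(start[i] + f$nSV[i] - 1L)
      rj <- start[j]:(start[j] + f$nSV[j] - 1L)
      w <- crossprod(f$coefs[ri, j - 1L], f$SV[ri, , drop = FALSE]) +
        crossprod(f$coefs[rj, i], f$SV[rj, , drop = FALSE])
      imp <- imp + drop(w)^2
    }
  }
  imp
}
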