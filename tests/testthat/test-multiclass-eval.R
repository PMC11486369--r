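balanced_dummy <- function(n_per_class = 200L, p = 10L, seed = 1L) {
  set.seed(seed)
  x <- matrix(rnorm(3 * n_per_class * p), 3 * n_per_class, p)
  colnames(x) <- paste0("f", seq_len(p))
  list(features = x, labels = factor(rep(c("ADHD", "ASD", "TD"),
                                         each = n_per_class)))
}

test_that("the 30% hold-out on 600 balanced rows reserves exactly 180", {
  d <- balanced_dummy(200)
  sp <- holdout_split(d, split_plan(test_fraction = 0.30, seed = 9))
  expect_equal(length(sp$test$y), 180)
  expect_equal(as.vector(table(sp$test$y)), c(60, 60, 60))
  expect_equal(length(sp$train$y), 420)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  sp2 <- holdout_split(d, split_plan(test_fraction = 0.30, seed = 9))
  expect_identical(sp$test_idx, sp2$test_idx)
})

test_that("stratification is preserved at other fractions", {
  x <- matrix(rnorm(20), 10, 2)
  d <- list(features = x, labels = factor(rep(c("A", "B"), each = 5)))
  sp <- holdout_split(d, split_plan(test_fraction = 0.5, seed = 1))
  expect_equal(as.vector(table(sp$test$y)), c(2, 2)) # round(0.5 * 5) = 2
  d$labels[1:9] <- "A"
  expect_error(holdout_split(d, split_plan(seed = 1)), ">= 2")
})

test_that("standardization follows the population convention without leakage", {
  tr <- matrix(c(1, 3), 2, 1)
  st <- standardize(tr)
  expect_equal(as.vector(st$train), c(-1, 1)) # mean 2, population sd 1

  te <- matrix(c(11, 13), 2, 1)
  st2 <- standardize(tr, te)
  expect_equal(as.vector(st2$test), c(9, 11)) # train parameters, not test's

  const <- cbind(a = c(1, 1), b = c(0, 2))
  expect_warning(st3 <- standardize(const), "zero-variance")
  expect_equal(as.vector(st3$train[, "a"]), c(1, 1))
})

test_that("stratified folds are balanced, seeded and bounded by class size", {
  y <- factor(rep(c("A", "B", "C"), each = 140))
  f <- teconnect:::make_folds(y, 10, seed = 3)
  expect_equal(as.vector(table(f)), rep(42, 10))
  for (k in 1:10) expect_equal(as.vector(table(y[f == k])), rep(14, 3))
  expect_identical(f, teconnect:::make_folds(y, 10, seed = 3))
  expect_error(teconnect:::make_folds(factor(rep(c("A", "B"), c(5, 100))),
                                      10, seed = 1), "smallest class")
})

test_that("cross-validation reaches perfect accuracy on a separable toy", {
  toy <- separable_toy()
  cv <- cross_validate(model_spec("SVM"), list(kernel = "linear", cost = 1),
                       toy, split_plan(k_folds = 5, seed = 2))
  expect_equal(unname(cv$mean[["accuracy"]]), 1)
  expect_equal(nrow(cv$folds), 5)
})

test_that("grid search is exhaustive, deterministic and refits the winner", {
  toy <- separable_toy()
  plan <- split_plan(k_folds = 5, seed = 4)
  single <- model_spec("SVM", grid = list(kernel = "linear", cost = 2))
  g1 <- grid_search(single, toy, plan)
  expect_equal(g1$best_params$cost, 2)

  spec <- model_spec("SVM", grid = list(kernel = "linear", cost = c(0.5, 5)))
  g2 <- grid_search(spec, toy, plan)
  expect_equal(max(g2$cv_table$cv_accuracy), 1)
  g3 <- grid_search(spec, toy, plan)
  expect_identical(g2$best_params, g3$best_params)
  expect_s3_class(g2$model, "classifier")

  rep <- evaluate(g2, toy)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$macro_auc, 1)
  expect_equal(rep$micro_auc, 1)
  expect_true(all(diag(rep$confusion) == table(toy$y)))
})

test_that("multiclass AUC matches a trapezoid oracle and the chance line", {
  # hand-listed 3-class scores on 6 instances
  y <- factor(c("A", "A", "B", "B", "C", "C"))
  s <- rbind(c(0.7, 0.2, 0.1), c(0.4, 0.5, 0.1), c(0.3, 0.6, 0.1),
             c(0.2, 0.3, 0.5), c(0.1, 0.2, 0.7), c(0.2, 0.2, 0.6))
  colnames(s) <- c("A", "B", "C")
  auc <- teconnect:::multiclass_auc(y, s)
  for (cl in levels(y)) {
    expect_equal(unname(auc$per_class[[cl]]),
                 trapezoid_auc(as.integer(y == cl), s[, cl]),
                 tolerance = 1e-12)
  }
  pooled_truth <- as.vector(vapply(levels(y), function(cl)
    as.integer(y == cl), integer(6)))
  expect_equal(auc$micro, trapezoid_auc(pooled_truth, as.vector(s)),
               tolerance = 1e-12)
  expect_equal(auc$macro, mean(auc$per_class), tolerance = 1e-12)

  # constant scores sit on the chance diagonal
  s0 <- matrix(1 / 3, 6, 3, dimnames = list(NULL, levels(y)))
  auc0 <- teconnect:::multiclass_auc(y, s0)
  expect_equal(unname(auc0$per_class), rep(0.5, 3))
})

test_that("accuracy, precision and recall are consistent with the confusion", {
  toy <- separable_toy(gap = 1.5) # imperfectly separable
  plan <- split_plan(k_folds = 5, seed = 6)
  sp <- holdout_split(toy, plan)
  gs <- grid_search(model_spec("SVM", grid = list(kernel = "linear", cost = 1)),
                    sp$train, plan)
  rep <- evaluate(gs, sp$test)
  conf <- rep$confusion
  expect_equal(rep$accuracy, sum(diag(conf)) / sum(conf))
  support <- rowSums(conf)
  prec_c <- diag(conf) / pmax(colSums(conf), 1)
  rec_c <- diag(conf) / support
  expect_equal(rep$precision, sum(prec_c * support) / sum(conf))
  expect_equal(rep$recall, sum(rec_c * support) / sum(conf))
})

test_that("all four classifier families emit calibrated score matrices", {
  toy <- separable_toy(n_per_class = 15, p = 3)
  st <- standardize(toy$x)
  for (fam in c("SVM", "LR", "MLP", "NB")) {
    spec <- model_spec(fam)
    params <- lapply(spec$grid, function(v) v[1])
    mod <- fit_classifier(spec, params, st$train, toy$y, seed = 1)
    sc <- predict_scores(mod, st$train)
    expect_equal(dim(sc), c(45, 3))
    expect_equal(unname(rowSums(sc)), rep(1, 45), tolerance = 1e-6)
    expect_gt(mean(predict_labels(mod, st$train) == toy$y), 0.9)
  }
})

test_that("RFE recovers a planted informative support", {
  runs <- lapply(1:6, function(r) {
    set.seed(r * 100)
    n <- 60
    y <- factor(rep(c("A", "B", "C"), each = 20))
    # each informative feature separates the classes by a distinct pattern
    shift <- 4 * outer(as.integer(y), 1:10, function(c, j) ((c + j) %% 3) - 1)
    x <- cbind(matrix(rnorm(n * 10), n, 10) + shift,
               matrix(rnorm(n * 90), n, 90))
    colnames(x) <- c(paste0("inf", 1:10), paste0("noise", 1:90))
    recursive_feature_elimination(list(x = x, y = y),
                                  split_plan(k_folds = 5, seed = r),
                                  step = 10)
  })
  kept_all <- vapply(runs, function(r)
    all(paste0("inf", 1:10) %in% r$selected), logical(1))
  expect_gte(mean(kept_all), 0.9)
  expect_true(all(vapply(runs, function(r) r$best_n, numeric(1)) <= 20))
})

test_that("RFE boundary and determinism behavior", {
  toy <- separable_toy(n_per_class = 10, p = 4)
  plan <- split_plan(k_folds = 5, seed = 3)
  r <- recursive_feature_elimination(toy, plan, step = 3)
  expect_equal(nrow(r$curve), 2) # p - step = 1 elimination possible
  r2 <- recursive_feature_elimination(toy, plan, step = 3)
  expect_identical(r$curve, r2$curve)
  expect_error(recursive_feature_elimination(toy, plan, step = 4), "step")
})

test_that("learning curves grow with data on a clean separable toy", {
  toy <- separable_toy(n_per_class = 30)
  plan <- split_plan(k_folds = 5, seed = 8)
  sp <- holdout_split(toy, plan)
  lc <- learning_curve(model_spec("SVM"), list(kernel = "linear", cost = 1),
                       sp$train, sp$test, plan,
                       sizes = c(0.4, 0.4, 0.7, 1.0))
  expect_equal(nrow(lc), 3) # duplicate size dropped
  expect_gte(lc$test_accuracy[3], lc$test_accuracy[1] - 0.02)
  expect_equal(lc$n_train[3], length(sp$train$y)) # size 1.0 = full fit
})

test_that("noise sweeps leave the clean limit untouched and are seeded", {
  toy <- separable_toy()
  plan <- split_plan(k_folds = 5, seed = 5)
  sp <- holdout_split(toy, plan)
  gs <- grid_search(model_spec("SVM", grid = list(kernel = "linear", cost = 1)),
                    sp$train, plan)
  clean <- evaluate(gs, sp$test)
  nr <- noise_robustness(gs, sp$test, means = c(0, 50), sd = 1e-9, seed = 2)
  expect_equal(nr$accuracy[1], clean$accuracy, tolerance = 1e-6)
  expect_lt(nr$accuracy[2], 0.5) # far-off cloud collapses to one class
  nr2 <- noise_robustness(gs, sp$test, means = c(0, 50), sd = 1e-9, seed = 2)
  expect_identical(nr, nr2)
})

test_that("k sweeps skip infeasible folds and stay flat when separable", {
  toy <- separable_toy(n_per_class = 12)
  plan <- split_plan(k_folds = 10, seed = 7)
  sp <- holdout_split(toy, plan)
  expect_warning(
    ks <- k_sweep(model_spec("SVM"), list(kernel = "linear", cost = 1),
                  sp$train, sp$test, plan, ks = c(2, 3, 5, 50)),
    "infeasible")
  expect_equal(ks$k, c(2, 3, 5))
  expect_true(all(abs(ks$cv_accuracy - ks$cv_accuracy[1]) <= 0.05))
})

test_that("no training-fold leakage: an unseen label feature cannot help", {
  # the label is encoded in a feature present only outside the CV loop;
  # inside CV, features are pure noise, so accuracy must sit at chance
  set.seed(12)
  n <- 90
  y <- factor(rep(c("A", "B", "C"), each = 30))
  x <- matrix(rnorm(n * 8), n, 8)
  colnames(x) <- paste0("f", 1:8)
  cv <- cross_validate(model_spec("SVM"), list(kernel = "linear", cost = 1),
                       list(x = x, y = y), split_plan(k_folds = 5, seed = 1))
  expect_gte(unname(cv$mean[["accuracy"]]), 0.15)
  expect_lte(unname(cv$mean[["accuracy"]]), 0.50)
})
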