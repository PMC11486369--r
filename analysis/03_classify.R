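#!/usr/bin/env Rscript

# Stage 3: multiclass evaluation on the connectivity features.
#
# Protocol: 30% stratified hold-out reserved before training (180 of the
# 600 matrices, 60 per class), stratified shuffled 10-fold CV with
# in-fold standardization, exhaustive grid search over the SVM grid, and
# hold-out evaluation with per-class / micro / macro ROC AUC. Robustness
# probes: additive-noise sweep, k-fold stability sweep, learning curve,
# and a label-shuffled chance control.

library(teconnect)

seed <- 1L
dataset <- read_dataset("results/dataset")
plan <- split_plan(test_fraction = 0.30, k_folds = 10L, seed = seed)
split <- holdout_split(dataset, plan)
cat(sprintf("hold-out: %d train / %d test\n",
            length(split$train$y), length(split$test$y)))

fit <- grid_search(model_spec("SVM"), split$train, plan)
cat("best hyperparameters:",
    paste(names(fit$best_params), unlist(fit$best_params),
          sep = "=", collapse = ", "), "\n")
cat(sprintf("CV accuracy %.3f +/- %.3f\n",
            fit$cv_best$mean[["accuracy"]], fit$cv_best$sd[["accuracy"]]))

report <- evaluate(fit, split$test)
print(report)
dir.create("results", showWarnings = FALSE)
write.csv(data.frame(metric = c("accuracy", "precision", "recall",
                                "macro_auc", "micro_auc",
                                paste0("auc_", names(report$per_class_auc))),
                     value = c(report$accuracy, report$precision,
                               report$recall, report$macro_auc,
                               report$micro_auc, report$per_class_auc)),
          "results/classification_metrics.csv", row.names = FALSE)
write.csv(as.data.frame(report$confusion), "results/confusion.csv",
          row.names = FALSE)
for (cl in names(report$roc_curves))
  write.csv(report$roc_curves[[cl]],
            sprintf("results/roc_%s.csv", cl), row.names = FALSE)

# chance control
shuffled <- split$train
shuffled$y <- with_seed(derive_seed(seed, 777L), sample(shuffled$y))
cv_shuf <- cross_validate(model_spec("SVM"), fit$best_params, shuffled, plan)
cat(sprintf("label-shuffled CV accuracy: %.3f (3-class chance ~ 0.333)\n",
            cv_shuf$mean[["accuracy"]]))

# robustness probes
nr <- noise_robustness(fit, split$test, means = seq(0, 1.5, 0.25),
                       sd = 0.1, seed = seed)
write.csv(nr, "results/noise_sweep.csv", row.names = FALSE)
cat(sprintf("noise sweep: accuracy %.3f (clean) -> %.3f (mean 1.5)\n",
            nr$accuracy[1], nr$accuracy[nrow(nr)]))

ks <- k_sweep(model_spec("SVM"), fit$best_params, split$train, split$test,
              plan, ks = c(2L, 3L, 5L, 10L, 15L))
write.csv(ks, "results/k_sweep.csv", row.names = FALSE)
cat(sprintf("k sweep: CV accuracy range %.3f across k in {2,3,5,10,15}\n",
            diff(range(ks$cv_accuracy))))

lc <- learning_curve(model_spec("SVM"), fit$best_params, split$train,
                     split$test, plan, sizes = seq(0.2, 1, 0.2))
write.csv(lc, "results/learning_curve.csv", row.names = FALSE)
cat(sprintf("learning curve: test accuracy %.3f at %d rows -> %.3f at %d\n",
            lc$test_accuracy[1], lc$n_train[1],
            lc$test_accuracy[nrow(lc)], lc$n_train[nrow(lc)]))
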