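#!/usr/bin/env Rscript

# Stage 2: sliding-window normalized-transfer-entropy connectivity.
#
# Each subject's series is cut into non-overlapping 20 s windows; each
# window is min-max normalized, binarized at 0.5, and converted into a
# 20 x 20 directed normalized-TE matrix. 600 matrices (200 per class)
# are drawn and vectorized into the feature dataset used by the
# classifiers. Also computes one full-series matrix per subject for the
# network-feature analyses.

library(teconnect)

seed <- 1L
cohort <- read_cohort("results/cohort")
cfg <- te_config(tau = 1L, window_seconds = 20, stride_seconds = 20,
                 binarize_threshold = 0.5)

dataset <- build_dataset(cohort, cfg, n_select = 600L, seed = seed)
write_dataset(dataset, "results/dataset")
cat(sprintf("dataset: %d windows x %d directed-pair features (%s)\n",
            nrow(dataset$features), ncol(dataset$features),
            paste(sprintf("%s=%d", levels(dataset$labels),
                          table(dataset$labels)), collapse = ", ")))

# subject-level (full-series) matrices for the graph-feature stage
dir.create("results/subject_matrices", showWarnings = FALSE, recursive = TRUE)
for (ts in cohort) {
  m <- connectivity_matrix(ts, cfg)
  write_conn_matrix(m, file.path("results/subject_matrices",
                                 paste0(ts$subject_id, ".csv")))
}
cat("wrote 60 subject-level connectivity matrices\n")
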