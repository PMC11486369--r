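#!/usr/bin/env Rscript

# Stage 1: generate the synthetic three-group cohort.
#
# 60 subjects (20 TD, 20 ADHD-like, 20 ASD-like), 20 ROIs each, 300 s of
# BOLD-like signal at TR = 2 s. Group identity is planted in the directed
# coupling: a dense distributed backbone for TD, two hub-out stars for
# ADHD, one hub-out star for ASD, plus subject-specific random edges
# whose density also decreases TD > ADHD > ASD. Writes one CSV + JSON
# sidecar per subject.

library(teconnect)

seed <- 1L
out_dir <- "results/cohort"

cohort <- make_cohort(counts = c(TD = 20L, ADHD = 20L, ASD = 20L),
                      n_roi = 20L, duration = 300, sampling_interval = 2,
                      noise_sd = 1, seed = seed)
write_cohort(cohort, out_dir)

cat(sprintf("wrote %d subjects to %s\n", length(cohort), out_dir))
cat(sprintf("series length %d samples x %d ROIs at TR %gs\n",
            nrow(cohort[[1]]$values), ncol(cohort[[1]]$values),
            cohort[[1]]$sampling_interval))
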