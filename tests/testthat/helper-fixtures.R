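# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# A small cohort for module-level tests: 3 x 3 subjects, 8 ROIs, 120 s.
small_cohort <- function() {
  fixture("small_cohort", function() {
    make_cohort(counts = c(TD = 3L, ADHD = 3L, ASD = 3L), n_roi = 8L,
                duration = 120, sampling_interval = 2, seed = 7L)
  })
}

# The full default-scale cohort and everything the end-to-end acceptance
# checks need; built once and reused across test files.
default_run <- function(seed = 1L) {
  fixture("default_run", function() {
    cohort <- make_cohort(seed = seed)
    ds <- build_dataset(cohort, te_config(), n_select = 600L, seed = seed)
    plan <- split_plan(test_fraction = 0.30, k_folds = 10L, seed = seed)
    sp <- holdout_split(ds, plan)
    gs <- grid_search(model_spec("SVM"), sp$train, plan)
    rep <- evaluate(gs, sp$test)
    subj_mats <- lapply(cohort, function(ts) connectivity_matrix(ts, te_config()))
    list(seed = seed, cohort = cohort, dataset = ds, plan = plan,
         split = sp, fit = gs, report = rep, subject_matrices = subj_mats)
  })
}

# Three well-separated Gaussian blobs: trivially separable toy set.
separable_toy <- function(n_per_class = 20L, p = 4L, gap = 8, seed = 11L) {
  centers <- matrix(0, 3, p)
  centers[2, 1] <- gap
  centers[3, 2] <- gap
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  x <- do.call(rbind, lapply(1:3, function(k) {
    matrix(rnorm(n_per_class * p), n_per_class, p) +
      matrix(centers[k, ], n_per_class, p, byrow = TRUE)
  }))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  colnames(x) <- paste0("f", seq_len(p))
  list(x = x, y = factor(rep(c("A", "B", "C"), each = n_per_class)))
}

# Hand-built "custom" classifier bundle around a scoring function, with an
# identity standardizer; used to test score-consuming code against models
# with known analytic behavior.
custom_bundle <- function(score_fn, levels, p, feature_names = NULL) {
  model <- structure(list(family = "custom", fit = score_fn,
                          levels = levels, params = list(),
                          feature_names = feature_names),
                     class = "classifier")
  transform <- list(center = rep(0, p), scale = rep(1, p))
  list(model = model, transform = transform)
}
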