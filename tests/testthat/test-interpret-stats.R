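test_that("star codes follow the printed intervals with inclusive bounds", {
  expect_equal(star_code(0.03), "*")
  expect_equal(star_code(5.0e-5), "****")
  expect_equal(star_code(0.05), "*")
  expect_equal(star_code(1.0e-2), "**")
  expect_equal(star_code(1.0e-3), "***")
  expect_equal(star_code(1.0e-4), "****")
  expect_equal(star_code(0.051), "ns")
  expect_equal(star_code(1), "ns")
  expect_error(star_code(0), "in \\(0, 1\\]")
  expect_error(star_code(1.2), "in \\(0, 1\\]")
})

test_that("rank-sum p-values match exhaustive enumeration", {
  # {1,2,3} vs {10,11,12}: most extreme of the 20 arrangements, two-sided
  r <- pairwise_group_tests(data.frame(v = c(1, 2, 3, 10, 11, 12)),
                            factor(rep(c("a", "b"), each = 3)))
  expect_equal(r$raw_p, 0.1, tolerance = 1e-12)
  expect_equal(r$raw_p, ranksum_exact_p(c(1, 2, 3), c(10, 11, 12)),
               tolerance = 1e-12)

  set.seed(14)
  for (rep in 1:20) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- sample(1:100, na); b <- sample(setdiff(1:100, a), nb) # no ties
    got <- pairwise_group_tests(data.frame(v = c(a, b)),
                                factor(rep(c("x", "y"), c(na, nb))),
                                family_size = 1)
    expect_equal(got$raw_p, ranksum_exact_p(a, b), tolerance = 1e-10)
  }
})

test_that("identical groups and constant features give p = 1", {
  same <- c(3, 1, 4, 1, 5)
  r <- pairwise_group_tests(data.frame(v = c(same, same)),
                            factor(rep(c("a", "b"), each = 5)))
  expect_equal(r$raw_p, 1)
  expect_equal(r$star, "ns")

  r2 <- pairwise_group_tests(data.frame(v = rep(2, 8)),
                             factor(rep(c("a", "b"), each = 4)))
  expect_equal(r2$raw_p, 1)
})

test_that("Bonferroni uses the 3-pairs-times-features family and dominates", {
  set.seed(15)
  ft <- data.frame(m1 = rnorm(30), m2 = rnorm(30), m3 = rnorm(30),
                   m4 = rnorm(30))
  lab <- factor(rep(c("TD", "ADHD", "ASD"), each = 10))
  res <- pairwise_group_tests(ft, lab)
  expect_equal(nrow(res), 3 * 4)
  expect_true(all(res$adjusted_p >= res$raw_p))
  expect_equal(res$adjusted_p, pmin(1, res$raw_p * 12))
  expect_true(all(vapply(res$adjusted_p, star_code, character(1)) ==
                    res$star))
})

test_that("the t-test variant is available behind the method flag", {
  set.seed(16)
  a <- rnorm(20); b <- rnorm(20) + 3
  r <- pairwise_group_tests(data.frame(v = c(a, b)),
                            factor(rep(c("x", "y"), each = 20)),
                            family_size = 1, method = "ttest")
  expect_equal(r$raw_p, t.test(a, b)$p.value, tolerance = 1e-12)
})

test_that("PCA finds a dominant axis and is rotation invariant", {
  set.seed(18)
  t_ <- rnorm(50)
  line3d <- cbind(t_, 2 * t_, -t_) + matrix(rnorm(150, sd = 1e-3), 50, 3)
  p <- pca_project(line3d, 2)
  expect_gt(p$explained_variance_fractions[1], 0.999)
  expect_true(all(diff(p$explained_variance_fractions) <= 1e-12))
  expect_lte(sum(p$explained_variance_fractions), 1 + 1e-9)

  x <- matrix(rnorm(200), 50, 4)
  # signed permutations are orthogonal rotations that preserve the
  # per-column standardization, so explained fractions match exactly
  q <- diag(c(1, -1, 1, -1))[, c(3, 1, 4, 2)]
  p1 <- pca_project(x, 2)
  p2 <- pca_project(x %*% q, 2)
  expect_equal(p1$explained_variance_fractions,
               p2$explained_variance_fractions, tolerance = 1e-9)

  expect_error(pca_project(x, 10), "n_components")
})

test_that("2-feature PCA matches the analytic eigendecomposition", {
  set.seed(19)
  z <- matrix(rnorm(400), 200, 2) %*% chol(matrix(c(1, 0.8, 0.8, 1), 2))
  p <- pca_project(z, 2)
  # correlation matrix of standardized 2-d data has eigenvectors
  # (1,1)/sqrt(2) and (1,-1)/sqrt(2) regardless of the correlation value
  zs <- scale(z)
  expect_equal(abs(cor(p$scores[, 1], zs %*% c(1, 1)))[1], 1,
               tolerance = 1e-9)
  expect_equal(abs(cor(p$scores[, 2], zs %*% c(1, -1)))[1], 1,
               tolerance = 1e-9)
  ev <- eigen(cor(z))$values
  expect_equal(p$explained_variance_fractions, ev / 2, tolerance = 1e-9)
})

test_that("attribution satisfies the null-player and local-accuracy axioms", {
  # score depends on feature 1 only; feature 2 is a null player
  score_fn <- function(x) {
    s <- plogis(x[, 1])
    cbind(A = s, B = 1 - s)
  }
  bundle <- custom_bundle(score_fn, c("A", "B"), p = 2,
                          feature_names = c("f1", "f2"))
  ex <- matrix(c(1.2, 5, -0.4, -2), 2, 2, dimnames = list(NULL, c("f1", "f2")))
  bg <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("f1", "f2")))
  rep <- shapley_attribution(bundle, ex, bg, seed = 1)
  expect_true(rep$exact)
  expect_equal(unname(rep$per_class_mean_abs[, "f2"]), c(0, 0))

  # local accuracy: attributions sum to score minus background base value
  base <- mean(score_fn(bg)[, "A"])
  for (i in 1:2) {
    expect_equal(sum(rep$values$A[i, ]),
                 unname(score_fn(ex)[i, "A"] - base), tolerance = 1e-9)
  }
})

test_that("duplicated features share attribution and rankings are stable", {
  score_fn <- function(x) {
    s <- plogis(x[, 1] + x[, 2])
    cbind(A = s, B = 1 - s)
  }
  bundle <- custom_bundle(score_fn, c("A", "B"), p = 3)
  set.seed(20)
  bg <- matrix(rnorm(30), 10, 3)
  base <- rnorm(3)
  ex <- matrix(base[c(1, 1, 3)], 1, 3) # features 1 and 2 identical
  bg[, 2] <- bg[, 1]
  colnames(bg) <- colnames(ex) <- c("dupA", "dupB", "other")
  rep <- shapley_attribution(bundle, ex, bg, seed = 2)
  expect_equal(rep$global_mean_abs[["dupA"]], rep$global_mean_abs[["dupB"]],
               tolerance = 1e-9)
  # tie broken lexicographically
  expect_lt(which(rep$global_ranking == "dupA"),
            which(rep$global_ranking == "dupB"))
})

test_that("a planted informative feature wins the global ranking", {
  wins <- vapply(1:50, function(r) {
    set.seed(1000 + r)
    n <- 60
    y <- factor(rep(c("A", "B", "C"), each = 20))
    x <- matrix(rnorm(n * 5), n, 5)
    x[, 3] <- x[, 3] + 4 * (as.integer(y) - 2) # informative feature
    colnames(x) <- paste0("f", 1:5)
    sp <- list(x = x, y = y)
    st <- standardize(x)
    mod <- fit_classifier(model_spec("SVM"),
                          list(kernel = "linear", cost = 1), st$train, y,
                          seed = r)
    bundle <- list(model = mod, transform = st)
    att <- shapley_attribution(bundle, x[seq(1, 60, by = 12), , drop = FALSE],
                               x, seed = r)
    att$global_ranking[1] == "f3"
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("sampling-mode attribution approximates exact enumeration", {
  score_fn <- function(x) {
    s <- plogis(0.8 * x[, 1] - 0.5 * x[, 2] + 0.2 * x[, 3])
    cbind(A = s, B = 1 - s)
  }
  bundle <- custom_bundle(score_fn, c("A", "B"), p = 3)
  set.seed(23)
  bg <- matrix(rnorm(24), 8, 3)
  ex <- matrix(rnorm(3), 1, 3)
  colnames(bg) <- colnames(ex) <- paste0("f", 1:3)
  exact <- shapley_attribution(bundle, ex, bg, seed = 3)
  sampled <- shapley_attribution(bundle, ex, bg, seed = 3, exact_max = 0,
                                 n_perm = 200)
  expect_false(sampled$exact)
  expect_equal(sampled$values$A[1, ], exact$values$A[1, ], tolerance = 0.05)
})

test_that("feature-name mismatches between model and data are rejected", {
  bundle <- custom_bundle(function(x) cbind(A = plogis(x[, 1]),
                                            B = 1 - plogis(x[, 1])),
                          c("A", "B"), p = 2, feature_names = c("f1", "f2"))
  ex <- matrix(0, 1, 2, dimnames = list(NULL, c("g1", "g2")))
  bg <- matrix(0, 2, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_error(shapley_attribution(bundle, ex, bg, seed = 1),
               "feature names")
})
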