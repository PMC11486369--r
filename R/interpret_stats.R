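#' @title Interpretation layer
#'
#' @description
#' Model-agnostic Shapley-value feature attribution, PCA projection with
#' feature-component correlations, and pairwise rank tests across the
#' three groups with Bonferroni correction and the conventional
#' significance star codes.
#'
#' @name interpret_stats
NULL

# Value function for Shapley attribution: the model's score for class
# `class_col` at instance `x_row`, with features outside the coalition
# replaced by background rows and averaged over the background.
coalition_value <- function(bundle, x_row, background, mask, class_col) {
  xm <- background
  xm[, mask] <- matrix(x_row[mask], nrow(background), sum(mask), byrow = TRUE)
  st <- bundle$transform
  xs <- sweep(sweep(xm, 2, st$center), 2, st$scale, "/")
  mean(predict_scores(bundle$model, xs)[, class_col])
}

# Exact Shapley values for one instance and one class by subset
# enumeration (p <= 12).
shapley_exact <- function(bundle, x_row, background, class_col) {
  p <- length(x_row)
  vals <- numeric(2^p)
  for (s in 0:(2^p - 1)) {
    mask <- as.logical(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))))
    vals[s + 1L] <- coalition_value(bundle, x_row, background, mask, class_col)
  }
  sizes <- vapply(0:(2^p - 1), function(s)
    sum(as.logical(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))))), numeric(1))
  # weight of v(S u j) - v(S) for |S| = s; the full set never appears as S
  wgt <- numeric(2^p)
  proper <- sizes < p
  wgt[proper] <- factorial(sizes[proper]) * factorial(p - sizes[proper] - 1) /
    factorial(p)
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(bitwAnd(0:(2^p - 1), bit) == 0L) # 1-based subset ids
    phi[j] <- sum(wgt[without] * (vals[without + bit] - vals[without]))
  }
  phi
}

# Permutation-sampling Shapley estimate (Castro-style) for one instance
# and one class; `n_perm` random feature orderings.
shapley_sampled <- function(bundle, x_row, background, class_col, n_perm,
                            seed) {
  p <- length(x_row)
  phi <- numeric(p)
  with_seed(seed, {
    for (r in seq_len(n_perm)) {
      ord <- sample.int(p)
      mask <- rep(FALSE, p)
      prev <- coalition_value(bundle, x_row, background, mask, class_col)
      for (j in ord) {
        mask[j] <- TRUE
        cur <- coalition_value(bundle, x_row, background, mask, class_col)
        phi[j] <- phi[j] + (cur - prev)
        prev <- cur
      }
    }
  })
  phi / n_perm
}

#' Shapley-value feature attribution
#'
#' Game-theoretic per-feature contributions to each class score,
#' estimated model-agnostically: features outside a coalition are
#' replaced by background-set values and the class probability is
#' averaged over the background. Exact subset enumeration is used for
#' at most `exact_max` features, otherwise seeded permutation sampling.
#' Satisfies the null-player axiom (an ignored feature gets 0) and, in
#' exact mode, local accuracy (attributions sum to the score minus the
#' background base value).
#'
#' @param bundle a [grid_search()] result (model + fitted standardizer)
#'   trained on raw features.
#' @param explain_x raw feature matrix of instances to explain.
#' @param background raw feature matrix of background instances
#'   (a seeded subsample of at most `background_size` rows is used).
#' @param seed integer seed.
#' @param n_perm permutations per instance in sampling mode.
#' @param exact_max maximum feature count for exact enumeration.
#' @param background_size background subsample cap (default 100).
#' @return an `attribution_report` with `per_class_mean_abs`
#'   (class x feature), `global_mean_abs`, `global_ranking`,
#'   `per_class_ranking`, `values` (per class: instance x feature), and
#'   bookkeeping fields.
#' @export
shapley_attribution <- function(bundle, explain_x, background, seed = 1L,
                                n_perm = 50L, exact_max = 12L,
                                background_size = 100L) {
  fn_model <- bundle$model$feature_names
  if (!is.null(fn_model) && !is.null(colnames(explain_x)) &&
      !identical(fn_model, colnames(explain_x)))
    abort_input("feature names of model and explain set differ")
  if (nrow(background) == 0) abort_input("background must be non-empty")
  if (nrow(background) > background_size)
    background <- background[with_seed(seed, sample(nrow(background),
                                                    background_size)), ,
                             drop = FALSE]
  p <- ncol(explain_x)
  classes <- bundle$model$levels
  fnames <- colnames(explain_x) %||% paste0("f", seq_len(p))
  exact <- p <= exact_max

  values <- lapply(classes, function(cl) {
    v <- t(vapply(seq_len(nrow(explain_x)), function(i) {
      if (exact)
        shapley_exact(bundle, explain_x[i, ], background, cl)
      else
        shapley_sampled(bundle, explain_x[i, ], background, cl, n_perm,
                        derive_seed(seed, i))
    }, numeric(p)))
    colnames(v) <- fnames
    v
  })
  names(values) <- classes

  per_class <- t(vapply(values, function(v) colMeans(abs(v)), numeric(p)))
  rownames(per_class) <- classes
  global <- colMeans(per_class)

  rank_features <- function(score) {
    # descending score; ties broken lexicographically by feature name
    fnames[order(-score, fnames)]
  }
  structure(list(
    per_class_mean_abs = per_class,
    global_mean_abs = global,
    global_ranking = rank_features(global),
    per_class_ranking = lapply(seq_len(nrow(per_class)), function(i)
      rank_features(per_class[i, ])) |> stats::setNames(classes),
    values = values,
    background_size = nrow(background), n_explained = nrow(explain_x),
    exact = exact, seed = seed), class = "attribution_report")
}

#' PCA projection with feature-component correlations
#'
#' Standardizes the features, projects onto the leading principal
#' components, and reports explained-variance fractions together with
#' the Pearson correlation of every original feature with every
#' retained component. Constant features are dropped with a warning
#' (they carry no variance to project).
#'
#' @param features numeric matrix or data.frame (no label column).
#' @param n_components number of components to retain.
#' @return a `pca_result` with `scores`, `explained_variance_fractions`,
#'   `feature_component_correlations`, `dropped_features`.
#' @export
pca_project <- function(features, n_components = 2L) {
  x <- as.matrix(features)
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning(sum(!keep), " constant feature(s) dropped before PCA")
    x <- x[, keep, drop = FALSE]
  }
  if (n_components > min(dim(x)))
    abort_input("n_components exceeds min(instances, features)")
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  evf <- pc$sdev^2 / sum(pc$sdev^2)
  corr <- stats::cor(x, scores)
  structure(list(scores = scores,
                 explained_variance_fractions = evf,
                 feature_component_correlations = corr,
                 dropped_features = colnames(features)[!keep] %||% character(0)),
            class = "pca_result")
}

#' Pairwise group rank tests with Bonferroni correction
#'
#' For every feature and every unordered pair of groups, a two-sided
#' independent-samples rank-sum (Mann-Whitney) test, or Welch t-test if
#' requested. P-values are Bonferroni-adjusted with family size
#' `3 * n_features` by default (all pairs of the three groups across
#' all features), and mapped to significance stars.
#'
#' @param feature_table data.frame of features (one column per measure).
#' @param labels factor of group labels, one per row.
#' @param family_size `"auto"` (pairs x features) or an integer.
#' @param method `"ranksum"` (default) or `"ttest"`.
#' @return data.frame with `feature`, `group1`, `group2`, `raw_p`,
#'   `adjusted_p`, `star`.
#' @export
pairwise_group_tests <- function(feature_table, labels,
                                 family_size = "auto",
                                 method = c("ranksum", "ttest")) {
  method <- match.arg(method)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) abort_input("need >= 2 groups")
  if (any(table(labels) < 2)) abort_input("every group needs >= 2 instances")
  feats <- as.data.frame(feature_table)
  pairs <- utils::combn(levels(labels), 2, simplify = FALSE)
  fam <- if (identical(family_size, "auto"))
    length(pairs) * ncol(feats) else as.numeric(family_size)

  rows <- list()
  for (f in names(feats)) {
    for (pr in pairs) {
      a <- feats[[f]][labels == pr[1]]
      b <- feats[[f]][labels == pr[2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      p <- if (length(unique(c(a, b))) < 2) {
        1 # both groups constant and equal: no evidence
      } else if (method == "ranksum") {
        suppressWarnings(stats::wilcox.test(a, b, exact = NULL)$p.value)
      } else {
        stats::t.test(a, b)$p.value
      }
      adj <- min(1, p * fam)
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group1 = pr[1], group2 = pr[2],
        raw_p = p, adjusted_p = adj, star = star_code(adj))
    }
  }
  do.call(rbind, rows)
}

#' Significance star code
#'
#' Maps a p-value to the conventional code with upper-inclusive
#' boundaries: `****` for p <= 1e-4, `***` for p <= 1e-3, `**` for
#' p <= 1e-2, `*` for p <= 5e-2, `ns` otherwise.
#'
#' @param p p-value in (0, 1].
#' @return one of `"ns"`, `"*"`, `"**"`, `"***"`, `"****"`.
#' @export
star_code <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    abort_input("p must be a single value in (0, 1]")
  if (p <= 1e-4) "****"
  else if (p <= 1e-3) "***"
  else if (p <= 1e-2) "**"
  else if (p <= 5e-2) "*"
  else "ns"
}
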