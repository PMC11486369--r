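#' @title Transfer-entropy connectivity
#'
#' @description
#' Turns ROI time series into per-window directed connectivity matrices.
#' Each channel is min-max normalized and binarized at a threshold
#' (default 0.5); pairwise coupling is then measured with a plug-in
#' estimate of transfer entropy over binary symbols at lag `tau`,
#' normalized by the target's conditional entropy so every entry lies in
#' [0, 1].
#'
#' @name te_connectivity
NULL

#' Configuration for the connectivity stage
#'
#' @param tau positive integer lag, in samples (default 1).
#' @param window_seconds sliding-window length in seconds (default 20).
#' @param stride_seconds window stride in seconds; defaults to the window
#'   length (non-overlapping windows).
#' @param binarize_threshold threshold in [0, 1] applied to min-max
#'   normalized series; values >= threshold map to symbol 1.
#' @return a `te_config` list.
#' @export
te_config <- function(tau = 1L, window_seconds = 20,
                      stride_seconds = window_seconds,
                      binarize_threshold = 0.5) {
  if (tau < 1) abort_input("tau must be >= 1")
  if (window_seconds <= 0 || stride_seconds <= 0)
    abort_input("window and stride must be positive")
  if (binarize_threshold < 0 || binarize_threshold > 1)
    abort_input("binarize_threshold must be in [0, 1]")
  structure(list(tau = as.integer(tau), window_seconds = window_seconds,
                 stride_seconds = stride_seconds,
                 binarize_threshold = binarize_threshold),
            class = "te_config")
}

#' Min-max normalization to [0, 1]
#'
#' @param x numeric vector, length >= 2, non-constant.
#' @param roi channel name used in the error message for degenerate input.
#' @return `(x - min) / (max - min)`.
#' @export
minmax_normalize <- function(x, roi = "channel") {
  if (length(x) < 2) abort_input("series must have length >= 2")
  r <- range(x)
  if (r[1] == r[2])
    stop(errorCondition(
      paste0("degenerate (constant) series in ", roi, ": min == max"),
      class = c("teconnect_degenerate", "teconnect_input_error", "error")))
  (x - r[1]) / (r[2] - r[1])
}

#' Binarize a [0, 1] series at a threshold
#'
#' Values greater than or equal to the threshold map to 1, others to 0.
#'
#' @param x numeric vector with entries in [0, 1].
#' @param threshold real threshold.
#' @return integer vector of 0/1 symbols.
#' @export
binarize <- function(x, threshold = 0.5) {
  as.integer(x >= threshold)
}

#' Cut a multichannel series into sliding windows
#'
#' Windows start at multiples of the stride; only full windows are
#' emitted, so the count is `floor((T - w) / s) + 1` for window length
#' `w` and stride `s` in samples.
#'
#' @param ts a `bold_ts` object.
#' @param cfg a [te_config()].
#' @return a list of `bold_ts` segments, each with a `window_index` field.
#' @export
sliding_windows <- function(ts, cfg = te_config()) {
  stopifnot(inherits(ts, "bold_ts"))
  w <- round(cfg$window_seconds / ts$sampling_interval)
  s <- round(cfg$stride_seconds / ts$sampling_interval)
  n <- nrow(ts$values)
  if (w < cfg$tau + 2)
    abort_input("window of ", w, " samples is too short for tau = ", cfg$tau)
  if (w > n)
    abort_input("window (", w, " samples) longer than series (", n, ")")
  starts <- seq(1L, n - w + 1L, by = max(1L, s))
  lapply(seq_along(starts), function(k) {
    seg <- ts
    seg$values <- ts$values[starts[k]:(starts[k] + w - 1L), , drop = FALSE]
    seg$window_index <- k
    seg
  })
}

#' Plug-in transfer entropy between binary symbol series
#'
#' Estimates the directed information flow from `source` (Y) to `target`
#' (X) at lag `tau`, in bits:
#' `TE = sum P(x_{t+tau}, x_t, y_t) log2[ P(x_{t+tau} | x_t, y_t) /
#' P(x_{t+tau} | x_t) ]`, with empirical (plug-in) frequencies over
#' `t = 1 .. N - tau` and zero-probability terms contributing 0.
#'
#' @param source,target integer 0/1 vectors of equal length `N > tau`.
#' @param tau positive integer lag in samples.
#' @return transfer entropy in bits (non-negative up to rounding).
#' @export
transfer_entropy <- function(source, target, tau = 1L) {
  check_symbols(source, target, tau)
  te_parts(source, target, tau)$te
}

#' Normalized transfer entropy
#'
#' Transfer entropy divided by the plug-in conditional entropy
#' `H(x_{t+tau} | x_t)` of the target, giving a value in [0, 1]
#' (the plug-in TE never exceeds that conditional entropy). The
#' degenerate 0/0 case maps to 0.
#'
#' @inheritParams transfer_entropy
#' @return normalized transfer entropy in [0, 1].
#' @export
normalized_transfer_entropy <- function(source, target, tau = 1L) {
  check_symbols(source, target, tau)
  p <- te_parts(source, target, tau)
  if (p$h_cond <= 0) return(0)
  min(1, max(0, p$te / p$h_cond))
}

check_symbols <- function(source, target, tau) {
  if (length(source) != length(target))
    abort_input("source and target lengths differ (",
                length(source), " vs ", length(target), ")")
  if (length(target) <= tau)
    abort_input("need N > tau samples, got N = ", length(target))
  if (!all(c(source, target) %in% c(0L, 1L)))
    abort_input("symbol series must be binary (0/1)")
  invisible(TRUE)
}

# Shared plug-in computation: TE(Y->X) and the target conditional entropy
# H(x_{t+tau} | x_t), both in bits, from joint counts of the 8 binary
# triples (x_{t+tau}, x_t, y_t).
te_parts <- function(source, target, tau) {
  n <- length(target)
  xf <- target[(1L + tau):n]
  xp <- target[1L:(n - tau)]
  yp <- source[1L:(n - tau)]
  m <- n - tau
  cnt <- tabulate(1L + xf * 4L + xp * 2L + yp, nbins = 8L)
  p_xyz <- cnt / m                               # (xf, xp, yp)
  # marginals: index layout is xf*4 + xp*2 + yp
  dim(p_xyz) <- c(2L, 2L, 2L)                    # [yp, xp, xf] (column-major)
  p_xy  <- apply(p_xyz, c(1, 2), sum)            # (yp, xp): P(xp, yp)
  p_xfx <- apply(p_xyz, c(2, 3), sum)            # (xp, xf): P(xf, xp)
  p_x   <- colSums(p_xy)                         # P(xp)

  te <- 0
  for (yp_i in 1:2) for (xp_i in 1:2) for (xf_i in 1:2) {
    pj <- p_xyz[yp_i, xp_i, xf_i]
    if (pj <= 0) next
    c1 <- pj / p_xy[yp_i, xp_i]                  # P(xf | xp, yp)
    c2 <- p_xfx[xp_i, xf_i] / p_x[xp_i]          # P(xf | xp)
    te <- te + pj * log2(c1 / c2)
  }
  h_cond <- 0
  for (xp_i in 1:2) for (xf_i in 1:2) {
    pj <- p_xfx[xp_i, xf_i]
    if (pj <= 0) next
    h_cond <- h_cond - pj * log2(pj / p_x[xp_i])
  }
  list(te = max(0, te), h_cond = h_cond)
}

#' Connectivity matrix of one window
#'
#' Each channel is min-max normalized and binarized; entry `(i, j)` of
#' the result is the normalized transfer entropy from channel `j` to
#' channel `i`. The diagonal is 0. A window containing a constant
#' channel raises a classed condition (`teconnect_degenerate`) that
#' [build_dataset()] catches to skip the window.
#'
#' @param window a `bold_ts` segment.
#' @param cfg a [te_config()].
#' @return an object of class `conn_matrix` with fields `values`,
#'   `roi_labels`, `subject_id`, `window_index`, `group`.
#' @export
connectivity_matrix <- function(window, cfg = te_config()) {
  stopifnot(inherits(window, "bold_ts"))
  n <- ncol(window$values)
  if (n < 2) abort_input("need >= 2 ROIs")
  labels <- colnames(window$values) %||% sprintf("ROI_%03d", seq_len(n) - 1L)
  sym <- lapply(seq_len(n), function(i) {
    binarize(minmax_normalize(window$values[, i], roi = labels[i]),
             cfg$binarize_threshold)
  })
  v <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v[i, j] <- normalized_transfer_entropy(sym[[j]], sym[[i]], cfg$tau)
  }
  structure(
    list(values = v, roi_labels = labels, subject_id = window$subject_id,
         window_index = window$window_index %||% 1L, group = window$group),
    class = "conn_matrix"
  )
}

#' Build a balanced vectorized feature dataset from a cohort
#'
#' Computes every window's connectivity matrix, draws a seeded balanced
#' subsample of `n_select` matrices (equal counts per class), and
#' vectorizes each matrix row-major over the ordered off-diagonal pairs,
#' giving `p = n (n - 1)` features named `"SRC->DST"`.
#'
#' @param cohort a list of `bold_ts` objects (see [make_cohort()]).
#' @param cfg a [te_config()].
#' @param n_select total number of matrices to keep (default 600).
#' @param balance draw equal counts per class (default TRUE).
#' @param seed integer seed for the subsample.
#' @return an object of class `feature_dataset` with fields `features`
#'   (m x p matrix), `labels` (factor), `feature_names`, `subject_ids`,
#'   `window_ids`, `matrices` (the selected `conn_matrix` objects),
#'   `cfg`, `seed`.
#' @export
build_dataset <- function(cohort, cfg = te_config(), n_select = 600L,
                          balance = TRUE, seed = 1L) {
  mats <- list()
  for (ts in cohort) {
    for (w in sliding_windows(ts, cfg)) {
      m <- tryCatch(connectivity_matrix(w, cfg),
                    teconnect_degenerate = function(e) {
                      message("skipping window ", w$window_index, " of ",
                              ts$subject_id, ": ", conditionMessage(e))
                      NULL
                    })
      if (!is.null(m)) mats[[length(mats) + 1L]] <- m
    }
  }
  groups <- vapply(mats, function(m) m$group, character(1))
  keep <- if (balance) {
    classes <- sort(unique(groups))
    per <- n_select %/% length(classes)
    avail <- table(groups)
    if (any(avail < per))
      abort_input("not enough windows per class: need ", per, ", have ",
                  paste(sprintf("%s=%d", names(avail), avail), collapse = ", "))
    with_seed(seed, unlist(lapply(classes, function(cl)
      sample(which(groups == cl), per))))
  } else {
    if (length(mats) < n_select)
      abort_input("only ", length(mats), " windows available, need ", n_select)
    with_seed(seed, sample(seq_along(mats), n_select))
  }
  keep <- sort(keep)
  mats <- mats[keep]

  labels0 <- mats[[1]]$roi_labels
  n <- length(labels0)
  # ordered off-diagonal pairs, row-major: (src 1, dst 2), (src 1, dst 3), ...
  src <- rep(seq_len(n), each = n)
  dst <- rep(seq_len(n), times = n)
  off <- src != dst
  src <- src[off]
  dst <- dst[off]
  fnames <- sprintf("%s->%s", labels0[src], labels0[dst])
  feats <- t(vapply(mats, function(m) {
    # values[i, j] = NTE(j -> i): feature "src->dst" reads values[dst, src]
    m$values[cbind(dst, src)]
  }, numeric(length(src))))
  colnames(feats) <- fnames

  structure(
    list(features = feats,
         labels = factor(vapply(mats, function(m) m$group, character(1))),
         feature_names = fnames,
         subject_ids = vapply(mats, function(m) m$subject_id, character(1)),
         window_ids = vapply(mats, function(m) m$window_index, numeric(1)),
         matrices = mats, cfg = cfg, seed = seed),
    class = "feature_dataset"
  )
}

#' @export
print.conn_matrix <- function(x, ...) {
  cat(sprintf("<conn_matrix> %s window %d (%s): %d x %d, mean NTE %.3f\n",
              x$subject_id, x$window_index, x$group, nrow(x$values),
              ncol(x$values), mean(x$values[row(x$values) != col(x$values)])))
  invisible(x)
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d windows x %d features; classes: %s\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s=%d", levels(x$labels), table(x$labels)),
                    collapse = ", ")))
  invisible(x)
}
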