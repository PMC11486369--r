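# Independent brute-force oracles, deliberately written differently from
# the implementations they check.

# Transfer entropy by explicit triple enumeration: separately coded joint,
# pair and single probability tables, looped over the 8 binary triples.
brute_te <- function(source, target, tau) {
  n <- length(target)
  xf <- target[(1 + tau):n]
  xp <- target[1:(n - tau)]
  yp <- source[1:(n - tau)]
  m <- n - tau
  p3 <- array(0, c(2, 2, 2)) # [xf+1, xp+1, yp+1]
  for (t in seq_len(m)) {
    p3[xf[t] + 1, xp[t] + 1, yp[t] + 1] <-
      p3[xf[t] + 1, xp[t] + 1, yp[t] + 1] + 1 / m
  }
  p_xpyp <- matrix(0, 2, 2)
  p_xfxp <- matrix(0, 2, 2)
  p_xp <- numeric(2)
  for (a in 1:2) for (b in 1:2) for (c in 1:2) {
    p_xpyp[b, c] <- p_xpyp[b, c] + p3[a, b, c]
    p_xfxp[a, b] <- p_xfxp[a, b] + p3[a, b, c]
  }
  for (b in 1:2) p_xp[b] <- sum(p_xfxp[, b])
  te <- 0
  for (a in 1:2) for (b in 1:2) for (c in 1:2) {
    pj <- p3[a, b, c]
    if (pj > 0) {
      num <- pj / p_xpyp[b, c]
      den <- p_xfxp[a, b] / p_xp[b]
      te <- te + pj * log2(num / den)
    }
  }
  te
}

# Conditional entropy H(x_{t+tau} | x_t) by direct counting.
brute_cond_entropy <- function(target, tau) {
  n <- length(target)
  xf <- target[(1 + tau):n]
  xp <- target[1:(n - tau)]
  m <- n - tau
  h <- 0
  for (a in 0:1) for (b in 0:1) {
    pj <- sum(xf == a & xp == b) / m
    pb <- sum(xp == b) / m
    if (pj > 0) h <- h - pj * log2(pj / pb)
  }
  h
}

# All-pairs BFS distances on an undirected 0/1 adjacency matrix.
bfs_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    depth <- 0
    while (length(frontier) > 0) {
      depth <- depth + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (d[s, w] > depth) {
            d[s, w] <- depth
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# APL / diameter over the largest component, density, transitivity --
# by explicit counting, for cross-checking global_measures().
brute_graph_measures <- function(adj) {
  n <- nrow(adj)
  d <- bfs_distances(adj)
  # largest component via reachability
  comp_id <- rep(NA_integer_, n)
  cid <- 0
  for (s in seq_len(n)) {
    if (is.na(comp_id[s])) {
      cid <- cid + 1
      comp_id[is.finite(d[s, ])] <- cid
    }
  }
  big <- which(comp_id == which.max(tabulate(comp_id)))
  if (length(big) >= 2) {
    sub <- d[big, big]
    off <- sub[row(sub) != col(sub)]
    apl <- mean(off)
    diam <- max(off)
  } else {
    apl <- diam <- 0
  }
  m_edges <- sum(adj) / 2
  # transitivity: 3 * triangles / connected triples
  tri <- 0
  triples <- 0
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    triples <- triples + k * (k - 1) / 2
    if (k >= 2) {
      for (a in seq_len(k - 1)) for (b in (a + 1):k) {
        if (adj[nb[a], nb[b]] > 0) tri <- tri + 1
      }
    }
  }
  trans <- if (triples > 0) tri / triples else 0 # each triangle counted 3x
  c(APL = apl, diameter = diam,
    density = 2 * m_edges / (n * (n - 1)), transitivity = trans)
}

# Exact two-sided rank-sum p-value by exhaustive enumeration of all
# group assignments (no ties assumed).
ranksum_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combos <- utils::combn(length(pooled), n)
  stats_all <- apply(combos, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats_all - mu) >= abs(r_obs - mu) - 1e-9)
}

# ROC AUC by explicit trapezoid integration over all score thresholds.
trapezoid_auc <- function(truth01, score) {
  ord <- order(score, decreasing = TRUE)
  truth01 <- truth01[ord]
  score <- score[ord]
  pos <- sum(truth01 == 1)
  neg <- sum(truth01 == 0)
  tp <- fp <- 0
  pts <- data.frame(fpr = 0, tpr = 0)
  i <- 1
  while (i <= length(score)) {
    j <- i
    while (j < length(score) && score[j + 1] == score[i]) j <- j + 1
    tp <- tp + sum(truth01[i:j] == 1)
    fp <- fp + sum(truth01[i:j] == 0)
    pts <- rbind(pts, data.frame(fpr = fp / neg, tpr = tp / pos))
    i <- j + 1
  }
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + tail(pts$tpr, -1)) / 2)
}

# Random 0/1 digraph adjacency (no self-loops unless asked).
random_digraph <- function(n, p = 0.3, self_loops = FALSE) {
  a <- matrix(as.numeric(runif(n * n) < p), n, n)
  if (!self_loops) diag(a) <- 0
  a
}
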