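#' @title Complex-network features of a connectivity matrix
#'
#' @description
#' Summarizes one directed connectivity matrix by 17 global graph
#' measures, 7 community-reduction scalars (average path length inside
#' the largest community found by each of seven community-detection
#' algorithms), and the effective-information triple (determinism,
#' degeneracy, EI) of the random-walker dynamics on the thresholded
#' directed graph.
#'
#' @name graph_features
NULL

GLOBAL_MEASURES <- c("APL", "BC", "CC", "diameter", "assortativity",
                     "hub_score", "eccentricity", "EC", "Knn", "mean_degree",
                     "degree_entropy", "transitivity", "SMD", "complexity",
                     "k_core", "density", "efficiency")
COMMUNITY_MEASURES <- c("AFC", "AIC", "ALC", "ALPC", "AEBC", "ASPC", "AMC")
EI_MEASURES <- c("EI", "determinism", "degeneracy")

#' Threshold a connectivity matrix into a graph view
#'
#' Directed edges keep their weight where it reaches the threshold; the
#' undirected view is the logical-OR symmetrization of the surviving
#' directed edges, unweighted. In the directed weight matrix returned
#' here, entry `(i, j)` is the weight of the edge `i -> j` (out-weights
#' in rows), the orientation the random-walker measures expect.
#'
#' @param m a `conn_matrix` (entry `(i, j)` = coupling `j -> i`) or a
#'   plain numeric matrix in the same orientation.
#' @param threshold edge-retention threshold in [0, 1] (default 0.5).
#' @return an object of class `graph_view` with fields `n`, `directed_w`,
#'   `undirected_adj`, `threshold`.
#' @export
to_graph <- function(m, threshold = 0.5) {
  v <- if (inherits(m, "conn_matrix")) m$values else as.matrix(m)
  if (threshold < 0 || threshold > 1)
    abort_input("threshold must be in [0, 1]")
  keep <- v * (v >= threshold)
  # self-loops stay in the directed (walker) view -- connectivity matrices
  # have zero diagonals anyway, but analytic fixtures may carry them; the
  # undirected view used by the graph measures excludes them.
  dw <- t(keep) # row i = out-weights of node i
  ua <- 1 * ((dw > 0) | (t(dw) > 0))
  diag(ua) <- 0
  structure(list(n = nrow(v), directed_w = dw, undirected_adj = ua,
                 threshold = threshold),
            class = "graph_view")
}

undirected_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$undirected_adj, mode = "undirected")
}

largest_component <- function(ig) {
  comp <- igraph::components(ig)
  keep <- which(comp$membership == which.max(comp$csize))
  igraph::induced_subgraph(ig, keep)
}

#' Seventeen global network measures
#'
#' All measures are computed on the undirected (OR-symmetrized) view.
#' Path-based measures (APL, efficiency, diameter, eccentricity,
#' closeness, Knn) use the largest connected component; node-level
#' measures are reduced to the node mean. Degenerate cases follow fixed
#' conventions instead of failing: a single-node component gives
#' APL = efficiency = diameter = 0; undefined transitivity or
#' assortativity (e.g. regular graphs) is recorded as 0.
#'
#' @param g a [to_graph()] result.
#' @return a named numeric vector with the 17 global measures.
#' @export
global_measures <- function(g) {
  stopifnot(inherits(g, "graph_view"))
  if (g$n < 2) abort_input("need >= 2 nodes")
  ig <- undirected_igraph(g)
  n <- g$n
  deg <- igraph::degree(ig)
  m_edges <- igraph::ecount(ig)

  lcc <- largest_component(ig)
  nl <- igraph::vcount(lcc)
  if (nl >= 2) {
    d <- igraph::distances(lcc)
    off <- d[row(d) != col(d)]
    apl <- mean(off)
    eff <- mean(1 / off)
    diam <- max(off)
    ecc <- mean(apply(d, 1, max))
    cc <- mean(igraph::closeness(lcc))
    knn_v <- igraph::knn(lcc)$knn
    knn <- mean(knn_v[is.finite(knn_v)])
  } else {
    apl <- eff <- diam <- ecc <- cc <- knn <- 0
  }

  trans <- igraph::transitivity(ig, type = "global")
  if (is.nan(trans)) trans <- 0
  assort <- suppressWarnings(igraph::assortativity_degree(ig))
  if (!is.finite(assort)) assort <- 0
  # ARPACK-based centralities consume the R RNG; fix it so identical
  # graphs give identical scalars
  hub <- if (m_edges > 0) with_seed(1L, mean(igraph::hits_scores(ig)$hub)) else 0
  ec <- if (m_edges > 0) with_seed(1L, mean(igraph::eigen_centrality(ig)$vector)) else 0

  mean_deg <- mean(deg)
  smd <- mean(deg^2)
  c(APL = apl,
    BC = mean(igraph::betweenness(ig)),
    CC = cc,
    diameter = diam,
    assortativity = assort,
    hub_score = hub,
    eccentricity = ecc,
    EC = ec,
    Knn = knn,
    mean_degree = mean_deg,
    degree_entropy = shannon_entropy(as.numeric(table(deg)) / n),
    transitivity = trans,
    SMD = smd,
    complexity = if (mean_deg > 0) smd / mean_deg else 0,
    k_core = mean(igraph::coreness(ig)),
    density = if (n > 1) 2 * m_edges / (n * (n - 1)) else 0,
    efficiency = eff)
}

# APL of the largest community found by `fun` on the (connected) graph `ig`.
community_apl <- function(ig, fun, seed) {
  memb <- with_seed(seed, igraph::membership(fun(ig)))
  big <- which(memb == names(sort(table(memb), decreasing = TRUE))[1])
  sub <- igraph::induced_subgraph(ig, big)
  if (igraph::vcount(sub) < 2) return(0)
  d <- igraph::distances(sub)
  off <- d[row(d) != col(d)]
  mean(off[is.finite(off)])
}

#' Community-reduction scalars (AFC, AIC, ALC, ALPC, AEBC, ASPC, AMC)
#'
#' Runs seven community-detection algorithms (fast-greedy, infomap,
#' leading-eigenvector, label-propagation, edge-betweenness, spin-glass,
#' multilevel) on the largest connected component of the undirected
#' view; each is reduced to the average shortest path length inside its
#' largest community. Stochastic algorithms consume seeds derived from
#' `seed`. If an algorithm is inapplicable to the graph at hand, the
#' whole-component APL is recorded with a note.
#'
#' @param g a [to_graph()] result.
#' @param seed integer seed for the stochastic algorithms.
#' @return named numeric vector of the 7 scalars.
#' @export
community_scalars <- function(g, seed = 1L) {
  stopifnot(inherits(g, "graph_view"))
  ig <- undirected_igraph(g)
  lcc <- largest_component(ig)
  if (igraph::vcount(lcc) < 2) {
    out <- rep(0, length(COMMUNITY_MEASURES))
    names(out) <- COMMUNITY_MEASURES
    return(out)
  }
  d <- igraph::distances(lcc)
  fallback <- mean(d[row(d) != col(d)])
  algos <- list(
    AFC  = igraph::cluster_fast_greedy,
    AIC  = igraph::cluster_infomap,
    ALC  = igraph::cluster_leading_eigen,
    ALPC = igraph::cluster_label_prop,
    AEBC = igraph::cluster_edge_betweenness,
    ASPC = igraph::cluster_spinglass,
    AMC  = igraph::cluster_louvain
  )
  out <- vapply(seq_along(algos), function(k) {
    tryCatch(
      community_apl(lcc, algos[[k]], derive_seed(seed, k)),
      error = function(e) {
        message(names(algos)[k], " inapplicable (", conditionMessage(e),
                "); recording whole-component APL")
        fallback
      })
  }, numeric(1))
  names(out) <- names(algos)
  out
}

#' Random-walker out-weight profiles
#'
#' Row-normalizes the thresholded directed weight matrix over the nodes
#' with positive out-strength ("active" nodes); each row is the
#' distribution of a random walker leaving that node.
#'
#' @param g a [to_graph()] result.
#' @return an object of class `walker_profile` with fields `profiles`
#'   (n_active x n matrix, rows summing to 1), `active_nodes`, `n_active`.
#' @export
walker_profiles <- function(g) {
  stopifnot(inherits(g, "graph_view"))
  s <- rowSums(g$directed_w)
  active <- which(s > 0)
  if (length(active) == 0)
    abort_input("no node has positive out-strength; walker dynamics undefined")
  prof <- g$directed_w[active, , drop = FALSE] / s[active]
  structure(list(profiles = prof, active_nodes = active,
                 n_active = length(active)),
            class = "walker_profile")
}

#' Effective information, determinism and degeneracy
#'
#' For the random-walker dynamics restricted to the `n` out-active
#' nodes: determinism is `log2(n)` minus the mean entropy of the
#' per-node out-profiles (how concentrated each node's outputs are);
#' degeneracy is `log2(n)` minus the entropy of the average profile
#' (how much different nodes' outputs pile onto the same targets);
#' effective information is their difference, equivalently the entropy
#' of the average profile minus the average per-node entropy. All in
#' bits. Restricting `n` to the out-active set keeps the
#' determinism-minus-degeneracy identity exact; note that when edges
#' point at sink nodes (nodes with no out-edges) the average profile can
#' spread over more than `n` targets, so degeneracy may be slightly
#' negative in that boundary case.
#'
#' @param p a [walker_profiles()] result.
#' @return an object of class `ei_result` with fields
#'   `effective_information`, `determinism`, `degeneracy`.
#' @export
effective_information <- function(p) {
  stopifnot(inherits(p, "walker_profile"))
  n <- p$n_active
  h_each <- apply(p$profiles, 1, shannon_entropy)
  h_mean_profile <- shannon_entropy(colMeans(p$profiles))
  det <- log2(n) - mean(h_each)
  deg <- log2(n) - h_mean_profile
  structure(list(effective_information = det - deg,
                 determinism = det, degeneracy = deg),
            class = "ei_result")
}

#' Feature table over a list of connectivity matrices
#'
#' One row per matrix: 17 global measures, 7 community scalars and the
#' effective-information triple (27 columns), plus the class label.
#' Matrices whose thresholded graph has no out-active node get `NA` in
#' the EI columns with a note; other degenerate conventions are applied
#' silently as documented in the individual measures.
#'
#' @param matrices list of `conn_matrix` objects.
#' @param threshold edge threshold passed to [to_graph()].
#' @param seed integer seed for the stochastic community algorithms.
#' @return a data.frame with the 27 measure columns plus `label`.
#' @export
feature_table <- function(matrices, threshold = 0.5, seed = 1L) {
  if (length(matrices) == 0) abort_input("need at least one matrix")
  rows <- lapply(seq_along(matrices), function(k) {
    m <- matrices[[k]]
    g <- to_graph(m, threshold)
    glob <- global_measures(g)
    comm <- community_scalars(g, seed = derive_seed(seed, k))
    ei <- tryCatch({
      r <- effective_information(walker_profiles(g))
      c(EI = r$effective_information, determinism = r$determinism,
        degeneracy = r$degeneracy)
    }, teconnect_input_error = function(e) {
      message("matrix ", k, ": ", conditionMessage(e), "; EI columns set NA")
      c(EI = NA_real_, determinism = NA_real_, degeneracy = NA_real_)
    })
    c(glob, comm, ei)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$label <- factor(vapply(matrices,
                             function(m) m$group %||% NA_character_,
                             character(1)))
  out
}

#' @export
print.ei_result <- function(x, ...) {
  cat(sprintf("<ei_result> EI %.4f = determinism %.4f - degeneracy %.4f (bits)\n",
              x$effective_information, x$determinism, x$degeneracy))
  invisible(x)
}
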