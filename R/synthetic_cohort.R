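#' @title Synthetic cohort generation
#'
#' @description
#' Generators for labeled multichannel BOLD-like time series with
#' group-dependent directed coupling. The three groups emulate the
#' qualitative network phenotypes reported for resting-state cohorts:
#' typically developing (TD) subjects get dense random directed coupling,
#' ASD-like subjects get sparse, hub-concentrated (star-like) coupling,
#' and ADHD-like subjects sit in between. Because the coupling is planted,
#' every downstream stage (transfer-entropy estimation, graph features,
#' classification, attribution) has a recoverable ground truth.
#'
#' @name synthetic_cohort
NULL

GROUPS <- c("TD", "ADHD", "ASD")

#' Default per-group coupling density profile
#'
#' Edge densities and hub settings chosen so the planted structures mirror
#' the qualitative group ordering: TD dense and well connected, ASD sparse
#' with most influence converging on a single hub (star-like), ADHD
#' intermediate. Weights are drawn uniformly and then rescaled to a fixed
#' spectral radius, so only the density/topology differs across groups.
#'
#' Alongside the subject-specific random edges, every subject carries a
#' fixed group *backbone*: a deterministic set of strong directed edges
#' shared by all subjects of the group, at group-specific positions.
#' This emulates the consistent, group-typical connections that real
#' cohorts exhibit (the premise of group classification), and gives the
#' downstream classifier a signal that is stable across subjects while
#' the random edges supply within-group variability. The backbone
#' topology encodes the group phenotype: TD's strong edges form ten
#' disjoint source-target pairs (distributed influence, star-free), the
#' ASD-like backbone is a single hub-out star (one hub drives ten
#' targets: sparse, star-shaped, maximally concentrated out-weights,
#' hence the lowest effective information), and the ADHD-like backbone
#' is two five-target hub-out stars (intermediate). Divergent (hub-out)
#' stars are used rather than convergent ones because pairwise transfer
#' entropy cannot attribute a multiply-driven target to any single
#' source, whereas a hub that solely drives each of its targets is
#' detected edge by edge.
#'
#' @return a named list with one entry per group; each entry has
#'   `density` (edge probability over ordered pairs), `hub_frac`
#'   (fraction of edges whose receiver is forced into the hub set),
#'   `n_hub` (hub set size), `n_backbone` (shared strong edges) and
#'   `backbone_weight` (their pre-scaling weight, relative to random
#'   edge weights drawn uniformly from `weight_range`).
#' @export
default_density_profile <- function() {
  list(
    TD   = list(density = 0.30, hub_frac = 0.0, n_hub = 0L,
                n_backbone = 10L, backbone_weight = 8,
                weight_range = c(0.15, 0.3)),
    ADHD = list(density = 0.15, hub_frac = 0.3, n_hub = 2L,
                n_backbone = 10L, backbone_weight = 8,
                weight_range = c(0.15, 0.3)),
    ASD  = list(density = 0.06, hub_frac = 0.7, n_hub = 1L,
                n_backbone = 10L, backbone_weight = 8,
                weight_range = c(0.15, 0.3))
  )
}

# Deterministic group-typical strong edges (receiver row, sender column).
# TD: disjoint pairs (1->2), (3->4), ...; ADHD: two hub-out stars from
# nodes 4 and 8; ASD: one hub-out star from node n_roi. Positions are
# disjoint across groups so the classifier sees group-specific features.
backbone_edges <- function(group, n_roi, n_backbone) {
  if (n_backbone == 0L) return(matrix(integer(0), 0, 2))
  k <- seq_len(n_backbone)
  if (group == "TD") {
    src <- (2L * k - 2L) %% n_roi + 1L
    dst <- (2L * k - 1L) %% n_roi + 1L
  } else if (group == "ADHD") {
    h <- c((4L - 1L) %% n_roi + 1L, (8L - 1L) %% n_roi + 1L)
    src <- h[1L + (k > ceiling(n_backbone / 2))]
    dst <- (2L * k - 2L) %% (n_roi - 1L) + 1L
  } else { # ASD
    src <- rep(n_roi, n_backbone)
    dst <- (2L * k - 2L) %% (n_roi - 1L) + 1L
  }
  bad <- src == dst
  dst[bad] <- dst[bad] %% n_roi + 1L
  unique(cbind(dst, src))
}

#' Build a group-dependent directed coupling specification
#'
#' Samples a directed influence graph for one subject. Entry `(i, j)` of
#' the adjacency is the influence of channel `j` on channel `i`. After
#' sampling, weights are rescaled (only ever shrunk) so the spectral
#' radius does not exceed `spectral_scale`, guaranteeing stationary
#' linear dynamics while preserving the designed weights of acyclic
#' backbones, whose own spectral radius is zero.
#'
#' @param group one of `"TD"`, `"ADHD"`, `"ASD"`.
#' @param n_roi number of channels (>= 4).
#' @param density_profile per-group settings, see [default_density_profile()].
#' @param seed integer seed; identical inputs give identical output.
#' @param spectral_scale target spectral radius in (0, 1).
#' @return an object of class `coupling_spec` with fields `n_roi`,
#'   `adjacency`, `group`, `spectral_scale`.
#' @export
make_coupling_graph <- function(group, n_roi = 20L,
                                density_profile = default_density_profile(),
                                seed = 1L, spectral_scale = 0.9) {
  group <- match.arg(group, GROUPS)
  if (!is.numeric(n_roi) || length(n_roi) != 1L || n_roi < 4)
    abort_input("n_roi must be a single integer >= 4, got ", n_roi)
  n_roi <- as.integer(n_roi)
  prof <- density_profile[[group]]
  if (is.null(prof)) abort_input("density_profile has no entry for group ", group)
  if (prof$density <= 0 || prof$density > 1)
    abort_input("edge density must be in (0, 1], got ", prof$density)
  if (spectral_scale <= 0 || spectral_scale >= 1)
    abort_input("spectral_scale must be in (0, 1), got ", spectral_scale)

  adj <- with_seed(seed, {
    a <- matrix(0, n_roi, n_roi)
    pairs <- which(row(a) != col(a)) # ordered off-diagonal pairs
    m <- max(1L, round(prof$density * length(pairs)))
    n_hub_edges <- round(prof$hub_frac * m)
    chosen <- integer(0)
    if (n_hub_edges > 0 && prof$n_hub > 0) {
      # hub-targeted edges: receiver (row) restricted to the hub set
      hub_rows <- seq_len(prof$n_hub)
      hub_pairs <- pairs[(row(a)[pairs] %in% hub_rows)]
      chosen <- sample(hub_pairs, min(n_hub_edges, length(hub_pairs)))
    }
    rest <- setdiff(pairs, chosen)
    chosen <- c(chosen, sample(rest, m - length(chosen)))
    wr <- prof$weight_range %||% c(0.25, 0.5)
    a[chosen] <- stats::runif(length(chosen), wr[1], wr[2])
    bb <- backbone_edges(group, n_roi, prof$n_backbone %||% 0L)
    a[bb] <- prof$backbone_weight %||% 1
    diag(a) <- 0
    a
  })

  # cap (never inflate) the spectral radius: acyclic backbones have
  # radius ~0 and must keep their designed weights
  rho <- max(Mod(eigen(adj, only.values = TRUE)$values))
  if (rho > spectral_scale) adj <- adj * (spectral_scale / rho)

  structure(
    list(n_roi = n_roi, adjacency = adj, group = group,
         spectral_scale = spectral_scale),
    class = "coupling_spec"
  )
}

#' Simulate BOLD-like series from a coupling specification
#'
#' First-order linear autoregressive network dynamics with Gaussian
#' innovations: `x_t = A x_{t-1} + eps_t`, `eps_t ~ N(0, noise_sd^2 I)`.
#' A burn-in is simulated and discarded so the retained samples are
#' (approximately) stationary. Output length is
#' `floor(duration / sampling_interval)`.
#'
#' @param spec a [make_coupling_graph()] result.
#' @param duration series duration in seconds.
#' @param sampling_interval seconds per sample (the repetition time).
#' @param noise_sd innovation standard deviation (>= 0).
#' @param seed integer seed.
#' @param burn_in number of initial samples discarded (default 100).
#' @param subject_id identifier carried through the pipeline.
#' @return an object of class `bold_ts` with fields `values`
#'   (T x n_roi matrix), `sampling_interval`, `group`, `subject_id`.
#' @export
simulate_bold <- function(spec, duration = 300, sampling_interval = 2,
                          noise_sd = 1, seed = 1L, burn_in = 100L,
                          subject_id = "sub_000") {
  stopifnot(inherits(spec, "coupling_spec"))
  n_out <- floor(duration / sampling_interval)
  if (n_out < 2) abort_input("duration / sampling_interval must be >= 2")
  if (noise_sd < 0) abort_input("noise_sd must be >= 0")
  rho <- max(Mod(eigen(spec$adjacency, only.values = TRUE)$values))
  if (rho >= 1)
    abort_input("unstable coupling: spectral radius ", round(rho, 3), " >= 1")

  n <- spec$n_roi
  total <- burn_in + n_out
  vals <- with_seed(seed, {
    eps <- matrix(stats::rnorm(total * n, 0, noise_sd), total, n)
    x <- matrix(0, total, n)
    x[1, ] <- eps[1, ]
    for (t in 2:total) x[t, ] <- drop(spec$adjacency %*% x[t - 1, ]) + eps[t, ]
    x[(burn_in + 1):total, , drop = FALSE]
  })
  colnames(vals) <- sprintf("ROI_%03d", seq_len(n) - 1L)

  structure(
    list(values = vals, sampling_interval = sampling_interval,
         group = spec$group, subject_id = subject_id),
    class = "bold_ts"
  )
}

#' Generate a balanced labeled cohort
#'
#' Per-subject seeds (one for the coupling graph, one for the dynamics)
#' are derived deterministically from the master seed, so cohorts are
#' reproducible and each subject has its own coupling realization drawn
#' from its group's profile.
#'
#' @param counts named integer vector of subjects per group,
#'   e.g. `c(TD = 20, ADHD = 20, ASD = 20)`.
#' @param n_roi,duration,sampling_interval,noise_sd simulation settings
#'   passed through to [make_coupling_graph()] / [simulate_bold()].
#' @param density_profile see [default_density_profile()].
#' @param seed master integer seed.
#' @return a list of `bold_ts` objects.
#' @export
make_cohort <- function(counts = c(TD = 20L, ADHD = 20L, ASD = 20L),
                        n_roi = 20L, duration = 300, sampling_interval = 2,
                        noise_sd = 1,
                        density_profile = default_density_profile(),
                        seed = 1L) {
  if (is.null(names(counts)) || !all(names(counts) %in% GROUPS))
    abort_input("counts must be named with groups among ",
                paste(GROUPS, collapse = ", "))
  if (any(counts < 1)) abort_input("each group count must be >= 1")
  idx <- 0L
  cohort <- list()
  for (g in names(counts)) {
    for (k in seq_len(counts[[g]])) {
      idx <- idx + 1L
      spec <- make_coupling_graph(g, n_roi, density_profile,
                                  seed = derive_seed(seed, 2L * idx))
      cohort[[idx]] <- simulate_bold(
        spec, duration, sampling_interval, noise_sd,
        seed = derive_seed(seed, 2L * idx + 1L),
        subject_id = sprintf("%s_%03d", g, k)
      )
    }
  }
  cohort
}

#' Canonical fixture graphs with known effective-information values
#'
#' Deterministic small digraphs used as analytic fixtures for the
#' effective-information measures: the all-to-hub star (every node's
#' single out-edge targets node 1, hub self-loop included), the directed
#' ring, the complete graph with self-loops, and an undirected path.
#'
#' @param kind one of `"star_all_to_hub"`, `"directed_ring"`,
#'   `"complete_with_self_loops"`, `"path"`.
#' @param n node count (>= 2; >= 3 for the ring).
#' @return an object of class `binary_graph` with fields `n`, `edges`
#'   (two-column from/to matrix, 1-indexed), `directed`.
#' @export
canonical_graph <- function(kind, n) {
  kinds <- c("star_all_to_hub", "directed_ring", "complete_with_self_loops",
             "path")
  if (!kind %in% kinds)
    abort_input("unknown graph kind '", kind, "'")
  if (n < 2 || (kind == "directed_ring" && n < 3))
    abort_input("n too small for kind ", kind)
  n <- as.integer(n)
  edges <- switch(kind,
    star_all_to_hub = cbind(seq_len(n), rep(1L, n)),
    directed_ring = cbind(seq_len(n), c(seq_len(n)[-1], 1L)),
    complete_with_self_loops = as.matrix(expand.grid(from = seq_len(n),
                                                     to = seq_len(n))),
    path = cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)
  )
  edges <- unname(as.matrix(edges))
  storage.mode(edges) <- "integer"
  structure(list(n = n, edges = edges, directed = kind != "path"),
            class = "binary_graph")
}

#' Adjacency matrix of a binary fixture graph
#'
#' @param g a [canonical_graph()] result.
#' @return an `n x n` 0/1 matrix with entry `(i, j) = 1` iff there is an
#'   edge `i -> j` (both directions filled for undirected graphs).
#' @export
graph_adjacency <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  a <- matrix(0, g$n, g$n)
  a[g$edges] <- 1
  if (!g$directed) a[g$edges[, c(2, 1), drop = FALSE]] <- 1
  a
}

#' @export
print.bold_ts <- function(x, ...) {
  cat(sprintf("<bold_ts> %s (%s): %d samples x %d ROIs, TR %gs\n",
              x$subject_id, x$group, nrow(x$values), ncol(x$values),
              x$sampling_interval))
  invisible(x)
}

#' @export
print.coupling_spec <- function(x, ...) {
  cat(sprintf("<coupling_spec> %s: %d ROIs, %d directed edges, spectral radius %.2f\n",
              x$group, x$n_roi, sum(x$adjacency != 0), x$spectral_scale))
  invisible(x)
}
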