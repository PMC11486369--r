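#' Shannon entropy of a probability vector, in bits
#'
#' Zero entries contribute nothing (the 0 * log 0 = 0 convention).
#' The vector is not renormalized; callers pass proper distributions.
#'
#' @param p numeric vector of non-negative probabilities summing to 1.
#' @return entropy in bits.
#' @keywords internal
shannon_entropy <- function(p) {
  p <- p[p > 0]
  if (length(p) == 0L) return(0)
  -sum(p * log2(p))
}

#' Derive a child seed from a master seed
#'
#' Deterministic mixing of a master seed and a stream index so that
#' per-subject / per-algorithm randomness is reproducible and decoupled.
#' The result is always a positive 32-bit integer.
#'
#' @param master integer master seed.
#' @param index non-negative integer stream index.
#' @return an integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master, index) {
  stopifnot(is.numeric(master), length(master) == 1L,
            is.numeric(index), length(index) == 1L, index >= 0)
  m <- .Machine$integer.max # 2^31 - 1
  v <- (abs(master) %% m) * 48271 + (index + 1) * 16807
  as.integer(v %% (m - 1L) + 1)
}

#' Evaluate an expression under a fixed seed
#'
#' Runs `expr` with the RNG seeded to `seed` and restores the caller's
#' RNG state afterwards, so seeded sub-computations do not perturb
#' surrounding randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Abort with a classed condition so callers can distinguish validation errors.
abort_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("teconnect_input_error", "error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
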