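# Internal helpers shared across modules.

#' Run an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded generators do not
#' disturb the global random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stage seed from a master seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# logit / inverse-logit on the log2 (M-value) scale used for methylation
beta_to_m <- function(beta) log2(beta / (1 - beta))
m_to_beta <- function(m) {
  b <- 2^m / (1 + 2^m)
  b[is.infinite(2^m)] <- 1
  b
}
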