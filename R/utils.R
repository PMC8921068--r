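# Internal helpers: seeded evaluation without touching global RNG state,
# and deterministic per-stage seed derivation from a master seed.

withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

# Deterministic child seed: keeps results reproducible from one master seed
# while decorrelating stages. Stays below 2^31.
deriveSeed <- function(master, stage) {
  (as.numeric(master) * 7919 + stage * 104729) %% 2147483647
}

stopIfNot <- function(cond, msg, ...) {
  if (!cond) stop(sprintf(msg, ...), call. = FALSE)
}

# symmetric PSD check with eigenvalue tolerance
isPSD <- function(S, tol = 1e-10) {
  is.matrix(S) && nrow(S) == ncol(S) && max(abs(S - t(S))) <= 1e-8 &&
    min(eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values) >= -tol
}
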