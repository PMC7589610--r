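# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a per-stage seed from a master seed; keeps results from one stage
# independent of changes in another stage's draw count.
derive_seed <- function(seed, stage) {
  offsets <- c(simulate = 101L, split = 211L, noise = 307L)
  off <- offsets[[stage]]
  as.integer((abs(seed) + off) %% (.Machine$integer.max - 1000L))
}

as_matrix <- function(x, what) {
  m <- as.matrix(x)
  if (!is.numeric(m)) stop(sprintf("`%s` must be numeric", what), call. = FALSE)
  storage.mode(m) <- "double"
  m
}

stopifnot_scalar_in <- function(x, name, lo, hi, open_lo = FALSE, open_hi = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_lo) x > lo else x >= lo) && (if (open_hi) x < hi else x <= hi)
  if (!ok) {
    stop(sprintf("`%s` must be a single value in %s%g, %g%s", name,
                 if (open_lo) "(" else "[", lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(x)
}
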