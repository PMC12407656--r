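# internal helpers shared across modules

# Derive a reproducible substream seed from a master seed and a stream name.
# Keeps results stable when one stage adds RNG draws: each stage consumes its
# own stream. Kept below 2^31 - 1 so it is always a valid R integer seed.
substreamSeed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) * 2654435761 + h) %% 2147483647)
}

withSubstream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substreamSeed(seed, name))
  expr
}

# z-score a vector; constant input is an error unless allowConstant
zscore <- function(x, allowConstant = FALSE) {
  s <- sd(x, na.rm = TRUE)
  if (is.na(s) || s == 0) {
    if (allowConstant) return(x - mean(x, na.rm = TRUE))
    stop("cannot standardize a constant (zero-variance) variable")
  }
  (x - mean(x, na.rm = TRUE)) / s
}

stopIfNot01 <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop(sprintf("%s must lie in [0, 1]", what))
  invisible(TRUE)
}
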