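# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Trapezoidal integral of y over x (x strictly increasing).
trapz <- function(x, y) {
  sum(diff(x) * (y[-length(y)] + y[-1]) / 2)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("synscreen_validation_error", "error")))
}

stop_schema <- function(...) {
  stop(errorCondition(paste0(...), class = c("synscreen_schema_error", "synscreen_validation_error", "error")))
}

# Multiplicative log-normal noise factors with mean 1 and coefficient of
# variation cv; cv = 0 returns exact ones so noise-free runs are bitwise exact.
lognormal_factors <- function(n, cv) {
  if (cv < 0) stop_validation("noise_cv must be >= 0")
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

# Run expr with a local RNG state seeded at `seed`; the caller's RNG stream
# is untouched, so simulators are deterministic without side effects.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_validation("seed must be a single finite number")
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
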