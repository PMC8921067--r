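## Internal helpers. Seeding discipline: every stochastic generator runs under
## with_seed() so the caller's RNG stream is left untouched.

with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop_input("%s must lie in [0, 1]", what)
  }
  invisible(x)
}

## One Dirichlet draw via normalized gammas; alpha on the concentration scale.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) {            # numerically degenerate; fall back to mean
    return(alpha / sum(alpha))
  }
  g / sum(g)
}
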