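# Internal numerical helpers.

# Self-contained RNG stream: draws are reproducible for a fixed seed and
# never disturb (or depend on) the caller's .Random.seed.
local_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  state <- NULL
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        get(".Random.seed", envir = globalenv())
      }
      if (is.null(state)) {
        set.seed(as.integer(seed))
      } else {
        assign(".Random.seed", state, envir = globalenv())
      }
      out <- f(...)
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
      out
    }
  }
  list(runif = with_state(stats::runif),
       rnorm = with_state(stats::rnorm),
       sample_int = with_state(function(n, size, replace = FALSE) {
         sample.int(n, size, replace = replace)
       }))
}

# Upper-triangular factor U with t(U) %*% U = r; eigen fallback for
# correlation matrices that are only numerically PSD.
chol_psd <- function(r) {
  out <- tryCatch(chol(r), error = function(e) NULL)
  if (is.null(out)) {
    e <- eigen(r, symmetric = TRUE)
    v <- pmax(e$values, 0)
    out <- diag(sqrt(v), nrow = length(v)) %*% t(e$vectors)
  }
  out
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf (with warning) when
# round-off drives the difference non-positive.
logdiff <- function(a, b) {
  if (b >= a) {
    if (b > a + 1e-12) warning("logdiff: negative difference clamped to -Inf")
    return(-Inf)
  }
  a + log1p(-exp(b - a))
}
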