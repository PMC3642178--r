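## Small internal helpers: scoped RNG seeding, Dirichlet draws, HPD intervals.

## Seed the RNG for the calling function only: the previous global RNG state
## is restored when the caller exits, so seeded routines do not disturb the
## session stream.
local_rng <- function(seed, envir = parent.frame()) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr <- if (is.null(old)) {
    quote(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  } else {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = envir)
  invisible(NULL)
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n, salt = 0L) {
  (as.numeric(seed) * 7919 + salt * 104729 + seq_len(n) * 31337) %% 2147483587
}

rdirichlet1 <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x <- rep(1, length(alpha))
  x / sum(x)
}

#' Shortest highest-posterior-density interval from samples
#'
#' @param x numeric vector of posterior draws.
#' @param prob interval mass (default 0.95).
#' @return Length-2 vector `c(lower, upper)`.
#' @export
hpdi <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  k <- max(1L, ceiling(prob * n))
  if (k >= n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  j <- which.min(widths)
  c(x[j], x[j + k])
}

logsumexp <- function(x) { m <- max(x); m + log(sum(exp(x - m))) }
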