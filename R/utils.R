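#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-stream seed
#'
#' Mixes a base seed with an arbitrary sequence of tags (integers or strings)
#' through a multiplicative-congruential hash so that every animal, visit and
#' pulse sequence gets its own deterministic RNG stream. The result always
#' lies in `[1, 2^31 - 2]`.
#'
#' @param seed Base integer seed.
#' @param ... Tags (character or numeric) identifying the sub-stream.
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, ...) {
  m <- 2147483647 # 2^31 - 1, prime
  s <- as.numeric(seed) %% m
  for (tag in list(...)) {
    ks <- if (is.character(tag)) as.numeric(utf8ToInt(tag)) else as.numeric(tag)
    for (k in ks) {
      s <- (s * 69069 + 101 + (k %% m)) %% m
    }
  }
  as.integer(s %% (m - 2) + 1)
}

# Evaluate expr with a local RNG state; the caller's .Random.seed is restored.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

# Multiplicative log-normal draw with mean `mean` and coefficient of
# variation `cv` (mean-preserving parameterization).
rlnorm_cv <- function(n, mean, cv) {
  if (cv <= 0) return(rep(mean, n))
  sdlog <- sqrt(log(1 + cv^2))
  mean * exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)
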