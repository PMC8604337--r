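#' @useDynLib CINspect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats median rbeta rbinom rnbinom rpois runif sd
#' @importFrom utils combn head read.csv read.table write.csv write.table
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so they are pure
# functions of (config, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Negative-binomial draw parameterized by mean and dispersion:
# var = mu + dispersion * mu^2; dispersion 0 reduces to Poisson.
rnbinom_md <- function(n, mu, dispersion) {
  stopifnot(dispersion >= 0)
  out <- numeric(n)
  pos <- mu > 0
  if (dispersion == 0) {
    out[pos] <- rpois(sum(pos), mu[pos])
  } else {
    out[pos] <- rnbinom(sum(pos), size = 1 / dispersion, mu = mu[pos])
  }
  out
}

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
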