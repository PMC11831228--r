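#' @useDynLib octccr, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mvfft rnorm runif var sd pf setNames
#' @importFrom utils head read.csv write.csv
NULL

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.  All stochastic package code routes through
# this so that global RNG state is never perturbed.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child seed from a parent seed and one or more indices;
# stays well below 2^31.
derive_seed <- function(seed, ...) {
  idx <- c(...)
  s <- as.double(seed) %% 2147480000
  for (i in idx) s <- (s * 69069 + as.double(i) * 30011 + 7) %% 2147480000
  as.integer(s)
}

clip01 <- function(x) pmax(pmin(x, 1), 0)

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 1
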