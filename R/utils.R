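#' @importFrom rlang abort warn %||%
#' @importFrom stats qnorm pt pbeta rbeta rnorm rbinom runif median sd var integrate
NULL

# round half away from zero (base round() is banker's); reports use half-up
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# evaluate code under a fixed seed, restoring the caller's RNG state afterwards
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  code
}

stopf <- function(class, fmt, ...) {
  abort(sprintf(fmt, ...), class = c(class, "missbench_error"))
}
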