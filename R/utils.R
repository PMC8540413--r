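#' Derive independent sub-seeds from a master seed
#'
#' All stochastic steps in the package (random effects, residual error,
#' covariate generation, sampling-time jitter, bootstrap resampling) draw from
#' purpose-specific streams split deterministically from one master seed, so
#' that e.g. toggling residual error does not change the eta sequence.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds to derive.
#' @return integer vector of `n` sub-seeds, each in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sample.int(.Machine$integer.max - 1L, n)
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# verbosity-gated message; silence with options(levipop.verbose = FALSE)
lp_log <- function(...) {
  if (isTRUE(getOption("levipop.verbose", FALSE))) message(sprintf(...))
  invisible(NULL)
}

# inverse-CDF draws from a normal truncated to [lo, hi]
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# log-normal truncated to [lo, hi] on the natural scale
rlnorm_trunc <- function(n, meanlog, sdlog, lo = 0, hi = Inf) {
  exp(rnorm_trunc(n, meanlog, sdlog, log(lo), log(hi)))
}
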