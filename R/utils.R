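# Internal numeric helpers shared across modules.

#' Logit transform
#'
#' `log(p / (1 - p))`, used to place propensity scores on the scale on which
#' the matching caliper is defined.
#'
#' @param p numeric vector of probabilities, all strictly inside (0, 1).
#' @return numeric vector of log-odds.
#' @examples
#' logit(0.5)      # 0
#' logit(0.75)     # log(3)
#' @export
logit <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("logit() requires probabilities strictly inside (0, 1)", call. = FALSE)
  }
  log(p / (1 - p))
}

expit <- function(x) 1 / (1 + exp(-x))

#' @keywords internal
#' Percent with 2-decimal, round-half-even formatting (base round() is
#' half-even). Exact fractions are kept alongside; this is display only.
as_percent <- function(x, digits = 2) round(100 * x, digits)

# Lognormal parameters (meanlog, sdlog) with given arithmetic mean and sd.
lognormal_params <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# Moments of a normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  pa <- stats::dnorm(al)
  pb <- stats::dnorm(be)
  m <- mu + sigma * (pa - pb) / z
  v <- sigma^2 * (1 + (al * pa - be * pb) / z - ((pa - pb) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) such that the [a,b]-truncated normal has the target
# mean and sd. Solved numerically; targets must be attainable inside [a,b].
truncnorm_params <- function(mean, sd, a = 1, b = 10) {
  stopifnot(mean > a, mean < b, sd > 0)
  obj <- function(par) {
    mo <- truncnorm_moments(par[1], exp(par[2]), a, b)
    (mo$mean - mean)^2 + (mo$sd - sd)^2
  }
  fit <- stats::optim(c(mean, log(sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  list(mu = fit$par[1], sigma = exp(fit$par[2]))
}

rtruncnorm <- function(n, mu, sigma, a = 1, b = 10) {
  lo <- stats::pnorm(a, mu, sigma)
  hi <- stats::pnorm(b, mu, sigma)
  stats::qnorm(lo + stats::runif(n) * (hi - lo), mu, sigma)
}

# Stable, platform-independent child seed from a master seed and a label.
# Stage insertion never perturbs other stages' randomness.
stable_seed <- function(seed, label) {
  mod <- 2147483629
  h <- 0
  for (byte in utf8ToInt(label)) h <- (h * 31 + byte) %% mod
  as.integer((abs(seed) %% mod * 48271 + h) %% mod)
}

# Evaluate expr under a temporary seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
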