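#' Ex-Gaussian log-density
#'
#' Density of the ex-Gaussian (exponentially modified Gaussian)
#' distribution: the sum of a Gaussian with mean `mu` and standard
#' deviation `sigma` and an independent exponential with mean `tau`.
#' In response-time modeling the Gaussian component absorbs additive
#' sensorimotor noise while the exponential component carries the
#' decision-related mass, so condition effects placed on `tau` shift
#' mean and variance together, as empirically observed for RTs.
#'
#' Two evaluation routes are used for numerical stability. For
#' `z = (x - mu)/sigma - sigma/tau >= 0` the direct form
#' `-log(tau) + (mu - x)/tau + sigma^2/(2 tau^2) + pnorm(z, log.p = TRUE)`
#' is safe. For `z < 0` (the regime where `sigma/tau` is large and the
#' direct form cancels catastrophically) the density is rewritten via the
#' scaled complementary error function as
#' `-log(2 tau) - (x - mu)^2 / (2 sigma^2) + log(erfcx(-z/sqrt(2)))`,
#' which is exact and stable because `erfcx` never overflows for
#' positive arguments. The crossover is at `z = 0`.
#'
#' @param x numeric vector of quantiles (ms).
#' @param mu Gaussian component mean (ms); may be a vector recycled
#'   against `x`.
#' @param sigma Gaussian component standard deviation (ms), positive.
#' @param tau exponential component mean (ms), positive.
#' @param log if `TRUE` (default for [exgauss_logpdf()]) return the
#'   log-density.
#' @return numeric vector of (log-)density values, finite for all finite
#'   `x`.
#' @examples
#' exgauss_logpdf(600, mu = 473, sigma = 50, tau = 166)
#' integrate(function(x) dexgauss(x, 0, 1, 1), -10, 30)$value # ~1
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(sigma, tau)
  n <- max(length(x), length(mu), length(sigma), length(tau))
  x <- rep_len(x, n)
  mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n)
  tau <- rep_len(tau, n)

  z <- (x - mu) / sigma - sigma / tau
  out <- numeric(n)
  direct <- z >= 0
  if (any(direct)) {
    i <- direct
    out[i] <- -base::log(tau[i]) + (mu[i] - x[i]) / tau[i] +
      sigma[i]^2 / (2 * tau[i]^2) + stats::pnorm(z[i], log.p = TRUE)
  }
  if (any(!direct)) {
    i <- !direct
    out[i] <- -base::log(2 * tau[i]) - (x[i] - mu[i])^2 / (2 * sigma[i]^2) +
      log_erfcx(-z[i] / sqrt(2))
  }
  if (log) out else exp(out)
}

#' @rdname dexgauss
#' @param params optionally, a list with elements `mu_ms`, `sigma_ms`,
#'   `tau_ms` (as produced by [exgauss_params()]), taking precedence
#'   over `mu`, `sigma`, `tau`.
#' @export
exgauss_logpdf <- function(x, mu, sigma, tau, params = NULL) {
  if (!is.null(params)) {
    mu <- params$mu_ms
    sigma <- params$sigma_ms
    tau <- params$tau_ms
  }
  dexgauss(x, mu, sigma, tau, log = TRUE)
}

#' Ex-Gaussian parameter container
#'
#' @param mu_ms Gaussian mean (ms).
#' @param sigma_ms Gaussian SD (ms), must be positive.
#' @param tau_ms exponential mean (ms), must be positive.
#' @return a list of class `exgauss_params`.
#' @export
exgauss_params <- function(mu_ms, sigma_ms, tau_ms) {
  check_exgauss_params(sigma_ms, tau_ms)
  structure(list(mu_ms = mu_ms, sigma_ms = sigma_ms, tau_ms = tau_ms),
            class = "exgauss_params")
}

# log of the scaled complementary error function for y >= 0:
# pracma's direct evaluation below y = 25, the asymptotic series
# 1/(y sqrt(pi)) (1 - 1/(2y^2) + 3/(4y^4) - ...) beyond (where the
# direct route overflows and the series error is < 1e-12 relative).
log_erfcx <- function(y) {
  out <- numeric(length(y))
  lo <- y < 25
  if (any(lo)) out[lo] <- base::log(pracma::erfcx(y[lo]))
  if (any(!lo)) {
    yy <- y[!lo]^2
    out[!lo] <- -base::log(y[!lo] * sqrt(pi)) +
      log1p(-0.5 / yy + 0.75 / yy^2 - 1.875 / yy^3 + 6.5625 / yy^4)
  }
  out
}

check_exgauss_params <- function(sigma, tau) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("ex-Gaussian `sigma` must be strictly positive", call. = FALSE)
  }
  if (any(!is.finite(tau)) || any(tau <= 0)) {
    stop("ex-Gaussian `tau` must be strictly positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Sample from the ex-Gaussian distribution
#'
#' Draws are the sum of a Gaussian and an independent exponential
#' deviate, so the mean is `mu + tau` and the variance `sigma^2 + tau^2`.
#'
#' @param n number of draws.
#' @param mu,sigma,tau ex-Gaussian parameters (ms); vectors of length
#'   `n` are allowed for trial-varying parameters.
#' @param seed optional integer seed applied locally (the caller's RNG
#'   state is restored on exit); omit to use the current RNG stream.
#' @return numeric vector of `n` draws in ms.
#' @export
rexgauss <- function(n, mu, sigma, tau, seed = NULL) {
  if (length(n) != 1L || !is.finite(n) || n < 1) {
    stop("`n` must be a single integer >= 1", call. = FALSE)
  }
  check_exgauss_params(sigma, tau)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  stats::rnorm(n, mean = mu, sd = sigma) + stats::rexp(n, rate = 1) * tau
}

#' Saturating-exponential trajectory of the exponential component
#'
#' The exponential-component mean `tau` evolves across trials as
#' `tau(t) = asym + (start - asym) * 2^(-(t - 1) / rate)`: it equals
#' `start` exactly at the first trial and approaches `asym`
#' monotonically. `rate` is a time constant in trials: at
#' `t = 1 + rate` exactly half of the start-to-asymptote change has
#' been completed. Smaller rates therefore mean faster change.
#'
#' @param t trial index, numeric vector with all elements `>= 1`.
#' @param start_ms trajectory value at trial 1 (ms).
#' @param rate_trials time constant (trials), positive: number of
#'   trials after onset needed to complete 50% of the change.
#' @param asym_ms limiting value as `t` grows (ms).
#' @param traj optionally a list with elements `start_ms`,
#'   `rate_trials`, `asym_ms` (see [trajectory_params()]), taking
#'   precedence over the individual arguments.
#' @return numeric vector of tau values (ms), same length as `t` (after
#'   recycling against parameter vectors).
#' @examples
#' tau_trajectory(1, 300, 10, 150)            # = 300
#' tau_trajectory(11, 300, 10, 150)           # = 225, half the change
#' @export
tau_trajectory <- function(t, start_ms, rate_trials, asym_ms, traj = NULL) {
  if (!is.null(traj)) {
    start_ms <- traj$start_ms
    rate_trials <- traj$rate_trials
    asym_ms <- traj$asym_ms
  }
  if (any(!is.finite(t)) || any(t < 1)) {
    stop("trial index `t` must be >= 1", call. = FALSE)
  }
  if (any(rate_trials <= 0)) {
    stop("`rate_trials` must be strictly positive", call. = FALSE)
  }
  asym_ms + (start_ms - asym_ms) * 2^(-(t - 1) / rate_trials)
}

#' Trajectory parameter container
#'
#' @param start_ms tau at trial 1 (ms), positive.
#' @param rate_trials time constant in trials, positive.
#' @param asym_ms asymptotic tau (ms), positive.
#' @return a list of class `trajectory_params`.
#' @export
trajectory_params <- function(start_ms, rate_trials, asym_ms) {
  vals <- c(start_ms, rate_trials, asym_ms)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("trajectory parameters must all be strictly positive",
         call. = FALSE)
  }
  structure(list(start_ms = start_ms, rate_trials = rate_trials,
                 asym_ms = asym_ms),
            class = "trajectory_params")
}

# RNG bookkeeping so seeded helpers do not disturb the caller's stream.
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
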