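# Adaptive random-walk Metropolis over the full parameter vector,
# started at the MAP solution with the Laplace covariance as the
# proposal shape. Intended for interval checks on small models; the
# map backend is the workhorse for realistic sizes.
mcmc_augment <- function(fit, control = list(), seed = 1L) {
  n_iter <- control$n_iter %||% 4000L
  warmup <- control$warmup %||% 1000L
  chains <- control$chains %||% 2L
  keep_ll <- control$keep_ll %||% 200L

  design <- fit$design
  layout <- fit$layout
  obj <- make_objective(design, layout, fit$prior, fit$sigma_b)
  logpost <- function(theta) -obj$fn(theta)
  p <- layout$n_par

  covm <- fit$cov
  if (is.null(covm)) covm <- diag(1e-4, p)
  ev <- eigen(covm, symmetric = TRUE)
  ev$values <- pmax(ev$values, 1e-10)
  L <- ev$vectors %*% diag(sqrt(ev$values), p)

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  n_keep <- n_iter - warmup
  draws <- array(NA_real_, dim = c(n_keep, chains, p))
  accept <- numeric(chains)
  for (ch in seq_len(chains)) {
    scale <- 2.38 / sqrt(p)
    theta <- fit$theta + if (ch == 1) 0 else
      as.vector(L %*% stats::rnorm(p)) * 0.5
    lp <- logpost(theta)
    acc_window <- 0L
    for (it in seq_len(n_iter)) {
      prop <- theta + scale * as.vector(L %*% stats::rnorm(p))
      prop <- pmin(pmax(prop, -30), 30)
      lp_prop <- logpost(prop)
      if (is.finite(lp_prop) &&
          log(stats::runif(1)) < lp_prop - lp) {
        theta <- prop
        lp <- lp_prop
        acc_window <- acc_window + 1L
        if (it > warmup) accept[ch] <- accept[ch] + 1
      }
      if (it <= warmup && it %% 100L == 0L) {
        rate <- acc_window / 100
        scale <- scale * exp(rate - 0.234)
        acc_window <- 0L
      }
      if (it > warmup) draws[it - warmup, ch, ] <- theta
    }
  }
  accept <- accept / n_keep

  rhat <- vapply(seq_len(p), function(j) {
    split_rhat(draws[, , j, drop = FALSE])
  }, numeric(1))
  ess <- vapply(seq_len(p), function(j) {
    crude_ess(draws[, , j, drop = FALSE])
  }, numeric(1))

  flat <- matrix(aperm(draws, c(1, 2, 3)), nrow = n_keep * chains, ncol = p)
  fixed_idx <- c(unlist(layout$beta, use.names = FALSE),
                 layout$log_sigma)
  qs <- apply(flat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975))
  pm <- colMeans(flat)
  fixed <- fit$fixed
  pos <- 0L
  for (tg in names(layout$beta)) {
    for (j in layout$beta[[tg]]) {
      pos <- pos + 1L
      fixed$estimate[pos] <- pm[j]
      fixed$ci_low[pos] <- qs[1, j]
      fixed$ci_high[pos] <- qs[3, j]
      fixed$se[pos] <- stats::sd(flat[, j])
    }
  }
  ls <- layout$log_sigma
  fixed$estimate[nrow(fixed)] <- pm[ls]
  fixed$ci_low[nrow(fixed)] <- qs[1, ls]
  fixed$ci_high[nrow(fixed)] <- qs[3, ls]
  fixed$se[nrow(fixed)] <- stats::sd(flat[, ls])
  fit$fixed <- fixed

  thin_idx <- unique(round(seq(1, nrow(flat),
                               length.out = min(keep_ll, nrow(flat)))))
  ll_draws <- t(vapply(thin_idx, function(s) {
    ll_pieces(design, layout, flat[s, ])$ll
  }, numeric(design$n)))
  fit$loglik_draws <- ll_draws
  fit$draws <- flat
  max_rhat <- max(rhat, na.rm = TRUE)
  fit$diagnostics <- utils::modifyList(fit$diagnostics, list(
    rhat = rhat, ess = ess, max_rhat = max_rhat,
    min_ess = min(ess, na.rm = TRUE), accept_rate = accept,
    n_iter = n_iter, warmup = warmup, chains = chains))
  if (max_rhat > 1.05) {
    warning(sprintf(
      "MCMC convergence is inadequate (max split R-hat = %.3f > 1.05)",
      max_rhat), call. = FALSE)
  } else if (max_rhat > 1.01) {
    message(sprintf("max split R-hat = %.3f (above 1.01; consider %s)",
                    max_rhat, "more iterations"))
  }
  fit
}

# Split-chain potential scale reduction (each chain halved).
split_rhat <- function(x) {
  n <- dim(x)[1]
  m <- dim(x)[2]
  half <- floor(n / 2)
  mats <- list()
  for (ch in seq_len(m)) {
    mats[[2 * ch - 1]] <- x[seq_len(half), ch, 1]
    mats[[2 * ch]] <- x[(half + 1):(2 * half), ch, 1]
  }
  means <- vapply(mats, mean, numeric(1))
  vars <- vapply(mats, stats::var, numeric(1))
  W <- mean(vars)
  B <- half * stats::var(means)
  if (W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# First-negative-autocorrelation ESS estimate, pooled over chains.
crude_ess <- function(x) {
  n <- dim(x)[1]
  m <- dim(x)[2]
  ess <- 0
  for (ch in seq_len(m)) {
    v <- x[, ch, 1]
    if (stats::sd(v) == 0) next
    ac <- stats::acf(v, lag.max = min(200, n - 1), plot = FALSE,
                     demean = TRUE)$acf[-1]
    neg <- which(ac < 0)
    cut <- if (length(neg) > 0) neg[1] - 1L else length(ac)
    ess <- ess + n / (1 + 2 * sum(ac[seq_len(cut)]))
  }
  ess
}

#' MCMC diagnostics of a sampled fit
#'
#' @param fit an `iat_fit` produced with `method = "mcmc"`.
#' @return list with `max_rhat`, `min_ess`, per-parameter `rhat` and
#'   `ess`, and the per-chain acceptance rates.
#' @export
mcmc_diagnostics <- function(fit) {
  if (fit$method != "mcmc") {
    stop("fit was not sampled; no MCMC diagnostics available",
         call. = FALSE)
  }
  d <- fit$diagnostics
  list(max_rhat = d$max_rhat, min_ess = d$min_ess, rhat = d$rhat,
       ess = d$ess, accept_rate = d$accept_rate)
}
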