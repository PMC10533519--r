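#' Effect-size result container
#'
#' @param kind one of `"paired_t"`, `"welch_t"`, `"cohen_d_between"`,
#'   `"wilcoxon_signrank"`.
#' @param statistic the test statistic (t, d, W or Z by kind).
#' @param effect_d the standardized effect size.
#' @param ci_low,ci_high interval bounds (analytic or bootstrap
#'   percentile).
#' @param n sample size(s).
#' @param p_value two-sided p value when defined.
#' @param degenerate flag for zero-variance inputs.
#' @param extra named list of kind-specific detail.
#' @return a list of class `iat_effect`.
#' @keywords internal
iat_effect <- function(kind, statistic, effect_d, ci_low, ci_high, n,
                       p_value = NA_real_, degenerate = FALSE,
                       extra = list()) {
  structure(list(kind = kind, statistic = statistic,
                 effect_d = effect_d, ci_low = ci_low,
                 ci_high = ci_high, n = n, p_value = p_value,
                 degenerate = degenerate, extra = extra),
            class = "iat_effect")
}

#' @export
print.iat_effect <- function(x, ...) {
  cat(sprintf("<%s> statistic = %.4g, d = %.4g, CI = [%.4g, %.4g]",
              x$kind, x$statistic, x$effect_d, x$ci_low, x$ci_high))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.3g", x$p_value))
  if (x$degenerate) cat("  [degenerate]")
  cat("\n")
  invisible(x)
}

#' Paired contrast with a paired-design Cohen's d
#'
#' Paired t test of `y - x` with the paired-design effect size
#' `d = mean(y - x) / sd(y - x)` and the analytic 95% CI of the mean
#' difference.
#'
#' @param x,y per-participant values of equal length (>= 2).
#' @return an `iat_effect` of kind `paired_t`.
#' @export
paired_contrast <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  if (length(x) < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- y - x
  if (stats::sd(d) == 0) {
    return(iat_effect("paired_t", statistic = NA_real_,
                      effect_d = NA_real_, ci_low = mean(d),
                      ci_high = mean(d), n = length(d),
                      degenerate = TRUE,
                      extra = list(mean_diff = mean(d))))
  }
  tt <- stats::t.test(d)
  iat_effect("paired_t", statistic = unname(tt$statistic),
             effect_d = mean(d) / stats::sd(d),
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             n = length(d), p_value = tt$p.value,
             extra = list(mean_diff = mean(d)))
}

#' Welch two-sample contrast with a pooled-SD Cohen's d
#'
#' Welch t with Satterthwaite degrees of freedom; the effect size is
#' the between-subjects `d = (mean(a) - mean(b)) / s_pooled` with the
#' classical pooled SD. The CI is the Welch interval for the mean
#' difference.
#'
#' @param a,b group value vectors, each of length >= 2.
#' @return an `iat_effect` of kind `welch_t`.
#' @export
welch_contrast <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop("each group needs at least 2 values", call. = FALSE)
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    stop("both groups are degenerate (zero variance)", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = FALSE)
  sp <- sqrt(((length(a) - 1) * stats::var(a) +
              (length(b) - 1) * stats::var(b)) /
             (length(a) + length(b) - 2))
  iat_effect("welch_t", statistic = unname(tt$statistic),
             effect_d = (mean(a) - mean(b)) / sp,
             ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
             n = c(length(a), length(b)), p_value = tt$p.value,
             extra = list(df = unname(tt$parameter),
                          mean_diff = mean(a) - mean(b)))
}

boot_percentile <- function(stat, data_list, n_boot, seed,
                            probs = c(0.025, 0.975)) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  lens <- vapply(data_list, length, integer(1))
  draws <- vapply(seq_len(n_boot), function(b) {
    resampled <- lapply(data_list, function(v) {
      v[sample.int(length(v), replace = TRUE)]
    })
    do.call(stat, resampled)
  }, numeric(1))
  stats::quantile(draws, probs, names = FALSE, na.rm = TRUE)
}

#' Between-subjects Cohen's d for one block, with bootstrap CI
#'
#' Compares a block's per-participant mean RTs between participants
#' for whom the block was incompatible versus compatible (the two
#' condition-order groups), with a seeded percentile-bootstrap 95% CI
#' of the pooled-SD d.
#'
#' @param x an [iat_trials()] dataset.
#' @param block dual-stimulus block index (3, 4, 6 or 7).
#' @param n_boot bootstrap resamples.
#' @param seed integer seed (mandatory).
#' @return an `iat_effect` of kind `cohen_d_between`; `effect_d` is
#'   the incompatible-minus-compatible standardized difference.
#' @export
blockwise_d <- function(x, block, n_boot = 5000, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  df <- tibble::as_tibble(x)
  df <- df[df$block_index == block & !is.na(df$compatibility), ,
           drop = FALSE]
  if (nrow(df) == 0) stop("no dual-stimulus trials in block ", block,
                          call. = FALSE)
  key <- interaction(df$participant_id, df$iat_type, drop = TRUE)
  means <- tapply(df$rt_ms, key, mean)
  compat <- tapply(df$compatibility, key, `[`, 1L)
  inc <- as.numeric(means[compat == "incompatible"])
  com <- as.numeric(means[compat == "compatible"])
  if (length(inc) < 2 || length(com) < 2) {
    stop("both order groups must be represented in block ", block,
         call. = FALSE)
  }
  pooled_d <- function(a, b) {
    sp <- sqrt(((length(a) - 1) * stats::var(a) +
                (length(b) - 1) * stats::var(b)) /
               (length(a) + length(b) - 2))
    (mean(a) - mean(b)) / sp
  }
  d <- pooled_d(inc, com)
  ci <- boot_percentile(pooled_d, list(inc, com), n_boot, seed)
  iat_effect("cohen_d_between", statistic = d, effect_d = d,
             ci_low = ci[1], ci_high = ci[2],
             n = c(length(inc), length(com)),
             extra = list(block = block, n_boot = n_boot, seed = seed))
}

#' Order effect on aggregate D-scores
#'
#' Welch contrast of per-participant overall D-scores between the
#' compatible-first and incompatible-first groups, with seeded
#' bootstrap 95% CIs of the two group means.
#'
#' @param dscores tibble from [d_score_all()] (columns `d_overall`,
#'   `condition_order`), or any data frame with those columns.
#' @param n_boot bootstrap resamples for the group-mean CIs.
#' @param seed integer seed (mandatory).
#' @return an `iat_effect` of kind `welch_t`, comparing
#'   compatible-first minus incompatible-first; `extra` carries the
#'   group means and their bootstrap CIs.
#' @export
order_effect <- function(dscores, n_boot = 5000, seed) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  cf <- dscores$d_overall[dscores$condition_order == "compatible_first"]
  if_ <- dscores$d_overall[dscores$condition_order ==
                           "incompatible_first"]
  if (length(cf) < 2 || length(if_) < 2) {
    stop("both condition orders must be present", call. = FALSE)
  }
  eff <- welch_contrast(cf, if_)
  ci_cf <- boot_percentile(mean, list(cf), n_boot, seed)
  ci_if <- boot_percentile(mean, list(if_), n_boot, seed + 1L)
  eff$extra <- c(eff$extra, list(
    mean_compatible_first = mean(cf),
    mean_incompatible_first = mean(if_),
    ci_compatible_first = ci_cf,
    ci_incompatible_first = ci_if,
    n_boot = n_boot, seed = seed))
  eff
}

#' Wilcoxon signed-rank contrast
#'
#' Signed-rank test of the paired differences `x - y`: zero
#' differences are dropped, ties receive mid-ranks, `W` is the sum of
#' ranks of positive differences, and `Z` is the tie-corrected normal
#' approximation (no continuity correction). The median difference is
#' reported alongside.
#'
#' @param x,y paired value vectors; at least 5 non-zero differences
#'   are required for the normal approximation.
#' @return an `iat_effect` of kind `wilcoxon_signrank` with
#'   `statistic = W`; `extra$z` holds the approximate Z and
#'   `extra$median_diff` the median of `x - y`.
#' @export
signrank_contrast <- function(x, y) {
  if (length(x) != length(y)) {
    stop("`x` and `y` must have equal length", call. = FALSE)
  }
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(iat_effect("wilcoxon_signrank", statistic = NA_real_,
                      effect_d = NA_real_, ci_low = NA_real_,
                      ci_high = NA_real_, n = 0L, degenerate = TRUE,
                      extra = list(median_diff = 0)))
  }
  if (n < 5) {
    stop("need at least 5 non-zero differences", call. = FALSE)
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
    sum(ties^3 - ties) / 48
  z <- (W - mu) / sqrt(sigma2)
  p <- 2 * stats::pnorm(-abs(z))
  iat_effect("wilcoxon_signrank", statistic = W,
             effect_d = z / sqrt(n), ci_low = NA_real_,
             ci_high = NA_real_, n = n, p_value = p,
             extra = list(z = z, median_diff = stats::median(x - y)))
}

#' Power of the product-moment correlation test
#'
#' Fisher-z approximation for the two-sided test of zero correlation:
#' `power = P(Z > z_{alpha/2} - atanh(rho) * sqrt(n - 3)) +
#'          P(Z > z_{alpha/2} + atanh(rho) * sqrt(n - 3))`
#' (the second term is the negligible wrong-sided rejection mass).
#'
#' @param n sample size (>= 4).
#' @param rho true correlation, `|rho| < 1`.
#' @param alpha two-sided level.
#' @return power in `[0, 1]`.
#' @examples
#' power_correlation(146, 0.23)  # ~0.80
#' @export
power_correlation <- function(n, rho, alpha = 0.05) {
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  if (abs(rho) >= 1) stop("`|rho|` must be below 1", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  za <- stats::qnorm(1 - alpha / 2)
  delta <- atanh(rho) * sqrt(n - 3)
  stats::pnorm(delta - za) + stats::pnorm(-delta - za)
}
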