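# Per-participant log-scale linear predictor of one target at a given
# incompatibility value, with all other covariates at their reference
# or centered-zero setting (first run, intermediate IAT type, mean
# gender/age, reference condition).
participant_eta <- function(fit, target, inc) {
  layout <- fit$layout
  design <- fit$design
  if (!"participant" %in% names(layout$ranef)) {
    stop("fit has no participant random effects; cannot extract ",
         "participant-level indices", call. = FALSE)
  }
  levels <- design$random$participant$levels
  eta <- rep(0, length(levels))
  terms <- design$targets[[target]]$terms
  cn <- colnames(design$targets[[target]]$X)
  beta <- fit$theta[layout$beta[[target]]]
  for (term in names(terms)) {
    for (j in terms[[term]]) {
      val <- switch(cn[j], intercept = 1, incomp = inc, 0)
      eta <- eta + val * beta[j]
    }
  }
  for (colname in names(layout$ranef$participant[[target]] %||%
                        list())) {
    info <- layout$ranef$participant[[target]][[colname]]
    val <- switch(colname, intercept = 1, incomp = inc, 0)
    eta <- eta + val * fit$theta[info$par]
  }
  stats::setNames(eta, levels)
}

#' Participant-level trajectory indices
#'
#' Extracts, per participant, the three time-resolved indices of IAT
#' performance on the response scale, combining fixed effects with the
#' participant random effects:
#'
#' * `start_diff_ms` — incompatible minus compatible tau at trial 1
#'   ("initial bias"),
#' * `rate_trials` — the time constant, evaluated at the intermediate
#'   incompatibility level (trials to 50% of change),
#' * `asym_diff_ms` — incompatible minus compatible asymptotic tau
#'   ("persistent bias").
#'
#' Other covariates (run, IAT type, condition, gender/age) are held at
#' their reference / centered-zero setting.
#'
#' @param fit a time-varying `iat_fit` with participant random
#'   effects.
#' @param z if `TRUE`, each index column is standardized to mean 0,
#'   SD 1 (the scale used when linking indices to external measures).
#' @return tibble with `participant_id` and the three index columns.
#' @export
extract_indices <- function(fit, z = FALSE) {
  if (!fit$spec$time_varying) {
    stop("indices are defined for the time-varying model", call. = FALSE)
  }
  s0 <- exp(participant_eta(fit, "start", 0))
  s1 <- exp(participant_eta(fit, "start", 1))
  a0 <- exp(participant_eta(fit, "asym", 0))
  a1 <- exp(participant_eta(fit, "asym", 1))
  rr <- exp(participant_eta(fit, "rate", 0.5))
  out <- tibble::tibble(
    participant_id = names(s0),
    start_diff_ms = unname(s1 - s0),
    rate_trials = unname(rr),
    asym_diff_ms = unname(a1 - a0))
  if (z) {
    out$start_diff_ms <- zscore(out$start_diff_ms)
    out$rate_trials <- zscore(log(out$rate_trials))
    out$asym_diff_ms <- zscore(out$asym_diff_ms)
  }
  out
}

#' Standardized early-to-late change in the trial-type difference
#'
#' Computes, per participant, the fitted incompatible-minus-compatible
#' tau difference at the first and at the last modeled trial, and
#' summarizes the change as a paired-design Cohen's d
#' (`mean(late - early) / sd(late - early)`). Negative values mean the
#' IAT effect shrinks over the session.
#'
#' @param fit a time-varying `iat_fit` with participant random
#'   effects.
#' @return a list of class `iat_effect` (kind `paired_t`); degenerate
#'   (zero-SD) populations are flagged rather than raising an error.
#' @export
early_late_effect <- function(fit) {
  if (!fit$spec$time_varying) {
    stop("early/late change is undefined for the static null model",
         call. = FALSE)
  }
  t_last <- max(fit$design$t)
  s0 <- exp(participant_eta(fit, "start", 0))
  s1 <- exp(participant_eta(fit, "start", 1))
  a0 <- exp(participant_eta(fit, "asym", 0))
  a1 <- exp(participant_eta(fit, "asym", 1))
  r0 <- exp(participant_eta(fit, "rate", 0))
  r1 <- exp(participant_eta(fit, "rate", 1))
  early <- (s1 - s0)  # difference at t = 1 is exactly start difference
  late <- (a1 + (s1 - a1) * 2^(-(t_last - 1) / r1)) -
    (a0 + (s0 - a0) * 2^(-(t_last - 1) / r0))
  ch <- late - early
  if (stats::sd(ch) == 0) {
    return(iat_effect("paired_t", statistic = NA_real_,
                      effect_d = if (all(ch == 0)) 0 else NA_real_,
                      ci_low = mean(ch), ci_high = mean(ch),
                      n = length(ch), degenerate = TRUE,
                      extra = list(mean_change_ms = mean(ch),
                                   t_last = t_last)))
  }
  eff <- paired_contrast(early, late)
  eff$extra$mean_change_ms <- mean(ch)
  eff$extra$t_last <- t_last
  eff
}
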