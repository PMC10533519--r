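#' Robust multivariate outlier rejection (MCD Mahalanobis distances)
#'
#' Robust location and scatter are estimated by the minimum covariance
#' determinant (MCD) on the best subset of `h = ceiling(h_fraction * n)`
#' cases; squared robust Mahalanobis distances are then compared to the
#' `1 - alpha` chi-square quantile on `ncol(X)` degrees of freedom.
#' With `h_fraction = 1` the estimate reduces to the classical mean and
#' covariance, and the distances to ordinary Mahalanobis distances.
#'
#' @param X numeric matrix or data frame (participants x variables);
#'   needs more rows than columns + 1.
#' @param h_fraction fraction of cases the robust covariance may use,
#'   in `(0.5, 1]`; 0.8 reproduces the "minimum 80% of cases" screen.
#' @param alpha rejection level for the chi-square cutoff.
#' @param seed integer seed for the MCD subset search.
#' @return a list of class `outlier_report`: `robust_distance`
#'   (non-squared), `cutoff` (on the squared scale), `flagged`,
#'   `h_fraction`, `center`, `cov`.
#' @export
mcd_outliers <- function(X, h_fraction = 0.8, alpha = 0.01, seed = 1L) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("`X` must be numeric", call. = FALSE)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) stop("need more rows than columns + 1", call. = FALSE)
  if (h_fraction <= 0.5 || h_fraction > 1) {
    stop("`h_fraction` must lie in (0.5, 1]", call. = FALSE)
  }
  h <- ceiling(h_fraction * n)
  if (h_fraction == 1) {
    center <- colMeans(X)
    scatter <- stats::cov(X)
  } else {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
    fit <- MASS::cov.rob(X, method = "mcd", quantile.used = h,
                         nsamp = if (n <= 25) "exact" else "sample")
    center <- fit$center
    scatter <- fit$cov
  }
  ev <- eigen(scatter, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10 * max(ev)) {
    stop("robust scatter is singular; check for collinear columns: ",
         paste(colnames(X) %||% seq_len(p), collapse = ", "),
         call. = FALSE)
  }
  d2 <- stats::mahalanobis(X, center, scatter)
  cutoff <- stats::qchisq(1 - alpha, df = p)
  structure(list(robust_distance = sqrt(d2), cutoff = cutoff,
                 flagged = d2 > cutoff, h_fraction = h_fraction,
                 center = center, cov = scatter),
            class = "outlier_report")
}

#' Standardize to mean zero and unit SD
#'
#' @param x numeric vector with positive SD.
#' @param na.rm drop `NA`s when computing the moments.
#' @return the z-scored vector; an error is raised on zero SD.
#' @export
zscore <- function(x, na.rm = FALSE) {
  s <- stats::sd(x, na.rm = na.rm)
  if (!is.finite(s) || s == 0) {
    stop("cannot z-score a zero-variance vector", call. = FALSE)
  }
  (x - mean(x, na.rm = na.rm)) / s
}

#' Bootstrapped robust linear regression
#'
#' Fits a Huber M-estimated linear model (iteratively reweighted least
#' squares) to `n_boot` case resamples drawn with replacement, and
#' summarizes each coefficient by its resample mean and percentile
#' 2.5/97.5% bounds. A term is flagged `reliable` when 0 lies outside
#' its 95% interval. Resamples whose IRLS fails to converge (or whose
#' design is rank-deficient after resampling) are dropped and counted;
#' more than 1% dropped is an error.
#'
#' @param formula model formula (interactions allowed).
#' @param data data frame holding the variables.
#' @param n_boot bootstrap resamples (default 5000).
#' @param seed integer seed (mandatory).
#' @param k Huber tuning constant; the default 1.345 gives 95%
#'   efficiency under Gaussian errors. Very large values make the fit
#'   coincide with ordinary least squares.
#' @param maxit IRLS iteration cap per resample.
#' @return a list of class `robust_boot`: tibble `coefficients`
#'   (`term`, `estimate`, `ci_low`, `ci_high`, `reliable`), the
#'   full-data fit `estimate_full`, counts, and the seed.
#' @export
robust_lm_boot <- function(formula, data, n_boot = 5000, seed,
                           k = 1.345, maxit = 50) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  mf <- stats::model.frame(formula, data)
  n <- nrow(mf)
  n_terms <- ncol(stats::model.matrix(formula, mf))
  if (n < 3 * n_terms) {
    stop("need at least 3 rows per model term", call. = FALSE)
  }
  fit_one <- function(d) {
    fit <- suppressWarnings(
      MASS::rlm(formula, data = d, psi = MASS::psi.huber, k = k,
                maxit = maxit, method = "M"))
    if (!fit$converged) return(NULL)
    stats::coef(fit)
  }
  full <- fit_one(mf)
  if (is.null(full)) {
    stop("robust fit on the full data did not converge", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  draws <- matrix(NA_real_, nrow = n_boot, ncol = length(full),
                  dimnames = list(NULL, names(full)))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, replace = TRUE)
    cf <- tryCatch(fit_one(mf[idx, , drop = FALSE]),
                   error = function(e) NULL)
    if (is.null(cf)) dropped <- dropped + 1L else draws[b, ] <- cf
  }
  if (dropped > 0.01 * n_boot) {
    stop(sprintf("%d of %d bootstrap resamples failed to converge",
                 dropped, n_boot), call. = FALSE)
  }
  est <- colMeans(draws, na.rm = TRUE)
  ci <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975),
              na.rm = TRUE)
  coefs <- tibble::tibble(
    term = names(full),
    estimate = unname(est),
    ci_low = unname(ci[1, ]),
    ci_high = unname(ci[2, ]),
    reliable = unname(ci[1, ] > 0 | ci[2, ] < 0))
  structure(list(coefficients = coefs, estimate_full = full,
                 n = n, n_boot = n_boot, n_dropped = dropped,
                 seed = seed, k = k, formula = formula),
            class = "robust_boot")
}

#' @export
print.robust_boot <- function(x, ...) {
  cat(sprintf("Bootstrapped robust regression (%d resamples, %d dropped)\n",
              x$n_boot, x$n_dropped))
  print(as.data.frame(x$coefficients), row.names = FALSE)
  invisible(x)
}

#' Linkage suite: IAT indices predicting external behavior
#'
#' For each IAT index (overall D-score, starting difference, rate,
#' asymptotic difference — each z-scored so coefficients share a
#' scale) fits the configured bootstrapped robust models:
#'
#' * `seeming_racist ~ interv_white * index * IMS`
#' * `seating_distance ~ interv_white * index * EMS`
#' * the Black-interviewer subset variant
#'   `seating_distance ~ index * EMS`
#'
#' Responses are z-scored; `interv_white` is the centered race code
#' (+1/2 White, -1/2 Black).
#'
#' @param indices tibble with `participant_id`, `d_overall`,
#'   `start_diff_ms`, `rate_trials` (log-transformed internally),
#'   `asym_diff_ms` — e.g. [extract_indices()] joined with
#'   [d_score_all()].
#' @param externals an [external_measures()] table.
#' @param models subset of `c("seeming_racist", "seating_distance",
#'   "seating_black_interviewer")` to fit.
#' @param n_boot,seed bootstrap controls, seed mandatory.
#' @param max_join_loss error if more than this fraction of index rows
#'   fails to join to the externals.
#' @return a list of class `linkage_result`: per model a named list of
#'   `robust_boot` fits, one per IAT index; `tidy(x)`-style export via
#'   [linkage_table()].
#' @export
linkage_suite <- function(indices, externals,
                          models = c("seeming_racist",
                                     "seating_distance",
                                     "seating_black_interviewer"),
                          n_boot = 5000, seed, max_join_loss = 0.1) {
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  models <- match.arg(models, several.ok = TRUE)
  ext <- tibble::as_tibble(externals)
  idx <- tibble::as_tibble(indices)
  joined <- merge(idx, ext, by = "participant_id")
  loss <- 1 - nrow(joined) / nrow(idx)
  if (loss > max_join_loss) {
    stop(sprintf(
      "join loss too high: %d of %d index rows matched externals",
      nrow(joined), nrow(idx)), call. = FALSE)
  }
  index_cols <- c(overall = "d_overall", start = "start_diff_ms",
                  rate = "rate_trials", asym = "asym_diff_ms")
  index_cols <- index_cols[index_cols %in% names(joined)]
  if (length(index_cols) == 0) {
    stop("no IAT index columns found in `indices`", call. = FALSE)
  }
  dat <- joined
  dat$interv_white <- ifelse(dat$interviewer_race == "white", 0.5, -0.5)
  dat$ims_z <- zscore(dat$ims)
  dat$ems_z <- zscore(dat$ems)
  for (nm in names(index_cols)) {
    v <- dat[[index_cols[[nm]]]]
    if (nm == "rate") v <- log(v)
    dat[[paste0("iat_", nm)]] <- zscore(v)
  }

  fit_menu <- function(model) {
    out <- list()
    for (nm in names(index_cols)) {
      d <- dat
      d$iat <- d[[paste0("iat_", nm)]]
      if (model == "seeming_racist") {
        d$resp <- zscore(d$seeming_racist)
        f <- resp ~ interv_white * iat * ims_z
      } else if (model == "seating_distance") {
        d$resp <- zscore(d$seating_distance_cm)
        f <- resp ~ interv_white * iat * ems_z
      } else {
        d <- d[d$interviewer_race == "black", , drop = FALSE]
        if (nrow(d) == 0) {
          stop("no Black-interviewer rows for the subset model",
               call. = FALSE)
        }
        d$resp <- zscore(d$seating_distance_cm)
        d$iat <- zscore(d$iat)
        d$ems_z <- zscore(d$ems)
        f <- resp ~ iat * ems_z
      }
      out[[nm]] <- robust_lm_boot(f, d, n_boot = n_boot,
                                  seed = seed + match(nm,
                                                      names(index_cols)))
    }
    out
  }

  res <- lapply(stats::setNames(models, models), fit_menu)
  structure(list(models = res, n = nrow(joined), seed = seed),
            class = "linkage_result")
}

#' Tidy table of linkage-suite coefficients
#'
#' @param x a `linkage_result`.
#' @return tibble with columns `model`, `IAT_measure`, `term`,
#'   `estimate`, `ci_low`, `ci_high`, `reliable`.
#' @export
linkage_table <- function(x) {
  rows <- list()
  for (model in names(x$models)) {
    for (measure in names(x$models[[model]])) {
      cf <- x$models[[model]][[measure]]$coefficients
      cf$model <- model
      cf$IAT_measure <- measure
      rows[[length(rows) + 1L]] <- cf
    }
  }
  out <- do.call(rbind, rows)
  out[, c("model", "IAT_measure", "term", "estimate", "ci_low",
          "ci_high", "reliable")]
}
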