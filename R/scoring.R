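#' Trial and participant filtering rules
#'
#' Bundles the exclusion rules applied before aggregate scoring.
#' Trial-level rules run first (RT window, incorrect responses), then
#' participant-level rules (overall accuracy, count of responses
#' outside the RT window, block-level screens).
#'
#' Two named presets ship with the package:
#' * `filter_preset("trialwise")` — lower RT cutoff 320 ms, upper
#'   2000 ms, incorrect responses dropped, participants excluded below
#'   80% accuracy or with 10+ responses outside the RT window (the
#'   screens used with trial-level online race-IAT data).
#' * `filter_preset("blockwise")` — no trial-level exclusions, but
#'   participants dropped when any block falls below 70% accuracy or
#'   has a mean RT above 1.5 s (the screens used with block-aggregated
#'   public data).
#'
#' @param lower_rt_ms lower RT cutoff (ms), or `"empirical"` to have
#'   [apply_filters()] call [empirical_lower_cutoff()].
#' @param upper_rt_ms upper RT cutoff (ms).
#' @param drop_incorrect drop incorrect trials before scoring.
#' @param participant_min_accuracy minimum pre-filter accuracy; whole
#'   participants below it are excluded. `NA` disables.
#' @param participant_max_out_of_window maximum tolerated count of a
#'   participant's responses outside the RT window; more than this
#'   excludes the participant. `NA` disables.
#' @param block_min_accuracy,block_max_mean_rt_ms block-level screens:
#'   a participant is excluded if any block violates either. `NA`
#'   disables.
#' @return a list of class `filter_rules`.
#' @export
filter_rules <- function(lower_rt_ms = 320,
                         upper_rt_ms = 2000,
                         drop_incorrect = TRUE,
                         participant_min_accuracy = NA,
                         participant_max_out_of_window = NA,
                         block_min_accuracy = NA,
                         block_max_mean_rt_ms = NA) {
  if (!identical(lower_rt_ms, "empirical")) {
    if (!is.na(lower_rt_ms) && !is.na(upper_rt_ms) &&
        lower_rt_ms >= upper_rt_ms) {
      stop("`lower_rt_ms` must be below `upper_rt_ms`", call. = FALSE)
    }
  }
  for (p in c(participant_min_accuracy, block_min_accuracy)) {
    if (!is.na(p) && (p < 0 || p > 1)) {
      stop("accuracy proportions must lie in [0, 1]", call. = FALSE)
    }
  }
  structure(as.list(environment()), class = "filter_rules")
}

#' @rdname filter_rules
#' @param name preset name.
#' @export
filter_preset <- function(name = c("trialwise", "blockwise")) {
  name <- match.arg(name)
  switch(name,
    trialwise = filter_rules(lower_rt_ms = 320, upper_rt_ms = 2000,
                             drop_incorrect = TRUE,
                             participant_min_accuracy = 0.8,
                             participant_max_out_of_window = 9),
    blockwise = filter_rules(lower_rt_ms = NA, upper_rt_ms = NA,
                             drop_incorrect = FALSE,
                             block_min_accuracy = 0.7,
                             block_max_mean_rt_ms = 1500))
}

#' Apply filtering rules to a trial dataset
#'
#' Trial-level exclusions are applied before participant-level rules;
#' participant-level accuracy and out-of-window counts are assessed on
#' the unfiltered trials (so an error-prone participant is excluded
#' even though their incorrect trials would be dropped anyway).
#'
#' @param x an [iat_trials()] dataset.
#' @param rules a [filter_rules()] object.
#' @return list with `trials` (the filtered dataset) and `report`
#'   (per-rule exclusion counts and the retained fraction).
#' @export
apply_filters <- function(x, rules) {
  if (!inherits(rules, "filter_rules")) {
    stop("`rules` must be a `filter_rules` object", call. = FALSE)
  }
  df <- tibble::as_tibble(x)
  n0 <- nrow(df)
  needs_acc <- isTRUE(rules$drop_incorrect) ||
    !is.na(rules$participant_min_accuracy) ||
    !is.na(rules$block_min_accuracy)
  if (needs_acc && !"correct" %in% names(df)) {
    stop("filter rules require an accuracy (`correct`) column, ",
         "which this dataset lacks", call. = FALSE)
  }

  lower <- rules$lower_rt_ms
  if (identical(lower, "empirical")) {
    lower <- empirical_lower_cutoff(x)$cutoff_ms
  }

  report <- list()
  keep <- rep(TRUE, n0)
  if (!is.na(lower)) {
    hit <- keep & df$rt_ms < lower
    report$rt_below_lower <- sum(hit)
    keep <- keep & !hit
  } else report$rt_below_lower <- 0L
  if (!is.na(rules$upper_rt_ms)) {
    hit <- keep & df$rt_ms > rules$upper_rt_ms
    report$rt_above_upper <- sum(hit)
    keep <- keep & !hit
  } else report$rt_above_upper <- 0L
  if (isTRUE(rules$drop_incorrect)) {
    hit <- keep & !df$correct
    report$incorrect <- sum(hit)
    keep <- keep & !hit
  } else report$incorrect <- 0L

  # participant-level screens, assessed on all of a participant's trials
  drop_pid <- character(0)
  if (!is.na(rules$participant_min_accuracy)) {
    acc <- tapply(df$correct, df$participant_id, mean)
    bad <- names(acc)[acc < rules$participant_min_accuracy]
    report$participant_low_accuracy <- length(bad)
    drop_pid <- union(drop_pid, bad)
  }
  if (!is.na(rules$participant_max_out_of_window)) {
    oow <- (!is.na(lower) & df$rt_ms < lower) |
      (!is.na(rules$upper_rt_ms) & df$rt_ms > rules$upper_rt_ms)
    cnt <- tapply(oow, df$participant_id, sum)
    bad <- names(cnt)[cnt > rules$participant_max_out_of_window]
    report$participant_out_of_window <- length(bad)
    drop_pid <- union(drop_pid, bad)
  }
  if (!is.na(rules$block_min_accuracy) ||
      !is.na(rules$block_max_mean_rt_ms)) {
    key <- interaction(df$participant_id, df$iat_type, df$block_index,
                       drop = TRUE)
    bad <- character(0)
    if (!is.na(rules$block_min_accuracy)) {
      acc <- tapply(df$correct, key, mean)
      pidkey <- tapply(df$participant_id, key, `[`, 1L)
      bad <- union(bad, pidkey[acc < rules$block_min_accuracy])
    }
    if (!is.na(rules$block_max_mean_rt_ms)) {
      mrt <- tapply(df$rt_ms, key, mean)
      pidkey <- tapply(df$participant_id, key, `[`, 1L)
      bad <- union(bad, pidkey[mrt > rules$block_max_mean_rt_ms])
    }
    report$participant_block_screen <- length(bad)
    drop_pid <- union(drop_pid, bad)
  }
  if (length(drop_pid) > 0) {
    keep <- keep & !(df$participant_id %in% drop_pid)
  }
  report$participants_excluded <- length(drop_pid)
  report$n_input <- n0
  report$n_retained <- sum(keep)
  report$retained_fraction <- sum(keep) / n0
  report$lower_rt_ms <- lower

  meta <- iat_metadata(x)
  meta$filters <- report
  out <- iat_trials(df[keep, , drop = FALSE], metadata = meta,
                    validate = FALSE)
  list(trials = out, report = report)
}

#' Empirically determined lower response-time cutoff
#'
#' Implements the idea of testing the lowest RTs at which participants
#' perform above chance: RTs are pooled across participants into bins
#' of `bin_ms`, and scanning upward from the fastest bin, the cutoff
#' is the lower edge of the first bin whose pooled accuracy exceeds
#' 50% by a one-sided binomial test at level `alpha`. Responses below
#' that edge are treated as anticipations / fast guesses.
#'
#' @param x an [iat_trials()] dataset with a `correct` column.
#' @param bin_ms bin width (ms).
#' @param alpha one-sided binomial level.
#' @param min_bin_n bins with fewer trials are skipped.
#' @return list with `cutoff_ms` and a per-bin diagnostic tibble.
#' @export
empirical_lower_cutoff <- function(x, bin_ms = 10, alpha = 0.05,
                                   min_bin_n = 10) {
  df <- tibble::as_tibble(x)
  if (!"correct" %in% names(df)) {
    stop("empirical lower cutoff requires an accuracy (`correct`) column",
         call. = FALSE)
  }
  edges <- seq(floor(min(df$rt_ms) / bin_ms) * bin_ms,
               max(df$rt_ms) + bin_ms, by = bin_ms)
  bin <- cut(df$rt_ms, edges, right = FALSE, labels = FALSE)
  tab <- lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    n <- sum(i)
    k <- sum(df$correct[i])
    p <- if (n >= min_bin_n) {
      stats::pbinom(k - 1L, n, 0.5, lower.tail = FALSE)
    } else NA_real_
    tibble::tibble(lower_edge = edges[b], n = n, accuracy = k / n,
                   p_above_chance = p)
  })
  tab <- do.call(rbind, tab)
  sig <- which(!is.na(tab$p_above_chance) & tab$p_above_chance < alpha)
  if (length(sig) == 0) {
    stop("no RT bin performs above chance; cannot determine a cutoff",
         call. = FALSE)
  }
  list(cutoff_ms = tab$lower_edge[sig[1]], bins = tab)
}

#' Improved IAT D-score for one participant
#'
#' The improved scoring algorithm computes one standardized difference
#' from the 20-trial pair of blocks (3 and 6, historically "practice")
#' and one from the 40-trial pair (4 and 7, "test"), then averages the
#' two subscores. Within a pair, the score is the incompatible-minus-
#' compatible difference in mean RT divided by the SD over all included
#' trials of both blocks. Because each subscore gets equal weight, each
#' early trial influences the total twice as much as each later trial
#' (see [effective_trial_weights()]). Incorrect trials are excluded by
#' the filtering rules rather than replaced with penalty latencies.
#'
#' @param x an [iat_trials()] dataset slice for one participant (and
#'   one IAT type).
#' @param rules optional [filter_rules()] applied first; `NULL` scores
#'   the trials as given.
#' @return a list of class `dscore_result`: `d_practice`, `d_test`,
#'   `d_overall`, `mean_diff_ms`, `n_trials_used`, `exclusion_report`.
#' @export
d_score <- function(x, rules = NULL) {
  report <- NULL
  if (!is.null(rules)) {
    f <- apply_filters(x, rules)
    x <- f$trials
    report <- f$report
  }
  df <- tibble::as_tibble(x)
  if (length(unique(df$participant_id)) != 1) {
    stop("`d_score` scores one participant; use `d_score_all` for many",
         call. = FALSE)
  }
  df <- df[!is.na(df$compatibility), , drop = FALSE]
  pair_d <- function(blocks, label) {
    sub <- df[df$block_index %in% blocks, , drop = FALSE]
    inc <- sub$rt_ms[sub$compatibility == "incompatible"]
    com <- sub$rt_ms[sub$compatibility == "compatible"]
    if (length(inc) < 2 || length(com) < 2) {
      stop(sprintf(
        "d_score undefined: fewer than 2 trials in a %s-pair cell",
        label), call. = FALSE)
    }
    (mean(inc) - mean(com)) / stats::sd(sub$rt_ms)
  }
  d_practice <- pair_d(c(3L, 6L), "practice")
  d_test <- pair_d(c(4L, 7L), "test")
  inc <- df$rt_ms[df$compatibility == "incompatible"]
  com <- df$rt_ms[df$compatibility == "compatible"]
  structure(list(
    participant_id = df$participant_id[1],
    d_practice = d_practice,
    d_test = d_test,
    d_overall = (d_practice + d_test) / 2,
    mean_diff_ms = mean(inc) - mean(com),
    n_trials_used = nrow(df),
    exclusion_report = report
  ), class = "dscore_result")
}

#' D-scores for every participant in a dataset
#'
#' @param x an [iat_trials()] dataset.
#' @param rules optional [filter_rules()] applied once to the whole
#'   dataset before per-participant scoring.
#' @return tibble with one row per (participant, iat_type):
#'   `participant_id`, `iat_type`, `condition_order`, `d_practice`,
#'   `d_test`, `d_overall`, `mean_diff_ms`, `n_trials_used`.
#' @export
d_score_all <- function(x, rules = NULL) {
  if (!is.null(rules)) {
    x <- apply_filters(x, rules)$trials
  }
  df <- tibble::as_tibble(x)
  grp <- split(seq_len(nrow(df)), list(df$participant_id, df$iat_type),
               drop = TRUE)
  rows <- lapply(grp, function(i) {
    d <- d_score(iat_trials(df[i, , drop = FALSE], validate = FALSE))
    tibble::tibble(participant_id = d$participant_id,
                   iat_type = df$iat_type[i[1]],
                   condition_order = df$condition_order[i[1]],
                   d_practice = d$d_practice, d_test = d$d_test,
                   d_overall = d$d_overall,
                   mean_diff_ms = d$mean_diff_ms,
                   n_trials_used = d$n_trials_used)
  })
  out <- do.call(rbind, rows)
  out[order(out$participant_id, out$iat_type), ]
}

#' Per-trial weight ratio implied by equal averaging of subscores
#'
#' Averaging a practice-pair subscore and a test-pair subscore with
#' equal weight gives each trial of the shorter pair proportionally
#' more influence: the early:late per-trial influence ratio is
#' `n_test / n_practice`, i.e. 2 for the standard 20/40 split.
#'
#' @param n_practice,n_test trials per block in the two pairs.
#' @return the early:late weight ratio.
#' @export
effective_trial_weights <- function(n_practice, n_test) {
  if (n_practice <= 0 || n_test <= 0) {
    stop("block lengths must be positive", call. = FALSE)
  }
  (1 / n_practice) / (1 / n_test)
}
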