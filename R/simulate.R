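#' Configuration for the synthetic IAT generator
#'
#' Defines the population that [simulate_iat()] draws from. Defaults
#' emulate a standard 7-block race IAT session: two dual-stimulus runs
#' of 60 trials (a 20-trial block followed by a 40-trial block per
#' pairing), response times drawn from an ex-Gaussian whose exponential
#' component follows a saturating trajectory over trials, incompatible
#' blocks elevated on the log scale, a carry-over (order) effect on the
#' second run's asymptote, and an accuracy model with a chance floor at
#' fast response times.
#'
#' Population intercepts default to the scale of observed group-level
#' estimates from online race-IAT samples: Gaussian mean `exp(6.161)`
#' = 473 ms, starting tau `exp(5.878)` = 357 ms, asymptotic tau
#' `exp(5.112)` = 166 ms, rate `exp(2.451)` = 11.6 trials; the
#' compatibility effects on log start/asymptote/rate default to 0.374,
#' 0.342 and 0.658 respectively.
#'
#' @param n_participants number of participants.
#' @param seed integer seed; mandatory — every draw is derived from it.
#' @param iat_types character vector of IAT types each participant
#'   completes (`"generic"`, or e.g. `c("good_bad",
#'   "competent_incompetent")` for a two-IAT session).
#' @param block_lengths named integer vector with the dual-stimulus
#'   trial counts of blocks 3, 4, 6, 7.
#' @param mean_log_gauss,mean_log_start,mean_log_asym,mean_log_rate
#'   population means of the log-scale parameters.
#' @param gauss_sd_ms Gaussian component SD (ms), trial-constant.
#' @param effect_compat_start,effect_compat_asym,effect_compat_rate
#'   fixed incompatibility effects on the log scale (incompatible
#'   minus compatible).
#' @param effect_order_asym carry-over shift applied to log asymptote
#'   on the second run (both pairings; negative = faster second run).
#' @param effect_word_vs_face shift of the log Gaussian mean for word
#'   (+1/2) versus face (-1/2) stimuli, centered coding.
#' @param effect_type_start,effect_type_asym,effect_type_rate
#'   zero-centered IAT-type main effects (second type coded +1/2)
#'   on the log scale; ignored with a single IAT type.
#' @param effect_type_compat_start,effect_type_compat_asym,
#'   effect_type_compat_rate IAT-type by incompatibility interactions.
#' @param sd_participant named numeric: between-participant SDs of the
#'   log-scale intercept deviations for `gauss`, `start`, `asym`,
#'   `rate`.
#' @param sd_participant_compat named numeric: between-participant SDs
#'   of the incompatibility-effect deviations for `start`, `asym`,
#'   `rate`.
#' @param accuracy_base asymptotic probability correct for slow
#'   responses.
#' @param accuracy_floor_ms RT below which accuracy sits at chance.
#' @param accuracy_scale_ms logistic width of the chance-to-base
#'   transition.
#' @param condition optional between-participant learning-condition
#'   factor: a list with `levels` (first = reference), and named
#'   effect vectors `start`, `rate`, `asym` and interaction vectors
#'   `start_x_incomp`, `rate_x_incomp`, `asym_x_incomp` (one value per
#'   non-reference level).
#' @param n_experiments number of experiment batches (for
#'   experiment-level random intercepts); 1 disables them.
#' @param sd_experiment SD of experiment-level log-scale intercept
#'   deviations (applied to start/asym/rate) when `n_experiments > 1`.
#' @param links external-measure generation: a list with per-outcome
#'   coefficient vectors, see [simulate_externals()].
#' @return a list of class `iat_sim_config`.
#' @export
iat_sim_config <- function(n_participants = 60,
                           seed,
                           iat_types = "generic",
                           block_lengths = c(b3 = 20L, b4 = 40L,
                                             b6 = 20L, b7 = 40L),
                           mean_log_gauss = 6.161,
                           mean_log_start = 5.878,
                           mean_log_asym = 5.112,
                           mean_log_rate = 2.451,
                           gauss_sd_ms = 50,
                           effect_compat_start = 0.374,
                           effect_compat_asym = 0.342,
                           effect_compat_rate = 0.658,
                           effect_order_asym = -0.1,
                           effect_word_vs_face = 0.127,
                           effect_type_start = 0,
                           effect_type_asym = 0,
                           effect_type_rate = 0,
                           effect_type_compat_start = 0,
                           effect_type_compat_asym = 0,
                           effect_type_compat_rate = 0,
                           sd_participant = c(gauss = 0.12, start = 0.25,
                                              asym = 0.25, rate = 0.45),
                           sd_participant_compat = c(start = 0.15,
                                                     asym = 0.15,
                                                     rate = 0.2),
                           accuracy_base = 0.95,
                           accuracy_floor_ms = 300,
                           accuracy_scale_ms = 25,
                           condition = NULL,
                           n_experiments = 1,
                           sd_experiment = 0,
                           links = default_external_links()) {
  if (missing(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` is mandatory and must be a single integer",
         call. = FALSE)
  }
  if (n_participants < 1) stop("`n_participants` must be >= 1",
                               call. = FALSE)
  if (length(block_lengths) != 4L || any(block_lengths <= 0)) {
    stop("`block_lengths` must give positive counts for blocks 3,4,6,7",
         call. = FALSE)
  }
  if (gauss_sd_ms <= 0 || any(sd_participant < 0) ||
      any(sd_participant_compat < 0) || sd_experiment < 0) {
    stop("scale parameters must be positive, SDs nonnegative",
         call. = FALSE)
  }
  if (!all(c("gauss", "start", "asym", "rate") %in%
           names(sd_participant))) {
    stop("`sd_participant` needs entries gauss, start, asym, rate",
         call. = FALSE)
  }
  if (!all(c("start", "asym", "rate") %in%
           names(sd_participant_compat))) {
    stop("`sd_participant_compat` needs entries start, asym, rate",
         call. = FALSE)
  }
  cfg <- as.list(environment())
  class(cfg) <- "iat_sim_config"
  cfg
}

#' Default links from latent indices to external measures
#'
#' Coefficients act on z-scored true participant indices
#' (`index_start`, `index_rate`, `index_asym`), z-scored IMS/EMS and
#' the centered interviewer-race code `interv_white` (+1/2 White,
#' -1/2 Black); products denote interactions. Outcomes are generated
#' as a linear combination plus Gaussian noise of `noise_sd`, on a
#' z-like latent scale, then mapped to the instrument's range.
#'
#' @return list with `seeming_racist` and `seating_distance` elements.
#' @export
default_external_links <- function() {
  list(
    seeming_racist = list(
      coef = c("index_rate" = -0.18, "index_asym:ims" = 0.25),
      noise_sd = 1),
    seating_distance = list(
      coef = c("index_rate:ems" = -0.31,
               "index_rate:ems:interv_white" = 0.57),
      noise_sd = 1)
  )
}

block_schedule <- function(block_lengths) {
  # run 1 = blocks 3 (20) + 4 (40); run 2 = blocks 6 + 7
  list(
    `1` = rep(c(3L, 4L), times = block_lengths[c("b3", "b4")]),
    `2` = rep(c(6L, 7L), times = block_lengths[c("b6", "b7")])
  )
}

#' Simulate a trial-level IAT dataset with known ground truth
#'
#' Generates the standard two dual-stimulus runs of concatenated
#' 20-trial and 40-trial blocks per participant and IAT type, with
#' condition order counterbalanced across participants. Per trial, RT
#' is drawn from an ex-Gaussian whose exponential mean follows
#' [tau_trajectory()] at that participant's cell parameters; accuracy
#' follows a logistic-in-RT model with a chance floor below
#' `accuracy_floor_ms`. Fully reproducible from `config$seed`.
#'
#' @param config an [iat_sim_config()].
#' @return a list with elements `trials` (an [iat_trials()] dataset)
#'   and `truth` (fixed effects, per-participant deviations and
#'   per-cell trajectory parameters — the recovery oracle).
#' @export
simulate_iat <- function(config) {
  if (!inherits(config, "iat_sim_config")) {
    stop("`config` must be an `iat_sim_config`", call. = FALSE)
  }
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(config$seed)

  np <- config$n_participants
  pid <- sprintf("P%03d", seq_len(np))
  orders <- rep(c("compatible_first", "incompatible_first"),
                length.out = np)
  experiment <- rep(sprintf("E%02d", seq_len(config$n_experiments)),
                    length.out = np)
  exp_dev <- matrix(stats::rnorm(config$n_experiments * 3, 0,
                                 config$sd_experiment),
                    ncol = 3,
                    dimnames = list(NULL, c("start", "asym", "rate")))
  if (config$n_experiments == 1) exp_dev[] <- 0

  cond_level <- NULL
  if (!is.null(config$condition)) {
    cond_level <- rep(config$condition$levels, length.out = np)
  }
  gender <- sample(c(-0.5, 0.5), np, replace = TRUE)
  age <- round(stats::rnorm(np, 21, 2.5), 1)

  sdp <- config$sd_participant
  sdc <- config$sd_participant_compat
  dev <- tibble::tibble(
    participant_id = pid,
    b_gauss = stats::rnorm(np, 0, sdp[["gauss"]]),
    b_start = stats::rnorm(np, 0, sdp[["start"]]),
    b_asym = stats::rnorm(np, 0, sdp[["asym"]]),
    b_rate = stats::rnorm(np, 0, sdp[["rate"]]),
    b_start_c = stats::rnorm(np, 0, sdc[["start"]]),
    b_asym_c = stats::rnorm(np, 0, sdc[["asym"]]),
    b_rate_c = stats::rnorm(np, 0, sdc[["rate"]])
  )

  sched <- block_schedule(config$block_lengths)
  n_types <- length(config$iat_types)
  type_code <- if (n_types == 2) c(-0.5, 0.5) else rep(0, n_types)

  rows <- vector("list", np * n_types * 2L)
  cells <- vector("list", np * n_types * 2L)
  k <- 0L
  for (p in seq_len(np)) {
    ei <- match(experiment[p], unique(experiment))
    cond_eff <- cond_effects(config$condition, cond_level[p])
    for (ty in seq_len(n_types)) {
      for (r in 1:2) {
        k <- k + 1L
        compat_run <- xor(orders[p] == "compatible_first", r == 2L)
        compat <- if (compat_run) "compatible" else "incompatible"
        inc <- as.numeric(compat == "incompatible")
        tc <- type_code[ty]

        ls <- config$mean_log_start + dev$b_start[p] + exp_dev[ei, "start"] +
          inc * (config$effect_compat_start + dev$b_start_c[p]) +
          tc * config$effect_type_start +
          tc * inc * config$effect_type_compat_start +
          cond_eff$start + inc * cond_eff$start_x_incomp
        la <- config$mean_log_asym + dev$b_asym[p] + exp_dev[ei, "asym"] +
          inc * (config$effect_compat_asym + dev$b_asym_c[p]) +
          tc * config$effect_type_asym +
          tc * inc * config$effect_type_compat_asym +
          (r == 2L) * config$effect_order_asym +
          cond_eff$asym + inc * cond_eff$asym_x_incomp
        lr <- config$mean_log_rate + dev$b_rate[p] + exp_dev[ei, "rate"] +
          inc * (config$effect_compat_rate + dev$b_rate_c[p]) +
          tc * config$effect_type_rate +
          tc * inc * config$effect_type_compat_rate +
          cond_eff$rate + inc * cond_eff$rate_x_incomp

        blocks <- sched[[r]]
        nt <- length(blocks)
        t_idx <- seq_len(nt)
        # stimulus class drawn at random per trial, as in the task
        stim <- sample(c("word", "face"), nt, replace = TRUE)
        stim_code <- ifelse(stim == "word", 0.5, -0.5)
        mu <- exp(config$mean_log_gauss + dev$b_gauss[p] +
                  stim_code * config$effect_word_vs_face)
        tau <- tau_trajectory(t_idx, exp(ls), exp(lr), exp(la))
        rt <- stats::rnorm(nt, mu, config$gauss_sd_ms) +
          stats::rexp(nt) * tau
        while (any(rt <= 0)) {
          i <- rt <= 0
          rt[i] <- stats::rnorm(sum(i), mu[i], config$gauss_sd_ms) +
            stats::rexp(sum(i)) * tau[i]
        }
        p_corr <- 0.5 + (config$accuracy_base - 0.5) *
          stats::plogis((rt - config$accuracy_floor_ms) /
                        config$accuracy_scale_ms)
        correct <- stats::runif(nt) < p_corr

        rows[[k]] <- tibble::tibble(
          participant_id = pid[p],
          iat_type = config$iat_types[ty],
          block_index = blocks,
          run_index = r,
          trial_index = t_idx,
          compatibility = compat,
          stimulus_class = stim,
          rt_ms = round(rt, 3),
          correct = correct,
          condition_order = orders[p]
        )
        cells[[k]] <- tibble::tibble(
          participant_id = pid[p],
          iat_type = config$iat_types[ty],
          run_index = r,
          compatibility = compat,
          start_ms = exp(ls), rate_trials = exp(lr), asym_ms = exp(la),
          gauss_mean_ms = exp(config$mean_log_gauss + dev$b_gauss[p])
        )
      }
    }
  }

  trials_df <- do.call(rbind, rows)
  participants <- tibble::tibble(
    participant_id = pid, condition_order = orders,
    experiment = experiment, gender = gender, age = age)
  if (!is.null(cond_level)) participants$condition <- cond_level

  truth <- list(
    fixed = c(log_gauss_intercept = config$mean_log_gauss,
              word_vs_face = config$effect_word_vs_face,
              log_start_intercept = config$mean_log_start,
              start_incompatibility = config$effect_compat_start,
              log_asym_intercept = config$mean_log_asym,
              asym_incompatibility = config$effect_compat_asym,
              log_rate_intercept = config$mean_log_rate,
              rate_incompatibility = config$effect_compat_rate,
              order_asym = config$effect_order_asym,
              gauss_sd = config$gauss_sd_ms),
    deviations = dev,
    cells = do.call(rbind, cells),
    participants = participants,
    config = config
  )

  trials <- iat_trials(
    trials_df,
    metadata = list(source = "iatdyn::simulate_iat",
                    seed = config$seed),
    validate = TRUE)
  list(trials = trials, truth = truth)
}

cond_effects <- function(condition, level) {
  zero <- list(start = 0, rate = 0, asym = 0,
               start_x_incomp = 0, rate_x_incomp = 0, asym_x_incomp = 0)
  if (is.null(condition) || is.null(level) ||
      level == condition$levels[1]) {
    return(zero)
  }
  pick <- function(v) {
    if (is.null(v)) 0 else unname(v[[level]] %||% 0)
  }
  list(start = pick(condition$start),
       rate = pick(condition$rate),
       asym = pick(condition$asym),
       start_x_incomp = pick(condition$start_x_incomp),
       rate_x_incomp = pick(condition$rate_x_incomp),
       asym_x_incomp = pick(condition$asym_x_incomp))
}

#' True participant-level trajectory indices from a ground truth
#'
#' Response-scale indices per participant, averaged over IAT types and
#' runs: starting difference (incompatible minus compatible tau at
#' trial 1), asymptotic difference, and the rate time constant.
#'
#' @param truth the `truth` element returned by [simulate_iat()].
#' @return tibble with `participant_id`, `start_diff_ms`,
#'   `rate_trials`, `asym_diff_ms`.
#' @export
true_indices <- function(truth) {
  cells <- truth$cells
  out <- lapply(split(cells, cells$participant_id), function(cc) {
    inc <- cc[cc$compatibility == "incompatible", ]
    com <- cc[cc$compatibility == "compatible", ]
    tibble::tibble(
      participant_id = cc$participant_id[1],
      start_diff_ms = mean(inc$start_ms) - mean(com$start_ms),
      rate_trials = exp(mean(log(cc$rate_trials))),
      asym_diff_ms = mean(inc$asym_ms) - mean(com$asym_ms))
  })
  res <- do.call(rbind, out)
  res[order(res$participant_id), ]
}

#' Simulate participant-level external measures linked to the truth
#'
#' IMS and EMS are drawn within their 1–9 bounds, interviewer race and
#' sex are assigned, and the behavioral outcomes (seating distance,
#' "seeming racist" rating) are generated from the configured linear
#' combinations of the z-scored true trajectory indices, z-scored
#' IMS/EMS and centered interviewer race, plus Gaussian noise.
#'
#' @param truth the `truth` element from [simulate_iat()].
#' @param config the same [iat_sim_config()]; its `links` element
#'   names the coefficients (see [default_external_links()]).
#' @param seed optional integer; defaults to `config$seed + 1` so the
#'   externals stream is independent of the trial stream.
#' @return an [external_measures()] tibble.
#' @export
simulate_externals <- function(truth, config, seed = NULL) {
  if (is.null(seed)) seed <- config$seed + 1L
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)

  idx <- true_indices(truth)
  np <- nrow(idx)
  clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))
  ims <- clamp(round(stats::rnorm(np, 6.5, 1.5), 1), 1, 9)
  ems <- clamp(round(stats::rnorm(np, 4.5, 1.5), 1), 1, 9)
  interviewer_race <- sample(c("white", "black"), np, replace = TRUE)
  interviewer_sex <- sample(c("male", "female"), np, replace = TRUE)

  vars <- list(
    index_start = zscore(idx$start_diff_ms),
    index_rate = zscore(log(idx$rate_trials)),
    index_asym = zscore(idx$asym_diff_ms),
    ims = zscore(ims),
    ems = zscore(ems),
    interv_white = ifelse(interviewer_race == "white", 0.5, -0.5)
  )
  latent <- function(link) {
    eta <- numeric(np)
    for (term in names(link$coef)) {
      parts <- strsplit(term, ":", fixed = TRUE)[[1]]
      unknown <- setdiff(parts, names(vars))
      if (length(unknown) > 0) {
        stop("external link names absent variable(s): ",
             paste(unknown, collapse = ", "), call. = FALSE)
      }
      col <- Reduce(`*`, vars[parts])
      eta <- eta + link$coef[[term]] * col
    }
    eta + stats::rnorm(np, 0, link$noise_sd)
  }
  seeming <- clamp(3 + 0.7 * latent(config$links$seeming_racist), 1, 5)
  seating <- 100 + 15 * latent(config$links$seating_distance)

  external_measures(tibble::tibble(
    participant_id = idx$participant_id,
    ims = ims, ems = ems,
    interviewer_race = interviewer_race,
    interviewer_sex = interviewer_sex,
    seating_distance_cm = round(seating, 1),
    seeming_racist = round(seeming, 2),
    gender = truth$participants$gender[
      match(idx$participant_id, truth$participants$participant_id)],
    age = truth$participants$age[
      match(idx$participant_id, truth$participants$participant_id)]
  ))
}

#' Two artificial participants with identical aggregate IAT effects
#'
#' Demonstrates how aggregation hides dynamics: participant 1 starts
#' with a large trial-type difference that decays to near zero, while
#' participant 2 starts smaller, changes very fast, and levels off with
#' a larger final difference — yet both have exactly the same mean RT
#' difference (0.082 s by default) when averaged over the run. The
#' asymptotic differences are solved analytically so the aggregate
#' equality is exact on the noise-free trajectories.
#'
#' @param mean_diff_ms the common aggregate mean difference (ms).
#' @param start_diff_ms length-2 starting differences.
#' @param rate_trials length-2 time constants.
#' @param n_trials trials per run.
#' @param gauss_mean_ms,compat_start_ms,compat_asym_ms base trajectory
#'   of the compatible trials (shared rate with the difference).
#' @param noise `FALSE` (default) emits noise-free expected RTs
#'   (`mu + tau(t)`), as in a schematic demonstration; `TRUE` draws
#'   ex-Gaussian RTs (requires `seed`).
#' @param seed integer seed, used only when `noise = TRUE`.
#' @return list with `trials` (an [iat_trials()] dataset of
#'   participants `A1`, `A2`) and `truth` (their cell trajectory
#'   parameters and the calibrated aggregate difference).
#' @export
fig1_pair <- function(mean_diff_ms = 82,
                      start_diff_ms = c(250, 120),
                      rate_trials = c(14, 3),
                      n_trials = 60L,
                      gauss_mean_ms = 470,
                      compat_start_ms = 300,
                      compat_asym_ms = 170,
                      noise = FALSE,
                      seed = 1L) {
  t_idx <- seq_len(n_trials)
  weight <- function(rate) mean(2^(-(t_idx - 1) / rate))
  asym_diff_ms <- vapply(seq_along(rate_trials), function(i) {
    m <- weight(rate_trials[i])
    (mean_diff_ms - start_diff_ms[i] * m) / (1 - m)
  }, numeric(1))

  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  rows <- list()
  cells <- list()
  for (i in 1:2) {
    pid <- paste0("A", i)
    for (r in 1:2) {
      compat <- if (r == 1) "compatible" else "incompatible"
      blocks <- rep(if (r == 1) c(3L, 4L) else c(6L, 7L),
                    times = c(min(20L, n_trials),
                              max(0L, n_trials - 20L)))
      start <- compat_start_ms + (compat == "incompatible") *
        start_diff_ms[i]
      asym <- compat_asym_ms + (compat == "incompatible") *
        asym_diff_ms[i]
      tau <- tau_trajectory(t_idx, start, rate_trials[i], asym)
      rt <- if (noise) {
        gauss_mean_ms + stats::rnorm(n_trials, 0, 25) +
          stats::rexp(n_trials) * tau
      } else {
        gauss_mean_ms + tau
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        participant_id = pid, iat_type = "generic",
        block_index = blocks, run_index = r, trial_index = t_idx,
        compatibility = compat, stimulus_class = "word",
        rt_ms = rt, correct = TRUE,
        condition_order = "compatible_first")
      cells[[length(cells) + 1L]] <- tibble::tibble(
        participant_id = pid, compatibility = compat,
        start_ms = start, rate_trials = rate_trials[i], asym_ms = asym)
    }
  }
  trials <- iat_trials(do.call(rbind, rows),
                       metadata = list(source = "iatdyn::fig1_pair",
                                       noise = noise, seed = seed))
  list(trials = trials,
       truth = list(cells = do.call(rbind, cells),
                    mean_diff_ms = mean_diff_ms,
                    asym_diff_ms = asym_diff_ms))
}
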