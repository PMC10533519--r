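test_that("d_score matches the hand-computed toy example", {
  toy <- toy_trials()
  d <- d_score(toy)
  # practice pair: blocks 3 & 6
  prac <- c(700, 800, 900, 1000)
  d_prac <- (mean(c(900, 1000)) - mean(c(700, 800))) / sd(prac)
  test <- c(650, 750, 700, 800, 850, 950, 900, 1000)
  d_test <- (mean(c(850, 950, 900, 1000)) -
             mean(c(650, 750, 700, 800))) / sd(test)
  expect_equal(d$d_practice, d_prac, tolerance = 1e-12)
  expect_equal(d$d_test, d_test, tolerance = 1e-12)
  expect_equal(d$d_overall, (d_prac + d_test) / 2, tolerance = 1e-12)
  expect_equal(d$mean_diff_ms,
               mean(c(900, 1000, 850, 950, 900, 1000)) -
               mean(c(700, 800, 650, 750, 700, 800)))
  expect_equal(d$n_trials_used, 12)
})

test_that("d_score symmetry, scale-freeness and order invariance", {
  sym <- toy_trials(practice_inc = c(700, 800), test_inc = c(650, 750, 700, 800))
  expect_equal(d_score(sym)$d_overall, 0, tolerance = 1e-12)

  toy <- toy_trials()
  d0 <- d_score(toy)
  scaled <- tibble::as_tibble(toy)
  scaled$rt_ms <- scaled$rt_ms * 3.7
  d1 <- d_score(iat_trials(scaled, validate = FALSE))
  expect_equal(d1$d_overall, d0$d_overall, tolerance = 1e-12)
  expect_equal(d1$mean_diff_ms, d0$mean_diff_ms * 3.7,
               tolerance = 1e-12)

  perm <- tibble::as_tibble(toy)
  set.seed(4)
  perm <- perm[sample(nrow(perm)), ]
  expect_equal(d_score(iat_trials(perm, validate = FALSE))$d_overall,
               d0$d_overall, tolerance = 1e-12)
})

test_that("empty cells after filtering raise a named scoring error", {
  toy <- toy_trials(practice_inc = c(2500, 2600))
  rules <- filter_rules(lower_rt_ms = NA, upper_rt_ms = 2000,
                        drop_incorrect = FALSE)
  expect_error(d_score(toy, rules), "practice")
})

test_that("trial filters exclude by window and accuracy, with counts", {
  toy <- toy_trials()
  df <- tibble::as_tibble(toy)
  df$rt_ms[1] <- 2500
  df$rt_ms[2] <- 150
  df$correct[3] <- FALSE
  x <- iat_trials(df, validate = FALSE)
  out <- apply_filters(x, filter_rules(lower_rt_ms = 320,
                                       upper_rt_ms = 2000))
  expect_equal(out$report$rt_above_upper, 1L)
  expect_equal(out$report$rt_below_lower, 1L)
  expect_equal(out$report$incorrect, 1L)
  expect_equal(nrow(out$trials), 9)
  expect_equal(out$report$retained_fraction, 9 / 12)

  # rules matching nothing are the identity
  idle <- apply_filters(toy, filter_rules(lower_rt_ms = 1,
                                          upper_rt_ms = 1e6))
  expect_equal(tibble::as_tibble(idle$trials)$rt_ms, toy$rt_ms)
})

test_that("participant-level accuracy screen removes whole participants", {
  sim <- small_sim(n = 8, seed = 15)
  df <- tibble::as_tibble(sim$trials)
  bad <- df$participant_id == "P001"
  df$correct[bad] <- rep(c(TRUE, FALSE, FALSE, FALSE),
                         length.out = sum(bad))  # 25% accuracy
  x <- iat_trials(df, validate = FALSE)
  out <- apply_filters(x, filter_rules(
    lower_rt_ms = NA, upper_rt_ms = NA, drop_incorrect = FALSE,
    participant_min_accuracy = 0.8))
  expect_false("P001" %in% out$trials$participant_id)
  expect_equal(out$report$participant_low_accuracy, 1L)
})

test_that("blockwise preset screens on block accuracy and mean RT", {
  sim <- small_sim(n = 8, seed = 15)
  df <- tibble::as_tibble(sim$trials)
  slow <- df$participant_id == "P002" & df$block_index == 3L
  df$rt_ms[slow] <- df$rt_ms[slow] + 2000
  out <- apply_filters(iat_trials(df, validate = FALSE),
                       filter_preset("blockwise"))
  expect_false("P002" %in% out$trials$participant_id)
})

test_that("filtering then scoring equals scoring pre-filtered input", {
  sim <- small_sim(n = 8, seed = 15)
  rules <- filter_preset("trialwise")
  pre <- apply_filters(sim$trials, rules)$trials
  a <- d_score_all(sim$trials, rules)
  b <- d_score_all(pre)
  expect_equal(a$d_overall, b$d_overall, tolerance = 1e-12)
})

test_that("empirical lower cutoff finds a planted accuracy step", {
  set.seed(2)
  n <- 6000
  rt <- runif(n, 200, 800)
  correct <- ifelse(rt < 300, runif(n) < 0.5, runif(n) < 0.95)
  df <- tibble::tibble(
    participant_id = "P1", iat_type = "generic", block_index = 3L,
    run_index = 1L, trial_index = seq_len(n),
    compatibility = "compatible", rt_ms = rt, correct = correct,
    condition_order = "compatible_first")
  x <- iat_trials(df, validate = FALSE)
  # stringent alpha so the at-chance bins below the step cannot fire
  cut <- empirical_lower_cutoff(x, bin_ms = 10, alpha = 0.001)
  expect_true(abs(cut$cutoff_ms - 300) <= 10)

  # all bins above chance: lowest edge returned
  df$correct <- runif(n) < 0.95
  allgood <- empirical_lower_cutoff(iat_trials(df, validate = FALSE),
                                    alpha = 0.001)
  expect_equal(allgood$cutoff_ms, min(allgood$bins$lower_edge))

  # uniform chance accuracy: sentinel error
  df$correct <- runif(n) < 0.5
  expect_error(empirical_lower_cutoff(iat_trials(df, validate = FALSE),
                                      alpha = 1e-6),
               "above chance")
})

test_that("subscore averaging weights early trials by the length ratio", {
  expect_equal(effective_trial_weights(20, 40), 2)
  expect_equal(effective_trial_weights(30, 30), 1)
  expect_equal(effective_trial_weights(10, 40), 4)
  expect_error(effective_trial_weights(0, 40), "positive")
})

test_that("mean difference converges to the configured tau difference", {
  # static generator (start = asym): population mean difference is the
  # tau difference exactly
  lvl <- log(200)
  eff <- 0.4
  cfg <- iat_sim_config(
    n_participants = 90, seed = 6,
    mean_log_start = lvl, mean_log_asym = lvl,
    effect_compat_start = eff, effect_compat_asym = eff,
    effect_order_asym = 0,
    sd_participant = c(gauss = 0, start = 0, asym = 0, rate = 0),
    sd_participant_compat = c(start = 0, asym = 0, rate = 0))
  sim <- simulate_iat(cfg)
  true_diff <- exp(lvl + eff) - exp(lvl)
  obs <- mean(d_score_all(sim$trials)$mean_diff_ms)
  expect_lt(abs(obs - true_diff) / true_diff, 0.1)
})
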