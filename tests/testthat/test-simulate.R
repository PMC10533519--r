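test_that("default config yields two dual-stimulus runs of 60 trials", {
  sim <- small_sim()
  tr <- tibble::as_tibble(sim$trials)
  expect_setequal(unique(tr$block_index), c(3L, 4L, 6L, 7L))
  per_run <- tapply(tr$trial_index,
                    paste(tr$participant_id, tr$run_index), max)
  expect_true(all(per_run == 60L))
  runs <- tapply(tr$run_index, tr$participant_id,
                 function(r) length(unique(r)))
  expect_true(all(runs == 2L))
  # trial index continues across the 20-trial block into the 40-trial
  counts <- table(tr$block_index) / length(unique(tr$participant_id))
  expect_equal(as.numeric(counts[c("3", "6")]), c(20, 20))
  expect_equal(as.numeric(counts[c("4", "7")]), c(40, 40))
  expect_identical(nrow(validate_iat_trials(sim$trials)), 0L)
})

test_that("condition order is counterbalanced and seed-reproducible", {
  sim <- small_sim()
  tr <- tibble::as_tibble(sim$trials)
  ord <- tapply(tr$condition_order, tr$participant_id, `[`, 1L)
  expect_equal(sum(ord == "compatible_first"), 6)
  sim2 <- simulate_iat(iat_sim_config(n_participants = 12, seed = 77))
  expect_identical(tibble::as_tibble(sim$trials),
                   tibble::as_tibble(sim2$trials))
  sim3 <- simulate_iat(iat_sim_config(n_participants = 12, seed = 78))
  expect_false(identical(sim$trials$rt_ms, sim3$trials$rt_ms))
})

test_that("null generator makes compatibility cells exchangeable", {
  cfg <- iat_sim_config(
    n_participants = 40, seed = 3,
    effect_compat_start = 0, effect_compat_asym = 0,
    effect_compat_rate = 0, effect_order_asym = 0,
    sd_participant = c(gauss = 0, start = 0, asym = 0, rate = 0),
    sd_participant_compat = c(start = 0, asym = 0, rate = 0))
  sim <- simulate_iat(cfg)
  tr <- tibble::as_tibble(sim$trials)
  a <- tr$rt_ms[tr$compatibility == "incompatible"]
  b <- tr$rt_ms[tr$compatibility == "compatible"]
  expect_gt(stats::t.test(a, b)$p.value, 0.01)
  # identical true cell parameters everywhere
  expect_equal(length(unique(round(sim$truth$cells$start_ms, 9))), 1L)
})

test_that("generated RTs are positive and track the configured trajectory", {
  cfg <- iat_sim_config(
    n_participants = 120, seed = 9,
    sd_participant = c(gauss = 0, start = 0, asym = 0, rate = 0),
    sd_participant_compat = c(start = 0, asym = 0, rate = 0),
    effect_order_asym = 0)
  sim <- simulate_iat(cfg)
  tr <- tibble::as_tibble(sim$trials)
  expect_true(all(tr$rt_ms > 0))
  com <- tr[tr$compatibility == "compatible", ]
  mu <- exp(cfg$mean_log_gauss)
  for (tt in c(1, 30, 60)) {
    expected_tau <- tau_trajectory(tt, exp(cfg$mean_log_start),
                                   exp(cfg$mean_log_rate),
                                   exp(cfg$mean_log_asym))
    observed <- mean(com$rt_ms[com$trial_index == tt]) - mu
    se <- sqrt(cfg$gauss_sd_ms^2 + expected_tau^2) /
      sqrt(sum(com$trial_index == tt))
    expect_lt(abs(observed - expected_tau), 4 * se)
  }
})

test_that("accuracy model yields a chance floor for fast responses", {
  sim <- small_sim(n = 60, seed = 21)
  tr <- tibble::as_tibble(sim$trials)
  fast <- tr$correct[tr$rt_ms < 280]
  slow <- tr$correct[tr$rt_ms > 500]
  expect_gt(mean(slow), 0.9)
  if (length(fast) >= 20) expect_lt(mean(fast), 0.75)
})

test_that("external measures respect bounds and configured links", {
  sim <- small_sim(n = 150, seed = 41)
  cfg <- sim$truth$config
  ext <- simulate_externals(sim$truth, cfg)
  expect_true(all(ext$ims >= 1 & ext$ims <= 9))
  expect_true(all(ext$ems >= 1 & ext$ems <= 9))
  expect_true(all(ext$seeming_racist >= 1 & ext$seeming_racist <= 5))
  expect_identical(ext, simulate_externals(sim$truth, cfg))
  # zero links: externals independent of the indices
  cfg0 <- iat_sim_config(n_participants = 150, seed = 41, links = list(
    seeming_racist = list(coef = c(index_rate = 0), noise_sd = 1),
    seating_distance = list(coef = c(index_rate = 0), noise_sd = 1)))
  sim0 <- simulate_iat(cfg0)
  ext0 <- simulate_externals(sim0$truth, cfg0)
  idx0 <- true_indices(sim0$truth)
  expect_gt(stats::cor.test(ext0$seating_distance_cm,
                            idx0$asym_diff_ms)$p.value, 0.01)
  expect_error(simulate_externals(sim$truth, utils::modifyList(
    cfg, list(links = list(
      seeming_racist = list(coef = c(index_bogus = 1), noise_sd = 1),
      seating_distance = list(coef = c(index_rate = 0),
                              noise_sd = 1))))),
    "absent variable")
})

test_that("fig1 pair shares one aggregate difference with opposite dynamics", {
  fp <- fig1_pair()
  cells <- fp$truth$cells
  # aggregate mean difference identical (82 ms) on the trajectories
  diffs <- sapply(c("A1", "A2"), function(p) {
    cc <- cells[cells$participant_id == p, ]
    inc <- cc[cc$compatibility == "incompatible", ]
    com <- cc[cc$compatibility == "compatible", ]
    mean(tau_trajectory(1:60, inc$start_ms, inc$rate_trials,
                        inc$asym_ms) -
         tau_trajectory(1:60, com$start_ms, com$rate_trials,
                        com$asym_ms))
  })
  expect_lt(abs(diffs[1] - 82), 1e-6)
  expect_lt(abs(diffs[2] - 82), 1e-6)
  # participant 1: larger initial, smaller final difference
  final_diff <- sapply(c("A1", "A2"), function(p) {
    cc <- cells[cells$participant_id == p, ]
    inc <- cc[cc$compatibility == "incompatible", ]
    com <- cc[cc$compatibility == "compatible", ]
    tau_trajectory(60, inc$start_ms, inc$rate_trials, inc$asym_ms) -
      tau_trajectory(60, com$start_ms, com$rate_trials, com$asym_ms)
  })
  expect_gt(fp$truth$cells$start_ms[2] - fp$truth$cells$start_ms[1],
            fp$truth$cells$start_ms[4] - fp$truth$cells$start_ms[3])
  expect_lt(final_diff[1], final_diff[2])
  # aggregate scoring cannot tell the two apart
  s <- d_score_all(fp$trials)
  expect_lt(abs(s$mean_diff_ms[1] - s$mean_diff_ms[2]), 1e-6)

  # the noisy variant draws valid ex-Gaussian RTs reproducibly
  fn1 <- fig1_pair(noise = TRUE, seed = 9)
  fn2 <- fig1_pair(noise = TRUE, seed = 9)
  expect_identical(fn1$trials$rt_ms, fn2$trials$rt_ms)
  expect_identical(nrow(validate_iat_trials(fn1$trials)), 0L)
  expect_gt(sd(fn1$trials$rt_ms - fp$trials$rt_ms), 0)
})
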