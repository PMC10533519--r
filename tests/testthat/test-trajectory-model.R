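test_that("design matrices use the documented deterministic codings", {
  sim <- small_sim()
  only_int <- iat_model_spec(start = "intercept", rate = "intercept",
                             asym = "intercept",
                             gauss_mean = "intercept", random = list())
  d <- build_design(only_int, sim$trials)
  for (tg in c("start", "rate", "asym", "gauss_mean")) {
    expect_true(all(d$targets[[tg]]$X[, 1] == 1))
    expect_equal(ncol(d$targets[[tg]]$X), 1L)
  }

  cen <- iat_model_spec(start = c("intercept", "incomp_c"),
                        rate = "intercept", asym = "intercept",
                        gauss_mean = "intercept", random = list())
  dc <- build_design(cen, sim$trials)
  # balanced data: zero-centered compatibility code has mean 0
  expect_equal(mean(dc$targets$start$X[, "incomp_c"]), 0)

  # condition design: intercept + 3 contrasts + incomp + gender + age
  # + 3 interaction contrasts = 10 fixed columns
  cfg <- iat_sim_config(
    n_participants = 16, seed = 55,
    condition = list(levels = c("control", "combined", "es", "rep"),
                     start_x_incomp = c(combined = -0.3, es = -0.35,
                                        rep = -0.1)))
  sim4 <- simulate_iat(cfg)
  d4 <- build_design(spec_condition(), sim4$trials,
                     participants = sim4$truth$participants)
  expect_equal(ncol(d4$targets$start$X), 10L)
  # centered covariates
  expect_lt(abs(mean(d4$targets$start$X[, "gender"])), 0.3)
  expect_equal(colnames(d4$targets$start$X)[2:4],
               c("condition_combined", "condition_es", "condition_rep"))

  expect_error(build_design(spec_condition(), sim$trials),
               "participants table")
})

test_that("model_loglik reduces to iid ex-Gaussian at intercepts only", {
  sim <- small_sim()
  spec <- iat_model_spec(start = "intercept", rate = "intercept",
                         asym = "intercept", gauss_mean = "intercept",
                         random = list())
  # equal start and asym intercepts: constant tau, any rate
  lvl <- log(200)
  th1 <- c(lvl, log(5), lvl, log(450), log(50))
  th2 <- c(lvl, log(50), lvl, log(450), log(50))
  ll1 <- model_loglik(sim$trials, spec, th1)
  ll2 <- model_loglik(sim$trials, spec, th2)
  expect_equal(as.numeric(ll1), as.numeric(ll2), tolerance = 1e-12)
  direct <- dexgauss(sim$trials$rt_ms, exp(log(450)), 50, 200,
                     log = TRUE)
  expect_equal(as.numeric(ll1), direct, tolerance = 1e-10)
  expect_length(ll1, nrow(sim$trials))
  expect_error(model_loglik(sim$trials, spec, th1[-1]), "parameters")
})

test_that("true parameters dominate perturbed ones in likelihood", {
  sim <- small_sim(n = 16, seed = 91)
  cfg <- sim$truth$config
  spec <- iat_model_spec(start = c("intercept", "incomp"),
                         rate = c("intercept", "incomp"),
                         asym = c("intercept", "incomp"),
                         gauss_mean = "intercept", random = list())
  th_true <- c(cfg$mean_log_start, cfg$effect_compat_start,
               cfg$mean_log_rate, cfg$effect_compat_rate,
               cfg$mean_log_asym, cfg$effect_compat_asym,
               cfg$mean_log_gauss, log(cfg$gauss_sd_ms))
  ll_true <- sum(model_loglik(sim$trials, spec, th_true))
  set.seed(1)
  worse <- replicate(10, {
    sum(model_loglik(sim$trials, spec,
                     th_true + rnorm(8, 0, 0.25)))
  })
  expect_gt(mean(ll_true > worse), 0.8)
  expect_gt(ll_true, mean(worse))
})

test_that("map fitting is deterministic and orderinvariant", {
  sim <- small_sim(n = 10, seed = 33)
  spec <- iat_model_spec(random = list(participant = list(
    start = "intercept", asym = "intercept",
    gauss_mean = "intercept")))
  f1 <- fit_trajectory(sim$trials, spec, control = list(eb_iter = 1))
  f2 <- fit_trajectory(sim$trials, spec, control = list(eb_iter = 1))
  expect_identical(f1$theta, f2$theta)
  expect_identical(f1$fixed, f2$fixed)

  # permuting row order leaves fixed effects essentially unchanged
  df <- tibble::as_tibble(sim$trials)
  set.seed(2)
  perm <- iat_trials(df[sample(nrow(df)), ], validate = FALSE)
  f3 <- fit_trajectory(perm, spec, control = list(eb_iter = 1))
  expect_equal(f3$fixed$estimate, f1$fixed$estimate, tolerance = 1e-4)
})

test_that("static data leave the start-asym contrast centered on zero", {
  lvl <- log(210)
  cfg <- iat_sim_config(
    n_participants = 14, seed = 63,
    mean_log_start = lvl, mean_log_asym = lvl,
    effect_compat_start = 0.35, effect_compat_asym = 0.35,
    effect_order_asym = 0,
    sd_participant = c(gauss = 0.1, start = 0.15, asym = 0.15,
                       rate = 0.2),
    sd_participant_compat = c(start = 0, asym = 0, rate = 0))
  sim <- simulate_iat(cfg)
  spec <- iat_model_spec(random = list(participant = list(
    start = "intercept", asym = "intercept",
    gauss_mean = "intercept")))
  f <- fit_trajectory(sim$trials, spec, control = list(eb_iter = 1))
  i_s <- which(f$fixed$target == "start" & f$fixed$term == "intercept")
  i_a <- which(f$fixed$target == "asym" & f$fixed$term == "intercept")
  js <- f$layout$beta$start[1]
  ja <- f$layout$beta$asym[1]
  contrast <- f$fixed$estimate[i_s] - f$fixed$estimate[i_a]
  se_c <- sqrt(f$cov[js, js] + f$cov[ja, ja] - 2 * f$cov[js, ja])
  expect_lt(abs(contrast), 2.58 * se_c)
})

test_that("static null fit matches the time-varying fit on static data", {
  lvl <- log(210)
  cfg <- iat_sim_config(
    n_participants = 10, seed = 64,
    mean_log_start = lvl, mean_log_asym = lvl,
    effect_compat_start = 0.35, effect_compat_asym = 0.35,
    effect_order_asym = 0,
    sd_participant = c(gauss = 0.1, start = 0.15, asym = 0.15,
                       rate = 0.2),
    sd_participant_compat = c(start = 0, asym = 0, rate = 0))
  sim <- simulate_iat(cfg)
  spec <- iat_model_spec(random = list(participant = list(
    asym = "intercept", gauss_mean = "intercept")))
  f_tv <- fit_trajectory(sim$trials, spec, control = list(eb_iter = 1))
  f_null <- fit_static(sim$trials, spec, control = list(eb_iter = 1))
  expect_false(f_null$spec$time_varying)
  # per-trial log-likelihoods close on average
  expect_lt(abs(mean(f_tv$pointwise_loglik) -
                mean(f_null$pointwise_loglik)), 0.02)
  # nesting: the null's likelihood cannot exceed the time-varying one
  expect_gte(sum(f_tv$pointwise_loglik) + 1e-6,
             sum(f_null$pointwise_loglik))
  # a static spec naming rate terms is structurally impossible
  expect_error(iat_model_spec(start = character(0),
                              rate = c("intercept"),
                              asym = "intercept",
                              time_varying = FALSE),
               "static null")
})

test_that("cross-validated comparison prefers the right model", {
  sim <- small_sim(n = 12, seed = 45)
  spec <- iat_model_spec(random = list(participant = list(
    start = "intercept", asym = "intercept",
    gauss_mean = "intercept")))
  f_tv <- fit_trajectory(sim$trials, spec, control = list(eb_iter = 1))
  f_null <- fit_static(sim$trials, spec, control = list(eb_iter = 1))

  self <- compare_loo(f_tv, f_tv)
  expect_identical(self$looic_diff, 0)
  expect_false(self$reliable)

  cmp <- compare_loo(f_tv, f_null)
  expect_lt(cmp$looic_diff, 0)
  expect_true(cmp$reliable)
  expect_equal(cmp$looic_diff, -2 * cmp$elpd_diff)

  other <- small_sim(n = 10, seed = 46)
  f_other <- fit_trajectory(other$trials, spec,
                            control = list(eb_iter = 1))
  expect_error(compare_loo(f_tv, f_other), "identical trial set")
})

test_that("participant indices recover heterogeneous asymptote differences", {
  cfg <- iat_sim_config(
    n_participants = 40, seed = 52,
    sd_participant_compat = c(start = 0.2, asym = 0.3, rate = 0.2))
  sim <- simulate_iat(cfg)
  f <- fit_trajectory(sim$trials, recovery_spec(),
                      control = list(eb_iter = 2))
  idx <- extract_indices(f)
  truth <- true_indices(sim$truth)
  expect_identical(idx$participant_id, truth$participant_id)
  expect_gt(cor(idx$asym_diff_ms, truth$asym_diff_ms,
                method = "spearman"), 0.6)
  expect_gt(cor(idx$start_diff_ms, truth$start_diff_ms,
                method = "spearman"), 0.5)
  zidx <- extract_indices(f, z = TRUE)
  for (col in c("start_diff_ms", "rate_trials", "asym_diff_ms")) {
    expect_equal(mean(zidx[[col]]), 0, tolerance = 1e-10)
    expect_equal(sd(zidx[[col]]), 1, tolerance = 1e-10)
  }
})

test_that("degenerate random-effect variance gives identical indices", {
  sim <- small_sim(n = 10, seed = 33)
  spec <- iat_model_spec(random = list(participant = list(
    start = "intercept", asym = "intercept",
    gauss_mean = "intercept")))
  # hold the shrinkage SDs at (effectively) zero: joint engine with
  # fixed variance components
  f <- fit_trajectory(sim$trials, spec,
                      control = list(eb_iter = 0, marginal = FALSE,
                                     sigma_b_init = 1e-3))
  idx <- extract_indices(f)
  expect_lt(diff(range(idx$asym_diff_ms)), 0.05)
  expect_lt(diff(range(idx$start_diff_ms)), 0.05)
  # early/late change is then identical for everyone: degenerate flag
  eff <- early_late_effect(f)
  expect_true(eff$degenerate || abs(eff$effect_d) >= 0)

  f_null <- fit_static(sim$trials, spec, control = list(eb_iter = 0))
  expect_error(extract_indices(f_null), "time-varying")
  expect_error(early_late_effect(f_null), "static")
})

test_that("shrinking trial-type differences give a negative early-late d", {
  cfg <- iat_sim_config(n_participants = 16, seed = 58,
                        effect_compat_start = 0.5,
                        effect_compat_asym = 0.15)
  sim <- simulate_iat(cfg)
  f <- fit_trajectory(sim$trials, recovery_spec(run2_on_asym = FALSE),
                      control = list(eb_iter = 1))
  eff <- early_late_effect(f)
  expect_lt(eff$effect_d, 0)
  expect_equal(eff$kind, "paired_t")
})

test_that("the mcmc backend agrees with map on a small model", {
  sim <- small_sim(n = 6, seed = 71)
  spec <- iat_model_spec(random = list(participant = list(
    gauss_mean = "intercept")))
  f_map <- fit_trajectory(sim$trials, spec,
                          control = list(eb_iter = 1))
  f_mc <- fit_trajectory(sim$trials, spec, method = "mcmc", seed = 3,
                         control = list(eb_iter = 1, n_iter = 1500,
                                        warmup = 500, chains = 2))
  dg <- mcmc_diagnostics(f_mc)
  expect_true(is.finite(dg$max_rhat))
  expect_gt(dg$min_ess, 5)
  # posterior means near the map optimum on the well-identified terms
  i <- which(f_map$fixed$target == "gauss_mean")
  expect_equal(f_mc$fixed$estimate[i], f_map$fixed$estimate[i],
               tolerance = 0.05)
  # PSIS route is exercised for sampled fits
  f_mc0 <- fit_static(sim$trials, spec, method = "mcmc", seed = 4,
                      control = list(eb_iter = 1, n_iter = 1500,
                                     warmup = 500, chains = 2))
  cmp <- compare_loo(f_mc, f_mc0)
  expect_equal(cmp$method, "psis")
  expect_lt(cmp$looic_diff, 0)
})

test_that("analytic gradient and curvature match finite differences", {
  sim <- small_sim(n = 4, seed = 5)
  spec <- iat_model_spec(random = list(participant = list(
    start = "intercept", rate = "intercept", asym = "intercept",
    gauss_mean = "intercept")))
  des <- build_design(spec, sim$trials)
  lay <- iatdyn:::make_layout(des)
  sb <- stats::setNames(rep(0.3, 4), iatdyn:::ranef_keys(lay))
  obj <- iatdyn:::make_objective(des, lay, iatdyn:::default_prior(), sb)
  set.seed(2)
  th <- iatdyn:::init_theta(des, lay) + rnorm(lay$n_par, 0, 0.05)

  g <- obj$gr(th)
  idx <- c(unlist(lay$beta), lay$log_sigma,
           sample(seq_len(lay$n_par), 6))
  for (j in unique(idx)) {
    h <- 1e-6
    tp <- th; tp[j] <- tp[j] + h
    tm <- th; tm[j] <- tm[j] - h
    fd <- (obj$fn(tp) - obj$fn(tm)) / (2 * h)
    expect_lt(abs(fd - g[j]), 1e-4 * (1 + abs(fd)))
  }

  # second derivatives wrt the linear predictors (diagonal and cross)
  p0 <- iatdyn:::ll_pieces(des, lay, th, grad = TRUE, hess = TRUE)
  targets <- c("start", "rate", "asym", "gauss_mean")
  h <- 1e-6
  for (q in targets) {
    thp <- th
    thp[lay$beta[[q]][1]] <- thp[lay$beta[[q]][1]] + h
    pp <- iatdyn:::ll_pieces(des, lay, thp, grad = TRUE)
    for (p in targets) {
      fd <- (pp$deta[[p]] - p0$deta[[p]]) / h
      an <- iatdyn:::cross_d2(p0, p, q, des$n)
      expect_lt(max(abs(fd - an)), 1e-4 * (1 + max(abs(an))))
    }
  }
})
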