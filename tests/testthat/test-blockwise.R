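test_that("paired contrast matches hand computation", {
  x <- c(5, 6, 7)
  y <- x + c(-1, -2, -3)
  eff <- paired_contrast(x, y)
  expect_equal(eff$effect_d, -2, tolerance = 1e-12)  # mean -2, sd 1
  tt <- t.test(y - x)
  expect_equal(eff$statistic, unname(tt$statistic))
  expect_equal(c(eff$ci_low, eff$ci_high), as.numeric(tt$conf.int))

  same <- paired_contrast(x, x)
  expect_true(same$degenerate)
  expect_equal(same$extra$mean_diff, 0)
  const <- paired_contrast(x, x + 2)
  expect_true(const$degenerate)  # SD of differences is zero
  expect_error(paired_contrast(x, 1:2), "equal length")
})

test_that("welch contrast matches the brute-force formulas", {
  a <- c(1, 2, 3)
  b <- c(3, 4, 5)
  eff <- welch_contrast(a, b)
  se <- sqrt(var(a) / 3 + var(b) / 3)
  t_hand <- (mean(a) - mean(b)) / se
  sp <- sqrt((2 * var(a) + 2 * var(b)) / 4)
  expect_equal(eff$statistic, t_hand, tolerance = 1e-12)
  expect_equal(eff$effect_d, (mean(a) - mean(b)) / sp,
               tolerance = 1e-12)
  expect_equal(welch_contrast(a, a + 0)$statistic, 0)
  # Satterthwaite df below the pooled df under heteroscedasticity
  set.seed(1)
  g1 <- rnorm(20, sd = 1)
  g2 <- rnorm(40, sd = 6)
  expect_lt(welch_contrast(g1, g2)$extra$df, 58)
})

test_that("welch reduces to the classical pooled t for equal groups", {
  set.seed(10)
  a <- rnorm(30, 5, 2)
  b <- rnorm(30, 6, 2)
  w <- welch_contrast(a, b)
  cl <- t.test(a, b, var.equal = TRUE)
  expect_equal(w$statistic, unname(cl$statistic), tolerance = 1e-10)
})

test_that("blockwise d separates order groups and is seed-stable", {
  sim <- small_sim(n = 40, seed = 19)
  e6 <- blockwise_d(sim$trials, 6, n_boot = 400, seed = 5)
  expect_gt(e6$effect_d, 0)   # incompatible block means are slower
  expect_lte(e6$ci_low, e6$effect_d)
  expect_gte(e6$ci_high, e6$effect_d)
  e6b <- blockwise_d(sim$trials, 6, n_boot = 400, seed = 5)
  expect_identical(c(e6$ci_low, e6$ci_high), c(e6b$ci_low, e6b$ci_high))

  # null generator: d near zero, CI straddles 0
  cfg0 <- iat_sim_config(
    n_participants = 40, seed = 23,
    effect_compat_start = 0, effect_compat_asym = 0,
    effect_compat_rate = 0, effect_order_asym = 0,
    sd_participant_compat = c(start = 0, asym = 0, rate = 0))
  sim0 <- simulate_iat(cfg0)
  e0 <- blockwise_d(sim0$trials, 4, n_boot = 400, seed = 5)
  expect_lt(e0$ci_low, 0)
  expect_gt(e0$ci_high, 0)
  expect_error(blockwise_d(sim$trials, 5, seed = 1), "block 5")
})

test_that("carry-over in the generator produces the order effect on D", {
  # second-run asymptote shifted down: compatible-first participants
  # get a relatively faster incompatible run, shrinking their D
  cfg <- iat_sim_config(n_participants = 60, seed = 29,
                        effect_order_asym = -0.35)
  sim <- simulate_iat(cfg)
  scores <- d_score_all(sim$trials)
  eff <- order_effect(scores, n_boot = 400, seed = 2)
  expect_lt(eff$extra$mean_compatible_first,
            eff$extra$mean_incompatible_first)

  # no carry-over: difference CI straddles zero
  cfg0 <- iat_sim_config(n_participants = 60, seed = 31,
                         effect_order_asym = 0)
  scores0 <- d_score_all(simulate_iat(cfg0)$trials)
  eff0 <- order_effect(scores0, n_boot = 400, seed = 2)
  expect_lt(eff0$ci_low, 0)
  expect_gt(eff0$ci_high, 0)

  # permuting labels destroys the effect
  set.seed(8)
  perm <- scores
  perm$condition_order <- sample(perm$condition_order)
  effp <- order_effect(perm, n_boot = 400, seed = 2)
  expect_gt(effp$p_value, 0.001)
})

test_that("signed-rank W matches exhaustive enumeration at n = 6", {
  # enumeration oracle: distribution of W over all sign assignments
  x <- c(3.2, -1.5, 0.7, 2.9, -0.3, 1.8)
  y <- rep(0, 6)
  eff <- signrank_contrast(x, y)
  r <- rank(abs(x))
  W_hand <- sum(r[x > 0])
  expect_equal(eff$statistic, W_hand)
  # two-sided p from full enumeration of the 2^6 sign patterns
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  W_all <- signs %*% r
  p_exact <- mean(abs(W_all - 10.5) >= abs(W_hand - 10.5))
  expect_equal(stats::wilcox.test(x, exact = TRUE)$p.value, p_exact,
               tolerance = 1e-12)
  # normal approximation is in the neighborhood of the exact p
  expect_lt(abs(eff$p_value - p_exact), 0.1)

  neg <- signrank_contrast(-(1:6), rep(0, 6))
  expect_equal(neg$statistic, 0)
  sym <- signrank_contrast(c(-3, -2, -1, 1, 2, 3), rep(0, 6))
  expect_gt(sym$p_value, 0.9)
  expect_true(signrank_contrast(rep(2, 6), rep(2, 6))$degenerate)
})

test_that("correlation power follows the Fisher-z approximation", {
  expect_equal(power_correlation(146, 0.23, 0.05), 0.80,
               tolerance = 0.005)
  expect_equal(power_correlation(100, 0, 0.05), 0.05,
               tolerance = 1e-10)
  pw <- sapply(c(20, 50, 100, 200, 400), power_correlation,
               rho = 0.23, alpha = 0.05)
  expect_true(all(diff(pw) > 0))
  expect_error(power_correlation(3, 0.2), "at least 4")
  expect_error(power_correlation(50, 1.2), "below 1")
})

test_that("power approximation matches Monte-Carlo rejection rates", {
  n <- 146
  rho <- 0.23
  set.seed(123)
  n_mc <- 50000
  # rejection iff |r| exceeds the critical correlation of the t test
  t_crit <- stats::qt(0.975, n - 2)
  r_crit <- t_crit / sqrt(n - 2 + t_crit^2)
  rej <- logical(n_mc)
  for (chunk in split(seq_len(n_mc), ceiling(seq_len(n_mc) / 5000))) {
    a <- matrix(rnorm(n * length(chunk)), nrow = n)
    b <- rho * a + sqrt(1 - rho^2) * matrix(rnorm(n * length(chunk)),
                                            nrow = n)
    a <- scale(a)
    b <- scale(b)
    r <- colSums(a * b) / (n - 1)
    rej[chunk] <- abs(r) > r_crit
  }
  expect_equal(mean(rej), power_correlation(n, rho, 0.05),
               tolerance = 0.01)
})
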