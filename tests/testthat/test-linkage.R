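test_that("planted gross outliers are flagged, clean data mostly kept", {
  set.seed(14)
  n <- 200
  X <- matrix(rnorm(n * 3), ncol = 3)
  X <- rbind(X, matrix(10, nrow = 3, ncol = 3))  # 3 points at 10 SD
  rep <- mcd_outliers(X, h_fraction = 0.8, alpha = 0.01, seed = 2)
  expect_true(all(rep$flagged[201:203]))
  expect_lt(mean(rep$flagged[1:200]), 0.05)
  expect_true(all(rep$flagged == (rep$robust_distance^2 > rep$cutoff)))
})

test_that("clean-data false-positive rate is near the nominal alpha", {
  rates <- sapply(1:6, function(s) {
    set.seed(100 + s)
    X <- matrix(rnorm(300 * 2), ncol = 2)
    mean(mcd_outliers(X, 0.8, alpha = 0.01, seed = s)$flagged)
  })
  expect_lt(mean(rates), 0.06)
})

test_that("h_fraction = 1 reduces to classical Mahalanobis distances", {
  set.seed(3)
  X <- matrix(rnorm(60 * 2), ncol = 2)
  rep <- mcd_outliers(X, h_fraction = 1, alpha = 0.01)
  d2 <- stats::mahalanobis(X, colMeans(X), stats::cov(X))
  expect_equal(rep$robust_distance^2, d2, tolerance = 1e-12)
})

test_that("mcd matches the exhaustive best-subset oracle at small n", {
  set.seed(21)
  n <- 18
  X <- rbind(matrix(rnorm(15 * 2), ncol = 2),
             matrix(rnorm(3 * 2, mean = 8), ncol = 2))
  h <- ceiling(0.8 * n)
  combos <- utils::combn(n, h)
  dets <- apply(combos, 2, function(idx) det(stats::cov(X[idx, ])))
  best <- combos[, which.min(dets)]
  oracle_center <- colMeans(X[best, ])
  rep <- mcd_outliers(X, h_fraction = 0.8, alpha = 0.01, seed = 5)
  expect_equal(as.numeric(rep$center), as.numeric(oracle_center),
               tolerance = 1e-8)
  # scatter proportional to the oracle subset covariance
  ratio <- rep$cov / stats::cov(X[best, ])
  expect_lt(diff(range(ratio)), 1e-6 * mean(ratio))
})

test_that("mcd is row-permutation invariant and rejects bad input", {
  set.seed(9)
  X <- matrix(rnorm(80 * 2), ncol = 2)
  a <- mcd_outliers(X, 0.8, seed = 7)
  b <- mcd_outliers(X[sample(80), ], 0.8, seed = 7)
  expect_equal(sort(round(a$robust_distance, 10)),
               sort(round(b$robust_distance, 10)))
  expect_error(mcd_outliers(X[1:3, ], 0.8), "rows")
  expect_error(mcd_outliers(X, 0.4), "h_fraction")
  expect_error(mcd_outliers(cbind(X[, 1], X[, 1] * 2), 1),
               "singular|collinear")
})

test_that("zscore standardizes and is affine invariant", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  x <- rnorm(50, 10, 4)
  z <- zscore(x)
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_equal(zscore(3 * x - 7), z, tolerance = 1e-12)
  expect_error(zscore(rep(2, 5)), "zero-variance")
})

test_that("robust regression is exact on noiseless data and seed-stable", {
  set.seed(5)
  d <- data.frame(x1 = rnorm(40), x2 = rnorm(40))
  d$y <- 2 + 1.5 * d$x1 - 0.8 * d$x2
  r <- robust_lm_boot(y ~ x1 + x2, d, n_boot = 200, seed = 11)
  expect_equal(unname(r$estimate_full), c(2, 1.5, -0.8),
               tolerance = 1e-8)
  expect_lt(max(r$coefficients$ci_high - r$coefficients$ci_low), 1e-6)
  expect_true(all(r$coefficients$reliable))
  r2 <- robust_lm_boot(y ~ x1 + x2, d, n_boot = 200, seed = 11)
  expect_identical(r$coefficients, r2$coefficients)
})

test_that("huber loss resists gross outliers better than least squares", {
  set.seed(6)
  n <- 100
  x <- rnorm(n)
  y <- 1 + 2 * x + rnorm(n, 0, 0.5)
  out <- sample(n, 5)
  y[out] <- y[out] + 40
  d <- data.frame(x = x, y = y)
  r <- robust_lm_boot(y ~ x, d, n_boot = 50, seed = 1)
  ols <- coef(lm(y ~ x, d))
  expect_lt(abs(r$estimate_full[["x"]] - 2), abs(ols[["x"]] - 2))
})

test_that("an effectively infinite tuning constant reproduces OLS", {
  set.seed(7)
  d <- data.frame(x = rnorm(60))
  d$y <- 0.5 + 1.2 * d$x + rnorm(60)
  r <- robust_lm_boot(y ~ x, d, n_boot = 10, seed = 1, k = 1e8)
  expect_equal(unname(r$estimate_full), unname(coef(lm(y ~ x, d))),
               tolerance = 1e-8)
})

test_that("linkage suite recovers a planted rate-by-EMS interaction", {
  cfg <- iat_sim_config(
    n_participants = 150, seed = 121,
    sd_participant_compat = c(start = 0.25, asym = 0.25, rate = 0.35),
    links = list(
      seeming_racist = list(coef = c(index_rate = 0), noise_sd = 1),
      seating_distance = list(coef = c("index_rate:ems" = -0.8),
                              noise_sd = 0.8)))
  sim <- simulate_iat(cfg)
  ext <- simulate_externals(sim$truth, cfg)
  idx <- true_indices(sim$truth)
  scores <- d_score_all(sim$trials)
  agg <- stats::aggregate(d_overall ~ participant_id, scores, mean)
  idx <- merge(idx, agg, by = "participant_id")
  res <- linkage_suite(idx, ext, models = "seating_distance",
                       n_boot = 400, seed = 17)
  tab <- linkage_table(res)
  rate_int <- tab[tab$IAT_measure == "rate" & tab$term == "iat:ems_z", ]
  start_int <- tab[tab$IAT_measure == "start" &
                   tab$term == "iat:ems_z", ]
  expect_true(rate_int$reliable)
  expect_lt(rate_int$estimate, 0)
  expect_false(start_int$reliable)
  # reproducible decisions under a fixed seed
  res2 <- linkage_suite(idx, ext, models = "seating_distance",
                        n_boot = 400, seed = 17)
  expect_identical(linkage_table(res2), tab)
})

test_that("independent externals yield about the nominal reliable rate", {
  cfg <- iat_sim_config(
    n_participants = 150, seed = 133,
    links = list(
      seeming_racist = list(coef = c(index_rate = 0), noise_sd = 1),
      seating_distance = list(coef = c(index_rate = 0), noise_sd = 1)))
  sim <- simulate_iat(cfg)
  ext <- simulate_externals(sim$truth, cfg)
  idx <- true_indices(sim$truth)
  idx$d_overall <- stats::aggregate(
    d_overall ~ participant_id, d_score_all(sim$trials), mean)$d_overall
  res <- linkage_suite(idx, ext, models = c("seeming_racist",
                                            "seating_distance"),
                       n_boot = 300, seed = 19)
  tab <- linkage_table(res)
  tab <- tab[tab$term != "(Intercept)", ]
  expect_lt(mean(tab$reliable), 0.2)
})

test_that("the black-interviewer subset variant needs black-interviewer rows", {
  cfg <- iat_sim_config(n_participants = 30, seed = 141)
  sim <- simulate_iat(cfg)
  ext <- simulate_externals(sim$truth, cfg)
  ext_white <- ext[ext$interviewer_race == "white", ]
  idx <- true_indices(sim$truth)
  idx_white <- idx[idx$participant_id %in% ext_white$participant_id, ]
  expect_error(
    linkage_suite(idx_white, ext_white,
                  models = "seating_black_interviewer",
                  n_boot = 50, seed = 1),
    "Black-interviewer")
  # join loss above the threshold is an error with counts
  expect_error(
    linkage_suite(idx, ext[1:10, ], models = "seeming_racist",
                  n_boot = 50, seed = 1),
    "join loss")
})
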