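test_that("log-scale MSE matches direct arithmetic", {
  obs <- c(2, 5, 9)
  expect_equal(mse_log(obs, obs), 0)
  # constant unit offset on the log1p scale
  pred <- expm1(log1p(obs) + 1)
  expect_equal(mse_log(pred, obs), 1, tolerance = 1e-12)
  # three-point hand computation
  pred3 <- c(1, 4, 20)
  expect_equal(mse_log(pred3, obs),
               mean((log(1 + pred3) - log(1 + obs))^2))
  expect_error(mse_log(numeric(0), numeric(0)), "empty")
})

test_that("GMFE is symmetric, scale-invariant and fold-exact", {
  obs <- c(3, 7, 11)
  expect_equal(gmfe(obs, obs), 1.0)
  expect_equal(gmfe(2 * obs, obs), 2.0)
  expect_equal(gmfe(c(2 * 3, 7 / 2), c(3, 7)), 2.0)  # symmetric folds
  set.seed(10)
  for (i in 1:25) {
    p <- rlnorm(20); o <- rlnorm(20); c0 <- runif(1, 0.1, 10)
    expect_equal(gmfe(p, o), gmfe(o, p), tolerance = 1e-12)
    expect_equal(gmfe(c0 * p, c0 * o), gmfe(p, o), tolerance = 1e-12)
    expect_gte(gmfe(p, o), 1)
  }
  expect_warning(g <- gmfe(c(-1, 2), c(2, 2)), "clipped")
  expect_gte(g, 1)
})

test_that("R-squared on the log1p scale matches hand computation", {
  obs <- c(1, 2, 4, 8)
  expect_equal(r_squared(obs, obs), 1)
  pred_mean <- expm1(rep(mean(log1p(obs)), 4))
  expect_equal(r_squared(pred_mean, obs), 0, tolerance = 1e-12)
  pred_anti <- expm1(2 * mean(log1p(obs)) - log1p(obs))
  lo <- log1p(obs)
  hand <- 1 - sum((2 * mean(lo) - lo - lo)^2) / sum((lo - mean(lo))^2)
  expect_equal(r_squared(pred_anti, obs), hand, tolerance = 1e-12)
  expect_lt(r_squared(pred_anti, obs), 0)
  expect_warning(r2 <- r_squared(c(1, 2), c(3, 3)), "constant")
  expect_true(is.na(r2))
})

test_that("DM test flags degenerate loss differentials", {
  e <- c(0.3, -0.2, 0.5, 0.1)
  d0 <- dm_test(e, e)
  expect_true(d0$degenerate)
  expect_equal(d0$statistic, 0)
  expect_equal(d0$p_value, 1)

  d1 <- dm_test(c(1, 1, 1, 1), c(0, 0, 0, 0))
  expect_true(d1$degenerate)
  expect_true(is.na(d1$statistic))
})

test_that("DM statistic follows the lag-0 formula", {
  set.seed(4)
  a <- rnorm(50); b <- rnorm(50)
  d <- a^2 - b^2
  expected <- mean(d) / sqrt(mean((d - mean(d))^2) / 50)
  r <- dm_test(a, b)
  expect_equal(r$statistic, expected, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pnorm(-abs(expected)), tolerance = 1e-12)
  expect_false(r$degenerate)
})

test_that("VD-range stratification routes and scores each bin", {
  obs <- c(0.4, 1.0, 3.0)
  r <- stratified_gmfe(2 * obs, 4 * obs, obs)
  expect_equal(r$bins$n, c(1, 1, 1))
  # inclusive mid bin at the boundary
  r2 <- stratified_gmfe(1, 1, 0.5)
  expect_equal(r2$bins$n[r2$bins$range == "mid"], 1)
  # six-point arithmetic oracle: 2x folds for model a, 4x for model b
  obs6 <- c(0.2, 0.4, 1.0, 1.5, 3.0, 6.0)
  r6 <- stratified_gmfe(2 * obs6, 4 * obs6, obs6)
  expect_equal(r6$bins$gmfe_a, rep(2, 3), tolerance = 1e-12)
  expect_equal(r6$bins$gmfe_b, rep(4, 3), tolerance = 1e-12)
  expect_equal(r6$bins$delta, rep(-2, 3), tolerance = 1e-12)
  # missing observations excluded but counted; bin ns sum to evaluable n
  obs_na <- c(obs6, NA, NA)
  rna <- stratified_gmfe(c(2 * obs6, 1, 1), c(4 * obs6, 1, 1), obs_na)
  expect_equal(rna$n_missing, 2)
  expect_equal(sum(rna$bins$n), rna$n_evaluable)
  # empty bin reported as NA
  re <- stratified_gmfe(c(1, 1), c(1, 1), c(0.1, 1.0))
  expect_true(is.na(re$bins$gmfe_a[re$bins$range == "high"]))
})

test_that("repeated-run summaries aggregate wins and deltas", {
  a <- c(1, 2, 3); b <- c(2, 3, 4)
  s <- summarize_repeats(a, b)
  expect_equal(s$win_rate, 1)
  expect_equal(s$win_count, 3)
  expect_equal(s$mean_delta_wins, -1)

  s2 <- summarize_repeats(c(5, 5), c(5, 5))
  expect_equal(s2$win_rate, 0)
  expect_equal(s2$mean_delta_losses, 0)

  set.seed(6)
  a10 <- runif(10, 10, 20); b10 <- runif(10, 10, 20)
  s3 <- summarize_repeats(a10, b10)
  expect_equal(s3$mean_a, mean(a10))
  expect_equal(s3$sd_b, sd(b10))
  w <- a10 < b10
  expect_equal(s3$win_count, sum(w))
  expect_equal(s3$mean_delta_wins, mean((a10 - b10)[w]))
  expect_equal(s3$mean_delta_losses, mean((a10 - b10)[!w]))

  s1 <- summarize_repeats(3, 4)
  expect_true(is.na(s1$sd_a))
})
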