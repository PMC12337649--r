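test_that("OLS matches exact cases and the grid-search SSE oracle", {
  fit <- ols_fit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  flat <- ols_fit(1:5, rep(3, 5))
  expect_equal(flat$slope, 0, tolerance = 1e-12)
  expect_equal(flat$r_squared, 0)
  set.seed(41)
  for (i in 1:5) {
    x <- rnorm(10); y <- 1.5 * x - 2 + rnorm(10)
    fit <- ols_fit(x, y)
    oracle <- grid_ols(x, y)
    expect_equal(fit$slope, unname(oracle[1]), tolerance = 1e-3)
    expect_equal(fit$intercept, unname(oracle[2]), tolerance = 1e-3)
  }
  expect_error(ols_fit(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(ols_fit(1:2, 1:2), "at least 3")
})

test_that("SMA slope is the sd ratio with the sign of r and obeys its identities", {
  fit <- sma_fit(c(0, 1, 2), c(0, 2, 4))
  expect_equal(fit$slope, 2, tolerance = 1e-12)  # equals OLS when r^2 = 1
  set.seed(42)
  x <- rnorm(30); y <- 0.8 * x + rnorm(30, sd = 0.7)
  s_yx <- sma_fit(x, y); s_xy <- sma_fit(y, x)
  # axis swap: slopes are exact reciprocals
  expect_equal(s_yx$slope * s_xy$slope, 1, tolerance = 1e-12)
  # scaling y by 11 scales the slope by 11 (the 1:11 retention geometry)
  expect_equal(sma_fit(x, 11 * y)$slope, 11 * s_yx$slope, tolerance = 1e-12)
  # |OLS slope| <= |SMA slope|, equality iff |r| = 1
  o <- ols_fit(x, y)
  expect_lt(abs(o$slope), abs(s_yx$slope))
  expect_equal(abs(s_yx$slope), sd(y) / sd(x))
  # SMA p equals the Pearson correlation test p
  expect_equal(s_yx$p_value, cor.test(x, y)$p.value)
  expect_error(sma_fit(x, rep(2, 30)), "zero variance")
})

test_that("fits are invariant to reordering of the (x, y) pairs", {
  set.seed(43)
  x <- rnorm(15); y <- 2 * x + rnorm(15)
  perm <- sample(15)
  for (f in list(ols_fit, sma_fit)) {
    a <- f(x, y); b <- f(x[perm], y[perm])
    expect_equal(a$slope, b$slope, tolerance = 1e-12)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  }
})

test_that("Pearson correlation matches exact cases and the permutation oracle", {
  x <- c(1, 2, 3, 5, 8)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_cor(x, -x)$r, -1, tolerance = 1e-12)
  set.seed(44)
  for (i in 1:3) {
    a <- rnorm(5); b <- 0.9 * a + rnorm(5, sd = 0.8)
    ct <- pearson_cor(a, b)
    expect_lt(abs(ct$p_value - perm_pearson_p(a, b)), 0.15)
  }
  expect_error(pearson_cor(1:5, rep(1, 5)), "zero variance")
})

test_that("Kruskal-Wallis reproduces the hand-ranked example exactly", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # rank formula: 12/42 * (36/3 + 225/3) - 21 = 27/7
  expect_equal(kw$H, 12 / 42 * (36 / 3 + 225 / 3) - 21, tolerance = 1e-12)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_true(kw$exact)
  expect_equal(kw$p_value, 0.10, tolerance = 1e-12)  # 2 of 20 assignments
  ident <- kruskal_wallis(list(rep(2, 4), rep(2, 3)))
  expect_equal(ident$H, 0)
  expect_equal(ident$p_value, 1)
})

test_that("Kruskal-Wallis agrees with the enumeration oracle and chi-square approx", {
  set.seed(45)
  for (i in 1:4) {
    g <- list(rnorm(5), rnorm(5, mean = runif(1, 0, 2)))
    exact <- kruskal_wallis(g)$p_value
    expect_equal(exact, oracle_kw_exact_p(g), tolerance = 1e-12)
    approx <- kruskal_wallis(g, exact_n_max = 0L)$p_value
    expect_lt(abs(exact - approx), 0.1)
  }
})

test_that("Kruskal-Wallis is invariant under strictly monotone transforms", {
  set.seed(46)
  g <- list(rexp(6), rexp(7, rate = 0.4), rexp(5, rate = 2))
  base <- kruskal_wallis(g)
  for (f in list(function(v) v^3, exp, function(v) log(v + 1))) {
    tr <- kruskal_wallis(lapply(g, f))
    expect_equal(tr$H, base$H, tolerance = 1e-12)
    expect_equal(tr$p_value, base$p_value, tolerance = 1e-12)
  }
})

test_that("linear detrending removes trends and is invariant to added trends", {
  t <- c(0, 3, 7, 10, 14, 17)
  expect_equal(detrend_linear(t, 2 + 0.5 * t), rep(0, 6), tolerance = 1e-9)
  set.seed(47)
  y <- rnorm(6)
  res <- detrend_linear(t, y)
  expect_equal(mean(res), 0, tolerance = 1e-9)
  expect_lt(abs(sum(res * t)) / sum(t^2), 1e-9)  # orthogonal to time
  expect_equal(detrend_linear(t, y + 3.7 * t), res, tolerance = 1e-9)
})

test_that("lagged residual correlation pairs the response after the forcing", {
  set.seed(48)
  forcing <- rnorm(12)
  response <- c(0, forcing[1:11])  # responds one cycle later
  r_by_lag <- vapply(0:3, function(L) {
    abs(lagged_residual_correlation(response, forcing, L)$r)
  }, numeric(1))
  expect_equal(which.max(r_by_lag), 2L)  # lag 1
  same <- lagged_residual_correlation(forcing, forcing, 0)
  expect_equal(same$r, 1, tolerance = 1e-12)
  expect_equal(lagged_residual_correlation(response, forcing, 1)$n, 11L)
  expect_error(lagged_residual_correlation(rnorm(4), rnorm(4), 2), "too few")
  # white-noise null at n = 12: |r| < 0.58 in at least 90% of draws
  set.seed(49)
  hits <- mean(replicate(200, {
    abs(lagged_residual_correlation(rnorm(12), rnorm(12), 0)$r) < 0.58
  }))
  expect_gte(hits, 0.9)
})

test_that("log-linear decay fit recovers exponential rates", {
  t <- seq(0, 40, by = 4)
  fit <- loglinear_decay_fit(t, exp(-0.1 * t + 0.3))
  expect_equal(fit$rate, -0.1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(loglinear_decay_fit(t, rep(2.5, length(t)))$rate, 0,
               tolerance = 1e-12)
  expect_error(loglinear_decay_fit(t, c(rep(1, 10), 0)), "positive")
  # multiplicative-noise instance vs nonlinear LSQ on an (A, rate) grid
  set.seed(50)
  ratio <- 2 * exp(-0.05 * t) * exp(rnorm(length(t), sd = 0.05))
  fit <- loglinear_decay_fit(t, ratio)
  rates <- seq(-0.1, 0, by = 0.002)
  amps <- seq(1.5, 2.5, by = 0.01)
  sse <- outer(amps, rates, Vectorize(function(A, b) sum((ratio - A * exp(b * t))^2)))
  grid_rate <- rates[arrayInd(which.min(sse), dim(sse))[2]]
  expect_lt(abs(fit$rate - grid_rate), 0.002 + 1e-12)
})

test_that("the significance labelling convention follows the two alpha levels", {
  expect_identical(significance_label(c(0.008, 0.068, 0.210, 0.01, 0.1)),
                   c("significant", "weak", "ns", "weak", "weak"))
  expect_error(significance_label(1.2), "\\[0, 1\\]")
})
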