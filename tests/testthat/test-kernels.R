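test_that("seasonal oscillation has the stated zeros and periodicity", {
  p <- gp_test(A = 0.8)
  expect_equal(seasonal_s(p$d_s, p), 0)
  expect_equal(seasonal_s(runif(5), gp_test(A = 0)), rep(0, 5))
  a <- runif(10, -1, 3)
  expect_equal(seasonal_s(a + 1, p), seasonal_s(a, p), tolerance = 1e-12)
})

test_that("size-at-age follows the seasonal von Bertalanffy curve", {
  p <- gp_test(A = 0.8, d_0 = 0.1)
  expect_equal(size_at_age(p$d_0, p), 0)
  expect_lt(abs(size_at_age(200, p) - p$x_inf), 1e-6)
  # A = 0 reduces to plain von Bertalanffy
  p0 <- gp_test(x_inf = 80.7, k = 0.6, d_0 = 0.05)
  expect_equal(size_at_age(p0$d_0 + 1, p0), 80.7 * (1 - exp(-0.6)))
  # monotone in age for |A| <= 1
  a <- seq(0.2, 5, by = 0.01)
  expect_true(all(diff(size_at_age(a, gp_test(A = 1, d_0 = 0.1))) >= -1e-9))
  expect_warning(size_at_age(0.05, p), "truncated")
})

test_that("incremental growth mean composes and respects the season", {
  p <- gp_test(A = 0.9, k = 0.8)
  x <- c(5, 40, 75)
  expect_equal(growth_mean(x, 0.3, 0.3, 0, p), x)
  # over an integer year the seasonal terms cancel
  expect_equal(growth_mean(x, 0.37, 0.37, 1, p),
               x + (p$x_inf - x) * (1 - exp(-p$k)), tolerance = 1e-12)
  # composition of sub-steps equals one step (26 biweeks = 1 year)
  d <- seq(0, 1, length.out = 27)
  xx <- 20
  for (i in seq_len(26)) {
    xx <- growth_mean(xx, d[i], d[i + 1], 1 / 26, p)
  }
  expect_equal(xx, growth_mean(20, 0, 1, 1, p), tolerance = 1e-10)
  # instantaneous growth is fastest at the inflection year-fraction d_s
  rate <- function(a) {
    (growth_mean(40, a, a + 1e-5, 1e-5, p) - 40) / 1e-5
  }
  a_grid <- seq(0, 0.99, by = 0.01)
  expect_equal(a_grid[which.max(vapply(a_grid, rate, 0))], p$d_s,
               tolerance = 0.011)
})

test_that("growth kernel rows are normalised probability vectors", {
  g <- default_grid()
  p <- gp_test(A = 0.9)
  for (d_t in c(0, 0.25, 0.53)) {
    K <- growth_kernel(g, d_t, d_t + 14 / 365, 14 / 365, p)
    expect_lt(max(abs(rowSums(K$matrix) - 1)), 1e-9)
    expect_true(all(K$matrix >= 0))
  }
  # no growth, tiny sd: identity-like
  K0 <- growth_kernel(g, 0.1, 0.1, 0, gp_test(sigma_G = 1e-6))
  expect_equal(unname(diag(K0$matrix)), rep(1, g$m), tolerance = 1e-9)
  # degenerate sigma_G = 0: nearest-bin assignment
  Kd <- growth_kernel(g, 0.1, 0.1, 0, gp_test(sigma_G = 0))
  expect_equal(unname(diag(Kd$matrix)), rep(1, g$m))
})

test_that("growth kernel mass matches a quadrature oracle", {
  g <- default_grid()
  p <- gp_test(x_inf = 80, k = 1, A = 0, sigma_G = 2.8)
  dt <- 14 / 365
  K <- growth_kernel(g, 0, dt, dt, p)
  i <- which(g$midpoints == 42.5)
  mu <- 42.5 + (80 - 42.5) * (1 - exp(-dt))
  oracle <- vapply(seq_len(g$m), function(j) {
    integrate(function(x) dnorm(x, mu, 2.8), g$edges[j], g$edges[j + 1],
              rel.tol = 1e-10)$value
  }, 0)
  oracle <- oracle / sum(oracle)
  expect_rel_equal(K$matrix[i, oracle > 1e-12], oracle[oracle > 1e-12],
                   1e-6)
  # mass is centred at the growth mean
  expect_lt(abs(sum(K$matrix[i, ] * g$midpoints) - mu), 0.05)
})

test_that("natural survival is a valid, size-monotone probability", {
  mp <- mortality_params(beta = 0.8, alpha = 8)
  x <- seq(2.5, 107.5, by = 5)
  s <- natural_survival(x, 0.53, mp)
  expect_true(all(s > 0 & s <= 1))
  expect_true(all(diff(s) >= 0))
  expect_equal(natural_survival(x, 0.5, mortality_params(0.8, 0)),
               rep(exp(-0.4), length(x)))
  expect_equal(natural_survival(x, 3, mortality_params(0, 0)),
               rep(1, length(x)))
  expect_equal(natural_survival(0, 1, mp), 0)
})

test_that("projection kernel factorises into growth times survival", {
  g <- default_grid()
  gp <- gp_test(A = 0.5)
  mp <- mortality_params(beta = 1, alpha = 8)
  K <- projection_kernel(g, 0.2, 0.2 + 14 / 365, 14 / 365, gp, mp)
  expect_lt(max(abs(rowSums(K$matrix) -
                      natural_survival(g$midpoints, 14 / 365, mp))), 1e-9)
  # survival == 1 conserves abundance
  K1 <- projection_kernel(g, 0.2, 0.2 + 14 / 365, 14 / 365, gp,
                          mortality_params(0, 0))
  n <- bin_density(function(x) pnorm(x, 40, 20), g, 321)
  expect_equal(sum(apply_kernel(K1, n)), 321, tolerance = 1e-9)
})

test_that("build_kernels matches the per-step constructor", {
  g <- default_grid()
  se <- season_config()
  gp <- default_params()
  kern <- build_kernels(g, se, gp, gp)
  expect_length(kern$within, se$t_max - 1)
  for (t in c(1, 7, 14)) {
    ref <- projection_kernel(g, se$d_t[t], se$d_t[t + 1], se$delta_t,
                             gp, gp)
    expect_equal(kern$within[[t]]$matrix, ref$matrix, tolerance = 1e-12)
  }
  ref_w <- growth_kernel(g, se$d_tmax, 1, se$delta_winter, gp)
  expect_equal(kern$winter$matrix, ref_w$matrix, tolerance = 1e-12)
})
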