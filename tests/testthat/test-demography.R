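test_that("within-season step applies removal, kernel and recruit pulse", {
  g <- default_grid()
  gp <- gp_test()
  K1 <- projection_kernel(g, 0, 14 / 365, 14 / 365, gp,
                          mortality_params(0, 0))
  n <- bin_density(function(x) pnorm(x, 50, 15), g, 400)
  rec <- recruit_density(100, default_params(), g)
  # removals equal to the state leave only the recruits
  expect_equal(step_within_season(n, n, K1, rec), rec)
  expect_equal(sum(step_within_season(n, 0 * n, K1, NULL)), 400,
               tolerance = 1e-9)
  # identity kernel: state minus removals
  Kid <- K1; Kid$matrix <- diag(g$m)
  rem <- pmin(n, 3)
  expect_equal(step_within_season(n, rem, Kid, NULL), n - rem)
  expect_error(step_within_season(n, n + 1, K1, NULL), "exceed")
})

test_that("overwinter survival is monotone in size and density", {
  x <- seq(2.5, 107.5, by = 5)
  p <- overwinter_params(alpha_o = 0.09, sigma_o = 0.4)
  expect_equal(overwinter_survival_prob(x, 500, overwinter_params(0), 0),
               rep(1 - 1e-12, length(x)))
  expect_equal(overwinter_survival_prob(5, 0, p, -0.3), exp(-0.3))
  s1 <- overwinter_survival_prob(x, 500, p, 0)
  s2 <- overwinter_survival_prob(x, 2000, p, 0)
  expect_true(all(diff(s1) >= 0))          # larger crabs survive better
  expect_true(all(s2 <= s1))               # higher density, lower survival
  expect_true(all(s1 >= 0 & s1 < 1))
  # alternative formulations
  expect_equal(overwinter_survival_prob(x, 1000, p, 0, form = "constant"),
               rep(exp(-0.09), length(x)))
  sd_only <- overwinter_survival_prob(x, 1, p, 0, form = "size")
  expect_true(all(diff(sd_only) >= 0))
  expect_equal(overwinter_survival_prob(x, 1000, p, 0, form = "density"),
               rep(exp(-0.09 * 1000), length(x)))
})

test_that("overwinter transition matches its binomial oracle", {
  g <- default_grid()
  gp <- gp_test()
  G_o <- growth_kernel(g, 0.53, 1, 0.47, gp)
  n_end <- bin_density(function(x) pnorm(x, 45, 18), g, 800)
  # survival ~ 1: all (rounded, grown) crabs persist
  set.seed(1)
  out1 <- overwinter_transition(n_end, 0 * n_end, G_o,
                                overwinter_params(0), 0)
  expect_equal(sum(out1), sum(round(apply_kernel(G_o, n_end))))
  # survival ~ 0
  out0 <- overwinter_transition(n_end, 0 * n_end, G_o,
                                overwinter_params(1e6), 0)
  expect_equal(sum(out0), 0)
  # Monte-Carlo mean against M * S within 3 MC standard errors
  p <- overwinter_params(0.09)
  M <- round(apply_kernel(G_o, n_end))
  S <- overwinter_survival_prob(g$midpoints, sum(n_end), p, 0)
  set.seed(42)
  draws <- replicate(1e4, sum(overwinter_transition(n_end, 0 * n_end,
                                                    G_o, p, 0)))
  mu <- sum(M * S)
  se <- sqrt(sum(M * S * (1 - S)) / 1e4)
  expect_lt(abs(mean(draws) - mu), 3 * se)
})

test_that("initial and recruit densities integrate to their abundances", {
  g <- default_grid()
  p <- recruit_init_params(mu_A = log(33), sigma_A = 0.2, lambda_A = 438,
                           mu_R = 5.4, sigma_R = 2, mu_lambda = 5.5,
                           sigma_lambda = 1.5)
  ini <- initial_density(p, g)
  expect_lt(abs(sum(ini) - 438), 1e-9)
  # CDF-difference oracle
  oracle <- diff(plnorm(g$edges, log(33), 0.2))
  oracle <- 438 * oracle / sum(oracle)
  expect_equal(ini, oracle, tolerance = 1e-12)
  # sigma_A -> 0 concentrates in the bin containing exp(mu_A)
  p0 <- p; p0$sigma_A <- 1e-6
  ini0 <- initial_density(p0, g)
  expect_equal(ini0[findInterval(33, g$edges)], 438)

  r <- recruit_density(694, p, g)
  expect_lt(abs(sum(r) - 694), 1e-9)
  expect_gt(sum(r[1:3]) / 694, 0.95)   # recruits sit in the first bins
  expect_equal(recruit_density(0, p, g), rep(0, g$m))
})

test_that("trajectory conserves abundance under identity dynamics", {
  g <- default_grid()
  se <- season_config()
  p <- default_params()
  p$beta <- 0; p$alpha <- 0; p$A <- 0; p$alpha_o <- 0; p$sigma_o <- 0
  set.seed(5)
  tr <- simulate_trajectory(p, g, se, n_years = 2, effort = NULL,
                            latents = list(lambda_R = c(0, 0),
                                           eps_y = 0))
  totals <- apply(tr$N, c(1, 2), sum)
  # within-year totals constant (no mortality, no removals, no recruits)
  expect_equal(totals[, 1], rep(totals[1, 1], se$t_max), tolerance = 1e-9)
  expect_true(all(tr$removals == 0))
})

test_that("trajectory recruit pulses follow their log-normal law", {
  g <- default_grid()
  se <- season_config()
  p <- default_params()
  set.seed(11)
  tr <- simulate_trajectory(p, g, se, n_years = 60, effort = NULL)
  ll <- log(tr$lambda_R)
  expect_lt(abs(mean(ll) - p$mu_lambda), 3 * p$sigma_lambda / sqrt(60))
  expect_lt(abs(sd(ll) - p$sigma_lambda), 0.45)
})
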