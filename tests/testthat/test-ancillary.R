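test_that("size-at-age likelihood is centred on the growth curve", {
  p <- default_params()
  rec <- data.frame(year = 2020, age_years = 2, carapace_mm = 1)
  rec$carapace_mm <- size_at_age(2, p)
  ll0 <- size_at_age_loglik(rec, p)
  # perturbing the observed width lowers the likelihood
  for (d in c(-10, -3, 3, 10)) {
    rec2 <- rec; rec2$carapace_mm <- rec$carapace_mm + d
    expect_lt(size_at_age_loglik(rec2, p), ll0)
  }
  # ages at or below d_0 are impossible
  bad <- data.frame(year = 2020, age_years = p$d_0, carapace_mm = 10)
  expect_equal(size_at_age_loglik(bad, p), -Inf)
  # year effect shifts the log-location
  ye <- c("2020" = 0.2)
  rec3 <- rec
  rec3$carapace_mm <- exp(log(size_at_age(2, p)) + 0.2)
  expect_gt(size_at_age_loglik(rec3, p, ye, include_effect_prior = FALSE),
            size_at_age_loglik(rec3, p, c("2020" = 0),
                               include_effect_prior = FALSE))
})

test_that("growth parameters are recoverable from size-at-age data alone", {
  truth <- growth_params(x_inf = 80, k = 1.2, A = 0.8, d_s = 0.25,
                         sigma_G = 2.8, d_0 = 0.05, sigma_w = 0.08,
                         sigma_u = 1e-4)
  set.seed(21)
  d2 <- generate_d2(truth, n = 300, years = 2016:2020,
                    age_range = c(0.5, 4))
  obj <- function(v) {
    p <- truth; p$x_inf <- v[1]; p$k <- v[2]
    -size_at_age_loglik(d2, p)
  }
  fit <- optim(c(70, 0.8), obj)
  expect_lt(abs(fit$par[1] - 80) / 80, 0.05)
  expect_lt(abs(fit$par[2] - 1.2) / 1.2, 0.05)
})

test_that("marked pool projection follows survival decay", {
  g <- default_grid()
  # minimal growth, survival ~ 0.9 per occasion
  dt <- 14 / 365
  beta <- -log(0.9) / dt
  gp <- gp_test(k = 1e-6, sigma_G = 0.5)
  mp <- mortality_params(beta = beta, alpha = 0)
  K <- projection_kernel(g, 0.3, 0.3 + dt, dt, gp, mp)
  pool <- numeric(g$m)
  m0 <- numeric(g$m); m0[g$midpoints == 52.5] <- 100
  pool <- mc_project(pool, m0, K)
  expect_equal(sum(pool), 90, tolerance = 0.01)
  pool <- mc_project(pool, 0 * m0, K)
  expect_equal(sum(pool), 81, tolerance = 0.02)
  # no marking: empty pool forever
  expect_equal(sum(mc_project(numeric(g$m), numeric(g$m), K)), 0)
  # identity growth and survival 1: pool accumulates marked crabs
  K1 <- projection_kernel(g, 0.3, 0.3, 0, gp_test(sigma_G = 1e-9),
                          mortality_params(0, 0))
  pool2 <- mc_project(numeric(g$m), m0, K1)
  pool2 <- mc_project(pool2, m0, K1)
  expect_equal(sum(pool2), 200, tolerance = 1e-9)
})

test_that("mark-recapture likelihood handles boundaries and recovers h_0", {
  g <- default_grid()
  p <- default_params()
  set.seed(31)
  d3 <- generate_d3(p, g, n_occasions = 8, marked_per_occ = 150,
                    n_traps = 20)
  expect_true(all(rowSums(d3$recaptured) <=
                    cumsum(rowSums(d3$marked))[seq_len(8)]))
  ll <- mc_recapture_loglik(d3, p, p, p, g)
  expect_true(is.finite(ll))
  # no traps: any recapture is impossible
  d3z <- d3; d3z$n_traps <- rep(0, 8)
  expect_equal(mc_recapture_loglik(d3z, p, p, p, g), -Inf)
  # profile likelihood over the Fukui midpoint recovers it within 5 mm
  prof <- vapply(seq(40, 60, by = 1), function(h0) {
    pp <- p; pp$h_0_F <- h0
    mc_recapture_loglik(d3, pp, pp, pp, g)
  }, 0)
  expect_lt(abs(seq(40, 60, by = 1)[which.max(prof)] - p$h_0_F), 5)
})

test_that("recapture fractions match the capture probability", {
  g <- default_grid()
  p <- default_params()
  set.seed(41)
  d3 <- generate_d3(p, g, n_occasions = 1, marked_per_occ = 10000,
                    n_traps = 20, marked_size_mean = 60,
                    marked_size_sd = 5)
  Hf <- hazard(g$midpoints, "fukui", p)
  p_t <- 1 - exp(-20 * Hf * 1)
  i <- which(g$midpoints == 62.5)
  kern <- crabipm:::mc_kernels(d3$year_frac, g, p, p)
  pool <- crabipm:::mc_pool_trajectory(d3$marked, kern, g)
  n_i <- round(pool[1, i])
  se <- sqrt(p_t[i] * (1 - p_t[i]) / n_i)
  expect_lt(abs(d3$recaptured[1, i] / n_i - p_t[i]), 3 * se)
})
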