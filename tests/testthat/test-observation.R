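tp_test <- function() default_params()

test_that("hazard curves have the documented shapes", {
  p <- tp_test()
  expect_equal(hazard(p$h_0_F, "fukui", p), p$h_max_F / 2)
  expect_equal(hazard(p$h_0_S, "shrimp", p), p$h_max_S / 2)
  expect_equal(hazard(p$h_A_M, "minnow", p), p$h_max_M)
  x <- seq(1, 109, by = 1)
  hm <- hazard(x, "minnow", p)
  expect_equal(x[which.max(hm)], p$h_A_M)     # bell-shaped with mode h_A
  expect_lt(hazard(200, "minnow", p), 1e-6)
  expect_true(all(diff(hazard(x, "fukui", p)) >= 0))   # logistic: monotone
  expect_error(hazard(50, "crabpot", p))
  # with default parameters no gear is effective below 30 mm
  for (g in c("fukui", "shrimp", "minnow")) {
    expect_lt(max(hazard(seq(1, 29), g, p)) /
                max(hazard(x, g, p)), 0.02)
  }
})

test_that("capture probability composes hazards across traps", {
  p <- tp_test()
  x <- c(20, 45, 60, 90)
  expect_equal(capture_probability(x, NULL, p), rep(0, 4))
  one <- data.frame(gear = "fukui", soak_days = 1)
  two <- data.frame(gear = c("fukui", "fukui"), soak_days = c(1, 1))
  p1 <- capture_probability(x, one, p)
  expect_equal(capture_probability(x, two, p), 1 - (1 - p1)^2,
               tolerance = 1e-12)
  # direct evaluation: H = 0.05/day at the logistic midpoint
  p2 <- p; p2$h_max_F <- 0.10
  expect_equal(capture_probability(p$h_0_F, one, p2), 1 - exp(-0.05))
  # monotone in soak time
  soaks <- c(0.5, 1, 2, 4)
  pc <- vapply(soaks, function(s)
    capture_probability(60, data.frame(gear = "shrimp", soak_days = s), p),
    0)
  expect_true(all(diff(pc) > 0))
  # n_traps multiplier equals repeating the trap row
  frac <- data.frame(gear = "fukui", soak_days = 1, n_traps = 2)
  expect_equal(capture_probability(x, frac, p),
               capture_probability(x, two, p))
})

test_that("conditional trap probabilities are hazard shares", {
  p <- tp_test()
  one <- data.frame(gear = "minnow", soak_days = 1)
  expect_equal(conditional_trap_probs(45, one, p), 1)
  two <- data.frame(gear = c("shrimp", "shrimp"), soak_days = c(1, 2))
  expect_equal(conditional_trap_probs(60, two, p), c(0.5, 0.5))
  fm <- data.frame(gear = c("fukui", "minnow"), soak_days = c(1, 1))
  pr <- conditional_trap_probs(90, fm, p)
  expect_gt(pr[1], 0.999)    # minnow hazard vanishes far from its mode
  expect_equal(sum(pr), 1)
  p0 <- p; p0$h_max_F <- 0; p0$h_max_M <- 0
  expect_warning(out <- conditional_trap_probs(60, fm, p0), "zero")
  expect_equal(out, c(0.5, 0.5))
})

test_that("Dirichlet-multinomial density and sampler behave at the limits", {
  x <- c(3L, 0L, 7L, 1L)
  pvec <- c(0.2, 0.1, 0.5, 0.2)
  # rho -> Inf recovers the multinomial
  expect_lt(abs(ddirmnom_log(x, 1e6 * pvec) -
                  dmultinom(x, prob = pvec, log = TRUE)), 1e-3)
  expect_lt(abs(ddirmnom_log(x, 1e8 * pvec) -
                  dmultinom(x, prob = pvec, log = TRUE)), 1e-5)
  # density normalises over a small support
  xs <- expand.grid(0:3, 0:3)
  xs <- xs[rowSums(xs) == 3, ]
  tot <- sum(apply(xs, 1, function(v) exp(ddirmnom_log(as.numeric(v),
                                                       c(2, 5)))))
  expect_equal(tot, 1, tolerance = 1e-10)
  # overdispersion: DM variance exceeds multinomial variance at small rho
  set.seed(3)
  dm <- replicate(4000, rdirmnom(20, 2 * pvec)[1])
  mn <- replicate(4000, rdirmnom(20, 1e7 * pvec)[1])
  expect_gt(var(dm), 1.5 * var(mn))
  expect_true(all(replicate(50, sum(rdirmnom(17, pvec))) == 17))
})

test_that("removal likelihood matches its generative counterpart", {
  g <- default_grid()
  p <- tp_test()
  traps <- data.frame(gear = c("fukui", "shrimp", "minnow"),
                      soak_days = c(1, 1, 2))
  latent <- bin_density(function(x) pnorm(x, 55, 15), g, 500)
  set.seed(8)
  s <- sample_removals(latent, traps, p, g)
  expect_true(all(colSums(s$counts) == s$totals))
  expect_true(all(s$totals <= round(latent)))
  ll <- removal_loglik(s$counts, traps, latent, p, g)
  expect_true(is.finite(ll) && ll < 0)
  # impossible observation
  bad <- s$counts; bad[1, g$m] <- round(latent[g$m]) + 5L
  expect_equal(removal_loglik(bad, traps, latent, p, g), -Inf)
  # certain outcome has log-likelihood 0: one trap with capture prob ~ 1
  # and all (large) crabs removed
  p_sure <- p; p_sure$h_max_F <- 1e4
  one <- data.frame(gear = "fukui", soak_days = 5)
  latent_big <- round(bin_density(function(x) pnorm(x, 90, 8), g, 200))
  ll_sure <- removal_loglik(matrix(latent_big, 1, g$m), one, latent_big,
                            p_sure, g)
  expect_lt(abs(ll_sure), 1e-6)
  # rho -> Inf: Dirichlet-multinomial term equals the multinomial
  p_inf <- p; p_inf$rho <- 1e6
  ll_dm <- removal_loglik(s$counts, traps, latent, p_inf, g)
  mult <- sum(stats::dbinom(s$totals, round(latent),
                            capture_probability(g$midpoints, traps, p_inf),
                            log = TRUE))
  for (i in which(s$totals > 0)) {
    mult <- mult + dmultinom(s$counts[, i],
                             prob = conditional_trap_probs(g$midpoints[i],
                                                           traps, p_inf),
                             log = TRUE)
  }
  expect_lt(abs(ll_dm - mult), 1e-4)
})

test_that("sampled removal totals match their binomial expectation", {
  g <- make_grid(0, 110, 22)   # coarse grid keeps the simulation cheap
  p <- tp_test()
  traps <- data.frame(gear = c("fukui", "shrimp"), soak_days = c(1, 1))
  latent <- c(0, 50, 400, 300, 100)
  pcap <- capture_probability(g$midpoints, traps, p)
  set.seed(9)
  tot <- replicate(1e4, sum(sample_removals(latent, traps, p, g)$totals))
  mu <- sum(latent * pcap)
  se <- sqrt(sum(latent * pcap * (1 - pcap)) / 1e4)
  expect_lt(abs(mean(tot) - mu), 3 * se)
  # zero capture probability
  p0 <- p; p0$h_max_F <- 0; p0$h_max_S <- 0; p0$h_max_M <- 0
  expect_true(all(sample_removals(latent, traps, p0, g)$totals == 0))
})

test_that("vectorised removal likelihood equals the per-occasion route", {
  st <- small_study()
  p <- default_params()
  tr <- st$truth
  # dual route: fast flat computation vs summing removal_loglik occasionwise
  fast <- crabipm:::d1_loglik(p, tr$N, st$data$d1p, st$data$grid)
  slow <- 0
  for (oc in st$d1$occ) {
    slow <- slow + removal_loglik(oc$counts, oc$traps, tr$N[oc$t, oc$y, ],
                                  p, st$data$grid)
  }
  expect_equal(fast, slow, tolerance = 1e-8)
  # and the pointwise matrix sums to the same value
  pw <- crabipm:::d1_loglik(p, tr$N, st$data$d1p, st$data$grid,
                            pointwise = TRUE)
  expect_equal(sum(pw), fast, tolerance = 1e-8)
})
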