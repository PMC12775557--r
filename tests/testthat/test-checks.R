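# fabricate a draws object by replicating a parameter set with its latents
# (handy for testing the WAIC / PPC machinery without an MCMC run)
fake_draws <- function(params, latents, n = 40, ow_latent = "binomial",
                       jitter_lam = 0) {
  Y <- length(latents$llam)
  pm <- matrix(rep(unlist(params[crabipm:::PARAM_NAMES]), each = n), n,
               length(crabipm:::PARAM_NAMES), dimnames = list(NULL, crabipm:::PARAM_NAMES))
  lam <- matrix(rep(exp(latents$llam), each = n), n, Y)
  if (jitter_lam > 0) {
    # jitter recruit pulses upward only, so every fake draw stays feasible
    # against the observed removals
    lam <- lam * exp(matrix(abs(rnorm(n * Y, 0, jitter_lam)), n, Y))
  }
  W <- array(rep(as.numeric(latents$W), each = n),
             dim = c(n, nrow(latents$W), ncol(latents$W)))
  eu <- if (length(latents$eps_u)) {
    matrix(rep(latents$eps_u, each = n), n, length(latents$eps_u),
           dimnames = list(NULL, names(latents$eps_u)))
  } else matrix(0, n, 0)
  structure(list(params = pm, lambda_R = lam,
                 eps_y = matrix(rep(latents$eps_y, each = n), n,
                                length(latents$eps_y)),
                 eps_u = eu, W = W, lp = rep(0, n), chain = rep(1L, n),
                 config = list(free = crabipm:::PARAM_NAMES, form = "density_size",
                               ow_latent = ow_latent)),
            class = "crab_draws")
}

test_that("WAIC is reproducible and orders truth above corrupted params", {
  st <- small_study()
  p <- default_params()
  set.seed(2)
  dr <- fake_draws(p, st$truth$latents, n = 25, ow_latent = "normal",
                   jitter_lam = 0.02)
  w1 <- compute_waic(dr, st$data, n_draws = 25)
  w2 <- compute_waic(dr, st$data, n_draws = 25)
  expect_equal(w1$waic, w2$waic)
  expect_true(is.finite(w1$waic))
  expect_equal(dim(w1$pointwise)[2],
               st$data$d1p$n_occ * st$data$grid$m)
  # corrupting the capture parameters worsens the fit
  p_bad <- p; p_bad$h_max_F <- p$h_max_F * 3; p_bad$h_max_S <- p$h_max_S / 3
  dr_bad <- fake_draws(p_bad, st$truth$latents, n = 25,
                       ow_latent = "normal", jitter_lam = 0.02)
  w_bad <- compute_waic(dr_bad, st$data, n_draws = 25)
  expect_gt(w_bad$waic, w1$waic)
})

test_that("posterior predictive checks are calibrated at the truth", {
  # conditional on the generating state the p-value is uniform over data
  # replicates, so check calibration across several generated datasets
  p <- default_params()
  in_range <- 0L
  for (r in 1:8) {
    set.seed(400 + r)
    st_r <- generate_study(p, n_years = 2, design = small_design(),
                           n_d2 = 30, n_occasions = 2,
                           marked_per_occ = 40, n_traps = 10)
    dr <- fake_draws(p, st_r$truth$latents, n = 40)
    ppc <- posterior_predictive_check(dr, st_r$data, "deviance",
                                      n_draws = 40)
    if (ppc$p_value >= 0.05 && ppc$p_value <= 0.95) {
      in_range <- in_range + 1L
    }
  }
  expect_gte(in_range, 6L)
  # prop-zero machinery returns a probability
  st <- small_study()
  dr <- fake_draws(p, st$truth$latents, n = 40)
  set.seed(3)
  ppc_z <- posterior_predictive_check(dr, st$data, "prop_zero",
                                      n_draws = 40)
  expect_gte(ppc_z$p_value, 0)
  expect_lte(ppc_z$p_value, 1)
})

test_that("structural zeros push the zero-proportion discrepancy outward", {
  st <- small_study()
  p <- default_params()
  # zero out the catches of a third of the traps (simulated trap failure)
  d1z <- st$d1
  set.seed(4)
  for (o in seq_along(d1z$occ)) {
    oc <- d1z$occ[[o]]
    kill <- runif(nrow(oc$traps)) < 1 / 3
    oc$counts[kill, ] <- 0L
    d1z$occ[[o]] <- oc
    d1z$CT[oc$t, oc$y, ] <- colSums(oc$counts)
  }
  suppressWarnings(data_z <- ipm_data(d1z, st$d2, st$d3, st$data$grid,
                                      st$data$season))
  dr <- fake_draws(p, st$truth$latents, n = 50)
  ppc_z <- posterior_predictive_check(dr, data_z, "prop_zero", n_draws = 50)
  # observed data now have more zeros than model replicates
  expect_lt(ppc_z$p_value, 0.1)
})
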