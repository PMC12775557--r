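# draw -> latents list, reconstructed from a crab_draws row
draw_latents <- function(draws, i) {
  Y <- ncol(draws$lambda_R)
  list(llam = log(draws$lambda_R[i, ]),
       eps_y = if (Y > 1) draws$eps_y[i, ] else numeric(0),
       eps_u = if (ncol(draws$eps_u)) stats::setNames(draws$eps_u[i, ],
                                                      colnames(draws$eps_u))
               else stats::setNames(numeric(0), character(0)),
       W = matrix(draws$W[i, , ], nrow = max(Y - 1, 0),
                  ncol = dim(draws$W)[3]))
}

draw_params <- function(draws, i) {
  p <- as.list(draws$params[i, ])
  class(p) <- c("crab_params", "list")
  p
}

#' WAIC of the removal-data component
#'
#' Watanabe-Akaike information criterion computed pointwise over the
#' removal-data observation cells (time point x year x size bin), with the
#' Dirichlet-multinomial trap-split term folded into its bin's cell.
#' Conditional on the sampled latent states.
#'
#' @param draws A `crab_draws` object.
#' @param data The [ipm_data()] bundle the model was fitted to.
#' @param form Overwinter survival formulation used in the fit (defaults to
#'   the fit's own).
#' @param n_draws Number of (evenly thinned) draws to use.
#' @return List with `waic`, `lppd`, `p_waic` and the pointwise matrix.
#' @export
compute_waic <- function(draws, data, form = draws$config$form,
                         n_draws = 400) {
  n <- nrow(draws$params)
  use <- unique(round(seq(1, n, length.out = min(n_draws, n))))
  ll <- NULL
  for (s in seq_along(use)) {
    i <- use[s]
    pp <- draw_params(draws, i)
    lat <- draw_latents(draws, i)
    tr <- latent_trajectory(pp, exp(lat$llam), lat$W, data, form,
                            mode = draws$config$ow_latent %||% "binomial",
                            eps_y = lat$eps_y)
    if (is.null(tr)) stop("stored draw ", i, " is infeasible")
    pw <- d1_loglik(pp, tr$N, data$d1p, data$grid, pointwise = TRUE)
    if (is.null(ll)) ll <- matrix(NA_real_, length(use), length(pw))
    ll[s, ] <- as.numeric(pw)
  }
  colmax <- apply(ll, 2, max)
  lppd <- sum(colmax + log(colMeans(exp(sweep(ll, 2, colmax)))))
  p_waic <- sum(apply(ll, 2, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic,
       pointwise = ll)
}

#' Fit and compare overwinter-mortality formulations by WAIC
#'
#' Refits the model under each candidate overwinter survival form (with the
#' form-appropriate prior scale on the intensity) and ranks them by WAIC.
#'
#' @param data An [ipm_data()] bundle.
#' @param forms Character vector of forms to compare.
#' @param config Base [mcmc_config()]; `form` and `priors` are overridden
#'   per candidate.
#' @param seed Seed passed to each fit.
#' @param n_draws Draws used in each WAIC evaluation.
#' @return Data frame with columns `form` and `waic`, sorted ascending.
#' @export
waic_compare <- function(data, forms = c("density_size", "size", "density",
                                         "constant"),
                         config = mcmc_config(), seed = 1, n_draws = 200) {
  res <- lapply(forms, function(f) {
    cf <- config
    cf$form <- f
    cf$priors <- default_priors(f)
    fit <- run_mcmc(data, cf, seed = seed)
    compute_waic(fit, data, form = f, n_draws = n_draws)$waic
  })
  out <- data.frame(form = forms, waic = unlist(res))
  out[order(out$waic), ]
}

# discrepancy of one dataset realisation: omnibus deviance or the
# proportion of zeros among per-trap count cells
d1_discrepancy <- function(params, N, occ, d1like_counts, grid,
                           type = "deviance") {
  if (type == "prop_zero") {
    cells <- unlist(lapply(d1like_counts, as.numeric))
    return(mean(cells == 0))
  }
  dev <- 0
  for (o in seq_along(occ)) {
    ll <- removal_loglik(d1like_counts[[o]], occ[[o]]$traps,
                         N[occ[[o]]$t, occ[[o]]$y, ], params, grid)
    dev <- dev - 2 * ll
  }
  dev
}

#' Posterior predictive check
#'
#' For each retained posterior draw, replicate removal data are generated
#' from the observation model conditional on that draw's latent trajectory,
#' and a discrepancy statistic is compared between replicate and observed
#' data. The Bayesian p-value is `Pr(T(y_rep) >= T(y_obs))`.
#'
#' @param draws A `crab_draws` object.
#' @param data The fitted [ipm_data()] bundle.
#' @param discrepancy `"deviance"` (omnibus, uses the joint removal
#'   log-likelihood) or `"prop_zero"` (targeted check for zero inflation).
#' @param n_draws Number of draws to use.
#' @param form Overwinter formulation (defaults to the fit's own).
#' @return List with `p_value` and the paired discrepancy values.
#' @export
posterior_predictive_check <- function(draws, data,
                                       discrepancy = c("deviance",
                                                       "prop_zero"),
                                       n_draws = 200,
                                       form = draws$config$form) {
  discrepancy <- match.arg(discrepancy)
  n <- nrow(draws$params)
  use <- unique(round(seq(1, n, length.out = min(n_draws, n))))
  occ <- data$d1$occ
  obs_counts <- lapply(occ, `[[`, "counts")
  T_obs <- T_rep <- numeric(length(use))
  for (s in seq_along(use)) {
    i <- use[s]
    pp <- draw_params(draws, i)
    lat <- draw_latents(draws, i)
    tr <- latent_trajectory(pp, exp(lat$llam), lat$W, data, form,
                            mode = draws$config$ow_latent %||% "binomial",
                            eps_y = lat$eps_y)
    rep_counts <- lapply(occ, function(oc) {
      sample_removals(tr$N[oc$t, oc$y, ], oc$traps, pp, data$grid)$counts
    })
    T_obs[s] <- d1_discrepancy(pp, tr$N, occ, obs_counts, data$grid,
                               discrepancy)
    T_rep[s] <- d1_discrepancy(pp, tr$N, occ, rep_counts, data$grid,
                               discrepancy)
  }
  list(p_value = mean(T_rep >= T_obs), T_obs = T_obs, T_rep = T_rep,
       discrepancy = discrepancy)
}
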