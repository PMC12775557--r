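#' Define a removal-effort scenario
#'
#' A total annual trap count of one gear type, applied evenly over the 14
#' biweeks of the trapping season (fractional traps per biweek are allowed:
#' the hazard scales linearly in effort).
#'
#' @param gear `"fukui"`, `"shrimp"`, `"minnow"` or `"none"`.
#' @param annual_traps Total traps fished per season.
#' @param soak_days Soak time per trap (days).
#' @param n_biweeks Biweeks over which effort is spread (default 14).
#' @param name Scenario label.
#' @return List of class `effort_scenario`.
#' @export
effort_scenario <- function(gear, annual_traps, soak_days = 1,
                            n_biweeks = 14,
                            name = paste0(gear, "_", annual_traps)) {
  stopifnot(gear %in% c(GEARS, "none"), annual_traps >= 0)
  eff <- if (gear == "none" || annual_traps == 0) NULL else
    data.frame(t = seq_len(n_biweeks), gear = gear,
               n_traps = annual_traps / n_biweeks, soak_days = soak_days)
  structure(list(name = name, gear = gear, annual_traps = annual_traps,
                 soak_days = soak_days, effort = eff),
            class = "effort_scenario")
}

# one 'horizon'-year forward simulation under a scenario, given one
# parameter draw; returns matrix [horizon x m] of post-overwinter states
simulate_forecast <- function(params, scenario, grid, season, horizon,
                              lambda_R, eps_y, form = "density_size") {
  tm <- season$t_max
  m <- grid$m
  kern <- build_kernels(grid, season, params, params)
  eff <- scenario$effort
  pcap <- if (!is.null(eff)) {
    capture_probability(grid$midpoints,
                        eff[1, , drop = FALSE], params)
  }
  eff_t <- if (!is.null(eff)) eff$t else integer(0)
  out <- matrix(0, horizon, m)
  N <- initial_density(params, grid)
  for (y in seq_len(horizon)) {
    R_y <- recruit_density(lambda_R[y], params, grid)
    Nt <- N
    for (t in seq_len(tm - 1)) {
      CT <- if (t %in% eff_t) stats::rbinom(m, round(pmax(Nt, 0)), pcap)
            else 0
      Nt <- as.numeric(crossprod(kern$within[[t]]$matrix, pmax(Nt - CT, 0)))
      if (t == season$t_R) Nt <- Nt + R_y
    }
    CT <- if (tm %in% eff_t) stats::rbinom(m, round(pmax(Nt, 0)), pcap)
          else 0
    N_total <- sum(Nt)
    M <- round(as.numeric(crossprod(kern$winter$matrix, pmax(Nt - CT, 0))))
    S_o <- overwinter_survival_prob(grid$midpoints, N_total, params,
                                    eps_y[y], form)
    N <- stats::rbinom(m, M, S_o)
    out[y, ] <- N
  }
  out
}

#' Stochastic equilibrium forecast under removal-effort scenarios
#'
#' For each replicate, one posterior sample is selected; annual recruit
#' pulses and overwinter random effects are drawn from that sample's
#' hyper-parameters and *shared across scenarios* (common random numbers:
#' each scenario restarts the replicate's random stream), the population is
#' projected `horizon` years, and the post-overwinter April state is
#' recorded each year.
#'
#' @param draws A `crab_draws` object (or a one-row parameter list wrapped
#'   via [param_set()] for fixed-parameter forecasts).
#' @param scenarios List of [effort_scenario()] objects.
#' @param n_rep Number of simulation replicates (posterior samples).
#' @param horizon Projection length in years (must exceed `transient`).
#' @param transient Initial years discarded as transient.
#' @param grid,season Domain and season configuration.
#' @param form Overwinter formulation.
#' @param seed Integer seed.
#' @return List of class `forecast_summary`: `summary` (data frame:
#'   scenario, size_bin_mid, mean_abundance, sd_abundance), `totals`
#'   (per-scenario mean and sd of total equilibrium abundance) and
#'   `equilibrium` (array replicate x bin per scenario).
#' @export
forecast_equilibrium <- function(draws, scenarios, n_rep = 100,
                                 horizon = 25, transient = 5,
                                 grid = make_grid(),
                                 season = season_config(),
                                 form = "density_size", seed = 1) {
  if (horizon <= transient) stop("`horizon` must exceed `transient`")
  if (inherits(scenarios, "effort_scenario")) scenarios <- list(scenarios)
  fixed <- inherits(draws, "crab_params")
  n_avail <- if (fixed) 1L else nrow(draws$params)
  set.seed(seed)
  pick <- sample.int(n_avail, n_rep, replace = n_rep > n_avail)
  rep_seed <- sample.int(.Machine$integer.max - 1, n_rep)
  m <- grid$m
  eq <- lapply(scenarios, function(s) matrix(0, n_rep, m))
  names(eq) <- vapply(scenarios, `[[`, "", "name")
  for (r in seq_len(n_rep)) {
    pp <- if (fixed) draws else draw_params(draws, pick[r])
    # process noise shared across scenarios for this replicate
    set.seed(rep_seed[r])
    lambda_R <- stats::rlnorm(horizon, pp$mu_lambda, pp$sigma_lambda)
    eps_y <- stats::rnorm(horizon, 0, pp$sigma_o)
    for (s in seq_along(scenarios)) {
      set.seed(rep_seed[r])
      traj <- simulate_forecast(pp, scenarios[[s]], grid, season, horizon,
                                lambda_R, eps_y, form)
      eq[[s]][r, ] <- colMeans(traj[(transient + 1):horizon, , drop = FALSE])
    }
  }
  summarize_forecast(eq, grid)
}

#' Summarise forecast replicates
#'
#' @param eq Named list (one element per scenario) of replicate x bin
#'   matrices of equilibrium abundance.
#' @param grid The size grid.
#' @return A `forecast_summary` (see [forecast_equilibrium()]). With a
#'   single replicate the sd is reported as 0 and flagged.
#' @export
summarize_forecast <- function(eq, grid) {
  one_rep <- any(vapply(eq, nrow, 1L) == 1)
  rows <- lapply(names(eq), function(nm) {
    x <- eq[[nm]]
    data.frame(scenario = nm, size_bin_mid = grid$midpoints,
               mean_abundance = colMeans(x),
               sd_abundance = if (nrow(x) > 1) apply(x, 2, stats::sd)
                              else rep(0, ncol(x)))
  })
  totals <- do.call(rbind, lapply(names(eq), function(nm) {
    tot <- rowSums(eq[[nm]])
    data.frame(scenario = nm, mean_total = mean(tot),
               sd_total = if (length(tot) > 1) stats::sd(tot) else 0)
  }))
  structure(list(summary = do.call(rbind, rows), totals = totals,
                 equilibrium = eq, single_replicate = one_rep),
            class = "forecast_summary")
}

#' @export
print.forecast_summary <- function(x, ...) {
  cat("Equilibrium forecast (mean total abundance by scenario):\n")
  print(x$totals, row.names = FALSE)
  invisible(x)
}
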