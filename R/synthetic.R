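#' Default trapping design for synthetic removal data
#'
#' One row per trap per biweek: a mixed fleet fished at every within-season
#' time point with 24-h soaks.
#'
#' @param t Time points fished (default the 14 biweeks, `1:14`).
#' @param n_fukui,n_shrimp,n_minnow Traps of each gear per time point.
#' @param soak_days Soak time per trap (days).
#' @return Data frame with columns `t`, `gear`, `soak_days`.
#' @export
default_design <- function(t = 1:14, n_fukui = 8, n_shrimp = 6,
                           n_minnow = 6, soak_days = 1) {
  g <- rep(GEARS, times = c(n_fukui, n_shrimp, n_minnow))
  out <- expand.grid(gear = g, t = t, stringsAsFactors = FALSE)
  out$soak_days <- soak_days
  out[, c("t", "gear", "soak_days")]
}

#' Generate a synthetic multi-year removal dataset (D1)
#'
#' Runs the full generative model forward: stochastic recruitment pulses,
#' biweekly projection, binomial/Dirichlet-multinomial removal sampling at
#' each fished time point (removed crabs are subtracted from the latent
#' state before projection), and overwinter binomial survival.
#'
#' @param params A [param_set()] truth.
#' @param design Trap design data frame ([default_design()]); recycled
#'   across years.
#' @param n_years Number of seasons.
#' @param grid,season Domain and season configuration.
#' @param form Overwinter survival formulation.
#' @return List with `d1` (class `ipm_d1`), `table` (long-format data
#'   frame) and `truth` (parameters, latent states and the full latent
#'   trajectory). Reproducible under `set.seed()`.
#' @export
generate_d1 <- function(params, design = default_design(), n_years = 4,
                        grid = make_grid(), season = season_config(),
                        form = "density_size") {
  traj <- simulate_trajectory(params, grid, season, n_years,
                              effort = design, form = form)
  occ <- list()
  for (y in seq_len(n_years)) {
    for (t in seq_len(season$t_max)) {
      rec <- traj$records[[y]][[t]]
      if (!is.null(rec)) {
        traps <- rec$traps
        traps$trap_id <- seq_len(nrow(traps))
        occ[[length(occ) + 1]] <- list(y = y, t = t, traps = traps,
                                       counts = rec$counts)
      }
    }
  }
  d1 <- structure(list(n_years = n_years, t_max = season$t_max,
                       years = seq_len(n_years), CT = traj$removals,
                       occ = occ), class = "ipm_d1")
  W <- matrix(0, max(n_years - 1, 0), grid$m)
  for (y in seq_len(max(n_years - 1, 0))) W[y, ] <- traj$N[1, y + 1, ]
  truth <- list(params = params,
                latents = list(llam = log(traj$lambda_R),
                               eps_y = traj$eps_y,
                               eps_u = NULL, W = W),
                N = traj$N, form = form)
  list(d1 = d1, table = d1_to_table(d1, grid), truth = truth)
}

#' Generate synthetic size-at-age records (D2)
#'
#' Ages are drawn uniformly over `age_range`, assigned to collection years,
#' and widths are log-normal around the seasonal growth curve with a shared
#' year effect.
#'
#' @param params A [param_set()] (growth fields used).
#' @param n Number of records.
#' @param years Collection years to assign (labels only).
#' @param age_range Range of ages (years); must stay above `d_0`.
#' @return Data frame (`crab_id`, `year`, `age_years`, `carapace_mm`) with
#'   the drawn year effects in attribute `eps_u`.
#' @export
generate_d2 <- function(params, n = 300, years = 2016:2020,
                        age_range = c(0.7, 4)) {
  stopifnot(age_range[1] > params$d_0)
  eps_u <- stats::setNames(stats::rnorm(length(years), 0, params$sigma_u),
                           years)
  year <- sample(years, n, replace = TRUE)
  age <- stats::runif(n, age_range[1], age_range[2])
  w_hat <- size_at_age(age, params)
  w <- stats::rlnorm(n, log(w_hat) + eps_u[as.character(year)],
                     params$sigma_w)
  structure(data.frame(crab_id = seq_len(n), year = year, age_years = age,
                       carapace_mm = w),
            eps_u = eps_u)
}

#' Generate a synthetic mark-recapture dataset (D3)
#'
#' Crabs are marked and released on occasions `0, ..., n_occasions - 1`,
#' the marked pool undergoes seasonal growth and natural mortality between
#' occasions, and recaptures on occasions `1, ..., n_occasions` are
#' binomial with a Fukui-trap capture probability. Recaptured crabs are
#' released and stay in the pool.
#'
#' @param params A [param_set()] truth.
#' @param grid A [make_grid()] object.
#' @param n_occasions Number of recapture occasions.
#' @param marked_per_occ Crabs marked at each marking occasion.
#' @param n_traps Fukui traps fished per recapture occasion.
#' @param soak_days Soak time (days).
#' @param start_frac Year fraction of occasion 0 (default 0.28, July).
#' @param gap_frac Year-fraction gap between occasions (default biweekly).
#' @param marked_size_mean,marked_size_sd Size distribution of marked crabs
#'   (trap-caught, hence adult-biased).
#' @return Mark-recapture data list (`marked`, `recaptured`, `n_traps`,
#'   `soak_days`, `year_frac`) as consumed by [mc_recapture_loglik()].
#' @export
generate_d3 <- function(params, grid = make_grid(), n_occasions = 8,
                        marked_per_occ = 100, n_traps = 20, soak_days = 1,
                        start_frac = 0.28, gap_frac = 14 / 365,
                        marked_size_mean = 55, marked_size_sd = 10) {
  m <- grid$m
  year_frac <- start_frac + gap_frac * (0:n_occasions)
  marked <- matrix(0, n_occasions + 1, m)
  for (t in seq_len(n_occasions)) {   # marking occasions 0..n_occasions-1
    sizes <- stats::rnorm(marked_per_occ, marked_size_mean, marked_size_sd)
    sizes <- sizes[sizes > grid$lower & sizes < grid$upper]
    marked[t, ] <- tabulate(findInterval(sizes, grid$edges), nbins = m)
  }
  kernels <- mc_kernels(year_frac, grid, params, params)
  pool <- mc_pool_trajectory(marked, kernels, grid)
  Hf <- hazard(grid$midpoints, "fukui", params)
  recaptured <- matrix(0L, n_occasions, m)
  for (t in seq_len(n_occasions)) {
    p_t <- 1 - exp(-n_traps * Hf * soak_days)
    recaptured[t, ] <- stats::rbinom(m, round(pool[t, ]), p_t)
  }
  list(marked = marked, recaptured = recaptured,
       n_traps = rep(n_traps, n_occasions),
       soak_days = rep(soak_days, n_occasions), year_frac = year_frac)
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper producing all three datasets from one truth, bundled
#' ready for fitting.
#'
#' @param params Truth parameter set.
#' @param n_years Seasons of removal data.
#' @param design Trap design for D1.
#' @param n_d2 Size-at-age sample size.
#' @param grid,season Domain and season configuration.
#' @param form Overwinter formulation.
#' @param ... Passed to [generate_d3()].
#' @return List with `data` ([ipm_data()]), `truth` (including D2 year
#'   effects) and the raw pieces.
#' @export
generate_study <- function(params = default_params(), n_years = 4,
                           design = default_design(), n_d2 = 300,
                           grid = make_grid(), season = season_config(),
                           form = "density_size", ...) {
  g1 <- generate_d1(params, design, n_years, grid, season, form)
  d2 <- generate_d2(params, n = n_d2)
  d3 <- generate_d3(params, grid, ...)
  truth <- g1$truth
  truth$latents$eps_u <- attr(d2, "eps_u")
  list(data = ipm_data(g1$d1, d2, d3, grid, season), truth = truth,
       d1 = g1$d1, d2 = d2, d3 = d3)
}

# long-format table for a D1 dataset (one row per trap per non-zero bin,
# plus a zero row registering every trap)
d1_to_table <- function(d1, grid) {
  rows <- list()
  for (oc in d1$occ) {
    for (j in seq_len(nrow(oc$traps))) {
      cnt <- oc$counts[j, ]
      keep <- which(cnt > 0)
      if (!length(keep)) keep <- 1L
      rows[[length(rows) + 1]] <- data.frame(
        year = d1$years[oc$y], t = oc$t, trap_id = oc$traps$trap_id[j],
        gear = as.character(oc$traps$gear[j]),
        soak_days = oc$traps$soak_days[j],
        size_bin_mid = grid$midpoints[keep], count = cnt[keep])
    }
  }
  do.call(rbind, rows)
}
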