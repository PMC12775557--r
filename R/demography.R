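#' One within-season projection step
#'
#' Removal counts are subtracted from the state, the projection kernel is
#' applied, and (at the recruit entry time only) the recruit pulse is added:
#' `n' = t(K) (n - c) + r`.
#'
#' @param state Per-bin abundance before removal (length `m`).
#' @param removals Per-bin removed counts, `0 <= removals <= state`.
#' @param K Projection kernel ([projection_kernel()]).
#' @param recruits Optional recruit pulse to add after projection
#'   (`NULL` when `t != t_R`).
#' @return Next per-bin abundance vector.
#' @export
step_within_season <- function(state, removals, K, recruits = NULL) {
  # removals are counts drawn from the *rounded* state, so allow the
  # half-count rounding slack
  if (any(removals < -1e-9) || any(removals > state + 0.5)) {
    stop("removals exceed abundance in at least one size bin")
  }
  nxt <- apply_kernel(K, pmax(state - removals, 0))
  if (!is.null(recruits)) nxt <- nxt + recruits
  nxt
}

#' Overwinter survival probability
#'
#' `S_o(x, N) = min(1, exp(-alpha_o * N / x^2 + eps))`: a density-by-size
#' interaction in which overwinter mortality of small crabs intensifies at
#' high total population density, with a year-specific random effect `eps`.
#' Alternative formulations (used in WAIC model comparison) drop the density
#' term, the size term, or both.
#'
#' @param x Size (mm), vectorised, `> 0`.
#' @param N_total Total pre-winter population abundance across all sizes.
#' @param p An [overwinter_params()] object (field `alpha_o`).
#' @param eps Year random effect (real).
#' @param form One of `"density_size"` (default), `"size"`, `"density"`,
#'   `"constant"`.
#' @return Survival probability in `[0, 1)` (clamped below 1 so a binomial
#'   draw is always valid).
#' @export
overwinter_survival_prob <- function(x, N_total, p, eps = 0,
                                     form = c("density_size", "size",
                                              "density", "constant")) {
  form <- match.arg(form)
  stopifnot(all(x > 0), N_total >= 0)
  loghaz <- switch(form,
    density_size = -p$alpha_o * N_total / x^2,
    size         = -p$alpha_o / x^2,
    density      = rep(-p$alpha_o * N_total, length(x)),
    constant     = rep(-p$alpha_o, length(x))
  )
  pmin(exp(loghaz + eps), 1 - 1e-12)
}

#' Overwinter transition
#'
#' End-of-season abundance (minus final removals) is projected by the
#' growth-only winter kernel, rounded to integer counts, and thinned by a
#' binomial draw with size- and density-dependent survival. Total density
#' entering the survival function is the pre-winter total
#' `sum(state_end)`.
#'
#' @param state_end Abundance at the last within-season time point.
#' @param removals_end Removals at the last time point.
#' @param G_o Overwinter growth kernel (growth only).
#' @param p [overwinter_params()].
#' @param eps_y Year random effect.
#' @param form Overwinter survival formulation (see
#'   [overwinter_survival_prob()]).
#' @param expected If `TRUE`, return the expected value `M * S_o` instead of
#'   a binomial draw (used by the moment-matched continuous approximation).
#' @return Integer per-bin abundance at the first time point of the next
#'   year (numeric when `expected = TRUE`).
#' @export
overwinter_transition <- function(state_end, removals_end, G_o, p, eps_y = 0,
                                  form = "density_size", expected = FALSE) {
  N_total <- sum(state_end)
  M <- round(apply_kernel(G_o, pmax(state_end - removals_end, 0)))
  S_o <- overwinter_survival_prob(G_o$grid$midpoints, N_total, p, eps_y, form)
  if (expected) return(M * S_o)
  stats::rbinom(length(M), M, S_o)
}

#' Initial adult size distribution
#'
#' Log-normal size distribution of the founding adult cohort, discretised
#' on the grid and scaled to total abundance `lambda_A`.
#'
#' @param p A [recruit_init_params()] object.
#' @param grid A [make_grid()] object.
#' @return Per-bin abundance vector summing to `lambda_A`.
#' @export
initial_density <- function(p, grid) {
  bin_density(function(x) stats::plnorm(x, p$mu_A, p$sigma_A), grid,
              p$lambda_A)
}

#' Recruit size distribution
#'
#' Normal size distribution of one annual recruit pulse, truncated to the
#' size domain and scaled to the pulse abundance `lambda_R`.
#'
#' @param lambda_R Recruit abundance for the year (`>= 0`).
#' @inheritParams initial_density
#' @return Per-bin abundance vector summing to `lambda_R`.
#' @export
recruit_density <- function(lambda_R, p, grid) {
  stopifnot(lambda_R >= 0)
  if (lambda_R == 0) return(numeric(grid$m))
  bin_density(function(x) stats::pnorm(x, p$mu_R, p$sigma_R), grid, lambda_R)
}

#' Simulate the latent population trajectory
#'
#' Runs the full stochastic process model forward: initial adults, biweekly
#' growth/natural-mortality projection with removals, annual recruit pulses
#' with log-normal abundance, and overwinter binomial survival with a
#' yearly random effect. Removals are generated through the observation
#' model when `effort` is non-null, or taken as zero.
#'
#' @param params A [param_set()] parameter set.
#' @param grid A [make_grid()] object.
#' @param season A [season_config()] object.
#' @param n_years Number of years to simulate.
#' @param effort Optional effort schedule: a data frame with columns
#'   `t`, `gear`, `n_traps`, `soak_days` (recycled across years), or a list
#'   of such data frames of length `n_years`.
#' @param form Overwinter survival formulation.
#' @param latents Optional list with pre-drawn `lambda_R` (length
#'   `n_years`) and `eps_y` (length `n_years - 1`); drawn from their
#'   distributions when omitted.
#' @return A list of class `crab_trajectory`:
#'   `N` (array `t_max x n_years x m` of latent abundance),
#'   `removals` (same shape, total removed counts),
#'   `records` (list over years and time points of per-trap removal draws),
#'   `lambda_R`, `eps_y`, and `M` (matrix of pre-survival winter counts).
#' @export
simulate_trajectory <- function(params, grid, season, n_years,
                                effort = NULL, form = "density_size",
                                latents = NULL) {
  tm <- season$t_max
  m <- grid$m
  kern <- build_kernels(grid, season, params, params)
  lambda_R <- if (!is.null(latents$lambda_R)) latents$lambda_R else
    stats::rlnorm(n_years, params$mu_lambda, params$sigma_lambda)
  eps_y <- if (!is.null(latents$eps_y)) latents$eps_y else
    stats::rnorm(max(n_years - 1, 0), 0, params$sigma_o)
  N <- array(0, dim = c(tm, n_years, m))
  CT <- array(0, dim = c(tm, n_years, m))
  Mw <- matrix(0, max(n_years - 1, 0), m)
  records <- vector("list", n_years)
  N[1, 1, ] <- initial_density(params, grid)
  per_year_effort <- function(y) {
    if (is.null(effort)) return(NULL)
    if (is.data.frame(effort)) effort else effort[[y]]
  }
  for (y in seq_len(n_years)) {
    eff <- per_year_effort(y)
    records[[y]] <- vector("list", tm)
    R_y <- recruit_density(lambda_R[y], params, grid)
    for (t in seq_len(tm)) {
      if (!is.null(eff)) {
        traps_t <- eff[eff$t == t, , drop = FALSE]
        if (nrow(traps_t) > 0) {
          drawn <- sample_removals(N[t, y, ], traps_t, params, grid)
          CT[t, y, ] <- drawn$totals
          records[[y]][[t]] <- drawn
        }
      }
      if (t < tm) {
        N[t + 1, y, ] <- step_within_season(
          N[t, y, ], CT[t, y, ], kern$within[[t]],
          if (t == season$t_R) R_y else NULL)
      }
    }
    if (y < n_years) {
      N_total <- sum(N[tm, y, ])
      Mw[y, ] <- round(apply_kernel(kern$winter,
                                    pmax(N[tm, y, ] - CT[tm, y, ], 0)))
      S_o <- overwinter_survival_prob(grid$midpoints, N_total, params,
                                      eps_y[y], form)
      N[1, y + 1, ] <- stats::rbinom(m, Mw[y, ], S_o)
    }
  }
  structure(list(N = N, removals = CT, records = records,
                 lambda_R = lambda_R, eps_y = eps_y, M = Mw,
                 grid = grid, season = season, form = form),
            class = "crab_trajectory")
}
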