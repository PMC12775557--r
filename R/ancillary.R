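#' Size-at-age log-likelihood
#'
#' Observed carapace widths are log-normal around the seasonal growth curve
#' [size_at_age()], with a year-specific normal random effect shifting the
#' log-location to absorb shared environmental variation:
#' `log W ~ Normal(log W(a) + eps_u, sigma_w)`. The Normal(0, sigma_u)
#' density of each year effect is included so the function returns the full
#' joint contribution of the size-at-age component.
#'
#' @param records Data frame with columns `year`, `age_years`,
#'   `carapace_mm`.
#' @param gp A [growth_params()] object.
#' @param year_effects Named numeric vector of year effects `eps_u`; names
#'   are years appearing in `records`. Missing years are taken as 0.
#' @param include_effect_prior Include the Normal(0, sigma_u) term for each
#'   year effect (default `TRUE`).
#' @return Log-likelihood (scalar; `-Inf` if any expected size is
#'   non-positive).
#' @export
size_at_age_loglik <- function(records, gp, year_effects = NULL,
                               include_effect_prior = TRUE) {
  stopifnot(all(c("year", "age_years", "carapace_mm") %in% names(records)))
  if (any(records$age_years <= gp$d_0)) return(-Inf)
  w_hat <- suppressWarnings(size_at_age(records$age_years, gp))
  if (any(w_hat <= 0)) return(-Inf)
  eps <- rep(0, nrow(records))
  if (!is.null(year_effects) && length(year_effects)) {
    eps <- unname(year_effects[match(as.character(records$year),
                                     names(year_effects))])
    eps[is.na(eps)] <- 0
  }
  ll <- sum(stats::dlnorm(records$carapace_mm,
                          meanlog = log(w_hat) + eps,
                          sdlog = gp$sigma_w, log = TRUE))
  if (include_effect_prior && !is.null(year_effects) && gp$sigma_u > 0) {
    ll <- ll + sum(stats::dnorm(year_effects, 0, gp$sigma_u, log = TRUE))
  }
  ll
}

#' Project the marked pool forward one occasion
#'
#' Newly marked crabs are added to the pool, which then undergoes seasonal
#' growth and natural mortality to the next recapture occasion.
#'
#' @param pool Per-bin marked abundance at the current occasion.
#' @param marked Per-bin newly marked-and-released counts (0 if none).
#' @param K Projection kernel for the occasion gap.
#' @return Per-bin marked abundance at the next occasion.
#' @export
mc_project <- function(pool, marked, K) {
  apply_kernel(K, pool + marked)
}

# occasion-gap projection kernels for a mark-recapture design:
# dates -> year fractions -> kernels with seasonal growth + natural survival
mc_kernels <- function(year_frac, grid, gp, mp) {
  n <- length(year_frac) - 1
  lapply(seq_len(n), function(t) {
    projection_kernel(grid, year_frac[t] %% 1, year_frac[t + 1] %% 1,
                      year_frac[t + 1] - year_frac[t], gp, mp)
  })
}

# latent marked-pool trajectory over occasions 1..t_max_mc given marking
# at occasions 0..t_max_mc-1 (row 1 of `marked` is occasion 0)
mc_pool_trajectory <- function(marked, kernels, grid) {
  n_occ <- nrow(marked) - 1
  pool <- matrix(0, n_occ, grid$m)
  cur <- numeric(grid$m)
  for (t in seq_len(n_occ)) {
    cur <- mc_project(cur, marked[t, ], kernels[[t]])
    pool[t, ] <- cur
  }
  pool
}

#' Mark-recapture log-likelihood
#'
#' Recapture counts at each occasion are binomial in the (rounded) marked
#' pool with a Fukui-trap capture probability
#' `p = 1 - exp(-O * H_F(x) * soak)`. Recaptured crabs are released and
#' remain in the pool.
#'
#' @param data A mark-recapture dataset as returned by [generate_d3()] or
#'   [read_d3()]: list with `marked` (matrix occasions+1 x m, row 1 =
#'   occasion 0), `recaptured` (occasions x m), `n_traps`, `soak_days`,
#'   `year_frac` (length occasions + 1).
#' @param gp,mp,tp Growth, mortality and trap parameter objects.
#' @param grid A [make_grid()] object.
#' @return Log-likelihood; `-Inf` if recaptures exceed the marked pool.
#' @export
mc_recapture_loglik <- function(data, gp, mp, tp, grid) {
  kernels <- mc_kernels(data$year_frac, grid, gp, mp)
  pool <- mc_pool_trajectory(data$marked, kernels, grid)
  Hf <- hazard(grid$midpoints, "fukui", tp)
  ll <- 0
  for (t in seq_len(nrow(data$recaptured))) {
    p_t <- 1 - exp(-data$n_traps[t] * Hf * data$soak_days[t])
    Np <- round(pool[t, ])
    r_t <- data$recaptured[t, ]
    if (any(r_t > Np)) return(-Inf)
    ll <- ll + sum(stats::dbinom(r_t, Np, p_t, log = TRUE))
  }
  ll
}
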