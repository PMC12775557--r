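#' @title Parameter sets
#' @description Constructors and validators for the demographic and
#'   observation parameters of the model. A full parameter set is a flat
#'   named list of class `crab_params`; the grouped constructors exist so
#'   that kernel- or likelihood-level functions can be used standalone.
#' @name parameters
NULL

#' Seasonal growth parameters
#'
#' @param x_inf Asymptotic average carapace width (mm).
#' @param k Rate of approach to the asymptote (1/year).
#' @param A Amplitude of the seasonal growth oscillation (dimensionless,
#'   `0 <= A <= 1` keeps growth monotone).
#' @param d_s Year fraction of the inflection point of the oscillation
#'   (time of fastest growth), in `[0, 1)`.
#' @param sigma_G Standard deviation of somatic growth per transition (mm).
#' @param d_0 Theoretical age at size zero (years); a curve-fitting offset,
#'   not a biological quantity.
#' @param sigma_w Log-scale sd of individual heterogeneity in size-at-age.
#' @param sigma_u Sd of the year random effect in size-at-age.
#' @return A named list of class `growth_params`.
#' @export
growth_params <- function(x_inf, k, A = 0, d_s = 0, sigma_G = 1,
                          d_0 = 0, sigma_w = 0.1, sigma_u = 0.1) {
  stopifnot(x_inf > 0, k > 0, sigma_G >= 0, d_s >= 0, d_s < 1,
            sigma_w > 0, sigma_u >= 0)
  if (abs(A) > 1) warning("|A| > 1 makes seasonal growth non-monotone")
  structure(list(x_inf = x_inf, k = k, A = A, d_s = d_s, sigma_G = sigma_G,
                 d_0 = d_0, sigma_w = sigma_w, sigma_u = sigma_u),
            class = c("growth_params", "list"))
}

#' Non-winter natural mortality parameters
#'
#' Survival over an interval `delta_t` (years) is
#' `S(x) = exp(-delta_t * (beta + (alpha/x)^2))`: a size-independent hazard
#' `beta` plus a size-dependent hazard that decays with size, so mortality
#' decreases as crabs grow.
#'
#' @param beta Size-independent mortality intensity (1/year).
#' @param alpha Size-dependent mortality scalar (mm).
#' @return A named list of class `mortality_params`.
#' @export
mortality_params <- function(beta, alpha = 0) {
  stopifnot(beta >= 0, alpha >= 0)
  structure(list(beta = beta, alpha = alpha),
            class = c("mortality_params", "list"))
}

#' Overwinter mortality parameters
#'
#' @param alpha_o Intensity of the density-by-size overwinter hazard.
#' @param sigma_o Sd of the year-specific overwinter random effect.
#' @return A named list of class `overwinter_params`.
#' @export
overwinter_params <- function(alpha_o, sigma_o = 0) {
  stopifnot(alpha_o >= 0, sigma_o >= 0)
  structure(list(alpha_o = alpha_o, sigma_o = sigma_o),
            class = c("overwinter_params", "list"))
}

#' Initial-density and recruitment parameters
#'
#' @param mu_A,sigma_A Log-mean and log-sd of adult size in the first year.
#' @param lambda_A Adult abundance in the first year.
#' @param mu_R,sigma_R Mean and sd (mm) of recruit size at entry.
#' @param mu_lambda,sigma_lambda Log-mean and log-sd of annual recruit
#'   abundance.
#' @param t_R Within-season time index at which recruits enter (default 6,
#'   mid-May).
#' @return A named list of class `recruit_init_params`.
#' @export
recruit_init_params <- function(mu_A, sigma_A, lambda_A, mu_R, sigma_R,
                                mu_lambda, sigma_lambda, t_R = 6L) {
  stopifnot(sigma_A > 0, lambda_A >= 0, mu_R > 0, sigma_R > 0,
            sigma_lambda > 0, t_R >= 1)
  structure(list(mu_A = mu_A, sigma_A = sigma_A, lambda_A = lambda_A,
                 mu_R = mu_R, sigma_R = sigma_R, mu_lambda = mu_lambda,
                 sigma_lambda = sigma_lambda, t_R = as.integer(t_R)),
            class = c("recruit_init_params", "list"))
}

#' Trap observation parameters
#'
#' Size-selective capture hazard rates (per day) for the three gear types.
#' Fukui and shrimp traps are logistic in size; minnow traps are
#' bell-shaped because large crabs cannot enter the mesh.
#'
#' @param h_max_F,h_k_F,h_0_F Fukui maximum hazard (1/day), logistic
#'   steepness (1/mm) and midpoint (mm).
#' @param h_max_S,h_k_S,h_0_S Same for shrimp traps.
#' @param h_max_M Minnow maximum hazard (1/day).
#' @param h_A_M Size of maximum minnow hazard (mm).
#' @param h_sigma_M Minnow width parameter (mm^2); the hazard is
#'   `h_max * exp(-(x - h_A)^2 / h_sigma)`.
#' @param rho Dirichlet-multinomial overdispersion (effective prior sample
#'   size; the multinomial is recovered as `rho -> Inf`).
#' @return A named list of class `trap_params`.
#' @export
trap_params <- function(h_max_F, h_k_F, h_0_F,
                        h_max_S, h_k_S, h_0_S,
                        h_max_M, h_A_M, h_sigma_M, rho) {
  stopifnot(h_max_F >= 0, h_max_S >= 0, h_max_M >= 0,
            h_k_F > 0, h_k_S > 0, h_sigma_M > 0, rho > 0)
  structure(list(h_max_F = h_max_F, h_k_F = h_k_F, h_0_F = h_0_F,
                 h_max_S = h_max_S, h_k_S = h_k_S, h_0_S = h_0_S,
                 h_max_M = h_max_M, h_A_M = h_A_M, h_sigma_M = h_sigma_M,
                 rho = rho),
            class = c("trap_params", "list"))
}

#' Assemble a full parameter set
#'
#' @param growth [growth_params()].
#' @param mortality [mortality_params()].
#' @param overwinter [overwinter_params()].
#' @param traps [trap_params()].
#' @param recruit_init [recruit_init_params()].
#' @return Flat named list of class `crab_params` containing all parameters.
#' @export
param_set <- function(growth, mortality, overwinter, traps, recruit_init) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(mortality, "mortality_params"),
            inherits(overwinter, "overwinter_params"),
            inherits(traps, "trap_params"),
            inherits(recruit_init, "recruit_init_params"))
  structure(c(unclass(growth), unclass(mortality), unclass(overwinter),
              unclass(traps), unclass(recruit_init)),
            class = c("crab_params", "list"))
}

#' Default scenario parameter set
#'
#' A full parameter set used as the default truth of the synthetic-data
#' generator and in examples. Values printed for the Drayton Harbour fit
#' (asymptotic size 80.7 mm, growth inflection at year fraction 0.25,
#' growth sd 2.8 mm, recruit entry size 5.4 mm, first-year adult abundance
#' 438, recruit pulses spanning roughly 50-1400) are used verbatim; the
#' remaining values are biologically plausible choices documented in the
#' methods vignette. These are scenario defaults, not estimates.
#'
#' @return A `crab_params` object.
#' @export
default_params <- function() {
  param_set(
    growth = growth_params(x_inf = 80.7, k = 0.8, A = 0.9, d_s = 0.25,
                           sigma_G = 2.8, d_0 = 0.1, sigma_w = 0.08,
                           sigma_u = 0.05),
    mortality = mortality_params(beta = 1.0, alpha = 8),
    overwinter = overwinter_params(alpha_o = 0.09, sigma_o = 0.4),
    traps = trap_params(h_max_F = 0.04, h_k_F = 0.40, h_0_F = 50,
                        h_max_S = 0.10, h_k_S = 0.40, h_0_S = 45,
                        h_max_M = 0.03, h_A_M = 45, h_sigma_M = 60,
                        rho = 5),
    recruit_init = recruit_init_params(mu_A = log(30), sigma_A = 0.3,
                                       lambda_A = 438, mu_R = 5.4,
                                       sigma_R = 2, mu_lambda = 5.5,
                                       sigma_lambda = 1.5, t_R = 6L)
  )
}

#' Season timing configuration
#'
#' The trapping season runs April-October and is discretised into biweekly
#' time points `t = 1, ..., t_max`. Year fractions are
#' `d_t = (t - 1) * d_tmax / (t_max - 1)`, so `d_1 = 0` (April 1) and
#' `d_{t_max} = d_tmax` (late October). Each within-season transition spans
#' `delta_t = 14/365` years; the overwinter transition spans
#' `1 - d_tmax` years back to `d = 0` of the next year.
#'
#' @param t_max Number of within-season time points (default 15, i.e. 14
#'   biweekly transitions).
#' @param t_R Recruit entry time index (default 6).
#' @param d_tmax Year fraction at the last time point (default 0.53).
#' @return A named list of class `season_config` with derived fields `d_t`
#'   (year fractions), `delta_t` (step length, years) and `delta_winter`.
#' @export
season_config <- function(t_max = 15L, t_R = 6L, d_tmax = 0.53) {
  stopifnot(t_max >= 2, t_R >= 1, t_R < t_max, d_tmax > 0, d_tmax < 1)
  d_t <- (seq_len(t_max) - 1) * d_tmax / (t_max - 1)
  structure(list(t_max = as.integer(t_max), t_R = as.integer(t_R),
                 d_tmax = d_tmax, d_t = d_t, delta_t = 14 / 365,
                 delta_winter = 1 - d_tmax),
            class = c("season_config", "list"))
}
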