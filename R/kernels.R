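#' Seasonal growth oscillation
#'
#' The sinusoidal modifier of the von Bertalanffy age-size curve:
#' `s(a) = (A * k / (2 * pi)) * sin(2 * pi * (a - d_s))`, periodic with
#' period one year. `d_s` marks the inflection point, i.e. the year
#' fraction of fastest growth.
#'
#' @param a Age or calendar time as a year fraction (years).
#' @param p A [growth_params()] object (or any list with `A`, `k`, `d_s`).
#' @return Offset on the growth exponent scale (same length as `a`).
#' @export
seasonal_s <- function(a, p) {
  (p$A * p$k / (2 * pi)) * sin(2 * pi * (a - p$d_s))
}

#' Expected size at age under seasonal von Bertalanffy growth
#'
#' `W(a) = x_inf * (1 - exp(-k * (a - d_0) - s(a) + s(d_0)))` where `s` is
#' the seasonal oscillation [seasonal_s()]. Ages below `d_0` would give
#' negative sizes; these are truncated to zero with a warning.
#'
#' @param a Age in years (vectorised).
#' @inheritParams seasonal_s
#' @return Expected carapace width (mm), in `[0, x_inf)`.
#' @export
size_at_age <- function(a, p) {
  w <- p$x_inf * (1 - exp(-p$k * (a - p$d_0) - seasonal_s(a, p) +
                            seasonal_s(p$d_0, p)))
  if (any(w < 0)) {
    warning("ages below d_0 give negative expected sizes; truncated to 0")
    w[w < 0] <- 0
  }
  w
}

#' Expected size after an incremental seasonal growth step
#'
#' Growth from size `x` at year fraction `d_t` over `delta_t` years to
#' year fraction `d_next`:
#' `mu = x + (x_inf - x) * (1 - exp(-k * delta_t - s(d_next) + s(d_t)))`.
#' Over an integer year the seasonal terms cancel and the increment reduces
#' to plain von Bertalanffy growth.
#'
#' @param x Size (mm), vectorised.
#' @param d_t,d_next Year fractions at the start and end of the step.
#' @param delta_t Elapsed time (years, `>= 0`).
#' @inheritParams seasonal_s
#' @return Expected size (mm).
#' @export
growth_mean <- function(x, d_t, d_next, delta_t, p) {
  stopifnot(delta_t >= 0)
  x + (p$x_inf - x) *
    (1 - exp(-p$k * delta_t - seasonal_s(d_next, p) + seasonal_s(d_t, p)))
}

#' Growth kernel on the size grid
#'
#' Transition matrix `G[i, j]`: probability that an individual at midpoint
#' `x_i` lies in bin `j` after the step, a normal distribution centred on
#' [growth_mean()] with sd `sigma_G`, truncated to the size domain and
#' renormalised so every row sums to exactly 1 (the paper's constant `q`).
#' Destination-bin mass uses CDF differences between bin edges. A
#' degenerate `sigma_G = 0` assigns all mass to the bin containing the
#' growth mean.
#'
#' @param grid A [make_grid()] object.
#' @inheritParams growth_mean
#' @return An object of class `ipm_kernel`: list with `grid`, `matrix`
#'   (m x m, rows = source bins) and `survival` (here all 1).
#' @export
growth_kernel <- function(grid, d_t, d_next, delta_t, p) {
  stopifnot(is_size_grid(grid))
  mu <- growth_mean(grid$midpoints, d_t, d_next, delta_t, p)
  m <- grid$m
  if (p$sigma_G <= 0) {
    G <- matrix(0, m, m)
    j <- pmin(pmax(findInterval(mu, grid$edges, rightmost.closed = TRUE),
                   1L), m)
    G[cbind(seq_len(m), j)] <- 1
  } else {
    # one pnorm call over all (source, edge) pairs
    z <- outer(mu, grid$edges, function(mu_i, e) (e - mu_i) / p$sigma_G)
    P <- pnorm(z)
    G <- P[, -1, drop = FALSE] - P[, -(m + 1), drop = FALSE]
    G <- G / rowSums(G)
  }
  structure(list(grid = grid, matrix = G, survival = rep(1, m)),
            class = "ipm_kernel")
}

#' Natural (non-winter) survival probability
#'
#' `S(x) = exp(-delta_t * (beta + (alpha / x)^2))`: the size-dependent
#' hazard decays with size so survival is non-decreasing in `x`. At
#' `x = 0` the hazard is infinite and survival is 0 by convention.
#'
#' @param x Size (mm), vectorised, `>= 0`.
#' @param delta_t Interval length (years).
#' @param p A [mortality_params()] object (fields `beta`, `alpha`).
#' @return Survival probability in `[0, 1]`.
#' @export
natural_survival <- function(x, delta_t, p) {
  stopifnot(all(x >= 0), delta_t >= 0)
  s <- ifelse(x > 0, exp(-delta_t * (p$beta + (p$alpha / x)^2)), 0)
  if (p$alpha == 0) s[x == 0] <- exp(-delta_t * p$beta)
  s
}

#' Projection kernel: growth times natural survival
#'
#' `K(x' | x) = G(x' | x) * S(x)`; row `i` of the matrix sums to
#' `S(x_i)`, so kernel rows are sub-probability vectors.
#'
#' @inheritParams growth_kernel
#' @param gp Growth parameters ([growth_params()]).
#' @param mp Mortality parameters ([mortality_params()]).
#' @return An `ipm_kernel` whose `survival` element holds `S(x_i)`.
#' @export
projection_kernel <- function(grid, d_t, d_next, delta_t, gp, mp) {
  K <- growth_kernel(grid, d_t, d_next, delta_t, gp)
  S <- natural_survival(grid$midpoints, delta_t, mp)
  K$matrix <- K$matrix * S
  K$survival <- S
  K
}

#' Apply a kernel to a per-bin abundance vector
#'
#' @param K An `ipm_kernel`.
#' @param n Numeric vector of per-bin abundance (length `grid$m`).
#' @return Projected abundance vector: `t(K$matrix) %*% n`.
#' @export
apply_kernel <- function(K, n) {
  stopifnot(inherits(K, "ipm_kernel"), length(n) == K$grid$m)
  as.numeric(crossprod(K$matrix, n))
}

# All within-season projection kernels plus the overwinter growth kernel,
# built once per parameter value. Within-season transitions use the biweekly
# delta_t with natural survival; the overwinter kernel is growth-only
# (winter mortality is the separate binomial survival stage). All growth
# normals are evaluated in a single pnorm call.
build_kernels <- function(grid, season, gp, mp) {
  tm <- season$t_max
  if (gp$sigma_G <= 0) {   # degenerate: nearest-bin assignment per kernel
    within <- lapply(seq_len(tm - 1), function(t)
      projection_kernel(grid, season$d_t[t], season$d_t[t + 1],
                        season$delta_t, gp, mp))
    return(list(within = within,
                winter = growth_kernel(grid, season$d_tmax, 1,
                                       season$delta_winter, gp)))
  }
  m <- grid$m
  s_d <- seasonal_s(season$d_t, gp)
  f <- c(1 - exp(-gp$k * season$delta_t - s_d[-1] + s_d[-tm]),
         1 - exp(-gp$k * season$delta_winter - seasonal_s(1, gp) +
                   s_d[tm]))
  n_k <- length(f)
  # MU[(t-1)*m + i] = expected size from midpoint i under kernel t
  MU <- rep(grid$midpoints, times = n_k) +
    rep(f, each = m) * (gp$x_inf - rep(grid$midpoints, times = n_k))
  P <- pnorm((rep(grid$edges, each = n_k * m) - MU) / gp$sigma_G)
  dim(P) <- c(n_k * m, m + 1)
  G <- P[, -1, drop = FALSE] - P[, -(m + 1), drop = FALSE]
  G <- G / rowSums(G)
  S <- natural_survival(grid$midpoints, season$delta_t, mp)
  within <- vector("list", tm - 1)
  for (t in seq_len(tm - 1)) {
    within[[t]] <- structure(
      list(grid = grid, matrix = G[(t - 1) * m + seq_len(m), ] * S,
           survival = S), class = "ipm_kernel")
  }
  winter <- structure(
    list(grid = grid, matrix = G[(n_k - 1) * m + seq_len(m), ],
         survival = rep(1, m)), class = "ipm_kernel")
  list(within = within, winter = winter)
}
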