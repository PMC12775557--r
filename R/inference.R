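#' Bundle the three datasets for joint inference
#'
#' Validates and preprocesses the removal time series (D1), size-at-age
#' records (D2) and mark-recapture data (D3) into the internal structures
#' used by the joint log-posterior. D2 and D3 are optional (degraded fits
#' with a warning).
#'
#' @param d1 Removal dataset of class `ipm_d1` (see [generate_d1()] /
#'   [read_d1()]).
#' @param d2 Size-at-age data frame (`crab_id`, `year`, `age_years`,
#'   `carapace_mm`), or `NULL`.
#' @param d3 Mark-recapture dataset (see [generate_d3()] / [read_d3()]),
#'   or `NULL`.
#' @param grid A [make_grid()] object.
#' @param season A [season_config()] object.
#' @return An object of class `ipm_data`.
#' @export
ipm_data <- function(d1, d2 = NULL, d3 = NULL, grid = make_grid(),
                     season = season_config()) {
  stopifnot(inherits(d1, "ipm_d1"))
  if (is.null(d2)) warning("no size-at-age data: growth parameters are ",
                           "informed by removal data alone")
  if (is.null(d3)) warning("no mark-recapture data: Fukui hazard ",
                           "parameters are informed by removal data alone")
  structure(list(d1 = d1, d1p = prepare_d1(d1, grid), d2 = d2, d3 = d3,
                 grid = grid, season = season, n_years = d1$n_years,
                 cache = new.env(parent = emptyenv())),
            class = "ipm_data")
}

# memoised pieces keyed on the parameters they actually depend on; most
# MCMC updates leave them unchanged
cache_get <- function(data, slot, key, build) {
  env <- data$cache
  if (is.null(env)) return(build())
  hit <- env[[slot]]
  if (!is.null(hit) && identical(hit$key, key)) return(hit$value)
  value <- build()
  env[[slot]] <- list(key = key, value = value)
  value
}

cached_kernels <- function(params, data) {
  key <- c(params$x_inf, params$k, params$A, params$d_s, params$sigma_G,
           params$beta, params$alpha)
  cache_get(data, "kernels", key, function()
    build_kernels(data$grid, data$season, params, params))
}

cached_init_density <- function(params, data) {
  key <- c(params$mu_A, params$sigma_A, params$lambda_A)
  cache_get(data, "init", key, function() initial_density(params, data$grid))
}

cached_recruit_shape <- function(params, data) {
  key <- c(params$mu_R, params$sigma_R)
  cache_get(data, "recruit", key, function()
    bin_density(function(x) stats::pnorm(x, params$mu_R, params$sigma_R),
                data$grid, 1))
}

cached_mc_pool <- function(params, data) {
  key <- c(params$x_inf, params$k, params$A, params$d_s, params$sigma_G,
           params$beta, params$alpha)
  cache_get(data, "mc_pool", key, function() {
    kernels <- mc_kernels(data$d3$year_frac, data$grid, params, params)
    mc_pool_trajectory(data$d3$marked, kernels, data$grid)
  })
}

# precompute per-occasion quantities for the removal likelihood
prepare_d1 <- function(d1, grid) {
  occ <- d1$occ
  n_occ <- length(occ)
  m <- grid$m
  totals <- matrix(0, n_occ, m)
  wgear <- matrix(0, n_occ, 3, dimnames = list(NULL, GEARS))
  ngear <- matrix(0, n_occ, 3, dimnames = list(NULL, GEARS))
  konst <- matrix(0, n_occ, m)   # data-only multinomial coefficient, per bin
  yy <- tt <- integer(n_occ)
  counts <- gear_idx <- vector("list", n_occ)
  for (o in seq_len(n_occ)) {
    oc <- occ[[o]]
    yy[o] <- oc$y; tt[o] <- oc$t
    gi <- match(as.character(oc$traps$gear), GEARS)
    if (anyNA(gi)) stop("unknown gear in D1 occasion ", o)
    counts[[o]] <- oc$counts
    gear_idx[[o]] <- gi
    totals[o, ] <- colSums(oc$counts)
    for (g in 1:3) {
      sel <- gi == g
      wgear[o, g] <- sum(oc$traps$soak_days[sel])
      ngear[o, g] <- sum(sel)
    }
    pos <- totals[o, ] > 0
    if (nrow(oc$traps) > 1 && any(pos)) {
      konst[o, pos] <- lgamma(totals[o, pos] + 1) -
        colSums(lgamma(oc$counts[, pos, drop = FALSE] + 1))
    }
  }
  # flat structures for the vectorised Dirichlet-multinomial term: one
  # entry per (occasion, trap, bin) with a positive multi-trap bin total
  e_cnt <- e_gb <- e_den <- integer(0)
  c_tot <- c_den <- numeric(0)
  for (o in seq_len(n_occ)) {
    gi <- gear_idx[[o]]
    if (length(gi) < 2) next
    pos <- which(totals[o, ] > 0)
    if (!length(pos)) next
    n_tr <- length(gi)
    e_cnt <- c(e_cnt, as.integer(counts[[o]][, pos]))
    e_gb <- c(e_gb, as.integer(outer(gi, (pos - 1) * 3, "+")))
    e_den <- c(e_den, rep(o + (pos - 1) * n_occ, each = n_tr))
    c_tot <- c(c_tot, totals[o, pos])
    c_den <- c(c_den, o + (pos - 1) * n_occ)
  }
  nidx <- matrix(0L, n_occ, m)   # flat index of each cell into the N array
  for (o in seq_len(n_occ)) {
    nidx[o, ] <- tt[o] + (yy[o] - 1L) * d1$t_max +
      (seq_len(m) - 1L) * d1$t_max * d1$n_years
  }
  list(n_occ = n_occ, y = yy, t = tt, totals = totals, wgear = wgear,
       ngear = ngear, konst = konst, counts = counts, gear_idx = gear_idx,
       e_cnt = e_cnt, e_gb = e_gb, e_den = e_den, c_tot = c_tot,
       c_den = c_den, konst_sum = sum(konst), nidx = nidx)
}

# removal log-likelihood over all occasions given the latent trajectory.
# Returns a scalar, or (pointwise = TRUE) an n_occ x m matrix of per-cell
# contributions (binomial total + Dirichlet-multinomial split per bin).
d1_loglik <- function(params, N, d1p, grid, pointwise = FALSE) {
  m <- grid$m
  H3 <- rbind(hazard(grid$midpoints, "fukui", params),
              hazard(grid$midpoints, "shrimp", params),
              hazard(grid$midpoints, "minnow", params))
  if (!pointwise) {   # vectorised path used inside MCMC
    NR <- round(N[d1p$nidx])
    if (any(d1p$totals > NR)) return(-Inf)
    PCAP <- 1 - exp(-d1p$wgear %*% H3)
    ll <- sum(stats::dbinom(d1p$totals, NR, PCAP, log = TRUE))
    if (!is.finite(ll)) return(-Inf)
    if (length(d1p$e_cnt)) {
      DEN <- d1p$ngear %*% H3
      a <- params$rho * H3[d1p$e_gb] / DEN[d1p$e_den]
      dm <- sum(lgamma(d1p$e_cnt + a) - lgamma(a)) +
        sum(lgamma(params$rho) - lgamma(d1p$c_tot + params$rho)) +
        d1p$konst_sum
      if (!is.finite(dm)) return(-Inf)
      ll <- ll + dm
    }
    return(ll)
  }
  cells <- matrix(NA_real_, d1p$n_occ, m)
  for (o in seq_len(d1p$n_occ)) {
    Nr <- round(N[d1p$t[o], d1p$y[o], ])
    tot <- d1p$totals[o, ]
    if (any(tot > Nr)) return(if (pointwise) NULL else -Inf)
    pcap <- 1 - exp(-as.numeric(d1p$wgear[o, ] %*% H3))
    cell <- stats::dbinom(tot, Nr, pcap, log = TRUE)
    gi <- d1p$gear_idx[[o]]
    if (length(gi) > 1) {
      pos <- which(tot > 0)
      if (length(pos)) {
        denom <- as.numeric(d1p$ngear[o, ] %*% H3)[pos]
        PC <- H3[gi, pos, drop = FALSE] / rep(denom, each = length(gi))
        bad <- denom <= 0
        if (any(bad)) PC[, bad] <- 1 / length(gi)
        a <- params$rho * PC
        C <- d1p$counts[[o]][, pos, drop = FALSE]
        dm <- lgamma(params$rho) - lgamma(tot[pos] + params$rho) +
          colSums(lgamma(C + a) - lgamma(a)) + d1p$konst[o, pos]
        cell[pos] <- cell[pos] + dm
      }
    }
    if (pointwise) cells[o, ] <- cell else ll <- ll + sum(cell)
  }
  if (pointwise) cells else ll
}

# deterministic latent trajectory given parameters and latent variables;
# returns N (t_max x Y x m), M (winter pools) and S_o (winter survival),
# or NULL when the observed removals are infeasible under the state
# mode "binomial": year y+1 starts at the sampled integer vector W[y, ]
# (the exact model). mode "expected": moment-matched continuous
# approximation, year y+1 starts at M * S_o(eps_y) and W is ignored.
# mode "resample": W is drawn sequentially from its binomial prior given
# the parameters (used for joint parameter/latent Metropolis proposals,
# where the prior cancels against the proposal density).
# mode "shift": like "normal", but V is translated by the change in its
# conditional mean relative to `old_mean` (a deterministic, unit-Jacobian
# coupling used for joint parameter/latent proposals).
latent_trajectory <- function(params, lambda_R, W, data, form,
                              mode = "binomial", eps_y = NULL,
                              old_mean = NULL) {
  grid <- data$grid; season <- data$season
  tm <- season$t_max; Y <- data$n_years; m <- grid$m
  kern <- cached_kernels(params, data)
  r_shape <- cached_recruit_shape(params, data)
  CT <- data$d1$CT
  N <- array(0, dim = c(tm, Y, m))
  M <- matrix(0, max(Y - 1, 0), m)
  mean_w <- matrix(0, max(Y - 1, 0), m)
  N[1, 1, ] <- cached_init_density(params, data)
  for (y in seq_len(Y)) {
    R_y <- r_shape * lambda_R[y]
    for (t in seq_len(tm - 1)) {
      st <- N[t, y, ] - CT[t, y, ]
      if (any(round(st) < 0)) return(NULL)
      N[t + 1, y, ] <- as.numeric(crossprod(kern$within[[t]]$matrix,
                                            pmax(st, 0)))
      if (t == season$t_R) N[t + 1, y, ] <- N[t + 1, y, ] + R_y
    }
    if (y < Y) {
      st <- N[tm, y, ] - CT[tm, y, ]
      if (any(round(st) < 0)) return(NULL)
      M[y, ] <- round(as.numeric(crossprod(kern$winter$matrix, pmax(st, 0))))
      if (mode == "binomial") {
        if (any(W[y, ] > M[y, ])) return(NULL)
        N[1, y + 1, ] <- W[y, ]
      } else if (mode == "normal" || mode == "shift") {
        S <- overwinter_survival_prob(grid$midpoints, sum(N[tm, y, ]),
                                      params, eps_y[y], form)
        mean_w[y, ] <- M[y, ] * S
        if (mode == "shift") {
          W[y, ] <- W[y, ] + mean_w[y, ] - old_mean[y, ]
        }
        # continuous moment-matched latent: V may wander slightly negative
        # under its random walk; the state is clamped at 0
        N[1, y + 1, ] <- pmax(W[y, ], 0)
      } else if (mode == "resample") {
        S <- overwinter_survival_prob(grid$midpoints, sum(N[tm, y, ]),
                                      params, eps_y[y], form)
        W[y, ] <- stats::rbinom(m, M[y, ], S)
        N[1, y + 1, ] <- W[y, ]
      } else {
        S <- overwinter_survival_prob(grid$midpoints, sum(N[tm, y, ]),
                                      params, eps_y[y], form)
        mean_w[y, ] <- M[y, ] * S
        N[1, y + 1, ] <- mean_w[y, ]
      }
    }
  }
  S_o <- matrix(0, max(Y - 1, 0), m)
  for (y in seq_len(max(Y - 1, 0))) {
    S_o[y, ] <- overwinter_survival_prob(grid$midpoints, sum(N[tm, y, ]),
                                         params, 0, form)
  }
  list(N = N, M = M, S_o = S_o, W = W, mean_w = mean_w)
}

# log-posterior components. `latents`: list(llam (log recruit abundance),
# eps_y, eps_u (named), W (integer matrix (Y-1) x m)).
# returns lp split into `core` (latent hyper-priors + removal likelihood;
# the part that enters joint parameter/W-resample Metropolis ratios) and
# `wprior` (the binomial density of the overwinter survivor vectors, which
# cancels against the resampling proposal). `lp` is their sum.
lp_part_p1 <- function(params, latents, data, form, ow_latent = "binomial",
                       resample_w = FALSE, shift_from = NULL) {
  mode <- if (resample_w && ow_latent == "binomial") "resample"
    else if (resample_w && ow_latent == "normal" && !is.null(shift_from))
      "shift"
    else ow_latent
  tr <- latent_trajectory(params, exp(latents$llam), latents$W, data, form,
                          mode = mode, eps_y = latents$eps_y,
                          old_mean = shift_from)
  if (is.null(tr)) {
    return(list(lp = -Inf, core = -Inf, wprior = -Inf, cache = NULL))
  }
  Y <- data$n_years
  core <- sum(stats::dnorm(latents$llam, params$mu_lambda,
                           params$sigma_lambda, log = TRUE))
  wprior <- 0
  if (Y > 1) {
    core <- core + sum(stats::dnorm(latents$eps_y, 0, params$sigma_o,
                                    log = TRUE))
    if (ow_latent == "binomial") {
      for (y in seq_len(Y - 1)) {
        S <- pmin(tr$S_o[y, ] * exp(latents$eps_y[y]), 1 - 1e-12)
        wprior <- wprior + sum(stats::dbinom(tr$W[y, ], tr$M[y, ], S,
                                             log = TRUE))
      }
    } else if (ow_latent == "normal") {
      # moment-matched normal density of the continuous winter latents;
      # smooth in the parameters, so it belongs to the core part
      for (y in seq_len(Y - 1)) {
        mu_w <- tr$mean_w[y, ]
        S <- ifelse(tr$M[y, ] > 0, mu_w / tr$M[y, ], 0)
        sd_w <- sqrt(pmax(mu_w * (1 - S), 0.25))
        core <- core + sum(stats::dnorm(tr$W[y, ], mu_w, sd_w, log = TRUE))
      }
    }
  }
  if (!is.finite(core) || !is.finite(wprior)) {
    return(list(lp = -Inf, core = -Inf, wprior = wprior, cache = tr))
  }
  core <- core + d1_loglik(params, tr$N, data$d1p, data$grid)
  list(lp = core + wprior, core = core, wprior = wprior, cache = tr,
       W = tr$W)
}

lp_part_p2 <- function(params, latents, data) {
  if (is.null(data$d2)) return(0)
  size_at_age_loglik(data$d2, params, latents$eps_u)
}

lp_part_p3 <- function(params, data) {
  if (is.null(data$d3)) return(0)
  pool <- cached_mc_pool(params, data)
  d3 <- data$d3
  Hf <- hazard(data$grid$midpoints, "fukui", params)
  ll <- 0
  for (t in seq_len(nrow(d3$recaptured))) {
    p_t <- 1 - exp(-d3$n_traps[t] * Hf * d3$soak_days[t])
    Np <- round(pool[t, ])
    if (any(d3$recaptured[t, ] > Np)) return(-Inf)
    ll <- ll + sum(stats::dbinom(d3$recaptured[t, ], Np, p_t, log = TRUE))
  }
  ll
}

lp_part_p0 <- function(params, priors) {
  lp <- 0
  for (nm in names(priors)) {
    lp <- lp + priors[[nm]](params[[nm]])
    if (!is.finite(lp)) return(-Inf)
  }
  lp
}

#' Joint log-posterior
#'
#' Sum of the removal-data likelihood and process-latent densities, the
#' size-at-age likelihood, the mark-recapture likelihood, and the log-priors.
#' Returns `-Inf` on any constraint violation (e.g. observed removals
#' exceeding latent abundance).
#'
#' @param params A full [param_set()] parameter list.
#' @param latents List with `llam` (log annual recruit abundance, length
#'   `n_years`), `eps_y` (overwinter year effects, length `n_years - 1`),
#'   `eps_u` (named size-at-age year effects) and `W` (integer matrix
#'   `(n_years - 1) x m` of overwinter survivors).
#' @param data An [ipm_data()] bundle.
#' @param form Overwinter survival formulation.
#' @param priors Prior list as from [default_priors()].
#' @return Scalar log-posterior with attribute `parts` (named components).
#' @export
joint_logpost <- function(params, latents, data, form = "density_size",
                          priors = default_priors(form),
                          ow_latent = c("binomial", "normal", "expected")) {
  ow_latent <- match.arg(ow_latent)
  p0 <- lp_part_p0(params, priors)
  if (!is.finite(p0)) {
    return(structure(-Inf, parts = c(p0 = -Inf, p1 = NA, p2 = NA, p3 = NA)))
  }
  p1 <- lp_part_p1(params, latents, data, form, ow_latent)$lp
  p2 <- lp_part_p2(params, latents, data)
  p3 <- lp_part_p3(params, data)
  total <- p0 + p1 + p2 + p3
  if (is.nan(total)) total <- -Inf
  structure(total, parts = c(p0 = p0, p1 = p1, p2 = p2, p3 = p3))
}

# feasible latent initialisation: expected-value trajectory, with recruit
# pulses and winter survivors inflated until the observed removals fit
init_latents <- function(params, data, form, inflate_max = 25) {
  Y <- data$n_years; m <- data$grid$m
  eps_u <- if (!is.null(data$d2)) {
    u <- sort(unique(data$d2$year))
    stats::setNames(rep(0, length(u)), u)
  } else stats::setNames(numeric(0), character(0))
  llam <- rep(params$mu_lambda, Y)
  bump <- 0
  repeat {
    # year-by-year forward pass: project each season, check that observed
    # removals fit, and set each winter's survivors to their expectation
    W <- matrix(0L, max(Y - 1, 0), m)
    kern <- build_kernels(data$grid, data$season, params, params)
    r_shape <- bin_density(function(x)
      stats::pnorm(x, params$mu_R, params$sigma_R), data$grid, 1)
    tm <- data$season$t_max
    CT <- data$d1$CT
    state <- initial_density(params, data$grid)
    ok <- TRUE
    for (y in seq_len(Y)) {
      Nt <- state
      for (t in seq_len(tm - 1)) {
        st <- Nt - CT[t, y, ]
        if (any(round(st) < 0)) { ok <- FALSE; break }
        Nt <- as.numeric(crossprod(kern$within[[t]]$matrix, pmax(st, 0)))
        if (t == data$season$t_R) Nt <- Nt + r_shape * exp(llam[y])
      }
      if (!ok) break
      st <- Nt - CT[tm, y, ]
      if (any(round(st) < 0)) { ok <- FALSE; break }
      if (y < Y) {
        M <- round(as.numeric(crossprod(kern$winter$matrix, pmax(st, 0))))
        S_o <- overwinter_survival_prob(data$grid$midpoints, sum(Nt),
                                        params, 0, form)
        W[y, ] <- round(M * S_o)
        state <- W[y, ]
      }
    }
    if (ok) ok <- !is.null(latent_trajectory(params, exp(llam), W, data,
                                             form))
    if (ok) break
    bump <- bump + 1
    if (bump > inflate_max) {
      stop("could not find a feasible latent initialisation; removal ",
           "counts are inconsistent with the initial parameter values")
    }
    llam <- llam + 0.35
    params$lambda_A <- params$lambda_A * 1.35
  }
  list(llam = llam, eps_y = rep(0, max(Y - 1, 0)), eps_u = eps_u, W = W,
       lambda_A_adj = params$lambda_A)
}
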