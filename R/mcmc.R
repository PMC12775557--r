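#' MCMC configuration
#'
#' @param n_iter Iterations per chain (post-adaptation draws are thinned
#'   from the iterations after `burn`).
#' @param burn Burn-in iterations discarded (adaptation also stops there).
#' @param thin Thinning interval.
#' @param n_chains Number of chains (run sequentially with per-chain seeds).
#' @param free Character vector of parameter names to sample; all others are
#'   held at their initial values.
#' @param form Overwinter survival formulation.
#' @param priors Prior list ([default_priors()]).
#' @param init Initial full parameter list (default [default_params()]).
#' @param init_latents Optional initial latents (e.g. the generating truth);
#'   derived from `init` when omitted.
#' @param jitter Sd of the initial jitter applied to free parameters on the
#'   unconstrained scale (per chain).
#' @param target_accept Target acceptance rate of the adaptive blocks.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iter = 5000, burn = 2000, thin = 5, n_chains = 4,
                        free = PARAM_NAMES, form = "density_size",
                        priors = default_priors(form),
                        init = default_params(), init_latents = NULL,
                        jitter = 0.05, target_accept = 0.25,
                        ow_latent = c("binomial", "normal", "expected")) {
  ow_latent <- match.arg(ow_latent)
  stopifnot(n_iter > burn, all(free %in% PARAM_NAMES))
  structure(list(n_iter = n_iter, burn = burn, thin = thin,
                 n_chains = n_chains, free = free, form = form,
                 priors = priors, init = init, init_latents = init_latents,
                 jitter = jitter, target_accept = target_accept,
                 ow_latent = ow_latent),
            class = "mcmc_config")
}

#' Fit the integrated model by adaptive MCMC
#'
#' Blockwise adaptive random-walk Metropolis on unconstrained parameter
#' scales, with dedicated updates for the latent variables: log recruit
#' abundances and year effects by random-walk blocks, and the integer
#' overwinter survivor vectors by a binomial independence proposal (which is
#' exact Metropolis-Hastings because the proposal equals the conditional
#' prior). Proposal scales adapt toward the target acceptance rate during
#' burn-in only. Runs with identical seeds are bit-reproducible.
#'
#' @param data An [ipm_data()] bundle.
#' @param config An [mcmc_config()].
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param verbose Print progress.
#' @return Object of class `crab_draws`: list with `params` (draws x 29
#'   matrix), `lambda_R`, `eps_y`, `eps_u` (draw matrices), `W` (array
#'   draws x winters x m), `lp`, `chain`, and `config` metadata.
#' @export
run_mcmc <- function(data, config = mcmc_config(), seed = 1,
                     verbose = FALSE) {
  stopifnot(inherits(data, "ipm_data"))
  chains <- lapply(seq_len(config$n_chains), function(ch) {
    set.seed(seed + ch - 1)
    run_chain(data, config, ch, verbose)
  })
  out <- list(
    params = do.call(rbind, lapply(chains, `[[`, "params")),
    lambda_R = do.call(rbind, lapply(chains, `[[`, "lambda_R")),
    eps_y = do.call(rbind, lapply(chains, `[[`, "eps_y")),
    eps_u = do.call(rbind, lapply(chains, `[[`, "eps_u")),
    W = abind_first(lapply(chains, `[[`, "W")),
    lp = unlist(lapply(chains, `[[`, "lp")),
    chain = rep(seq_len(config$n_chains),
                vapply(chains, function(x) nrow(x$params), 1L)),
    accept = lapply(chains, `[[`, "accept"),
    config = config, seed = seed
  )
  class(out) <- "crab_draws"
  out
}

abind_first <- function(lst) {
  if (is.null(dim(lst[[1]])) || length(dim(lst[[1]])) < 3) {
    return(do.call(rbind, lst))
  }
  d <- dim(lst[[1]])
  out <- array(0, dim = c(sum(vapply(lst, function(x) dim(x)[1], 1L)),
                          d[2], d[3]))
  at <- 0
  for (x in lst) {
    out[at + seq_len(dim(x)[1]), , ] <- x
    at <- at + dim(x)[1]
  }
  out
}

run_chain <- function(data, config, chain_id, verbose = FALSE) {
  free <- config$free
  form <- config$form
  owl <- config$ow_latent %||% "binomial"
  priors <- config$priors
  params <- config$init
  Y <- data$n_years
  m <- data$grid$m

  lat <- config$init_latents
  if (is.null(lat)) {
    lat <- init_latents(params, data, form)
    params$lambda_A <- lat$lambda_A_adj
  }
  lat <- lat[c("llam", "eps_y", "eps_u", "W")]
  lat$W <- matrix(as.numeric(lat$W), nrow = max(Y - 1, 0), ncol = m)

  kind <- PARAM_TRANSFORM[free]
  z0 <- vapply(free, function(nm) to_unconstrained(params[[nm]], kind[nm]),
               0)
  lat0 <- lat

  blocks <- Filter(function(b) length(b$pars) > 0, lapply(PARAM_BLOCKS,
    function(b) list(pars = intersect(b$pars, free), parts = b$parts)))

  # current log-posterior components and trajectory cache
  eval_p0 <- function(pp, zz) {
    lp_part_p0(pp, priors) + sum(vapply(seq_along(free), function(i)
      log_jacobian(zz[i], kind[i]), 0))
  }

  # overdisperse the start by jittering the free parameters, shrinking the
  # jitter until the state is feasible (the hard support constraints of
  # the removal model make large jitters land outside the posterior)
  jit <- config$jitter
  init0 <- params
  repeat {
    z <- z0 + stats::rnorm(length(z0), 0, jit)
    params <- init0
    for (i in seq_along(free)) {
      params[[free[i]]] <- from_unconstrained(z[i], kind[i])
    }
    lat <- lat0
    if (owl == "normal") {
      # condition the continuous winter latents on these parameters:
      # starting V at a stale mean puts the chain in a deep valley of the
      # moment-matched prior
      tr_e <- latent_trajectory(params, exp(lat$llam), lat$W, data, form,
                                mode = "expected", eps_y = lat$eps_y)
      if (!is.null(tr_e)) lat$W <- tr_e$mean_w
    }
    p1 <- lp_part_p1(params, lat, data, form, owl)
    if (!is.finite(p1$lp) && owl == "binomial") {
      # redraw the survivor vectors from their prior under these parameters
      p1 <- lp_part_p1(params, lat, data, form, owl, resample_w = TRUE)
      if (!is.null(p1$W)) lat$W <- p1$W
    }
    if (is.finite(p1$lp) || jit == 0) break
    jit <- if (jit < 1e-4) 0 else jit / 2
  }
  if (!is.finite(p1$lp)) {
    # last resort: re-derive all latents from scratch
    li <- init_latents(params, data, form)
    params$lambda_A <- li$lambda_A_adj
    if ("lambda_A" %in% free) {
      z[match("lambda_A", free)] <- log(params$lambda_A)
    }
    lat <- li[c("llam", "eps_y", "eps_u", "W")]
    lat$W <- matrix(as.numeric(lat$W), nrow = max(Y - 1, 0), ncol = m)
    p1 <- lp_part_p1(params, lat, data, form, owl)
  }
  cur <- list(p0 = eval_p0(params, z), p1c = p1$core, p1w = p1$wprior,
              p2 = lp_part_p2(params, lat, data),
              p3 = lp_part_p3(params, data))
  cache <- p1$cache
  if (!is.finite(p1$lp)) {
    stop("initial state has zero posterior density; supply feasible ",
         "`init`/`init_latents`")
  }

  # per-block adaptive-Metropolis state: scalar step size (Robbins-Monro
  # toward the target acceptance) and running mean/covariance of the block
  # (Haario-style full-covariance proposals once enough history exists)
  scales <- lapply(blocks, function(b) {
    d <- length(b$pars)
    list(s = 0.1, mu = rep(0, d), C = diag(d), L = diag(d), n = 0)
  })
  lat_scales <- list(llam = 0.1, eps_y = 0.1, eps_u = 0.05)
  v_scale <- 2   # abundance-scale step of the continuous winter latents
  acc <- stats::setNames(numeric(length(blocks) + 4),
                         c(names(blocks), "llam", "eps_y", "eps_u", "W"))
  try_n <- acc

  keep <- floor((config$n_iter - config$burn) / config$thin)
  out_par <- matrix(NA_real_, keep, length(PARAM_NAMES),
                    dimnames = list(NULL, PARAM_NAMES))
  out_lam <- matrix(NA_real_, keep, Y)
  out_epsy <- matrix(NA_real_, keep, max(Y - 1, 0))
  out_epsu <- matrix(NA_real_, keep, length(lat$eps_u))
  colnames(out_epsu) <- names(lat$eps_u)
  out_W <- array(NA_real_, dim = c(keep, max(Y - 1, 0), m))
  out_lp <- numeric(keep)
  kd <- 0

  total <- function(x) x$p0 + x$p1c + x$p1w + x$p2 + x$p3
  # Metropolis ratio for joint (parameter, W-resample) moves: the binomial
  # prior of W cancels against the resampling proposal, so `p1w` is excluded
  core_total <- function(x) x$p0 + x$p1c + x$p2 + x$p3

  for (it in seq_len(config$n_iter)) {
    adapting <- it <= config$burn
    gamma <- min(0.5, 3 / sqrt(it))

    # --- parameter blocks ---
    for (bi in seq_along(blocks)) {
      b <- blocks[[bi]]
      idx <- match(b$pars, free)
      zp <- z
      zp[idx] <- z[idx] + scales[[bi]]$s *
        as.numeric(scales[[bi]]$L %*% stats::rnorm(length(idx)))
      pp <- params
      for (i in idx) pp[[free[i]]] <- from_unconstrained(zp[i], kind[i])
      new <- cur
      new$p0 <- eval_p0(pp, zp)
      cache_new <- cache
      W_new <- NULL
      okp <- is.finite(new$p0)
      if (okp && "p1" %in% b$parts) {
        r <- lp_part_p1(pp, lat, data, form, owl, resample_w = TRUE,
                        shift_from = cache$mean_w)
        new$p1c <- r$core; new$p1w <- r$wprior
        cache_new <- r$cache; W_new <- r$W
      }
      if (okp && "p2" %in% b$parts) new$p2 <- lp_part_p2(pp, lat, data)
      if (okp && "p3" %in% b$parts) new$p3 <- lp_part_p3(pp, data)
      lr <- core_total(new) - core_total(cur)
      a <- is.finite(core_total(new)) && is.finite(new$p1w) &&
        (lr >= 0 || log(stats::runif(1)) < lr)
      try_n[bi] <- try_n[bi] + 1
      if (a) {
        z <- zp; params <- pp; cur <- new; cache <- cache_new
        if (!is.null(W_new)) lat$W <- W_new
        acc[bi] <- acc[bi] + 1
      }
      if (adapting) {
        sc <- scales[[bi]]
        sc$s <- exp(log(sc$s) + gamma * ((a * 1) - config$target_accept))
        # running mean / covariance of the block state
        sc$n <- sc$n + 1
        dlt <- z[idx] - sc$mu
        sc$mu <- sc$mu + dlt / sc$n
        sc$C <- sc$C + (tcrossprod(dlt, z[idx] - sc$mu) - sc$C) / sc$n
        if (sc$n > 50 && it %% 25 == 0) {
          ch <- tryCatch(chol(sc$C + diag(1e-8, length(idx))),
                         error = function(e) NULL)
          if (!is.null(ch)) sc$L <- t(ch)
        }
        scales[[bi]] <- sc
      }
    }

    # --- latent blocks (random walk) ---
    for (lv in c("llam", "eps_y", "eps_u")) {
      v <- lat[[lv]]
      if (!length(v)) next
      lp_name <- if (lv == "eps_u") "p2" else "p1"
      vp <- v + stats::rnorm(length(v), 0, lat_scales[[lv]])
      latp <- lat; latp[[lv]] <- vp
      new <- cur
      cache_new <- cache
      if (lp_name == "p1") {
        # joint move: resample or mean-shift W under the proposed latents
        r <- lp_part_p1(params, latp, data, form, owl, resample_w = TRUE,
                        shift_from = cache$mean_w)
        new$p1c <- r$core; new$p1w <- r$wprior; cache_new <- r$cache
        if (!is.null(r$W)) latp$W <- r$W
        lr <- core_total(new) - core_total(cur)
        a <- is.finite(core_total(new)) && is.finite(new$p1w) &&
          (lr >= 0 || log(stats::runif(1)) < lr)
      } else {
        new$p2 <- lp_part_p2(params, latp, data)
        lr <- total(new) - total(cur)
        a <- is.finite(total(new)) && (lr >= 0 || log(stats::runif(1)) < lr)
      }
      try_n[lv] <- try_n[lv] + 1
      if (a) { lat <- latp; cur <- new; cache <- cache_new
               acc[lv] <- acc[lv] + 1 }
      if (adapting) {
        lat_scales[[lv]] <- exp(log(lat_scales[[lv]]) +
                                  gamma * ((a * 1) - config$target_accept))
      }
    }

    # --- continuous winter latents: random-walk refinement ---
    if (Y > 1 && owl == "normal") {
      for (y in seq_len(Y - 1)) {
        j <- sample.int(m, min(8L, m))
        Wp <- lat$W
        Wp[y, j] <- Wp[y, j] + stats::rnorm(length(j), 0, v_scale)
        latp <- lat; latp$W <- Wp
        r <- lp_part_p1(params, latp, data, form, owl)
        lr <- r$lp - (cur$p1c + cur$p1w)
        a <- is.finite(r$lp) && (lr >= 0 || log(stats::runif(1)) < lr)
        try_n["W"] <- try_n["W"] + 1
        if (a) { lat <- latp; cur$p1c <- r$core; cur$p1w <- r$wprior
                 cache <- r$cache; acc["W"] <- acc["W"] + 1 }
        if (adapting) {
          v_scale <- exp(log(v_scale) +
                           gamma * ((a * 1) - config$target_accept))
        }
      }
    }

    # --- overwinter survivor vectors: binomial independence proposal ---
    if (Y > 1 && owl == "binomial") {
      for (y in seq_len(Y - 1)) {
        S <- pmin(cache$S_o[y, ] * exp(lat$eps_y[y]), 1 - 1e-12)
        My <- cache$M[y, ]
        sel <- which(My > 0)
        if (!length(sel)) next
        j <- if (length(sel) > 4) sample(sel, 4) else sel
        Wp <- lat$W
        Wp[y, j] <- stats::rbinom(length(j), My[j], S[j])
        latp <- lat; latp$W <- Wp
        r <- lp_part_p1(params, latp, data, form, owl)
        # proposal density equals the conditional prior for winter y (whose
        # M and S do not depend on W[y, ]), so those terms cancel
        qfwd <- sum(stats::dbinom(Wp[y, j], My[j], S[j], log = TRUE))
        qrev <- sum(stats::dbinom(lat$W[y, j], My[j], S[j], log = TRUE))
        lr <- (r$lp - (cur$p1c + cur$p1w)) - (qfwd - qrev)
        a <- is.finite(r$lp) && (lr >= 0 || log(stats::runif(1)) < lr)
        try_n["W"] <- try_n["W"] + 1
        if (a) { lat <- latp; cur$p1c <- r$core; cur$p1w <- r$wprior
                 cache <- r$cache; acc["W"] <- acc["W"] + 1 }
      }
    }

    # --- store ---
    if (it > config$burn && (it - config$burn) %% config$thin == 0) {
      kd <- kd + 1
      out_par[kd, ] <- vapply(PARAM_NAMES, function(nm) params[[nm]], 0)
      out_lam[kd, ] <- exp(lat$llam)
      if (Y > 1) out_epsy[kd, ] <- lat$eps_y
      if (length(lat$eps_u)) out_epsu[kd, ] <- lat$eps_u
      if (Y > 1) {
        out_W[kd, , ] <- if (owl == "binomial") lat$W else
          t(vapply(seq_len(Y - 1), function(y) cache$N[1, y + 1, ],
                   numeric(m)))
      }
      out_lp[kd] <- total(cur)
    }
    if (verbose && it %% 500 == 0) {
      message(sprintf("chain %d iter %d lp %.1f", chain_id, it, total(cur)))
    }
  }
  list(params = out_par[seq_len(kd), , drop = FALSE],
       lambda_R = out_lam[seq_len(kd), , drop = FALSE],
       eps_y = out_epsy[seq_len(kd), , drop = FALSE],
       eps_u = out_epsu[seq_len(kd), , drop = FALSE],
       W = out_W[seq_len(kd), , , drop = FALSE],
       lp = out_lp[seq_len(kd)],
       accept = ifelse(try_n > 0, acc / pmax(try_n, 1), NA))
}

#' Potential scale reduction factor (split-chain R-hat)
#'
#' @param x Matrix of draws (iterations x chains) or a vector (split in
#'   half).
#' @return Scalar R-hat.
#' @export
rhat <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  half <- floor(n / 2)
  xs <- cbind(x[seq_len(half), , drop = FALSE],
              x[half + seq_len(half), , drop = FALSE])
  mns <- colMeans(xs)
  vrs <- apply(xs, 2, stats::var)
  W <- mean(vrs)
  B <- half * stats::var(mns)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Effective sample size (initial positive sequence estimator)
#'
#' @param x Numeric vector of draws from one chain.
#' @return Estimated effective sample size.
#' @export
ess <- function(x) {
  n <- length(x)
  if (stats::var(x) == 0) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq_along(ac)) {
    if (ac[k] < 0.05) break
    s <- s + ac[k]
  }
  n / (1 + 2 * s)
}

#' R-hat table for all sampled parameters
#'
#' @param draws A `crab_draws` object.
#' @param pars Parameter names (default: the free parameters of the fit).
#' @return Named numeric vector of split R-hat values.
#' @export
rhat_table <- function(draws, pars = draws$config$free) {
  vapply(pars, function(nm) {
    per_chain <- split(draws$params[, nm], draws$chain)
    n <- min(lengths(per_chain))
    rhat(vapply(per_chain, function(v) v[seq_len(n)], numeric(n)))
  }, 0)
}

#' Posterior summary of a fit
#'
#' @param object A `crab_draws` object.
#' @param probs Quantiles to report.
#' @param ... Unused.
#' @return Data frame with mean, median and credible-interval bounds for
#'   each free parameter.
#' @export
summary.crab_draws <- function(object,
                               probs = c(0.025, 0.5, 0.975), ...) {
  pars <- object$config$free
  qs <- t(apply(object$params[, pars, drop = FALSE], 2,
                stats::quantile, probs = probs))
  data.frame(parameter = pars, mean = colMeans(
    object$params[, pars, drop = FALSE]), qs, row.names = NULL,
    check.names = FALSE)
}
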