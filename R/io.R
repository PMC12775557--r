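snap_to_grid <- function(size, grid) {
  idx <- findInterval(size, grid$edges, rightmost.closed = TRUE)
  off <- size <= grid$lower | size > grid$upper |
    abs(size - grid$midpoints[pmax(pmin(idx, grid$m), 1)]) > grid$delta / 2
  # sizes on a bin edge are at exactly delta/2 from two midpoints: snap down
  if (any(off)) {
    stop("sizes outside the size domain or off the grid: ",
         paste(utils::head(size[off], 5), collapse = ", "))
  }
  pmax(pmin(idx, grid$m), 1)
}

require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required columns: ", paste(miss, collapse = ", "))
  }
}

#' Read a removal time-series dataset (D1)
#'
#' Long format, one row per trap and size bin with a positive count (plus
#' optionally zero-count rows that register a trap): columns `year`, `t`,
#' `trap_id`, `gear` (fukui/shrimp/minnow), `soak_days`, `size_bin_mid`,
#' `count`. Sizes are snapped to grid midpoints within `delta/2`; anything
#' else is an error.
#'
#' @param path CSV file.
#' @param grid,season Domain and season configuration.
#' @return An `ipm_d1` object.
#' @export
read_d1 <- function(path, grid = make_grid(), season = season_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("year", "t", "trap_id", "gear", "soak_days",
                        "size_bin_mid", "count"), "D1")
  bad <- !(df$gear %in% GEARS)
  if (any(bad)) stop("unknown gear in D1 rows: ",
                     paste(which(bad)[1:min(5, sum(bad))], collapse = ", "))
  if (any(df$count < 0) || any(df$count != round(df$count))) {
    stop("D1 counts must be non-negative integers (rows ",
         paste(utils::head(which(df$count < 0 |
                                   df$count != round(df$count)), 5),
               collapse = ", "), ")")
  }
  if (any(df$soak_days <= 0)) stop("D1 soak_days must be positive")
  if (any(df$t < 1 | df$t > season$t_max)) {
    stop("D1 time index outside 1..t_max")
  }
  df$bin <- snap_to_grid(df$size_bin_mid, grid)
  years <- sort(unique(df$year))
  n_years <- length(years)
  CT <- array(0, dim = c(season$t_max, n_years, grid$m))
  occ <- list()
  for (y in seq_len(n_years)) {
    dy <- df[df$year == years[y], , drop = FALSE]
    for (t in sort(unique(dy$t))) {
      dt <- dy[dy$t == t, , drop = FALSE]
      ids <- sort(unique(dt$trap_id))
      counts <- matrix(0L, length(ids), grid$m)
      gear <- soak <- rep(NA, length(ids))
      for (j in seq_along(ids)) {
        dj <- dt[dt$trap_id == ids[j], , drop = FALSE]
        gear[j] <- dj$gear[1]
        soak[j] <- dj$soak_days[1]
        agg <- rowsum(dj$count, dj$bin)
        counts[j, as.integer(rownames(agg))] <- as.integer(agg[, 1])
      }
      traps <- data.frame(trap_id = ids, gear = gear, soak_days = soak)
      occ[[length(occ) + 1]] <- list(y = y, t = t, traps = traps,
                                     counts = counts)
      CT[t, y, ] <- CT[t, y, ] + colSums(counts)
    }
  }
  structure(list(n_years = n_years, t_max = season$t_max, years = years,
                 CT = CT, occ = occ), class = "ipm_d1")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a removal dataset to CSV
#'
#' @param d1 An `ipm_d1` object.
#' @param path Output CSV path.
#' @param grid The size grid.
#' @return `path`, invisibly.
#' @export
write_d1 <- function(d1, path, grid = make_grid()) {
  utils::write.csv(d1_to_table(d1, grid), path, row.names = FALSE)
  invisible(path)
}

#' Read size-at-age records (D2)
#'
#' Columns: `crab_id`, `year`, `age_years`, `carapace_mm`.
#'
#' @param path CSV file.
#' @return Validated data frame.
#' @export
read_d2 <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("crab_id", "year", "age_years", "carapace_mm"),
                  "D2")
  if (any(df$carapace_mm <= 0)) stop("D2 carapace widths must be positive")
  if (any(df$age_years <= 0)) stop("D2 ages must be positive")
  df
}

#' Write size-at-age records
#' @param d2 Data frame as from [generate_d2()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_d2 <- function(d2, path) {
  utils::write.csv(d2[, c("crab_id", "year", "age_years", "carapace_mm")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a mark-recapture dataset (D3)
#'
#' Long format: `occasion` (0-based), `year_frac` (or `date`, ISO), `
#' size_bin_mid`, `marked`, `recaptured`, `n_traps`, `soak_days`.
#'
#' @param path CSV file.
#' @param grid The size grid.
#' @return Mark-recapture list as consumed by [mc_recapture_loglik()].
#' @export
read_d3 <- function(path, grid = make_grid()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_columns(df, c("occasion", "size_bin_mid", "marked", "recaptured",
                        "n_traps", "soak_days"), "D3")
  if (!"year_frac" %in% names(df)) {
    if (!"date" %in% names(df)) stop("D3 needs `year_frac` or `date`")
    d <- as.Date(df$date)
    df$year_frac <- (as.numeric(format(d, "%j")) - 91) / 365 +
      (as.numeric(format(d, "%Y")) - min(as.numeric(format(d, "%Y"))))
  }
  if (any(df$marked < 0) || any(df$recaptured < 0)) {
    stop("D3 counts must be non-negative")
  }
  occs <- sort(unique(df$occasion))
  n_occ <- max(occs)
  df$bin <- snap_to_grid(df$size_bin_mid, grid)
  marked <- matrix(0, n_occ + 1, grid$m)
  recaptured <- matrix(0L, n_occ, grid$m)
  year_frac <- numeric(n_occ + 1)
  n_traps <- soak <- numeric(n_occ)
  for (o in occs) {
    d_o <- df[df$occasion == o, , drop = FALSE]
    year_frac[o + 1] <- d_o$year_frac[1]
    marked[o + 1, d_o$bin] <- marked[o + 1, d_o$bin] + d_o$marked
    if (o >= 1) {
      recaptured[o, d_o$bin] <- recaptured[o, d_o$bin] +
        as.integer(d_o$recaptured)
      n_traps[o] <- d_o$n_traps[1]
      soak[o] <- d_o$soak_days[1]
    }
  }
  list(marked = marked, recaptured = recaptured, n_traps = n_traps,
       soak_days = soak, year_frac = year_frac)
}

#' Write a mark-recapture dataset
#' @param d3 Mark-recapture list.
#' @param path Output CSV path.
#' @param grid The size grid.
#' @return `path`, invisibly.
#' @export
write_d3 <- function(d3, path, grid = make_grid()) {
  n_occ <- nrow(d3$recaptured)
  rows <- lapply(0:n_occ, function(o) {
    data.frame(occasion = o, year_frac = d3$year_frac[o + 1],
               size_bin_mid = grid$midpoints,
               marked = d3$marked[o + 1, ],
               recaptured = if (o >= 1) d3$recaptured[o, ] else 0L,
               n_traps = if (o >= 1) d3$n_traps[o] else 0,
               soak_days = if (o >= 1) d3$soak_days[o] else 0)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Write posterior draws to a long CSV plus a JSON manifest
#'
#' @param draws A `crab_draws` object.
#' @param path Output CSV path; the manifest is written next to it as
#'   `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_draws <- function(draws, path) {
  n <- nrow(draws$params)
  per_chain <- ave(seq_len(n), draws$chain, FUN = seq_along)
  blocks <- list(draws$params,
                 name_cols(draws$lambda_R, "lambda_R"),
                 name_cols(draws$eps_y, "eps_y"),
                 if (ncol(draws$eps_u))
                   name_cols(draws$eps_u, "eps_u") else NULL)
  wide <- do.call(cbind, Filter(Negate(is.null), blocks))
  long <- data.frame(
    chain = rep(draws$chain, ncol(wide)),
    draw = rep(per_chain, ncol(wide)),
    parameter = rep(colnames(wide), each = n),
    value = as.numeric(wide))
  utils::write.csv(long, path, row.names = FALSE)
  manifest <- list(seed = draws$seed,
                   n_chains = draws$config$n_chains,
                   n_iter = draws$config$n_iter, burn = draws$config$burn,
                   thin = draws$config$thin, free = draws$config$free,
                   form = draws$config$form,
                   rhat = as.list(round(rhat_table(draws), 4)),
                   package_version = as.character(
                     utils::packageVersion("crabipm")))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

name_cols <- function(m, base) {
  if (is.null(m) || !ncol(m)) return(NULL)
  colnames(m) <- paste0(base, "[", colnames(m) %||% seq_len(ncol(m)), "]")
  m
}

#' Run the simulate-fit-check-forecast pipeline
#'
#' A small end-to-end driver: generates a synthetic study (or reads CSVs),
#' fits the model, runs the posterior predictive deviance check, forecasts
#' a no-removal and a heavy-removal scenario, and writes all artifacts plus
#' a JSON manifest to `out_dir`. Intended for demos and smoke tests; scale
#' up via `config`.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Root seed; per-stage seeds are derived from it.
#' @param config Optional overrides: `n_years`, `design`, `n_d2`,
#'   `mcmc` ([mcmc_config()]), `n_rep`, `horizon`, `d1`, `d2`, `d3` (paths
#'   to CSVs instead of simulation).
#' @return Invisible list of artifact paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  grid <- make_grid()
  season <- season_config()
  params <- config$params %||% default_params()
  set.seed(seed)
  if (!is.null(config$d1)) {
    data <- ipm_data(read_d1(config$d1, grid, season),
                     if (!is.null(config$d2)) read_d2(config$d2),
                     if (!is.null(config$d3)) read_d3(config$d3, grid),
                     grid, season)
    truth <- NULL
  } else {
    study <- generate_study(params, n_years = config$n_years %||% 3,
                            design = config$design %||%
                              default_design(n_fukui = 4, n_shrimp = 3,
                                             n_minnow = 3),
                            n_d2 = config$n_d2 %||% 150, grid = grid,
                            season = season)
    data <- study$data
    truth <- study$truth
    write_d1(study$d1, file.path(out_dir, "d1.csv"), grid)
    write_d2(study$d2, file.path(out_dir, "d2.csv"))
    write_d3(study$d3, file.path(out_dir, "d3.csv"), grid)
  }
  mcfg <- config$mcmc %||% mcmc_config(
    n_iter = 600, burn = 300, thin = 3, n_chains = 2,
    free = c("x_inf", "k", "d_s", "sigma_G", "beta", "h_max_F", "h_0_F"),
    init = params, init_latents = truth$latents, ow_latent = "normal")
  fit <- run_mcmc(data, mcfg, seed = seed + 1)
  write_draws(fit, file.path(out_dir, "draws.csv"))
  ppc <- posterior_predictive_check(fit, data, "deviance", n_draws = 50)
  fc <- forecast_equilibrium(fit, list(
    effort_scenario("none", 0), effort_scenario("shrimp", 2800)),
    n_rep = config$n_rep %||% 20, horizon = config$horizon %||% 10,
    transient = 3, grid = grid, season = season, seed = seed + 2)
  utils::write.csv(fc$summary, file.path(out_dir, "forecast.csv"),
                   row.names = FALSE)
  manifest <- list(seed = seed, ppc_deviance_p = ppc$p_value,
                   rhat = as.list(round(rhat_table(fit), 4)),
                   forecast_totals = fc$totals)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(dir = out_dir,
                 files = list.files(out_dir, full.names = TRUE)))
}
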