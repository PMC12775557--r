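GEARS <- c("fukui", "shrimp", "minnow")

#' Size-selective capture hazard rate
#'
#' Instantaneous capture intensity (1/day) of one trap as a function of crab
#' size. Fukui and shrimp traps follow a logistic curve
#' `h_max / (1 + exp(-h_k (x - h_0)))`; minnow traps follow a bell curve
#' `h_max * exp(-(x - h_A)^2 / h_sigma)` because large crabs cannot enter
#' the mesh.
#'
#' @param x Size (mm), vectorised.
#' @param gear One of `"fukui"`, `"shrimp"`, `"minnow"`.
#' @param p A [trap_params()] object.
#' @return Hazard rate (1/day), `>= 0`.
#' @export
hazard <- function(x, gear, p) {
  switch(match.arg(gear, GEARS),
    fukui  = p$h_max_F / (1 + exp(-p$h_k_F * (x - p$h_0_F))),
    shrimp = p$h_max_S / (1 + exp(-p$h_k_S * (x - p$h_0_S))),
    minnow = p$h_max_M * exp(-(x - p$h_A_M)^2 / p$h_sigma_M)
  )
}

# hazard matrix [n_traps x length(x)] for a trap table (gear, soak_days,
# n_traps optional multiplier)
hazard_matrix <- function(x, traps, p) {
  H <- vapply(as.character(traps$gear), function(g) hazard(x, g, p),
              numeric(length(x)))
  # vapply drops to a vector when length(x) == 1; keep traps in rows
  t(matrix(H, nrow = length(x)))
}

# summed integrated hazard sum_j n_j * H_j(x) * soak_j over a trap table
total_hazard <- function(x, traps, p) {
  H <- hazard_matrix(x, traps, p)
  w <- traps$soak_days * trap_count(traps)
  as.numeric(crossprod(H, w))
}

trap_count <- function(traps) {
  if ("n_traps" %in% names(traps)) traps$n_traps else rep(1, nrow(traps))
}

#' Capture probability over a set of traps
#'
#' Hazards are additive across simultaneously fished traps, so the
#' probability of being captured by at least one trap during the interval is
#' `p(x) = 1 - exp(-sum_j H_j(x) * soak_j)`.
#'
#' @param x Size (mm), vectorised.
#' @param traps Data frame with columns `gear` and `soak_days` (days), and
#'   optionally `n_traps` (identical-trap multiplier, default 1).
#' @param p A [trap_params()] object.
#' @return Capture probability in `[0, 1)`.
#' @export
capture_probability <- function(x, traps, p) {
  if (is.null(traps) || nrow(traps) == 0) return(rep(0, length(x)))
  stopifnot(all(traps$soak_days > 0))
  1 - exp(-total_hazard(x, traps, p))
}

#' Conditional probability of capture in each trap
#'
#' Given that a crab of size `x` is captured, the probability it is caught
#' in trap `j` is the hazard share `H_j(x) / sum_j H_j(x)` (soak times do
#' not enter the share). If every hazard vanishes at `x`, no crab of that
#' size can be caught: a uniform vector is returned with a warning.
#'
#' @param x A single size (mm).
#' @inheritParams capture_probability
#' @return Probability vector over the rows of `traps`, summing to 1.
#' @export
conditional_trap_probs <- function(x, traps, p) {
  stopifnot(length(x) == 1, nrow(traps) >= 1)
  h <- hazard_matrix(x, traps, p)[, 1]
  tot <- sum(h)
  if (tot <= 0) {
    warning("all trap hazards are zero at x = ", x,
            "; returning uniform conditional probabilities")
    return(rep(1 / nrow(traps), nrow(traps)))
  }
  h / tot
}

# conditional probability matrix [n_traps x m] over grid midpoints;
# zero-hazard sizes get a uniform column (their binomial totals are 0
# anyway, so the DM term never sees them)
conditional_prob_matrix <- function(grid, traps, p) {
  H <- hazard_matrix(grid$midpoints, traps, p)
  tot <- colSums(H)
  bad <- tot <= 0
  tot[bad] <- 1
  PC <- sweep(H, 2, tot, "/")
  PC[, bad] <- 1 / nrow(traps)
  PC
}

#' Dirichlet-multinomial log-density
#'
#' Log-pmf of counts `x` given total `sum(x)` and concentration vector
#' `alpha` (here `rho * p^C`). As `sum(alpha) -> Inf` this converges to the
#' multinomial log-pmf with probabilities `alpha / sum(alpha)`.
#'
#' @param x Integer count vector.
#' @param alpha Positive concentration vector, same length.
#' @return Log-density (scalar).
#' @export
ddirmnom_log <- function(x, alpha) {
  stopifnot(length(x) == length(alpha), all(alpha > 0), all(x >= 0),
            all(x == round(x)))
  n <- sum(x)
  # rising factorials as explicit log sums: exact for integer counts and
  # numerically stable for very large concentrations, where the usual
  # lgamma differences lose absolute precision
  rising <- function(a, k) {
    if (k == 0) return(0)
    sum(log(a + seq_len(k) - 1))
  }
  lgamma(n + 1) - sum(lgamma(x + 1)) - rising(sum(alpha), n) +
    sum(vapply(seq_along(x), function(j) rising(alpha[j], x[j]), 0))
}

#' Dirichlet-multinomial random draw
#'
#' @param n Total count to distribute.
#' @param alpha Positive concentration vector.
#' @return Integer count vector summing to `n`.
#' @export
rdirmnom <- function(n, alpha) {
  if (n == 0) return(integer(length(alpha)))
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  as.integer(stats::rmultinom(1, n, g / sum(g)))
}

#' Removal log-likelihood for one time point
#'
#' The total removed count in each size bin is binomial in the (rounded)
#' latent abundance with the multi-trap capture probability; conditional on
#' the total, the split across traps is Dirichlet-multinomial with
#' concentration `rho * p^C`.
#'
#' @param counts Matrix `n_traps x m` of per-trap removed counts.
#' @param traps Trap table for the time point (`gear`, `soak_days`).
#' @param latent Per-bin latent abundance (length `m`).
#' @param p A [trap_params()] object.
#' @param grid A [make_grid()] object.
#' @return Log-likelihood; `-Inf` when a total exceeds the latent abundance.
#' @export
removal_loglik <- function(counts, traps, latent, p, grid) {
  stopifnot(ncol(counts) == grid$m, nrow(counts) == nrow(traps))
  totals <- colSums(counts)
  Nr <- round(latent)
  if (any(totals > Nr)) return(-Inf)
  pcap <- capture_probability(grid$midpoints, traps, p)
  ll <- sum(stats::dbinom(totals, Nr, pcap, log = TRUE))
  if (nrow(counts) > 1) {
    PC <- conditional_prob_matrix(grid, traps, p)
    for (i in which(totals > 0)) {
      ll <- ll + ddirmnom_log(counts[, i], p$rho * PC[, i])
    }
  }
  ll
}

#' Sample removal counts from the observation model
#'
#' Generative counterpart of [removal_loglik()]: binomial totals per size
#' bin, then a Dirichlet-multinomial split across traps.
#'
#' @inheritParams removal_loglik
#' @param latent Per-bin latent abundance.
#' @return List with `totals` (length `m`) and `counts`
#'   (`n_traps x m` matrix), plus the `traps` table.
#' @export
sample_removals <- function(latent, traps, p, grid) {
  m <- grid$m
  Nr <- round(pmax(latent, 0))
  pcap <- capture_probability(grid$midpoints, traps, p)
  totals <- stats::rbinom(m, Nr, pcap)
  counts <- matrix(0L, nrow(traps), m)
  if (nrow(traps) > 1 && any(totals > 0)) {
    PC <- conditional_prob_matrix(grid, traps, p)
    for (i in which(totals > 0)) {
      counts[, i] <- rdirmnom(totals[i], p$rho * PC[, i])
    }
  } else if (nrow(traps) == 1) {
    counts[1, ] <- totals
  }
  list(totals = totals, counts = counts, traps = traps)
}
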