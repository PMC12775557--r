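# Prior and transform machinery. Priors are weakly informative defaults,
# fully exposed through `default_priors()` so a user can substitute their
# own specification; each prior is a closure returning a log-density.

prior_normal <- function(mu, sd) {
  force(mu); force(sd)
  function(x) stats::dnorm(x, mu, sd, log = TRUE)
}
prior_halfnormal <- function(sd) {
  force(sd)
  function(x) ifelse(x < 0, -Inf, stats::dnorm(x, 0, sd, log = TRUE) + log(2))
}
prior_lognormal <- function(mulog, sdlog) {
  force(mulog); force(sdlog)
  function(x) stats::dlnorm(x, mulog, sdlog, log = TRUE)
}
prior_uniform <- function(a, b) {
  force(a); force(b)
  function(x) ifelse(x < a | x > b, -Inf, -log(b - a))
}

#' Default prior specification
#'
#' Weakly informative priors for every model parameter: half-normals on
#' standard deviations, normals on logistic midpoints (within the size
#' domain), log-normals on rates and abundances. The scale of the
#' overwinter intensity prior depends on the functional form because the
#' parameter multiplies quantities of very different magnitude across
#' forms.
#'
#' @param form Overwinter survival formulation (see
#'   [overwinter_survival_prob()]).
#' @return Named list of log-density closures, one per parameter.
#' @export
default_priors <- function(form = "density_size") {
  alpha_o_sd <- switch(form, density_size = 0.5, size = 200,
                       density = 0.01, constant = 2)
  list(
    x_inf = prior_normal(80, 20),
    k = prior_lognormal(log(0.8), 0.5),
    A = prior_uniform(0, 1),
    d_s = prior_uniform(0, 1),
    sigma_G = prior_halfnormal(5),
    d_0 = prior_normal(0, 0.5),
    sigma_w = prior_halfnormal(0.5),
    sigma_u = prior_halfnormal(0.5),
    beta = prior_halfnormal(2),
    alpha = prior_halfnormal(20),
    alpha_o = prior_halfnormal(alpha_o_sd),
    sigma_o = prior_halfnormal(1),
    h_max_F = prior_lognormal(log(0.05), 1),
    h_k_F = prior_lognormal(log(0.3), 0.7),
    h_0_F = prior_normal(50, 30),
    h_max_S = prior_lognormal(log(0.05), 1),
    h_k_S = prior_lognormal(log(0.3), 0.7),
    h_0_S = prior_normal(50, 30),
    h_max_M = prior_lognormal(log(0.05), 1),
    h_A_M = prior_normal(50, 30),
    h_sigma_M = prior_lognormal(log(100), 1),
    rho = prior_lognormal(log(5), 1),
    mu_A = prior_normal(3.5, 1),
    sigma_A = prior_halfnormal(1),
    lambda_A = prior_lognormal(log(300), 1.5),
    mu_R = prior_lognormal(log(5), 0.7),
    sigma_R = prior_halfnormal(3),
    mu_lambda = prior_normal(5, 3),
    sigma_lambda = prior_halfnormal(2)
  )
}

# unconstraining transforms used by the sampler
PARAM_TRANSFORM <- c(
  x_inf = "log", k = "log", A = "logit01", d_s = "logit01", sigma_G = "log",
  d_0 = "identity", sigma_w = "log", sigma_u = "log", beta = "log",
  alpha = "log", alpha_o = "log", sigma_o = "log",
  h_max_F = "log", h_k_F = "log", h_0_F = "identity",
  h_max_S = "log", h_k_S = "log", h_0_S = "identity",
  h_max_M = "log", h_A_M = "identity", h_sigma_M = "log", rho = "log",
  mu_A = "identity", sigma_A = "log", lambda_A = "log", mu_R = "log",
  sigma_R = "log", mu_lambda = "identity", sigma_lambda = "log"
)

to_unconstrained <- function(x, kind) {
  switch(kind, log = log(x), logit01 = stats::qlogis(pmin(pmax(x, 1e-12),
                                                          1 - 1e-12)),
         identity = x)
}
from_unconstrained <- function(z, kind) {
  switch(kind, log = exp(z), logit01 = stats::plogis(z), identity = z)
}
# log |dx/dz| for the change of variables
log_jacobian <- function(z, kind) {
  switch(kind, log = z, logit01 = stats::plogis(z, log.p = TRUE) +
           stats::plogis(-z, log.p = TRUE), identity = 0)
}

PARAM_NAMES <- names(PARAM_TRANSFORM)

# parameter blocks used by the sampler, with the log-posterior components
# each block can change (p1 = process + removal data, p2 = size-at-age,
# p3 = mark-recapture)
PARAM_BLOCKS <- list(
  growth  = list(pars = c("x_inf", "k", "A", "d_s", "sigma_G", "d_0",
                          "sigma_w", "sigma_u"),
                 parts = c("p1", "p2", "p3")),
  mort    = list(pars = c("beta", "alpha"), parts = c("p1", "p3")),
  ow      = list(pars = c("alpha_o", "sigma_o"), parts = "p1"),
  trap_f  = list(pars = c("h_max_F", "h_k_F", "h_0_F"),
                 parts = c("p1", "p3")),
  trap_s  = list(pars = c("h_max_S", "h_k_S", "h_0_S"), parts = "p1"),
  trap_m  = list(pars = c("h_max_M", "h_A_M", "h_sigma_M"), parts = "p1"),
  dm      = list(pars = "rho", parts = "p1"),
  init    = list(pars = c("mu_A", "sigma_A", "lambda_A"), parts = "p1"),
  recruit = list(pars = c("mu_R", "sigma_R"), parts = "p1"),
  hyper   = list(pars = c("mu_lambda", "sigma_lambda"), parts = "p1")
)
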