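# shared fixtures, built in code (no data files)

default_grid <- function() make_grid(0, 110, 5)

# a small, fast trapping design: fewer traps than the full study design
small_design <- function(t = 1:14) {
  default_design(t = t, n_fukui = 3, n_shrimp = 2, n_minnow = 2)
}

# small synthetic study used across test files; memoised per seed
.study_cache <- new.env(parent = emptyenv())
small_study <- function(seed = 101, n_years = 3, n_d2 = 150) {
  key <- paste(seed, n_years, n_d2)
  if (is.null(.study_cache[[key]])) {
    set.seed(seed)
    .study_cache[[key]] <- generate_study(
      default_params(), n_years = n_years, design = small_design(),
      n_d2 = n_d2, n_occasions = 6, marked_per_occ = 80, n_traps = 15)
  }
  .study_cache[[key]]
}

# deterministic growth parameters used in closed-form tests
gp_test <- function(...) {
  args <- list(x_inf = 80, k = 1, A = 0, d_s = 0.25, sigma_G = 2.8,
               d_0 = 0, sigma_w = 0.1, sigma_u = 0.05)
  args[names(list(...))] <- list(...)
  do.call(growth_params, args)
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected) / pmax(abs(expected), 1e-12)), tol)
}
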