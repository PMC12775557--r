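---
title: "Methods: a state-space integral projection model for size-structured removal programs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a state-space integral projection model for size-structured removal programs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crabipm)
```

## The problem

Removal (trapping) programs for invasive European green crab (*Carcinus
maenas*) produce size-binned catch records whose raw catch-per-unit-effort is
a biased index of abundance: traps are strongly size-selective, natural
mortality is size-dependent, growth is seasonal, and overwinter mortality is
density-dependent. `crabipm` implements an integrated state-space integral
projection model (IPM) that separates these processes by combining three data
streams in one joint likelihood:

* **D1** — a multi-year time series of removal counts by biweek, trap and
  5-mm carapace-width bin;
* **D2** — size-at-age records from cohorts of known age;
* **D3** — a size-binned mark-recapture experiment with a single gear type.

The package simulates such data from known parameters, fits the model by
MCMC, checks it (WAIC over overwinter-mortality formulations, posterior
predictive p-values), and forecasts the stable size distribution under
removal-effort scenarios.

## The model

### State and kernel

The latent state is the abundance density $N_{t,y}(x)$ over carapace width
$x \in \Omega = (0, 110]$ mm, discretised into $m = 22$ bins of width
$\Delta x = 5$ mm (midpoint rule; `make_grid()`). Bin vectors store per-bin
abundance, so totals are plain sums. Within a trapping season
(April–October, time points $t = 1, \dots, 15$ at biweekly spacing,
year fractions $d_t = (t-1)\,0.53/14$),

$$N_{t+1,y}(x') = \int_\Omega K_t(x' \mid x)\,
  \bigl(N_{t,y}(x) - C^T_{t,y}(x)\bigr)\,dx + R_y(x)\,I(t = t_R),$$

where $C^T$ are the observed removals, $R_y$ the annual recruit pulse
entering at $t_R = 6$ (mid-May), and the kernel factorises as
$K_t(x'\mid x) = G_t(x'\mid x)\,S(x)$.

### Seasonal growth

Growth follows a seasonally oscillating von Bertalanffy model. With
$s(a) = \tfrac{Ak}{2\pi}\sin 2\pi(a - d_s)$,
the expected size at age is
$\tilde W(a) = x_\infty\{1 - \exp(-k(a - d_0) - s(a) + s(d_0))\}$ and the
incremental form used in the kernel is
$\mu^G = x + (x_\infty - x)\{1 - \exp(-k\Delta t - s(d_{t+1}) + s(d_t))\}$.
$G_t$ is a normal density with sd $\sigma_G$ around $\mu^G$, truncated to
$\Omega$ and renormalised so each kernel row sums to one. Destination-bin
mass is computed from normal CDF differences between bin edges (exact for
the discretisation, identical to pdf × $\Delta x$ as $\Delta x \to 0$);
kernels are evaluated at bin midpoints. Over an integer year the seasonal
terms cancel, and sub-steps compose exactly — both properties are tested.

### Mortality

Non-winter natural survival over $\Delta t$ years is
$S(x) = \exp\{-\Delta t(\beta + (\alpha/x)^2)\}$: a size-independent hazard
plus a hazard decaying with size, so survival increases with size. The
size term is read as $(\alpha/x)^2$ — the only reading on which mortality
*decreases* with size while $\alpha$ carries length units.

Between seasons the population first grows through a growth-only winter
kernel ($d = 0.53 \to 1$), is rounded to integer counts $\tilde M_y(x_i)$,
and then survives the winter with probability

$$S^o_y(x, N) = \min\bigl\{1 - 10^{-12},\
  \exp(-\alpha_o N_{t_{max},y}/x^2 + \epsilon_y)\bigr\},
  \qquad \epsilon_y \sim \mathrm{Normal}(0, \sigma_o),$$

a density-by-size interaction: small crabs die at much higher rates in
high-density winters. Survivors are binomial,
$\tilde N_{1,y+1}(x_i) \sim \mathrm{Binomial}(\tilde M_y(x_i), S^o_y)$.
$N_{t_{max},y}$ is the pre-winter total abundance. The survival is clamped
just below 1 because the random effect's support includes positive values.
Alternative formulations (size-only, density-only, constant), compared by
WAIC, are available through the `form` argument.

### Initial state and recruitment

The founding adult cohort is log-normal in size,
$N_{1,1}(x) = \phi_L(x \mid \mu_A, \sigma_A)\,\lambda_A$; annual recruit
pulses are normal in size ($\mu_R, \sigma_R$, truncated to $\Omega$) with
log-normal abundance $\lambda^R_y \sim \mathrm{LogNormal}(\mu_\lambda,
\sigma_\lambda)$. Initial and recruit densities are binned by CDF
differences and renormalised over $\Omega$ so totals are exact — recruits
sit almost entirely in the first two bins ($\mu_R \approx 5$ mm), where
midpoint-rule binning would be visibly wrong.

### Observation models

Each trap fishes with a size-selective hazard rate (per day): logistic in
size for fukui and shrimp traps, $h_{max}/(1 + e^{-h_k(x - h_0)})$, and
bell-shaped for minnow traps, $h_{max}\exp\{-(x - h_A)^2/h_\sigma\}$ (large
crabs cannot enter the mesh; the bell form follows the stated shape of the
selectivity). Hazards add across traps, so the capture probability over a
set of soaks is $p(x) = 1 - \exp\{-\sum_j H_j(x)\,\Delta b_j\}$.

Removal totals per bin are binomial in the rounded latent abundance;
conditional on the total, the split across traps is Dirichlet-multinomial
with concentration $\rho\,p^C(x)$, where $p^C_j = H_j / \sum_j H_j$ (soak
times do not enter the share) and $\rho$ acts as an effective prior sample
size: the multinomial is recovered as $\rho \to \infty$, small $\rho$ gives
the over-dispersed, aggregated catches seen in real trap data. Swapping in
a different concentration convention is a one-line change at the two
`ddirmnom_log()` call sites.

Size-at-age widths are log-normal around $\tilde W(a)$ with log-sd
$\sigma_w$ and a year-level random effect $\epsilon_u \sim
\mathrm{Normal}(0, \sigma_u)$ added to the log-location (the insertion
point is a design choice: it preserves positivity and matches the log-scale
error semantics). The mark-recapture pool is projected between occasions by
the same growth × survival kernels; recaptures are binomial with
fukui-trap capture probability, and recaptured crabs stay in the pool.

## Inference

The joint posterior combines the three likelihoods, the latent process
densities ($\lambda^R_y$, $\epsilon_y$, $\epsilon_u$, overwinter survivor
vectors) and weakly-informative priors (half-normals on standard
deviations, normals on logistic midpoints within $\Omega$, log-normals on
rates and abundances; `default_priors()` is fully user-replaceable, and the
overwinter-intensity prior scale is form-specific because the parameter
multiplies quantities of very different magnitude across formulations).

`run_mcmc()` is a blockwise adaptive random-walk Metropolis sampler on
unconstrained scales (log, logit), with Haario-style full-covariance
adaptation per block during burn-in and Robbins–Monro step-size tuning.

**Handling the discrete winter latents.** The exact model's integer
survivor vectors make the conditional posterior of the continuous
parameters pathologically stiff: a small parameter move changes the rounded
winter pool $\tilde M$ and violates $W \le \tilde M$ somewhere, so naive
fixed-latent Metropolis stalls. Three treatments are provided
(`ow_latent` in `mcmc_config()`):

* `"binomial"` (default, exact): parameter proposals are *joint* with a
  sequential redraw of $W$ from its binomial prior; the prior cancels
  against the proposal density in the Metropolis ratio. Exact but
  slow-mixing — the redraw injects likelihood noise — suited to long runs.
* `"normal"` (desk-scale default in the tests): a moment-matched continuous
  latent $V_y \sim \mathrm{Normal}(\tilde M S^o,\ \tilde M S^o(1 - S^o))$
  (variance floored at 0.25) replaces the binomial. Parameter proposals
  translate $V$ by the change in its conditional mean — a triangular,
  unit-Jacobian coupling that lets parameters and latents move together —
  and $V$ is refined by its own random-walk updates.
* `"expected"`: the winter transition is deterministic at its expectation
  (process noise only through $\epsilon_y$); cheapest, and biased when
  binomial noise matters.

Convergence is monitored by split-chain $\hat R$ (`rhat_table()`); seeds
make runs bit-reproducible.

**Model checking.** `compute_waic()` scores the removal-data component
pointwise per (time, year, bin) cell, conditional on sampled latents, with
the trap-split term folded into its bin's cell; `waic_compare()` refits
under each overwinter formulation. `posterior_predictive_check()` draws
replicate removal data conditional on each retained draw's latent
trajectory and compares an omnibus discrepancy (deviance) or a targeted one
(proportion of zero per-trap counts); the p-value is
$\Pr(T(y^{rep}) \ge T(y^{obs}))$.

## Forecasting

`forecast_equilibrium()` projects each selected posterior draw 25 years
under an effort scenario (a gear and an annual trap total spread evenly
over the 14 biweeks; fractional traps per biweek are fine because hazards
scale linearly, soak 24 h by default). Recruit pulses and winter random
effects are drawn per replicate and *shared across scenarios* (common
random numbers — each scenario restarts the replicate's stream), removals
are sampled, not expected values, and the post-winter April states of years
6–25 are averaged into the equilibrium size distribution. The initial
adult population of each replicate is generated from that draw's
($\lambda_A, \mu_A, \sigma_A$) — the construction of the founding cohort is
unspecified in the source analysis and is documented here as a choice.
With heavy large-crab-selective effort the model reproduces the
overcompensation ("hydra") pattern: large crabs are suppressed, winter
density dependence relaxes, and small-crab equilibrium abundance rises.

## The synthetic-data generator

`generate_study()` draws D1/D2/D3 from a known `param_set()`. The default
truth (`default_params()`) uses the values reported for the Drayton Harbour
system where available — $x_\infty = 80.7$ mm, $d_s = 0.25$,
$\sigma_G = 2.8$ mm, $\mu_R = 5.4$ mm, $\lambda_A = 438$, recruit pulses
spanning ~50–1400 ($\mu_\lambda = 5.5, \sigma_\lambda = 1.5$) — and
biologically motivated choices elsewhere, fixed once:

* $k = 0.8$: yearlings reach ~40 mm of an 80-mm asymptote;
* $A = 0.9$, $d_0 = 0.1$: strong seasonality (near-zero winter growth);
* $\beta = 1.0$, $\alpha = 8$ mm: ~59% seasonal survival of large adults,
  steep juvenile mortality without annihilating the recruit pulse;
* $\alpha_o = 0.09$, $\sigma_o = 0.4$: winter survival of small crabs drops
  below 0.5 when total density exceeds ~1000;
* trap hazards ($h^F_{max} = 0.04$, $h^S_{max} = 0.10$, $h^M_{max} = 0.03$
  per day, logistic midpoints 50/45 mm with slope 0.4/mm, minnow mode 45 mm
  with width 60 mm²) giving shrimp > fukui > minnow capture rates,
  minnow selectivity confined to ~30–60 mm, and essentially no capture
  below 30 mm — the selectivity pattern described for the real fleet;
* $\rho = 5$: visibly over-dispersed trap splits.

These are *scenario defaults*, not estimates. The generator emulates the
size-binned, gear-mixed, seasonal structure of real removal programs; it
does not emulate spatial trap placement, tag loss, trap saturation, or
behavioural responses, so a green test establishes correctness of the
machinery under the stated model, not adequacy of that model for any
particular harbour.

## Numerical choices and limitations

* Binomial likelihoods use `round()` of the real-valued latent abundance;
  observed counts exceeding the rounded latent give $-\infty$ (an
  impossible observation), which also truncates the posterior near
  data-imposed boundaries.
* Kernel rows are renormalised to sum exactly to 1 (the truncation constant
  $q$); degenerate $\sigma_G = 0$ falls back to nearest-bin assignment.
* $\sigma_G$ is per-transition, not scaled by $\sqrt{\Delta t}$, matching
  the kernel definition in the source model; the overwinter kernel
  therefore uses the same $\sigma_G$ over its longer step.
* Conditional trap shares at sizes where all hazards vanish are undefined;
  a uniform share is returned with a warning (no crab of that size can be
  caught, so the likelihood never consumes it).
* Desk-scale MCMC configurations (short chains, the `"normal"` latent
  treatment, subsets of free parameters with the rest held at known truth)
  are used in the test suite for runtime; they are stated in each test and
  are *not* the recommended analysis settings (`mcmc_config()` defaults:
  4 chains, all parameters free, exact binomial latents).
* The recruit pulse enters the state one step after $t_R$ via the
  projection equation's indicator; entry size parameters refer to sizes at
  entry.
* Year fractions use $d_{t_{max}} = 0.53$ with 14 biweekly transitions and
  $\Delta t = 14/365$; the winter step spans the remaining 0.47 year.
* The curved $x_\infty$–$k$ ridge of the growth posterior mixes very slowly
  under random-walk proposals; short-chain fits should free only one of the
  two (they trade off through the growth curve at the observed ages), and
  the desk-scale test configurations fix $k$.
* WAIC comparisons between the density-by-size, size-only and constant
  overwinter forms are decisive only with long data series: with a handful
  of winters, the free year effects and winter latents absorb most of the
  difference between those forms and their WAIC values differ by only a few
  units, whereas the density-only form (no size gradient at all) is
  rejected by orders of magnitude more. Expect form selection to need the
  full-scale protocol.
* The proportion-of-zeros check is one-sided in a direction that depends on
  the misspecification: data with *extra* structural zeros push the
  p-value $\Pr(T^{rep} \ge T^{obs})$ toward 0, while a fitted model that
  over-clumps catches (small $\rho$) pushes it toward 1. Either extreme
  flags misspecification.
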