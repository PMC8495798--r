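---
title: "Multilevel hidden Markov models for weed seed-bank demography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilevel hidden Markov models for weed seed-bank demography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seedhmm)
```

## The inference problem

Annual flora surveys record which weed species are standing in a plot each
spring, but the demographic engine of an annual weed population is the soil
seed bank, which surveys never observe. seedhmm treats the seed bank as the
hidden state of a Markov chain and estimates three demographic
probabilities per plot and species from presence–absence series alone:

* **g** — germination: the joint probability that seeds germinate and the
  plant survives to adulthood within a year;
* **s** — seed-bank survival: the probability the bank persists one year
  without any new seed input;
* **c** — external colonization: the probability that at least one seed
  arrives from outside and survives to the next season;

plus **p0**, the probability that seeds were already in the soil the year
before the first survey.

## The hidden Markov model

The chain runs on three states coding the pair (seed bank last year,
standing flora this year): 1 = (0,0), 2 = (1,0), 3 = (1,1). The initial
vector is $(1-p_0,\; p_0(1-g),\; p_0 g)$. Emission is deterministic —
states 1 and 2 are observed as "absent", state 3 as "present" — so there
is no detection-error layer. The transition matrix is

$$
P = \begin{pmatrix}
1-c & c(1-g) & cg \\
(1-c)(1-s) & [1-(1-c)(1-s)](1-g) & [1-(1-c)(1-s)]\,g \\
0 & 1-g & g
\end{pmatrix},
$$

with a structural zero at (3,1): standing flora replenishes the bank with
certainty. The marginal likelihood of a series is computed by the forward
algorithm with per-step normalization (log normalizers accumulated), so
arbitrarily long series cannot underflow. A year in which the plot was not
surveyed contributes an all-ones emission row — the observation is summed
out, but the year's transition still happens, so gaps in the survey never
shorten the chain. `brute_force_loglik()` enumerates all $3^T$ hidden
paths from the same building blocks and serves as an independent oracle
for the forward recursion in the tests.

Two numerical decisions matter here. First, all probabilities are clamped
to $[10^{-12}, 1-10^{-12}]$ inside the likelihood: the hierarchical layer
places logit-normal distributions on the parameters, and boundary
proposals would otherwise produce `log(0)`. A consequence is that
"impossible" observations get an extremely small but finite
log-likelihood rather than $-\infty$, which keeps the sampler ergodic.
Second, the first observation is handled by treating the initial vector
as already encoding it (state 3 if and only if the species is seen), with
the deterministic emission applied as a consistency filter — the only
reading compatible with p0 being defined for the year *before* the first
survey.

## The multilevel layer

Covariates act on one *focal* demographic parameter $\theta \in \{g,s,c\}$
on the logit scale, with one coefficient vector per species $j$:

$$
\mathrm{logit}\,\theta_{ij} = \alpha_{0j} + \alpha_{1j}\,\mathrm{lat}_i +
\alpha_{2j}\,\mathrm{pH}_i + \alpha_{3j}\,\mathrm{silt}_i +
\alpha_{4j}\,\mathrm{clay}_i + \alpha_{5j}\,\mathrm{mow}_i +
\alpha_{6j}\,\mathrm{till}_i + \alpha_{7j}\,\mathrm{herb}_i .
$$

Plot-environment coefficients ($k = 0\ldots4$) are exchangeable across
species, $\alpha_{kj} \sim N(\bar\alpha_k, \sigma_k^2)$. The three
management-practice coefficients ($k = 5,6,7$) get a trait-dependent mean,
$\alpha_{kj} \sim N(\gamma_k + \beta_k\, m_j, \sigma_k^2)$, where $m_j$ is
log10 seed mass, centered and scaled across the modeled species. The
$\beta_k$ are the quantities of scientific interest: they measure how
much a species' response to mowing, tillage or herbicide shifts per
standard deviation of log seed mass.

There is a separate fit per focal parameter. In each fit the two
non-focal demographic parameters get species-level logit-normal random
intercepts ($\eta_j \sim N(\mu, \tau^2)$) and p0 is Uniform(0,1) per
species. This keeps each fit identifiable — with seven-year binary
series there is little information to support the full covariate
structure on all three parameters at once — and mirrors the one-panel-
per-parameter structure of the reported effect figures.

### Priors and their defaults

| parameter | prior | default | why |
|---|---|---|---|
| $\bar\alpha_k, \gamma_k, \beta_k, \mu$ | Normal(0, `prior_sd`$^2$) | `prior_sd = 1.5` | weakly informative on the logit scale: ±2 sd spans probabilities 0.05–0.95 |
| $\sigma_k, \tau$ | Uniform(0, `sd_upper`) | `sd_upper = 5` | flat on the SD; 5 logit units is far beyond any plausible species spread |
| $p_{0j}$ | Uniform(0, 1) | — | no information about pre-study seed banks |

Covariates are standardized (population-SD convention) before entering
the linear predictor, so all slopes are per-SD effects and directly
comparable; the `(center, scale)` pairs are kept for back-transformation.

## Sampling

The hidden states are never sampled: the forward algorithm marginalizes
them exactly, and MCMC runs on the marginalized posterior. The sampler is
an adaptive random-walk Metropolis-within-Gibbs scheme, written in C++:

* species-level scalars (the eight $\alpha_{kj}$, the two non-focal
  intercepts, p0) move one at a time by Gaussian random-walk proposals
  whose scales adapt during warmup toward a 0.44 acceptance rate
  (Robbins–Monro on the log scale, rate $t^{-0.6}$; adaptation stops at
  the end of warmup, preserving the stationary distribution);
* hyper-means ($\bar\alpha_k$, $\gamma_k$, $\beta_k$, $\mu$) are conjugate
  normal Gibbs draws given the species effects;
* hyper-SDs are Gibbs draws from the truncated inverse-gamma conditional
  implied by the uniform-on-SD prior, via inverse-CDF sampling.

Because the likelihood factorizes over species, each species update needs
only that species' plot series, which makes a default fit (2 chains ×
10,000 iterations, 2,500 warmup, the full-length protocol of
`fit_full_protocol()`) take a few minutes at the default design and a
40-plot × 25-species × 8-year fit with 2 × 3,000 iterations around ten
seconds. Chain 1 starts from the prior center and later chains from
independent prior draws (overdispersed starts), with chain seeds derived
deterministically from the master seed, so fits are exactly reproducible.

Convergence is summarized by the split-chain potential scale reduction
factor (each chain is halved before comparing between- to
within-sequence variance) and by the effective sample size; a fit whose
hyper-parameter split-Rhat exceeds 1.1 completes but warns prominently.
The random-effect SDs $\sigma_k$ are the slowest-mixing quantities under
this centered parameterization; the point estimates of the regression
hyper-parameters are far less affected, but short chains may trip the
Rhat flag on a $\sigma_k$ — the remedy is simply more iterations.

## Reporting conventions

Credible intervals are equal-tailed (not HPD): the significance
convention used downstream — an effect is "significant" when its 95%
interval excludes zero — references an unqualified credible interval,
and equal-tailed is the convention of the BUGS-era toolchain this model
family grew up in. Zero lying exactly on an endpoint counts as *not*
excluded, the conservative tie-break.

The explained variance of the seed-mass regression is the multilevel
$R^2$ decomposition

$$
R^2_k = 1 - \frac{E\left[V_j\!\left(\alpha_{kj} - \gamma_k - \beta_k m_j\right)\right]}
             {E\left[V_j\!\left(\alpha_{kj}\right)\right]},
$$

with $V_j$ the finite-sample variance across species and the expectation
over posterior draws, clipped to [0,1]. With degenerate draws and a
least-squares line it reduces exactly to the classical regression $R^2$.
Other decompositions exist (e.g. ratios of expected variances draw by
draw); this one was chosen because it is well-defined for any posterior,
collapses to the familiar quantity in the degenerate case, and is the
standard summary for multilevel models with modeled group-level means.
`effect_table()` and `slope_trait_table()` export the data behind the
interval and slope-versus-seed-mass figures; `plot_effects()` and
`plot_slope_trait()` draw them.

## The synthetic-data generator

`sb_design()` + `generate_dataset()` emulate the survey design the model
was built for: 46 plots, 30 species, 7 annual surveys, with roughly 10%
of plot-years unsurveyed. Missingness is survey-level — a skipped
plot-year is missing for *all* species, which is how flora surveys fail
in practice — and the generator follows the generative model end to end:
covariates drawn (latitude uniform over 43.5–49.5°, pH normal, soil
texture from a Dirichlet so silt + clay never exceeds one, management
counts as means of yearly Poisson draws), seed masses log-uniform over
0.1–14.5 mg (the span from the smallest-seeded composites to bindweed),
species coefficients from their population distributions, series from
the hidden chain. The full latent truth (hyper-parameters, species
effects, hidden seed-bank states) is returned for recovery experiments.

The default truth sets all plot-environment effects to zero,
$\gamma = (0,0,0)$, $\beta = (0.4, 0.6, 0.8)$ and $\sigma_k = 0.3$ — a
moderate trait-mediated signal. Non-focal parameters default to typical
mid-range levels (s around 0.45, c around 0.25, species SD 0.5 on the
logit scale). What the generator does *not* emulate: spatial correlation
between plots, phylogenetic correlation among species effects,
time-varying management within a plot, and sub-plot (row versus
inter-row) structure. Passing recovery tests therefore demonstrates that
the estimator works when the model is true, not that real vineyard data
satisfy these assumptions.

## Verification at a glance

The test suite checks, among other things: exact agreement (to 1e-10)
between the forward recursion and full path enumeration on random short
series including unsurveyed years; stochastic-matrix identities over
random parameter triples; agreement of simulated trajectories with the
transition kernel and its stationary distribution; recovery of
$\gamma_k$ and $\beta_k$ with nominal credible-interval coverage over 20
replicate surveys of 40 plots × 25 species × 8 years (2 × 3,000
iterations per fit — problem sizes chosen so the whole suite runs in
minutes); and calibration under a null truth (≈5% false significance,
near-zero $R^2$). `scripts/acceptance.R` recomputes all of these from
scratch at a user-supplied seed.

## A worked example

```{r example, eval = FALSE}
design <- sb_design(n_plots = 40, n_species = 25, years = 2005:2012,
                    seed = 11)
sim <- generate_dataset(design)
fit <- fit_seedbank(sim$data, focal = "g", chains = 2, iter = 3000,
                    warmup = 1000, seed = 7)
tidy(fit)                  # hyper-parameter summaries
effect_table(fit)          # environment effects on germination
slope_trait_table(fit)     # seed-mass slopes per practice, with R^2
plot_slope_trait(fit)
```

## Known limitations

* Emission is deterministic: a species present above ground is always
  detected. Imperfect detection would bias g downward.
* Seeds are modeled as a single one-year pool; multi-year dormancy
  classes are out of scope.
* The centered random-effect parameterization mixes slowly for
  $\sigma_k$ when species-level information is weak; fits warn on Rhat
  rather than silently reporting.
* Per-plot management is a single study-period average (mean annual
  count; totals available via `assemble_dataset(management = "total")`);
  year-matched covariates would require a time-varying extension of the
  transition matrices.
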