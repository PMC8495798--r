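# seedhmm

Weed population dynamics in perennial crops are driven by the soil seed
bank, which field surveys never observe: a spring flora survey only
records which species are standing above ground. **seedhmm** estimates
the hidden seed-bank dynamics — germination, seed-bank survival, and
external colonization — from yearly presence–absence records, and asks
whether a species' seed mass explains how strongly its demography
responds to management disturbance (mowing, tillage, herbicide). It is
written for plant demographers and agro-ecologists with multi-year,
multi-species occupancy panels and plot-level covariates.

## The model

The observation for plot *i*, species *j*, year *t* is presence/absence
X<sub>t</sub> ∈ {0,1}. The latent chain runs on three states
Z<sub>t</sub> = (S<sub>t−1</sub>, X<sub>t</sub>), where S is the
unobserved seed-bank indicator: 1 = (0,0), 2 = (1,0), 3 = (1,1).
With germination probability *g*, seed survival *s*, colonization *c*
and initial seed-bank probability *p0*:

- initial vector: (1 − p0, p0(1 − g), p0·g)
- emission: deterministic — states 1,2 → absent, state 3 → present
- transitions:

  | from \ to | (0,0) | (1,0) | (1,1) |
  |---|---|---|---|
  | (0,0) | 1−c | c(1−g) | c·g |
  | (1,0) | (1−c)(1−s) | [1−(1−c)(1−s)](1−g) | [1−(1−c)(1−s)]g |
  | (1,1) | 0 | 1−g | g |

The likelihood of each series is computed exactly by the forward
algorithm (unsurveyed years marginalized, never imputed). On top of this
sits a multilevel layer: the focal parameter θ ∈ {g, s, c} of plot *i*
and species *j* follows

logit θ<sub>ij</sub> = α<sub>0j</sub> + α<sub>1j</sub>·latitude<sub>i</sub> + α<sub>2j</sub>·pH<sub>i</sub> + α<sub>3j</sub>·silt<sub>i</sub> + α<sub>4j</sub>·clay<sub>i</sub> + α<sub>5j</sub>·mowing<sub>i</sub> + α<sub>6j</sub>·tillage<sub>i</sub> + α<sub>7j</sub>·herbicide<sub>i</sub>

with species random effects α<sub>kj</sub> ~ N(ᾱ<sub>k</sub>, σ<sub>k</sub>²)
for the environmental terms (k = 0..4) and trait-dependent means
α<sub>kj</sub> ~ N(γ<sub>k</sub> + β<sub>k</sub>·seedmass<sub>j</sub>, σ<sub>k</sub>²)
for the management terms (k = 5,6,7; seed mass on the standardized log
scale). The β<sub>k</sub> — how much the response to each practice
shifts with seed mass — are the quantities of interest, summarized with
equal-tailed 95% credible intervals (an effect is "significant" when the
interval excludes zero) and a multilevel explained variance R²<sub>k</sub>.
Fitting is by adaptive Metropolis-within-Gibbs MCMC over the
marginalized likelihood (hidden states are never sampled), implemented
in C++.

## Worked example

Simulate a survey with known truth (40 plots, 25 species, 8 years;
seed-mass slopes β = 0.4, 0.6, 0.8 for mowing, tillage, herbicide), fit
the germination model, and read off the hyper-parameters:

```r
library(seedhmm)

design <- sb_design(n_plots = 40, n_species = 25, years = 2005:2012,
                    seed = 11)
sim <- generate_dataset(design)
fit <- fit_seedbank(sim$data, focal = "g", chains = 2, iter = 3000,
                    warmup = 1000, seed = 7)

summarize_posterior(fit)[6:11, ]
#> # A tibble: 6 × 6
#>   term                 mean   lower  upper  rhat   ess
#>   <chr>               <dbl>   <dbl>  <dbl> <dbl> <dbl>
#> 1 gamma[mowing]     0.0776  -0.0874 0.248   1.00 1023.
#> 2 gamma[tillage]   -0.00795 -0.164  0.132   1.00  426.
#> 3 gamma[herbicide] -0.0597  -0.208  0.0927  1.00  781.
#> 4 beta[mowing]      0.429    0.259  0.602   1.00  833.
#> 5 beta[tillage]     0.605    0.466  0.751   1.00  434.
#> 6 beta[herbicide]   0.797    0.636  0.966   1.01  594.
```

(This short 3,000-iteration fit warns that one random-effect SD has
split-Rhat 1.14 — those are the slowest-mixing quantities; the slope
summaries above are well mixed, and the full 10,000-iteration protocol
of `fit_full_protocol()` clears the flag.) The management intercepts γ
(truth 0) straddle zero; all three seed-mass slopes β are recovered
close to their true values with intervals excluding zero — large-seeded species respond more strongly to each
practice, exactly the signal that was simulated. `effect_table(fit)`
gives the latitude/pH/silt/clay effect intervals, `slope_trait_table(fit)`
the per-species slopes against seed mass with the fitted line
γ + β·seedmass and R² per practice, and `plot_effects()` /
`plot_slope_trait()` draw them. `tidy(fit)` and `glance(fit)` give
broom-style summaries.

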