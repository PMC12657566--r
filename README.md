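# nirsconnect

Resting-state functional connectivity from continuous-wave fNIRS, and
Bayesian inference on connectivity degree.

Functional near-infrared spectroscopy (fNIRS) measures cortical hemodynamics
through dual-wavelength light attenuation. In resting-state designs — for
example when tracking how a neuromodulation protocol reshapes prefrontal
networks across sessions — the question is whether a channel's *degree of
connectivity* (the number of other channels whose activity it tracks)
differs between groups and sessions. `nirsconnect` implements that analysis
end to end for researchers working with NIRSport2-style frontal montages:

- **Preprocessing**: optical density, TDDR motion correction,
  short-separation channel regression, scalp-coupling-index screening
  (SCI < 0.7 flags a channel), spherical-spline interpolation of bad
  channels, the modified Beer–Lambert law (PPF 6.0), negative correlation
  enhancement, and a 0.01–0.20 Hz zero-phase FIR band-pass.
- **Connectivity**: 30-s epochs with 5-s overlap, exclusion of annotated or
  saturated (|HbO| ≥ 10 µM) epochs, epoch-averaged |Pearson r| matrices,
  binarization at 0.5 (inclusive), and per-channel degree.
- **Inference**: a multilevel Poisson regression of degree,

  ```
  y ~ Poisson(alpha)
  log(alpha) = (b0 + u0i + w0j) + (b1 + u1i)·Group
             + (b2 + u2i + w1j)·Session + (b3 + u3i)·Group×Session
  b ~ Normal(0, 2.5),  sigma_u, sigma_w ~ Exponential(2)
  ```

  with channel (i) and participant (j) random effects, sampled by MCMC
  (8 chains × 2,000 iterations, 1,000 warm-up, by default). Hypotheses are
  evaluated on average marginal posterior predictions per Group × Session
  cell: pairwise difference distributions Δ, their 89% highest density
  intervals, and a region of practical equivalence (ROPE) of ±0.1 response
  SD. The null difference is *rejected* when less than 2.5% of the HDI
  draws fall in the ROPE, *supported* above 97.5%, *inconclusive* otherwise.
- **Synthetic data**: optical recordings generated from latent networks with
  known coupling (including physiological oscillations, a superficial scalp
  compartment shared with short channels, motion artifacts, and saturation
  episodes), and degree tables drawn from the exact generative model — so
  the whole pipeline is testable against ground truth.

## Worked example

Simulate a degree dataset with a known Group × Session interaction
(DLPFC at the one-month follow-up raised by 0.5 on the log scale, i.e.
about 65% more connections), fit the model, and run the decision layer:

```r
library(nirsconnect)

params <- degree_model_params(
  beta0 = log(15),
  beta_interaction = matrix(c(0, 0, 0.5, 0), 2, 2)  # DLPFC x Post1month
)
d <- simulate_degree_dataset(params, n_per_group = c(DLPFC = 15, VLPFC = 15, Sham = 15),
                             n_channels = 44, seed = 7)
fit <- fit_poisson_glmm(d, chains = 2, iter = 800, warmup = 300, seed = 1)
tidy(fit)
#> # A tibble: 16 x 7
#>   term                          estimate std.error conf.low conf.high
#> 1 (Intercept)                     2.7621    0.0748   2.6473    2.884
#> 2 groupDLPFC                      0.0668    0.0814  -0.0678    0.180
#> 7 groupDLPFC:sessionPost1month    0.5226    0.0494   0.4349    0.596
#> ...

cmp <- compare_cells(fit, d, n_draws = 1000, seed = 2)
tidy(cmp)[, c("within", "contrast", "median", "rope_overlap", "decision")]
#>    within     contrast         median rope_overlap decision
#>  5 DLPFC      Post1month - Pre   12.7        0.000 rejected
#> 17 Post1month DLPFC - Sham       13.8        0.000 rejected
#>  1 Sham       Post - Pre          0.8        0.726 inconclusive
#> ...
```

The injected interaction is recovered (posterior median 0.52, 89% interval
[0.43, 0.60] containing the generating 0.5), the follow-up contrasts for
the treated group are flagged non-zero (`rejected`), and contrasts between
cells that truly share coefficients come out `supported` or
`inconclusive`. `autoplot()` methods
exist for connectivity matrices, marginal predictions, and the comparison
table; `glance(fit)` and `check_convergence(fit)` summarize sampler health
(R-hat ≤ 1.01, ESS thresholds).

The full optical route — simulate raw intensities, preprocess, build the
degree table, fit, decide — is one call:

```r
cfg <- pipeline_config(duration = 120, n_channels = 24, n_short_channels = 6,
                       n_per_group = c(DLPFC = 4, VLPFC = 4, Sham = 4),
                       chains = 2, iter = 1600, warmup = 600, seed = 1)
report <- run_pipeline(cfg, verbose = TRUE)
report$comparisons
```

(The defaults emulate the full acquisition — 44 channels, 300-s recordings,
8 chains of 2,000 iterations — and take correspondingly longer.)

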