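---
title: "From raw optical intensities to Bayesian degree inference: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw optical intensities to Bayesian degree inference: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(nirsconnect)
```

## Scope

`nirsconnect` implements a complete resting-state fNIRS analysis chain:
dual-wavelength continuous-wave intensities are converted to oxy-/deoxy-
hemoglobin concentration changes, an epoch-based binarized functional
connectivity graph is built per recording, the per-channel *degree* (number
of supra-threshold connections) is modelled with a Bayesian multilevel
Poisson regression, and group-by-session inferences are drawn from average
marginal posterior predictions with 89% highest density intervals (HDI) and
a region of practical equivalence (ROPE) decision rule. A synthetic-data
generator with known latent connectivity and known generative coefficients
makes every stage testable against ground truth without any recordings.

## The preprocessing chain

The chain order is fixed and enforced at run time; each stage refuses input
at the wrong stage:

1. **Optical density**: `OD(t) = -log10(I(t) / mean(I))` per channel and
   wavelength.
2. **TDDR motion correction**: the signal is split at 0.5 Hz with a
   3rd-order zero-phase Butterworth filter; the slow component's temporal
   derivative is iteratively re-weighted with Tukey's biweight (tuning
   constant 4.685, scale 1.4826 x MAD, iterated until the maximum weight
   change is below 1e-8 or 50 iterations), re-integrated, and recombined
   with the untouched fast component.
3. **Short-separation regression**: each long channel is replaced by its
   least-squares residual against the spatially nearest short channel
   (Euclidean midpoint distance), per wavelength. Nearest-channel pairing
   is the simplest reproducible variant.
4. **Scalp coupling index**: the zero-lag Pearson correlation between the
   two wavelengths filtered to the cardiac band (0.7-1.5 Hz). Channels with
   SCI strictly below 0.7 are marked bad; an SCI exactly at threshold is
   kept.
5. **Spherical-spline interpolation** of bad channels over channel midpoints
   projected to a best-fit sphere (order m = 4, 7 Legendre terms, ridge
   1e-5). Interpolation runs in channel space because channels, not
   optodes, are screened.
6. **Manual annotations** (interval lists from visual inspection) attach to
   the recording; they are an input, not an algorithm.
7. **Modified Beer-Lambert law**: per channel,
   `[HbO, HbR]' = E^-1 [OD_760/(d ppf), OD_850/(d ppf)]'` with a partial
   pathlength factor of 6.0 at both wavelengths and `d * ppf` treated as
   the total effective pathlength (the PPF is assumed to absorb the
   differential pathlength). Extinction coefficients are a standard
   compiled in-vitro tabulation (586 / 1548.52 at 760 nm and 1058 / 691.32
   at 850 nm, base-10, cm^-1 M^-1). Only long channels are retained.
8. **Negative correlation enhancement**: with `a = sd(HbO)/sd(HbR)`,
   `HbO' = (HbO - a HbR)/2`, `HbR' = (HbR - HbO/a)/2`, after which
   `cor(HbO', HbR') = -1` exactly.
9. **Band-pass 0.01-0.20 Hz**: Hamming windowed-sinc FIR, zero-phase by
   symmetric-kernel convolution with mirrored edges. The two band edges get
   independent transition widths (0.01 Hz low, 0.2 Hz high) by convolving a
   high-pass and a low-pass kernel whose lengths follow the standard
   Hamming rule (about 3.3 / normalized transition width). The stated upper
   transition width equals the upper cutoff itself; it is implemented
   literally. Kernel length is capped at the signal length, which widens
   the lower transition on recordings shorter than about 330 s.

### What TDDR does to clean signals

TDDR's biweight weights fall below 1 for any derivative beyond about one
robust SD, so the repair *compresses* even artifact-free signals: a smooth
band-limited series loses amplitude (roughly a third in RMS terms) while
its band-passed *shape* is preserved almost exactly (correlation > 0.94).
We verified this behaviour is identical in an independent reference
implementation of the published algorithm. Because the downstream
connectivity statistic is a correlation, uniform amplitude compression is
inconsequential there. The package's end-to-end recovery check therefore
runs on artifact-free data with motion correction disabled (there is
nothing to repair), and TDDR's artifact behaviour - at least 80% peak
reduction for multi-second motion spikes, near-complete flattening of
baseline shifts - is asserted separately.

## Connectivity and degree

Recordings are segmented into 30-s epochs with 5-s overlap (hop 25 s;
`floor((T - 30)/25) + 1` epochs). An epoch is excluded when it intersects
an annotated artifact interval with positive measure or when any HbO sample
reaches 10 µM in absolute value (the limit itself counts as saturated; the
signed-vs-absolute convention is configurable). Within each retained epoch
the pairwise |Pearson r| over HbO is computed; epochs are aggregated by
element-wise averaging (the default; concatenation of retained epochs is
available as `aggregate = "concatenate"`). Epoch-wise computation is what
makes per-epoch exclusion meaningful. The aggregated matrix is binarized
once at 0.5 - entries *equal to or above* the threshold become edges - and
a channel's degree is its number of edges. Raising the threshold can never
increase a degree, degree sums are even, and permuting channels permutes
results consistently; all three are asserted as properties in the suite.

## The multilevel Poisson model

Degree `y` for channel *i* of participant *j* follows
`y ~ Poisson(alpha)` with

```
log(alpha) = (b0 + u0i + w0j) + (b1 + u1i) Group
           + (b2 + u2i + w1j) Session + (b3 + u3i) Group x Session
```

Factors use treatment coding with Sham and Pre as reference levels, so
Group and Session each contribute two contrast coefficients and the
interaction four. Channel-level random effects comprise an intercept and
slopes for Group, Session and the interaction; each block shares one SD
(four `sigma_u` values). Participant-level effects are an intercept and the
two Session-contrast slopes, each with its own SD (three `sigma_w` values).
Random-effect correlations are not modelled - the generative equation
writes independent terms - and priors are Normal(0, 2.5) on all fixed
effects and Exponential(rate 2, mean 0.5) on all SDs.

Sampling uses JAGS with its `glm` block samplers (auxiliary-variable
updates for Poisson regression), 8 chains x 2,000 iterations with 1,000
warm-up by default, retaining `chains * (iter - warmup)` draws. Because
marginal predictions are averaged over units including their random
effects, the inferences are invariant to the factor coding. Two numerical
choices matter:

- **SD initialization**: all random-effect SDs start at 1. The centered
  Gibbs parameterization has an absorbing corner at `sigma ~ 0` (tiny SD
  implies tiny effects implies tiny SD); starting at the prior's upper
  range lets chains find the posterior bulk reliably.
- **Diagnostics**: R-hat (potential scale reduction) and
  autocorrelation-adjusted ESS are computed for every non-constant
  parameter; `check_convergence()` passes at R-hat <= 1.01 and
  ESS >= 400 by default. Near-zero hierarchical SDs mix slowly under Gibbs
  sampling; when a scale parameter is genuinely close to zero, longer
  chains are needed to pass the default thresholds.

Simulation-based calibration at reduced scale (200 prior-drawn replicates,
2 participants per group, 4 channels) shows uniform rank statistics for the
intercept and the interaction coefficient, confirming that the sampler and
the generator implement the same model.

## Decision layer

For each of 1,000 posterior draws (a seeded subsample of the retained
draws), the expected degree of every observed (participant, channel) unit
is computed under each Group x Session cell - including the unit's random
effects - and averaged, giving 1,000 average marginal predictions per cell.
Contrasts are formed as later minus earlier session (within groups) and
first-listed minus second-listed group in the order DLPFC, VLPFC, Sham
(within sessions): 9 + 9 = 18 comparisons for a full design. For each
difference distribution the 89% HDI is found by the sorted-window algorithm
(narrowest window containing `ceiling(0.89 n)` sorted draws; ties break to
the lowest start). The ROPE is zero plus or minus one tenth of the response
SD - computed from the analyzed degree table, overridable - and the
reported overlap is the proportion *of the draws inside the HDI* that also
fall inside the ROPE. Decisions: below 0.025 the null difference is
rejected, above 0.975 it is supported, anything else - including an HDI
crossing both ROPE bounds - is inconclusive.

## The synthetic-data generator

The generator emulates the acquisition geometry (16 sources, 16 detectors,
44 long channels near 3.5 cm separation on a spherical frontal patch, 8
short channels near 0.76 cm, 5.1 Hz sampling, 760/850 nm) and layers the
signal structure the preprocessing chain assumes:

- **Latent connectivity.** Two models. `simulate_latent_network()` draws an
  Erdos-Renyi graph with per-edge coupling strengths. The correlation
  structure is realized by mixing independent 0.01-0.2 Hz band-limited
  Gaussian factors through the square root of the PSD-projected target
  correlation matrix (unit diagonal, coupling on edges). For isolated pairs
  the realized correlation equals the coupling exactly. A dense incoherent
  graph, however, cannot carry uniformly high pairwise correlations - the
  PSD constraint forces transitive fill-in - so thresholded degree in such
  graphs cannot track the latent degree. `simulate_clustered_network()`
  therefore provides the pipeline's default latent model: a union of
  cliques (compound-symmetry blocks, exactly PSD), mirroring the block
  structure of real resting-state matrices. Cluster size maps directly to
  degree, and the pipeline recovers it essentially exactly; group or
  session effects are injected by varying cluster size per cell.
- **Physiology.** Cardiac pulsation (a jittered sinusoid drawn from
  1-1.5 Hz, 0.3 µM) rides in the cortical signal, and HbR carries an
  attenuated in-phase copy (0.2x) - arterial pulsation is in-phase across
  chromophores, and a purely negative HbR would cancel the 760 nm cardiac
  signal and destroy the SCI. Respiration (0.2-0.5 Hz) and Mayer waves
  (~0.1 Hz) are predominantly systemic and enter mainly through the
  superficial compartment - which is precisely why short-separation
  regression exists - with only small cortical residues (0.05 / 0.08 µM).
- **Superficial compartment.** One global plus one per-region slow process
  (regions indexed by the nearest short channel), carrying the systemic
  oscillations, scaled to 0.4 µM, mixed into long channels at weight 0.3
  and dominating the short channels.
- **Artifacts.** Motion events at a configurable rate per minute: half are
  1-s half-cosine spikes at 5-20x the signal SD, half are baseline shifts;
  events hit all channels with random gains. Saturation episodes are slow
  3-s excursions sized to push reconstructed HbO past 15 µM.
- **Degree counts.** `simulate_degree_dataset()` draws from the exact
  model likelihood with known coefficients; the Poisson support is
  unbounded by default to match the analysis model, with an optional clip
  at the graph bound `n_channels - 1`. Default random-effect SDs (0.3
  channel intercept, 0.1 slopes; 0.2 participant intercept, 0.1 session
  slopes) were chosen once as plausible magnitudes for between-channel and
  between-participant heterogeneity of log-degree. The hemodynamic
  amplitude (0.5 µM), noise levels, and the default 300-s duration are
  likewise fixed realistic choices; recording duration is otherwise
  unreported and treated as free.

What the generator does *not* emulate: photon transport through anatomy,
optode-scalp coupling drift, non-stationary physiology, heavy-tailed
instrument noise, or any relationship between the clinical intervention and
physiology. Passing tests demonstrate internal consistency of the pipeline
and calibration of the inference under the generator's assumptions - not
performance on real recordings.

## Problem sizes used by the automated checks

The test suite fits the model at the generative-study scale (15
participants per group, 44 channels) for the interaction-recovery
experiment (100 replicates, single chains of 800 iterations) and for the
20-replicate follow-up-only pattern experiment, uses 9-participant
16-channel cohorts for the 100-replicate null decision-rate experiment,
and a reduced 12-participant 24-channel optical cohort for the full
end-to-end pattern check. Balanced cohorts of at least 15 per group are
needed for the baseline-silence half of the pattern: at 5 per group the
participant random intercepts produce realized baseline differences that
the model correctly flags. The acceptance script runs the complete optical pipeline at
the emulated subset size (5/5/4, 44 channels, 300 s) and reduced-count
replicate experiments. These sizes are the package's standing choices for
its reproducibility artifacts.

## Known limitations

- The Poisson likelihood ignores the hard upper bound `degree <= 43`; with
  means near 15 the truncation mass is negligible, but the model is used
  as specified rather than bounded.
- Epoch-averaged |r| is one of two defensible aggregations; concatenation
  is provided but not the default, and the two differ slightly in finite
  samples.
- The Gibbs sampler mixes slowly in the small-SD funnel; fits with
  near-zero hierarchical scales need longer chains than the defaults.
- Graph metrics beyond degree (strength, clustering, modularity),
  HbR-based connectivity, and directionality are out of scope.
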