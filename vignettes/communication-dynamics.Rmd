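---
title: "Quantifying dynamic inter-areal communication from paired silencing recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic inter-areal communication from paired silencing recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(commdyn)
```

## The problem

Correlations between simultaneously recorded cortical areas cannot, by
themselves, establish that one area causally drives the other: common input
and unobserved sources produce the same statistical dependence. The
experimental design this package analyzes breaks that ambiguity by
manipulation. Two areas — a source and a target, for instance primary
visual cortex (V1) and the higher visual area LM in mice — are recorded
simultaneously while the source is transiently silenced by optogenetic
activation of inhibitory interneurons. Silencing lasts 150 ms and is
applied at one of 8 onsets tiling a 500-ms visual stimulus in ~65-ms
steps; the onset is randomized across trials and control trials are
interleaved. Any change in target-area firing during a silencing window,
relative to the same window of control trials, is a causal effect of the
source area on the target.

The animals perform a go/no-go discrimination: two grating orientations,
one rewarded, with licking as the report. Behavioral context (rewarded
versus unrewarded stimulus) is therefore available as an experimental
factor.

The package implements the full analysis chain on this design:

* per-neuron silencing effects with bootstrap significance,
* behavioral metrics (d-prime with a trial-shuffle chance level,
  onset-corrected reaction times and d-primes),
* a Gaussian encoding model relating silencing effects to cell properties,
* population-level **communication directions** and their cross-validated
  similarity dynamics,
* a Poisson **time-invariant influence** null simulation,
* Bhattacharyya magnitudes of population-level influence,
* windowed PCA of trial-to-trial covariance,
* exponential decay fits, initial slopes, and a go/no-go permutation test,
* spike-count autocorrelations and pairwise noise correlations,

together with a synthetic two-area session simulator with exported ground
truth that every stage is validated against.

## Core quantities

**Per-neuron silencing effect.** For neuron $n$, window $T$:
$100\,(R_s - R_c)/R_c$, where $R_s$ is the mean spike count in the 150-ms
silencing window over silencing trials and $R_c$ the mean count in the same
window of control trials. Neurons whose window rate falls below 2.5 Hz are
masked (the percent change is a ratio; masking protects the denominator).
Significance comes from a bootstrap null built only from control trials:
control counts are resampled with replacement into two pseudo-condition
groups of the observed sizes, and the observed effect must fall outside the
[2.5, 97.5] percentile interval of the resulting percent changes
(Bonferroni-adjusted percentiles for counting significant windows across
the 8 comparisons).

**Communication direction (CD).** In the target area's population activity
space, the CD of a window is the unit normal to the regularized-LDA
decision boundary separating control from source-silencing trials:
$\mathrm{CD} \propto \Sigma_\gamma^{-1}(\mu_c - \mu_s)$ with
$\Sigma_\gamma = (1-\gamma)\,\hat\Sigma + \gamma\,\mathrm{diag}(\hat\Sigma)$,
where $\hat\Sigma$ is the pooled within-class covariance (df-weighted over
the two classes) and $\gamma$, together with a relative coefficient
threshold $\delta$, is tuned per animal by 10-fold cross-validated
classification error. The sign convention (control minus silencing) makes
CD signs comparable across windows.

**Cross-validated cosine similarity.** To compare directions across
windows without conflating estimation noise with real rotation, trials are
split in half at random; direction $i$ is estimated from one half and
direction $j$ from the other, their dot product taken, the halves swapped,
the two products averaged, and the whole procedure repeated over (default)
100 random partitions. The diagonal (lag 0) of the resulting matrix is the
split-half reliability: its shortfall from 1 measures trial-to-trial
variability, and for a truly static direction the attenuation at lag 0
equals the attenuation at any other lag, so a static geometry yields a
*flat* lag profile rather than a decaying one. Because a CD needs both
classes, control and silencing trials are both split in half in each
partition.

**Lag-profile statistics.** The similarity as a function of window lag is
summarized two ways: the model-free *initial slope* (lag-1 value minus
lag-0 value), and an exponential fit $y = A(e^{-t/\tau} + B)$ with $t$ the
lag in ms (lags convert to ms by the mean silencing-onset spacing,
~65 ms). Context dependence is tested by exchanging go/no-go trial labels
within each animal (within the control pool and within each window's
silencing pool, preserving counts), recomputing everything, and comparing
$\Delta\tau = \tau_{go} - \tau_{nogo}$ to its permutation null with the
add-one-corrected p-value.

**Time-invariant null.** To ask whether CD rotation could be an artifact
of firing-rate dynamics or trial noise, surrogate silencing trials are
generated per neuron by drawing one of its 8 observed window effects at
random, applying it to all windows, and emitting Poisson counts at the
control-trial mean of each window scaled by $1 + E/100$. The surrogate
preserves mean rates, effect sizes and Poisson variability, but holds the
*pattern* of influence fixed in time; its similarity profile is flat up to
attenuation, so a genuinely rotating influence shows a steeper initial
decay than its surrogate.

**Influence magnitude.** The Bhattacharyya distance between control and
silencing population activity under the equal-covariance Gaussian
assumption, $D = \tfrac18 (\mu_c-\mu_s)^\top \Sigma_\gamma^{-1}
(\mu_c-\mu_s)$ (the log-determinant term vanishes when the covariance is
shared), with a noise floor from control-vs-control bootstrap resamples.

**Windowed PCA.** Principal components of the trial-by-neuron count matrix
per 150-ms window, per stimulus and condition with equal trial counts
across the four groups; their across-window similarity uses the *absolute*
cross-validated cosine because PC signs are arbitrary (the rectification
happens before the half-swap average — averaging signed cosines of
sign-ambiguous estimates would cancel).

## The simulator

`sim_config()` / `simulate_session()` generate sessions with the
statistical structure the analysis assumes, with every generating quantity
exported as ground truth:

* log-normal baseline rates (default median 5 Hz, log-sd 0.5) and
  per-stimulus multiplicative gains (median 1.6);
* a shared temporal envelope across the window grid (default a mild onset
  transient, 1.3 down to 0.9);
* a rank-k log-rate latent factor per trial producing realistic noise
  correlations (the leading factor is a common gain with non-negative
  loadings, giving positive-mean pairwise correlations; the remaining
  factors have random-direction loadings); the first loading direction
  can rotate a controlled angle per window to plant PC rotation;
* silencing: source-area rates multiplied by a residual fraction (default
  0.05, emulating ~−95% suppression), target-area rates multiplied by
  $1 + e_{w,n}/100$ where the per-window percent-change vectors $e_w$ are
  either static or form a Markov rotation with an exact adjacent-window
  cosine (each next unit pattern is $c\,u_w + \sqrt{1-c^2}\,q$ with $q$ a
  fresh random orthogonal unit vector, giving lag-$k$ cosine $\approx
  c^k$); patterns are scaled to a mean absolute effect (default 25%) and
  entries are drawn from a truncated normal so no neuron crosses −100%;
* trial structure per the targeted design: 97 control trials, 78 silencing
  trials per window, 8 onsets at 0, 56, 123, 189, 256, 323, 390, 456 ms,
  go/no-go equiprobable and counterbalanced within condition-by-window
  strata;
* behavior: licks with hit rate 0.75 and false-alarm rate 0.15 (d-prime
  ≈ 1.7), reaction times from a shifted log-normal (median ≈ 280 ms)
  truncated at 100 ms.

Spikes are emitted as an exact piecewise-constant-rate Poisson process
(per-segment Poisson count, uniform times within the segment). Every
statistic in the package is a window count, so sub-millisecond structure
(refractoriness, spike-time correlations) is deliberately not modeled.
The simulator also does not model conduction delays, oscillations, slow
drift across a session, or non-Poisson dispersion; passing the validation
suite therefore shows correctness of the estimators under the assumed
generative family, not robustness to every property of real recordings.

Where the targeted design leaves a quantity unstated, the defaults were
chosen once as field-typical values: cortical baseline rates of a few Hz
with log-normal spread, ~1.5–2x visual stimulus gains, weak
positive-mean pairwise noise correlations from a low-rank latent factor
with a common-gain leading component, and a zero-median
Gaussian pattern of signed feedback effects across neurons (the in-vivo
feedback effect distribution is diverse with near-zero median; no
parametric form is reported, so this is a modeling choice).

## Numerical choices

* **Windows** are half-open `[onset, onset + duration)`; a spike at the
  right edge belongs to the next window, so tiling windows partition
  spikes exactly.
* **Masking**: the rate threshold sets an explicit validity mask rather
  than NaNs; a neuron enters a pairwise window computation only if
  unmasked in both windows, and cosines are taken on the common support.
* **Responsiveness** pairs each trial's stimulus-window count with an
  equal-length pre-stimulus count (two-sided Wilcoxon signed-rank,
  p < 0.05, plus at least one spike on average for one stimulus);
  pairing is chosen for power.
* **Rate threshold scope**: evaluated per window, pooled across
  conditions, configurable (`by = "condition"`).
* **LDA**: pooled covariance is the df-weighted within-class covariance;
  the $\delta$ grid is expressed relative to the largest absolute
  coefficient, because absolute thresholds are scale-fragile; ties in the
  $(\gamma, \delta)$ grid search resolve to the smallest $\gamma$, then
  the smallest $\delta$.
* **Exponential fits** profile $\tau$ on a log-spaced grid (the model is
  linear in $A$ and $AB$ given $\tau$), refine the optimum continuously
  between neighboring grid points (a raw grid quantizes $\tau$ and
  produces ties in permutation statistics), and optionally polish with
  bounded Levenberg–Marquardt from multiple starts
  ($\tau_0 \in \{20, 65, 130, 500\}$ ms). $\tau$ is bounded in
  $[0, 10^4]$ ms; a constant profile leaves $\tau$ unidentified and is
  flagged (`converged = FALSE`).
* **Decay-fit confidence intervals** use a residual bootstrap
  (leverage-adjusted, centered residuals resampled onto the fitted curve,
  100 replicates) with symmetric studentized (bootstrap-t) intervals from
  linearization standard errors. Plain percentile intervals undercover
  substantially on 8-point profiles (~80% observed vs 95% nominal in our
  calibration runs); the symmetric bootstrap-t restores near-nominal
  coverage. Resampling profile points ("pairs") frequently discards the
  low lags entirely and leaves $\tau$ unidentified, so it is not the
  single-profile default; bootstrap over animals is the natural mode when
  several sessions are pooled.
* **Permutation fits** pool every window pair as one point at its lag
  ("points" pooling), so single-pair long lags do not dominate, and use
  the deterministic grid fitter applied identically to observed and
  permuted data.
* **Encoding model**: Gaussian IRLS (equal to least squares); covariate
  and control activity are z-scored inside the fit (re-standardized per
  training fold), making performance invariant to affine covariate
  rescaling; the test-fold likelihood uses the training-fold residual SD.
  The default observation unit is one (neuron, silencing trial) per
  window, pooled across windows, with per-neuron means available by
  `unit = "neuron_mean"`; folds are stratified over observations, not
  neurons.
* **Degenerate PCA**: eigenvectors are ordered by descending eigenvalue;
  PC similarity uses absolute cosines (signs arbitrary). Exactly isotropic
  covariance leaves PCs undefined; tests avoid that degeneracy.
* **Behavioral clipping**: hit/false-alarm rates of 0 or 1 are clipped by
  the 1/(2N) rule before the normal quantile, keeping d-prime finite.
* **Control pseudo-windows**: onset-corrected behavioral contrasts assign
  each control trial one of the 8 onsets uniformly at random (seeded),
  since control trials have no physical silencing onset.
* **Effect pooling**: per-neuron effect tables are computed per stimulus
  by default (matching the per-stimulus direction analyses), with a pooled
  mode available.
* All resampling is seeded; pipeline stages derive independent seed
  streams from one master seed and record them in the run manifest.

## Validation strategy and problem sizes

The validation suite (`tests/testthat/`) checks every stage against
independent oracles: a brute-force linear solve for the regularized LDA, a
standard-normal quantile oracle for d-prime, the closed-form
equal-covariance Bhattacharyya distance on empirically whitened data,
law-of-total-covariance oracles for doubly-stochastic Poisson correlations,
and ground-truth recovery on simulated sessions (planted effect sizes,
planted rotation cosines, planted PC rotations, planted reaction-time
shifts).

Monte-Carlo studies run at sizes chosen to keep a desk run practical while
leaving the statistical assertions well-powered; the sizes are stated in
the test code and include: 200 random LDA instances; 1000 null neurons for
bootstrap calibration at 5000 trials per recovery session; 50-neuron,
80-trials-per-window sessions for direction-dynamics recovery; 20
simulated animals for the time-invariant null contrast; 500 noisy profiles
for decay-CI coverage; 500 simulated datasets (5 windows, 12 target
neurons, 80/32 trials) at 200 permutations each for permutation
calibration, with exchangeability made exact by sharing all generating
parameters between go and no-go; and 30 datasets (6 windows, 16 neurons,
160/64 trials, 40 similarity splits) for permutation power.

One validation target is knowingly hard: detecting a planted
fast-rotating-go versus strictly-static-no-go contrast via the difference
in fitted decay constants. A strictly static geometry yields a flat
similarity profile, and the decay constant of a constant-plus-noise
profile is unidentified — the fitted $\tau$ lands at the small-$\tau$
step solution, at the upper bound, or anywhere between, depending on
noise alone. The $\Delta\tau$ permutation test therefore has limited
power against *literally* time-invariant alternatives (in our runs roughly
half of such datasets reject), even though it is well calibrated and
powerful against fast-versus-slow rotation contrasts where both profiles
decay. The model-free initial-slope contrast — which the analysis chain
also provides, and which the time-invariant null comparison uses — is the
appropriate statistic in that regime. This limitation is inherent to
comparing decay constants when one condition does not decay, not to the
implementation.

## Limitations

Beyond the simulator scope noted above: the pipeline assumes two areas and
one silencing grid per session; the encoding model is Gaussian (counts are
not variance-stabilized); the LDA assumes shared within-class covariance
(the shrinkage estimator mitigates, but does not remove, small-sample
bias); reduced-rank regression style communication-subspace estimators and
spectral measures of interaction are out of scope.
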