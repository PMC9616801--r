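# commdyn

Analysis of **causal communication between cortical areas** from paired
two-area spiking recordings with transient optogenetic silencing. One area
(the *source*) is silenced for 150 ms at one of 8 onsets tiling a 500-ms
visual stimulus while the other area (the *target*) is recorded; control
trials are interleaved, and the animal performs a go/no-go discrimination.
`commdyn` turns such sessions — or synthetic sessions with known ground
truth — into the quantities that describe how one area influences the
other and how that influence evolves over tens of milliseconds.

The core population-level object is the **communication direction** (CD)
of a time window: the unit normal to the regularized linear-discriminant
boundary separating target-area population activity in control versus
source-silencing trials,

```
CD ∝ Σγ⁻¹ (μ_c − μ_s),    Σγ = (1 − γ) Σ̂ + γ diag(Σ̂),
```

with Σ̂ the pooled within-class covariance and γ (plus a coefficient
threshold δ) tuned per animal by cross-validated classification error.
How fast CDs rotate across windows is measured by **cross-validated cosine
similarity** (split-half estimates, half-swap averaged, 100 random
partitions), summarized by initial slopes and exponential decay fits
`y = A(exp(−t/τ) + B)`, compared between go and no-go trials by a label
permutation test on Δτ, and benchmarked against a Poisson
**time-invariant influence** surrogate that holds each neuron's silencing
effect fixed across windows. Around this sit per-neuron silencing effects
`100 (Rs − Rc)/Rc` with bootstrap significance, behavioral d-prime with a
trial-shuffle chance level, onset-corrected reaction-time contrasts, a
Gaussian encoding model scored in cross-validated bits/trial,
Bhattacharyya influence magnitudes, windowed PCA of trial-to-trial
covariance, and spike-count auto/noise correlations.

A built-in simulator (`sim_config()`, `simulate_session()`) generates
two-area sessions with Poisson spiking, low-rank latent co-fluctuations,
and planted silencing-effect geometry (static, or rotating with a
controlled adjacent-window cosine), exporting the ground truth that the
test suite validates every stage against.

## Worked example

```r
library(commdyn)

# a session under the default study conditions: 40 + 35 neurons,
# 97 control trials, 78 silencing trials per window, with go-stimulus
# feedback effects rotating at adjacent-window cosine 0.2 and static
# no-go effects
cfg <- sim_config(effect_mode = c(go = "rotating", nogo = "static"),
                  effect_rotation_cos = c(go = 0.2, nogo = 1),
                  seed = 1)
sim <- simulate_session(cfg)
x <- classify_trials(sim$session)
x
#> <commdyn_session> sim-seed1
#>   neurons: 75 (source=40, target=35)
#>   trials:  721 (control=97, silencing=624)
#>   stimulus 500 ms; silencing 150 ms at onsets 0, 56, 123, 189, 256, 323, 390, 456 ms

behavior_summary(x)
#> # A tibble: 1 × 5
#>    n_go n_nogo hit_rate fa_rate dprime
#>   <int>  <int>    <dbl>   <dbl>  <dbl>
#> 1   361    360    0.753   0.147   1.73

# responsive target neurons, then cross-validated CD similarity per stimulus
tgt <- intersect(select_responsive_neurons(x),
                 x$neurons$neuron_id[x$neurons$area == "target"])
s_go <- communication_similarity(x, "go", gamma = 0.5, neuron_ids = tgt,
                                 n_splits = 100, seed = 2)
lag_profile(s_go)
#> # A tibble: 8 × 4
#>     lag lag_ms similarity n_pairs
#>   <int>  <dbl>      <dbl>   <int>
#> 1     0    0      0.471         8
#> 2     1   65.1    0.0478       14
#> 3     2  130.    -0.00190      12
#> # … lag-0 is split-half reliability; similarity collapses within one
#> #   ~65-ms lag step, as planted

pr <- lag_profile(s_go)
fit_decay(pr$lag_ms, pr$similarity, n_boot = 100, seed = 3)
#> <commdyn_decay> A = 0.4106, tau = 6.514 ms, B = 0.1461 (rss 0.0172, NOT converged/identifiable)
#>   tau 95% CI: [0, 4768] (bootstrap, 100 reps)

# is the go rotation faster than no-go? permutation test on delta tau
permutation_test_tau(x, n_perm = 200, gamma = 0.5, n_splits = 3, seed = 4)
#> <commdyn_permtest> tau_go = 18.3 ms, tau_nogo = 1e+04 ms, delta = -9.98e+03 ms
#>   p = 0.0199 (200 permutations, 0 dropped)
```

The numbers above are from an actual run (seeds as shown). The
interpretation: the animal discriminates well (d′ ≈ 1.7 against a
shuffle chance level near 0.5). Go-trial communication directions are
estimated with split-half reliability ≈ 0.47, and their similarity
collapses essentially within one lag step — the planted fast rotation.
A decay this fast is below the 65-ms lag resolution, so the exponential
fit honestly flags its τ as unidentified (the profile carries the
information, not the fitted constant). The static no-go effects produce
a flat profile (τ at the fitting bound), and the label-permutation test
calls the go/no-go difference significant (p ≈ 0.02). The vignette
discusses when the model-free initial-slope contrast is the more
appropriate statistic than Δτ.

`autoplot()` methods (similarity matrices, decay fits, effect
distributions) and `tidy()`/`glance()` methods on fitted objects support
the usual tidyverse workflow; `run_pipeline(pipeline_config(...))`
executes the whole chain on one session and `write_report()` serializes
it.

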