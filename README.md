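# synkit

Muscle synergy analysis of multi-channel surface EMG recorded during
walking, for motion-analysis researchers who want to quantify how well a
patient's pre-treatment motor control explains their post-treatment or a
typically-developing (TD) child's muscle activity.

## What it computes

A muscle synergy is a pair (weight vector over muscles, activation profile
over the gait cycle). Given an envelope matrix *EMG* (*Nm* muscles ×
*Nc*·*Nt* time-normalised samples), non-negative matrix factorisation finds
*W* (*Nm* × *Nsyn*) and *H* (*Nsyn* × *Nc*·*Nt*) with

&nbsp;&nbsp;&nbsp;&nbsp;*EMG* ≈ *W* · *H*, &nbsp; *W*, *H* ≥ 0.

Fit quality is the variance accounted for,

&nbsp;&nbsp;&nbsp;&nbsp;VAF = (Σ<sub>t</sub>Σ<sub>m</sub> EMG<sup>xp</sup><sub>m,t</sub> · recEMG<sub>m,t</sub>)² / (Σ EMG<sup>xp</sup>² · Σ recEMG²) × 100,

the squared uncentred correlation of the vectorised matrices. The number of
synergies is chosen by a bootstrap: time columns of *EMG* and *H* are
resampled together (500 replicates) and the smallest rank whose 95th VAF
percentile exceeds 90 % is kept.

Pre-treatment synergies are then used to reconstruct other data under two
hypotheses, each a convex non-negative least-squares problem solved to
global optimality:

* **AOA** (activation optimisation): keep *W*<sub>pre</sub> fixed, fit
  non-negative activations to the target.
* **WOA** (weight optimisation): keep the cycle-averaged activation
  profiles fixed, fit non-negative weights.

Derived metrics: GOOD = VAF<sub>PRE</sub> − VAF<sub>POST</sub>,
SPEC = VAF<sub>POST</sub> − VAF<sub>TD</sub>,
IMP = VAF<sub>PRE</sub> − VAF<sub>TD</sub>, plus dW (mean correlation of
optimally matched pre/post weight columns) and dH (mean RMSE of matched,
peak-normalised activation profiles). Generic synergies extracted from
concatenated same-*Nsyn* cohorts give the generic VAF variants.

A seeded synthetic-EMG generator with known ground-truth synergies
(band-limited carrier, amplitude-modulated by *W*·*H* envelopes) makes the
whole pipeline testable end to end.

## Worked example

```r
library(synkit)

cfg <- simulation_config(envelope_noise_sd = 0.05, seed = 42)
gt  <- make_ground_truth(8, 3, seed = 42)       # 8 muscles, 3 synergies
raw <- simulate_raw(simulate_envelope(gt, cfg), cfg)
raw
#> <emg_recording> 8 channels x 12833 samples @ 2000 Hz, 6 heel strikes (5 cycles)

emg <- preprocess_emg(raw)   # 40 Hz HP, rectify, 6 Hz LP, 101-sample strides
emg
#> <gait_cycle_matrix> 8 muscles x (5 cycles x 101 samples), unit-SD scaled

sel <- select_n_synergies(emg, n_boot = 100, seed = 1)
sel
#> <nsyn_selection> n_syn = 3 (criterion met)
fit <- sel$fits[[sel$n_syn]]
glance(fit)
#> # A tibble: 1 × 4
#>   n_syn n_muscles source           fit_vaf
#> 1     3         8 subject-specific    99.7
```

The bootstrap recovers the generative rank (3) and the factorisation
explains 99.7 % of the signal variance. Reconstructing a perturbed
"post-treatment" recording:

```r
post_gt <- perturb_ground_truth(gt, dW_mag = 0.2, dH_mag = 0.2, seed = 43)
cfg2 <- cfg; cfg2$seed <- 44
post <- preprocess_emg(simulate_raw(simulate_envelope(post_gt, cfg2), cfg2))

reconstruct_aoa(fit$W, post, target_label = "post")
#> <synergy_reconstruction> AOA on 'post': VAF 98.6%
reconstruct_woa(fit$H_avg, post, target_label = "post")
#> <synergy_reconstruction> WOA on 'post': VAF 69.3%

refit <- extract_synergies(post, sel$n_syn, seed = 2)
m <- match_synergies(fit$W, refit$W)
delta_w(m)                                     # 0.985
delta_h(fit$H_avg, refit$H_avg, m$pairing)     # 0.199
```

The injected perturbation shifted activation timing much more than muscle
weighting, and the two reconstruction approaches see exactly that: fixed
weights still fit well (AOA 98.6 %), fixed activation profiles do not
(WOA 69.3 %), dW stays near 1 while dH is large. `compute_leg_metrics()`
turns such VAFs into GOOD/SPEC/IMP rows, and `simulate_cohort()` +
`run_cohort()` run the whole study design — eligibility filtering, rank
selection, subject-specific and generic synergies, both reconstructions,
all metrics — over many legs at once, returning a tidy tibble.

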