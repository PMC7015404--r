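---
title: "Muscle synergy extraction and reconstruction: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Muscle synergy extraction and reconstruction: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synkit)
```

## The model

Surface EMG recorded from `Nm` muscles during walking is summarised by its
envelope, segmented into gait cycles (heel strike to ipsilateral heel
strike), time-normalised to `Nt = 101` samples per cycle, concatenated into
an `Nm x (Nc * Nt)` matrix and scaled so every channel has unit standard
deviation. Non-negative matrix factorisation (NNMF) approximates this matrix
as `W %*% H` with non-negative weights `W` (`Nm x Nsyn`) and activations `H`
(`Nsyn x Nc*Nt`), minimising the Frobenius reconstruction error. Each
synergy is a muscle co-activation pattern (column of `W`) driven by one
activation profile over the gait cycle (row of `H`).

Fit quality is the variance accounted for (VAF): the squared uncentred
correlation between the vectorised experimental and reconstructed matrices,
times 100. It is invariant to global positive rescaling of either argument
and bounded in [0, 100] by the Cauchy–Schwarz inequality. Because it is
uncentred, VAF rewards matching the overall activation level as well as its
modulation; values are therefore higher than a centred R² would be, and the
90% selection threshold below must be read on that scale.

Two reconstruction hypotheses transfer pre-treatment synergies to new data.
The activation optimisation approach (AOA) keeps `W_pre` fixed and fits
non-negative activations; the weight optimisation approach (WOA) keeps the
cycle-averaged activation profiles fixed (tiled across the target's cycles)
and fits non-negative weights. Both are separable convex non-negative
least-squares (NNLS) problems — per time sample for AOA, per muscle for
WOA — and are solved exactly with the Lawson–Hanson active-set algorithm
rather than a general-purpose constrained optimiser: the exact solution
dominates any iterative local method, is deterministic, and can be verified
against an exhaustive active-set enumeration oracle, which the test suite
does on small instances.

Derived metrics are plain VAF differences: `GOOD = VAF_PRE - VAF_POST`,
`SPEC = VAF_POST - VAF_TD`, `IMP = VAF_PRE - VAF_TD`, so `SPEC = IMP - GOOD`
holds identically (tests assert it to 1e-12; the two sides are computed by
different floating-point paths). Changes in synergy composition are `d_w`,
the mean Pearson correlation of optimally matched pre/post weight columns,
and `d_h`, the mean RMSE of matched, peak-normalised activation profiles.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `hp_cutoff` | 40 | Hz | removes motion artefact and baseline drift before rectification |
| `lp_cutoff` | 6 | Hz | envelope smoothing; retains burst timing at gait time scales |
| `order` | 6 | – | Butterworth order per pass |
| `n_samples` | 101 | samples/cycle | uniform phase grid, 0 and 100 % of the stride inclusive |
| `n_cycles` | 5 | cycles | eligibility requirement: five complete cycles per condition |
| `n_boot` | 500 | replicates | bootstrap VAF distribution per candidate rank |
| `percentile`, `vaf_threshold` | 95, 90 | %, % | rank accepted when the 95th VAF percentile exceeds 90% |
| `n_restarts` | 10 | – | seeded random NNMF initialisations; best kept |
| `tol`, `max_iter` | 1e-6, 2000 | – | relative objective change / iteration cap per restart |

## Numerical choices

* **NNMF algorithm.** Multiplicative updates (Lee–Seung, Frobenius loss)
  with seeded uniform random initialisation. The objective is
  non-increasing across iterations (asserted on traces in the tests). The
  scale ambiguity between `W` and `H` is left unresolved during fitting;
  comparisons that need a common scale (weight matching, `d_h`) normalise
  explicitly. Synergies are presented ordered by the phase of their peak
  averaged activation so repeated runs list them stably. For noiseless
  exact-recovery checks the tests tighten `tol` to 1e-9 with
  `max_iter = 5000`: near an exact factorisation the multiplicative updates
  approach the optimum slowly, and the default tolerance stops short of the
  accuracy those checks measure.
* **Filtering.** Both Butterworth filters are designed as cascades of
  second-order sections. A 6th-order low-pass at 6 Hz against a 2000 Hz
  sampling rate is numerically fragile in single transfer-function form
  (linearity errors around 1e-5 of signal scale); the biquad cascade is
  well-conditioned at any cutoff. Filters are applied forward–backward
  (zero phase) by default so the envelope is not delayed relative to gait
  events, with odd reflective padding at the ends to suppress edge
  ringing; `zero_phase = FALSE` gives the causal single pass. Demeaning is
  applied per channel over the whole recording, not per cycle. Negative
  values left by low-pass ringing are clipped to zero because NNMF requires
  non-negative input.
* **Stride normalisation.** Linear interpolation onto a uniform phase grid
  with both endpoints included; linear interpolation is monotone and
  therefore preserves non-negativity. Cycles are half-open in time; the
  next heel strike supplies the phase-1.0 sample.
* **Bootstrap semantics.** One set of column indices is drawn per replicate
  and applied to both the data matrix and `H`, with `W` fixed from the
  full-data fit; replicates are *not* refitted. Degenerate resamples (an
  all-zero resampled matrix) are rejected and redrawn. Replicate VAFs are
  computed from per-column sufficient statistics and clamped at 100 to
  absorb floating-point overshoot of the analytic bound. Candidate ranks
  are scanned upward from 1 and scanning stops at the first acceptance;
  if no rank passes, the number of muscles is returned with a warning flag.
* **Synergy matching.** Implemented as the optimal one-to-one assignment
  maximising total Pearson correlation between weight columns — exhaustive
  over permutations, which is exact and cheap for the synergy counts met in
  gait analysis (2–4, capped at 8); a greedy variant is selectable. Weight
  distinctness in the generator and matching in the metrics use *signed*
  correlation: two columns are near-duplicates only if strongly positively
  correlated, and with only two muscles any two weight vectors have
  correlation ±1, so an absolute-value criterion would be unsatisfiable.
* **`d_h` normalisation.** "Normalised to one" is interpreted as peak
  normalisation (maximum = 1); a unit-norm alternative is available via
  `normalize = "norm"`. Undefined quantities (zero-variance weight columns,
  all-zero profiles, all-zero per-muscle rows) propagate as `NA` or raise
  typed errors — never as silent zeros.
* **Reconstruction targets** are unit-SD scaled by their own channel SDs
  before fitting, the same rule applied before extraction, so electrode
  placement differences between sessions do not masquerade as motor-control
  change. For WOA the averaged profile is tiled across all target cycles
  rather than averaging the target, so every cycle informs the fit; VAF is
  computed on the full matrix either way.

## The synthetic-EMG generator

The generator is the package's test bed: every downstream claim is verified
against data whose synergies are known.

* **Ground truth.** Each synergy owns a dominant, mostly disjoint muscle
  group (weights 0.6–1) over a weak background (0–0.08), the module-like
  structure of gait EMG; columns are redrawn until pairwise (signed)
  correlation stays below 0.9. Activation profiles are one or two circular
  Gaussian bursts in gait-cycle phase (SD 4–8 % of the cycle, secondary
  burst at 15–35 % amplitude), peak-normalised, with negligible tails
  truncated to zero and bursts redrawn while their cosine overlap with an
  earlier synergy exceeds 0.2. The truncation and overlap rules keep the
  factorisation essentially unique, so that weight recovery is a
  well-posed check; without them NNMF admits alternative exact
  factorisations that trade background weights against overlapping tails.
* **Envelope.** `W %*% H` tiled over `n_cycles = 5` cycles with per-cycle
  phase jitter (SD 1 % of the cycle) and amplitude jitter (SD 3 %) as
  stride-to-stride variability, plus additive Gaussian noise (SD 5 % of
  the envelope SD by default) truncated at zero; a multiplicative noise
  model is selectable. Amplitudes are O(1) and arbitrary, since the
  pipeline scales channels to unit SD anyway.
* **Raw EMG.** A band-limited Gaussian carrier (20–450 Hz, the standard
  surface-EMG interference-pattern surrogate) normalised to unit mean
  absolute value and amplitude-modulated by the time-upsampled envelope at
  2000 Hz, with seeded cycle durations (mean 1.1 s, CV 3 % — typical
  paediatric self-selected walking) and heel-strike times emitted to match.
  Half a second of periodic continuation pads each end so filter
  transients fall outside the analysed cycles.
* **Post-treatment model.** Weight change mixes each column toward a random
  non-negative direction by fraction `dW_mag`; activation change shifts
  each profile by up to a quarter cycle times `dH_mag` (random direction
  per synergy). Both are monotone in their magnitudes, zero magnitudes are
  an exact identity, and the defaults (0.2 each) are moderate effect sizes
  chosen once as plausible for treatment-scale change — no cohort exists to
  calibrate them against, so they are stated free parameters.
* **TD surrogate.** An independent 5-synergy ground truth, richer than any
  patient's, so the specificity statistic has a true positive signal.

What the generator does *not* emulate: motor-unit physiology, crosstalk
between electrodes, force or kinematics, non-stationary noise, or the
empirical distribution of any clinical cohort. Passing tests therefore
demonstrate that the pipeline's statistics behave correctly under the
model's own assumptions, not that any clinical effect size is reproduced.

## Problem sizes used by tests and the acceptance script

Simulation-based checks use the study geometry (8 muscles, 5 cycles,
101 samples) with 20 seeds per condition, 100 bootstrap replicates and 5
NNMF restarts; the cohort-level script runs 11 legs in three synergy-count
groups with 7 TD datasets. These sizes give stable means while keeping a
full run in minutes; the package defaults (500 replicates, 10 restarts)
remain those of the analysis itself.

## Known limitations

* With cycle-to-cycle phase jitter, the cycle-averaged profile used by WOA
  under-fits each individual cycle, so WOA self-reconstruction can sit a
  few VAF points below the NNMF fit; the gap closes as jitter goes to
  zero and grows with narrow activation bursts.
* The bootstrap criterion inherits the uncentred VAF's optimism: on
  strongly co-activated data a low rank can clear 90% even when more
  structure exists. The diagnostics tibble retains all replicate VAFs so
  the rank decision can be inspected.
* Generic synergies are extracted from members that share a group label,
  not a common ground truth; on heterogeneous synthetic groups their VAF
  can be far below the subject-specific fit, which is the expected
  behaviour of the statistic, not a solver failure.
* `pracma::lsqnonneg` solves each NNLS subproblem; for rank-deficient fixed
  factors the minimiser is non-unique and results are flagged
  (`non_unique = TRUE`) rather than disambiguated.
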