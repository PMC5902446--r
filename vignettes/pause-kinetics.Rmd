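---
title: "Kinetics of the initial-transcription pause from smFRET trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kinetics of the initial-transcription pause from smFRET trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The system and the model

During initial transcription, bacterial RNA polymerase stays anchored to the
promoter and pulls downstream DNA into itself ("scrunching").  A FRET sensor
with a donor on the promoter and an acceptor on downstream DNA reports three
conformations as distinct efficiency levels: the unscrunched open complex
(US, E ≈ 0.49), a partly scrunched paused complex holding a 6-nt RNA
(PS, E ≈ 0.37), and a fully scrunched complex near the end of initiation
(FS, E ≈ 0.80).  Trajectories of E(t) therefore encode the kinetics of
initiation.

scrunchFRET implements both directions of the problem:

* a **generative model** — a continuous-time Markov scheme in which the open
  complex scrunches into the pause (rate `k_entry`), the pause exits with
  rate `k_itc6`, and each pause exit either escapes productively to the
  absorbing FS state with the isotherm probability
  `p(NTP) = P_max * NTP / (NTP + K_ntp)` or unscrunches into a cycling
  subsystem that shuttles between US and PS; and
* an **analysis pipeline** — trace selection, hidden-Markov segmentation with
  an Allan-deviation step filter, dwell-time pooling, multi-exponential
  maximum-likelihood fits with BIC and bootstrap, pathway classification,
  and the NTP escape-isotherm fit.

Because the generator's parameters are known, every analysis stage can be
validated by parameter recovery; that is what the test suite and
`scripts/acceptance.R` do.

### Two hidden substates per cycling observable

Measured US and PS cycling dwell times are two-exponential (fast rate `k1`,
slow rate `k2`, fast-branch probability `P_k1`).  The minimal memory-less
mechanism producing this is two hidden substates per observable, entered
independently at each visit with probability `P_k1` / `1 - P_k1`.  Because
the substate is re-drawn at every entry, successive dwell times are
uncorrelated, which `dwellMemoryTest()` verifies on simulated paths.  The
microscopic identity of the substates is deliberately left open; the scheme
is the simplest one consistent with the observable statistics.

### The first pause vs cycling PS dwells

The first PS dwell of a trajectory is the initial-transcription pause with
single-exponential exit `k_itc6`; later PS dwells belong to the cycling
subsystem with the two-exponential law.  The analysis treats them
accordingly: `pauseExitRate()` pools the pause dwell of single-scrunch
trajectories, while the cycling PS pool (`extractDwells(...,
skip_first_visit = TRUE)`) excludes each trace's first PS visit.  Whether a
re-entered pause shares `k_itc6` is not observable in this design; the
model re-enters cycling PS states with `k1`/`k2` kinetics and exposes
`k_itc6` only on the first pause.

## Generator defaults (the simulated experiment)

| parameter | default | unit | meaning |
|---|---|---|---|
| `k_itc6` | 0.11 | s⁻¹ | initial pause exit rate |
| `K_ntp` | 28 | µM | half-saturation of productive escape |
| `P_max` | 0.79 | — | saturating escape probability |
| `k1`, `k2` | 0.15, 0.02 | s⁻¹ | fast/slow cycling exit rates |
| `P_k1` | 0.6 | — | probability of the fast substate |
| `k_entry` | 0.2 | s⁻¹ | scrunching rate after NTP addition |
| frame time | 0.2 | s | ALEX acquisition (0.08 s selectable) |
| record length | 600 | s | 10-minute movies |
| total intensity | 1000 | a.u. | I_DD + I_DA while both dyes live |
| channel noise SD | 70 | a.u. | gives per-frame E SD ≈ 0.05 |
| bleach rate per dye | 0.001 | s⁻¹ | bleach-limited windows of a few hundred s |

`k_entry` and the bleaching rates are not constrained by dwell statistics in
the modeled experiments; they are set to values typical of surface-immobilized
two-color FRET measurements (a few seconds to scrunch after NTP arrival;
several-hundred-second photobleaching-limited observation windows).

The NTP-withdrawal generator (`buildWithdrawalScheme()`) mixes two cycling
subpopulations — US/PS-only (`k1 = 0.16`, `k2 = 0.02`, `P = 0.57`) and
US/PS/FS (`k1 = 0.96`, `k2 = 0.07`, `P = 0.79`) — with observable-level
branching fractions (US→FS 0.82, PS→US 0.93, FS→US 0.93) chosen analytically
so that stationary transition counts give US↔FS about four-fold more frequent
than US↔PS with PS↔FS rare.

### What the generator does and does not emulate

Emulated: three calibrated FRET levels, Gaussian per-channel detector noise,
ALEX framing by majority occupancy (events shorter than half a frame are
invisible by construction — the detection floor), single-step donor and
acceptor photobleaching, NTP-dependent pathway branching, and memory-less
cycling.

Not emulated: dye blinking kinetics, spectral cross-talk and gamma
correction, diffusion/drift of the focal plane, multi-step or correlated
photophysics, abortive-RNA chemistry, and any non-exponential microscopic
substructure.  Passing recovery tests on these simulations therefore shows
the *analysis* is unbiased under the stated noise model; it does not certify
behavior under photophysics the generator omits.

## Analysis choices

**Trace selection.** The published workflow sorted traces manually; here the
policy is automated: change-point step counting (binary segmentation on mean
shifts) on I_AA and on I_DD + I_DA enforces a single acceptor presence and at
most a single-step donor bleach, a bounded blink count, and a
relative-brightness cut (initial intensity > 1.5× the cohort median in
either channel rejects multi-dye spots, which need not show a second bleach
step inside a bleach-limited record).  The analysis window runs from the
start of the record to the first bleach event.

**Segmentation.** A Gaussian-emission HMM is fit by maximum-likelihood EM
with pooled (ensemble) parameters across traces, the state count chosen by
BIC between 2 and `max_states`, and traces decoded by Viterbi.  This
replaces the empirical-Bayes variational scheme of ebFRET-style software:
what the downstream analysis consumes is only the state sequence plus the
published post-filter, and ML-EM with BIC is reproducible without
re-implementing variational hyperpriors.  Initialization is deterministic
(data quantiles, an even grid, and seeded k-means centers; each init gets a
short warm run and the best continues to convergence), so repeated runs are
identical.  The pipeline default `max_states = 4` deserves a note: E is a
ratio of noisy intensities, so its noise is skewed at high E and a 3-state
Gaussian HMM can prefer splitting the FS peak over separating the nearby
PS/US peaks.  Allowing a fourth state lets FS absorb two Gaussians; the
fitted state means are then grouped into the three physical levels by cutting
at the two largest gaps.

**Step filter.** Only steps longer than `min_len = 2` frames and separated
from their neighbor by more than twice the Allan deviation at five frames
are conserved: shorter segments are absorbed into the nearer-in-level
neighbor and close-in-level neighbors are merged (duration-weighted mean),
iteratively to a fixed point, shortest segment first with ties to the
earliest.  The filter is idempotent and conserves total duration exactly.
The Allan deviation is estimated on the longest constant-level stretch of
the raw segmentation; estimating it across genuine level steps would inflate
the threshold past the PS–US separation and erase real transitions.

**Level calibration.** Segments are clustered on their mean E (seeded by the
grouped HMM state means) and each level's Gaussian is fit by least squares
to the histogram of the per-frame E values of its segments, so the reported
peak SD reflects frame noise.  That SD matters: `mapStates()` labels each
segment by the nearest center and declares segments farther than
`tol_sd = 3` SDs from every center unassigned; a peak SD narrower than the
frame noise would reject ordinary short segments and silently merge their
neighbors.  Exact ties break deterministically to the lower level and are
flagged.  E is never clipped to [0, 1]: clipping would bias the Gaussian
fits.

**Dwell pooling and censoring.** The first dwell of each trace (pre-NTP
baseline) and the last (cut off by bleaching or by reaching the absorbing FS
level) are dropped from the pooled distributions.  Interior-only pooling is
length-biased — long dwells are more likely to be cut off — so the pipeline
additionally passes each trace's final dwell as right-censored and includes
survival terms in the likelihood (`censor_last = TRUE`); `fitExpMixture()`
itself defaults to excluding censored dwells, since the plain mixture
likelihood carries no censoring term.

**Detection-floor truncation.** Segmented data cannot contain dwells at or
below the filter minimum, and detection of 3–8-frame dwells is
noise-limited.  Dwell fits from segmented paths therefore use a
left-truncated likelihood, conditioning on `tau > t_min` with `t_min` one
frame above the filter minimum (0.6 s at 200-ms frames).  Fitting without
the truncation biases the fast rate low by roughly 15–30% at the default
noise level.

**Mixture MLE.** The m-exponential density `sum_n p_n k_n exp(-k_n tau)` is
maximized in log-rate / softmax-weight space by L-BFGS-B with 20 restarts
(quantile-spread initialization around 1/mean, then random log-spread),
rates bounded to [1e-4, 1e3] s⁻¹ (frame time and record length bound what is
observable), components reported sorted by descending rate.  m = 1 uses the
closed form.  BIC is `-2 L + (2m - 1) log N`, ties to the smaller m, and
orders whose sample-size guard `N >= 5 (2m - 1)` fails are skipped (the
guard applies to m ≥ 2; the m = 1 closed form is defined for any N).
Bootstrap SDs come from 1000 nonparametric resamples refit with warm starts
and components matched by rate order.

**Classification and escape probabilities.** Deterministic rules on the
filtered label sequence partition trajectories into
single-scrunch (with/without a detectable pause), cycling-then-FS,
cycling-only and inactive; "single attempt" includes trajectories whose
pause is below the detection floor.  The outcome of the *first* attempt is
tracked separately (success / failure / unresolved) so that traces bleaching
during their first pause do not deflate the escape probability.  For the
isotherm the pipeline uses `escapeFraction()`: in the branching model every
detected PS exit is an independent Bernoulli(p(NTP)) trial, so pooling
PS→FS versus PS→US transition counts estimates p(NTP) with many more events
per condition and is far less sensitive to returns hidden below the
detection floor than per-trace first-attempt counting (which those misses
bias upward).  Both estimators are reported per condition.

**Isotherm fit.** Weighted least squares of `P_max * x / (x + K)` with
inverse squared CI half-widths as default weights, bounds `0 <= P_max <= 1`,
`K > 0`; at least four distinct concentrations are required and an
all-saturated design is rejected as unidentifiable.  A caution on precision:
at a 6-concentration design of {1, 5, 10, 30, 80, 500} µM with 100 molecules
per condition, the Fisher information for K = 28 µM bounds any unbiased
estimator's SD at about 5.4 µM, so single replicates of that size scatter
around ±20% of K — a property of the design, not of the fitting code.

**k_ITC6 summary.** Pause exit is NTP-independent, so the pipeline reports
both the pooled single-exponential fit and a precision-weighted
(inverse-bootstrap-variance) mean of per-condition fits; the weighting
matters because low-NTP conditions contribute few single-scrunch
trajectories, and the ones they do contribute are enriched for undetected
cycling.

## Numerical and reproducibility choices

* One root seed per run; per-stage substreams are derived deterministically
  so stages can be re-run independently (`runConfig()$seed` is echoed in all
  outputs).  Simulators and fitters save and restore the caller's RNG state.
* EM convergence: relative log-likelihood change below 1e-6; hitting the
  iteration cap raises an error carrying the log-likelihood trajectory.
* State-mean ties in decoding collapse into one segment; emission SDs are
  floored at 1e-3 to keep noiseless data finite.
* Segment intervals are half-open `[start, start + n)` with 0-based frames.

The test suite and the acceptance script run the full pipeline at 6 NTP
concentrations × 150 traces × 600 s (the scale of the modeled experiments);
property checks use 10⁴-event simulations, 200-replicate isotherm studies
and 100-replicate BIC studies.

## Known limitations

* Events shorter than about three frames are invisible; dwell fits correct
  for this by truncation, but merged dwells caused by an *undetected*
  intervening visit remain in the pooled distributions and leave residual
  biases of order 5–15% on the fast cycling rate at per-frame E SD 0.05.
* The Gaussian emission model ignores the skew of ratio noise; it is
  absorbed by allowing an extra HMM state rather than modeled.
* Censored-likelihood support exists for right censoring only; interval
  censoring from frame discretization is handled by the truncation floor,
  not modeled exactly.
* The classification-based first-attempt probability is biased upward when
  short returns are missed; use the transition-pooled escape fraction for
  quantitative isotherm work.
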