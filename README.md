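# scrunchFRET

Kinetic analysis of bacterial transcription initiation from single-molecule
FRET trajectories — and a generative simulator of the underlying branching
kinetic model, so that every stage of the analysis can be validated by
parameter recovery.

## The problem

During initial transcription, RNA polymerase stays bound to the promoter and
"scrunches" downstream DNA into itself. A donor/acceptor FRET pair on the
promoter and downstream DNA reports three conformations as distinct
efficiency levels: the unscrunched open complex (**US**, E ≈ 0.49), the
partly scrunched paused complex holding a 6-nt RNA (**PS**, E ≈ 0.37), and
the fully scrunched complex near the end of initiation (**FS**, E ≈ 0.80).
From per-molecule intensity trajectories (I_DD, I_DA, I_AA with alternating
laser excitation), the package extracts:

* FRET efficiency `E = I_DA / (I_DA + I_DD)` with automated single-pair
  trace selection,
* piecewise-constant FRET states via a Gaussian-emission hidden Markov
  model, post-filtered so that only steps longer than two frames and
  separated by more than twice the Allan deviation at five frames survive,
* pooled state dwell times fit by m-exponential maximum likelihood,

  `p(τ) = Σₙ pₙ kₙ exp(−kₙ τ)`,  `L = Σᵢ ln p(τᵢ)`,

  with the number of exponentials chosen by BIC = −2L + (2m−1) ln N and
  1 SD errors from 1000 bootstrap resamples,
* the exit rate `k_ITC6` of the initial-transcription pause
  (single-exponential, from single-scrunch trajectories),
* the NTP-dependent probability of productive pause escape, fit to the
  isotherm `p(NTP) = P_max,esc · [NTP] / ([NTP] + K_NTP)`,
* pathway classification (single-scrunch vs unscrunching/scrunching
  cycling), consecutive-dwell transition histograms, and a permutation test
  for dwell-time memory.

The simulator (`buildDefaultScheme()`, `gillespieSimulate()`,
`renderTrace()`) generates continuous-time Markov paths of the branching
model — pause exit branching between productive escape and two-timescale
US/PS cycling (`k1`, `k2`, `P(k1)` via hidden fast/slow substates) — and
renders them into noisy three-channel traces with photobleaching, so ground
truth is always available. `buildWithdrawalScheme()` emulates
NTP-withdrawal experiments with their US/PS-only and US/PS/FS cycling
subpopulations.

Intended users: single-molecule biophysicists analyzing smFRET trajectories
of transcription (or any three-state level-switching system), and method
developers who need a fully seeded, ground-truthed benchmark for dwell-time
pipelines.

## Worked example

Simulate one condition of the modeled experiment (80 µM NTP, 60 molecules,
600 s records) and run the full pipeline:

```r
library(scrunchFRET)

scheme <- buildDefaultScheme(k_itc6 = 0.11, K_ntp = 28, P_max = 0.79,
                             k1 = 0.15, k2 = 0.02, P_k1 = 0.6, ntp = 80)
scheme
#> KineticScheme: 7 states (1 absorbing), 14 transitions
#>   observables: US (E=0.49), PS (E=0.37), FS (E=0.80)
#>   escape isotherm: P_max=0.79, K_NTP=28 uM, [NTP]=80 uM

em     <- emissionParams()                       # 200 ms frames, E SD ~ 0.05
paths  <- gillespieSimulate(scheme, duration = 600, n_traces = 60, seed = 7,
                            injectionTime = 20)
traces <- lapply(seq_along(paths), function(i)
  renderTrace(paths[[i]], em, seed = 100 + i, meta = list(ntp = 80)))

report <- runPipeline(traces, runConfig(seed = 7, B = 200))

report$levels
#>   label    center         sd    se_center
#> 1    PS 0.3693789 0.05116137 0.0006197536
#> 2    US 0.4907416 0.04940813 0.0004769521
#> 3    FS 0.7983553 0.05729484 0.0004859656

report$conditions[, c("ntp", "n_traces", "p_first", "p_escape", "n_exits")]
#>   ntp n_traces   p_first  p_escape n_exits
#> 1  80       60 0.5892857 0.5604396      91

report$pause$fit
#> ExpMixtureFit: m=1, N=31, logLik=-97.66, BIC=198.75
#>   k1 = 0.1165 s^-1 (SD 0.0183), p1 = 1.000 (SD 0)

table(report$classes$class)
#>              cycling_only           cycling_then_FS
#>                         4                        19
#>                  inactive   single_scrunch_no_pause
#>                         4                         1
#> single_scrunch_with_pause
#>                        32
```

Reading the output: the calibrated FRET levels land on the generator's
0.37/0.49/0.80 with peak widths equal to the frame noise; the pause exit
rate (0.117 ± 0.018 s⁻¹ from 31 pause dwells) recovers the generator's
`k_itc6 = 0.11`; and the escape fraction at 80 µM (0.56 from 91 pooled PS
exits) matches the isotherm value `0.79 × 80 / 108 = 0.585`. With traces
from four or more NTP concentrations, `report$isotherm` additionally
contains the fitted `K_NTP` and `P_max,esc`.

Small deterministic demonstration data sets (productive-dominated,
cycling-heavy, NTP-withdrawal, and artifact-doped bundles with ground-truth
sidecars) are written by `makeFixtures(seed, dir)`; traces, state paths and
schemes round-trip through plain CSV/JSON via `writeTraces()`/
`readTraces()`, `writePaths()`/`readPaths()` and `writeScheme()`/
`readScheme()`.

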