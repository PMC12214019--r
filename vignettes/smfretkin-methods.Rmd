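---
title: "Models and methods behind smfretkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind smfretkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`smfretkin` simulates and analyzes single-molecule FRET (smFRET)
experiments on single-stranded DNA-binding proteins — bacterial SSB and
eukaryotic RPA — covering four mechanisms: direct strand transfer to a
competing nucleic acid through a ternary intermediate, homotypic protein
exchange (facilitated dissociation), stepwise hetero-protein exchange,
and DNA/RNA binding competition. Because this class of experiment
publishes rate constants and dwell times rather than raw movies, the
package is built as a closed loop: a generative simulator whose ground
truth is configurable, and an analysis pipeline that must recover that
truth through the same reduction steps an experimentalist would use
(FRET histograms, Gaussian decompositions, exponential decays, linear
titration fits, event detection, spot counting).

# Kinetic model

Each mechanism is a labelled continuous-time Markov chain
(`kinetic_scheme`): a generator matrix `Q` plus, per state, a FRET
efficiency, a donor-dye count and an acceptor-present flag. Solution
species are in large excess over tethered molecules, so all bimolecular
steps are pseudo-first-order: an association constant `k_on`
(M^-1 s^-1) enters `Q` as `k_on * c`. Competitor depletion and rebinding
of departed complexes are ignored (the regenerated tethered substrate is
a stable endpoint), and intrinsic dissociation defaults to zero because
bound complexes persist for hours without competitor.

## Strand transfer

The transfer scheme is `Bound -> Ternary -> {Bound, FreeDNA}`. Attempts
arrive at `k_on * c`; a ternary visit lasts `1/(k_fail + k_succ)` and
succeeds with probability `p = k_succ / (k_fail + k_succ)`, so the
number of attempts is geometric and the effective pseudo-first-order
rate is

```
k_obs = k_on * c * k_succ / (k_succ + k_fail)
```

(`effective_kobs()`, valid when resolution is fast compared to attempt
arrival; the exact relaxation rate is the slow eigenvalue of `Q`, about
1% below the reduction at the rates used here, and the test suite checks
against the eigenvalue where four-figure accuracy is asserted).

The published observables constrain only the product `k_on * p` (the
measured bimolecular constant) and the ~0.3 s mean resolution time, not
`k_fail` and `k_succ` separately. The presets therefore fix `p = 0.1` —
of order ten failed attempts per transfer, matching the spike-rich
real-time traces — and set `k_on = k_bi / p`. This under-determination
is deliberate and documented rather than hidden.

## Dwell-time substructure

Measured binding-to-transfer dwell histograms are bell-shaped and are
summarized by Gaussian fits. A memoryless (single-exponential) ternary
lifetime cannot produce that shape — its histogram is monotone
decreasing — so the real resolution process must traverse several
sub-steps. The dwell presets model the ternary lifetime as an Erlang
distribution with shape 12 (twelve sequential sub-states of equal rate;
mean 0.31 s for SSB, 0.27 s for RPA, CV 0.29). Shape 12 was chosen once,
for approximate symmetry consistent with the published histograms, and
not revisited. Two consequences are worth knowing:

* a least-squares Gaussian fitted to binned Erlang-12 samples sits about
  4% below the true mean (the distribution retains skew 0.58); the
  pipeline reports the sample mean and an exponential-rate summary next
  to the Gaussian mean so this is visible;
* `build_transfer_scheme(n_sub = 1)` recovers the memoryless scheme used
  everywhere else (titration recoveries, attempt statistics, occupancy
  oracles).

The dwell presets use a 20 nM labeled competitor rather than the 3 nM of
the corresponding real-time experiments: the dwell distribution is
independent of concentration (which only sets attempt frequency), and
3 nM would require hour-long synthetic traces per event.

## Exchange, hetero-exchange, competition

Homotypic exchange reuses the ternary topology with states
`LabeledBound -> Ternary -> UnlabeledBound`; the absorbing state carries
zero donors, so the fluorescent spot disappears on exchange. A preset
fraction of complexes never exchanges, producing the measured residual
plateaus (90/60% for SSB on dT70/dT40, 80/75% for RPA on dT40/dT70).
Hetero-exchange is a linear ladder of one or two irreversible steps with
its own FRET level per rung; per-step rates are package presets because
only the qualitative one-/two-step behavior and single-exponential dwell
distributions are published. Competition folds the active displacement
routes into one effective association; the DNA-substrate scheme sets the
RNA-competitor displacement constant to zero, encoding the observation
that even 10 uM RNA leaves DNA-bound protein untouched.

# Synthetic data

`gillespie_simulate()` draws statistically exact paths (exponential
sojourns, categorical jumps); `gillespie_ensemble()` is a vectorized
multi-path variant used for 10^4–10^5-path property checks. Both are
checked against the matrix-exponential master-equation solution
(`analytic_occupancy()`).

`synthesize_trace()` renders a path into 50 ms camera frames. Per green
frame, expected donor counts are
`n_donors * total * (1 - E) * survival + background (+ flow step)` and
acceptor counts `n_donors * total * E + leakage * donor + background`;
during ternary occupancy with a labeled competitor `n_donors = 2`, which
doubles the acceptor signal — the intensity boost that marks competitor
binding in real-time traces. Red frames report direct acceptor
excitation (for donor-only exclusion), dark frames background only, in
10 green / 1 dark / 10 red ALEX cycles. State changes and photobleaching
cut-offs mid-frame are time-weighted within the frame, mimicking camera
integration. Noise is Poisson shot noise plus Gaussian read noise,
clipped at zero.

The acquisition conditions publish no count levels, leakage magnitude or
noise figures. Defaults — 1000 counts/frame per dye pair, read noise sd
15, leakage 0.08, backgrounds 50, flow step 120, per-molecule static
FRET offset sd 0.04 — are assumptions chosen once to give histogram peak
widths (FWHM ~0.1) comparable to published population histograms. They
are parameters of `optics_model()`, not constants. A green test
therefore establishes that the pipeline recovers truth *under this noise
model*; it says nothing about artifacts the generator does not emulate
(spectral crosstalk beyond one leakage term, diffusing-spot backgrounds,
stage drift, non-Poissonian camera noise).

Field-of-view series for the spot-count assay place spots uniformly with
a minimum separation, render Gaussian PSFs (sigma 1.3 px, peak 800
counts over background 100) and remove each spot at its first-passage
time sampled from the exchange scheme; a residual fraction never
exchanges.

# Analysis pipeline

* `compute_fret()`: per green frame, `I_A' = I_A - l * I_D` (floored at
  0), `E = I_A' / (I_D + I_A')` clamped to [0, 1]; frames below 20% of
  the nominal total intensity are flagged invalid (bleached/dark).
* `estimate_leakage()`: median of `(I_A - bg_A) / (I_D - bg_D)` over
  donor-only traces, with channel backgrounds taken from the ALEX dark
  frames; exact on noise-free input.
* `exclude_donor_only()`: a molecule is donor-only iff its mean
  red-frame acceptor signal is within 3 sd of the red background.
* `build_histogram()`: first 21 valid frames per molecule, bin width
  0.025 over [-0.05, 1.05], unit area. The bin width resolves peaks 0.1
  apart; the published work does not state its binning.
* `fit_gaussian_mixture()`: bounded least squares on the binned density
  with K and initial means fixed per experiment preset. Component means
  are constrained to ±0.08 of their initial (calibrated) positions, and
  an optional shared component width is available; both matter when
  bound and free levels are closer than the peak width (RPA on dT70),
  where unconstrained components trade population freely. Components are
  reported sorted by mean.
* `bound_fraction()`: summed weight of bound components, assigned by
  *proximity* to the configured bound level — never "high FRET", since
  RPA-bound DNA lies below the free-DNA level. When the free level is
  supplied each component goes to the nearest level, which is the only
  well-defined rule when the levels are closer than any fixed window.
  Whether the published bound fractions came from Gaussian areas or
  threshold counts is not stated; Gaussian areas are primary here and a
  threshold alternative (`method = "threshold"`) is kept for sensitivity
  checks.
* `fit_exponential_decay()`: `A e^{-kt} + c` by weighted `nls` (port),
  plateau optional; near-constant input returns a flagged degenerate fit
  instead of an error. `fit_bimolecular()`: weighted linear regression
  of `k_obs` on concentration with free intercept (a through-origin
  slope is reported alongside).
* `fit_exponential_mle()`: censoring-aware exponential rate
  (`events / total observation time`); horizons comparable to `1/k` bias
  the naive uncensored mean by >2x, which the tests pin down.
* `detect_events()`: on green-frame total intensity, attempts are
  excursions above `baseline + 4 robust sd`; the successful transfer is
  the excursion followed, without return to baseline, by the FRET
  efficiency settling at the free level for 4 consecutive frames (0.2 s).
  The baseline is the post-flow median — the flow background step makes a
  pre-flow baseline systematically wrong, which is a deliberate deviation
  from the obvious choice. Event times are localized to sub-frame
  precision by intensity interpolation: the boundary frame's excess over
  baseline is proportional to the time spent elevated. Against generator
  truth this removes a ~0.7-frame systematic of frame-start timestamps.
* `measure_dwell_times()`: histogram (bin 0.05 s) fitted with one
  Gaussian, mirroring the published summary; sample mean and exponential
  rate reported alongside (see the Erlang-bias note above). Fewer than
  20 events: raw dwell times with the fit flagged unavailable.
* `detect_spots()` / `count_series()`: local-mean background subtraction
  (radius 5 PSF sigma), PSF-scale smoothing, 8-neighbor local maxima
  above 5 robust sd, merge within 3 px keeping the brighter peak.
  Optional photobleaching correction against a no-exchange control
  series is off by default, matching the short-movie acquisition that
  minimizes bleaching.

# Numerical and design choices

* Seeds: `derive_seed()` implements MINSTD-style modular streams; every
  molecule/target/condition gets an independent, order-independent
  stream, and all results are reproducible from one master seed.
* Horizons: transfer/exchange recoveries observe for `min(2.5/k, 3600)` s
  (or `4.5/k` for spot decays) — the experimenter's choice of imaging
  long enough to see the decay. Censored molecules are handled by the
  MLE estimator where first-passage times are fitted directly.
* Degenerate inputs: all-zero-outflow states simply end paths at the
  horizon; saturated images are flagged; corrupt trace-CSV rows are
  skipped with a counted warning; over-parameterized mixtures (3K
  parameters vs non-empty bins) are refused.
* Units: configs accept concentrations in nM (the units experiment
  tables use) and convert to molar internally; all rates are reported in
  s^-1 and M^-1 s^-1, dwell times in seconds, exchange fractions as
  fractions (percent only in the acceptance report).
* The stated-world FRET level for RPA-bound dT70 (0.05, vs 0.2 for bare
  dT70) is a package choice: the value is not published, and the two
  populations must be resolvable for the histogram workflow to exist, as
  they visibly are in the published assays.

# Known limitations

* Dwell-time Gaussian means inherit the ~4% skew bias described above;
  use `sample_mean`/`exp_rate` for unbiased location summaries.
* The simulator omits spatial effects entirely (no diffusion along the
  strand, no binding-mode transitions, no sequence dependence); length
  and salt dependences enter only through preset rates and FRET levels.
* Spot counting does no sub-pixel localization or tracking; it is a
  counting assay, and the recall/precision tests hold only at the
  default SNR preset.
* `cli_simulate`/`cli_analyze` cover trace-based experiments; the
  image-based exchange assay is exposed through `recover` and the R API.
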