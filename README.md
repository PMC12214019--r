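# smfretkin

Simulation and kinetic analysis of single-molecule FRET (smFRET)
experiments on single-stranded DNA-binding proteins.

## The problem

Bacterial SSB and eukaryotic RPA bind single-stranded DNA with
sub-nanomolar affinity, yet inside cells they relocate in seconds. Two
mechanisms explain the paradox, and both are measured by smFRET on
surface-tethered substrates:

* **Direct strand transfer** — a bound protein moves to a competing
  strand through a transient *ternary intermediate* in which it contacts
  both strands at once, without ever becoming free protein. The observed
  decay rate of the bound population grows linearly with competitor
  concentration (pseudo-first-order kinetics); the slope is the
  bimolecular transfer constant `k_bi` (M⁻¹ s⁻¹).
* **Facilitated dissociation / protein exchange** — a solution-phase
  protein replaces the incumbent, seen as the concentration-dependent
  disappearance of labeled-protein spots from a field of view.

The quantities such experiments publish are `k_obs` per concentration,
`k_bi`, residual exchange fractions, and binding-to-transfer dwell times
(Δt ~ 0.3 s). Raw movies are rarely deposited, so `smfretkin` validates
its analysis pipeline by *closed-loop recovery*: simulate an experiment
whose mechanism and rates are known exactly, push the synthetic camera
frames through the full analysis, and compare the recovered constants
with the configured truth.

## What is in the package

* **Kinetic schemes** (`build_transfer_scheme`, `build_exchange_scheme`,
  `build_hetero_scheme`, `build_competition_scheme`): labelled CTMCs with
  per-state FRET levels and dye bookkeeping; exact stochastic sampling
  (`gillespie_simulate`, `gillespie_ensemble`) and a master-equation
  oracle (`analytic_occupancy`).
* **Trace synthesis** (`synthesize_trace`, `synthesize_ensemble`,
  `synthesize_snapshots`, `synthesize_fov_series`): 50 ms camera frames
  with ALEX excitation (10 green / 1 dark / 10 red), donor leakage, shot
  and read noise, photobleaching, flow background steps and the
  two-donor acceptor boost of labeled-competitor ternary intermediates;
  plus field-of-view image series for the spot assay.
* **FRET pipeline** (`compute_fret`, `estimate_leakage`,
  `exclude_donor_only`, `build_histogram`, `fit_gaussian_mixture`,
  `bound_fraction`): leakage-corrected efficiencies, donor-only
  screening via red-excitation frames, unit-area population histograms
  and constrained multi-Gaussian decomposition.
* **Kinetics inference** (`fit_exponential_decay`, `fit_bimolecular`,
  `fit_exponential_mle`, `detect_events`, `measure_dwell_times`,
  `synchronize_traces`, `fit_spot_decay`, `hetero_exchange_analysis`).
* **Spot counting** (`detect_spots`, `count_series`).
* **Presets and harnesses** (`smfret_presets`, `recover_*`): one preset
  per measured condition with the published constant as ground truth.
* **CLI** (`smfretkin_main`): `simulate`, `analyze`, `recover`,
  `make-fixtures` subcommands with JSON configs and deterministic
  outputs.

## Worked example

Recover the SSB dT70→dT60 transfer constant (truth 6.1×10⁴ M⁻¹ s⁻¹)
through the full histogram pipeline — 150 molecules per concentration,
short-movie snapshots, two-Gaussian decomposition, exponential decays,
linear titration fit:

```r
library(smfretkin)
r <- recover_transfer_kbi("ssb_dT70_to_dT60", seed = 1, n_molecules = 150)
print(r$bimolecular)
#> <bimolecular_fit> k_bi = 5.789e+04 M^-1 s^-1 (se 1.8e+03), intercept = 4.9e-05 s^-1, R^2 = 0.9971
r$per_conc
#>      conc        k_obs           sd
#> 1 1.0e-08 0.0006341804 2.370238e-05
#> 2 2.5e-08 0.0014910578 3.808558e-05
#> 3 5.0e-08 0.0029146379 9.354334e-05
#> 4 7.5e-08 0.0041575906 1.013294e-04
#> 5 1.0e-07 0.0060917415 1.170294e-04
```

The recovered slope is 5.8×10⁴ M⁻¹ s⁻¹, 5.1% from the configured truth,
with the intercept statistically indistinguishable from zero — the
signature of pure pseudo-first-order transfer.

Real-time dwell times (truth: mean binding→transfer interval 0.31 s,
~10 attempts per success) from 220 labeled-competitor traces:

```r
d <- recover_dwell("ssb_dwell", seed = 5, n_traces = 220)
print(d$dwells)
#> <dwell_time_set> n = 206, gaussian mean = 0.313 s (sd 0.0969), sample mean = 0.326 s
round(d$mean_failed_attempts, 1)
#> [1] 7.2
```

From the command line:

```sh
Rscript -e 'smfretkin::smfretkin_main()' recover \
    --preset ssb_exchange_dT70 --seed 1 --out report.json
```

## Reproducibility

Every source of randomness derives from one master seed through
per-molecule/per-target streams (`derive_seed`), so ensembles are
reproducible and order-independent; `cli_simulate` outputs are
byte-identical across runs of the same config. See the methods vignette
(`vignettes/smfretkin-methods.Rmd`) for the model assumptions, noise
defaults, estimator choices and known limitations.
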